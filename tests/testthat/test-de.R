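two_group <- factor(c("wt", "wt", "mut", "mut"), levels = c("wt", "mut"))

test_that("TMM factors: symmetry, scale invariance, unit product", {
  set.seed(1)
  base <- matrix(rnbinom(5000 * 2, mu = rlnorm(5000, log(20), 1.5), size = 5),
                 ncol = 2, dimnames = list(paste0("g", 1:5000), c("s1", "s2")))
  same <- cbind(s1 = base[, 1], s2 = base[, 1])
  expect_equal(unname(tmm_factors(count_matrix(same))), c(1, 1))
  ## doubling a library changes depth, not composition
  doubled <- cbind(s1 = base[, 1], s2 = 2L * base[, 1])
  expect_equal(unname(tmm_factors(count_matrix(doubled))), c(1, 1),
               tolerance = 1e-8)
  set.seed(2)
  m <- matrix(rnbinom(4000 * 4, mu = rlnorm(4000, log(10), 1), size = 5),
              ncol = 4, dimnames = list(paste0("g", 1:4000), paste0("s", 1:4)))
  f <- tmm_factors(count_matrix(m))
  expect_equal(prod(f), 1, tolerance = 1e-12)
  expect_error(tmm_factors(count_matrix(m[, 1, drop = FALSE])), "2 samples")
})

test_that("TMM hand check: one inflated gene is trimmed, its depth cost corrected", {
  ## s2 = 2 x s1 for 19 genes; g20 is additionally 10-fold up and inflates
  ## s2's library (N1 = 19500, N2 = 48000). Every kept gene then shares
  ## M = log2(2 * 19500 / 48000); g20 (top M rank) falls inside the 30%
  ## trim, so the factor ratio is exactly 2^M = 39000/48000 = 0.8125 --
  ## TMM charging the composition bias back to s2.
  s1 <- c(seq(100, 1900, by = 100), 500)
  s2 <- 2 * s1; s2[20] <- s2[20] * 10
  m <- matrix(c(s1, s2), ncol = 2,
              dimnames = list(paste0("g", 1:20), c("s1", "s2")))
  f <- tmm_factors(count_matrix(m), ref_sample = "s1")
  expect_equal(unname(f[2] / f[1]), 39000 / 48000, tolerance = 1e-8)
})

test_that("TMM agrees with the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(44)
  m <- matrix(rnbinom(5000 * 4, mu = rlnorm(5000, log(20), 1.5), size = 5),
              ncol = 4, dimnames = list(paste0("g", 1:5000), paste0("s", 1:4)))
  m[1:500, 4] <- m[1:500, 4] * 8L
  expect_equal(unname(tmm_factors(count_matrix(m))),
               unname(edgeR::calcNormFactors(m, method = "TMM")),
               tolerance = 0.005)
})

test_that("common dispersion recovers the simulated truth", {
  grp <- two_group
  cfg_pois <- simulation_config(seed = 5, n_background_genes = 2000, bcv = 0,
                                background_lfc_sd = 0)
  pois <- simulate_counts(NULL, cfg_pois)
  expect_lte(estimate_common_dispersion(pois$counts, grp), 0.01)
  cfg_nb <- simulation_config(seed = 11, n_background_genes = 2000, bcv = 0.4,
                              background_lfc_sd = 0)
  nb <- simulate_counts(NULL, cfg_nb)
  est <- estimate_common_dispersion(nb$counts, grp)
  expect_gte(est, 0.12)
  expect_lte(est, 0.20)
  ## single replicate per group: estimation impossible
  one <- count_matrix(nb$counts$counts[, c(1, 3)])
  expect_error(estimate_common_dispersion(one, c("wt", "mut")), "fixed-BCV")
})

test_that("tagwise shrinkage interpolates between own MLE and common value", {
  set.seed(33)
  n <- 2000
  phi_true <- rlnorm(n, log(0.16), 0.7)
  mu <- rlnorm(n, log(100), 1)
  cnt <- sapply(1:6, function(s) rnbinom(n, size = 1 / phi_true, mu = mu))
  rownames(cnt) <- sprintf("g%04d", 1:n); colnames(cnt) <- paste0("s", 1:6)
  grp <- factor(rep(c("a", "b"), each = 3))
  cm <- count_matrix(cnt)
  common <- estimate_common_dispersion(cm, grp)
  tw <- shrink_tagwise(cm, grp, common, prior_weight = 10)
  expect_true(all(tw >= 1e-6 & tw <= 10))
  expect_gt(cor(phi_true, tw[rownames(cnt)], method = "spearman"), 0.5)
  ## prior_weight -> Inf: all equal the common value
  tw_inf <- shrink_tagwise(cnt[1:50, ], grp, common, prior_weight = Inf)
  expect_true(all(tw_inf == common))
  ## prior_weight = 0, single gene: the gene's own conditional MLE
  g1 <- cnt[1, , drop = FALSE]
  tw0 <- shrink_tagwise(g1, grp, common, prior_weight = 0, normalize = FALSE)
  own <- estimate_common_dispersion(g1, grp, normalize = FALSE)
  expect_equal(unname(tw0), own, tolerance = 1e-3)
})

test_that("exact NB test symmetries", {
  set.seed(9)
  m <- matrix(rnbinom(200 * 4, mu = 50, size = 5), ncol = 4,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  ## a feature identical across groups: no evidence of change
  m[1, ] <- c(40L, 60L, 40L, 60L)
  cm <- count_matrix(m, library_sizes = rep(1e6, 4))
  de <- exact_nb_test(cm, two_group, dispersion = 0.16, normalize = FALSE)
  expect_equal(de$log2FC[1], 0)
  expect_equal(de$pvalue[1], 1)
  ## swapping group labels negates log2FC, p unchanged
  de_swap <- exact_nb_test(cm, factor(two_group, levels = c("mut", "wt")),
                           dispersion = 0.16, normalize = FALSE)
  expect_equal(de_swap$log2FC, -de$log2FC, tolerance = 1e-12)
  expect_equal(de_swap$pvalue, de$pvalue, tolerance = 1e-12)
  ## all-zero feature
  m2 <- m; m2[5, ] <- 0L
  de0 <- exact_nb_test(count_matrix(m2, library_sizes = rep(1e6, 4)),
                       two_group, dispersion = 0.16, normalize = FALSE)
  expect_equal(de0$pvalue[5], 1)
  expect_equal(de0$log2FC[5], 0)
})

test_that("dispersion zero reduces to the conditional Poisson enumeration", {
  for (n1 in 1:3) for (n2 in 1:3) {
    for (t in c(1, 7, 23, 50)) {
      for (a in unique(c(0, 1, t %/% 2, t))) {
        cnt <- matrix(0L, 1, n1 + n2,
                      dimnames = list("g", paste0("s", seq_len(n1 + n2))))
        cnt[1, seq_len(n1)] <- c(a, rep(0L, n1 - 1))
        cnt[1, n1 + seq_len(n2)] <- c(t - a, rep(0L, n2 - 1))
        grp <- factor(rep(c("A", "B"), c(n1, n2)), levels = c("A", "B"))
        de <- exact_nb_test(count_matrix(cnt, library_sizes =
                                           rep(1e6, n1 + n2)),
                            grp, dispersion = 0, normalize = FALSE)
        expect_equal(de$pvalue, oracle_conditional_poisson(a, t - a, n1, n2),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("null simulation at BCV 0.4 keeps type-I error near nominal", {
  cfg <- simulation_config(seed = 11, n_background_genes = 2000, bcv = 0.4,
                           background_lfc_sd = 0)
  sc <- simulate_counts(NULL, cfg)
  de <- exact_nb_test(sc$counts, two_group, dispersion = 0.16)
  frac <- mean(de$pvalue < 0.05)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.065)
})

test_that("a 4-fold effect at mean 100 is detected in most features (2 vs 2)", {
  set.seed(21)
  n <- 2000; nde <- 200
  lfc <- c(rep(2, nde), rep(0, n - nde))
  mk <- function(cond) rnbinom(n, size = 1 / 0.16, mu = 100 * 2^(lfc * cond))
  cnt <- cbind(wt1 = mk(0), wt2 = mk(0), mut1 = mk(1), mut2 = mk(1))
  rownames(cnt) <- sprintf("g%04d", 1:n)
  de <- exact_nb_test(count_matrix(cnt), two_group, dispersion = 0.16)
  expect_gt(mean(de$fdr[1:nde] < 0.05), 0.5)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  ## monotone non-decreasing in the order statistics
  set.seed(3)
  p <- runif(100)
  fdr <- bh_adjust(p)
  expect_true(all(diff(fdr[order(p)]) >= -1e-12))
  expect_true(all(fdr >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})
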