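#' Trimmed-mean-of-M-values normalization factors
#'
#' Composition-bias normalization between libraries: for each sample versus
#' a reference sample, genes expressed in both are compared on their
#' log2 expression ratio (M) and average log2 expression (A); the most
#' extreme 30% of M values and 5% of A values are trimmed and the factor is
#' the precision-weighted mean of the remaining M values. Factors are
#' rescaled to multiply to 1.
#'
#' @param counts A [count_matrix()] or integer matrix (>= 2 samples, each
#'   with positive total counts).
#' @param ref_sample Optional reference sample name; default picks the
#'   sample whose upper-quartile expression is closest to the mean.
#' @param logratio_trim,sum_trim Two-sided trim fractions for M and A.
#' @return Named numeric vector of scaling factors (product 1).
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  cm <- .as_counts(counts)
  x <- cm$counts
  if (ncol(x) < 2) stop("TMM needs at least 2 samples", call. = FALSE)
  lib <- colSums(x)
  if (any(lib <= 0)) stop("sample(s) with zero total counts: ",
                          paste(colnames(x)[lib <= 0], collapse = ", "),
                          call. = FALSE)
  if (is.null(ref_sample)) {
    uq <- apply(sweep(x, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref_sample <- colnames(x)[which.min(abs(uq - mean(uq)))]
  }
  stopifnot(ref_sample %in% colnames(x))
  ref <- x[, ref_sample]
  nR <- lib[ref_sample]
  f <- vapply(colnames(x), function(s) {
    if (s == ref_sample) return(1)
    obs <- x[, s]
    nO <- lib[s]
    keep <- obs > 0 & ref > 0
    if (sum(keep) == 0) return(1)
    o <- obs[keep]; r <- ref[keep]
    M <- log2((o / nO) / (r / nR))
    A <- (log2(o / nO) + log2(r / nR)) / 2
    v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - floor(n * logratio_trim)
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - floor(n * sum_trim)
    rM <- rank(M); rA <- rank(A)
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2)) return(1)
    wm <- sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
    if (!is.finite(wm) || abs(wm) < 1e-6) 1 else 2^wm
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(x))
}

## Conditional NB log-likelihood for one group of samples with (near-)equal
## library sizes: counts y_{gi}, group total z_g, n samples, r = 1/phi.
## Constant-in-phi terms are dropped; lgamma accepts the non-integer
## pseudo-counts produced by library-size equalization.
.cond_loglik_group <- function(y, phi) {
  n <- ncol(y)
  r <- 1 / phi
  z <- rowSums(y)
  rowSums(lgamma(y + r)) + lgamma(n * r) - lgamma(z + n * r) - n * lgamma(r)
}

.equalize_counts <- function(cm, normalize = TRUE) {
  x <- cm$counts
  lib <- cm$library_sizes
  f <- if (normalize && ncol(x) >= 2) tmm_factors(cm) else
    stats::setNames(rep(1, ncol(x)), colnames(x))
  eff <- lib * f[names(lib)]
  target <- exp(mean(log(eff)))
  pseudo <- sweep(x, 2, target / eff, "*")
  list(pseudo = pseudo, eff = eff, target = target)
}

.cond_loglik_total <- function(pseudo, groups, phi) {
  total <- 0
  for (g in levels(groups)) {
    cols <- which(groups == g)
    if (length(cols) >= 2) {
      total <- total + sum(.cond_loglik_group(pseudo[, cols, drop = FALSE], phi))
    }
  }
  total
}

#' Common NB dispersion by conditional maximum likelihood
#'
#' Library sizes are equalized by scaling counts to their geometric-mean
#' effective library size, then the dispersion shared by all features is
#' the maximizer of the summed conditional NB likelihood (each group's
#' counts conditioned on its total), found by 1-D search on
#' \[1e-6, 10\]. Only groups with at least two samples contribute.
#'
#' @param counts A [count_matrix()] or matrix.
#' @param groups Factor (or vector) of group labels, one per sample.
#' @param normalize Apply TMM factors to the library sizes (default TRUE).
#' @return The common dispersion (squared BCV) as a scalar.
#' @export
estimate_common_dispersion <- function(counts, groups, normalize = TRUE) {
  cm <- .as_counts(counts)
  groups <- factor(groups)
  if (!any(table(groups) >= 2)) {
    stop("no group has replicates; use fixed-BCV mode (dispersion = bcv^2) ",
         "instead", call. = FALSE)
  }
  eq <- .equalize_counts(cm, normalize)
  keep <- rowSums(eq$pseudo) > 0
  pseudo <- eq$pseudo[keep, , drop = FALSE]
  opt <- stats::optimize(function(lp) .cond_loglik_total(pseudo, groups, exp(lp)),
                         interval = log(c(1e-6, 10)), maximum = TRUE,
                         tol = 1e-6)
  exp(opt$maximum)
}

#' Per-feature dispersions shrunk toward the common value
#'
#' Each feature's dispersion maximizes its own conditional likelihood plus
#' `prior_weight` times the average per-feature likelihood (which peaks at
#' the common dispersion), i.e. the individual estimate is stabilized with
#' `prior_weight` pseudo-observations of the ensemble. `prior_weight = 0`
#' gives per-feature maximum likelihood; `prior_weight = Inf` returns the
#' common value for every feature.
#'
#' @inheritParams estimate_common_dispersion
#' @param common_dispersion Value from [estimate_common_dispersion()].
#' @param prior_weight Number of pseudo-observations (default 10).
#' @return Named numeric vector of per-feature dispersions in \[1e-6, 10\].
#' @export
shrink_tagwise <- function(counts, groups, common_dispersion,
                           prior_weight = 10, normalize = TRUE) {
  cm <- .as_counts(counts)
  groups <- factor(groups)
  eq <- .equalize_counts(cm, normalize)
  pseudo <- eq$pseudo
  use <- lapply(levels(groups), function(g) which(groups == g))
  use <- use[vapply(use, length, integer(1)) >= 2]
  if (length(use) == 0) stop("no group has replicates", call. = FALSE)
  lgrid <- seq(log(1e-6), log(10), length.out = 81)
  ## per-feature likelihood on the grid (features x grid)
  L <- vapply(lgrid, function(lp) {
    tot <- 0
    for (cols in use) {
      tot_g <- .cond_loglik_group(pseudo[, cols, drop = FALSE], exp(lp))
      tot <- tot + tot_g
    }
    tot
  }, numeric(nrow(pseudo)))
  if (is.null(dim(L))) L <- matrix(L, nrow = 1)
  lbar <- colMeans(L)
  lbar_fun <- stats::splinefun(lgrid, lbar)
  own_loglik <- function(i, lp) {
    tot <- 0
    for (cols in use) {
      tot <- tot + .cond_loglik_group(pseudo[i, cols, drop = FALSE], exp(lp))
    }
    tot
  }
  out <- vapply(seq_len(nrow(pseudo)), function(i) {
    if (is.infinite(prior_weight)) return(common_dispersion)
    obj <- function(lp) own_loglik(i, lp) + prior_weight * lbar_fun(lp)
    exp(stats::optimize(obj, interval = log(c(1e-6, 10)), maximum = TRUE,
                        tol = 1e-6)$maximum)
  }, numeric(1))
  stats::setNames(out, rownames(pseudo))
}

## Two-sided exact conditional NB p-value for one feature: given group sums
## a (n1 libs) and b (n2 libs) with common per-library mean mu and
## dispersion phi, sum the probabilities of all splits of t = a + b that are
## no more likely than the observed one.
.exact_nb_pvalue <- function(a, b, n1, n2, phi) {
  t <- a + b
  if (t == 0) return(1)
  k <- 0:t
  if (phi < 1e-10) {
    logp <- stats::dbinom(k, t, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- t / (n1 + n2)
    logp <- stats::dnbinom(k, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(t - k, size = n2 / phi, mu = n2 * mu, log = TRUE)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  pobs <- logp[a + 1]
  min(1, sum(exp(logp[logp <= pobs + 1e-8])))
}

#' Exact negative-binomial test for two groups
#'
#' For each feature, library sizes are equalized (TMM-scaled, geometric
#' mean target) and the group sums are compared through the conditional
#' distribution of one group's sum given the total, under a negative
#' binomial with the supplied dispersion. The two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed split.
#' With dispersion 0 this reduces to the exact conditional Poisson
#' (binomial) test. Log2 fold-changes (second group level over the first)
#' use normalized group means with a small prior count to avoid infinite
#' ratios.
#'
#' @inheritParams estimate_common_dispersion
#' @param groups Factor with exactly two levels; the first level is the
#'   baseline (e.g. wild type), the second the condition of interest, so
#'   positive `log2FC` means higher in the second level.
#' @param dispersion Scalar or per-feature vector of NB dispersions. For
#'   fixed-BCV mode pass `bcv^2` (e.g. `0.4^2 = 0.16`).
#' @param prior_count Prior count added to each group mean for the
#'   fold-change (default 0.125).
#' @return A data.frame with columns `feature_id`, `log2FC`, `aveExpr`
#'   (average log2 counts-per-million), `pvalue`, `fdr`
#'   (Benjamini–Hochberg).
#' @export
exact_nb_test <- function(counts, groups, dispersion, normalize = TRUE,
                          prior_count = 0.125) {
  cm <- .as_counts(counts)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (length(groups) != ncol(cm$counts)) {
    stop("groups length must match the number of samples", call. = FALSE)
  }
  nfeat <- nrow(cm$counts)
  phi <- rep_len(dispersion, nfeat)
  if (any(phi < 0)) stop("dispersion must be >= 0", call. = FALSE)
  eq <- .equalize_counts(cm, normalize)
  pseudo <- eq$pseudo
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  a <- round(rowSums(pseudo[, g1, drop = FALSE]))
  b <- round(rowSums(pseudo[, g2, drop = FALSE]))
  m1 <- rowMeans(pseudo[, g1, drop = FALSE])
  m2 <- rowMeans(pseudo[, g2, drop = FALSE])
  log2FC <- log2((m2 + prior_count) / (m1 + prior_count))
  aveExpr <- log2((rowMeans(pseudo) + prior_count) / eq$target * 1e6)
  pvalue <- vapply(seq_len(nfeat), function(i) {
    .exact_nb_pvalue(a[i], b[i], length(g1), length(g2), phi[i])
  }, numeric(1))
  zero <- (a + b) == 0
  log2FC[zero] <- 0
  pvalue[zero] <- 1
  data.frame(feature_id = rownames(cm$counts), log2FC = log2FC,
             aveExpr = aveExpr, pvalue = pvalue, fdr = bh_adjust(pvalue),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini–Hochberg adjusted p-values
#'
#' Step-up false discovery rate control with monotonicity enforcement
#' (via [stats::p.adjust()]); input p-values must lie in \[0, 1\].
#'
#' @param pvalues Numeric vector of p-values.
#' @return Vector of FDR values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must be in [0, 1] and non-missing", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
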