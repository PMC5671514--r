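#' Detection filter on accumulated reads
#'
#' Keeps the features whose counts, summed over all libraries of one
#' experiment, reach `min_total` (default 4) accumulated reads.
#'
#' @param counts A [count_matrix()] or matrix restricted to one
#'   experiment's libraries.
#' @param feature_subset Optional character vector restricting the features
#'   considered (e.g. the pri-miRNA model ids).
#' @param min_total Minimum summed count (default 4, inclusive).
#' @return Character vector of feature ids passing the filter.
#' @export
detection_filter <- function(counts, feature_subset = NULL, min_total = 4) {
  cm <- .as_counts(counts)
  x <- cm$counts
  if (!is.null(feature_subset)) {
    x <- x[rownames(x) %in% feature_subset, , drop = FALSE]
  }
  rownames(x)[rowSums(x) >= min_total]
}

#' One-sided Wilcoxon rank-sum test (x greater)
#'
#' Tests whether `x` is stochastically greater than `y`. The p-value comes
#' from [stats::wilcox.test()]: exact enumeration when the pooled sample
#' has at most 20 observations and no ties, otherwise the normal
#' approximation with tie and continuity corrections. The reported
#' statistic is the rank sum of `x` in the pooled midrank ranking.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `statistic` (rank sum of `x`) and `pvalue`.
#' @export
wilcoxon_greater <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("empty input", call. = FALSE)
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(is.na(c(x, y)))) stop("missing values in input", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 20
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "greater", exact = exact, correct = TRUE))
  m <- length(x)
  ranksum <- unname(wt$statistic) + m * (m + 1) / 2
  list(statistic = ranksum, pvalue = unname(wt$p.value))
}

#' Per-group expression-shift tests
#'
#' For each positional group, tests whether the log2 fold-changes of that
#' group's pri-miRNA models are shifted upwards relative to a background
#' set (by default, all protein-coding features), via the one-sided
#' Wilcoxon rank-sum test. Empty groups are skipped with a note.
#'
#' @param de A differential-expression table ([exact_nb_test()] output).
#' @param models The model table from [build_annotation()] (columns `id`,
#'   `group`), or a named character vector mapping model id to group.
#' @param background_ids Feature ids of the comparison set; must be
#'   disjoint from the model ids.
#' @return A data.frame with one row per group: `group`, `n_group`,
#'   `statistic`, `pvalue`, `direction`, `note`.
#' @export
group_shift_tests <- function(de, models, background_ids) {
  if (is.data.frame(models)) {
    grp <- stats::setNames(models$group, models$id)
  } else {
    grp <- models
  }
  if (length(intersect(names(grp), background_ids)) > 0) {
    stop("background set must be disjoint from the pri-miRNA models",
         call. = FALSE)
  }
  y <- de$log2FC[de$feature_id %in% background_ids]
  if (length(y) == 0) stop("no background features found in the DE table",
                           call. = FALSE)
  rows <- lapply(.GROUPS, function(g) {
    ids <- names(grp)[grp == g]
    x <- de$log2FC[de$feature_id %in% ids]
    if (length(x) == 0) {
      return(data.frame(group = g, n_group = 0L, statistic = NA_real_,
                        pvalue = NA_real_, direction = "greater",
                        note = "skipped: no members in DE table",
                        stringsAsFactors = FALSE))
    }
    wt <- wilcoxon_greater(x, y)
    data.frame(group = g, n_group = length(x), statistic = wt$statistic,
               pvalue = wt$pvalue, direction = "greater", note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-experiment up/down contingency table
#'
#' Classifies each common feature by the sign of its log2 fold-change in
#' two experiments (up: > 0, down: < 0; exact zeros and missing values are
#' excluded with counts) and tabulates the 2x2 agreement. Optionally the
#' common set is first restricted to features significant in experiment A
#' (`fdr < fdr_filter_a`), mirroring a "significant in A, any direction in
#' B" comparison when experiment B lacks replicates.
#'
#' @param de_a,de_b Differential-expression tables with `feature_id`,
#'   `log2FC` and (for `de_a`) `fdr` columns.
#' @param common_ids Features detected in both experiments.
#' @param fdr_filter_a Optional FDR threshold applied to experiment A.
#' @return An object of class `ContingencyTable`: list with `table` (2x2
#'   integer matrix, rows = experiment A up/down, columns = experiment B),
#'   `n_entering`, `n_excluded_zero`, `n_excluded_missing`, and `margins`.
#' @export
cross_tabulate <- function(de_a, de_b, common_ids, fdr_filter_a = NULL) {
  ids <- intersect(intersect(common_ids, de_a$feature_id), de_b$feature_id)
  n_missing <- length(common_ids) - length(ids)
  if (!is.null(fdr_filter_a)) {
    sig <- de_a$feature_id[!is.na(de_a$fdr) & de_a$fdr < fdr_filter_a]
    ids <- intersect(ids, sig)
  }
  la <- de_a$log2FC[match(ids, de_a$feature_id)]
  lb <- de_b$log2FC[match(ids, de_b$feature_id)]
  bad <- is.na(la) | is.na(lb)
  n_missing <- n_missing + sum(bad)
  zero <- !bad & (la == 0 | lb == 0)
  n_zero <- sum(zero)
  keep <- !bad & !zero
  tab <- matrix(0L, 2, 2,
                dimnames = list(A = c("up", "down"), B = c("up", "down")))
  tab["up", "up"] <- sum(la[keep] > 0 & lb[keep] > 0)
  tab["up", "down"] <- sum(la[keep] > 0 & lb[keep] < 0)
  tab["down", "up"] <- sum(la[keep] < 0 & lb[keep] > 0)
  tab["down", "down"] <- sum(la[keep] < 0 & lb[keep] < 0)
  stopifnot(sum(tab) == sum(keep))
  structure(list(table = tab, n_entering = length(ids),
                 n_excluded_zero = n_zero, n_excluded_missing = n_missing,
                 margins = list(A = rowSums(tab), B = colSums(tab))),
            class = "ContingencyTable")
}

#' @export
print.ContingencyTable <- function(x, ...) {
  cat("ContingencyTable (", x$n_entering, "features entering,",
      x$n_excluded_zero, "zero-FC excluded )\n")
  print(x$table)
  invisible(x)
}
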