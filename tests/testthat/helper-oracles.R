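## Independent brute-force oracles and small fixture builders. The oracles
## deliberately avoid the package's interval and index machinery: overlap
## and gap are computed by base enumeration, classification by pair loops
## with plain comparisons, Wilcoxon by rank-assignment enumeration, the
## conditional count test by explicit Poisson joint probabilities.

oracle_overlap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0L)
  length(intersect(seq(s1, e1), seq(s2, e2)))
}

oracle_gap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(NA_integer_)
  if (oracle_overlap(c1, s1, e1, c2, s2, e2) > 0) return(0L)
  lo <- min(e1, e2); hi <- max(s1, s2)
  between <- seq(lo + 1, hi - 1)
  between <- between[between > lo & between < hi]
  length(between)
}

## Hairpin-level group by exhaustive pair scan (comparisons only, no base
## enumeration, so it scales to thousands of features).
oracle_classify <- function(chrom, start, end, genes_df, g2_window = 400,
                            model_level = FALSE, member_rows = NULL) {
  ov_with <- function(df) {
    any(vapply(seq_len(nrow(df)), function(j) {
      df$chrom[j] == chrom && df$start[j] <= end && df$end[j] >= start
    }, logical(1)))
  }
  coding <- genes_df[genes_df$biotype == "protein_coding", , drop = FALSE]
  noncod <- genes_df[genes_df$biotype == "non_coding", , drop = FALSE]
  if (model_level && !is.null(member_rows)) {
    for (j in seq_len(nrow(member_rows))) {
      h <- member_rows[j, ]
      hov <- any(vapply(seq_len(nrow(coding)), function(k) {
        coding$chrom[k] == h$chrom && coding$start[k] <= h$end &&
          coding$end[k] >= h$start
      }, logical(1)))
      if (hov) return("G3A")
    }
    if (nrow(coding) > 0 && ov_with(coding)) return("G3B")
  } else {
    if (nrow(coding) > 0 && ov_with(coding)) return("G3A")
  }
  if (nrow(noncod) > 0 && ov_with(noncod)) return("G4")
  gaps <- vapply(seq_len(nrow(coding)), function(j) {
    if (coding$chrom[j] != chrom) return(Inf)
    if (coding$start[j] <= end && coding$end[j] >= start) return(0)
    if (coding$start[j] > end) coding$start[j] - end - 1
    else start - coding$end[j] - 1
  }, numeric(1))
  g <- if (length(gaps) == 0) Inf else min(gaps)
  if (g >= 1 && g <= g2_window) "G2" else "G1"
}

## Exact one-sided (x greater) rank-sum p-value by full enumeration of all
## choose(m+n, m) rank assignments. No ties assumed.
oracle_wilcoxon_greater <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  sets <- utils::combn(m + n, m)
  sums <- apply(sets, 2, function(idx) sum(r[idx]))
  list(statistic = obs, pvalue = mean(sums >= obs))
}

## Two-sided conditional test of an a/b split of total t between n1 and n2
## Poisson libraries: joint Poisson probabilities normalised over all
## splits, p = total mass of splits no more likely than the observed one.
oracle_conditional_poisson <- function(a, b, n1, n2, mu = 1) {
  t <- a + b
  if (t == 0) return(1)
  k <- 0:t
  joint <- dpois(k, n1 * mu) * dpois(t - k, n2 * mu)
  probs <- joint / sum(joint)
  sum(probs[probs <= probs[a + 1] * (1 + 1e-10)])
}

## -- fixture builders --------------------------------------------------

make_features <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], chrom = r[[2]], start = as.integer(r[[3]]),
               end = as.integer(r[[4]]),
               strand = if (length(r) >= 6) r[[6]] else "+",
               biotype = r[[5]], stringsAsFactors = FALSE)
  }))
  feature_set(df)
}

## Random unconstrained annotation for classifier-vs-oracle properties.
random_annotation <- function(n_hairpins, n_genes, max_pos = 50000L) {
  n <- n_hairpins + n_genes
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- c(sample(60:300, n_hairpins, replace = TRUE),
           sample(200:3000, n_genes, replace = TRUE))
  chrom <- sample(c("c1", "c2"), n, replace = TRUE)
  biotype <- c(rep("pre_miRNA", n_hairpins),
               sample(c("protein_coding", "non_coding"), n_genes,
                      replace = TRUE, prob = c(0.7, 0.3)))
  feature_set(data.frame(
    id = sprintf("f%04d", seq_len(n)), chrom = chrom, start = start,
    end = start + len - 1L, strand = "+", biotype = biotype,
    stringsAsFactors = FALSE))
}

## A small SAM file built from explicit records.
write_sam <- function(path, records, chroms = c(c1 = 100000L)) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  body <- vapply(records, function(r) {
    paste(r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar, "*", 0, 0,
          "*", "*", sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

sam_rec <- function(qname, chrom, pos, cigar, mapq = 30, flag = 0) {
  list(qname = qname, flag = flag, chrom = chrom, pos = pos, mapq = mapq,
       cigar = cigar)
}
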