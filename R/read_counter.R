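## CIGAR -> reference-aligned blocks. Reference-consuming ops are M/=/X/D/N;
## D (deletion) stays inside a block (counts as overlap), N (intron) splits
## blocks and contributes no overlap. Returns a matrix of (start, end) rows
## in 1-based inclusive reference coordinates, or NULL on a malformed CIGAR.
.cigar_blocks <- function(cigar, pos) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1) return(NULL)
  toks <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) return(NULL)
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  ops <- sub("^\\d+", "", toks)
  blocks <- list()
  cur_start <- pos
  cur_len <- 0L
  for (i in seq_along(ops)) {
    op <- ops[i]
    if (op %in% c("M", "=", "X", "D")) {
      cur_len <- cur_len + lens[i]
    } else if (op == "N") {
      if (cur_len > 0L) {
        blocks[[length(blocks) + 1L]] <- c(cur_start, cur_start + cur_len - 1L)
      }
      cur_start <- cur_start + cur_len + lens[i]
      cur_len <- 0L
    }
    ## I, S, H, P consume no reference
  }
  if (cur_len > 0L) {
    blocks[[length(blocks) + 1L]] <- c(cur_start, cur_start + cur_len - 1L)
  }
  if (length(blocks) == 0) return(NULL)
  do.call(rbind, blocks)
}

.read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    return(data.frame(qname = b$qname, flag = b$flag,
                      rname = as.character(b$rname), pos = b$pos,
                      mapq = b$mapq, cigar = b$cigar,
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, integer(1)) < 11L)
  if (length(bad) > 0) {
    stop("malformed SAM record (fewer than 11 fields) at data line ", bad[1],
         call. = FALSE)
  }
  data.frame(
    qname = vapply(f, `[`, character(1), 1),
    flag = as.integer(vapply(f, `[`, character(1), 2)),
    rname = vapply(f, `[`, character(1), 3),
    pos = as.integer(vapply(f, `[`, character(1), 4)),
    mapq = as.integer(vapply(f, `[`, character(1), 5)),
    cigar = vapply(f, `[`, character(1), 6),
    stringsAsFactors = FALSE)
}

#' Count reads over an annotation
#'
#' Reimplements the read-assignment semantics used for quantification:
#' only mapped, primary alignments with mapping quality at or above
#' `min_mapq` are considered (multi-mapping reads thereby contribute once,
#' through their primary record), and each read (or fragment) is assigned
#' to the single feature with the largest number of overlapping bases.
#' Equal-overlap ties are left ambiguous and uncounted. Overlap is measured
#' on reference-consuming CIGAR operations, with deletions (`D`) counted as
#' overlap and skips (`N`) as gaps.
#'
#' @param alignments Path to a SAM or BAM file (extension decides), or a
#'   data.frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`.
#' @param features A [feature_set()]; all features are candidate targets.
#' @param min_mapq Minimum mapping quality (default 10).
#' @param mode `"fragment"` (default): records sharing a read id are
#'   assigned together, pooling their overlaps, and count once —
#'   appropriate for paired-end data; `"read"`: every record is assigned
#'   and counted independently.
#' @return A list with `counts` (named integer vector over all feature ids)
#'   and `stats` (named integer vector: `total`, `assigned`, `ambiguous`,
#'   `no_overlap`, `below_mapq`, `not_primary`, `unmapped`,
#'   `unknown_chrom`, `malformed_cigar`; the categories partition the
#'   processed records, with `assigned`/`ambiguous`/`no_overlap` counted in
#'   units of fragments in fragment mode).
#' @export
count_reads <- function(alignments, features, min_mapq = 10,
                        mode = c("fragment", "read")) {
  mode <- match.arg(mode)
  stopifnot(inherits(features, "FeatureSet"))
  aln <- if (is.data.frame(alignments)) alignments else .read_alignments(alignments)
  fdf <- features$features
  counts <- stats::setNames(rep(0L, nrow(fdf)), fdf$id)
  stats <- c(total = nrow(aln), assigned = 0L, ambiguous = 0L,
             no_overlap = 0L, below_mapq = 0L, not_primary = 0L,
             unmapped = 0L, unknown_chrom = 0L, malformed_cigar = 0L)
  if (nrow(aln) == 0) return(list(counts = counts, stats = stats))

  unmapped <- bitwAnd(aln$flag, 4L) != 0L
  not_primary <- bitwAnd(aln$flag, 256L) != 0L | bitwAnd(aln$flag, 2048L) != 0L
  stats["unmapped"] <- sum(unmapped)
  stats["not_primary"] <- sum(!unmapped & not_primary)
  pass <- !unmapped & !not_primary
  low <- pass & (is.na(aln$mapq) | aln$mapq < min_mapq)
  stats["below_mapq"] <- sum(low)
  pass <- pass & !low
  known <- aln$rname %in% unique(fdf$chrom)
  stats["unknown_chrom"] <- sum(pass & !known)
  pass <- pass & known

  idx <- which(pass)
  ## per-record overlap with each candidate feature
  rec_overlaps <- vector("list", length(idx))
  malformed <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    blocks <- .cigar_blocks(aln$cigar[i], aln$pos[i])
    if (is.null(blocks)) {
      malformed[k] <- TRUE
      next
    }
    same <- which(fdf$chrom == aln$rname[i])
    if (length(same) == 0) next
    ov <- numeric(0)
    for (b in seq_len(nrow(blocks))) {
      w <- .overlap_vec(aln$rname[i], blocks[b, 1], blocks[b, 2],
                        fdf$chrom[same], fdf$start[same], fdf$end[same])
      if (b == 1) ov <- w else ov <- ov + w
    }
    hit <- which(ov > 0)
    if (length(hit) > 0) {
      rec_overlaps[[k]] <- stats::setNames(ov[hit], fdf$id[same][hit])
    }
  }
  stats["malformed_cigar"] <- sum(malformed)
  keep <- !malformed
  idx <- idx[keep]
  rec_overlaps <- rec_overlaps[keep]

  ## group into assignment units
  units <- if (mode == "fragment") {
    split(seq_along(idx), aln$qname[idx])
  } else {
    as.list(seq_along(idx))
  }
  for (u in units) {
    pooled <- list()
    for (k in u) {
      for (fid in names(rec_overlaps[[k]])) {
        pooled[[fid]] <- (if (is.null(pooled[[fid]])) 0 else pooled[[fid]]) +
          rec_overlaps[[k]][[fid]]
      }
    }
    if (length(pooled) == 0) {
      stats["no_overlap"] <- stats["no_overlap"] + 1L
    } else {
      ov <- unlist(pooled)
      best <- names(ov)[ov == max(ov)]
      if (length(best) > 1) {
        stats["ambiguous"] <- stats["ambiguous"] + 1L
      } else {
        counts[best] <- counts[best] + 1L
        stats["assigned"] <- stats["assigned"] + 1L
      }
    }
  }
  list(counts = counts, stats = stats)
}

#' Combine per-sample count columns into a CountMatrix
#'
#' @param columns Named list of per-sample count vectors (as produced by
#'   `count_reads()$counts`); all must carry identical feature ids.
#' @return A [count_matrix()].
#' @export
merge_columns <- function(columns) {
  stopifnot(is.list(columns), length(columns) >= 1, !is.null(names(columns)))
  ids <- names(columns[[1]])
  for (s in names(columns)) {
    if (!identical(sort(names(columns[[s]])), sort(ids))) {
      stop("sample '", s, "' has a mismatched feature id list", call. = FALSE)
    }
  }
  m <- vapply(columns, function(col) as.integer(col[ids]),
              integer(length(ids)))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(columns),
                                   dimnames = list(ids, names(columns)))
  rownames(m) <- ids
  count_matrix(m)
}

#' Construct a CountMatrix
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param library_sizes Per-sample totals; defaults to column sums of the
#'   assigned counts.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature and sample names", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  library_sizes <- stats::setNames(as.numeric(library_sizes), colnames(counts))
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

.as_counts <- function(x) {
  if (inherits(x, "CountMatrix")) return(x)
  count_matrix(x)
}

#' Read / write a counts table (TSV)
#'
#' Plain tab-separated text: `feature_id` column followed by one integer
#' column per sample.
#'
#' @param path File path.
#' @return For `read_counts_tsv`, a [count_matrix()].
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m)
}

#' @rdname read_counts_tsv
#' @param cm A [count_matrix()].
#' @export
write_counts_tsv <- function(cm, path) {
  cm <- .as_counts(cm)
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
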