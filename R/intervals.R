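#' Construct a genomic interval
#'
#' Intervals use the GFF3/GTF convention: 1-based coordinates, inclusive at
#' both ends, so an interval covers `end - start + 1` bases.
#'
#' @param chrom Chromosome name.
#' @param start First covered base (integer, >= 1).
#' @param end Last covered base (integer, >= start).
#' @param strand One of `"+"`, `"-"` or `"*"` (unknown). Strand is recorded
#'   but ignored by [overlap_bp()] and [gap_bp()].
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("Chr1", 100, 200)
#' interval_length(gi)
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("invalid interval: require end >= start >= 1 (got [",
         start, ", ", end, "])", call. = FALSE)
  }
  strand <- match.arg(strand, c("+", "-", "*"))
  structure(
    list(chrom = as.character(chrom), start = start, end = end,
         strand = strand),
    class = "genomic_interval"
  )
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d(%s)>\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_length <- function(x) {
  x <- .as_interval(x)
  x$end - x$start + 1L
}

.as_interval <- function(x) {
  if (inherits(x, "genomic_interval")) return(x)
  if (is.list(x) && all(c("chrom", "start", "end") %in% names(x))) {
    return(genomic_interval(x$chrom, x$start, x$end,
                            if (is.null(x$strand)) "*" else x$strand))
  }
  stop("not a genomic interval", call. = FALSE)
}

## Vectorised primitives used throughout the package: plain arithmetic on
## parallel coordinate vectors, 1-based inclusive at both ends.
.overlap_vec <- function(chrom1, start1, end1, chrom2, start2, end2) {
  ifelse(chrom1 == chrom2,
         pmax(0L, pmin(end1, end2) - pmax(start1, start2) + 1L),
         0L)
}

.gap_vec <- function(chrom1, start1, end1, chrom2, start2, end2) {
  ifelse(chrom1 == chrom2,
         pmax(0L, pmax(start1, start2) - pmin(end1, end2) - 1L),
         NA_integer_)
}

#' Number of bases shared by two intervals
#'
#' Symmetric; 0 when the intervals are on different chromosomes or disjoint.
#' Strand is ignored.
#'
#' @param a,b Intervals (see [genomic_interval()]).
#' @return Non-negative integer count of shared bases.
#' @examples
#' overlap_bp(genomic_interval("c", 100, 200), genomic_interval("c", 150, 250))
#' @export
overlap_bp <- function(a, b) {
  a <- .as_interval(a); b <- .as_interval(b)
  .overlap_vec(a$chrom, a$start, a$end, b$chrom, b$start, b$end)
}

#' Number of bases strictly between two intervals
#'
#' Returns 0 for overlapping or immediately adjacent intervals, the count of
#' intervening bases otherwise, and `NA` when the intervals sit on different
#' chromosomes (the gap is undefined; callers treat this as "no neighbour").
#' Symmetric; strand is ignored.
#'
#' @inheritParams overlap_bp
#' @return Non-negative integer, or `NA_integer_` across chromosomes.
#' @examples
#' gap_bp(genomic_interval("c", 1, 100), genomic_interval("c", 102, 200)) # 1
#' @export
gap_bp <- function(a, b) {
  a <- .as_interval(a); b <- .as_interval(b)
  .gap_vec(a$chrom, a$start, a$end, b$chrom, b$start, b$end)
}
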