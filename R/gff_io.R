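#' Default GFF3 type -> biotype map
#'
#' Covers common reference annotation spellings (Araport/TAIR-style types)
#' plus this package's own output types, so that [write_gff3()] followed by
#' [read_gff3()] round-trips. Whether hairpin coordinates come from `miRNA`
#' or `miRNA_primary_transcript`-style records is a user decision: edit the
#' map accordingly.
#'
#' @return Named character vector mapping GFF3 column-3 types to biotypes.
#' @export
default_biotype_map <- function() {
  c(miRNA = "pre_miRNA",
    miRNA_primary_transcript = "pre_miRNA",
    pre_miRNA = "pre_miRNA",
    gene = "protein_coding",
    protein_coding_gene = "protein_coding",
    protein_coding = "protein_coding",
    ncRNA = "non_coding",
    ncRNA_gene = "non_coding",
    lnc_RNA = "non_coding",
    non_coding = "non_coding",
    pri_miRNA = "pri_miRNA",
    transcript_model = "transcript_model")
}

.parse_gff3_attributes <- function(txt) {
  if (is.na(txt) || txt == "" || txt == ".") return(character(0))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[parts != ""]
  keys <- sub("=.*$", "", parts)
  vals <- sub("^[^=]*=", "", parts)
  stats::setNames(vals, keys)
}

.format_gff3_attributes <- function(attrs) {
  if (length(attrs) == 0) return(".")
  paste(paste0(names(attrs), "=", unname(attrs)), collapse = ";")
}

#' Read a GFF3 file into a FeatureSet
#'
#' Coordinates are taken verbatim (GFF3 is 1-based, inclusive). Records whose
#' column-3 type is not covered by `biotype_map` are skipped; their per-type
#' counts are attached as the `skipped_types` attribute of the result and
#' reported via `message()` — unknown types are never guessed.
#'
#' @param path Path to a tab-delimited GFF3 file.
#' @param biotype_map Named character vector mapping GFF3 types to biotypes
#'   (see [default_biotype_map()]).
#' @return A [feature_set()]; feature ids come from the `ID` attribute
#'   (falling back to `Name`, then to `<type>_<line>`).
#' @export
read_gff3 <- function(path, biotype_map = default_biotype_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(length(biotype_map) >= 1, !is.null(names(biotype_map)))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  skipped <- integer(0)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop("malformed GFF3 line ", lineno[i], ": expected 9 columns, got ",
           length(f), call. = FALSE)
    }
    type <- f[3]
    if (!type %in% names(biotype_map)) {
      skipped[type] <- if (type %in% names(skipped)) skipped[[type]] + 1L else 1L
      next
    }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop("malformed GFF3 line ", lineno[i], ": non-integer coordinates",
           call. = FALSE)
    }
    if (end < start || start < 1L) {
      stop("malformed GFF3 line ", lineno[i], ": end < start (",
           start, " > ", end, ")", call. = FALSE)
    }
    attrs <- .parse_gff3_attributes(f[9])
    id <- if ("ID" %in% names(attrs)) attrs[["ID"]]
          else if ("Name" %in% names(attrs)) attrs[["Name"]]
          else paste0(type, "_", lineno[i])
    strand <- if (f[7] %in% c("+", "-")) f[7] else "*"
    rows[[i]] <- data.frame(
      id = id, chrom = f[1], start = start, end = end, strand = strand,
      biotype = unname(biotype_map[[type]]), stringsAsFactors = FALSE)
    rows[[i]]$attributes <- list(attrs)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), biotype = character(0))
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    stop("duplicate feature id(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  fs <- feature_set(df)
  if (length(skipped) > 0) {
    message("read_gff3: skipped ", sum(skipped), " record(s) of unmapped type(s): ",
            paste(names(skipped), collapse = ", "))
  }
  attr(fs, "skipped_types") <- skipped
  fs
}

.BIOTYPE_TO_GFF3 <- c(pre_miRNA = "miRNA", protein_coding = "gene",
                      non_coding = "ncRNA", transcript_model = "transcript_model",
                      pri_miRNA = "pri_miRNA")

#' Write a FeatureSet as GFF3
#'
#' Column 3 carries the GFF3 type for each biotype (`miRNA`, `gene`,
#' `ncRNA`, `pri_miRNA`, `transcript_model`), and column 9 starts with
#' `ID=<id>` followed by the stored attributes, so `read_gff3(write_gff3(x))`
#' with the default biotype map is the identity on id, interval, biotype and
#' attributes.
#'
#' @param fs A non-empty [feature_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(fs, path) {
  stopifnot(inherits(fs, "FeatureSet"))
  if (length(fs) == 0) stop("refusing to write an empty FeatureSet", call. = FALSE)
  df <- fs$features
  lines <- character(nrow(df) + 1L)
  lines[1] <- "##gff-version 3"
  for (i in seq_len(nrow(df))) {
    attrs <- df$attributes[[i]]
    attrs <- attrs[setdiff(names(attrs), "ID")]
    attrs <- c(ID = df$id[i], attrs)
    lines[i + 1L] <- paste(
      df$chrom[i], "primirna", .BIOTYPE_TO_GFF3[[df$biotype[i]]],
      df$start[i], df$end[i], ".", df$strand[i], ".",
      .format_gff3_attributes(attrs), sep = "\t")
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

.parse_gtf_attributes <- function(txt) {
  m <- gregexpr('(\\S+)\\s+"([^"]*)"', txt)
  hits <- regmatches(txt, m)[[1]]
  if (length(hits) == 0) return(character(0))
  keys <- sub('\\s.*$', "", hits)
  vals <- sub('^\\S+\\s+"', "", hits)
  vals <- sub('"$', "", vals)
  stats::setNames(vals, keys)
}

#' Read assembled transcript models from a GTF file
#'
#' Exon (and transcript) records are grouped by `transcript_id`; each
#' transcript becomes one `transcript_model` feature spanning from its first
#' exon start to its last exon end, with the exon structure retained in the
#' `exons` attribute as `start1-end1,start2-end2,...`.
#'
#' @param path Path to a GTF file (attribute syntax `key "value";`).
#' @return A [feature_set()] of biotype `transcript_model`.
#' @export
read_gtf_transcripts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  recs <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop("malformed GTF line ", lineno[i], ": expected 9 columns", call. = FALSE)
    }
    if (!f[3] %in% c("transcript", "exon")) next
    attrs <- .parse_gtf_attributes(f[9])
    if (!"transcript_id" %in% names(attrs)) {
      stop("GTF line ", lineno[i], ": ", f[3], " record without transcript_id",
           call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || end < start) {
      stop("malformed GTF line ", lineno[i], ": bad coordinates", call. = FALSE)
    }
    recs[[length(recs) + 1L]] <- list(
      tid = attrs[["transcript_id"]],
      gid = if ("gene_id" %in% names(attrs)) attrs[["gene_id"]] else NA_character_,
      type = f[3], chrom = f[1], start = start, end = end,
      strand = if (f[7] %in% c("+", "-")) f[7] else "*")
  }
  tids <- unique(vapply(recs, `[[`, character(1), "tid"))
  rows <- vector("list", length(tids))
  for (j in seq_along(tids)) {
    sub <- recs[vapply(recs, function(r) r$tid == tids[j], logical(1))]
    exons <- sub[vapply(sub, function(r) r$type == "exon", logical(1))]
    if (length(exons) == 0) exons <- sub  # transcript record only
    starts <- vapply(exons, `[[`, integer(1), "start")
    ends <- vapply(exons, `[[`, integer(1), "end")
    ord <- order(starts, ends)
    attrs <- c(
      transcript_id = tids[j],
      gene_id = sub[[1]]$gid,
      exons = paste(sprintf("%d-%d", starts[ord], ends[ord]), collapse = ","))
    attrs <- attrs[!is.na(attrs)]
    rows[[j]] <- data.frame(
      id = tids[j], chrom = sub[[1]]$chrom,
      start = min(starts), end = max(ends), strand = sub[[1]]$strand,
      biotype = "transcript_model", stringsAsFactors = FALSE)
    rows[[j]]$attributes <- list(attrs)
  }
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), biotype = character(0))
  feature_set(df)
}

#' Write transcript models as GTF
#'
#' Emits one `transcript` record per feature plus its `exon` records (from
#' the `exons` attribute when present, otherwise a single exon covering the
#' whole span).
#'
#' @param fs A [feature_set()] of `transcript_model` features.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(fs, path) {
  stopifnot(inherits(fs, "FeatureSet"))
  if (length(fs) == 0) stop("refusing to write an empty FeatureSet", call. = FALSE)
  df <- fs$features
  lines <- character(0)
  for (i in seq_len(nrow(df))) {
    attrs <- df$attributes[[i]]
    gid <- if ("gene_id" %in% names(attrs)) attrs[["gene_id"]] else df$id[i]
    tag <- sprintf('gene_id "%s"; transcript_id "%s";', gid, df$id[i])
    lines <- c(lines, paste(df$chrom[i], "primirna", "transcript",
                            df$start[i], df$end[i], ".", df$strand[i], ".",
                            tag, sep = "\t"))
    exons <- if ("exons" %in% names(attrs)) {
      do.call(rbind, lapply(strsplit(attrs[["exons"]], ",")[[1]], function(e) {
        as.integer(strsplit(e, "-")[[1]])
      }))
    } else {
      matrix(c(df$start[i], df$end[i]), nrow = 1)
    }
    for (k in seq_len(nrow(exons))) {
      lines <- c(lines, paste(df$chrom[i], "primirna", "exon",
                              exons[k, 1], exons[k, 2], ".", df$strand[i], ".",
                              sprintf('%s exon_number "%d";', tag, k), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
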