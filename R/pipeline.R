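.default_params <- function() {
  list(g2_window = 400, min_mapq = 10, min_reads = 4, bcv = 0.4,
       fdr = 0.05, de_mode = "fixed-bcv", background = "protein_coding",
       strand_aware = FALSE)
}

.validation_error <- function(msg) {
  stop(structure(class = c("primirna_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) .validation_error(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$params <- utils::modifyList(.default_params(),
                                     if (is.null(config$params)) list() else config$params)
  if (is.null(config$stages)) config$stages <- list()
  defaults <- list(annotate = TRUE, count = TRUE, de = TRUE, groups = TRUE,
                   crosstab = FALSE, report = TRUE)
  config$stages <- utils::modifyList(defaults, config$stages)
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.validate_pipeline <- function(config) {
  st <- config$stages
  inp <- config$inputs
  need_file <- function(x, what) {
    if (is.null(x)) .validation_error(paste("missing input:", what))
    for (p in unlist(x)) {
      if (!file.exists(p)) .validation_error(paste0(what, " not found: ", p))
    }
  }
  if (is.null(config$out_dir)) .validation_error("out_dir is required")
  if (isTRUE(st$annotate)) {
    need_file(inp$reference, "reference GFF3")
    if (!is.null(inp$predictions)) need_file(inp$predictions, "predictions GTF")
  }
  if (isTRUE(st$count)) {
    if (!isTRUE(st$annotate)) need_file(inp$annotation, "annotation for counting")
    need_file(inp$alignments, "alignment file(s)")
    if (is.null(names(inp$alignments))) {
      .validation_error("inputs$alignments must be a named list (sample = path)")
    }
  }
  if (isTRUE(st$de)) {
    if (!isTRUE(st$count)) need_file(inp$counts, "counts table (counting disabled)")
    if (is.null(config$design)) .validation_error("design (sample = group) is required for DE")
    p <- config$params
    if (!p$de_mode %in% c("fixed-bcv", "tagwise")) {
      .validation_error("de_mode must be 'fixed-bcv' or 'tagwise'")
    }
    if (p$bcv < 0 || p$fdr <= 0 || p$fdr > 1 || p$min_reads < 0 ||
        p$min_mapq < 0 || p$g2_window < 0) {
      .validation_error("pipeline parameter out of range")
    }
  }
  if (isTRUE(st$groups) && !isTRUE(st$de)) {
    need_file(inp$de, "DE table (DE stage disabled)")
  }
  if (isTRUE(st$crosstab)) {
    need_file(inp$de_b, "second experiment DE table")
    need_file(inp$counts_b, "second experiment counts")
  }
  invisible(TRUE)
}

#' Run the annotation / quantification / DE pipeline
#'
#' Orchestrates the stages annotate -> count -> de -> groups (and
#' optionally crosstab and report) from one configuration, writing all
#' artifacts under `out_dir` plus a `manifest.json` recording parameters
#' and outputs. Validation of inputs and parameters happens before any
#' work; runs are deterministic given identical inputs, parameters and
#' seed.
#'
#' @param config Path to a YAML configuration or an equivalent list, with
#'   elements `out_dir`, `seed`, `stages` (logical toggles `annotate`,
#'   `count`, `de`, `groups`, `crosstab`, `report`), `inputs` (paths:
#'   `reference`, `predictions`, `alignments` named by sample, or
#'   pre-computed `annotation` / `counts` / `de` / `de_b` / `counts_b`),
#'   `design` (named sample -> group, first listed group = baseline) and
#'   `params` (`g2_window`, `min_mapq`, `min_reads`, `bcv`, `fdr`,
#'   `de_mode`, `background`).
#' @return The manifest, invisibly: list with `seed`, `parameters`,
#'   `stages`, `artifacts` (data.frame `name`, `path`).
#' @export
run_pipeline <- function(config) {
  config <- .load_config(config)
  .validate_pipeline(config)
  st <- config$stages
  p <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- data.frame(name = character(0), path = character(0),
                          stringsAsFactors = FALSE)
  note <- function(name, path) {
    artifacts <<- rbind(artifacts, data.frame(name = name, path = path,
                                              stringsAsFactors = FALSE))
  }

  ann <- NULL
  if (isTRUE(st$annotate)) {
    reference <- read_gff3(config$inputs$reference)
    predictions <- if (is.null(config$inputs$predictions)) NULL else
      read_gtf_transcripts(config$inputs$predictions)
    ann <- build_annotation(reference, predictions,
                            g2_window = p$g2_window,
                            strand_aware = p$strand_aware)
    write_gff3(ann$merged, out("merged.gff3"))
    note("merged_annotation", out("merged.gff3"))
    utils::write.table(summarize_report(ann$report), out("classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("classification_report", out("classification.tsv"))
  }

  cm <- NULL
  if (isTRUE(st$count)) {
    fs <- if (!is.null(ann)) ann$merged else read_gff3(config$inputs$annotation)
    cols <- lapply(config$inputs$alignments, function(path) {
      count_reads(path, fs, min_mapq = p$min_mapq)$counts
    })
    cm <- merge_columns(cols)
    write_counts_tsv(cm, out("counts.tsv"))
    note("counts", out("counts.tsv"))
  }

  de <- NULL
  if (isTRUE(st$de)) {
    if (is.null(cm)) cm <- read_counts_tsv(config$inputs$counts)
    design <- config$design
    samples <- colnames(cm$counts)
    if (!all(samples %in% names(design))) {
      stop("design lacks group assignments for sample(s): ",
           paste(setdiff(samples, names(design)), collapse = ", "),
           call. = FALSE)
    }
    grp <- factor(unlist(design[samples]), levels = unique(unlist(design)))
    dispersion <- if (p$de_mode == "fixed-bcv") {
      p$bcv^2
    } else {
      common <- estimate_common_dispersion(cm, grp)
      shrink_tagwise(cm, grp, common)
    }
    de <- exact_nb_test(cm, grp, dispersion)
    utils::write.table(de, out("de.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("de", out("de.tsv"))
  }

  if (isTRUE(st$groups)) {
    if (is.null(de)) {
      de <- utils::read.delim(config$inputs$de, stringsAsFactors = FALSE)
    }
    if (is.null(ann)) stop("groups stage requires the annotate stage",
                           call. = FALSE)
    model_grp <- stats::setNames(ann$models$group, ann$models$id)
    bg_ids <- if (identical(p$background, "protein_coding")) {
      fs <- ann$merged$features
      fs$id[fs$biotype == "protein_coding"]
    } else {
      p$background
    }
    bg_ids <- setdiff(intersect(bg_ids, de$feature_id), names(model_grp))
    gt <- group_shift_tests(de, model_grp, bg_ids)
    utils::write.table(gt, out("group_tests.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("group_tests", out("group_tests.tsv"))
  }

  if (isTRUE(st$crosstab)) {
    de_b <- utils::read.delim(config$inputs$de_b, stringsAsFactors = FALSE)
    cm_b <- read_counts_tsv(config$inputs$counts_b)
    model_ids <- ann$models$id
    det_a <- detection_filter(cm, model_ids, min_total = p$min_reads)
    det_b <- detection_filter(cm_b, model_ids, min_total = p$min_reads)
    common <- intersect(det_a, det_b)
    ct <- cross_tabulate(de, de_b, common)
    ct_f <- cross_tabulate(de, de_b, common, fdr_filter_a = p$fdr)
    df <- data.frame(
      filter = c(rep("none", 4), rep(sprintf("fdr_a<%g", p$fdr), 4)),
      cell = rep(c("up_up", "up_down", "down_up", "down_down"), 2),
      n = c(as.vector(t(ct$table)), as.vector(t(ct_f$table))))
    utils::write.table(df, out("crosstab.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("crosstab", out("crosstab.tsv"))
  }

  manifest <- list(seed = config$seed, parameters = p,
                   stages = st[order(names(st))],
                   package_version = as.character(utils::packageVersion("primirna")),
                   artifacts = artifacts)

  if (isTRUE(st$report)) {
    report_path <- out("report.md")
    writeLines(render_report(manifest), report_path)
    note("report", report_path)
    manifest$artifacts <- artifacts
  }
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Render the pipeline report
#'
#' Produces a plain-markdown report from a pipeline manifest: the
#' positional-group summary table (five group rows plus totals, with the
#' bookkeeping identities re-checked on read), the group shift tests, and
#' the cross-experiment contingency cells when present. Regenerating the
#' report from the same manifest yields byte-identical output.
#'
#' @param manifest A manifest list from [run_pipeline()], or the path to a
#'   `manifest.json`.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  art <- manifest$artifacts
  path_of <- function(name) {
    p <- art$path[art$name == name]
    if (length(p) == 0) return(NULL)
    if (!file.exists(p)) stop("missing artifact: ", name, " (", p, ")",
                              call. = FALSE)
    p
  }
  md <- c("# pri-miRNA annotation pipeline report", "")
  cls <- path_of("classification_report")
  if (!is.null(cls)) {
    tab <- utils::read.delim(cls, stringsAsFactors = FALSE)
    md <- c(md, "## Positional groups", "",
            paste(names(tab), collapse = " | "),
            paste(rep("---", ncol(tab)), collapse = " | "),
            apply(tab, 1, paste, collapse = " | "), "")
    tot <- tab[tab$group == "Total", ]
    md <- c(md, sprintf(
      "Identities: final (%d) = predicted (%d) + reference (%d); hairpins (%d) = final (%d) + two-hairpin (%d).",
      tot$final_models, tot$predicted_models, tot$reference_models,
      tot$hairpins, tot$final_models, tot$two_hairpin_models), "")
  }
  gt <- path_of("group_tests")
  if (!is.null(gt)) {
    tab <- utils::read.delim(gt, stringsAsFactors = FALSE)
    md <- c(md, "## Group shift tests (one-sided Wilcoxon, up in mutant)", "",
            paste(names(tab), collapse = " | "),
            paste(rep("---", ncol(tab)), collapse = " | "),
            apply(tab, 1, paste, collapse = " | "), "")
  }
  ct <- path_of("crosstab")
  if (!is.null(ct)) {
    tab <- utils::read.delim(ct, stringsAsFactors = FALSE)
    md <- c(md, "## Cross-experiment agreement", "",
            paste(names(tab), collapse = " | "),
            paste(rep("---", ncol(tab)), collapse = " | "),
            apply(tab, 1, paste, collapse = " | "), "",
            sprintf("Cell-sum conservation: %d features tabulated per filter.",
                    sum(tab$n[tab$filter == "none"])), "")
  }
  md
}
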