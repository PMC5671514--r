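#' Simulation configuration
#'
#' Defaults describe a compact single-chromosome genome whose statistical
#' structure mirrors the study design: hairpins placed intergenic (G1),
#' 1–400 bp from a coding gene (G2), inside coding genes (G3A), with a
#' predicted transcript reaching into a nearby coding gene (G3B), or
#' overlapping a non-coding gene (G4); transcript predictions extending a
#' subset of hairpins; and NB counts for two genotypes (wild type and a
#' biogenesis mutant, two replicates each) with BCV 0.4 and group-specific
#' up-regulation of the pri-miRNA models in the mutant.
#'
#' @param seed Integer seed; every generator output is reproducible from
#'   (config, seed).
#' @param chrom Chromosome name.
#' @param chrom_length Optional fixed chromosome length; the generator
#'   errors if the layout does not fit (`NULL`: auto-sized).
#' @param n_g1,n_g2,n_g3a,n_g3b,n_g4 Hairpins to place per positional group.
#' @param n_two_hairpin Pairs of intergenic hairpins spanned by a single
#'   prediction (two-hairpin gene models).
#' @param n_background_genes Protein-coding genes with no hairpin.
#' @param detect_prob Probability that a G1/G2/G4 hairpin has a transcript
#'   prediction (G3B hairpins always do, by definition; G3A never —
#'   the host gene rule takes precedence).
#' @param hairpin_length,gene_length,nc_length,extension Uniform ranges
#'   (bp) for hairpin, coding-gene and non-coding-gene lengths and for the
#'   extension of predictions beyond the hairpin.
#' @param g2_window Width of the near-gene window (bp).
#' @param boundary_cases Add two prediction-free hairpins at gaps exactly
#'   `g2_window` (G2) and `g2_window + 1` (G1) for edge testing.
#' @param library_sizes Named per-library totals; names are sample ids.
#' @param condition 0/1 vector (per library): 1 = mutant.
#' @param bcv Biological coefficient of variation (dispersion = bcv^2).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters for
#'   baseline expression (counts per million).
#' @param group_lfc Named true log2 fold-changes (mutant over wild type)
#'   per positional group.
#' @param background_lfc_sd Standard deviation of background-gene log2
#'   fold-changes (0 = strict null).
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom = "Chr1",
                              chrom_length = NULL,
                              n_g1 = 10L, n_g2 = 6L, n_g3a = 6L,
                              n_g3b = 5L, n_g4 = 4L,
                              n_two_hairpin = 2L,
                              n_background_genes = 150L,
                              detect_prob = 0.6,
                              hairpin_length = c(80L, 250L),
                              gene_length = c(1000L, 3000L),
                              nc_length = c(300L, 1000L),
                              extension = c(50L, 300L),
                              g2_window = 400L,
                              boundary_cases = FALSE,
                              library_sizes = c(wt1 = 2e7, wt2 = 2e7,
                                                mut1 = 2e7, mut2 = 2e7),
                              condition = c(0, 0, 1, 1),
                              bcv = 0.4,
                              baseline_meanlog = log(5),
                              baseline_sdlog = 1,
                              group_lfc = c(G1 = 2, G2 = 1.5, G3A = 0.5,
                                            G3B = 2.5, G4 = 1.5),
                              background_lfc_sd = 0.5) {
  cfg <- list(seed = as.integer(seed), chrom = chrom,
              chrom_length = chrom_length,
              n_g1 = n_g1, n_g2 = n_g2, n_g3a = n_g3a, n_g3b = n_g3b,
              n_g4 = n_g4, n_two_hairpin = n_two_hairpin,
              n_background_genes = n_background_genes,
              detect_prob = detect_prob, hairpin_length = hairpin_length,
              gene_length = gene_length, nc_length = nc_length,
              extension = extension, g2_window = g2_window,
              boundary_cases = boundary_cases,
              library_sizes = library_sizes, condition = condition,
              bcv = bcv, baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, group_lfc = group_lfc,
              background_lfc_sd = background_lfc_sd)
  counts <- c(n_g1, n_g2, n_g3a, n_g3b, n_g4, n_two_hairpin,
              n_background_genes)
  if (any(counts < 0)) stop("feature counts must be >= 0", call. = FALSE)
  if (detect_prob < 0 || detect_prob > 1) stop("detect_prob must be in [0,1]",
                                               call. = FALSE)
  if (bcv < 0) stop("bcv must be >= 0", call. = FALSE)
  if (detect_prob == 0 && n_g3b > 0) {
    stop("G3B hairpins require a predicted transcript: set detect_prob > 0 ",
         "or n_g3b = 0", call. = FALSE)
  }
  if (length(condition) != length(library_sizes)) {
    stop("condition must have one entry per library", call. = FALSE)
  }
  if (any(library_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  class(cfg) <- "SimulationConfig"
  cfg
}

.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

#' Simulate a genome annotation with known ground truth
#'
#' Places coding genes, non-coding genes and hairpins on one chromosome so
#' that every hairpin's positional group holds unambiguously by
#' construction: units are separated by wide spacers so no feature of one
#' unit can fall within the near-gene window of another, G2 gaps are drawn
#' inside `[1, g2_window]`, G3A hairpins sit strictly inside their host
#' gene, G3B hairpins sit just beyond the window with a prediction
#' extending into the neighbouring gene, and G4 hairpins overlap only a
#' non-coding gene. Labels are re-derived by direct coordinate arithmetic
#' before returning; any inconsistency is an error.
#'
#' @param config A [simulation_config()].
#' @return A list with `reference` (FeatureSet: hairpins + genes),
#'   `predictions` (FeatureSet of transcript models), `truth` (data.frame:
#'   `hairpin_id`, `hairpin_group`, `model_group`, `model_id`,
#'   `source_rule`, `prediction_id`, `host_gene`), and `chrom_length`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  W <- config$g2_window
  ext_max <- config$extension[2]
  spacer <- c(ext_max + W + 150L, ext_max + W + 800L)  # always > W after extension

  units <- c(rep("g1", config$n_g1), rep("g2", config$n_g2),
             rep("g3a", config$n_g3a), rep("g3b", config$n_g3b),
             rep("g4", config$n_g4), rep("pair", config$n_two_hairpin),
             rep("bg", config$n_background_genes))
  if (config$boundary_cases) units <- c(units, "edge400", "edge401")
  units <- sample(units)

  feats <- list()   # rows for the reference FeatureSet
  preds <- list()   # rows for the prediction FeatureSet
  truth <- list()
  ids <- c(gene = 0L, nc = 0L, mir = 0L, pred = 0L)
  nid <- function(kind, fmt) {
    ids[kind] <<- ids[kind] + 1L
    sprintf(fmt, ids[kind])
  }
  add_feat <- function(id, start, end, biotype, strand = "+") {
    feats[[length(feats) + 1L]] <<- data.frame(
      id = id, chrom = config$chrom, start = as.integer(start),
      end = as.integer(end), strand = strand, biotype = biotype,
      stringsAsFactors = FALSE)
  }
  add_pred <- function(id, start, end, strand = "+") {
    preds[[length(preds) + 1L]] <<- data.frame(
      id = id, chrom = config$chrom, start = as.integer(start),
      end = as.integer(end), strand = strand, biotype = "transcript_model",
      stringsAsFactors = FALSE)
  }
  add_truth <- function(hid, hg, mg, members, rule, pid = NA, host = NA) {
    truth[[length(truth) + 1L]] <<- data.frame(
      hairpin_id = hid, hairpin_group = hg, model_group = mg,
      model_id = paste0("PRI-", paste(sort(members), collapse = ".")),
      source_rule = rule, prediction_id = pid, host_gene = host,
      stringsAsFactors = FALSE)
  }
  maybe_predict <- function(hid, hstart, hend, group) {
    if (stats::runif(1) >= config$detect_prob) return(NULL)
    extl <- .runif_int(1, config$extension)
    extr <- .runif_int(1, config$extension)
    pid <- nid("pred", "PRED.%04d")
    add_pred(pid, max(1L, hstart - extl), hend + extr)
    pid
  }

  cursor <- 1L
  for (u in units) {
    cursor <- cursor + .runif_int(1, spacer)
    hl <- .runif_int(1, config$hairpin_length)
    if (u == "bg") {
      gl <- .runif_int(1, config$gene_length)
      add_feat(nid("gene", "GENE%04d"), cursor, cursor + gl - 1L,
               "protein_coding")
      cursor <- cursor + gl
    } else if (u == "g1") {
      hid <- nid("mir", "MIR%04d")
      add_feat(hid, cursor, cursor + hl - 1L, "pre_miRNA")
      pid <- maybe_predict(hid, cursor, cursor + hl - 1L, "G1")
      add_truth(hid, "G1", "G1", hid,
                if (is.null(pid)) "hairpin_fallback" else "predicted_transcript",
                if (is.null(pid)) NA else pid)
      cursor <- cursor + hl
    } else if (u %in% c("g2", "edge400", "edge401")) {
      gl <- .runif_int(1, config$gene_length)
      gene_id <- nid("gene", "GENE%04d")
      add_feat(gene_id, cursor, cursor + gl - 1L, "protein_coding")
      gap <- switch(u, g2 = .runif_int(1, c(1L, W)), edge400 = W,
                    edge401 = W + 1L)
      hstart <- cursor + gl + gap
      hid <- nid("mir", "MIR%04d")
      add_feat(hid, hstart, hstart + hl - 1L, "pre_miRNA")
      hg <- if (gap <= W) "G2" else "G1"
      pid <- NULL
      if (u == "g2") {
        ## prediction may extend toward the gene only up to gap - 1 bases,
        ## so the model stays in the window without touching the gene
        if (stats::runif(1) < config$detect_prob) {
          extl <- min(.runif_int(1, config$extension), gap - 1L)
          extr <- .runif_int(1, config$extension)
          pid <- nid("pred", "PRED.%04d")
          add_pred(pid, hstart - extl, hstart + hl - 1L + extr)
        }
      }
      add_truth(hid, hg, hg, hid,
                if (is.null(pid)) "hairpin_fallback" else "predicted_transcript",
                if (is.null(pid)) NA else pid)
      cursor <- hstart + hl
    } else if (u == "g3a") {
      gl <- .runif_int(1, pmax(config$gene_length, hl + 20L))
      gene_id <- nid("gene", "GENE%04d")
      add_feat(gene_id, cursor, cursor + gl - 1L, "protein_coding")
      off <- .runif_int(1, c(0L, gl - hl))
      hid <- nid("mir", "MIR%04d")
      add_feat(hid, cursor + off, cursor + off + hl - 1L, "pre_miRNA")
      add_truth(hid, "G3A", "G3A", hid, "host_gene", host = gene_id)
      cursor <- cursor + gl
    } else if (u == "g3b") {
      hid <- nid("mir", "MIR%04d")
      hstart <- cursor
      add_feat(hid, hstart, hstart + hl - 1L, "pre_miRNA")
      gap <- .runif_int(1, c(W + 1L, W + 200L))
      gl <- .runif_int(1, config$gene_length)
      gene_id <- nid("gene", "GENE%04d")
      gstart <- hstart + hl + gap
      add_feat(gene_id, gstart, gstart + gl - 1L, "protein_coding")
      ## the prediction always exists and reaches into the gene
      pid <- nid("pred", "PRED.%04d")
      reach <- .runif_int(1, c(10L, min(200L, gl)))
      extl <- .runif_int(1, config$extension)
      add_pred(pid, max(1L, hstart - extl), gstart + reach - 1L)
      add_truth(hid, "G1", "G3B", hid, "predicted_transcript", pid)
      cursor <- gstart + gl
    } else if (u == "g4") {
      ncl <- max(.runif_int(1, config$nc_length), hl)
      nc_id <- nid("nc", "NC%04d")
      add_feat(nc_id, cursor, cursor + ncl - 1L, "non_coding")
      off <- .runif_int(1, c(0L, ncl - hl))
      hid <- nid("mir", "MIR%04d")
      add_feat(hid, cursor + off, cursor + off + hl - 1L, "pre_miRNA")
      pid <- maybe_predict(hid, cursor + off, cursor + off + hl - 1L, "G4")
      add_truth(hid, "G4", "G4", hid,
                if (is.null(pid)) "hairpin_fallback" else "predicted_transcript",
                if (is.null(pid)) NA else pid)
      cursor <- cursor + ncl
    } else if (u == "pair") {
      hl2 <- .runif_int(1, config$hairpin_length)
      between <- .runif_int(1, c(50L, 200L))
      h1 <- nid("mir", "MIR%04d")
      h2 <- nid("mir", "MIR%04d")
      add_feat(h1, cursor, cursor + hl - 1L, "pre_miRNA")
      s2 <- cursor + hl + between
      add_feat(h2, s2, s2 + hl2 - 1L, "pre_miRNA")
      pid <- nid("pred", "PRED.%04d")
      extl <- .runif_int(1, config$extension)
      extr <- .runif_int(1, config$extension)
      add_pred(pid, max(1L, cursor - extl), s2 + hl2 - 1L + extr)
      add_truth(h1, "G1", "G1", c(h1, h2), "predicted_transcript", pid)
      add_truth(h2, "G1", "G1", c(h1, h2), "predicted_transcript", pid)
      cursor <- s2 + hl2
    }
  }
  total_len <- cursor + 2L * (ext_max + W + 800L)
  if (!is.null(config$chrom_length) && total_len > config$chrom_length) {
    stop("infeasible config: layout needs ", total_len,
         " bp but chrom_length is ", config$chrom_length, call. = FALSE)
  }
  chrom_length <- if (is.null(config$chrom_length)) total_len else
    as.integer(config$chrom_length)

  ref <- feature_set(do.call(rbind, feats))
  pred_fs <- if (length(preds) > 0) feature_set(do.call(rbind, preds)) else
    feature_set(do.call(rbind, feats)[0, , drop = FALSE])
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(hairpin_id = character(0), hairpin_group = character(0),
               model_group = character(0), model_id = character(0),
               source_rule = character(0), prediction_id = character(0),
               host_gene = character(0), stringsAsFactors = FALSE)

  ## generation-time consistency check by direct coordinate arithmetic
  rdf <- ref$features
  coding <- rdf[rdf$biotype == "protein_coding", , drop = FALSE]
  noncod <- rdf[rdf$biotype == "non_coding", , drop = FALSE]
  for (i in seq_len(nrow(truth))) {
    h <- rdf[truth$hairpin_id[i], ]
    lab <- .classify_interval(h$chrom, h$start, h$end, "*", coding, noncod,
                              W, FALSE)
    if (lab != truth$hairpin_group[i]) {
      stop("generator self-check failed for ", h$id, ": placed as ",
           truth$hairpin_group[i], " but classifies as ", lab, call. = FALSE)
    }
  }

  list(reference = ref, predictions = pred_fs, truth = truth,
       chrom_length = chrom_length, config = config)
}

#' Simulate an NB count matrix with known effects
#'
#' Counts for the pri-miRNA models (from the annotation ground truth) and a
#' set of background protein-coding features are drawn from a negative
#' binomial with mean `baseline_cpm * 2^(lfc * condition) * libsize / 1e6`
#' and variance `mu + bcv^2 * mu^2`. Baseline expression is log-normal;
#' model log2 fold-changes come from the per-group effects in the config,
#' background fold-changes from a centred normal. Reproducible from
#' `config$seed` (offset so annotation and counts use distinct streams).
#'
#' @param truth The `truth` table from [simulate_annotation()], or `NULL`
#'   for background features only.
#' @param config A [simulation_config()].
#' @param background_ids Optional explicit background feature ids (default
#'   `BG0001...` per `n_background_genes`).
#' @return List with `counts` (a [count_matrix()]) and `truth` (data.frame
#'   `feature_id`, `baseline_cpm`, `log2FC`, `is_model`).
#' @export
simulate_counts <- function(truth, config, background_ids = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1000003L)
  if (is.null(background_ids)) {
    background_ids <- sprintf("BG%04d", seq_len(config$n_background_genes))
  }
  model_df <- if (is.null(truth)) {
    data.frame(feature_id = character(0), log2FC = numeric(0))
  } else {
    u <- unique(truth[, c("model_id", "model_group")])
    data.frame(feature_id = u$model_id,
               log2FC = unname(config$group_lfc[u$model_group]),
               stringsAsFactors = FALSE)
  }
  bg_df <- data.frame(
    feature_id = background_ids,
    log2FC = if (config$background_lfc_sd > 0)
      stats::rnorm(length(background_ids), 0, config$background_lfc_sd)
    else rep(0, length(background_ids)),
    stringsAsFactors = FALSE)
  ft <- rbind(model_df, bg_df)
  n <- nrow(ft)
  ft$baseline_cpm <- stats::rlnorm(n, config$baseline_meanlog,
                                   config$baseline_sdlog)
  ft$is_model <- ft$feature_id %in% model_df$feature_id
  libs <- config$library_sizes
  cond <- config$condition
  m <- matrix(0L, n, length(libs),
              dimnames = list(ft$feature_id, names(libs)))
  for (s in seq_along(libs)) {
    mu <- ft$baseline_cpm * 2^(ft$log2FC * cond[s]) * libs[s] / 1e6
    m[, s] <- if (config$bcv > 0) {
      stats::rnbinom(n, size = 1 / config$bcv^2, mu = mu)
    } else {
      stats::rpois(n, mu)
    }
  }
  list(counts = count_matrix(m, library_sizes = colSums(m)),
       truth = ft[, c("feature_id", "baseline_cpm", "log2FC", "is_model")])
}

#' Simulate single-end alignments as a SAM file
#'
#' Writes uniquely placed primary alignments (MAPQ 50, simple `<len>M`
#' CIGAR) with read starts uniform inside each source feature, so that
#' [count_reads()] recovers the requested per-feature read numbers exactly
#' whenever the features are disjoint.
#'
#' @param features A [feature_set()] of source features.
#' @param reads_per_feature Named integer vector: reads to draw per
#'   feature id.
#' @param read_length Read length in bp; every source feature must be at
#'   least this long.
#' @param path Output SAM path.
#' @param seed Integer seed.
#' @param chrom_lengths Optional named chromosome lengths for the header
#'   (defaults to max feature end + 1000 per chromosome).
#' @return Invisibly, `path`.
#' @export
simulate_alignments <- function(features, reads_per_feature, read_length = 50,
                                path, seed = 1L, chrom_lengths = NULL) {
  stopifnot(inherits(features, "FeatureSet"))
  set.seed(as.integer(seed))
  fdf <- features$features
  stopifnot(!is.null(names(reads_per_feature)),
            all(names(reads_per_feature) %in% fdf$id))
  lens <- stats::setNames(fdf$end - fdf$start + 1L, fdf$id)
  short <- names(reads_per_feature)[lens[names(reads_per_feature)] < read_length]
  if (length(short) > 0) {
    stop("feature(s) shorter than the read length: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(fdf$end, fdf$chrom, max) + 1000L
  }
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)))
  seq_str <- strrep("A", read_length)
  for (fid in names(reads_per_feature)) {
    nr <- reads_per_feature[[fid]]
    if (nr == 0) next
    f <- fdf[fid, ]
    starts <- f$start + floor(stats::runif(nr, 0, lens[[fid]] - read_length + 1))
    for (j in seq_len(nr)) {
      lines <- c(lines, paste(sprintf("%s_r%03d", fid, j), 0L, f$chrom,
                              as.integer(starts[j]), 50L,
                              paste0(read_length, "M"), "*", 0L, 0L,
                              seq_str, "*", sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
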