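.GROUPS <- c("G1", "G2", "G3A", "G3B", "G4")

## Minimum gap (bp) from `interval` to any feature of `df` on the same
## chromosome; Inf when no such feature exists. Overlap gives gap 0.
.nearest_gap <- function(chrom, start, end, df, strand = "*",
                         strand_aware = FALSE) {
  if (nrow(df) == 0) return(Inf)
  if (strand_aware && strand %in% c("+", "-")) {
    df <- df[df$strand %in% c(strand, "*"), , drop = FALSE]
  }
  g <- .gap_vec(chrom, start, end, df$chrom, df$start, df$end)
  g <- g[!is.na(g)]
  if (length(g) == 0) Inf else min(g)
}

.any_overlap <- function(chrom, start, end, df, strand = "*",
                         strand_aware = FALSE) {
  if (nrow(df) == 0) return(FALSE)
  if (strand_aware && strand %in% c("+", "-")) {
    df <- df[df$strand %in% c(strand, "*"), , drop = FALSE]
  }
  any(.overlap_vec(chrom, start, end, df$chrom, df$start, df$end) > 0)
}

.classify_interval <- function(chrom, start, end, strand, coding, noncoding,
                               g2_window, strand_aware) {
  if (.any_overlap(chrom, start, end, coding, strand, strand_aware)) return("G3A")
  if (.any_overlap(chrom, start, end, noncoding, strand, strand_aware)) return("G4")
  gap <- .nearest_gap(chrom, start, end, coding, strand, strand_aware)
  if (gap >= 1 && gap <= g2_window) return("G2")
  "G1"
}

#' Positional group of a pre-miRNA hairpin
#'
#' First-pass classification of a hairpin against the gene annotation:
#' `G3A` if the hairpin overlaps any protein-coding gene (full genomic
#' span), else `G4` if it overlaps a non-coding gene, else `G2` if the gap
#' to the nearest protein-coding gene is within `[1, g2_window]` bp, else
#' `G1` (intergenic). Precedence is fixed as G3A > G4 > G2 > G1; a hairpin
#' is never `G3B` — that label exists only at the gene-model level
#' ([classify_model()]).
#'
#' @param pre A one-row data.frame (or list) describing a `pre_miRNA`
#'   feature: `chrom`, `start`, `end`, `strand`.
#' @param genes A [feature_set()] containing `protein_coding` and
#'   `non_coding` features.
#' @param g2_window Width of the "close to a coding gene" window in bp
#'   (default 400, inclusive at both ends).
#' @param strand_aware Restrict comparisons to same-strand genes
#'   (default `FALSE`).
#' @return One of `"G1"`, `"G2"`, `"G3A"`, `"G4"`.
#' @export
classify_hairpin <- function(pre, genes, g2_window = 400, strand_aware = FALSE) {
  stopifnot(inherits(genes, "FeatureSet"))
  pre <- as.list(pre)
  gdf <- genes$features
  coding <- gdf[gdf$biotype == "protein_coding", , drop = FALSE]
  noncoding <- gdf[gdf$biotype == "non_coding", , drop = FALSE]
  .classify_interval(pre$chrom, as.integer(pre$start), as.integer(pre$end),
                     if (is.null(pre$strand)) "*" else pre$strand,
                     coding, noncoding, g2_window, strand_aware)
}

#' Positional group of a pri-miRNA gene model
#'
#' Second-pass classification of a candidate gene model: `G3A` if any
#' member hairpin overlaps a protein-coding gene; else `G3B` if the model
#' interval overlaps a protein-coding gene (the model, but not the hairpin,
#' reaches into the gene); else `G4` on non-coding overlap; else `G2`
#' within the 1–`g2_window` bp window of the nearest coding gene; else `G1`.
#'
#' @param model_interval A [genomic_interval()] for the candidate model; it
#'   must overlap every member hairpin.
#' @param members Character vector of member hairpin ids (1 or 2).
#' @param reference A [feature_set()] holding the hairpins and genes.
#' @inheritParams classify_hairpin
#' @return One of `"G1"`, `"G2"`, `"G3A"`, `"G3B"`, `"G4"`.
#' @export
classify_model <- function(model_interval, members, reference,
                           g2_window = 400, strand_aware = FALSE) {
  stopifnot(inherits(reference, "FeatureSet"))
  iv <- .as_interval(model_interval)
  gdf <- reference$features
  coding <- gdf[gdf$biotype == "protein_coding", , drop = FALSE]
  noncoding <- gdf[gdf$biotype == "non_coding", , drop = FALSE]
  for (m in members) {
    h <- get_feature(reference, m)
    if (.overlap_vec(iv$chrom, iv$start, iv$end, h$chrom, h$start, h$end) == 0) {
      stop("model interval does not overlap member hairpin '", m, "'",
           call. = FALSE)
    }
    if (.any_overlap(h$chrom, h$start, h$end, coding, h$strand, strand_aware)) {
      return("G3A")
    }
  }
  if (.any_overlap(iv$chrom, iv$start, iv$end, coding, iv$strand, strand_aware)) {
    return("G3B")
  }
  if (.any_overlap(iv$chrom, iv$start, iv$end, noncoding, iv$strand, strand_aware)) {
    return("G4")
  }
  gap <- .nearest_gap(iv$chrom, iv$start, iv$end, coding, iv$strand, strand_aware)
  if (gap >= 1 && gap <= g2_window) return("G2") else return("G1")
}

#' Assign a pri-miRNA gene model to one hairpin
#'
#' Applies the per-group model-assignment rules: a hairpin overlapping a
#' protein-coding gene (first-pass `G3A`) takes the host gene's interval as
#' its gene model (`source_rule = "host_gene"`; with several overlapping
#' genes the one sharing most bases wins, an exact tie is flagged); a
#' hairpin with a matched transcript prediction takes the prediction's
#' interval (`predicted_transcript`); otherwise the model is the hairpin
#' annotation itself (`hairpin_fallback`). The final group label is then the
#' second-pass [classify_model()] of the chosen interval.
#'
#' @param pre One-row data.frame for the hairpin (`id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param hairpin_label First-pass label from [classify_hairpin()].
#' @param prediction One-row data.frame for the matched transcript model, or
#'   `NULL` when no prediction is available.
#' @param reference A [feature_set()] with hairpins and genes.
#' @inheritParams classify_hairpin
#' @return A one-row data.frame (`id`, coordinates, `group`, `source_rule`,
#'   list columns `members` and `conflict_flags`).
#' @export
assign_model <- function(pre, hairpin_label, prediction, reference,
                         g2_window = 400, strand_aware = FALSE) {
  pre <- as.data.frame(pre, stringsAsFactors = FALSE)
  flags <- character(0)
  if (identical(hairpin_label, "G3A")) {
    gdf <- reference$features
    coding <- gdf[gdf$biotype == "protein_coding", , drop = FALSE]
    ov <- .overlap_vec(pre$chrom, pre$start, pre$end,
                       coding$chrom, coding$start, coding$end)
    cand <- coding[ov > 0, , drop = FALSE]
    ovc <- ov[ov > 0]
    if (nrow(cand) == 0) stop("hairpin labelled G3A overlaps no coding gene",
                              call. = FALSE)
    best <- which(ovc == max(ovc))
    if (length(best) > 1) {
      flags <- c(flags, "host_gene_tie")
      best <- best[order(cand$start[best], cand$id[best])][1]
    }
    host <- cand[best, , drop = FALSE]
    iv <- host
    source_rule <- "host_gene"
    source_id <- host$id
  } else if (!is.null(prediction)) {
    prediction <- as.data.frame(prediction, stringsAsFactors = FALSE)
    if (.overlap_vec(pre$chrom, pre$start, pre$end, prediction$chrom,
                     prediction$start, prediction$end) == 0) {
      stop("prediction '", prediction$id, "' does not overlap hairpin '",
           pre$id, "'", call. = FALSE)
    }
    iv <- prediction
    source_rule <- "predicted_transcript"
    source_id <- prediction$id
  } else {
    iv <- pre
    source_rule <- "hairpin_fallback"
    source_id <- pre$id
  }
  group <- classify_model(
    genomic_interval(iv$chrom, iv$start, iv$end, iv$strand),
    members = pre$id, reference = reference,
    g2_window = g2_window, strand_aware = strand_aware)
  out <- data.frame(
    id = paste0("PRI-", pre$id), chrom = iv$chrom,
    start = as.integer(iv$start), end = as.integer(iv$end),
    strand = pre$strand, group = group, source_rule = source_rule,
    source_id = source_id, stringsAsFactors = FALSE)
  out$members <- list(pre$id)
  out$conflict_flags <- list(flags)
  out
}

#' Build the pri-miRNA annotation
#'
#' The full two-pass procedure: (1) each hairpin is matched to at most one
#' transcript prediction — the one sharing most bases, ties broken by
#' leftmost start then lexicographic id; (2) [assign_model()] is applied per
#' hairpin; (3) models derived from the same prediction or the same host
#' gene are merged into one two-hairpin model; (4) group bookkeeping is
#' collected into a [classification_report()]; (5) the merged annotation
#' (all non-hairpin reference features plus the final pri-miRNA models) is
#' returned; (6) final models from different sources whose intervals overlap
#' are flagged in `conflict_flags` for manual review — no automated
#' coordinate editing is attempted.
#'
#' @param reference A [feature_set()] containing at least one `pre_miRNA`
#'   feature plus the `protein_coding` / `non_coding` gene annotation.
#' @param predictions A [feature_set()] of `transcript_model` features (may
#'   be empty or `NULL`).
#' @inheritParams classify_hairpin
#' @return A list with elements `models` (data.frame of final pri-miRNA
#'   models), `report` (a `ClassificationReport`), and `merged` (a
#'   [feature_set()] for quantification).
#' @export
build_annotation <- function(reference, predictions = NULL,
                             g2_window = 400, strand_aware = FALSE) {
  stopifnot(inherits(reference, "FeatureSet"))
  rdf <- reference$features
  hairpins <- rdf[rdf$biotype == "pre_miRNA", , drop = FALSE]
  if (nrow(hairpins) == 0) stop("reference contains no pre_miRNA features",
                                call. = FALSE)
  pdf <- if (is.null(predictions)) {
    rdf[0, , drop = FALSE]
  } else {
    stopifnot(inherits(predictions, "FeatureSet"))
    predictions$features[predictions$features$biotype == "transcript_model", ,
                         drop = FALSE]
  }

  ## pass 1: hairpin-level labels
  hairpin_label <- vapply(seq_len(nrow(hairpins)), function(i) {
    classify_hairpin(hairpins[i, ], reference, g2_window, strand_aware)
  }, character(1))
  names(hairpin_label) <- hairpins$id

  ## hairpin -> prediction matching (largest overlap; deterministic ties)
  match_pred <- rep(NA_character_, nrow(hairpins))
  names(match_pred) <- hairpins$id
  if (nrow(pdf) > 0) {
    for (i in seq_len(nrow(hairpins))) {
      ov <- .overlap_vec(hairpins$chrom[i], hairpins$start[i], hairpins$end[i],
                         pdf$chrom, pdf$start, pdf$end)
      if (any(ov > 0)) {
        cand <- which(ov == max(ov[ov > 0]) & ov > 0)
        cand <- cand[order(pdf$start[cand], pdf$id[cand])]
        match_pred[i] <- pdf$id[cand[1]]
      }
    }
  }

  ## cap predictions claimed by more than two hairpins: keep the two with
  ## the largest hairpin overlap (greedy), flag the rest back to fallback
  overload_flags <- stats::setNames(vector("list", nrow(hairpins)), hairpins$id)
  for (pid in unique(stats::na.omit(match_pred))) {
    claimed <- names(match_pred)[!is.na(match_pred) & match_pred == pid]
    if (length(claimed) > 2) {
      p <- pdf[pdf$id == pid, , drop = FALSE]
      h <- hairpins[claimed, , drop = FALSE]
      ov <- .overlap_vec(h$chrom, h$start, h$end, p$chrom, p$start, p$end)
      keep <- claimed[order(-ov, h$start, claimed)][1:2]
      dropped <- setdiff(claimed, keep)
      match_pred[dropped] <- NA_character_
      for (d in dropped) {
        overload_flags[[d]] <- c(overload_flags[[d]],
                                 paste0("prediction_overloaded:", pid))
      }
    }
  }

  ## per-hairpin model assignment
  per_hairpin <- lapply(seq_len(nrow(hairpins)), function(i) {
    pid <- match_pred[[hairpins$id[i]]]
    pred <- if (is.na(pid)) NULL else pdf[pdf$id == pid, , drop = FALSE]
    m <- assign_model(hairpins[i, c("id", "chrom", "start", "end", "strand")],
                      hairpin_label[[hairpins$id[i]]], pred, reference,
                      g2_window, strand_aware)
    m$conflict_flags[[1]] <- c(m$conflict_flags[[1]],
                               overload_flags[[hairpins$id[i]]])
    m
  })
  per_hairpin <- do.call(rbind, per_hairpin)

  ## merge models sharing a prediction or a host gene
  key <- paste(per_hairpin$source_rule, per_hairpin$source_id)
  mergeable <- per_hairpin$source_rule %in% c("predicted_transcript", "host_gene")
  key[!mergeable] <- paste("solo", per_hairpin$id[!mergeable])
  merged_rows <- lapply(split(seq_len(nrow(per_hairpin)), key), function(idx) {
    sub <- per_hairpin[idx, , drop = FALSE]
    members <- sort(unlist(sub$members))
    row <- sub[1, , drop = FALSE]
    row$id <- paste0("PRI-", paste(members, collapse = "."))
    row$members <- list(members)
    row$conflict_flags <- list(unique(unlist(sub$conflict_flags)))
    ## re-classify the merged interval with all members
    row$group <- classify_model(
      genomic_interval(row$chrom, row$start, row$end, row$strand),
      members = members, reference = reference,
      g2_window = g2_window, strand_aware = strand_aware)
    row
  })
  models <- do.call(rbind, merged_rows)
  models <- models[order(models$chrom, models$start, models$id), , drop = FALSE]
  rownames(models) <- NULL

  ## overlapping final models from different sources: flag, do not resolve
  n <- nrow(models)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (.overlap_vec(models$chrom[i], models$start[i], models$end[i],
                         models$chrom[j], models$start[j], models$end[j]) > 0) {
          models$conflict_flags[[i]] <- unique(c(
            models$conflict_flags[[i]], paste0("overlaps_model:", models$id[j])))
          models$conflict_flags[[j]] <- unique(c(
            models$conflict_flags[[j]], paste0("overlaps_model:", models$id[i])))
        }
      }
    }
  }

  ## bookkeeping
  zero <- stats::setNames(rep(0L, 5), .GROUPS)
  cnt <- function(groups) {
    t <- table(factor(groups, levels = .GROUPS))
    stats::setNames(as.integer(t), .GROUPS)
  }
  n_members <- vapply(models$members, length, integer(1))
  report <- classification_report(
    hairpins = cnt(hairpin_label),
    predicted = cnt(models$group[models$source_rule == "predicted_transcript"]),
    reference = cnt(models$group[models$source_rule != "predicted_transcript"]),
    two_hairpin = cnt(models$group[n_members == 2]),
    final = cnt(models$group))

  ## merged annotation for quantification
  keepref <- rdf[rdf$biotype != "pre_miRNA", , drop = FALSE]
  mfeat <- models[, c("id", "chrom", "start", "end", "strand")]
  mfeat$biotype <- "pri_miRNA"
  mfeat$attributes <- lapply(seq_len(nrow(models)), function(i) {
    c(group = models$group[i], source_rule = models$source_rule[i],
      members = paste(models$members[[i]], collapse = ","))
  })
  merged <- feature_set(rbind(keepref[, names(mfeat)], mfeat))

  list(models = models, report = report, merged = merged)
}

#' Construct a ClassificationReport from per-group counts
#'
#' Normally produced by [build_annotation()]; the constructor is exported so
#' that externally tabulated per-group counts can be checked against the
#' bookkeeping identities with [summarize_report()].
#'
#' @param hairpins,predicted,reference,two_hairpin,final Named integer
#'   vectors over the groups `G1`, `G2`, `G3A`, `G3B`, `G4`: first-pass
#'   hairpin counts, prediction-derived model counts, reference-derived
#'   model counts (host gene or hairpin fallback), two-hairpin model counts,
#'   and final model counts.
#' @return An object of class `ClassificationReport`.
#' @export
classification_report <- function(hairpins, predicted, reference,
                                  two_hairpin, final) {
  as_counts <- function(x) {
    stopifnot(all(.GROUPS %in% names(x)))
    v <- as.integer(x[.GROUPS])
    stopifnot(all(v >= 0))
    stats::setNames(v, .GROUPS)
  }
  structure(list(hairpins = as_counts(hairpins),
                 predicted = as_counts(predicted),
                 reference = as_counts(reference),
                 two_hairpin = as_counts(two_hairpin),
                 final = as_counts(final)),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  print(summarize_report(x))
  invisible(x)
}

#' Tabulate a ClassificationReport
#'
#' Returns the per-group summary table (five group rows plus a Total row)
#' and enforces the column identities that must hold for any consistent
#' annotation: total final models = total predicted-derived +
#' reference-derived models, and total hairpins = total final models +
#' total two-hairpin models (each two-hairpin model accounts for one extra
#' hairpin). A report violating either identity raises an error. The
#' per-row hairpin counts are informative only — the first-pass hairpin
#' label can legitimately differ from the final model group (e.g. a G1
#' hairpin whose predicted model becomes G3B).
#'
#' @param report A [classification_report()].
#' @return A data.frame with columns `group`, `hairpins`,
#'   `predicted_models`, `reference_models`, `two_hairpin_models`,
#'   `final_models`.
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "ClassificationReport"))
  df <- data.frame(
    group = .GROUPS,
    hairpins = report$hairpins,
    predicted_models = report$predicted,
    reference_models = report$reference,
    two_hairpin_models = report$two_hairpin,
    final_models = report$final,
    stringsAsFactors = FALSE, row.names = NULL)
  tot <- data.frame(group = "Total",
                    hairpins = sum(df$hairpins),
                    predicted_models = sum(df$predicted_models),
                    reference_models = sum(df$reference_models),
                    two_hairpin_models = sum(df$two_hairpin_models),
                    final_models = sum(df$final_models),
                    stringsAsFactors = FALSE)
  if (tot$final_models != tot$predicted_models + tot$reference_models) {
    stop("report identity violated: total final models (", tot$final_models,
         ") != predicted (", tot$predicted_models, ") + reference (",
         tot$reference_models, ")", call. = FALSE)
  }
  if (tot$hairpins != tot$final_models + tot$two_hairpin_models) {
    stop("report identity violated: total hairpins (", tot$hairpins,
         ") != final models (", tot$final_models, ") + two-hairpin models (",
         tot$two_hairpin_models, ")", call. = FALSE)
  }
  rbind(df, tot)
}
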