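# End-to-end orchestration: reads -> tags -> annotation -> normalisation ->
# consensus DE -> effect/power, and Cq -> curves -> quantification ->
# spike-in normalisation -> enrichment impact -> group comparison, joined
# into a cross-platform concordance report.

#' Run the full cross-platform pipeline
#'
#' Executes the sequencing arm (when `reads` are given) and the qPCR arm
#' (when `cq` data are given), in stage order, and joins the two into a
#' concordance report. All intermediate tables can be written to
#' `out_dir`; outputs are identical for identical inputs, config and seed.
#'
#' @param config A [load_config()] object.
#' @param reads Named list (by sample_id) of raw read character vectors, or
#'   of FASTQ/FASTA file paths.
#' @param reference A `reference_set` (see [as_reference_set()]).
#' @param groups Named `"control"`/`"case"` vector by sample_id (sequencing
#'   samples).
#' @param cq Cq table for target assays (see [read_cq_table()]).
#' @param standards Dilution-series data.frame covering every assay in `cq`
#'   plus the spike-in.
#' @param spike_assay Assay id of the exogenous spike-in control.
#' @param qpcr_groups Named group vector by sample_id for the qPCR cohort;
#'   defaults to `groups`.
#' @param out_dir Optional output directory for stage TSVs.
#' @return A list with (depending on inputs): `tag_matrix`, `annotation`,
#'   `de` (consensus table), `exclusive`, `curves`, `quant`,
#'   `enrichment`, `qpcr_groups` (group-comparison table), `concordance`.
#' @export
run_pipeline <- function(config = load_config(quiet = TRUE),
                         reads = NULL, reference = NULL, groups = NULL,
                         cq = NULL, standards = NULL,
                         spike_assay = "aly-mir-159",
                         qpcr_groups = NULL, out_dir = NULL) {
  if (is.null(reads) && is.null(cq)) {
    stop2("need at least one of sequencing reads or Cq data")
  }
  res <- list()
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(out_dir, paste0(name, ".tsv"))
      con <- file(path, "w")
      writeLines(paste0("# crossmir ", pkg_version(), " ", name,
                        " config_hash=", config_hash(config)), con)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
  }

  if (!is.null(reads)) {
    if (is.null(reference) || is.null(groups)) {
      stop2("sequencing arm needs a reference and group labels")
    }
    tag_list <- lapply(names(reads), function(s) {
      r <- reads[[s]]
      if (is.character(r) && length(r) == 1L && file.exists(r)) {
        r <- read_reads(r)$sequence
      }
      process_reads(r, config, sample_id = s)
    })
    names(tag_list) <- names(reads)
    tags <- tags_to_matrix(tag_list)
    res$tag_matrix <- tags

    ann <- annotate_tags(tags, reference,
                         max_shift = config$isomir_max_shift,
                         max_mismatch = config$isomir_max_mismatch)
    res$annotation <- ann
    lib_sizes <- attr(tags, "lib_sizes")

    g <- groups[colnames(ann$counts)]
    res$exclusive <- exclusive_rule(ann$counts, g,
                                    config$exclusive_min_reads)
    filtered <- cpm_filter(ann$counts, lib_sizes, config$cpm_threshold,
                           config$cpm_min_samples)
    de <- consensus_test(filtered, g, ann$lengths,
                         attr(filtered, "lib_sizes"), config)

    # Effect size / power from the raw filtered counts per transcript.
    eff <- do.call(rbind, lapply(seq_len(nrow(filtered)), function(i) {
      x <- filtered[i, g == "control"]
      y <- filtered[i, g == "case"]
      if (stats::sd(x) == 0 || stats::sd(y) == 0 || mean(y) == 0) {
        return(data.frame(fold_change = NA_real_, d = NA_real_,
                          power = NA_real_))
      }
      as.data.frame(effect_and_power(mean(x), stats::sd(x), length(x),
                                     mean(y), stats::sd(y), length(y),
                                     alpha = config$alpha))
    }))
    de <- cbind(de, eff)
    res$de <- de
    emit(de, "consensus_de")
    emit(res$exclusive, "exclusive_transcripts")
    emit(ann$composition, "isoform_composition")
  }

  if (!is.null(cq)) {
    if (is.null(standards)) stop2("qPCR arm needs standard-curve dilutions")
    curves <- fit_standard_curves(standards)
    res$curves <- curves
    target_cq <- cq[cq$assay_id != spike_assay, , drop = FALSE]
    spike_rows <- cq[cq$assay_id == spike_assay, , drop = FALSE]
    if (nrow(spike_rows) == 0L) stop2("no rows for spike assay '",
                                      spike_assay, "'")
    quant <- quantify_cq(target_cq, curves)
    eff_spike <- curves[[spike_assay]]$efficiency
    quant <- spikein_normalise(quant, spike_rows, eff_spike)
    res$quant <- quant
    res$enrichment <- enrichment_impact(quant,
                                        value_col = "normalised_copies")
    gq <- qpcr_groups %||% groups
    if (is.null(gq)) stop2("qPCR arm needs group labels")
    res$qpcr_groups <- group_compare(quant, gq,
                                     value_col = "normalised_copies")
    emit(quant, "qpcr_quant")
    emit(res$enrichment, "enrichment_impact")
    emit(res$qpcr_groups, "qpcr_group_compare")
  }

  if (!is.null(res$de) && !is.null(res$qpcr_groups)) {
    res$concordance <- concordance(res$de, res$qpcr_groups)
    emit(res$concordance, "concordance")
  }
  res
}

#' Cross-platform concordance report
#'
#' Joins sequencing consensus results with qPCR group comparisons on the
#' shared transcript/assay identifier, flags whether all reported fold
#' changes agree in sign, and ranks targets by the magnitude of the
#' enriched-fraction qPCR fold change.
#'
#' @param de Consensus table from [consensus_test()]/[run_pipeline()]
#'   (needs `transcript_id`, `consensus`, `fold_change` control/case).
#' @param qpcr Group-comparison table from [group_compare()].
#' @return Data.frame with per-target sequencing and qPCR fold changes,
#'   the consensus verdict and `direction_agree`; empty (with a warning)
#'   when no identifiers are shared.
#' @export
concordance <- function(de, qpcr) {
  shared <- intersect(de$transcript_id, qpcr$assay_id)
  if (length(shared) == 0L) {
    warn2("no shared identifiers between platforms")
    return(data.frame(id = character(), seq_fold_change = numeric(),
                      seq_consensus = logical(),
                      qpcr_fold_total = numeric(),
                      qpcr_fold_enriched = numeric(),
                      direction_agree = logical(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(shared, function(id) {
    d <- de[de$transcript_id == id, , drop = FALSE]
    # Convert the control/case ratio to the signed convention.
    seq_fc <- if (is.na(d$fold_change)) NA_real_
              else if (d$fold_change >= 1) -d$fold_change
              else 1 / d$fold_change
    qt <- qpcr[qpcr$assay_id == id & qpcr$fraction == "total",
               "fold_change"]
    qe <- qpcr[qpcr$assay_id == id & qpcr$fraction == "enriched",
               "fold_change"]
    fcs <- c(seq_fc, qt, qe)
    data.frame(id = id, seq_fold_change = seq_fc,
               seq_consensus = d$consensus,
               qpcr_fold_total = if (length(qt)) qt else NA_real_,
               qpcr_fold_enriched = if (length(qe)) qe else NA_real_,
               direction_agree = length(unique(sign(fcs[!is.na(fcs)]))) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$qpcr_fold_enriched)), , drop = FALSE]
}

pkg_version <- function() {
  as.character(utils::packageVersion("crossmir"))
}

# Short stable hash of the effective configuration for output provenance.
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, format, ""), collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}
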