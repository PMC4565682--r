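# Seedable generator for synthetic references, small-RNA read libraries and
# RT-qPCR Cq datasets with the statistical structure the analysis pipeline
# assumes: a whole-blood-like expression profile dominated by a few miRNAs,
# an isomiR length/variant mixture, negative-binomial between-sample count
# variation, log-normal between-sample copy-number variation for qPCR,
# precursor cross-detection contaminating the total-RNA fraction, and a
# recovery loss after small-RNA enrichment tracked by an exogenous
# spike-in.
#
# All randomness derives from the single `seed` field; each generator
# draws from its own fixed offset of that seed (reference +101, reads
# +202, copies +303, Cq +404) so stages can be re-run independently with
# identical results.

#' Build a simulation specification
#'
#' Defaults emulate the study conditions the pipeline targets: 26 control
#' and 15 case libraries, a profile dominated by one miRNA at ~60% of
#' reads (with ~13% and ~3% runners-up), an isomiR mixture of 83.1%
#' canonical sequence, 13.8% with one extra 3' nucleotide and 3.1% other
#' variants, one true target down-regulated 2.3-fold in cases, and qPCR
#' parameters giving a ~4.4-cycle spike-in shift between the total and
#' enriched fractions (enrichment recovery 0.048). Library depth is a
#' scaled-down 20,000 reads per sample so whole-pipeline simulations stay
#' fast; counts scale linearly with it.
#'
#' @param n_mirnas Number of mature miRNAs in the reference.
#' @param n_control,n_case Samples per group.
#' @param lib_size_mean Mean cleaned reads per sample.
#' @param nb_dispersion Negative-binomial dispersion of counts (variance
#'   `mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param de_targets Data.frame `(ref_id, fold_change)`; fold change is
#'   control/case, so case means are divided by it.
#' @param isomir_profile Data.frame `(offset5, offset3, fraction)` of
#'   emitted isomiR variants; fractions must sum to 1. Extension bases are
#'   templated from the precursor when one exists, else an `A` is added.
#' @param adapter 3' adapter ligated to every read.
#' @param mature_len Length of simulated mature sequences (nt).
#' @param read_length Sequencer read length; inserts plus adapter are
#'   truncated to this.
#' @param qpcr List of qPCR parameters: `slope` (cycles/log10),
#'   `intercept` (cycles at 1 copy), `cq_sd` (replicate noise, cycles),
#'   `precursor_fraction_total` (fraction of precursor copies detected by
#'   the mature assay in total RNA), `enrichment_recovery` (fraction of
#'   mature copies surviving enrichment), `spike_copies` (spiked input),
#'   `recovery_cv` (between-sample CV of processing recovery),
#'   `copies_sdlog` (log-SD of between-sample biological copy variation),
#'   `mature_mean_control` (target assay mean copies, control group),
#'   `precursor_mean` (non-dysregulated precursor pool mean copies),
#'   `stable_mean` (mean copies of the stable endogenous control assay).
#' @param seed Master seed for all generators.
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(n_mirnas = 30L,
                     n_control = 26L,
                     n_case = 15L,
                     lib_size_mean = 2e4,
                     nb_dispersion = 0.1,
                     de_targets = data.frame(
                       ref_id = "mir-sim-001", fold_change = 2.3,
                       stringsAsFactors = FALSE),
                     isomir_profile = data.frame(
                       offset5 = c(0L, 0L, 1L),
                       offset3 = c(0L, 1L, 0L),
                       fraction = c(0.831, 0.138, 0.031)),
                     adapter = "TGGAATTCTCGGGTGCCAAGG",
                     mature_len = 22L,
                     read_length = 32L,
                     qpcr = list(),
                     seed = 1L) {
  qdef <- list(slope = -3.3219, intercept = 40, cq_sd = 0.25,
               precursor_fraction_total = 0.5,
               enrichment_recovery = 0.048,
               spike_copies = 1.2e7,
               recovery_cv = 0.3,
               copies_sdlog = 0.8,
               mature_mean_control = 4.2e7,
               precursor_mean = 8e7,
               stable_mean = 2.5e8)
  unknown <- setdiff(names(qpcr), names(qdef))
  if (length(unknown)) {
    stop2("unknown qpcr parameter(s): ", paste(unknown, collapse = ", "))
  }
  qdef[names(qpcr)] <- qpcr
  spec <- list(n_mirnas = as.integer(n_mirnas),
               n_control = as.integer(n_control),
               n_case = as.integer(n_case),
               lib_size_mean = lib_size_mean,
               nb_dispersion = nb_dispersion,
               de_targets = de_targets,
               isomir_profile = isomir_profile,
               adapter = normalise_dna(adapter),
               mature_len = as.integer(mature_len),
               read_length = as.integer(read_length),
               qpcr = qdef,
               seed = as.integer(seed))
  if (abs(sum(spec$isomir_profile$fraction) - 1) > 1e-8) {
    stop2("isomir_profile fractions must sum to 1")
  }
  if (any(spec$de_targets$fold_change <= 0)) {
    stop2("fold_change must be positive")
  }
  if (qdef$enrichment_recovery <= 0 || qdef$enrichment_recovery > 1) {
    stop2("enrichment_recovery must lie in (0, 1]")
  }
  if (qdef$slope >= 0) stop2("qpcr slope must be negative")
  class(spec) <- "sim_spec"
  spec
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

#' Simulate a mature/precursor reference set
#'
#' Generates `n_mirnas` random mature sequences; each differential-
#' expression target additionally receives a precursor containing its
#' mature sequence as an exact substring (8 nt of 5' flank, 30 nt of 3'
#' flank). Deterministic under the spec seed.
#'
#' @param spec A [sim_spec()] object.
#' @return A `reference_set` data.frame.
#' @export
simulate_reference <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"), spec$n_mirnas >= 1L)
  with_seed(spec$seed + 101L, {
    ids <- sprintf("mir-sim-%03d", seq_len(spec$n_mirnas))
    mat <- random_dna(spec$n_mirnas, spec$mature_len)
    while (anyDuplicated(mat)) {  # vanishingly unlikely at 22 nt
      mat[duplicated(mat)] <- random_dna(sum(duplicated(mat)),
                                         spec$mature_len)
    }
    ref <- data.frame(ref_id = ids, sequence = mat, kind = "mature",
                      stringsAsFactors = FALSE)
    tgt <- intersect(spec$de_targets$ref_id, ids)
    if (length(tgt)) {
      i <- match(tgt, ids)
      pre <- paste0(random_dna(length(i), 8L), mat[i],
                    random_dna(length(i), 30L))
      ref <- rbind(ref, data.frame(ref_id = tgt, sequence = pre,
                                   kind = "precursor",
                                   stringsAsFactors = FALSE))
    }
    as_reference_set(ref)
  })
}

# Whole-blood-like abundance weights: the last three reference miRNAs take
# 60%, 13% and 3% of reads (keeping differential-expression targets, by
# convention the low-numbered ids, at moderate abundance) and the rest
# share the remainder equally.
abundance_weights <- function(n) {
  if (n < 4L) return(rep(1 / n, n))
  w <- rep(0.24 / (n - 3L), n)
  w[n] <- 0.60
  w[n - 1L] <- 0.13
  w[n - 2L] <- 0.03
  w
}

#' Simulate small-RNA read libraries and the true count table
#'
#' Per-sample counts for each miRNA are drawn negative-binomially with
#' group-specific means (`case mean = control mean / fold_change` for
#' targets). Each read is emitted as a canonical or isomiR variant of its
#' mature sequence per the isomiR profile, with the 3' adapter appended and
#' the result truncated to the read length.
#'
#' @param spec A [sim_spec()] object.
#' @param reference Reference set from [simulate_reference()].
#' @param out_dir If non-`NULL`, per-sample FASTQ files plus a truth-count
#'   TSV and sample sheet are written here.
#' @param emit_reads Set `FALSE` to skip building read sequences and return
#'   only the truth counts (fast path for count-level simulations).
#' @return A list: `truth` (miRNA x sample integer matrix of true counts),
#'   `sample_sheet` (data.frame `sample_id`, `group`), `reads` (named list
#'   of character vectors, when emitted in memory), `files` (FASTQ paths,
#'   when written).
#' @export
simulate_reads <- function(spec, reference, out_dir = NULL,
                           emit_reads = TRUE) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed + 202L, {
    mat <- reference[reference$kind == "mature", , drop = FALSE]
    n <- nrow(mat)
    samples <- c(sprintf("ctrl_%02d", seq_len(spec$n_control)),
                 sprintf("case_%02d", seq_len(spec$n_case)))
    groups <- rep(c("control", "case"), c(spec$n_control, spec$n_case))

    mu <- abundance_weights(n) * spec$lib_size_mean
    mu_mat <- matrix(mu, n, length(samples),
                     dimnames = list(mat$ref_id, samples))
    for (k in seq_len(nrow(spec$de_targets))) {
      rid <- spec$de_targets$ref_id[k]
      if (rid %in% mat$ref_id) {
        mu_mat[rid, groups == "case"] <-
          mu_mat[rid, groups == "case"] / spec$de_targets$fold_change[k]
      }
    }
    truth <- mu_mat
    truth[] <- if (spec$nb_dispersion > 0) {
      stats::rnbinom(length(mu_mat), size = 1 / spec$nb_dispersion,
                     mu = as.vector(mu_mat))
    } else {
      stats::rpois(length(mu_mat), as.vector(mu_mat))
    }
    storage.mode(truth) <- "integer"

    sheet <- data.frame(sample_id = samples, group = groups,
                        stringsAsFactors = FALSE)
    out <- list(truth = truth, sample_sheet = sheet)
    if (!emit_reads) return(out)

    variants <- variant_sequences(spec, reference)  # miRNA x variant reads
    reads <- vector("list", length(samples))
    names(reads) <- samples
    nv <- nrow(spec$isomir_profile)
    for (s in seq_along(samples)) {
      per <- character(0)
      cnt <- truth[, s]
      pos <- which(cnt > 0L)
      if (length(pos)) {
        split_counts <- vapply(pos, function(i) {
          stats::rmultinom(1L, cnt[i], spec$isomir_profile$fraction)[, 1L]
        }, integer(nv))
        per <- rep(as.vector(variants[, pos]), as.vector(split_counts))
        per <- sample(per)  # shuffle read order within the library
      }
      reads[[s]] <- per
    }

    if (is.null(out_dir)) {
      out$reads <- reads
    } else {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      files <- character(length(samples))
      names(files) <- samples
      for (s in samples) {
        files[s] <- file.path(out_dir, paste0(s, ".fastq"))
        write_fastq(reads[[s]], files[s], prefix = s)
      }
      write_count_matrix(truth, file.path(out_dir, "truth_counts.tsv"))
      utils::write.table(sheet, file.path(out_dir, "sample_sheet.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$files <- files
    }
    out
  })
}

# One read string per (variant, miRNA): variant insert + adapter, truncated
# to the read length. Extension bases are templated from the precursor
# context when available ('N' context falls back to a non-templated 'A').
variant_sequences <- function(spec, reference) {
  ctx <- reference_contexts(reference)
  nv <- nrow(spec$isomir_profile)
  v <- matrix("", nv, nrow(ctx))
  for (i in seq_len(nrow(ctx))) {
    for (k in seq_len(nv)) {
      o5 <- spec$isomir_profile$offset5[k]
      o3 <- spec$isomir_profile$offset3[k]
      lt <- ctx$mature_len[i] - o5 + o3
      ins <- substr(ctx$context[i], o5 + 3L, o5 + 3L + lt - 1L)
      ins <- gsub("N", "A", ins, fixed = TRUE)
      v[k, i] <- substr(paste0(ins, spec$adapter), 1L, spec$read_length)
    }
  }
  v
}

write_fastq <- function(reads, path, prefix = "read") {
  if (length(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  lines <- character(4L * length(reads))
  idx <- seq(1L, length(lines), by = 4L)
  lines[idx] <- sprintf("@%s_%06d", prefix, seq_along(reads))
  lines[idx + 1L] <- reads
  lines[idx + 2L] <- "+"
  lines[idx + 3L] <- strrep("I", nchar(reads))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate per-sample true copy numbers for qPCR assays
#'
#' Between-sample biological variation is log-normal with log-SD
#' `copies_sdlog` around group means: the target assay's case mean is the
#' control mean divided by the (first) target fold change; the stable
#' control assay and the precursor pool are not dysregulated.
#'
#' @param spec A [sim_spec()] object.
#' @return Data.frame: `sample_id`, `group`, `assay_id`, `mature_copies`,
#'   `precursor_copies`.
#' @export
simulate_copies <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed + 303L, {
    q <- spec$qpcr
    samples <- c(sprintf("ctrl_%02d", seq_len(spec$n_control)),
                 sprintf("case_%02d", seq_len(spec$n_case)))
    groups <- rep(c("control", "case"), c(spec$n_control, spec$n_case))
    fc <- spec$de_targets$fold_change[1L]
    target <- spec$de_targets$ref_id[1L]
    sl <- q$copies_sdlog

    rln <- function(mean) {
      stats::rlnorm(length(samples), meanlog = log(mean) - sl^2 / 2,
                    sdlog = sl)
    }
    tgt_mean <- ifelse(groups == "case",
                       q$mature_mean_control / fc, q$mature_mean_control)
    rows <- rbind(
      data.frame(sample_id = samples, group = groups, assay_id = target,
                 mature_copies = stats::rlnorm(
                   length(samples), log(tgt_mean) - sl^2 / 2, sl),
                 precursor_copies = rln(q$precursor_mean),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = samples, group = groups,
                 assay_id = "mir-stable",
                 mature_copies = rln(q$stable_mean),
                 precursor_copies = rln(q$precursor_mean),
                 stringsAsFactors = FALSE))
    rownames(rows) <- NULL
    rows
  })
}

#' Simulate a Cq dataset: standard curves, samples and spike-in
#'
#' Cq values follow `intercept + slope * log10(effective copies)` plus
#' Gaussian replicate noise of SD `cq_sd`, in triplicate. Effective copies
#' per fraction:
#' \describe{
#'   \item{total}{`mature + precursor_fraction_total * precursor` (the
#'     mature assay cross-detects the precursor pool);}
#'   \item{enriched}{`enrichment_recovery * mature` only (size selection
#'     removes precursors but loses material).}
#' }
#' Every sample/fraction additionally receives a log-normal processing
#' recovery factor (CV `recovery_cv`) applied to all assays including the
#' spike-in, which is what spike-in normalisation corrects. Standard-curve
#' dilution series (10^4..10^9 copies, triplicate) are generated for every
#' assay and for the spike-in. Rows with non-positive effective copies are
#' omitted with a warning.
#'
#' @param spec A [sim_spec()] object.
#' @param copies Per-sample truth from [simulate_copies()].
#' @return A list: `cq` (Cq table incl. spike assay `aly-mir-159`),
#'   `standards` (dilution series data.frame), `truth` (the `copies`
#'   input).
#' @export
simulate_cq <- function(spec, copies = simulate_copies(spec)) {
  stopifnot(inherits(spec, "sim_spec"))
  q <- spec$qpcr
  with_seed(spec$seed + 404L, {
    cq_of <- function(eff_copies) {
      q$intercept + q$slope * log10(eff_copies) +
        stats::rnorm(length(eff_copies), 0, q$cq_sd)
    }
    assays <- c(unique(copies$assay_id), "aly-mir-159")
    standards <- do.call(rbind, lapply(assays, function(a) {
      pts <- rep(10^(4:9), each = 3L)
      data.frame(assay_id = a, copies = pts, cq = cq_of(pts),
                 stringsAsFactors = FALSE)
    }))

    key <- unique(copies[, c("sample_id", "group")])
    sl_rec <- sqrt(log(1 + q$recovery_cv^2))
    rows <- list()
    for (f in c("total", "enriched")) {
      h <- stats::rlnorm(nrow(key), -sl_rec^2 / 2, sl_rec)
      names(h) <- key$sample_id
      eff <- if (f == "total") {
        h[copies$sample_id] *
          (copies$mature_copies +
             q$precursor_fraction_total * copies$precursor_copies)
      } else {
        h[copies$sample_id] * q$enrichment_recovery * copies$mature_copies
      }
      spike_eff <- if (f == "total") h * q$spike_copies
                   else h * q$enrichment_recovery * q$spike_copies
      eff_all <- c(eff, spike_eff)
      meta <- data.frame(
        sample_id = c(copies$sample_id, key$sample_id),
        assay_id = c(copies$assay_id, rep("aly-mir-159", nrow(key))),
        stringsAsFactors = FALSE)
      ok <- eff_all > 0
      if (any(!ok)) {
        warn2(sum(!ok), " row(s) with non-positive copies omitted")
      }
      for (r in 1:3) {
        rows[[paste(f, r)]] <- data.frame(
          sample_id = meta$sample_id[ok], assay_id = meta$assay_id[ok],
          fraction = f, replicate = r, cq = cq_of(eff_all[ok]),
          stringsAsFactors = FALSE)
      }
    }
    cq <- do.call(rbind, rows)
    rownames(cq) <- NULL
    list(cq = validate_cq_table(cq), standards = standards, truth = copies)
  })
}
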