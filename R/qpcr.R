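# RT-qPCR absolute quantification: standard-curve fitting with
# amplification-efficiency QC, conversion of quantification cycles (Cq) to
# absolute copy numbers, spike-in based enrichment-process normalisation,
# enrichment-impact statistics and between-group comparison.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies) over a dilution series.
#' The amplification efficiency is `10^(-1/slope)` (fold amplification per
#' cycle; 2 is ideal); the curve passes QC when the efficiency lies
#' between 1.8 and 2.1.
#'
#' @param dilution Data.frame with columns `copies` and `cq` (one row per
#'   replicate measurement); an `assay_id` column, if present, labels the
#'   result.
#' @return A list of class `standard_curve`: `assay_id`, `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `qc_pass`, `cq_range`.
#' @export
fit_standard_curve <- function(dilution) {
  stopifnot(all(c("copies", "cq") %in% names(dilution)))
  if (any(dilution$copies <= 0)) stop2("dilution copies must be positive")
  conc <- unique(dilution$copies)
  if (length(conc) < 3L) stop2("need >= 3 distinct dilution concentrations")
  if (length(conc) < 6L) {
    warn2("fewer than 6 dilution points; curve may be unreliable")
  }
  fit <- stats::lm(cq ~ log10(copies), data = dilution)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # R^2 by hand: summary.lm() warns on the zero-residual fits that arise
  # from noise-free dilution series
  tss <- sum((dilution$cq - mean(dilution$cq))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  eff <- 10^(-1 / slope)
  # small epsilon so curves sitting numerically on the 1.8/2.1 bounds pass
  qc <- is.finite(eff) && slope < 0 &&
    eff >= 1.8 - 1e-9 && eff <= 2.1 + 1e-9
  if (slope >= 0) warn2("standard curve has non-negative slope; QC failed")
  structure(list(
    assay_id = if ("assay_id" %in% names(dilution)) dilution$assay_id[1L]
               else NA_character_,
    slope = slope, intercept = intercept,
    r_squared = r2,
    efficiency = eff, qc_pass = qc,
    cq_range = range(dilution$cq)
  ), class = "standard_curve")
}

#' Fit standard curves for every assay in a dilution series
#'
#' @param dilution Data.frame with columns `assay_id`, `copies`, `cq`.
#' @return Named list of `standard_curve` objects.
#' @export
fit_standard_curves <- function(dilution) {
  lapply(split(dilution, dilution$assay_id), fit_standard_curve)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve [%s]: Cq = %.3f %+.4f*log10(copies), R2 = %.4f\n",
    x$assay_id, x$intercept, x$slope, x$r_squared))
  cat(sprintf("  efficiency %.3f (QC %s)\n", x$efficiency,
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

#' Absolute quantification of Cq measurements
#'
#' Technical replicates are combined by arithmetic mean of Cq (log-domain
#' averaging) per (sample, assay, fraction); copies follow from the assay's
#' standard curve as `10^((mean_cq - intercept) / slope)`. Mean Cq outside
#' the curve's calibrated range is flagged as extrapolated.
#'
#' @param cq A validated Cq table (see [read_cq_table()]).
#' @param curves Named list of `standard_curve` objects (one per assay), or
#'   a single curve when `cq` holds one assay.
#' @param allow_qc_fail Quantify against curves that failed efficiency QC
#'   instead of erroring.
#' @return A quantification data.frame: `sample_id`, `assay_id`,
#'   `fraction`, `mean_cq`, `raw_copies`, `extrapolated`.
#' @export
quantify_cq <- function(cq, curves, allow_qc_fail = FALSE) {
  validate_cq_table(cq)
  if (inherits(curves, "standard_curve")) {
    curves <- stats::setNames(list(curves), unique(cq$assay_id)[1L])
  }
  missing <- setdiff(unique(cq$assay_id), names(curves))
  if (length(missing)) {
    stop2("no standard curve for assay(s): ", paste(missing, collapse = ", "))
  }
  for (a in unique(cq$assay_id)) {
    if (!curves[[a]]$qc_pass && !allow_qc_fail) {
      stop2("standard curve for '", a, "' failed efficiency QC; ",
            "set allow_qc_fail = TRUE to quantify anyway")
    }
  }
  agg <- stats::aggregate(cq ~ sample_id + assay_id + fraction, data = cq,
                          FUN = mean)
  names(agg)[names(agg) == "cq"] <- "mean_cq"
  agg$raw_copies <- NA_real_
  agg$extrapolated <- NA
  for (a in unique(agg$assay_id)) {
    cv <- curves[[a]]
    i <- agg$assay_id == a
    agg$raw_copies[i] <- 10^((agg$mean_cq[i] - cv$intercept) / cv$slope)
    agg$extrapolated[i] <- agg$mean_cq[i] < cv$cq_range[1L] |
      agg$mean_cq[i] > cv$cq_range[2L]
  }
  agg[order(agg$assay_id, agg$fraction, agg$sample_id), , drop = FALSE]
}

#' Spike-in enrichment-process normalisation
#'
#' An exogenous control miRNA spiked into every sample at a fixed
#' concentration tracks per-sample recovery through processing. Within each
#' RNA fraction, the median spike Cq across samples defines the expected
#' recovery; each sample's normalisation factor is
#' `NF = efficiency^(cq_sample - median_cq_fraction)`, so a sample whose
#' spike came up later than the median (poorer recovery) is scaled *up*.
#' Normalised copies are `raw_copies * NF`. Because medians are taken per
#' fraction, the factor corrects within-fraction recovery variation and
#' deliberately leaves the enrichment loss itself untouched.
#'
#' @param quant A quantification table from [quantify_cq()] (target assays).
#' @param spike_cq Cq table rows for the spike-in assay (replicates
#'   allowed), covering every sample/fraction present in `quant`.
#' @param efficiency Amplification efficiency of the spike-in assay
#'   (typically the fitted spike standard-curve efficiency).
#' @return `quant` with added columns `spike_cq`, `norm_factor`,
#'   `normalised_copies`; also carries the per-fraction spike medians as
#'   attribute `spike_medians`.
#' @export
spikein_normalise <- function(quant, spike_cq, efficiency = 2) {
  stopifnot(efficiency > 1)
  sp <- stats::aggregate(cq ~ sample_id + fraction, data = spike_cq,
                         FUN = mean)
  med <- tapply(sp$cq, sp$fraction, stats::median)
  key_q <- paste(quant$sample_id, quant$fraction)
  key_s <- paste(sp$sample_id, sp$fraction)
  idx <- match(key_q, key_s)
  if (any(is.na(idx))) {
    stop2("missing spike-in measurement for: ",
          paste(unique(key_q[is.na(idx)]), collapse = "; "))
  }
  quant$spike_cq <- sp$cq[idx]
  quant$norm_factor <- as.numeric(
    efficiency^(quant$spike_cq - med[quant$fraction]))
  quant$normalised_copies <- quant$raw_copies * quant$norm_factor
  attr(quant, "spike_medians") <- med
  quant
}

#' Impact of small-RNA enrichment on measured copy numbers
#'
#' For each assay present in both RNA fractions, reports the fold decrease
#' `mean(total copies) / mean(enriched copies)` with a Welch t-test
#' p-value for the fraction difference.
#'
#' @param quant Quantification table covering both fractions.
#' @param value_col Copies column to compare (`"raw_copies"` or
#'   `"normalised_copies"`).
#' @return Data.frame: `assay_id`, `mean_total`, `mean_enriched`,
#'   `fold_decrease`, `p`.
#' @export
enrichment_impact <- function(quant, value_col = "raw_copies") {
  out <- list()
  for (a in unique(quant$assay_id)) {
    tot <- quant[quant$assay_id == a & quant$fraction == "total",
                 value_col]
    enr <- quant[quant$assay_id == a & quant$fraction == "enriched",
                 value_col]
    if (length(tot) < 2L || length(enr) < 2L) {
      warn2("assay '", a, "' not present in both fractions; skipped")
      next
    }
    wt <- welch_t(tot, enr)
    out[[a]] <- data.frame(assay_id = a, mean_total = mean(tot),
                           mean_enriched = mean(enr),
                           fold_decrease = mean(tot) / mean(enr),
                           p = wt$p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signed fold change between groups
#'
#' Convention matching "fold change control to case" reporting: positive
#' `mean_case / mean_control` when expression is higher in cases, negative
#' `mean_control / mean_case` when lower (a decrease of x-fold prints as
#' -x).
#'
#' @param mean_control,mean_case Group means (positive).
#' @return Signed fold change; `+1`/`-1` bounds at equality (`+1`).
#' @export
signed_fold_change <- function(mean_control, mean_case) {
  if (mean_control <= 0 || mean_case <= 0) {
    stop2("group means must be positive for a fold change")
  }
  if (mean_case >= mean_control) mean_case / mean_control
  else -(mean_control / mean_case)
}

#' Between-group comparison of absolute copy numbers
#'
#' Per assay and fraction: group means, SDs, standard errors, a Welch
#' t-test p-value and the signed fold change (see [signed_fold_change()]).
#'
#' @param quant Quantification table.
#' @param groups Named vector mapping `sample_id` to `"control"`/`"case"`.
#' @param value_col Copies column to compare.
#' @return Data.frame with one row per (assay, fraction).
#' @export
group_compare <- function(quant, groups, value_col = "normalised_copies") {
  if (!value_col %in% names(quant)) value_col <- "raw_copies"
  out <- list()
  for (a in unique(quant$assay_id)) {
    for (f in unique(quant$fraction[quant$assay_id == a])) {
      q <- quant[quant$assay_id == a & quant$fraction == f, , drop = FALSE]
      g <- groups[q$sample_id]
      x <- q[[value_col]][g == "control"]
      y <- q[[value_col]][g == "case"]
      if (length(x) < 2L || length(y) < 2L) {
        stop2("each group needs >= 2 samples for assay '", a, "'")
      }
      wt <- welch_t(x, y)
      out[[paste(a, f)]] <- data.frame(
        assay_id = a, fraction = f,
        mean_control = mean(x), sd_control = stats::sd(x),
        se_control = stats::sd(x) / sqrt(length(x)),
        mean_case = mean(y), sd_case = stats::sd(y),
        se_case = stats::sd(y) / sqrt(length(y)),
        p = wt$p,
        fold_change = signed_fold_change(mean(x), mean(y)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
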