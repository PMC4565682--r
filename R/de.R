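# Consensus differential expression: Welch t-tests with Benjamini-Hochberg
# correction under RPKM, quantile and TMM normalisation; a transcript is
# called differentially expressed only when it is significant under all
# three. Also: the group-exclusive transcript rule, fold change, Cohen's d
# effect size and noncentral-t power.

#' Welch's two-sample t-test
#'
#' Unequal-variance t-statistic with Welch-Satterthwaite degrees of freedom
#' and a two-tailed p-value. Thin wrapper around [stats::t.test()] with the
#' zero-variance contract made explicit.
#'
#' @param x,y Numeric vectors (control, case), each of length >= 2.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop2("both groups have zero variance; the t-statistic is undefined")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Welch's t-test from group summary statistics
#'
#' @param mean1,sd1,n1 Control-group mean, SD and size.
#' @param mean2,sd2,n2 Case-group mean, SD and size.
#' @return A list with `t`, `df`, `p` (two-tailed).
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2L, n2 >= 2L)
  se1 <- sd1^2 / n1
  se2 <- sd2^2 / n2
  if (se1 + se2 == 0) stop2("both groups have zero variance")
  t <- (mean1 - mean2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1.
#' Delegates to [stats::p.adjust()] after validating the input range.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop2("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Row-wise Welch t over a values matrix given a two-level group factor.
# Degenerate rows (both group variances zero) get t = 0, p = 1 when the
# means agree and p = 0 otherwise.
welch_t_rows <- function(values, groups) {
  g1 <- groups == "control"
  g2 <- groups == "case"
  n1 <- sum(g1)
  n2 <- sum(g2)
  m1 <- rowMeans(values[, g1, drop = FALSE])
  m2 <- rowMeans(values[, g2, drop = FALSE])
  v1 <- row_vars(values[, g1, drop = FALSE])
  v2 <- row_vars(values[, g2, drop = FALSE])
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  if (any(zero)) {
    t[zero] <- ifelse(m1[zero] == m2[zero], 0, Inf * sign(m1 - m2)[zero])
    p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  }
  data.frame(t = t, df = df, p = p, row.names = rownames(values))
}

#' Consensus differential-expression test
#'
#' For each normalisation method, performs a per-transcript Welch t-test
#' between groups, Benjamini-Hochberg-adjusts the two-tailed p-values
#' across the tested transcript set, and ranks transcripts by ascending
#' p-value (ties broken by descending `|t|`, then transcript id). A
#' transcript's consensus verdict is `TRUE` iff its q-value is below
#' `alpha` under *all three* methods.
#'
#' @param counts CPM-filtered integer count matrix (transcripts x samples).
#' @param groups Character vector of `"control"`/`"case"` per sample.
#' @param lengths Per-transcript lengths in nt (for RPKM).
#' @param lib_sizes Per-sample library sizes.
#' @param config A [load_config()] object.
#' @return A data.frame with one row per transcript: per-method `t`, `p`,
#'   `q`, `rank` columns (prefixed `rpkm_`, `quantile_`, `tmm_`) and a
#'   logical `consensus` column.
#' @export
consensus_test <- function(counts, groups, lengths, lib_sizes = NULL,
                           config = load_config(quiet = TRUE)) {
  stopifnot(ncol(counts) == length(groups))
  if (any(table(factor(groups, c("control", "case"))) < 2L)) {
    stop2("each group needs at least 2 samples")
  }
  lib_sizes <- resolve_lib_sizes(counts, lib_sizes)
  norms <- normalise_all(counts, lengths, lib_sizes, config)
  out <- data.frame(transcript_id = rownames(counts),
                    stringsAsFactors = FALSE)
  sig <- matrix(NA, nrow(counts), length(norms))
  for (i in seq_along(norms)) {
    method <- names(norms)[i]
    wt <- welch_t_rows(norms[[i]]$values, groups)
    q <- bh_adjust(wt$p)
    rk <- integer(nrow(wt))
    rk[order(wt$p, -abs(wt$t), rownames(wt))] <- seq_len(nrow(wt))
    out[[paste0(method, "_t")]] <- wt$t
    out[[paste0(method, "_p")]] <- wt$p
    out[[paste0(method, "_q")]] <- q
    out[[paste0(method, "_rank")]] <- rk
    sig[, i] <- q < config$alpha
  }
  out$consensus <- rowSums(sig) == length(norms)
  out
}

#' Group-exclusive transcript rule
#'
#' Transcripts with all-zero raw counts in one group and nonzero counts in
#' the other are reported as group-exclusive only when their total count
#' reaches `min_total`; lower-total exclusives are dropped as likely
#' sequencing artifacts.
#'
#' @param counts Raw integer count matrix.
#' @param groups `"control"`/`"case"` per sample.
#' @param min_total Minimum total read count across all samples.
#' @return Data.frame of flagged transcripts with the group they are
#'   exclusive to and their total count.
#' @export
exclusive_rule <- function(counts, groups, min_total = 10L) {
  g1 <- groups == "control"
  g2 <- groups == "case"
  s1 <- rowSums(counts[, g1, drop = FALSE])
  s2 <- rowSums(counts[, g2, drop = FALSE])
  excl_case <- s1 == 0 & s2 > 0
  excl_ctrl <- s2 == 0 & s1 > 0
  total <- s1 + s2
  keep <- (excl_case | excl_ctrl) & total >= min_total
  data.frame(
    transcript_id = rownames(counts)[keep],
    exclusive_to = ifelse(excl_case[keep], "case", "control"),
    total_count = unname(total[keep]),
    stringsAsFactors = FALSE
  )
}

#' Effect size and power from group summaries
#'
#' Computes the control/case fold change, Cohen's d with the *average-SD*
#' denominator `d = (mean1 - mean2) / ((sd1 + sd2) / 2)` (the convention
#' this package standardises on; classical n-weighted pooling is available
#' via `sd_method = "pooled"`), and the power of a two-tailed two-sample
#' t-test at `alpha` using the exact noncentral t distribution with
#' noncentrality `d * sqrt(n1 n2 / (n1 + n2))` and `n1 + n2 - 2` degrees
#' of freedom.
#'
#' @param mean1,sd1,n1 Control-group summary.
#' @param mean2,sd2,n2 Case-group summary.
#' @param alpha Two-tailed significance level.
#' @param sd_method `"average"` (mean of the two SDs) or `"pooled"`
#'   (classical n-1-weighted pooled SD).
#' @return A list with `fold_change` (control/case), `d`, `power`.
#' @export
effect_and_power <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05,
                             sd_method = c("average", "pooled")) {
  sd_method <- match.arg(sd_method)
  stopifnot(n1 >= 2L, n2 >= 2L, sd1 > 0, sd2 > 0)
  if (mean2 == 0) stop2("case mean is zero; fold change undefined")
  denom <- switch(sd_method,
    average = (sd1 + sd2) / 2,
    pooled = sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)))
  d <- (mean1 - mean2) / denom
  list(fold_change = mean1 / mean2, d = d,
       power = t_test_power(d, n1, n2, alpha))
}

#' Power of the two-sample t-test via the noncentral t distribution
#'
#' @param d Standardised effect size.
#' @param n1,n2 Group sizes.
#' @param alpha Two-tailed significance level.
#' @return Rejection probability in `[0, 1]`; equals `alpha` at `d = 0`.
#' @export
t_test_power <- function(d, n1, n2, alpha = 0.05) {
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
}
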