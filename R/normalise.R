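# Expression filtering and the three normalisations feeding the consensus
# differential-expression test: RPKM (within-sample), quantile
# (distribution-equalising, full or upper-quartile scaling) and TMM
# (between-sample trimmed, precision-weighted log-ratio factors).
#
# Library sizes are the total cleaned read counts per sample, passed
# explicitly: column sums of the annotated matrix would double-count
# multi-mapped tags.

#' Counts-per-million expression filter
#'
#' Retains transcript g iff `counts[g, s] / lib_sizes[s] * 1e6 >= threshold`
#' in at least `min_samples` samples.
#'
#' @param counts Integer matrix, transcripts x samples.
#' @param lib_sizes Per-sample library sizes (cleaned read totals); defaults
#'   to the matrix `lib_sizes` attribute, else column sums.
#' @param threshold CPM threshold.
#' @param min_samples Minimum number of samples at or above the threshold.
#' @return The row-subset matrix (attributes preserved on `lib_sizes`).
#' @export
cpm_filter <- function(counts, lib_sizes = NULL, threshold = 1,
                       min_samples = 3L) {
  lib_sizes <- resolve_lib_sizes(counts, lib_sizes)
  cpm <- sweep(counts, 2L, lib_sizes, "/") * 1e6
  keep <- rowSums(cpm >= threshold) >= min_samples
  out <- counts[keep, , drop = FALSE]
  attr(out, "lib_sizes") <- lib_sizes
  out
}

resolve_lib_sizes <- function(counts, lib_sizes) {
  lib_sizes <- lib_sizes %||% attr(counts, "lib_sizes") %||% colSums(counts)
  if (any(lib_sizes <= 0)) stop2("library sizes must be positive")
  if (length(lib_sizes) != ncol(counts)) {
    stop2("lib_sizes length must equal the number of samples")
  }
  lib_sizes
}

#' RPKM normalisation
#'
#' `value[g, s] = counts[g, s] * 1e9 / (lengths[g] * lib_sizes[s])`. For
#' mature miRNAs the length is the mature reference length; being a
#' per-transcript constant it cancels from fold changes and t-statistics.
#'
#' @inheritParams cpm_filter
#' @param lengths Per-transcript lengths in nt (named or positional).
#' @return A `normalised_matrix` list: `method`, `values`.
#' @export
rpkm_normalise <- function(counts, lengths, lib_sizes = NULL) {
  lib_sizes <- resolve_lib_sizes(counts, lib_sizes)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts) || any(is.na(lengths))) {
    stop2("a length is required for every transcript")
  }
  v <- counts * 1e9 / outer(as.numeric(lengths), as.numeric(lib_sizes))
  dimnames(v) <- dimnames(counts)
  structure(list(method = "rpkm", values = v), class = "normalised_matrix")
}

#' Quantile normalisation
#'
#' `mode = "full"`: each sample's order statistics are replaced by the
#' cross-sample mean of order statistics; tied values receive the average
#' of the quantiles they span. `mode = "upper_quartile"`: each sample is
#' divided by a scale factor equal to its 75th percentile of *nonzero*
#' counts over the geometric mean of those percentiles, so upper quartiles
#' are equalised without reshaping the distributions.
#'
#' @inheritParams cpm_filter
#' @param mode `"full"` or `"upper_quartile"`.
#' @return A `normalised_matrix` list: `method`, `values` (and
#'   `scale_factors` for upper-quartile mode).
#' @export
quantile_normalise <- function(counts, mode = c("full", "upper_quartile")) {
  mode <- match.arg(mode)
  if (ncol(counts) < 2L) stop2("quantile normalisation needs >= 2 samples")
  if (any(colSums(counts != 0) == 0L)) {
    stop2("a sample with all-zero counts has no quantiles to normalise")
  }
  if (mode == "full") {
    target <- rowMeans(apply(counts, 2L, sort))
    v <- counts
    for (j in seq_len(ncol(counts))) {
      col <- counts[, j]
      y <- numeric(length(col))
      y[order(col)] <- target
      v[, j] <- stats::ave(y, col, FUN = mean)  # average quantiles over ties
    }
    structure(list(method = "quantile", values = v),
              class = "normalised_matrix")
  } else {
    q75 <- apply(counts, 2L, function(col) {
      stats::quantile(col[col > 0], 0.75, names = FALSE)
    })
    f <- q75 / geometric_mean(q75)
    v <- sweep(counts, 2L, f, "/")
    structure(list(method = "quantile", values = v, scale_factors = f),
              class = "normalised_matrix")
  }
}

#' TMM scale factors
#'
#' Trimmed mean of M-values between each sample and a reference sample (the
#' one whose 75th percentile of scaled counts is closest to the mean across
#' samples). Over transcripts with nonzero counts in both samples, the
#' log2 ratio `M` and average log2 abundance `A` are computed; the extreme
#' `trim_m` of M-values and `trim_a` of A-values (each side) are discarded;
#' the factor is 2 to the inverse-variance weighted mean of the surviving
#' M-values, using the delta-method binomial precision weights. Factors are
#' rescaled to geometric mean 1.
#'
#' @inheritParams cpm_filter
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @return Numeric vector of per-sample scale factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, lib_sizes = NULL, trim_m = 0.30,
                        trim_a = 0.05) {
  lib_sizes <- resolve_lib_sizes(counts, lib_sizes)
  if (ncol(counts) < 2L) stop2("TMM needs >= 2 samples")
  # Reference sample: 75th percentile of scaled counts closest to the mean.
  f75 <- vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j] / lib_sizes[j], 0.75, names = FALSE)
  }, 0)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib_sizes[j], lib_sizes[ref],
             trim_m, trim_a)
  }, 0)
  f <- f / geometric_mean(f)
  names(f) <- colnames(counts)
  f
}

tmm_pair <- function(obs, ref, n_o, n_r, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- as.numeric(obs[keep])
  ref <- as.numeric(ref[keep])
  m <- log2((obs / n_o) / (ref / n_r))
  a <- (log2(obs / n_o) + log2(ref / n_r)) / 2
  v <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
  if (length(m) == 0L || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m)
  ra <- rank(a)
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (sum(sel) < 10L) {
    warn2("fewer than 10 transcripts survive the TMM trims; ",
          "using the untrimmed weighted mean")
    sel <- rep(TRUE, n)
  }
  f <- sum(m[sel] / v[sel]) / sum(1 / v[sel])
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM-normalised expression values
#'
#' `value[g, s] = counts[g, s] / (lib_sizes[s] * factors[s]) * 1e6`, i.e.
#' CPM on TMM-adjusted effective library sizes.
#'
#' @inheritParams tmm_factors
#' @return A `normalised_matrix` list: `method`, `values`, `scale_factors`.
#' @export
tmm_normalise <- function(counts, lib_sizes = NULL, trim_m = 0.30,
                          trim_a = 0.05) {
  lib_sizes <- resolve_lib_sizes(counts, lib_sizes)
  f <- tmm_factors(counts, lib_sizes, trim_m, trim_a)
  v <- sweep(counts, 2L, lib_sizes * f, "/") * 1e6
  structure(list(method = "tmm", values = v, scale_factors = f),
            class = "normalised_matrix")
}

#' Normalise a count matrix under all three methods
#'
#' @inheritParams cpm_filter
#' @param lengths Per-transcript lengths (for RPKM).
#' @param config A [load_config()] object (quantile mode, TMM trims).
#' @return Named list of `normalised_matrix` objects: `rpkm`, `quantile`,
#'   `tmm`.
#' @export
normalise_all <- function(counts, lengths, lib_sizes = NULL,
                          config = load_config(quiet = TRUE)) {
  lib_sizes <- resolve_lib_sizes(counts, lib_sizes)
  list(
    rpkm = rpkm_normalise(counts, lengths, lib_sizes),
    quantile = quantile_normalise(counts, config$quantile_mode),
    tmm = tmm_normalise(counts, lib_sizes, config$tmm_trim_m,
                        config$tmm_trim_a)
  )
}
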