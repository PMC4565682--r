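# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-derivations from first principles; they must never
# call the package functions they are used to check.

# Benjamini-Hochberg step-up by direct definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, mapped back to input order.
bh_step_up_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Naive isomiR matcher: enumerate every placement with substr() and
# character comparison. `precursor` (optional) must contain `mature`.
brute_match_oracle <- function(tag, mature, precursor = NULL,
                               max_shift = 2, max_mismatch = 1) {
  lm_ <- nchar(mature)
  lt <- nchar(tag)
  # coordinates of mature within an (optional) precursor
  ctx <- mature
  ctx_start <- 1
  if (!is.null(precursor)) {
    at <- regexpr(mature, precursor, fixed = TRUE)
    stopifnot(at > 0)
    ctx <- precursor
    ctx_start <- as.integer(at)
  }
  best <- NULL
  for (off5 in -max_shift:max_shift) {
    off3 <- off5 + lt - lm_
    if (abs(off3) > max_shift) next
    mm <- 0
    for (i in seq_len(lt)) {
      ref_pos <- ctx_start + off5 + i - 1  # position in ctx
      ref_base <- if (ref_pos >= 1 && ref_pos <= nchar(ctx)) {
        substr(ctx, ref_pos, ref_pos)
      } else {
        "?"  # no context: always a mismatch
      }
      if (ref_base != substr(tag, i, i)) mm <- mm + 1
    }
    if (mm <= max_mismatch) {
      cand <- c(off5, off3, mm)
      if (is.null(best) || mm < best[3] ||
          (mm == best[3] &&
           abs(off5) + abs(off3) < abs(best[1]) + abs(best[2]))) {
        best <- cand
      }
    }
  }
  best
}

# Random DNA strings for fixtures; `len` may be a vector (recycled to n).
rand_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = "")
  }, "")
}

# A small negative-binomial count matrix with no group effect.
null_nb_matrix <- function(n_transcripts, n_samples, mu_range = c(20, 2000),
                           size = 10) {
  mu <- exp(runif(n_transcripts, log(mu_range[1]), log(mu_range[2])))
  m <- matrix(rnbinom(n_transcripts * n_samples, size = size, mu = mu),
              n_transcripts, n_samples)
  rownames(m) <- sprintf("t%03d", seq_len(n_transcripts))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  m
}
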