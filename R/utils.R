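# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# DNA ingestion rule: upper-case and map RNA U to T so all matching happens
# in a single alphabet.
normalise_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

geometric_mean <- function(x) exp(mean(log(x)))

# Row-wise sample variance of a numeric matrix without apply() overhead.
# Clamped at zero: the sum-of-squares form can go slightly negative by
# round-off for constant rows.
row_vars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  pmax((rowSums(x * x) - n * m * m) / (n - 1), 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
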