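test_that("Welch t from summaries reproduces published-style statistics", {
  # group summaries: mean/SD pairs with n = 26 controls, 15 cases
  r1 <- welch_t_summary(845, 528, 26, 368, 379, 15)
  expect_equal(r1$t, 3.35, tolerance = 0.005)
  r2 <- welch_t_summary(3687, 1407, 26, 2141, 1190, 15)
  expect_equal(r2$t, 3.74, tolerance = 0.005)
  # agrees with stats::t.test on raw data
  set.seed(2)
  x <- rnorm(10, 5, 2)
  y <- rnorm(8, 3, 1)
  a <- welch_t(x, y)
  b <- welch_t_summary(mean(x), sd(x), 10, mean(y), sd(y), 8)
  expect_equal(a$t, b$t)
  expect_equal(a$df, b$df)
  expect_equal(a$p, b$p)
})

test_that("Welch t is antisymmetric in group order and errors on zero variance", {
  set.seed(4)
  x <- rnorm(6)
  y <- rnorm(9, 1)
  a <- welch_t(x, y)
  b <- welch_t(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_error(welch_t(rep(1, 3), rep(2, 4)), "zero variance")
  ident <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  for (len in 1:8) {
    for (rep in 1:25) {
      p <- round(runif(len), sample(c(1, 2, 3, 8), 1))  # force some ties
      expect_equal(bh_adjust(p), bh_step_up_oracle(p))
    }
  }
})

test_that("consensus requires significance under all three normalisations", {
  set.seed(71)
  m <- null_nb_matrix(40, 20, mu_range = c(100, 2000))
  groups <- rep(c("control", "case"), each = 10)
  # inject a strong true effect in one transcript
  m[1, groups == "case"] <- rnbinom(10, size = 10, mu = 3000)
  m[1, groups == "control"] <- rnbinom(10, size = 10, mu = 300)
  lens <- rep(22, 40)
  de <- consensus_test(m, groups, lens, colSums(m))
  expect_true(de$consensus[1])
  expect_true(all(de$consensus == (de$rpkm_q < 0.05 & de$quantile_q < 0.05 &
                                     de$tmm_q < 0.05)))
  # ranks are a permutation, 1-based by ascending p
  for (pref in c("rpkm", "quantile", "tmm")) {
    rk <- de[[paste0(pref, "_rank")]]
    expect_setequal(rk, seq_len(nrow(de)))
    expect_false(is.unsorted(de[[paste0(pref, "_p")]][order(rk)]))
  }
})

test_that("a transcript significant under a single method is not consensus", {
  set.seed(72)
  m <- null_nb_matrix(30, 12, mu_range = c(200, 800))
  groups <- rep(c("control", "case"), each = 6)
  de <- consensus_test(m, groups, rep(22, 30), colSums(m))
  single <- de$rpkm_q < 0.05 & !(de$quantile_q < 0.05 & de$tmm_q < 0.05)
  expect_true(all(!de$consensus[single]))
})

test_that("consensus type-I error stays at or below alpha on null data", {
  set.seed(73)
  n_sims <- 500
  false_pos <- 0L
  tested <- 0L
  for (i in seq_len(n_sims)) {
    m <- null_nb_matrix(40, 16, mu_range = c(50, 1000))
    groups <- rep(c("control", "case"), each = 8)
    de <- suppressWarnings(
      consensus_test(m, groups, rep(22, 40), colSums(m)))
    false_pos <- false_pos + sum(de$consensus)
    tested <- tested + nrow(de)
  }
  expect_lte(false_pos / tested, 0.05)
})

test_that("the exclusive-transcript rule applies the 10-read total threshold", {
  m <- rbind(reported = c(0L, 0L, 6L, 5L),
             too_few = c(0L, 0L, 5L, 4L),
             both_groups = c(1L, 0L, 8L, 7L),
             ctrl_only = c(9L, 3L, 0L, 0L))
  colnames(m) <- paste0("s", 1:4)
  groups <- c("control", "control", "case", "case")
  out <- exclusive_rule(m, groups, min_total = 10L)
  expect_setequal(out$transcript_id, c("reported", "ctrl_only"))
  expect_equal(out$exclusive_to[out$transcript_id == "reported"], "case")
  expect_equal(out$exclusive_to[out$transcript_id == "ctrl_only"], "control")
  expect_equal(out$total_count[out$transcript_id == "reported"], 11)
})

test_that("effect size and power reproduce the published-style table rows", {
  r <- effect_and_power(845, 528, 26, 368, 379, 15)
  expect_equal(r$fold_change, 2.3, tolerance = 0.005)
  expect_equal(r$d, 1.05, tolerance = 0.005)
  expect_equal(round(r$power, 2), 0.89)  # printed precision
  r2 <- effect_and_power(4137, 1532, 26, 2255, 896, 15)
  expect_equal(r2$d, 1.55, tolerance = 0.005)
  # equal means: d = 0 and power collapses to alpha
  r3 <- effect_and_power(100, 10, 26, 100, 12, 15)
  expect_equal(r3$d, 0)
  expect_equal(r3$power, 0.05)
  expect_error(effect_and_power(10, 1, 5, 0, 1, 5), "zero")
})

test_that("power is monotone in effect size and in each group size", {
  d_grid <- seq(0, 2, by = 0.25)
  pw <- vapply(d_grid, t_test_power, 0, n1 = 10, n2 = 10)
  expect_true(all(diff(pw) > 0))
  pw_neg <- vapply(-d_grid, t_test_power, 0, n1 = 10, n2 = 10)
  expect_equal(pw_neg, pw)  # two-tailed symmetry
  for (n_grid in list(cbind(5:15, 10), cbind(10, 5:15))) {
    pw_n <- mapply(t_test_power, n1 = n_grid[, 1], n2 = n_grid[, 2],
                   MoreArgs = list(d = 0.8))
    expect_true(all(diff(pw_n) > 0))
  }
})
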