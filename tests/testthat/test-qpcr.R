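# Noise-free dilution series for closed-form checks.
dilution_for <- function(slope, intercept, copies = 10^(3:8)) {
  data.frame(assay_id = "a", copies = copies,
             cq = intercept + slope * log10(copies),
             stringsAsFactors = FALSE)
}

test_that("standard-curve fitting recovers slope, efficiency and QC status", {
  sc <- fit_standard_curve(dilution_for(-3.3219, 38))
  expect_equal(sc$slope, -3.3219, tolerance = 1e-6)
  expect_equal(sc$efficiency, 2, tolerance = 1e-4)
  expect_equal(sc$r_squared, 1)
  expect_true(sc$qc_pass)
  # efficiency 1.8 boundary still passes; 2.51 fails
  expect_true(fit_standard_curve(dilution_for(-1 / log10(1.8), 38))$qc_pass)
  expect_false(suppressWarnings(
    fit_standard_curve(dilution_for(-2.5, 38)))$qc_pass)
  expect_false(suppressWarnings(
    fit_standard_curve(dilution_for(3.3, 38)))$qc_pass)
  expect_warning(fit_standard_curve(dilution_for(-3.3, 38, 10^(3:6))),
                 "fewer than 6")
  expect_error(fit_standard_curve(dilution_for(-3.3, 38, 10^(3:4))),
               ">= 3 distinct")
  expect_error(fit_standard_curve(
    data.frame(assay_id = "a", copies = c(0, 10), cq = c(30, 25))),
    "positive")
})

test_that("quantification inverts the curve: Cq at the intercept is one copy", {
  sc <- fit_standard_curve(dilution_for(-3.3219, 38))
  cq <- data.frame(sample_id = c("s1", "s2", "s3"), assay_id = "a",
                   fraction = "total", replicate = 1L,
                   cq = c(38, 38 + 3.3219, 38 - 3.3219),
                   stringsAsFactors = FALSE)
  q <- quantify_cq(cq, list(a = sc))
  q <- q[order(q$sample_id), ]
  expect_equal(q$raw_copies, c(1, 0.1, 10), tolerance = 1e-9)
  expect_true(q$extrapolated[q$sample_id == "s1"])  # below the curve range
})

test_that("replicates are averaged on the Cq scale before conversion", {
  sc <- fit_standard_curve(dilution_for(-3.3219, 38))
  cq <- data.frame(sample_id = "s1", assay_id = "a", fraction = "total",
                   replicate = 1:3, cq = c(20, 21, 22),
                   stringsAsFactors = FALSE)
  q <- quantify_cq(cq, list(a = sc))
  expect_equal(q$mean_cq, 21)
  expect_equal(q$raw_copies, 10^((21 - 38) / -3.3219))
})

test_that("quantification refuses a failed curve unless overridden", {
  bad <- suppressWarnings(fit_standard_curve(dilution_for(-2.5, 38)))
  cq <- data.frame(sample_id = "s1", assay_id = "a", fraction = "total",
                   replicate = 1L, cq = 25, stringsAsFactors = FALSE)
  expect_error(quantify_cq(cq, list(a = bad)), "QC")
  expect_silent(quantify_cq(cq, list(a = bad), allow_qc_fail = TRUE))
  expect_error(quantify_cq(cq, list(b = bad)), "no standard curve")
})

test_that("zero-noise simulation round-trips copies through quantification", {
  spec <- sim_spec(n_mirnas = 3, n_control = 4, n_case = 4, seed = 19,
                   qpcr = list(cq_sd = 0, recovery_cv = 0,
                               precursor_fraction_total = 0.4,
                               enrichment_recovery = 0.25))
  sim <- simulate_cq(spec)
  curves <- fit_standard_curves(sim$standards)
  q <- quantify_cq(sim$cq[sim$cq$assay_id != "aly-mir-159", ], curves)
  truth <- sim$truth
  key <- paste(q$sample_id, q$assay_id)
  tkey <- paste(truth$sample_id, truth$assay_id)
  expected_total <- truth$mature_copies + 0.4 * truth$precursor_copies
  expected_enr <- 0.25 * truth$mature_copies
  tot <- q$fraction == "total"
  expect_equal(q$raw_copies[tot],
               expected_total[match(key[tot], tkey)], tolerance = 1e-9)
  expect_equal(q$raw_copies[!tot],
               expected_enr[match(key[!tot], tkey)], tolerance = 1e-9)
})

test_that("spike-in normalisation is the identity at the median and doubles per cycle", {
  quant <- data.frame(sample_id = c("s1", "s2", "s3"), assay_id = "a",
                      fraction = "total", mean_cq = 25,
                      raw_copies = c(100, 100, 100),
                      stringsAsFactors = FALSE)
  spike <- data.frame(sample_id = c("s1", "s2", "s3"), assay_id = "spike",
                      fraction = "total", replicate = 1L,
                      cq = c(27, 28, 26), stringsAsFactors = FALSE)
  out <- spikein_normalise(quant, spike, efficiency = 2)
  # s1 sits at the median: unchanged; s2 one cycle later: doubled;
  # s3 one cycle earlier: halved
  expect_equal(out$normalised_copies, c(100, 200, 50))
  expect_error(spikein_normalise(quant, spike[1:2, ], 2), "missing spike")
})

test_that("spike-in normalisation reduces copy-number CV when recovery varies", {
  # conditions isolating the mechanism: strong per-sample recovery jitter,
  # little biological variation, near-noise-free Cq measurement
  spec <- sim_spec(n_mirnas = 3, n_control = 12, n_case = 12, seed = 23,
                   qpcr = list(cq_sd = 0.02, recovery_cv = 0.6,
                               copies_sdlog = 0.1))
  sim <- simulate_cq(spec)
  curves <- fit_standard_curves(sim$standards)
  q <- quantify_cq(sim$cq[sim$cq$assay_id != "aly-mir-159", ], curves)
  q <- spikein_normalise(q, sim$cq[sim$cq$assay_id == "aly-mir-159", ],
                         curves[["aly-mir-159"]]$efficiency)
  for (f in c("total", "enriched")) {
    sub <- q[q$assay_id == "mir-stable" & q$fraction == f, ]
    cv <- function(x) sd(x) / mean(x)
    expect_lt(cv(sub$normalised_copies), cv(sub$raw_copies))
  }
})

test_that("enrichment impact reports the fold decrease between fractions", {
  quant <- data.frame(
    sample_id = rep(paste0("s", 1:6), 2), assay_id = "a",
    fraction = rep(c("total", "enriched"), each = 6), mean_cq = 20,
    raw_copies = c(95, 100, 105, 98, 102, 100,
                   19, 20, 21, 19.6, 20.4, 20),
    stringsAsFactors = FALSE)
  imp <- enrichment_impact(quant)
  expect_equal(imp$fold_decrease, 5)
  expect_lt(imp$p, 0.01)
  same <- quant
  same$raw_copies <- rep(quant$raw_copies[1:6], 2)
  expect_equal(enrichment_impact(same)$fold_decrease, 1)
})

test_that("simulated enrichment impact approaches 1/recovery without precursor", {
  spec <- sim_spec(n_mirnas = 3, n_control = 15, n_case = 15, seed = 29,
                   qpcr = list(cq_sd = 0.05, recovery_cv = 0,
                               copies_sdlog = 0.3,
                               precursor_fraction_total = 0,
                               enrichment_recovery = 0.2))
  sim <- simulate_cq(spec)
  curves <- fit_standard_curves(sim$standards)
  q <- quantify_cq(sim$cq[sim$cq$assay_id != "aly-mir-159", ], curves)
  imp <- enrichment_impact(q)
  expect_equal(imp$fold_decrease[imp$assay_id == "mir-stable"], 5,
               tolerance = 0.15)
})

test_that("group comparison applies the signed fold-change convention", {
  expect_equal(signed_fold_change(1.53e8, 6.63e7), -2.3077, tolerance = 1e-3)
  expect_equal(signed_fold_change(4.24e7, 7.78e6), -5.4499, tolerance = 1e-3)
  expect_equal(signed_fold_change(100, 100), 1)
  expect_equal(signed_fold_change(50, 100), 2)
  expect_error(signed_fold_change(0, 10), "positive")

  quant <- data.frame(
    sample_id = rep(paste0("s", 1:8), 1), assay_id = "a",
    fraction = "enriched", mean_cq = 20,
    raw_copies = c(400, 410, 390, 405, 100, 95, 105, 98),
    stringsAsFactors = FALSE)
  groups <- setNames(rep(c("control", "case"), each = 4),
                     paste0("s", 1:8))
  gc <- group_compare(quant, groups, value_col = "raw_copies")
  expect_equal(gc$fold_change, -signed_fold_change(1, 4), tolerance = 0.02)
  expect_lt(gc$p, 0.001)
  expect_equal(gc$se_control, gc$sd_control / 2)
})
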