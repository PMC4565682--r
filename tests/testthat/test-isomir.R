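mature <- "AAAAGCTGGGTTGAGAGGGCTA"  # 22 nt

test_that("a tag identical to the mature sequence gets the null assignment", {
  hit <- match_tag(mature, mature)
  expect_equal(hit$offset5, 0L)
  expect_equal(hit$offset3, 0L)
  expect_equal(hit$mismatches, 0L)
})

test_that("a 3' A addition is accepted with offset3 = +1", {
  hit <- match_tag(paste0(mature, "A"), mature)
  expect_equal(hit$offset5, 0L)
  expect_equal(hit$offset3, 1L)
  expect_lte(hit$mismatches, 1L)  # non-templated without precursor context
  # with precursor context whose next base is A, the extension is templated
  pre <- paste0("GG", mature, "AG")
  hit2 <- match_tag(paste0(mature, "A"), mature, context = pre)
  expect_equal(hit2$mismatches, 0L)
})

test_that("shifts beyond two bases are rejected", {
  expect_null(match_tag(substr(mature, 4, 22), mature))   # 5' truncated by 3
  expect_null(match_tag(paste0("TTT", mature), mature))   # 5' extended by 3
  # exactly two is still allowed
  hit <- match_tag(substr(mature, 3, 22), mature)
  expect_equal(hit$offset5, 2L)
})

test_that("one internal mismatch is tolerated, two are not", {
  one <- mature
  substr(one, 10, 10) <- "C"
  expect_equal(match_tag(one, mature)$mismatches, 1L)
  two <- one
  substr(two, 15, 15) <- "A"
  expect_null(match_tag(two, mature))
})

test_that("annotation assigns multi-mapped tags fully to every match", {
  ref <- as_reference_set(data.frame(
    ref_id = c("x", "y", "z"),
    sequence = c(mature, mature, paste0(strrep("C", 11), strrep("G", 11))),
    kind = "mature"))
  tags <- matrix(5L, 1, 1, dimnames = list(mature, "s1"))
  ann <- annotate_tags(tags, ref)
  expect_equal(ann$counts["x", "s1"], 5L)
  expect_equal(ann$counts["y", "s1"], 5L)
  expect_equal(ann$counts["z", "s1"], 0L)
  expect_equal(nrow(ann$unannotated), 0L)
})

test_that("tags matching nothing land in the unannotated set", {
  ref <- as_reference_set(data.frame(
    ref_id = "x", sequence = mature, kind = "mature"))
  alien <- paste0(strrep("C", 10), strrep("G", 10))
  tags <- matrix(c(3L, 4L), 2, 1,
                 dimnames = list(c(alien, mature), "s1"))
  ann <- annotate_tags(tags, ref)
  expect_equal(rownames(ann$unannotated), alien)
  expect_equal(ann$counts["x", "s1"], 4L)
})

test_that("all assignments respect the offset and mismatch invariants", {
  set.seed(31)
  spec <- sim_spec(n_mirnas = 8, n_control = 3, n_case = 3,
                   lib_size_mean = 4000, seed = 13)
  ref <- simulate_reference(spec)
  sim <- simulate_reads(spec, ref)
  cfg <- load_config(quiet = TRUE)
  tl <- lapply(names(sim$reads), function(s)
    process_reads(sim$reads[[s]], cfg, s))
  names(tl) <- names(sim$reads)
  ann <- annotate_tags(tags_to_matrix(tl), ref)
  expect_true(all(abs(ann$assignments$offset5) <= 2))
  expect_true(all(abs(ann$assignments$offset3) <= 2))
  expect_true(all(ann$assignments$mismatches <= 1))
})

test_that("mismatch-free simulated libraries are recovered exactly", {
  spec <- sim_spec(n_mirnas = 10, n_control = 4, n_case = 4,
                   lib_size_mean = 5000, seed = 17)
  ref <- simulate_reference(spec)
  sim <- simulate_reads(spec, ref)
  cfg <- load_config(quiet = TRUE)
  tl <- lapply(names(sim$reads), function(s)
    process_reads(sim$reads[[s]], cfg, s))
  names(tl) <- names(sim$reads)
  ann <- annotate_tags(tags_to_matrix(tl), ref)
  expect_equal(ann$counts[rownames(sim$truth), colnames(sim$truth)],
               sim$truth)
  # composition report close to the emitted isomiR profile
  comp <- ann$composition
  expect_lt(max(abs(comp$canonical_fraction - 0.831)), 0.05)
})

test_that("the matcher agrees with a brute-force placement enumerator", {
  set.seed(41)
  for (rep in 1:3) {
    matures <- rand_dna(8, sample(20:23, 8, replace = TRUE))
    pres <- paste0(rand_dna(8, 5), matures, rand_dna(8, 5))
    use_pre <- runif(8) < 0.5
    # tags: perturbed copies of references plus random decoys
    tags <- character(0)
    for (i in 1:8) {
      m <- matures[i]
      tags <- c(tags, m,
                paste0(m, "A"),
                substr(m, 2, nchar(m)),
                substr(pres[i], 4, nchar(m) + 7),
                rand_dna(1, 21))
    }
    mut <- vapply(tags, function(t) {
      p <- sample(nchar(t), 1)
      substr(t, p, p) <- sample(c("A", "C", "G", "T"), 1)
      t
    }, "", USE.NAMES = FALSE)
    tags <- unique(c(tags, mut))
    tags <- tags[nchar(tags) >= 18 & nchar(tags) <= 25]

    for (i in 1:8) {
      ref <- data.frame(ref_id = "r", sequence = matures[i],
                        kind = "mature", stringsAsFactors = FALSE)
      pre_arg <- NULL
      if (use_pre[i]) {
        ref <- rbind(ref, data.frame(ref_id = "r", sequence = pres[i],
                                     kind = "precursor"))
        pre_arg <- pres[i]
      }
      ref <- as_reference_set(ref)
      ctx <- crossmir:::reference_contexts(ref)
      for (tag in tags) {
        mine <- match_tag(tag, matures[i], context = ctx$context[1])
        oracle <- brute_match_oracle(tag, matures[i], pre_arg)
        if (is.null(oracle)) {
          expect_null(mine)
        } else {
          expect_equal(unlist(mine, use.names = FALSE), oracle)
        }
      }
    }
  }
})
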