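test_that("hypothetical maximum is mean + multiplier * sample SD", {
  expect_equal(hypothetical_maximum(c(-1, 0, 1)), 6.0)
  expect_equal(hypothetical_maximum(c(0, 0, 0, 0, 4)), 0.8 + 6 * sqrt(3.2))
  expect_equal(round(hypothetical_maximum(c(0, 0, 0, 0, 4)), 4), 11.5331)
  expect_error(hypothetical_maximum(rep(0, 5)), "non-positive")
  expect_warning(hypothetical_maximum(c(2, 2, 2)), "SD is zero")
  expect_error(hypothetical_maximum(1), "at least 2")
})

test_that("the cutoff sweep runs 90..15 percent of H, most stringent first", {
  lv <- cutoff_levels(6.0)
  expect_equal(nrow(lv), 16)
  expect_equal(unlist(lv[1, ]), c(percent = 90, cutoff_value = 5.4))
  expect_equal(unlist(lv[16, ]), c(percent = 15, cutoff_value = 0.9))
  expect_equal(cutoff_levels(1.0)$cutoff_value, cutoff_levels(1.0)$percent / 100)
  one <- cutoff_levels(2, peak_call_params(cutoff_percent_max = 50,
                                           cutoff_percent_min = 50))
  expect_equal(nrow(one), 1)
  expect_equal(one$cutoff_value, 1.0)
  expect_warning(
    ragged <- cutoff_levels(1, peak_call_params(cutoff_percent_max = 90,
                                                cutoff_percent_min = 14)),
    "appending")
  expect_equal(utils::tail(ragged$percent, 1), 14)
})

test_that("the window rule needs >= 4 above-cutoff probes within 500 bp", {
  # four above probes at 100 bp spacing -> one peak spanning all four
  tr <- make_track(c(25, 125, 225, 325), rep(2, 4))
  pk <- detect_peaks_at_cutoff(tr, 1)
  expect_length(pk, 1)
  expect_equal(pk[[1]], 1:4)

  # only three above anywhere -> nothing
  tr <- make_track(c(25, 125, 225, 325), c(2, 2, 2, 0))
  expect_length(detect_peaks_at_cutoff(tr, 1), 0)

  # no 500-bp window holds four above probes
  tr <- make_track(c(50, 150, 250, 650), rep(2, 4))
  expect_length(detect_peaks_at_cutoff(tr, 1), 0)
})

test_that("windows never cross promoter boundaries", {
  tr <- probe_track(
    tibble::tibble(chrom = "chr1",
                   start = c(100, 200, 300, 400) - 25,
                   end = c(100, 200, 300, 400) + 25,
                   probe_id = sprintf("q%d", 1:4),
                   promoter_id = c("P1", "P1", "P2", "P2"),
                   log2_ratio = rep(2, 4)),
    "H3K4me3", "S", 1)
  expect_length(detect_peaks_at_cutoff(tr, 1), 0)
})

test_that("fast detection equals 1-bp brute-force window enumeration", {
  withr::local_seed(101)
  for (i in 1:60) {
    tr <- random_small_track(sample(5:30, 1))
    cutoff <- stats::runif(1, -0.2, 0.8)
    fast <- detect_peaks_at_cutoff(tr, cutoff)
    slow <- brute_force_detect(tr, cutoff)
    expect_identical(lapply(fast, as.integer), lapply(slow, as.integer),
                     info = sprintf("case %d", i))
  }
})

test_that("observed peak counts are monotone in cutoff stringency", {
  cfg <- small_config(n_promoters = 120)
  expt <- simulate_experiment(cfg)
  pk <- call_peaks(expt$tracks[["ICM/H3K4me3/1"]], peak_call_params(seed = 5))
  ft <- attr(pk, "fdr_table")
  expect_true(all(diff(ft$observed_count) >= 0))  # stringent first
  expect_true(all(ft$fdr >= 0 & ft$fdr <= 1, na.rm = TRUE))
})

test_that("peak members all exceed their detection cutoff", {
  cfg <- small_config(n_promoters = 120)
  expt <- simulate_experiment(cfg)
  tr <- expt$tracks[["ICM/H3K4me3/1"]]
  pk <- call_peaks(tr, peak_call_params(seed = 5))
  ft <- attr(pk, "fdr_table")
  h <- attr(pk, "hypothetical_maximum")
  for (r in seq_len(nrow(pk))) {
    members <- tr$log2_ratio[pk$first_probe[r]:pk$last_probe[r]]
    cut <- pk$best_cutoff_percent[r] / 100 * h
    expect_gt(pk$peak_score[r], cut)
    expect_gte(pk$n_probes[r], 4)
  }
})

test_that("per-level FDR is mean permuted count over observed count, capped", {
  cfg <- small_config(n_promoters = 200, seed = 21)
  expt <- simulate_experiment(cfg)
  pk <- call_peaks(expt$tracks[["ICM/H3K4me3/1"]], peak_call_params(seed = 5))
  ft <- attr(pk, "fdr_table")
  has <- ft$observed_count > 0
  expect_equal(ft$fdr[has],
               pmin(1, ft$mean_permuted_count[has] / ft$observed_count[has]))
  expect_true(all(is.na(ft$fdr[!has])))
})

test_that("a planted noise-free block yields exactly one near-zero-FDR peak", {
  withr::local_seed(55)
  mids <- seq(0, by = 125, length.out = 20)
  tracks <- lapply(sprintf("P%02d", 1:10), function(pid) {
    ratios <- rep(0, 20)
    if (pid == "P01") ratios[8:13] <- 1.5
    ratios + stats::rnorm(20, 0, 1e-6)   # break SD degeneracy only
  })
  tr <- probe_track(
    tibble::tibble(chrom = "chr1",
                   start = rep(mids, 10) + rep(seq(0, by = 5000, length.out = 10),
                                               each = 20) - 25,
                   end = rep(mids, 10) + rep(seq(0, by = 5000, length.out = 10),
                                             each = 20) + 25,
                   probe_id = sprintf("q%03d", 1:200),
                   promoter_id = rep(sprintf("P%02d", 1:10), each = 20),
                   log2_ratio = unlist(tracks)),
    "H3K4me3", "S", 1)
  pk <- call_peaks(tr, peak_call_params(seed = 9))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$promoter_id, "P01")
  expect_equal(pk$n_probes, 6)
  expect_lte(pk$fdr, 0.1)
})

test_that("peak calling is deterministic and empty input yields empty output", {
  cfg <- small_config(n_promoters = 80)
  expt <- simulate_experiment(cfg)
  tr <- expt$tracks[["TE/H3K27me3/1"]]
  p1 <- call_peaks(tr, peak_call_params(seed = 77))
  p2 <- call_peaks(tr, peak_call_params(seed = 77))
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_identical(attr(p1, "fdr_table"), attr(p2, "fdr_table"))

  empty <- probe_track(
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   probe_id = character(), promoter_id = character(),
                   log2_ratio = double()),
    "H3K4me3", "S", 1)
  expect_equal(nrow(call_peaks(empty)), 0)
})

test_that("tidy and glance summarise a peak-calling run", {
  cfg <- small_config(n_promoters = 80)
  expt <- simulate_experiment(cfg)
  pk <- call_peaks(expt$tracks[["ICM/H3K4me3/1"]], peak_call_params(seed = 2))
  td <- tidy(pk)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("promoter_id", "fdr", "best_cutoff_percent") %in% names(td)))
  gl <- glance(pk)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_peaks, nrow(pk))
})
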