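test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_promoters = 0), "n_promoters")
  expect_error(simulation_config(state_distribution = c(none = 0.7, K4 = 0.7,
                                                        K27 = 0, bivalent = 0)),
               "state_distribution")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(n_replicates = 4), "n_replicates")
  expect_error(simulation_config(
    cross_lineage_sharing = c(K4 = 0.2, K27 = 0.2, bivalent = 0.5)) |>
      assign_states(), "infeasible")
})

test_that("full sharing with identical marginals copies the mark sets", {
  cfg <- simulation_config(n_promoters = 500, seed = 11,
                           cross_lineage_sharing = c(K4 = 1, K27 = 1, bivalent = 1))
  truth <- assign_states(cfg)
  t1 <- truth[truth$lineage == "ICM", ]
  t2 <- truth[truth$lineage == "TE", ]
  expect_identical(t1$promoter_id[t1$k4], t2$promoter_id[t2$k4])
  expect_identical(t1$promoter_id[t1$k27], t2$promoter_id[t2$k27])
  expect_identical(t1$state, t2$state)
})

test_that("zero sharing yields disjoint planted mark sets", {
  cfg <- simulation_config(n_promoters = 1000, seed = 12,
                           cross_lineage_sharing = c(K4 = 0, K27 = 0, bivalent = 0))
  truth <- assign_states(cfg)
  t1 <- truth[truth$lineage == "ICM", ]
  t2 <- truth[truth$lineage == "TE", ]
  expect_length(intersect(t1$promoter_id[t1$k27], t2$promoter_id[t2$k27]), 0)
  expect_length(intersect(t1$promoter_id[t1$k4], t2$promoter_id[t2$k4]), 0)
})

test_that("planted sharing fraction matches the configured probability", {
  cfg <- simulation_config(n_promoters = 2000, seed = 13)
  truth <- assign_states(cfg)
  t1 <- truth[truth$lineage == "ICM", ]
  t2 <- truth[truth$lineage == "TE", ]
  k4_1 <- t1$promoter_id[t1$k4]
  shared <- length(intersect(k4_1, t2$promoter_id[t2$k4])) / length(k4_1)
  se <- sqrt(0.8 * 0.2 / length(k4_1))
  expect_lt(abs(shared - 0.80), 3 * se)
})

test_that("first-lineage state frequencies match the distribution within 3 SE", {
  cfg <- simulation_config(n_promoters = 2000, seed = 14)
  truth <- assign_states(cfg)
  t1 <- truth[truth$lineage == "ICM", ]
  p <- cfg$state_distribution
  for (st in names(p)) {
    freq <- mean(t1$state == st)
    se <- sqrt(p[[st]] * (1 - p[[st]]) / nrow(t1))
    expect_lt(abs(freq - p[[st]]), 3 * se + 1e-9)
  }
  # derived lineage: per-mark marginals are matched in expectation
  t2 <- truth[truth$lineage == "TE", ]
  for (frac in list(c(mean(t2$k4), 0.35), c(mean(t2$k27), 0.25))) {
    se <- sqrt(frac[2] * (1 - frac[2]) / nrow(t2))
    expect_lt(abs(frac[1] - frac[2]), 3 * se)
  }
})

test_that("noise-free tracks reproduce the planted signal geometry", {
  cfg <- simulation_config(n_promoters = 40, seed = 15, noise_sd = 0,
                           k4_center = -1125)   # places the peak on a probe
  prom <- simulate_promoters(cfg)
  truth <- assign_states(cfg)
  tr <- render_track(truth, cfg, prom, "ICM", "H3K4me3", 1)
  t1 <- truth[truth$lineage == "ICM", ]
  none_ids <- t1$promoter_id[t1$state == "none" | t1$state == "K27"]
  expect_true(all(tr$log2_ratio[tr$promoter_id %in% none_ids] == 0))
  k4_ids <- t1$promoter_id[t1$k4]
  if (length(k4_ids) > 0) {
    peak_vals <- vapply(k4_ids, function(id) {
      max(tr$log2_ratio[tr$promoter_id == id])
    }, double(1))
    # probe exactly at the Gaussian centre; the TSS dip there is ~4e-13
    expect_true(all(abs(peak_vals - cfg$signal_amplitude) < 1e-9))
  }
})

test_that("tracks are deterministic and replicate-stable under one seed", {
  cfg <- small_config()
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$tracks, e2$tracks)
  expect_identical(e1$truth, e2$truth)
  # adding a third replicate must not perturb replicates 1 and 2
  cfg3 <- small_config(n_replicates = 3)
  e3 <- simulate_experiment(cfg3)
  expect_identical(e3$tracks[["ICM/H3K4me3/1"]], e1$tracks[["ICM/H3K4me3/1"]])
  expect_identical(e3$tracks[["TE/H3K27me3/2"]], e1$tracks[["TE/H3K27me3/2"]])
})

test_that("replicates share planted signal and differ only in noise", {
  cfg <- small_config(noise_sd = 0)
  expt <- simulate_experiment(cfg)
  expect_equal(expt$tracks[["ICM/H3K4me3/1"]]$log2_ratio,
               expt$tracks[["ICM/H3K4me3/2"]]$log2_ratio)
})

test_that("X-chromosome assignment is binomial with the configured fraction", {
  cfg <- simulation_config(n_promoters = 5000, seed = 16)
  prom <- simulate_promoters(cfg)
  n_x <- sum(prom$chrom == "chrX")
  se <- sqrt(5000 * 0.04 * 0.96)
  expect_lt(abs(n_x - 200), 3 * se)
})

test_that("the expression matrix has one binary column per cell", {
  cfg <- small_config()
  expt <- simulate_experiment(cfg)
  expect_equal(ncol(expt$expression), 1 + cfg$n_cells)
  expect_equal(nrow(expt$expression), cfg$n_promoters)
  vals <- unlist(expt$expression[, -1])
  expect_true(all(vals %in% c(0L, 1L)))
})
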