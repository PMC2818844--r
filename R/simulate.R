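#' Synthetic promoter tiling-array experiments
#'
#' The generator emulates a RefSeq promoter tiling design: each promoter
#' is covered by evenly spaced probes across a -2000..+500 bp window
#' around its TSS, and each (lineage, mark, replicate) array reports a
#' log2 ChIP/input ratio per probe. Enrichment states
#' (none / K4 / K27 / bivalent) are planted per promoter and lineage;
#' probe-level signal is a Gaussian bump in TSS-relative coordinates
#' (H3K4me3 additionally carries a dip just at the TSS, mimicking the
#' nucleosome-depleted region), plus i.i.d. Gaussian replicate noise.
#' A binary single-cell expression matrix is generated from the planted
#' states. All randomness is organised into named substreams of one base
#' seed, so e.g. adding a replicate never changes existing tracks.
#'
#' @name synthetic-chipchip
NULL

.STATES <- c("none", "K4", "K27", "bivalent")

#' Build a simulation configuration
#'
#' Defaults define the reference study conditions: 2000 promoters with
#' 20 probes each at 125 bp spacing (covering -2000..+500 bp), state
#' frequencies 50/25/15/10% (none/K4/K27/bivalent), cross-lineage
#' sharing 0.80/0.34/0.22 (K4 mark / K27 mark / bivalent state), signal
#' amplitude 1.5 log2 units over noise SD 0.3, and a 20-cell binary
#' expression model with P(expressed | state) = 0.10/0.76/0.19/0.51.
#'
#' @param n_promoters Number of promoters on the array.
#' @param probes_per_promoter Probes tiled per promoter.
#' @param probe_spacing Distance between probe midpoints (bp).
#' @param probe_length Probe length in bp.
#' @param tile_upstream,tile_downstream Tiled window around the TSS (bp).
#' @param chrx_fraction Fraction of promoters assigned to the X chromosome.
#' @param lineages Character vector of sample names; states of lineages
#'   after the first are derived from the first via `cross_lineage_sharing`.
#' @param state_distribution Named probabilities over
#'   `c("none","K4","K27","bivalent")`; either one vector used for every
#'   lineage or a named list with one vector per lineage.
#' @param cross_lineage_sharing Named vector `c(K4=, K27=, bivalent=)`:
#'   probability that a first-lineage K4 mark, K27 mark, or full bivalent
#'   state is retained in a derived lineage.
#' @param signal_amplitude Planted peak height A (log2 units).
#' @param k4_center,k4_width H3K4me3 Gaussian center/SD (bp rel. TSS).
#' @param k27_center,k27_width H3K27me3 Gaussian center/SD (bp rel. TSS).
#' @param tss_dip_depth Depth of the TSS dip subtracted from planted
#'   H3K4me3 signal (log2 units; 150 bp SD).
#' @param noise_sd Per-probe replicate noise SD (log2 units; >= 0).
#' @param n_replicates Replicates per (lineage, mark): 2 or 3.
#' @param p_expressed Named vector: P(expressed | state) per lineage state.
#' @param p_detect_expressed,p_detect_silent Per-cell detection
#'   probability for expressed / silent genes.
#' @param n_cells Cells in the expression matrix.
#' @param seed Base seed for all substreams.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_promoters = 2000,
                              probes_per_promoter = 20,
                              probe_spacing = 125,
                              probe_length = 50,
                              tile_upstream = 2000,
                              tile_downstream = 500,
                              chrx_fraction = 0.04,
                              lineages = c("ICM", "TE"),
                              state_distribution = c(none = 0.50, K4 = 0.25,
                                                     K27 = 0.15, bivalent = 0.10),
                              cross_lineage_sharing = c(K4 = 0.80, K27 = 0.34,
                                                        bivalent = 0.22),
                              signal_amplitude = 1.5,
                              k4_center = -1150, k4_width = 400,
                              k27_center = -1000, k27_width = 500,
                              tss_dip_depth = 0.4,
                              noise_sd = 0.3,
                              n_replicates = 2,
                              p_expressed = c(none = 0.10, K4 = 0.76,
                                              K27 = 0.19, bivalent = 0.51),
                              p_detect_expressed = 0.7,
                              p_detect_silent = 0.02,
                              n_cells = 20,
                              seed = 1L) {
  cfg <- list(
    n_promoters = as.integer(n_promoters),
    probes_per_promoter = as.integer(probes_per_promoter),
    probe_spacing = probe_spacing,
    probe_length = probe_length,
    tile_upstream = tile_upstream,
    tile_downstream = tile_downstream,
    chrx_fraction = chrx_fraction,
    lineages = lineages,
    state_distribution = state_distribution,
    cross_lineage_sharing = cross_lineage_sharing,
    signal_amplitude = signal_amplitude,
    k4_center = k4_center, k4_width = k4_width,
    k27_center = k27_center, k27_width = k27_width,
    tss_dip_depth = tss_dip_depth,
    noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates),
    p_expressed = p_expressed,
    p_detect_expressed = p_detect_expressed,
    p_detect_silent = p_detect_silent,
    n_cells = as.integer(n_cells),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

.state_dist_for <- function(config, lineage) {
  sd <- config$state_distribution
  if (is.list(sd)) {
    if (is.null(sd[[lineage]])) {
      abort(sprintf("state_distribution has no entry for lineage '%s'", lineage))
    }
    sd <- sd[[lineage]]
  }
  sd[.STATES]
}

#' Validate a simulation configuration
#'
#' @param config A `simulation_config` list.
#' @return The config, invisibly checked; aborts with a configuration
#'   error message on any violated invariant.
#' @export
validate_simulation_config <- function(config) {
  need <- c("n_promoters", "probes_per_promoter", "probe_spacing",
            "state_distribution", "cross_lineage_sharing", "signal_amplitude",
            "noise_sd", "n_replicates", "lineages", "seed")
  miss <- need[!need %in% names(config)]
  if (length(miss) > 0) {
    abort(sprintf("configuration error: missing key(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (is.na(config$n_promoters) || config$n_promoters <= 0) {
    abort("configuration error: n_promoters must be a positive integer")
  }
  for (lin in config$lineages) {
    p <- .state_dist_for(config, lin)
    if (anyNA(p) || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8) {
      abort(sprintf(
        "configuration error: state_distribution for '%s' must be probabilities over %s summing to 1",
        lin, paste(.STATES, collapse = "/")))
    }
  }
  s <- config$cross_lineage_sharing
  if (anyNA(s[c("K4", "K27", "bivalent")]) || any(s < 0) || any(s > 1)) {
    abort("configuration error: cross_lineage_sharing needs K4, K27, bivalent in [0,1]")
  }
  if (config$noise_sd < 0) abort("configuration error: noise_sd must be >= 0")
  if (config$signal_amplitude <= 0) abort("configuration error: signal_amplitude must be > 0")
  if (!config$n_replicates %in% c(2L, 3L)) {
    abort("configuration error: n_replicates must be 2 or 3")
  }
  pe <- config$p_expressed[.STATES]
  if (anyNA(pe) || any(pe < 0) || any(pe > 1)) {
    abort("configuration error: p_expressed needs probabilities for all four states")
  }
  invisible(config)
}

#' Simulate promoter annotation for the synthetic array
#'
#' Promoters are spread over chr1..chr19 plus chrX (X membership is
#' Bernoulli with `chrx_fraction`), placed 10 kb apart along each
#' chromosome with random strand, so tiled windows never overlap.
#'
#' @param config A `simulation_config`.
#' @return A `promoter_set` tibble.
#' @export
simulate_promoters <- function(config) {
  n <- config$n_promoters
  .with_substream(config$seed, "promoters", code = {
    on_x <- stats::runif(n) < config$chrx_fraction
    chrom <- ifelse(on_x, "chrX", paste0("chr", sample.int(19, n, replace = TRUE)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    idx_in_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
    promoter_set(
      tibble(
        promoter_id = sprintf("P%05d", seq_len(n)),
        gene_id = sprintf("G%05d", seq_len(n)),
        chrom = chrom,
        strand = strand,
        tss = as.integer(10000 * idx_in_chrom + 5000)
      ),
      tile_upstream = config$tile_upstream,
      tile_downstream = config$tile_downstream)
  })
}

# Probe layout shared by every track of one experiment: midpoints at
# tile_start + i * spacing in TSS-relative coordinates (i = 0 .. p-1),
# mapped to the genome according to promoter strand.
.array_probes <- function(promoters, config) {
  p <- config$probes_per_promoter
  rel <- -config$tile_upstream + config$probe_spacing * (seq_len(p) - 1)
  half <- config$probe_length / 2
  grid <- tidyr::crossing(promoter_id = promoters$promoter_id, probe_i = seq_len(p)) |>
    dplyr::left_join(
      dplyr::select(as_tibble(promoters), "promoter_id", "chrom", "strand", "tss"),
      by = "promoter_id") |>
    dplyr::mutate(
      rel_mid = rel[.data$probe_i],
      gmid = ifelse(.data$strand == "+", .data$tss + .data$rel_mid,
                    .data$tss - .data$rel_mid),
      start = as.integer(.data$gmid - half),
      end = as.integer(.data$gmid + half),
      probe_id = sprintf("%s_p%02d", .data$promoter_id, .data$probe_i)
    )
  dplyr::select(grid, "chrom", "start", "end", "probe_id", "promoter_id", "rel_mid")
}

#' Plant per-lineage enrichment states and expression flags
#'
#' States of the first lineage are drawn from its `state_distribution`.
#' For every further lineage, first-lineage marks are retained with the
#' configured sharing probabilities (a bivalent promoter keeps both
#' marks with probability `sharing["bivalent"]`, and each single mark
#' with its own marginal sharing), and fresh enrichments are added only
#' on promoters carrying no first-lineage mark, at rates chosen so the
#' derived lineage's per-mark marginals match its state distribution in
#' expectation. Sharing fractions measured downstream therefore converge
#' exactly to the configured values.
#'
#' @param config A `simulation_config`.
#' @return Truth tibble: one row per promoter x lineage with columns
#'   `promoter_id`, `lineage`, `k4`, `k27`, `state`, `expressed`.
#' @export
assign_states <- function(config) {
  validate_simulation_config(config)
  n <- config$n_promoters
  ids <- sprintf("P%05d", seq_len(n))
  s4 <- config$cross_lineage_sharing[["K4"]]
  s27 <- config$cross_lineage_sharing[["K27"]]
  sb <- config$cross_lineage_sharing[["bivalent"]]
  if (sb > min(s4, s27) + 1e-9 || s4 + s27 - sb > 1 + 1e-9) {
    abort(paste("configuration error: infeasible cross_lineage_sharing:",
                "need bivalent <= min(K4, K27) and K4 + K27 - bivalent <= 1"))
  }

  lin1 <- config$lineages[[1]]
  p1 <- .state_dist_for(config, lin1)
  truth1 <- .with_substream(config$seed, "states", lin1, code = {
    state <- sample(.STATES, n, replace = TRUE, prob = p1)
    tibble(promoter_id = ids, lineage = lin1, state = state)
  })

  truths <- list(truth1)
  for (lin in config$lineages[-1]) {
    p2 <- .state_dist_for(config, lin)
    # expected retained mass per mark / per bivalent state
    p1_k4m <- p1[["K4"]] + p1[["bivalent"]]
    p1_k27m <- p1[["K27"]] + p1[["bivalent"]]
    pool <- p1[["none"]]
    m4 <- max(0, (p2[["K4"]] + p2[["bivalent"]]) - p1_k4m * s4)
    m27 <- max(0, (p2[["K27"]] + p2[["bivalent"]]) - p1_k27m * s27)
    b <- min(max(0, p2[["bivalent"]] - p1[["bivalent"]] * sb), m4, m27)
    if (pool <= 0 && (m4 > 0 || m27 > 0)) {
      abort("configuration error: infeasible sharing/marginal combination (no unmarked pool)")
    }
    f <- if (pool > 0) c(b, m4 - b, m27 - b) / pool else c(0, 0, 0)
    if (sum(f) > 1 + 1e-9) {
      abort("configuration error: infeasible sharing/marginal combination (fresh rate > 1)")
    }
    truths[[lin]] <- .with_substream(config$seed, "states", lin, code = {
      st1 <- truth1$state
      u <- stats::runif(n)
      k4 <- logical(n); k27 <- logical(n)
      i <- st1 == "K4"; k4[i] <- u[i] < s4
      i <- st1 == "K27"; k27[i] <- u[i] < s27
      i <- st1 == "bivalent"
      k4[i] <- u[i] < s4                      # total K4 retention s4
      k27[i] <- u[i] < sb | u[i] >= s4 & u[i] < s4 + (s27 - sb)
      i <- st1 == "none"                       # fresh enrichments
      k4[i] <- u[i] < f[1] + f[2]
      k27[i] <- u[i] < f[1] | (u[i] >= f[1] + f[2] & u[i] < sum(f))
      tibble(promoter_id = ids, lineage = lin,
             state = dplyr::case_when(k4 & k27 ~ "bivalent", k4 ~ "K4",
                                      k27 ~ "K27", TRUE ~ "none"))
    })
  }

  truth <- dplyr::bind_rows(truths) |>
    dplyr::mutate(k4 = .data$state %in% c("K4", "bivalent"),
                  k27 = .data$state %in% c("K27", "bivalent"))
  expressed <- .with_substream(config$seed, "expression-flags", code = {
    stats::runif(nrow(truth)) < config$p_expressed[truth$state]
  })
  truth$expressed <- expressed
  truth[, c("promoter_id", "lineage", "k4", "k27", "state", "expressed")]
}

# Planted mean signal (no noise) for one mark at TSS-relative position x.
.planted_signal <- function(x, has_mark, mark, config) {
  A <- config$signal_amplitude
  sig <- numeric(length(x))
  if (mark == "H3K4me3") {
    sig[has_mark] <- A * exp(-(x[has_mark] - config$k4_center)^2 / (2 * config$k4_width^2)) -
      config$tss_dip_depth * exp(-x[has_mark]^2 / (2 * 150^2))
  } else if (mark == "H3K27me3") {
    sig[has_mark] <- A * exp(-(x[has_mark] - config$k27_center)^2 / (2 * config$k27_width^2))
  } else {
    abort(sprintf("unknown mark '%s'", mark))
  }
  sig
}

#' Render one synthetic array track
#'
#' Probe ratios are the planted mean signal of the promoter's state for
#' this mark plus i.i.d. Normal(0, noise_sd^2) noise; replicates share
#' the planted signal and differ only in noise.
#'
#' @param truth Truth tibble from [assign_states()].
#' @param config A `simulation_config`.
#' @param promoters `promoter_set` from [simulate_promoters()].
#' @param lineage,mark,replicate Which track to render.
#' @return A `probe_track` tibble.
#' @export
render_track <- function(truth, config, promoters, lineage, mark, replicate) {
  if (!lineage %in% config$lineages) {
    abort(sprintf("unknown lineage '%s'", lineage))
  }
  if (!mark %in% c("H3K4me3", "H3K27me3")) {
    abort(sprintf("unknown mark '%s'", mark))
  }
  probes <- .array_probes(promoters, config)
  flags <- truth |>
    dplyr::filter(.data$lineage == !!lineage) |>
    dplyr::select("promoter_id", "k4", "k27")
  probes <- dplyr::left_join(probes, flags, by = "promoter_id")
  has <- if (mark == "H3K4me3") probes$k4 else probes$k27
  mu <- .planted_signal(probes$rel_mid, has, mark, config)
  eps <- .with_substream(config$seed, "track", lineage, mark, replicate, code = {
    stats::rnorm(nrow(probes), 0, config$noise_sd)
  })
  probes$log2_ratio <- mu + eps
  probe_track(dplyr::select(probes, dplyr::all_of(.TRACK_COLS)),
              mark, lineage, replicate)
}

#' Simulate a binary single-cell expression matrix
#'
#' Detection calls per cell are Bernoulli with `p_detect_expressed` for
#' genes expressed in the profiled lineage and `p_detect_silent`
#' otherwise, mimicking present/absent calls on single-cell arrays.
#'
#' @param truth Truth tibble from [assign_states()].
#' @param config A `simulation_config`.
#' @param lineage Lineage whose expression flags drive detection
#'   (default: first configured lineage).
#' @return Tibble `promoter_id` x `cell_01..cell_N` of 0/1 calls.
#' @export
simulate_expression <- function(truth, config, lineage = config$lineages[[1]]) {
  flags <- truth |>
    dplyr::filter(.data$lineage == !!lineage)
  n <- nrow(flags)
  p <- ifelse(flags$expressed, config$p_detect_expressed, config$p_detect_silent)
  mat <- .with_substream(config$seed, "expression-matrix", lineage, code = {
    matrix(stats::rbinom(n * config$n_cells, 1L, rep(p, config$n_cells)),
           nrow = n, ncol = config$n_cells)
  })
  colnames(mat) <- sprintf("cell_%02d", seq_len(config$n_cells))
  dplyr::bind_cols(tibble(promoter_id = flags$promoter_id), as_tibble(mat))
}

#' Simulate a complete ChIP-chip experiment
#'
#' Generates annotation, planted truth, every (lineage, mark, replicate)
#' probe track for H3K4me3 and H3K27me3, and a single-cell expression
#' matrix for the first lineage. Each component draws from its own named
#' RNG substream of `config$seed`.
#'
#' @param config A `simulation_config`.
#' @return A list of class `chip_experiment` with elements `config`,
#'   `promoters`, `truth`, `tracks` (named `"lineage/mark/replicate"`),
#'   and `expression`.
#' @export
simulate_experiment <- function(config) {
  validate_simulation_config(config)
  promoters <- simulate_promoters(config)
  truth <- assign_states(config)
  combos <- tidyr::crossing(lineage = config$lineages,
                            mark = c("H3K4me3", "H3K27me3"),
                            replicate = seq_len(config$n_replicates))
  tracks <- purrr::pmap(combos, function(lineage, mark, replicate) {
    render_track(truth, config, promoters, lineage, mark, replicate)
  })
  names(tracks) <- sprintf("%s/%s/%d", combos$lineage, combos$mark, combos$replicate)
  out <- list(config = config,
              promoters = promoters,
              truth = truth,
              tracks = tracks,
              expression = simulate_expression(truth, config))
  class(out) <- "chip_experiment"
  out
}

#' @export
print.chip_experiment <- function(x, ...) {
  cat(sprintf("<chip_experiment> %d promoters, lineages %s, %d tracks, seed %d\n",
              x$config$n_promoters, paste(x$config$lineages, collapse = "/"),
              length(x$tracks), x$config$seed))
  invisible(x)
}
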