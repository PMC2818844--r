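#' Sliding-window peak detection with randomization FDR
#'
#' Reimplementation of the promoter-array peak-calling procedure: peaks
#' are runs of four or more probes whose log2 ChIP/input ratios exceed a
#' cutoff within a 500-bp sliding window. Cutoffs are percentages (90%
#' down to 15%) of a hypothetical maximum `mean + 6 * SD` of all ratios
#' on the track, higher percentages being more stringent. The ratio data
#' are permuted across probe positions (20 randomizations by default)
#' and detection re-run at every cutoff level; the per-level false
#' discovery rate is the mean permuted peak count divided by the
#' observed peak count, and each observed peak is assigned the FDR of
#' the most stringent level at which it is detected.
#'
#' @name peak-caller
NULL

#' Peak-calling parameters
#'
#' @param window_bp Sliding-window width in bp (default 500).
#' @param min_probes Minimum above-cutoff probes per window (default 4).
#' @param sd_multiplier Multiplier on the ratio SD in the hypothetical
#'   maximum (default 6).
#' @param cutoff_percent_max,cutoff_percent_min,cutoff_percent_step
#'   Cutoff sweep as percentages of the hypothetical maximum: most
#'   stringent, least stringent, and step (defaults 90, 15, 5).
#' @param n_randomizations Number of genome-wide ratio permutations used
#'   for the FDR (default 20).
#' @param fdr_max FDR threshold used downstream for enrichment calls
#'   (default 0.1).
#' @param seed Seed for the permutation substreams.
#' @return A validated list of class `peak_call_params`.
#' @export
peak_call_params <- function(window_bp = 500, min_probes = 4, sd_multiplier = 6,
                             cutoff_percent_max = 90, cutoff_percent_min = 15,
                             cutoff_percent_step = 5, n_randomizations = 20,
                             fdr_max = 0.1, seed = 1L) {
  p <- list(window_bp = window_bp, min_probes = as.integer(min_probes),
            sd_multiplier = sd_multiplier,
            cutoff_percent_max = cutoff_percent_max,
            cutoff_percent_min = cutoff_percent_min,
            cutoff_percent_step = cutoff_percent_step,
            n_randomizations = as.integer(n_randomizations),
            fdr_max = fdr_max, seed = as.integer(seed))
  if (p$window_bp <= 0) abort("window_bp must be > 0")
  if (p$min_probes < 1) abort("min_probes must be >= 1")
  if (!(p$cutoff_percent_max >= p$cutoff_percent_min && p$cutoff_percent_min > 0)) {
    abort("need cutoff_percent_max >= cutoff_percent_min > 0")
  }
  if (p$n_randomizations < 1) abort("n_randomizations must be >= 1")
  if (!(p$fdr_max > 0 && p$fdr_max <= 1)) abort("fdr_max must be in (0, 1]")
  class(p) <- "peak_call_params"
  p
}

#' Hypothetical maximum of a track
#'
#' `H = mean(ratios) + sd_multiplier * SD(ratios)` with the sample
#' (n - 1) standard deviation; peak-calling cutoffs are percentages of H.
#'
#' @param ratios Numeric vector of all probe ratios of one track.
#' @param sd_multiplier SD multiplier (default 6).
#' @return The hypothetical maximum H (positive scalar).
#' @export
hypothetical_maximum <- function(ratios, sd_multiplier = 6) {
  if (length(ratios) < 2) abort("need at least 2 ratios")
  s <- stats::sd(ratios)
  h <- mean(ratios) + sd_multiplier * s
  if (h <= 0) abort("non-positive hypothetical maximum: cutoff sweep undefined")
  if (s == 0) warn("ratio SD is zero; hypothetical maximum equals the mean")
  h
}

#' Cutoff sweep levels
#'
#' Percent levels from most to least stringent; each cutoff value is
#' `percent / 100 * H`. If the step does not land exactly on the
#' minimum percentage, the minimum is appended as a final level with a
#' warning.
#'
#' @param h Hypothetical maximum (positive).
#' @param params A `peak_call_params` list.
#' @return Tibble with columns `percent`, `cutoff_value`, ordered most
#'   stringent first.
#' @export
cutoff_levels <- function(h, params = peak_call_params()) {
  if (h <= 0) abort("hypothetical maximum must be > 0")
  pct <- seq(params$cutoff_percent_max, params$cutoff_percent_min,
             by = -params$cutoff_percent_step)
  if (utils::tail(pct, 1) != params$cutoff_percent_min) {
    warn("cutoff step does not land on cutoff_percent_min; appending it as final level")
    pct <- c(pct, params$cutoff_percent_min)
  }
  tibble(percent = pct, cutoff_value = pct / 100 * h)
}

# Track geometry reused across cutoff levels and permutations: probe
# midpoints globalized to a strictly increasing coordinate (chromosomes
# offset by more than the window width) plus contiguous promoter-run
# block ids, so one findInterval per level implements the window rule
# without windows crossing chromosome or promoter boundaries.
.track_geometry <- function(track, window_bp) {
  n <- nrow(track)
  if (n == 0) {
    return(list(gpos = numeric(0), block = integer(0), n = 0L))
  }
  mid <- track$midpoint
  chrom_r <- rle(track$chrom)
  chrom_id <- rep(seq_along(chrom_r$lengths), chrom_r$lengths)
  span <- tapply(mid, chrom_id, max) + window_bp + 1
  offset <- c(0, cumsum(span))[chrom_id]
  gpos <- mid + offset
  prom_r <- rle(track$promoter_id)
  block <- rep(seq_along(prom_r$lengths), prom_r$lengths)
  list(gpos = gpos, block = block, n = n)
}

# Core window rule on prepared geometry. For each above-cutoff probe p,
# the window [pos(p), pos(p) + window_bp) is examined; if it holds >=
# min_probes above-cutoff probes of the same promoter, all become peak
# members; member sets sharing a probe are merged. Returns the merged
# peak count, or member index ranges (in track row indices).
.detect_core <- function(geom, ratios, cutoff, window_bp, min_probes,
                         count_only = FALSE) {
  above <- which(ratios > cutoff)
  empty <- if (count_only) 0L else list()
  if (length(above) < min_probes) return(empty)
  ap <- geom$gpos[above]
  ab <- geom$block[above]
  j_win <- findInterval(ap + window_bp - 0.5, ap)
  r <- rle(ab)
  j_blk <- rep(cumsum(r$lengths), r$lengths)
  j <- pmin(j_win, j_blk)
  k <- seq_along(above)
  qual <- which(j - k + 1L >= min_probes)
  if (length(qual) == 0) return(empty)
  je <- j[qual]
  run_end <- cummax(je)
  new_grp <- c(TRUE, qual[-1] > utils::head(run_end, -1))
  if (count_only) return(sum(new_grp))
  grp <- cumsum(new_grp)
  first <- qual[new_grp]
  last <- as.integer(tapply(je, grp, max))
  Map(function(s, e) above[s:e], first, last)
}

#' Detect candidate peaks at one cutoff
#'
#' Applies the >= `min_probes`-above-cutoff-in-`window_bp` rule ("above"
#' is strict `>`); windows are anchored at above-cutoff probe midpoints
#' and never cross promoter boundaries. Member sets sharing any probe
#' are merged into one candidate peak.
#'
#' @param track A `probe_track` tibble, sorted by `(chrom, start)`.
#' @param cutoff_value Ratio cutoff.
#' @param params A `peak_call_params` list.
#' @return List of integer vectors of member probe row indices, one per
#'   candidate peak (possibly empty).
#' @export
detect_peaks_at_cutoff <- function(track, cutoff_value, params = peak_call_params()) {
  geom <- .track_geometry(track, params$window_bp)
  .detect_core(geom, track$log2_ratio, cutoff_value, params$window_bp,
               params$min_probes)
}

.peaks_from_members <- function(track, members, percent, fdr) {
  purrr::map2_dfr(members, seq_along(members), function(idx, i) {
    tibble(chrom = track$chrom[idx[1]],
           start = min(track$start[idx]),
           end = max(track$end[idx]),
           promoter_id = track$promoter_id[idx[1]],
           n_probes = length(idx),
           best_cutoff_percent = percent,
           peak_score = max(track$log2_ratio[idx]),
           fdr = fdr,
           first_probe = idx[1],
           last_probe = idx[length(idx)])
  })
}

#' Permutation FDR over the cutoff sweep
#'
#' For each randomization the multiset of ratios is permuted uniformly
#' across all probe positions of the track and detection re-run at every
#' cutoff level. `FDR(level) = mean permuted peak count / observed peak
#' count`, capped at 1; levels with zero observed peaks get no FDR. Each
#' observed peak is reported once, at the most stringent level at which
#' it is detected, with that level's FDR.
#'
#' @param track A `probe_track` tibble.
#' @param params A `peak_call_params` list.
#' @return Tibble of peaks (class `peak_calls`) with columns `chrom`,
#'   `start`, `end`, `promoter_id`, `n_probes`, `best_cutoff_percent`,
#'   `peak_score`, `fdr`, plus `mark`, `sample`, `replicate`; the
#'   per-level FDR table is attached as attribute `fdr_table`
#'   (columns `percent`, `cutoff_value`, `observed_count`,
#'   `mean_permuted_count`, `fdr`).
#' @export
assign_fdr <- function(track, params = peak_call_params()) {
  h <- hypothetical_maximum(track$log2_ratio, params$sd_multiplier)
  levels <- suppressWarnings(cutoff_levels(h, params))
  geom <- .track_geometry(track, params$window_bp)
  ratios <- track$log2_ratio

  observed <- purrr::map(levels$cutoff_value, function(cv) {
    .detect_core(geom, ratios, cv, params$window_bp, params$min_probes)
  })
  obs_count <- lengths(observed)

  perm_counts <- matrix(0L, nrow = params$n_randomizations, ncol = nrow(levels))
  for (r in seq_len(params$n_randomizations)) {
    perm <- .with_substream(params$seed, "randomization", r, code = sample(ratios))
    stopifnot(identical(sort(perm), sort(ratios)))  # permutation preserves multiset
    perm_counts[r, ] <- vapply(levels$cutoff_value, function(cv) {
      .detect_core(geom, perm, cv, params$window_bp, params$min_probes,
                   count_only = TRUE)
    }, integer(1))
  }
  mean_perm <- colMeans(perm_counts)
  fdr_level <- ifelse(obs_count > 0, pmin(1, mean_perm / obs_count), NA_real_)

  fdr_table <- dplyr::bind_cols(levels,
                                tibble(observed_count = obs_count,
                                       mean_permuted_count = mean_perm,
                                       fdr = fdr_level))

  # report each peak once at its most stringent detection level
  covered <- logical(geom$n)
  out <- vector("list", nrow(levels))
  for (l in seq_len(nrow(levels))) {
    mem <- observed[[l]]
    if (length(mem) == 0) next
    fresh <- !vapply(mem, function(idx) any(covered[idx]), logical(1))
    for (idx in mem) covered[idx] <- TRUE
    if (any(fresh)) {
      out[[l]] <- .peaks_from_members(track, mem[fresh], levels$percent[l],
                                      fdr_level[l])
    }
  }
  peaks <- dplyr::bind_rows(out)
  if (nrow(peaks) == 0) {
    peaks <- tibble(chrom = character(), start = integer(), end = integer(),
                    promoter_id = character(), n_probes = integer(),
                    best_cutoff_percent = double(), peak_score = double(),
                    fdr = double(), first_probe = integer(), last_probe = integer())
  }
  peaks <- peaks |>
    dplyr::mutate(mark = track$mark[1] %||% NA_character_,
                  sample = track$sample[1] %||% NA_character_,
                  replicate = track$replicate[1] %||% NA_integer_) |>
    dplyr::arrange(.data$chrom, .data$start)
  attr(peaks, "fdr_table") <- fdr_table
  attr(peaks, "params") <- params
  attr(peaks, "hypothetical_maximum") <- h
  class(peaks) <- c("peak_calls", class(peaks))
  peaks
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Call peaks on a probe track
#'
#' Composition of [hypothetical_maximum()], [cutoff_levels()],
#' [detect_peaks_at_cutoff()] and [assign_fdr()]; deterministic given
#' `params$seed`. An empty track yields an empty result.
#'
#' @inheritParams assign_fdr
#' @return A `peak_calls` tibble (see [assign_fdr()]).
#' @export
call_peaks <- function(track, params = peak_call_params()) {
  if (nrow(track) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  promoter_id = character(), n_probes = integer(),
                  best_cutoff_percent = double(), peak_score = double(),
                  fdr = double(), first_probe = integer(), last_probe = integer(),
                  mark = character(), sample = character(), replicate = integer())
    attr(out, "fdr_table") <- tibble(percent = double(), cutoff_value = double(),
                                     observed_count = integer(),
                                     mean_permuted_count = double(), fdr = double())
    attr(out, "params") <- params
    class(out) <- c("peak_calls", class(out))
    return(out)
  }
  assign_fdr(track, params)
}

#' Write the per-level FDR table
#'
#' @param peaks A `peak_calls` tibble.
#' @param path Output TSV path.
#' @export
write_fdr_table <- function(peaks, path) {
  readr::write_tsv(attr(peaks, "fdr_table"), path)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy peak calls into a plain tibble
#'
#' @param x A `peak_calls` tibble.
#' @param ... Unused.
#' @return A plain tibble of peaks without attributes.
#' @method tidy peak_calls
#' @export
tidy.peak_calls <- function(x, ...) {
  out <- as_tibble(x)
  out[, c("chrom", "start", "end", "promoter_id", "n_probes",
          "best_cutoff_percent", "peak_score", "fdr", "mark", "sample",
          "replicate")]
}

#' One-row summary of a peak-calling run
#'
#' @param x A `peak_calls` tibble.
#' @param ... Unused.
#' @return Tibble with peak counts, the hypothetical maximum, and the
#'   number of cutoff levels.
#' @method glance peak_calls
#' @export
glance.peak_calls <- function(x, ...) {
  ft <- attr(x, "fdr_table")
  p <- attr(x, "params")
  tibble(n_peaks = nrow(x),
         n_peaks_fdr_le_max = sum(x$fdr <= (p$fdr_max %||% 0.1), na.rm = TRUE),
         hypothetical_maximum = attr(x, "hypothetical_maximum") %||% NA_real_,
         n_levels = nrow(ft),
         n_randomizations = p$n_randomizations %||% NA_integer_)
}
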