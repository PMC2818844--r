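# Independent brute-force oracles used to validate the fast implementations.

# MaxTen: literal maximum over all contiguous windows of `w` ratios.
brute_force_maxten <- function(r, w = 10) {
  n <- length(r)
  if (n < w) return(mean(r))
  max(vapply(seq_len(n - w + 1), function(i) mean(r[i:(i + w - 1)]), double(1)))
}

# Sliding-window peak detection by 1-bp enumeration of window starts,
# per promoter, followed by iterative merging of member sets that share
# a probe. Returns a list of sorted track row-index vectors.
brute_force_detect <- function(track, cutoff, window_bp = 500, min_probes = 4) {
  mem <- list()
  for (pid in unique(track$promoter_id)) {
    rows <- which(track$promoter_id == pid)
    mids <- track$midpoint[rows]
    above <- track$log2_ratio[rows] > cutoff
    if (sum(above) < min_probes) next
    for (s in (min(mids) - window_bp):max(mids)) {
      inwin <- which(mids >= s & mids < s + window_bp & above)
      if (length(inwin) >= min_probes) mem[[length(mem) + 1]] <- rows[inwin]
    }
  }
  merged <- list()
  for (m in mem) {
    repeat {
      hit <- which(vapply(merged, function(x) length(intersect(x, m)) > 0, logical(1)))
      if (length(hit) == 0) break
      m <- sort(unique(c(m, unlist(merged[hit]))))
      merged <- merged[-hit]
    }
    merged[[length(merged) + 1]] <- sort(unique(m))
  }
  merged[order(vapply(merged, min, numeric(1)))]
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, via binomial coefficients.
enum_fisher_p <- function(a, b, cc, d) {
  m <- a + b; n2 <- cc + d; k <- a + cc; N <- m + n2
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  supp <- max(0, k - n2):min(k, m)
  probs <- vapply(supp, function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(N, k))
  }, double(1))
  p_obs <- probs[supp == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A minimal single-chromosome probe track fixture from midpoints/ratios.
# Probes are 50-mers centred on the given midpoints.
make_track <- function(midpoints, ratios, promoter_id = "P1", chrom = "chr1",
                       mark = "H3K4me3", sample = "S", replicate = 1) {
  stopifnot(length(midpoints) == length(ratios))
  n <- length(midpoints)
  probe_track(
    tibble::tibble(chrom = chrom, start = midpoints - 25, end = midpoints + 25,
                   probe_id = sprintf("%s_q%03d", promoter_id, seq_len(n)),
                   promoter_id = promoter_id, log2_ratio = ratios),
    mark = mark, sample = sample, replicate = replicate)
}

# Random multi-promoter track for oracle comparisons (<= 30 probes).
random_small_track <- function(n_probes, n_promoters = sample(1:2, 1)) {
  gaps <- sample(30:200, n_probes, replace = TRUE)
  mids <- 1000 + cumsum(gaps)
  pid <- sort(sample(sprintf("P%d", seq_len(n_promoters)), n_probes, replace = TRUE))
  tr <- probe_track(
    tibble::tibble(chrom = "chr1", start = mids - 25, end = mids + 25,
                   probe_id = sprintf("q%03d", seq_len(n_probes)),
                   promoter_id = pid,
                   log2_ratio = stats::rnorm(n_probes, 0.2, 0.6)),
    mark = "H3K4me3", sample = "S", replicate = 1)
  tr
}

# Default test configuration, small enough for unit tests.
small_config <- function(...) {
  args <- list(n_promoters = 60, seed = 42)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}
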