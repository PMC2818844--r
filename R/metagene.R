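#' TSS-anchored metagene profiles
#'
#' A metagene profile averages probe ratios of a promoter class in bins
#' of TSS-relative position over the tiled window (default
#' -2000..+500 bp, 50-bp right-open bins). Positions are
#' strand-oriented: upstream of the TSS is negative on both strands.
#' Replicates are pooled, each probe observation weighted equally, and
#' each probe contributes wholly to the bin containing its midpoint.
#'
#' @name metagene
NULL

#' TSS-relative position of probes
#'
#' For plus-strand promoters `midpoint - tss`; for minus-strand
#' promoters `tss - midpoint`, so upstream is negative either way.
#'
#' @param probes Data frame with columns `promoter_id`, `midpoint` (or
#'   `start`/`end`, from which midpoints are derived).
#' @param promoters A `promoter_set` tibble covering all probe promoters.
#' @return Integer vector of TSS-relative positions, one per probe row.
#' @export
relative_position <- function(probes, promoters) {
  probes <- as_tibble(probes)
  if (!"midpoint" %in% names(probes)) {
    probes$midpoint <- floor((probes$start + probes$end) / 2)
  }
  ann <- as_tibble(promoters)[, c("promoter_id", "strand", "tss")]
  j <- match(probes$promoter_id, ann$promoter_id)
  if (anyNA(j)) {
    abort(sprintf("probe promoter_id(s) not in promoter set: %s",
                  paste(utils::head(unique(probes$promoter_id[is.na(j)]), 5),
                        collapse = ", ")))
  }
  rel <- ifelse(ann$strand[j] == "+",
                probes$midpoint - ann$tss[j],
                ann$tss[j] - probes$midpoint)
  up <- attr(promoters, "tile_upstream") %||% 2000
  down <- attr(promoters, "tile_downstream") %||% 500
  if (any(rel < -up | rel >= down)) {
    abort("probe midpoint outside the tiled window")
  }
  as.integer(rel)
}

#' Metagene profile of a promoter class
#'
#' Pools all probe observations of the given promoters across the
#' supplied replicate tracks and averages ratios per TSS-relative bin.
#'
#' @param tracks A `probe_track` tibble or list of them (replicates are
#'   pooled).
#' @param promoters A `promoter_set` tibble.
#' @param promoter_ids Character vector: the promoter class to profile.
#' @param bin_width Bin width in bp (default 50).
#' @param class_label Label stored with the profile.
#' @return Tibble of class `metagene_profile` with columns `class`,
#'   `bin_start_rel`, `bin_end_rel`, `mean_ratio`, `n_probes`; bins tile
#'   the window exactly and `mean_ratio` is `NA` where `n_probes` is 0.
#' @export
metagene_profile <- function(tracks, promoters, promoter_ids, bin_width = 50,
                             class_label = "class") {
  if (length(promoter_ids) == 0) abort("empty promoter class")
  if (is.data.frame(tracks)) tracks <- list(tracks)
  up <- attr(promoters, "tile_upstream") %||% 2000
  down <- attr(promoters, "tile_downstream") %||% 500
  edges <- seq(-up, down, by = bin_width)
  if (utils::tail(edges, 1) != down) {
    abort("bin_width must tile the promoter window exactly")
  }
  obs <- purrr::map_dfr(tracks, function(tr) {
    sub <- dplyr::filter(as_tibble(tr), .data$promoter_id %in% promoter_ids)
    if (nrow(sub) == 0) return(tibble(rel = integer(), ratio = double()))
    tibble(rel = relative_position(sub, promoters), ratio = sub$log2_ratio)
  })
  bin <- findInterval(obs$rel, edges, rightmost.closed = FALSE)
  n_bins <- length(edges) - 1
  counts <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(obs$ratio[bin == b]), double(1))
  out <- tibble(class = class_label,
                bin_start_rel = edges[-length(edges)],
                bin_end_rel = edges[-1],
                mean_ratio = ifelse(counts > 0, sums / pmax(counts, 1), NA_real_),
                n_probes = counts)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("metagene_profile", class(out))
  out
}

#' Null-peak promoter set
#'
#' Promoters whose probes all lie strictly below the minimal peak
#' detection cutoff (the 15% level of the hypothetical maximum); used as
#' the background class in metagene analysis.
#'
#' @param track A `probe_track` tibble.
#' @param min_cutoff_value The least-stringent cutoff value.
#' @return Character vector of promoter ids.
#' @export
null_peak_set <- function(track, min_cutoff_value) {
  if (nrow(track) == 0) return(character(0))
  track |>
    as_tibble() |>
    dplyr::group_by(.data$promoter_id) |>
    dplyr::summarise(all_below = all(.data$log2_ratio < min_cutoff_value),
                     .groups = "drop") |>
    dplyr::filter(.data$all_below) |>
    dplyr::pull("promoter_id")
}

#' Plot metagene profiles
#'
#' @param object A `metagene_profile` tibble (profiles of several
#'   classes may be row-bound first).
#' @param ... Unused.
#' @return A ggplot object: mean ratio vs bin midpoint, one line per
#'   class, TSS marked at 0.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(pos = (.data$bin_start_rel + .data$bin_end_rel) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$mean_ratio,
                                   colour = .data$class)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, colour = "red", linewidth = 0.3) +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "mean log2 ChIP/input", colour = NULL) +
    ggplot2::theme_minimal()
}
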