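#' Promoter scoring and chromatin-state classification
#'
#' Promoter-level quantities: the MaxTen amplification score (highest
#' mean of 10 consecutive probe ratios in genome order, averaged over
#' replicates) and the replicate-concordant enrichment call (at least
#' one peak at FDR <= 0.1 in both of 2, or two of 3, replicates), which
#' combine into the four-way promoter state
#' none / K4 / K27 / bivalent. MaxTen is diagnostic only and never gates
#' classification; calls are peak-based.
#'
#' @name promoter-state
NULL

#' MaxTen score of one promoter on one track
#'
#' Maximum over all windows of `window_probes` consecutive ratios (in
#' genome order) of the window mean. Promoters with fewer than
#' `window_probes` probes fall back to the mean of all their probes and
#' are flagged via the `"short_promoter"` attribute.
#'
#' @param ratios Probe ratios of one promoter, in genome order.
#' @param window_probes Window size in probes (default 10).
#' @return The MaxTen score, with logical attribute `"short_promoter"`.
#' @export
maxten <- function(ratios, window_probes = 10) {
  n <- length(ratios)
  if (n == 0) abort("maxten of an empty ratio vector is undefined")
  if (n < window_probes) {
    return(structure(mean(ratios), short_promoter = TRUE))
  }
  means <- vapply(seq_len(n - window_probes + 1), function(i) {
    mean(ratios[i:(i + window_probes - 1)])
  }, double(1))
  structure(max(means), short_promoter = FALSE)
}

#' Replicate-averaged MaxTen of one promoter
#'
#' @param ratio_list List with one numeric vector of promoter probe
#'   ratios per replicate; replicates without probes for this promoter
#'   are passed as `NULL`.
#' @param window_probes Window size in probes (default 10).
#' @return Arithmetic mean of the per-replicate MaxTen values, with
#'   attribute `"short_promoter"` true if any replicate was short.
#' @export
promoter_maxten <- function(ratio_list, window_probes = 10) {
  ratio_list <- ratio_list[!vapply(ratio_list, is.null, logical(1))]
  if (length(ratio_list) == 0) {
    abort("promoter absent from all replicates")
  }
  vals <- lapply(ratio_list, maxten, window_probes = window_probes)
  structure(mean(vapply(vals, as.numeric, double(1))),
            short_promoter = any(vapply(vals, attr, logical(1), "short_promoter")))
}

#' Replicate-concordant enrichment call
#'
#' A promoter is enriched for a mark when a peak at `fdr <= fdr_max` is
#' present in both replicates (N = 2) or in at least two of three
#' replicates (N = 3).
#'
#' @param peak_fdrs Numeric vector of length 2 or 3: per replicate, the
#'   minimum FDR over peaks in this promoter, or `NA` if the replicate
#'   has no peak there.
#' @param fdr_max FDR threshold (default 0.1).
#' @return Logical enrichment call.
#' @export
enrichment_call <- function(peak_fdrs, fdr_max = 0.1) {
  if (!length(peak_fdrs) %in% c(2L, 3L)) {
    abort(sprintf("enrichment_call needs 2 or 3 replicates, got %d",
                  length(peak_fdrs)))
  }
  sum(!is.na(peak_fdrs) & peak_fdrs <= fdr_max) >= 2L
}

#' Classify promoters by mark co-occurrence
#'
#' @param k4_calls,k27_calls Named logical vectors (or tibbles with
#'   columns `promoter_id`, `enriched`) of per-promoter enrichment calls
#'   for H3K4me3 and H3K27me3, over the same promoter universe.
#' @return Tibble with columns `promoter_id`, `k4_enriched`,
#'   `k27_enriched`, `state` (`bivalent` if both marks, `K4`/`K27` if
#'   one, `none` if neither).
#' @export
classify_promoters <- function(k4_calls, k27_calls) {
  as_named <- function(x, what) {
    if (is.data.frame(x)) {
      .stop_if_not_cols(x, c("promoter_id", "enriched"), what)
      stats::setNames(x$enriched, x$promoter_id)
    } else if (is.logical(x) && !is.null(names(x))) {
      x
    } else {
      abort(sprintf("%s must be a named logical vector or a tibble with promoter_id/enriched",
                    what))
    }
  }
  k4 <- as_named(k4_calls, "k4_calls")
  k27 <- as_named(k27_calls, "k27_calls")
  miss <- c(setdiff(names(k4), names(k27)), setdiff(names(k27), names(k4)))
  if (length(miss) > 0) {
    abort(sprintf("promoter universe mismatch between marks; missing: %s",
                  paste(utils::head(miss, 10), collapse = ", ")))
  }
  ids <- names(k4)
  k27 <- k27[ids]
  tibble(promoter_id = ids,
         k4_enriched = unname(k4),
         k27_enriched = unname(k27),
         state = dplyr::case_when(k4 & k27 ~ "bivalent",
                                  k4 ~ "K4",
                                  k27 ~ "K27",
                                  TRUE ~ "none"))
}

# Minimum peak FDR per promoter for one peak_calls tibble, as a tibble.
.min_fdr_by_promoter <- function(peaks) {
  if (nrow(peaks) == 0) {
    return(tibble(promoter_id = character(), min_fdr = double()))
  }
  peaks |>
    as_tibble() |>
    dplyr::group_by(.data$promoter_id) |>
    dplyr::summarise(min_fdr = min(.data$fdr), .groups = "drop")
}

# MaxTen per promoter averaged over replicate tracks.
.maxten_by_promoter <- function(tracks, ids, window_probes = 10) {
  per_rep <- purrr::map(tracks, function(tr) {
    split(tr$log2_ratio, factor(tr$promoter_id, levels = ids))
  })
  vals <- double(length(ids)); short <- logical(length(ids))
  for (i in seq_along(ids)) {
    rl <- lapply(per_rep, function(x) {
      v <- x[[i]]
      if (is.null(v) || length(v) == 0) NULL else v
    })
    mt <- promoter_maxten(rl, window_probes)
    vals[i] <- as.numeric(mt)
    short[i] <- attr(mt, "short_promoter")
  }
  tibble(promoter_id = ids, maxten = vals, short_promoter = short)
}

#' Full promoter-state table for one sample
#'
#' Combines replicate peak calls and MaxTen scores for both marks into
#' the per-promoter classification table written as
#' `classification.tsv` by the pipeline.
#'
#' @param k4_peaks,k27_peaks Lists of `peak_calls` tibbles, one per
#'   replicate, for H3K4me3 and H3K27me3.
#' @param k4_tracks,k27_tracks The corresponding `probe_track` tibbles
#'   (used for MaxTen).
#' @param promoters A `promoter_set` tibble defining the universe.
#' @param fdr_max FDR threshold for the enrichment call (default 0.1).
#' @param window_probes MaxTen window (default 10).
#' @return Tibble of class `promoter_states` with columns `promoter_id`,
#'   `state`, `k4_enriched`, `k27_enriched`, `maxten_k4`, `maxten_k27`,
#'   `short_promoter`.
#' @export
promoter_state_table <- function(k4_peaks, k27_peaks, k4_tracks, k27_tracks,
                                 promoters, fdr_max = 0.1, window_probes = 10) {
  ids <- promoters$promoter_id
  call_mark <- function(peaks_list) {
    fdr_mat <- vapply(peaks_list, function(pk) {
      mf <- .min_fdr_by_promoter(pk)
      mf$min_fdr[match(ids, mf$promoter_id)]
    }, double(length(ids)))
    fdr_mat <- matrix(fdr_mat, nrow = length(ids))
    apply(fdr_mat, 1, enrichment_call, fdr_max = fdr_max)
  }
  k4 <- stats::setNames(call_mark(k4_peaks), ids)
  k27 <- stats::setNames(call_mark(k27_peaks), ids)
  cls <- classify_promoters(k4, k27)
  mt4 <- .maxten_by_promoter(k4_tracks, ids, window_probes)
  mt27 <- .maxten_by_promoter(k27_tracks, ids, window_probes)
  out <- cls |>
    dplyr::left_join(dplyr::rename(mt4, maxten_k4 = "maxten",
                                   short4 = "short_promoter"),
                     by = "promoter_id") |>
    dplyr::left_join(dplyr::rename(mt27, maxten_k27 = "maxten",
                                   short27 = "short_promoter"),
                     by = "promoter_id") |>
    dplyr::mutate(short_promoter = .data$short4 | .data$short27) |>
    dplyr::select("promoter_id", "state", "k4_enriched", "k27_enriched",
                  "maxten_k4", "maxten_k27", "short_promoter")
  class(out) <- c("promoter_states", class(out))
  out
}

#' MaxTen scatter of promoter states
#'
#' Two-dimensional scatter of averaged MaxTen values (H3K4me3 vs
#' H3K27me3) colored by promoter state, the standard diagnostic view of
#' a classification.
#'
#' @param object A `promoter_states` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot promoter_states
#' @export
autoplot.promoter_states <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$maxten_k4, y = .data$maxten_k27,
                               colour = .data$state)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(none = "grey70", K4 = "forestgreen",
                                            K27 = "firebrick", bivalent = "blue")) +
    ggplot2::labs(x = "MaxTen H3K4me3 (log2)", y = "MaxTen H3K27me3 (log2)",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
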