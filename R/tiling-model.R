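#' Probe tracks and promoter annotation for promoter tiling arrays
#'
#' A *probe track* holds the normalized log2 ChIP/input ratio of every
#' probe of one array (one histone mark, one sample, one replicate) on a
#' promoter tiling design in which probes cover a fixed window around
#' each annotated transcription start site (by default -2000..+500 bp).
#' All coordinates are 0-based, half-open, as in BED. Each probe belongs
#' to exactly one promoter; for windowing and profile purposes a probe is
#' represented by its midpoint, `floor((start + end) / 2)`.
#'
#' @name tiling-model
NULL

.TRACK_COLS <- c("chrom", "start", "end", "probe_id", "promoter_id", "log2_ratio")
.MARKS <- c("H3K4me3", "H3K27me3", "H3", "IgG")

#' Construct and validate a probe track
#'
#' @param probes Data frame with columns `chrom`, `start`, `end`,
#'   `probe_id`, `promoter_id`, `log2_ratio`.
#' @param mark Histone mark / antibody: one of `"H3K4me3"`, `"H3K27me3"`,
#'   `"H3"`, `"IgG"`.
#' @param sample Sample label, e.g. `"ICM"`, `"TE"`, `"ESC"`.
#' @param replicate Replicate number (integer >= 1).
#' @return A tibble of class `probe_track`, sorted by `(chrom, start)`,
#'   with columns `mark`, `sample`, `replicate` appended and a `midpoint`
#'   column holding `floor((start + end) / 2)`.
#' @export
probe_track <- function(probes, mark, sample, replicate) {
  probes <- as_tibble(probes)
  .stop_if_not_cols(probes, .TRACK_COLS, "probe track")
  mark <- match.arg(mark, .MARKS)
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1) abort("replicate must be an integer >= 1")
  if (nrow(probes) > 0) {
    if (!is.numeric(probes$log2_ratio) || any(!is.finite(probes$log2_ratio))) {
      abort("all log2 ratios must be finite numbers")
    }
    if (any(probes$end <= probes$start)) {
      abort("every probe must have end > start")
    }
    if (anyDuplicated(probes$probe_id)) {
      dup <- unique(probes$probe_id[duplicated(probes$probe_id)])
      abort(sprintf("duplicate probe_id in track: %s",
                    paste(utils::head(dup, 5), collapse = ", ")))
    }
  }
  out <- probes |>
    dplyr::mutate(
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      midpoint = as.integer(floor((.data$start + .data$end) / 2)),
      mark = mark,
      sample = as.character(sample),
      replicate = replicate
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
  class(out) <- c("probe_track", class(out))
  out
}

#' Read a probe track from tab-delimited text
#'
#' Expects six tab-separated columns `chrom, start, end, probe_id,
#' promoter_id, log2_ratio`; a header line is optional and detected by a
#' leading `chrom` field. Rows are re-sorted into genome order.
#'
#' @inheritParams probe_track
#' @param path Path to the TSV file.
#' @return A `probe_track` tibble (see [probe_track()]).
#' @export
read_probe_track <- function(path, mark, sample, replicate) {
  lines <- readLines(path)
  offset <- 0L
  if (length(lines) > 0 && grepl("^chrom\t", lines[[1]])) {
    lines <- lines[-1]
    offset <- 1L
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(probe_track(
      tibble(chrom = character(), start = integer(), end = integer(),
             probe_id = character(), promoter_id = character(),
             log2_ratio = double()),
      mark, sample, replicate))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1]
    abort(sprintf("parse error at line %d of %s: expected 6 tab-separated fields, found %d",
                  bad + offset, path, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  ratio <- suppressWarnings(as.numeric(m[, 6]))
  nonnum <- is.na(ratio) & !toupper(m[, 6]) %in% c("NA", "NAN")
  if (any(nonnum)) {
    bad <- which(nonnum)[1]
    abort(sprintf("parse error at line %d of %s: non-numeric log2 ratio '%s'",
                  bad + offset, path, m[bad, 6]))
  }
  probe_track(
    tibble(chrom = m[, 1],
           start = as.integer(m[, 2]),
           end = as.integer(m[, 3]),
           probe_id = m[, 4],
           promoter_id = m[, 5],
           log2_ratio = ratio),
    mark, sample, replicate)
}

#' Write a probe track as tab-delimited text
#'
#' Emits the six canonical columns with a header line; a round trip
#' through [read_probe_track()] reproduces the in-memory track.
#'
#' @param track A `probe_track` tibble.
#' @param path Output path.
#' @export
write_probe_track <- function(track, path) {
  track |>
    dplyr::select(dplyr::all_of(.TRACK_COLS)) |>
    readr::write_tsv(path)
  invisible(path)
}

#' Construct a promoter set from annotation fields
#'
#' @param promoters Data frame with columns `promoter_id`, `gene_id`,
#'   `chrom`, `strand` (`"+"`/`"-"`), `tss`.
#' @param tile_upstream,tile_downstream Extent of the tiled window in bp
#'   upstream/downstream of the TSS in transcription orientation
#'   (defaults 2000 and 500).
#' @param x_chrom Chromosome label treated as the X chromosome in
#'   X-linkage statistics.
#' @return A tibble of class `promoter_set` with genomic tile bounds
#'   `tile_start`/`tile_end` (0-based half-open) added.
#' @export
promoter_set <- function(promoters, tile_upstream = 2000, tile_downstream = 500,
                         x_chrom = "chrX") {
  promoters <- as_tibble(promoters)
  .stop_if_not_cols(promoters, c("promoter_id", "gene_id", "chrom", "strand", "tss"),
                    "promoter set")
  if (nrow(promoters) > 0) {
    if (anyDuplicated(promoters$promoter_id)) {
      dup <- unique(promoters$promoter_id[duplicated(promoters$promoter_id)])
      abort(sprintf("duplicate promoter id(s): %s",
                    paste(utils::head(dup, 5), collapse = ", ")))
    }
    if (!all(promoters$strand %in% c("+", "-"))) {
      abort("strand must be '+' or '-'")
    }
    if (any(promoters$tss < 0)) abort("tss must be >= 0")
  }
  if (tile_upstream + tile_downstream <= 0) abort("tiled window must have positive length")
  out <- promoters |>
    dplyr::mutate(
      tss = as.integer(.data$tss),
      tile_start = as.integer(ifelse(.data$strand == "+",
                                     .data$tss - tile_upstream,
                                     .data$tss - tile_downstream)),
      tile_end = as.integer(ifelse(.data$strand == "+",
                                   .data$tss + tile_downstream,
                                   .data$tss + tile_upstream))
    )
  attr(out, "tile_upstream") <- tile_upstream
  attr(out, "tile_downstream") <- tile_downstream
  attr(out, "x_chrom") <- x_chrom
  class(out) <- c("promoter_set", class(out))
  out
}

#' Read promoter annotation from BED6
#'
#' The BED interval is the transcript; the TSS is taken as `start` on the
#' plus strand and `end` on the minus strand, and the tiled window
#' `[tss - tile_upstream, tss + tile_downstream)` is laid out in
#' transcription orientation. The BED name field is used as both gene and
#' promoter id and must be unique; the score field is ignored.
#'
#' @param path BED6 file path.
#' @inheritParams promoter_set
#' @return A `promoter_set` tibble.
#' @export
read_promoters <- function(path, tile_upstream = 2000, tile_downstream = 500,
                           x_chrom = "chrX") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    return(promoter_set(
      tibble(promoter_id = character(), gene_id = character(),
             chrom = character(), strand = character(), tss = integer()),
      tile_upstream, tile_downstream, x_chrom))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    abort(sprintf("parse error at line %d of %s: expected >= 6 BED fields, found %d",
                  which(nf < 6L)[1], path, nf[which(nf < 6L)[1]]))
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  strand <- m[, 6]
  if (!all(strand %in% c("+", "-"))) {
    abort(sprintf("unknown strand symbol '%s' in %s",
                  strand[!strand %in% c("+", "-")][1], path))
  }
  start <- as.integer(m[, 2])
  end <- as.integer(m[, 3])
  promoter_set(
    tibble(promoter_id = m[, 4],
           gene_id = m[, 4],
           chrom = m[, 1],
           strand = strand,
           tss = ifelse(strand == "+", start, end)),
    tile_upstream, tile_downstream, x_chrom)
}

#' Write promoter annotation as BED6
#'
#' Inverse of [read_promoters()]: the emitted interval runs from the TSS
#' to the far tile bound so that the TSS is recoverable from the strand.
#'
#' @param promoters A `promoter_set` tibble.
#' @param path Output path.
#' @param span_bp Length of the emitted transcript interval (default 2000).
#' @export
write_promoters <- function(promoters, path, span_bp = 2000) {
  bed <- promoters |>
    dplyr::mutate(
      bed_start = ifelse(.data$strand == "+", .data$tss, .data$tss - span_bp),
      bed_end = ifelse(.data$strand == "+", .data$tss + span_bp, .data$tss)
    ) |>
    dplyr::arrange(.data$chrom, .data$bed_start) |>
    dplyr::transmute(.data$chrom, start = as.integer(.data$bed_start),
                     end = as.integer(.data$bed_end), name = .data$promoter_id,
                     score = 0L, .data$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write peaks as BED6
#'
#' One line per peak: `chrom, start, end, promoter_id:mark,
#' round(1000 * (1 - fdr)), "."`, sorted by `(chrom, start)`.
#'
#' @param peaks A peak tibble as returned by [call_peaks()].
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  .stop_if_not_cols(peaks, c("chrom", "start", "end", "promoter_id", "mark", "fdr"),
                    "peaks")
  if (nrow(peaks) > 0 && any(is.na(peaks$fdr) | peaks$fdr < 0 | peaks$fdr > 1)) {
    abort("peak fdr values must lie in [0, 1]")
  }
  bed <- peaks |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::transmute(.data$chrom, .data$start, .data$end,
                     name = paste0(.data$promoter_id, ":", .data$mark),
                     score = as.integer(round(1000 * (1 - .data$fdr))),
                     strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
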