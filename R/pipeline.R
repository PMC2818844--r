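#' Pipeline orchestration
#'
#' `run_pipeline()` drives simulate -> call peaks -> classify ->
#' metagene -> compare from a single configuration, writing every module
#' output plus a machine-readable manifest of file checksums under one
#' output directory. Reruns with the same configuration and seed
#' reproduce byte-identical outputs.
#'
#' @name pipeline
NULL

#' Read and validate a pipeline configuration
#'
#' The configuration is a nested key-value file (YAML) with sections
#' `simulation` (required keys: `n_promoters`, `state_distribution`,
#' `seed`; all other [simulation_config()] fields optional), `peaks`
#' (any [peak_call_params()] fields), `classification` (`fdr_max`) and
#' `metagene` (`bin_width`).
#'
#' @param config Path to a YAML file, or an equivalent nested list.
#' @return List of class `pipeline_config` with validated elements
#'   `simulation`, `peaks`, `fdr_max`, `bin_width`.
#' @export
read_pipeline_config <- function(config) {
  raw <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(raw)) abort("configuration error: config must be a file path or list")
  sim_raw <- raw$simulation
  if (is.null(sim_raw)) abort("configuration error: missing section 'simulation'")
  for (key in c("n_promoters", "state_distribution", "seed")) {
    if (is.null(sim_raw[[key]])) {
      abort(sprintf("configuration error: missing key 'simulation.%s'", key))
    }
  }
  for (key in c("state_distribution", "cross_lineage_sharing", "p_expressed")) {
    if (!is.null(sim_raw[[key]]) && is.list(sim_raw[[key]])) {
      sim_raw[[key]] <- unlist(sim_raw[[key]])
    }
  }
  if (!is.null(sim_raw$lineages)) sim_raw$lineages <- unlist(sim_raw$lineages)
  bad <- setdiff(names(sim_raw), names(formals(simulation_config)))
  if (length(bad) > 0) {
    abort(sprintf("configuration error: unknown simulation key(s): %s",
                  paste(bad, collapse = ", ")))
  }
  sim <- do.call(simulation_config, sim_raw)
  pk_raw <- raw$peaks %||% list()
  bad <- setdiff(names(pk_raw), names(formals(peak_call_params)))
  if (length(bad) > 0) {
    abort(sprintf("configuration error: unknown peaks key(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (is.null(pk_raw$seed)) pk_raw$seed <- sim$seed
  out <- list(simulation = sim,
              peaks = do.call(peak_call_params, pk_raw),
              fdr_max = (raw$classification %||% list())$fdr_max %||% 0.1,
              bin_width = (raw$metagene %||% list())$bin_width %||% 50)
  class(out) <- "pipeline_config"
  out
}

.write_tsv_quiet <- function(df, path) {
  readr::write_tsv(df, path)
  path
}

.mark_sets <- function(states) {
  list(K4 = states$promoter_id[states$k4_enriched],
       K27 = states$promoter_id[states$k27_enriched],
       bivalent = states$promoter_id[states$state == "bivalent"])
}

#' Run the full analysis pipeline
#'
#' Stages: simulate the experiment; call peaks on every track; classify
#' promoter states per lineage; compute metagene profiles per lineage,
#' mark and promoter class (including the null-peak background class);
#' and compare the first two lineages (overlap report, three-way Venn
#' when three samples are present, percent expressed by class).
#'
#' @param config A path to a YAML configuration, a `pipeline_config`, or
#'   a nested list (see [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return The run manifest (list, also written as `manifest.json`):
#'   configuration hash, seed, package version, and the md5 checksum of
#'   every output file.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  sim <- cfg$simulation
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)

  say("[simulate] %d promoters, lineages %s", sim$n_promoters,
      paste(sim$lineages, collapse = "/"))
  expt <- simulate_experiment(sim)
  files <- c(files, .write_tsv_quiet(as_tibble(expt$promoters),
                                     file.path(out_dir, "promoters.tsv")))
  write_promoters(expt$promoters, file.path(out_dir, "promoters.bed"))
  files <- c(files, file.path(out_dir, "promoters.bed"))
  files <- c(files, .write_tsv_quiet(expt$truth, file.path(out_dir, "truth_table.tsv")))
  files <- c(files, .write_tsv_quiet(expt$expression,
                                     file.path(out_dir, "expression_matrix.tsv")))
  for (nm in names(expt$tracks)) {
    p <- file.path(out_dir, "tracks", paste0(gsub("/", "_", nm), ".tsv"))
    write_probe_track(expt$tracks[[nm]], p)
    files <- c(files, p)
  }

  say("[callpeaks] %d tracks", length(expt$tracks))
  peaks <- purrr::map(expt$tracks, call_peaks, params = cfg$peaks)
  for (nm in names(peaks)) {
    stub <- gsub("/", "_", nm)
    pb <- file.path(out_dir, "peaks", paste0(stub, ".bed"))
    write_peaks_bed(peaks[[nm]], pb)
    pf <- file.path(out_dir, "peaks", paste0(stub, "_fdr.tsv"))
    write_fdr_table(peaks[[nm]], pf)
    files <- c(files, pb, pf)
  }

  say("[classify] fdr_max = %g", cfg$fdr_max)
  states <- list()
  for (lin in sim$lineages) {
    reps <- seq_len(sim$n_replicates)
    key <- function(mark) sprintf("%s/%s/%d", lin, mark, reps)
    states[[lin]] <- promoter_state_table(
      k4_peaks = peaks[key("H3K4me3")],
      k27_peaks = peaks[key("H3K27me3")],
      k4_tracks = expt$tracks[key("H3K4me3")],
      k27_tracks = expt$tracks[key("H3K27me3")],
      promoters = expt$promoters, fdr_max = cfg$fdr_max)
    files <- c(files, .write_tsv_quiet(
      as_tibble(states[[lin]]),
      file.path(out_dir, sprintf("classification_%s.tsv", lin))))
  }

  say("[metagene] bin width %g bp", cfg$bin_width)
  mg <- list()
  for (lin in sim$lineages) {
    cls_sets <- .mark_sets(states[[lin]])
    cls_sets$K4_only <- states[[lin]]$promoter_id[states[[lin]]$state == "K4"]
    for (mark in c("H3K4me3", "H3K27me3")) {
      keys <- sprintf("%s/%s/%d", lin, mark, seq_len(sim$n_replicates))
      h <- hypothetical_maximum(expt$tracks[[keys[1]]]$log2_ratio,
                                cfg$peaks$sd_multiplier)
      min_cut <- cfg$peaks$cutoff_percent_min / 100 * h
      cls_sets$null_peak <- null_peak_set(expt$tracks[[keys[1]]], min_cut)
      for (cl in names(cls_sets)) {
        if (length(cls_sets[[cl]]) == 0) next
        prof <- metagene_profile(expt$tracks[keys], expt$promoters,
                                 cls_sets[[cl]], cfg$bin_width, cl)
        mg[[paste(lin, mark, cl)]] <- dplyr::bind_cols(
          tibble(lineage = lin, mark = mark), as_tibble(prof))
      }
    }
  }
  files <- c(files, .write_tsv_quiet(dplyr::bind_rows(mg),
                                     file.path(out_dir, "metagene.tsv")))

  say("[compare] %s vs %s", sim$lineages[1], sim$lineages[2])
  universe <- expt$promoters$promoter_id
  s1 <- .mark_sets(states[[sim$lineages[1]]])
  s2 <- .mark_sets(states[[sim$lineages[2]]])
  overlap <- purrr::map_dfr(names(s1), function(nm) {
    dplyr::bind_cols(tibble(set = nm),
                     suppressWarnings(overlap_counts(s1[[nm]], s2[[nm]], universe)))
  })
  files <- c(files, .write_tsv_quiet(overlap, file.path(out_dir, "overlap_report.tsv")))
  if (length(sim$lineages) >= 3) {
    s3 <- .mark_sets(states[[sim$lineages[3]]])
    venn <- purrr::map_dfr(names(s1), function(nm) {
      dplyr::bind_cols(tibble(set = nm),
                       three_way_overlap(s1[[nm]], s2[[nm]], s3[[nm]],
                                         labels = sim$lineages[1:3]))
    })
    files <- c(files, .write_tsv_quiet(venn, file.path(out_dir, "venn3.tsv")))
  }
  pres <- present_calls(expt$expression)
  expr_by_class <- percent_expressed_by_class(states[[sim$lineages[1]]], pres)
  files <- c(files, .write_tsv_quiet(expr_by_class,
                                     file.path(out_dir, "expression_by_class.tsv")))

  cfg_dump <- jsonlite::toJSON(list(simulation = unclass(sim),
                                    peaks = unclass(cfg$peaks),
                                    fdr_max = cfg$fdr_max,
                                    bin_width = cfg$bin_width),
                               auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(as.character(cfg_dump), tmp)
  manifest <- list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = sim$seed,
    package_version = as.character(utils::packageVersion("chromtile")),
    files = lapply(stats::setNames(files, ifelse(
      startsWith(files, paste0(out_dir, "/")),
      substring(files, nchar(out_dir) + 2), files)),
      function(f) unname(tools::md5sum(f)))
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("[done] %d files written to %s", length(files), out_dir)
  invisible(manifest)
}
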