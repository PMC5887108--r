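#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end synthetic study into one
#' serializable object: the master seed, cohort structure, analysis
#' flags (fold set, data-reduction fraction) and output directory. The
#' configuration hash (MD5 of the canonical JSON, excluding the output
#' directory) is embedded in every written artifact for provenance.
#'
#' @param seed master seed for the whole pipeline.
#' @param n_young,n_old,n_runs,run_duration,tr,n_voxels cohort shape,
#'   see [cohort_spec()].
#' @param folds directional symmetries to evaluate (6 = grid model,
#'   5/7 = controls).
#' @param reduction_fraction translation-data fraction for the
#'   data-reduction control.
#' @param stability compute stability metrics?
#' @param out_dir output directory.
#' @return a `pipeline_config` list with a `hash` element.
#' @export
pipeline_config <- function(seed = 1L, n_young = 20, n_old = 21,
                            n_runs = 4, run_duration = 960, tr = 1.5,
                            n_voxels = 30, folds = 6,
                            reduction_fraction = 0.8016,
                            stability = TRUE, out_dir = "gridpi_out") {
  cfg <- list(seed = seed, n_young = n_young, n_old = n_old,
              n_runs = n_runs, run_duration = run_duration, tr = tr,
              n_voxels = n_voxels, folds = folds,
              reduction_fraction = reduction_fraction,
              stability = stability, out_dir = out_dir)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  cfg$hash <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic pipeline
#'
#' simulate -> grid analysis -> stability -> path-integration scoring
#' -> group statistics, writing all artifacts (per-participant grid
#' result JSONs and PI record TSVs, the cohort table TSV, the group
#' statistics JSON, the configuration) plus a manifest of MD5 file
#' hashes. Deterministic: rerunning with the same configuration
#' reproduces identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages?
#' @return list with `table` (cohort table), `stats`
#'   ([cohort_stats()] output), `manifest`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "participants"), showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[gridpi] ", ...)
  spec <- cohort_spec(n_young = config$n_young, n_old = config$n_old,
                      n_runs = config$n_runs,
                      run_duration = config$run_duration, tr = config$tr,
                      n_voxels = config$n_voxels, seed = config$seed)
  paths <- default_path_set()
  session <- build_session(paths)
  n <- spec$n_young + spec$n_old
  seeds <- derive_seeds(spec$seed, n)
  groups <- c(rep("young", spec$n_young), rep("old", spec$n_old))
  say("simulating and analyzing ", n, " participants")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- generate_participant(spec, groups[i], i, seeds[i], paths, session)
    row <- analyze_participant(p, paths, folds = config$folds,
                               stability = config$stability)
    gr <- crossval_grid_magnitude(p$bold, p$events, n_fold = 6)
    if (config$stability)
      gr$stability <- unclass(stability_summary(p$bold, p$events))
    write_grid_result(gr, file.path(out_dir, "participants",
                                    sprintf("sub%02d_grid.json", i)),
                      config_hash = config$hash)
    write_pi_tsv(p$pi_records,
                 file.path(out_dir, "participants",
                           sprintf("sub%02d_pi.tsv", i)))
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  npsych <- c("sbsod", "corsi", "tap_visual_scanning",
              "tap_working_memory", "dsst", "moca")
  old_ids <- which(tab$group == "old")
  tab[old_ids[length(old_ids)], npsych] <- NA
  class(tab) <- c("cohort_table", "data.frame")
  utils::write.table(format_num_df(as.data.frame(tab)),
                     file.path(out_dir, "cohort_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
  say("group statistics")
  stats_out <- cohort_stats(tab)
  jsonlite::write_json(
    list(stats = stats_out, provenance = provenance(config$hash)),
    file.path(out_dir, "group_stats.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  cfg_out <- unclass(config)
  cfg_out$out_dir <- NULL   # path is environment-specific, not provenance
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  say("done: ", out_dir)
  invisible(list(table = tab, stats = stats_out, manifest = manifest,
                 config = config))
}
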