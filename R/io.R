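#' Write / read an event table as BIDS-style TSV
#'
#' Columns `run_id`, `trial_id`, `onset`, `duration`, `trial_type`,
#' `direction` (`n/a` for non-translation rows); run durations go into
#' a JSON sidecar next to the TSV (`<path>.json`).
#'
#' @param events an `event_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_event_tsv <- function(events, path) {
  df <- data.frame(run_id = events$run_id, trial_id = events$trial_id,
                   onset = events$onset, duration = events$duration,
                   trial_type = events$kind,
                   direction = ifelse(is.na(events$direction), "n/a",
                                      format(events$direction, digits = 17)))
  utils::write.table(format_num_df(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(run_durations = as.list(
    attr(events, "run_durations"))), paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_event_tsv
#' @export
read_event_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("run_id", "onset", "duration", "trial_type", "direction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df$direction <- suppressWarnings(as.numeric(df$direction))
  names(df)[names(df) == "trial_type"] <- "kind"
  make_event_table(df, unlist(side$run_durations))
}

# full-precision numeric formatting for TSV round trips (NAs stay NA
# so that write.table's na= marker applies)
format_num_df <- function(df) {
  for (j in names(df))
    if (is.numeric(df[[j]])) {
      x <- format(df[[j]], digits = 17)
      x[is.na(df[[j]])] <- NA
      df[[j]] <- x
    }
  df
}

#' Write / read a voxel time-series set as dense TSV matrices
#'
#' One signal and one motion TSV per run plus a JSON sidecar
#' (`meta.json`) carrying TR, run ids and voxel ids.
#'
#' @param ts a `voxel_ts`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_timeseries <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ts$runs)) {
    r <- ts$runs[[i]]
    utils::write.table(format(r$signal, digits = 17),
                       file.path(dir, sprintf("run%d_signal.tsv", r$run_id)),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(format(r$motion, digits = 17),
                       file.path(dir, sprintf("run%d_motion.tsv", r$run_id)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(tr = ts$tr, voxel_ids = ts$voxel_ids,
         run_ids = vapply(ts$runs, function(r) r$run_id, 0)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  runs <- lapply(meta$run_ids, function(rid) {
    sig <- as.matrix(utils::read.table(
      file.path(dir, sprintf("run%d_signal.tsv", rid)), sep = "\t"))
    dimnames(sig) <- NULL
    mot <- as.matrix(utils::read.table(
      file.path(dir, sprintf("run%d_motion.tsv", rid)), sep = "\t",
      header = TRUE))
    list(signal = sig, motion = mot, n_scans = ncol(sig), run_id = rid)
  })
  structure(list(runs = runs, tr = meta$tr, voxel_ids = meta$voxel_ids),
            class = "voxel_ts")
}

#' Write / read a grid result as JSON
#'
#' Serializes magnitude, mean orientation, fold, per-voxel aligned
#' betas and (when present) the stability block, together with
#' provenance (package version and configuration hash).
#'
#' @param gr a `grid_result` (optionally with a `stability` element).
#' @param path output JSON path.
#' @param config_hash provenance hash to embed.
#' @return `path`, invisibly.
#' @export
write_grid_result <- function(gr, path, config_hash = NA_character_) {
  obj <- list(magnitude = gr$magnitude, phi = gr$phi, n_fold = gr$n_fold,
              voxel_aligned_betas = gr$voxel_aligned_betas,
              per_run_magnitude = gr$per_run_magnitude,
              excluded_runs = gr$excluded_runs,
              settings = gr$settings,
              stability = gr$stability,
              provenance = provenance(config_hash))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_grid_result
#' @export
read_grid_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("magnitude", "phi", "n_fold"))
    if (is.null(obj[[f]])) stop("grid result JSON missing field: ", f)
  structure(obj, class = "grid_result")
}

#' Write / read path-integration records as TSV
#'
#' @param records a `pi_records` data.frame.
#' @param path TSV path.
#' @return `path` (write) or the validated records (read).
#' @export
write_pi_tsv <- function(records, path) {
  utils::write.table(format_num_df(as.data.frame(records)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_pi_tsv
#' @export
read_pi_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  need <- c("modality", "type", "path_id", "stop", "response", "bearing")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("PI TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- df$type == "path" & (!is.finite(df$response) | !is.finite(df$bearing))
  if (any(bad)) stop("invalid PI record: missing response/bearing on path row")
  class(df) <- c("pi_records", "data.frame")
  df
}

provenance <- function(config_hash = NA_character_) {
  list(package = "gridpi",
       version = as.character(utils::packageVersion("gridpi")),
       config_hash = config_hash)
}
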