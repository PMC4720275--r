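#' On-disk epoch container
#'
#' Epoch sets are stored as a directory holding `data.bin` -- float64,
#' little-endian, laid out trial-major then channel then time (i.e. the R
#' array written with time fastest) -- and `meta.json` with the dimensions,
#' time axis, channel labels, per-trial labels and, when available, the
#' montage.  Synthetic ground truth, when present, goes to a
#' `ground_truth.json` sidecar.
#'
#' @param ep an `eeg_epochs`
#' @param dir directory to create/use
#' @return `read_epochs_dir` returns an `eeg_epochs`.
#' @export
write_epochs_dir <- function(ep, dir) {
  stopifnot(inherits(ep, "eeg_epochs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ep$data)
  # write with time fastest: aperm to time x channel x trial then stream out
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(ep$data, c(3, 2, 1))), con, size = 8,
           endian = "little")
  meta <- list(n_trials = d[1], n_channels = d[2], n_time = d[3],
               time_ms = ep$time_ms, channels = ep$channels,
               labels = ep$labels, bad_channels = ep$bad_channels,
               rejected_trials = ep$rejected_trials,
               byte_order = "little", dtype = "float64",
               layout = "trial-major, time fastest")
  if (!is.null(ep$montage)) meta$montage <- ep$montage
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  gt <- attr(ep, "ground_truth")
  if (!is.null(gt))
    writeLines(jsonlite::toJSON(rapply(gt, unclass, how = "replace"),
                                auto_unbox = TRUE, digits = NA,
                                force = TRUE),
               file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' @rdname write_epochs_dir
#' @export
read_epochs_dir <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  n <- meta$n_trials * meta$n_channels * meta$n_time
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  data <- aperm(array(raw, dim = c(meta$n_time, meta$n_channels,
                                   meta$n_trials)), c(3, 2, 1))
  eeg_epochs(data, time_ms = meta$time_ms, channels = meta$channels,
             labels = as.data.frame(meta$labels),
             montage = if (!is.null(meta$montage))
               as.data.frame(meta$montage),
             bad_channels = unlist(meta$bad_channels) %||% character(0),
             rejected_trials = unlist(meta$rejected_trials) %||% integer(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [sim_config()] and [cv_config()] arguments under the
#' top-level sections `simulation:` and `classification:`; missing keys keep
#' the package defaults (the standard protocol values).
#'
#' @param path YAML file path
#' @return list with `sim` (a `sim_config`) and `cv` (a `cv_config`).
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- do.call(sim_config, raw$simulation %||% list())
  cv <- do.call(cv_config, raw$classification %||% list())
  list(sim = sim, cv = cv)
}

#' Serialize an N100 detection to JSON
#'
#' @param det an `n100_detection`
#' @param path optional output file
#' @return JSON string (invisibly when written).
#' @export
detection_to_json <- function(det, path = NULL) {
  keep <- det[c("frequency_hz", "modality", "channel", "latency_ms",
                "scale_ms", "t_min", "t2_stat", "p_value", "significant",
                "n_trials", "p_eff")]
  js <- jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
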