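#' End-to-end single-subject assessment
#'
#' Runs the whole bedside pipeline on one subject: preprocessing (when given
#' a continuous recording), automatic N100 detection for each of the twelve
#' stimulus conditions, and the four-task classification suite.  Every
#' stage's failure is caught and recorded so the report is always produced.
#'
#' @param input an `eeg_epochs`, an `eeg_recording`, or a [sim_config()]
#'   (in which case a synthetic subject is simulated)
#' @param cfg a [cv_config()] controlling the classification stage
#' @param subject_id identifier stored in the report
#' @param detect_alpha N100 significance level (default 0.05)
#' @param classify_alpha classification significance level (default 0.01)
#' @return object of class `subject_report` with elements `subject_id`,
#'   `n100` (12 detections), `classification` (4 outcomes),
#'   `artifact_summary`, `config`, `seeds`.
#' @export
run_subject <- function(input, cfg = cv_config(profile = "test"),
                        subject_id = "subject", detect_alpha = 0.05,
                        classify_alpha = 0.01) {
  artifact_summary <- NULL
  sim_cfg <- NULL
  if (inherits(input, "sim_config")) {
    sim_cfg <- input
    ep <- simulate_epochs(input)
  } else if (inherits(input, "eeg_recording")) {
    pp <- preprocess_pipeline(input)
    ep <- pp$epochs
    artifact_summary <- list(
      bad_channels = pp$report$bad_channels,
      interpolated_fraction = pp$report$interpolated_fraction,
      n_rejected_trials = length(pp$report$rejected_trials))
  } else if (inherits(input, "eeg_epochs")) {
    ep <- input
  } else stop("input must be eeg_epochs, eeg_recording or sim_config")

  types <- stimulus_types()
  n100 <- vector("list", nrow(types))
  names(n100) <- .type_key(types$frequency_hz, types$modality)
  for (i in seq_len(nrow(types))) {
    n100[[i]] <- tryCatch(
      detect_n100(ep, types$frequency_hz[i], types$modality[i],
                  alpha = detect_alpha),
      error = function(e) structure(list(frequency_hz = types$frequency_hz[i],
                                         modality = types$modality[i],
                                         error = conditionMessage(e)),
                                    class = "n100_error"))
    # the embedded t-scalogram is large; keep reports lightweight
    if (inherits(n100[[i]], "n100_detection")) n100[[i]]$t_scalogram <- NULL
  }

  classification <- run_classification_suite(ep, cfg, alpha = classify_alpha)

  structure(list(subject_id = subject_id, n100 = n100,
                 classification = classification,
                 artifact_summary = artifact_summary,
                 config = list(cv = unclass(cfg),
                               sim = if (!is.null(sim_cfg)) unclass(sim_cfg),
                               detect_alpha = detect_alpha,
                               classify_alpha = classify_alpha),
                 seeds = list(cv_seed = cfg$seed,
                              sim_seed = if (!is.null(sim_cfg))
                                sim_cfg$seed)),
            class = "subject_report")
}

#' @export
print.subject_report <- function(x, ...) {
  nsig <- sum(vapply(x$n100, function(d)
    isTRUE(d$significant), logical(1)))
  cat(sprintf("<subject_report> %s\n  N100: %d/%d conditions significant\n",
              x$subject_id, nsig, length(x$n100)))
  for (cl in x$classification) {
    if (inherits(cl, "classification_error")) {
      cat(sprintf("  %s: failed (%s)\n", cl$task, cl$error))
    } else {
      lab <- if (cl$task == "modality") "modality"
      else paste0("frequency/", cl$modality)
      cat(sprintf("  %s: accuracy %.4f, p = %.4g%s\n", lab,
                  cl$global_accuracy, cl$p_global,
                  if (cl$significant) " *" else ""))
    }
  }
  invisible(x)
}

#' Serialize a subject report to JSON
#'
#' @param report a `subject_report`
#' @param path optional output file; when `NULL` the JSON string is returned
#' @return the JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- rapply(unclass(report), function(x) x, how = "replace")
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE, force = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Render subject reports as a classification results table
#'
#' One row per subject; for each stimulation modality (right, left,
#' binaural) a block of five accuracy/p-value column pairs: the global
#' four-class frequency accuracy ("All") followed by the per-frequency
#' recalls (250, 500, 1000, 2000 Hz).  P-values below `alpha` (1%) carry a
#' significance flag column convention when written as markdown.
#'
#' @param reports list of `subject_report` objects (or a single one)
#' @param alpha significance flag level, default 0.01
#' @return data.frame with `subject` plus 30 numeric columns
#'   (`<modality>_<All|250|500|1000|2000>_<accuracy|p>`).
#' @export
render_table <- function(reports, alpha = 0.01) {
  if (inherits(reports, "subject_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  mods <- c("right", "left", "binaural")
  cls <- c("All", "250", "500", "1000", "2000")
  rows <- lapply(reports, function(rep) {
    row <- list(subject = rep$subject_id)
    for (m in mods) {
      cl <- rep$classification[[paste0("frequency_", m)]]
      ok <- inherits(cl, "classification_outcome")
      for (k in cls) {
        acc <- p <- NA_real_
        if (ok) {
          if (k == "All") {
            acc <- cl$global_accuracy
            p <- cl$p_global
          } else if (k %in% names(cl$per_class_accuracy)) {
            acc <- unname(cl$per_class_accuracy[[k]])
            p <- unname(cl$p_per_class[[k]])
          }
        }
        row[[paste(m, k, "accuracy", sep = "_")]] <- acc
        row[[paste(m, k, "p", sep = "_")]] <- p
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' Write a rendered results table
#'
#' `write_results_csv` keeps full double precision (17 significant digits)
#' so the table round-trips exactly; `render_table_markdown` marks p-values
#' below the significance level in bold, mirroring the usual presentation.
#'
#' @param tab data.frame from [render_table()]
#' @param path output file
#' @param alpha bold threshold for markdown p-values
#' @return path (csv) or character vector of markdown lines.
#' @export
write_results_csv <- function(tab, path) {
  fmt <- tab
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) sprintf("%.17g", v))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(names(tab), "subject")
  tab[num] <- lapply(tab[num], as.numeric)
  tab
}

#' @rdname write_results_csv
#' @export
render_table_markdown <- function(tab, alpha = 0.01) {
  cols <- setdiff(names(tab), "subject")
  header <- paste0("| subject | ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(cols) + 1), collapse = "|"), "|")
  lines <- vapply(seq_len(nrow(tab)), function(i) {
    cells <- vapply(cols, function(cn) {
      v <- tab[i, cn]
      if (is.na(v)) return("")
      s <- sprintf("%.4g", v)
      if (grepl("_p$", cn) && v < alpha) s <- paste0("**", s, "**")
      s
    }, character(1))
    paste0("| ", tab$subject[i], " | ", paste(cells, collapse = " | "), " |")
  }, character(1))
  c(header, sep, lines)
}
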