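#' The twelve auditory stimulus types
#'
#' Tone bursts come in four frequencies (250, 500, 1000, 2000 Hz) and three
#' stimulation modalities (left ear, right ear, binaural), giving twelve
#' distinct stimulus types.  Canonical order: frequency ascending, modality
#' in the order left, right, binaural.
#'
#' @return data.frame with columns `frequency_hz` (integer) and `modality`
#'   (character), 12 rows.
#' @export
#' @examples
#' stimulus_types()
stimulus_types <- function() {
  data.frame(
    frequency_hz = rep(c(250L, 500L, 1000L, 2000L), each = 3),
    modality = rep(c("left", "right", "binaural"), times = 4),
    stringsAsFactors = FALSE)
}

.type_key <- function(frequency_hz, modality) paste0(frequency_hz, "@", modality)

#' Generate a pseudo-random stimulus protocol
#'
#' Builds one session's stimulus schedule: `n_per_type` presentations of each
#' stimulus type in pseudo-random order with no immediate repetition of the
#' same type, and a uniformly jittered silent interstimulus interval (ISI).
#' The order is obtained by shuffling the full multiset of types and then
#' repairing adjacent repeats by swapping the offending event with the
#' nearest position where the swap creates no new repeat; per-type counts are
#' therefore exact by construction.
#'
#' By default the ISI is interpreted as the offset-to-onset silence, so
#' consecutive onsets are separated by `stim_duration_ms + U(isi_min_ms,
#' isi_max_ms)`.  Set `isi_mode = "onset"` for an onset-to-onset reading.
#'
#' @param n_per_type presentations per stimulus type (standard session: 200)
#' @param isi_min_ms,isi_max_ms ISI jitter bounds in ms (default 600–800)
#' @param seed integer RNG seed; the schedule is reproducible given the seed
#' @param stim_duration_ms tone-burst duration in ms (default 200)
#' @param isi_mode `"offset"` (default, gap measured from stimulus offset) or
#'   `"onset"` (gap measured onset-to-onset)
#' @param types data.frame of stimulus types to schedule (a subset of
#'   [stimulus_types()]); defaults to all 12
#' @return object of class `stimulus_protocol`: data.frame with columns
#'   `onset_ms`, `frequency_hz`, `modality`, plus attributes recording the
#'   generation parameters.
#' @export
#' @examples
#' p <- generate_protocol(n_per_type = 2, seed = 1)
#' validate_protocol(p)$n_violations
generate_protocol <- function(n_per_type = 200, isi_min_ms = 600,
                              isi_max_ms = 800, seed = 1,
                              stim_duration_ms = 200,
                              isi_mode = c("offset", "onset"),
                              types = stimulus_types()) {
  isi_mode <- match.arg(isi_mode)
  stopifnot(n_per_type >= 1, isi_min_ms > 0, isi_min_ms <= isi_max_ms,
            stim_duration_ms > 0, nrow(types) >= 1)
  if (nrow(types) == 1 && n_per_type > 1)
    stop("no-repeat constraint unsatisfiable: a single stimulus type cannot ",
         "be presented more than once without immediate repetition")
  n <- nrow(types) * n_per_type
  withr::with_seed(seed, {
    order_idx <- .norepeat_shuffle(rep(seq_len(nrow(types)), each = n_per_type))
    isi <- stats::runif(n, isi_min_ms, isi_max_ms)
  })
  gap <- if (isi_mode == "offset") stim_duration_ms + isi else isi
  onset <- cumsum(c(0, gap[-n]))
  out <- data.frame(onset_ms = onset,
                    frequency_hz = types$frequency_hz[order_idx],
                    modality = types$modality[order_idx],
                    stringsAsFactors = FALSE)
  structure(out, class = c("stimulus_protocol", "data.frame"),
            n_per_type = n_per_type, isi_min_ms = isi_min_ms,
            isi_max_ms = isi_max_ms, stim_duration_ms = stim_duration_ms,
            isi_mode = isi_mode, seed = seed)
}

# shuffle a multiset of type indices avoiding adjacent repeats:
# random shuffle, then repair each repeat by swapping with the nearest
# position where neither side of either swap target creates a repeat
.norepeat_shuffle <- function(v) {
  v <- sample(v)
  n <- length(v)
  for (i in seq_len(n)[-1]) {
    if (v[i] != v[i - 1]) next
    fixed <- FALSE
    for (d in seq_len(n)) {
      for (j in c(i - d, i + d)) {
        if (j < 1 || j > n || j == i) next
        # value arriving at i must differ from neighbours of i,
        # value arriving at j must differ from neighbours of j (minus i itself)
        ok_i <- v[j] != v[i - 1] && (i + 1 > n || j == i + 1 || v[j] != v[i + 1])
        nl <- if (j - 1 >= 1 && j - 1 != i) v[j - 1] else NA
        nr <- if (j + 1 <= n && j + 1 != i) v[j + 1] else NA
        ok_j <- (is.na(nl) || v[i] != nl) && (is.na(nr) || v[i] != nr)
        if (ok_i && ok_j) {
          tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed)
      stop("no-repeat constraint unsatisfiable for the given type multiset")
  }
  v
}

#' Validate a stimulus protocol
#'
#' Checks the protocol invariants: exact per-type counts, strictly increasing
#' onsets, no immediate repetition of a stimulus type, and all onset-to-onset
#' gaps inside the admissible interval implied by the stimulus duration and
#' ISI bounds.
#'
#' @param p a `stimulus_protocol` (or any data.frame with columns `onset_ms`,
#'   `frequency_hz`, `modality`)
#' @param stim_duration_ms,isi_min_ms,isi_max_ms gap bounds; default to the
#'   protocol's own attributes when present
#' @return list with `counts` (per-type table), `repeat_violations`,
#'   `isi_violations`, `order_violations` (index vectors), `min_gap_ms`,
#'   `max_gap_ms` and `n_violations`.
#' @export
validate_protocol <- function(p, stim_duration_ms = NULL, isi_min_ms = NULL,
                              isi_max_ms = NULL) {
  g <- function(x, a) if (!is.null(x)) x else attr(p, a)
  stim_duration_ms <- g(stim_duration_ms, "stim_duration_ms")
  isi_min_ms <- g(isi_min_ms, "isi_min_ms")
  isi_max_ms <- g(isi_max_ms, "isi_max_ms")
  isi_mode <- if (is.null(attr(p, "isi_mode"))) "offset" else attr(p, "isi_mode")
  key <- .type_key(p$frequency_hz, p$modality)
  counts <- table(factor(key, levels = .type_key(stimulus_types()$frequency_hz,
                                                 stimulus_types()$modality)))
  rep_viol <- which(key[-1] == key[-length(key)]) + 1L
  gaps <- diff(p$onset_ms)
  order_viol <- which(gaps <= 0) + 1L
  isi_viol <- integer(0)
  if (!is.null(stim_duration_ms) && !is.null(isi_min_ms) &&
      !is.null(isi_max_ms)) {
    lo <- if (isi_mode == "offset") stim_duration_ms + isi_min_ms else isi_min_ms
    hi <- if (isi_mode == "offset") stim_duration_ms + isi_max_ms else isi_max_ms
    tol <- 1e-9
    isi_viol <- which(gaps < lo - tol | gaps > hi + tol) + 1L
  }
  list(counts = counts,
       repeat_violations = rep_viol,
       isi_violations = isi_viol,
       order_violations = order_viol,
       min_gap_ms = if (length(gaps)) min(gaps) else NA_real_,
       max_gap_ms = if (length(gaps)) max(gaps) else NA_real_,
       n_violations = length(rep_viol) + length(isi_viol) + length(order_viol))
}

#' Read / write a stimulus protocol as CSV
#'
#' CSV columns: `onset_ms,frequency_hz,modality`, with modality spelled
#' `left`, `right` or `binaural`.
#'
#' @param p protocol data.frame
#' @param path file path
#' @return `read_protocol` returns a `stimulus_protocol` data.frame.
#' @export
write_protocol <- function(p, path) {
  utils::write.csv(p[, c("onset_ms", "frequency_hz", "modality")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset_ms", "frequency_hz", "modality") %in% names(p)))
  stopifnot(all(p$modality %in% c("left", "right", "binaural")))
  structure(p, class = c("stimulus_protocol", "data.frame"))
}
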