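#' Mexican hat (Ricker) mother wavelet
#'
#' The L2-normalized second derivative of a Gaussian,
#' `psi(u) = 2 / (sqrt(3) * pi^(1/4)) * (1 - u^2) * exp(-u^2 / 2)`.
#'
#' @param u numeric
#' @return numeric, same length as `u`
#' @export
#' @examples
#' mexican_hat(0)   # ~0.8673
#' mexican_hat(c(-1, 1))  # zeros
mexican_hat <- function(u) {
  (2 / (sqrt(3) * pi^0.25)) * (1 - u^2) * exp(-u^2 / 2)
}

#' The detector's wavelet scale grid
#'
#' 120 scales, linearly spaced from 8.33 to 250 ms.
#'
#' @param n_scales number of scales (default 120)
#' @param min_ms,max_ms grid endpoints in ms (defaults 8.33 and 250)
#' @return numeric vector of scales, strictly increasing
#' @export
scale_grid <- function(n_scales = 120, min_ms = 8.33, max_ms = 250) {
  seq(min_ms, max_ms, length.out = n_scales)
}

# cached wavelet design matrices, keyed by (n samples, grid hash)
.tcwt_cache <- new.env(parent = emptyenv())

# design matrix turning a length-n signal into its scales x n scalogram:
# rows are (scale, shift) pairs; W[(s,b), t] = psi((t - b)/s) / sqrt(s) * dt
.cwt_design <- function(n, grid, dt_ms = 1) {
  key <- paste0(n, "|", dt_ms, "|", paste(signif(grid, 10), collapse = ","))
  if (!is.null(.tcwt_cache[[key]])) return(.tcwt_cache[[key]])
  t_ms <- (seq_len(n) - 1) * dt_ms
  W <- matrix(0, n, length(grid) * n)
  for (si in seq_along(grid)) {
    s <- grid[si]
    # columns for this scale: shift b = each sample time
    U <- outer(t_ms, t_ms, function(t, b) mexican_hat((t - b) / s)) /
      sqrt(s) * dt_ms
    W[, (si - 1) * n + seq_len(n)] <- U
  }
  .tcwt_cache[[key]] <- W
  W
}

#' Continuous wavelet transform of a signal (Mexican hat)
#'
#' Computes `c(b, s) = s^(-1/2) * sum_t x(t) * psi((t - b)/s) * dt` at every
#' sample shift `b` and every scale in the grid, with zero padding beyond
#' the signal ends.
#'
#' @param x numeric time series (microvolts, 1 kHz sampling assumed via
#'   `dt_ms`)
#' @param grid scale grid in ms, see [scale_grid()]
#' @param time_ms optional time axis for the shifts (defaults to
#'   0..length(x)-1)
#' @param dt_ms sample spacing in ms
#' @return object of class `scalogram`: list with `values` (scales x time
#'   matrix), `scales_ms`, `time_ms`.
#' @export
cwt_mexh <- function(x, grid = scale_grid(), time_ms = NULL, dt_ms = 1) {
  stopifnot(length(x) >= 2)
  n <- length(x)
  if (is.null(time_ms)) time_ms <- (seq_len(n) - 1) * dt_ms
  W <- .cwt_design(n, grid, dt_ms)
  v <- matrix(as.numeric(x %*% W), nrow = length(grid), ncol = n, byrow = TRUE)
  structure(list(values = v, scales_ms = grid, time_ms = time_ms),
            class = "scalogram")
}

# CWT of many trials at once: X is trials x time; returns trials x scales x time
.cwt_trials <- function(X, grid = scale_grid(), dt_ms = 1) {
  n <- ncol(X)
  W <- .cwt_design(n, grid, dt_ms)
  M <- X %*% W  # trials x (scales * time), columns scale-major then shift
  aperm(array(M, dim = c(nrow(X), n, length(grid))), c(1, 3, 2))
}

#' Pointwise Student-t scalogram across trials
#'
#' For each (scale, time) point, the one-sample t statistic of the trial
#' wavelet coefficients against zero: `t = mean / (sd / sqrt(n))`.
#'
#' @param coef array trials x scales x time of wavelet coefficients, or a
#'   list of `scalogram` objects (one per trial)
#' @param scales_ms,time_ms axes (taken from the scalograms when a list is
#'   given)
#' @return object of class `t_scalogram`: `t_values` (scales x time),
#'   `n_trials`, axes.
#' @export
t_scalogram <- function(coef, scales_ms = NULL, time_ms = NULL) {
  if (is.list(coef) && inherits(coef[[1]], "scalogram")) {
    scales_ms <- coef[[1]]$scales_ms
    time_ms <- coef[[1]]$time_ms
    coef <- aperm(simplify2array(lapply(coef, `[[`, "values")), c(3, 1, 2))
  }
  n <- dim(coef)[1]
  if (n < 2) stop("t_scalogram needs at least 2 trials")
  d <- dim(coef)
  M <- matrix(coef, n, d[2] * d[3])
  mu1 <- colMeans(M)
  var1 <- pmax(0, (colSums(M^2) - n * mu1^2) / (n - 1))
  mu <- matrix(mu1, d[2], d[3])
  sdv <- matrix(sqrt(var1), d[2], d[3])
  if (any(sdv == 0))
    stop("zero trial variance at ", sum(sdv == 0),
         " scalogram point(s); t statistic undefined")
  structure(list(t_values = mu / (sdv / sqrt(n)), n_trials = n,
                 scales_ms = scales_ms, time_ms = time_ms),
            class = "t_scalogram")
}

#' Locate the t-scalogram minimum in a poststimulus window
#'
#' Finds the global minimum of the t statistic over all scales and all time
#' samples in the closed window (default \[80, 150] ms).  Ties are broken by
#' earliest time, then smallest scale.
#'
#' @param ts a `t_scalogram` (or a plain scales x time matrix plus axes)
#' @param window_ms closed time window, default `c(80, 150)`
#' @param scales_ms,time_ms axes when `ts` is a plain matrix
#' @return list with `latency_ms`, `scale_ms`, `t_min`, `scale_index`,
#'   `time_index` (indices into the full axes).
#' @export
locate_minimum <- function(ts, window_ms = c(80, 150), scales_ms = NULL,
                           time_ms = NULL) {
  if (inherits(ts, "t_scalogram")) {
    tv <- ts$t_values
    scales_ms <- ts$scales_ms
    time_ms <- ts$time_ms
  } else tv <- ts
  sel <- which(time_ms >= window_ms[1] & time_ms <= window_ms[2])
  stopifnot(length(sel) > 0)
  sub <- tv[, sel, drop = FALSE]
  tmin <- min(sub)
  hits <- which(sub == tmin, arr.ind = TRUE)
  # earliest time first, then smallest scale
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
  si <- as.integer(hits[1, 1])
  ti <- as.integer(sel[hits[1, 2]])
  list(latency_ms = time_ms[ti], scale_ms = scales_ms[si], t_min = tmin,
       scale_index = si, time_index = ti)
}

#' One-sample Hotelling T-squared test
#'
#' Tests whether the mean of `n` p-dimensional observations is zero:
#' `T2 = n * xbar' S^-1 xbar`, referred to an F distribution via
#' `F = (n - p) / (p (n - 1)) * T2` with `(p, n - p)` degrees of freedom.
#'
#' When the variables are exactly or numerically collinear the sample
#' covariance is singular.  With `rank_tol = 0` (the default) this is an
#' error and the caller must reduce the feature dimension.  With a positive
#' `rank_tol` the statistic is instead computed in the principal subspace of
#' `S` whose eigenvalues exceed `rank_tol * max(eigenvalue)`; the discarded
#' directions carry essentially no variance (they are numerically
#' deterministic), so the T-squared null distribution in the retained
#' r-dimensional subspace is the usual one with `(r, n - r)` degrees of
#' freedom.
#'
#' @param X numeric matrix, n observations x p variables (n > p >= 1)
#' @param rank_tol relative eigenvalue tolerance for rank reduction
#'   (default 0: strict, error on singular covariance)
#' @return list with `t2`, `f`, `df1`, `df2`, `p_value`, `rank` (effective
#'   dimension used).
#' @export
hotelling_t2 <- function(X, rank_tol = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(p >= 1)
  xbar <- colMeans(X)
  S <- stats::cov(X)
  if (rank_tol <= 0) {
    if (n <= p)
      stop("Hotelling T2 requires n > p (got n = ", n, ", p = ", p, ")")
    sol <- tryCatch(solve(S, xbar), error = function(e)
      stop("singular covariance matrix in Hotelling T2; reduce the feature ",
           "dimension", call. = FALSE))
    t2 <- n * sum(xbar * sol)
    r <- p
  } else {
    eg <- eigen(S, symmetric = TRUE)
    keep <- eg$values > rank_tol * max(eg$values)
    r <- sum(keep)
    if (r < 1 || n <= r)
      stop("Hotelling T2: effective rank ", r, " not testable with n = ", n)
    z <- drop(crossprod(eg$vectors[, keep, drop = FALSE], xbar))
    t2 <- n * sum(z^2 / eg$values[keep])
  }
  f <- (n - r) / (r * (n - 1)) * t2
  list(t2 = t2, f = f, df1 = r, df2 = n - r,
       p_value = stats::pf(f, r, n - r, lower.tail = FALSE), rank = r)
}

#' Automatic N100 detection by t-CWT at one channel
#'
#' Full detection chain for one stimulus condition: per-trial Mexican-hat
#' CWT of the chosen channel (default Cz), pointwise Student-t scalogram
#' across trials, minimum search over all scales in the \[80, 150] ms
#' poststimulus window, then a one-sample Hotelling T-squared test on the
#' per-trial coefficient vectors at the detected time across a decimated
#' scale grid (every 4th scale, p = 30; decimated once more to every 8th
#' scale when the trial count is too small to estimate the covariance, i.e.
#' when `n <= 3 p`).  A detection is declared significant when the
#' T-squared p-value is below `alpha` (5%, one-sided as the F upper tail)
#' *and* the located extremum is a negativity (`t_min < 0`).
#'
#' @param ep an `eeg_epochs`
#' @param frequency_hz,modality the stimulus condition to test
#' @param channel channel label, default `"Cz"`
#' @param grid scale grid, default [scale_grid()]
#' @param window_ms search window, default `c(80, 150)`
#' @param alpha significance level, default 0.05
#' @param scale_decim decimation step of the scale grid for the Hotelling
#'   feature vector, default 4
#' @return object of class `n100_detection`: `latency_ms`, `scale_ms`,
#'   `t_min`, `t2_stat`, `p_value`, `significant`, `n_trials`, `p_eff`,
#'   plus the condition and the t-scalogram.
#' @export
detect_n100 <- function(ep, frequency_hz, modality, channel = "Cz",
                        grid = scale_grid(), window_ms = c(80, 150),
                        alpha = 0.05, scale_decim = 4) {
  stopifnot(inherits(ep, "eeg_epochs"), channel %in% ep$channels)
  idx <- which(ep$labels$frequency_hz == frequency_hz &
                 ep$labels$modality == modality)
  ci <- match(channel, ep$channels)
  X <- ep$data[idx, ci, , drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, nrow = length(idx))
  n <- nrow(X)

  decim_idx <- seq(1, length(grid), by = scale_decim)
  if (n <= 3 * length(decim_idx))
    decim_idx <- seq(1, length(grid), by = 2 * scale_decim)
  p_eff <- length(decim_idx)
  if (n < p_eff + 2)
    stop("insufficient trials for condition ", frequency_hz, "@", modality,
         ": need at least ", p_eff + 2, ", got ", n)

  coef <- .cwt_trials(X, grid)
  ts <- t_scalogram(coef, scales_ms = grid, time_ms = ep$time_ms)
  loc <- locate_minimum(ts, window_ms)

  feats <- coef[, decim_idx, loc$time_index, drop = TRUE]
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = n)
  # the scale functionals are numerically collinear on a finite epoch, so
  # the test runs in the numerical-rank subspace of the covariance
  ht <- tryCatch(hotelling_t2(feats, rank_tol = 1e-8),
                 error = function(e) e)
  if (inherits(ht, "error")) {
    # one automatic retry at half the feature dimension
    step <- (decim_idx[2] - decim_idx[1]) * 2
    decim_idx <- seq(1, length(grid), by = step)
    feats <- coef[, decim_idx, loc$time_index, drop = TRUE]
    ht <- hotelling_t2(feats, rank_tol = 1e-8)
  }
  p_eff <- ht$rank

  structure(list(frequency_hz = frequency_hz, modality = modality,
                 channel = channel,
                 latency_ms = loc$latency_ms, scale_ms = loc$scale_ms,
                 t_min = loc$t_min, t2_stat = ht$t2, p_value = ht$p_value,
                 significant = (ht$p_value < alpha) && (loc$t_min < 0),
                 alpha = alpha, n_trials = n, p_eff = p_eff,
                 t_scalogram = ts),
            class = "n100_detection")
}

#' @export
print.n100_detection <- function(x, ...) {
  cat(sprintf(paste0("<n100_detection> %d Hz / %s @ %s: latency %.0f ms, ",
                     "scale %.1f ms, t_min %.2f, T2 %.1f, p %.4g [%s]\n"),
              x$frequency_hz, x$modality, x$channel, x$latency_ms,
              x$scale_ms, x$t_min, x$t2_stat, x$p_value,
              if (x$significant) "significant" else "n.s."))
  invisible(x)
}
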