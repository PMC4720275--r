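test_that("Mexican hat closed form: peak, zeros, zero mean", {
  expect_equal(mexican_hat(0), 2 / (sqrt(3) * pi^0.25))
  expect_equal(mexican_hat(0), 0.8673, tolerance = 1e-4)
  expect_equal(mexican_hat(c(-1, 1)), c(0, 0))
  # admissibility: numerical integral over [-10, 10] vanishes
  igr <- stats::integrate(mexican_hat, -10, 10, abs.tol = 1e-10)
  expect_lt(abs(igr$value), 1e-8)
})

test_that("the scale grid spans 8.33-250 ms in 120 steps", {
  g <- scale_grid()
  expect_length(g, 120)
  expect_equal(g[1], 8.33)
  expect_equal(g[120], 250)
  expect_true(all(diff(g) > 0))
  expect_equal(unique(round(diff(g), 10)),
               round((250 - 8.33) / 119, 10))
})

test_that("CWT is linear and vanishes on the zero signal", {
  g <- scale_grid(30)  # coarser grid keeps this test quick
  z <- cwt_mexh(numeric(400), g, time_ms = -50:349)
  expect_true(all(z$values == 0))
  x <- rnorm(400); y <- rnorm(400); a <- 2.5
  lhs <- cwt_mexh(a * x + y, g, time_ms = -50:349)$values
  rhs <- a * cwt_mexh(x, g, time_ms = -50:349)$values +
    cwt_mexh(y, g, time_ms = -50:349)$values
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("CWT magnitude peaks at the location and scale of a wavelet input", {
  g <- scale_grid()
  s0 <- g[10]  # a scale whose wavelet support fits inside the epoch
  tt <- -50:349
  x <- mexican_hat((tt - 100) / s0)
  sc <- cwt_mexh(x, g, time_ms = tt)
  # brute-force argmax over the computed scalogram
  hit <- which(abs(sc$values) == max(abs(sc$values)), arr.ind = TRUE)
  expect_equal(sc$time_ms[hit[1, 2]], 100)
  expect_equal(sc$scales_ms[hit[1, 1]], s0)
})

test_that("CWT is covariant under time shifts (interior region)", {
  g <- scale_grid(20, 8.33, 60)  # small scales: support well inside epoch
  set.seed(5)
  x <- numeric(400)
  x[180:220] <- rnorm(41)
  delta <- 30
  xs <- c(numeric(delta), x)[1:400]
  a <- cwt_mexh(x, g)$values
  b <- cwt_mexh(xs, g)$values
  # rows shift by delta where wavelet support stays inside the epoch
  interior <- 150:300
  expect_equal(b[, interior + delta], a[, interior], tolerance = 1e-9)
})

test_that("t-scalogram implements the one-sample t and its error path", {
  # two trials +1/-1 -> t = 0 everywhere it is defined is impossible for
  # CWT coefficients; test the statistic on a raw coefficient array instead
  coef <- array(0, dim = c(2, 3, 4))
  coef[1, , ] <- 1
  coef[2, , ] <- -1
  ts <- t_scalogram(coef, scales_ms = 1:3, time_ms = 1:4)
  expect_true(all(ts$t_values == 0))
  # identical nonzero trials: zero variance -> error
  coef[2, , ] <- 1
  expect_error(t_scalogram(coef, 1:3, 1:4), "zero trial variance")
  # n = 1 refused
  expect_error(t_scalogram(coef[1, , , drop = FALSE], 1:3, 1:4), "2 trials")
})

test_that("t statistics of i.i.d. normal coefficients follow Student-t", {
  set.seed(12)
  n <- 200
  draws <- matrix(rnorm(1e4 * n), ncol = n)
  tstat <- rowMeans(draws) / (apply(draws, 1, sd) / sqrt(n))
  expect_gte(mean(abs(tstat) < 4), 0.999)
  ks <- stats::ks.test(stats::pt(tstat, df = n - 1), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("locate_minimum matches an exhaustive scan and breaks ties", {
  set.seed(9)
  g <- scale_grid(15)
  tt <- -50:349
  for (rep in 1:100) {
    tv <- matrix(rnorm(15 * 400), 15, 400)
    loc <- locate_minimum(tv, c(80, 150), scales_ms = g, time_ms = tt)
    # independent brute force
    best <- list(t = Inf)
    for (ti in which(tt >= 80 & tt <= 150)) for (si in 1:15) {
      if (tv[si, ti] < best$t)
        best <- list(t = tv[si, ti], si = si, ti = ti)
    }
    expect_equal(loc$t_min, best$t)
    expect_equal(loc$scale_index, best$si)
    expect_equal(loc$time_index, best$ti)
  }
  # engineered minimum and tie-breaking
  tv <- matrix(0, 15, 400)
  tv[7, 151] <- -5           # 100 ms
  loc <- locate_minimum(tv, c(80, 150), scales_ms = g, time_ms = tt)
  expect_equal(loc$latency_ms, 100)
  expect_equal(loc$scale_index, 7L)
  tv2 <- matrix(-1, 15, 400)  # everything tied: earliest time, smallest scale
  loc2 <- locate_minimum(tv2, c(80, 150), scales_ms = g, time_ms = tt)
  expect_equal(loc2$latency_ms, 80)
  expect_equal(loc2$scale_index, 1L)
  # monotone-in-time surface: minimum at the window edge
  tv3 <- matrix(rep(1:400, each = 15), 15, 400)
  expect_equal(locate_minimum(-tv3, c(80, 150), g, tt)$latency_ms, 150)
})

test_that("Hotelling T2 reduces to the squared t at p = 1 and calibrates", {
  set.seed(21)
  x <- rnorm(40, 0.3)
  ht <- hotelling_t2(matrix(x, ncol = 1))
  tt <- stats::t.test(x)
  expect_equal(ht$t2, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(ht$p_value, tt$p.value, tolerance = 1e-9)

  # null calibration and p-value uniformity, p = 5, n = 100
  reps <- 1e4
  pv <- numeric(reps)
  for (i in seq_len(reps))
    pv[i] <- hotelling_t2(matrix(rnorm(500), 100, 5))$p_value
  rate <- mean(pv < 0.05)
  expect_gte(rate, 0.04); expect_lte(rate, 0.06)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)

  # power: 1 SD shift on each coordinate
  rej <- mean(replicate(2000,
    hotelling_t2(matrix(rnorm(500, mean = 1), 100, 5))$p_value < 0.05))
  expect_gt(rej, 0.99)

  # degenerate inputs
  expect_error(hotelling_t2(matrix(rnorm(10), 5, 2)[, c(1, 1, 2)]),
               "singular|n > p")
  X <- matrix(rnorm(60), 30, 2)
  Xc <- cbind(X, X[, 1] + X[, 2])  # exactly collinear third column
  expect_error(hotelling_t2(Xc), "singular")
  # rank-reduced version agrees with the clean 2-column test
  hr <- hotelling_t2(Xc, rank_tol = 1e-10)
  expect_equal(hr$rank, 2)
  expect_equal(hr$t2, hotelling_t2(X)$t2, tolerance = 1e-6)
})

test_that("detect_n100 recovers an injected N100 and rejects tiny samples", {
  ep <- bump_cz_epochs(120, amplitude = -10, noise_sd = 5)
  det <- detect_n100(ep, 1000, "left")
  expect_true(det$significant)
  expect_lt(det$p_value, 0.05)
  expect_true(det$latency_ms >= 90 && det$latency_ms <= 110)
  expect_lt(det$t_min, 0)

  expect_error(detect_n100(subset_trials(ep, 1:3), 1000, "left"),
               "insufficient trials")
})

test_that("detected latency tracks the injected latency within +/-5 ms", {
  # SNR (|amplitude| / noise SD) = 2, 120 trials
  for (lat in c(95, 110)) {
    ep <- bump_cz_epochs(120, amplitude = -10, latency = lat, noise_sd = 5)
    det <- detect_n100(ep, 1000, "left")
    expect_lte(abs(det$latency_ms - lat), 5)
  }
})

test_that("detection rate grows with injected amplitude", {
  rate <- function(amp, ndat = 12) {
    mean(vapply(seq_len(ndat), function(d) {
      ep <- bump_cz_epochs(40, amplitude = amp, noise_sd = 5, seed = 100 + d)
      detect_n100(ep, 1000, "left")$significant
    }, logical(1)))
  }
  r0 <- rate(0); r1 <- rate(-3); r2 <- rate(-10)
  # monotone over the 3-point grid, allowing binomial slack at n = 12
  slack <- 2 * sqrt(0.25 / 12)
  expect_lte(r0, r1 + slack)
  expect_lte(r1, r2 + slack)
  expect_equal(r2, 1)  # strong signal always detected
  expect_lt(r0, 0.35)  # null rate nowhere near the strong-signal rate
})
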