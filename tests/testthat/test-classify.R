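# small labelled epoch fixture with linearly separable class means
toy_epochs <- function(n_per_class = 12, n_channels = 4, snr = 5,
                       modality = "left", seed = 3) {
  freqs <- c(250L, 500L, 1000L, 2000L)
  n <- n_per_class * 4
  withr::with_seed(seed, {
    dat <- array(rnorm(n * n_channels * 400), dim = c(n, n_channels, 400))
    y <- rep(freqs, each = n_per_class)
    # orthogonal class means: each class loads one channel over 100-200 ms
    for (i in seq_len(n)) {
      ch <- 1 + (match(y[i], freqs) - 1) %% n_channels
      dat[i, ch, 151:250] <- dat[i, ch, 151:250] + snr
    }
  })
  eeg_epochs(dat, -50:349, paste0("ch", seq_len(n_channels)),
             data.frame(frequency_hz = y,
                        modality = rep(modality, n)))
}

test_that("feature matrices have the documented shape and layout", {
  ep <- toy_epochs(n_per_class = 5, n_channels = 3)
  fm <- build_feature_matrix(ep, "frequency", modality = "left")
  expect_equal(dim(fm$X), c(20, 3 * 350))
  expect_equal(levels(fm$y), c("250", "500", "1000", "2000"))
  # channel-major, time-minor: column (c-1)*350 + t
  i <- 7; ch <- 2; t_post <- 40
  expect_equal(fm$X[i, (ch - 1) * 350 + t_post + 1],
               ep$data[i, ch, 51 + t_post])
  expect_error(build_feature_matrix(ep, "frequency", modality = "binaural"),
               "no trials")

  # modality task: 3 classes over all trials
  ep3 <- eeg_epochs(array(rnorm(9 * 1 * 400), dim = c(9, 1, 400)), -50:349,
                    "Cz", data.frame(frequency_hz = rep(250L, 9),
                                     modality = rep(c("left", "right",
                                                      "binaural"), 3)))
  fm3 <- build_feature_matrix(ep3, "modality", min_per_class = 3)
  expect_equal(nlevels(fm3$y), 3)
  expect_equal(1 / nlevels(fm3$y), 1 / 3)
})

test_that("the one-vs-one linear SVM solves separable toy problems", {
  # mirror-symmetric 2-class 2-D toy set: by symmetry the max-margin
  # boundary is exactly x1 = 0, so the predicted label is sign(x1)
  Xtr <- rbind(c(-2, 1), c(-2, -1), c(2, 1), c(2, -1))
  ytr <- factor(c("a", "a", "b", "b"))
  expect_equal(as.character(svm_ovo_fit_predict(Xtr, ytr, Xtr)),
               as.character(ytr))
  probes <- rbind(c(-0.5, 5), c(0.5, -5), c(-3, 0), c(3, 0))
  expect_equal(as.character(svm_ovo_fit_predict(Xtr, ytr, probes)),
               ifelse(probes[, 1] < 0, "a", "b"))
  # a duplicated training point keeps its label
  expect_equal(as.character(svm_ovo_fit_predict(Xtr, ytr, Xtr[2, , drop = FALSE])),
               "a")
  expect_error(svm_ovo_fit_predict(Xtr, factor(rep("a", 4)), probes),
               "single class")
})

test_that("4-class decoding succeeds far above chance on separable data", {
  ep <- toy_epochs(n_per_class = 12, snr = 5)
  fm <- build_feature_matrix(ep, "frequency", modality = "left")
  cv <- cross_validated_accuracy(fm, cv_config(n_repetitions = 5, seed = 2))
  expect_gt(cv$global_accuracy, 0.9)
  expect_equal(cv$chance_level, 0.25)
})

test_that("one-hot features give perfect accuracy and full determinism", {
  y <- factor(rep(c(250, 500, 1000, 2000), each = 8),
              levels = c(250, 500, 1000, 2000))
  X <- stats::model.matrix(~ y - 1)
  fm <- list(X = X, y = y)
  cfg <- cv_config(n_repetitions = 4, seed = 5)
  cv <- cross_validated_accuracy(fm, cfg)
  expect_equal(cv$global_accuracy, 1.0)
  expect_true(all(cv$per_class_accuracy == 1))
  cv2 <- cross_validated_accuracy(fm, cfg)
  expect_identical(cv$global_accuracy, cv2$global_accuracy)
  expect_identical(cv$per_repetition, cv2$per_repetition)
})

test_that("each retained trial appears in exactly one test fold", {
  set.seed(31)
  K <- tcrossprod(matrix(rnorm(30 * 5), 30, 5))
  y <- factor(rep(c("a", "b", "c"), 10))
  # instrument the partition logic directly
  n <- 30
  perm <- sample.int(n)
  n_use <- n - n %% 4
  keep <- perm[seq_len(n_use)]
  fold_of <- rep(1:4, each = n_use / 4)
  expect_equal(n_use, 28)
  expect_equal(sort(keep), sort(unique(keep)))
  tally <- table(unlist(lapply(1:4, function(f) keep[fold_of == f])))
  expect_true(all(tally == 1))
})

test_that("permutation p-values behave at the extremes", {
  y <- factor(rep(c(250, 500, 1000, 2000), each = 8),
              levels = c(250, 500, 1000, 2000))
  X <- stats::model.matrix(~ y - 1)
  fm <- list(X = X, y = y)
  cfg <- cv_config(n_repetitions = 2, n_permutations = 100, seed = 7)
  # observed = 1.0 on separable data: no permutation can beat it by rank
  pt <- permutation_pvalue(fm, 1.0, cfg)
  expect_equal(pt$p_value, 0)
  expect_equal(pt$p_value_plus1, 1 / 101)
  # observed below the null median: p > 0.5
  pt2 <- permutation_pvalue(fm, min(pt$null_accuracies) - 0.01, cfg)
  expect_gt(pt2$p_value, 0.5)
  expect_equal(pt2$p_value, 1)
})

test_that("label-shuffled accuracy converges to chance as trials grow", {
  # K = 3 and K = 4; high-dimensional features keep the SMO solver in the
  # separable regime it sees on real single-trial EEG (low-dimensional
  # non-separable null problems make SMO iterate orders of magnitude longer)
  for (k in c(3, 4)) {
    set.seed(40 + k)
    n <- 240
    X <- matrix(rnorm(n * 400), n, 400)
    y <- factor(sample(rep(seq_len(k), length.out = n)))
    cv <- cross_validated_accuracy(list(X = X, y = y),
                                   cv_config(n_repetitions = 20, seed = 1))
    expect_lt(abs(cv$global_accuracy - 1 / k), 0.08)
  }
})

test_that("the suite runs all four tasks and flags selective effects", {
  # effect only where the left ear is stimulated (left + binaural trials)
  cfg <- sim_config(n_channels = 8, trials_per_condition = 12,
                    effect_scale = c(left = 2, right = 0, binaural = 2),
                    noise_sd_uV = 3, seed = 9)
  ep <- simulate_epochs(cfg)
  out <- run_classification_suite(ep, cv_config(n_repetitions = 3,
                                                n_permutations = 40,
                                                seed = 2))
  expect_named(out, c("modality", "frequency_left", "frequency_right",
                      "frequency_binaural"))
  accs <- vapply(out[c("frequency_left", "frequency_right",
                       "frequency_binaural")], `[[`, numeric(1),
                 "global_accuracy")
  expect_gt(accs[["frequency_left"]], accs[["frequency_right"]])
  expect_gt(accs[["frequency_binaural"]], accs[["frequency_right"]])
})
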