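#' Cross-validation / permutation-test configuration
#'
#' @param n_folds folds per repetition (the protocol's scheme uses 4)
#' @param n_repetitions repetitions of the random equal-size split (full
#'   profile: 1000; reduced test profile: 50)
#' @param n_permutations label permutations for the significance test
#'   (default 1000; reduced profile: 200)
#' @param svm_tolerance SMO gradient tolerance (default 1e-3)
#' @param C SVM regularization constant (default 1)
#' @param seed integer RNG seed; the whole suite is deterministic given it
#' @param profile `"full"` or `"test"`: convenience presets for
#'   `n_repetitions` / `n_permutations` (explicit arguments win)
#' @return list of class `cv_config`
#' @export
cv_config <- function(n_folds = 4, n_repetitions = NULL,
                      n_permutations = NULL, svm_tolerance = 1e-3, C = 1,
                      seed = 1, profile = c("full", "test")) {
  profile <- match.arg(profile)
  if (is.null(n_repetitions))
    n_repetitions <- if (profile == "full") 1000L else 50L
  if (is.null(n_permutations))
    n_permutations <- if (profile == "full") 1000L else 200L
  stopifnot(n_folds >= 2, n_repetitions >= 1, n_permutations >= 1,
            svm_tolerance > 0, C > 0)
  structure(list(n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 n_permutations = as.integer(n_permutations),
                 svm_tolerance = svm_tolerance, C = C, seed = seed,
                 profile = profile),
            class = "cv_config")
}

#' Build a single-trial feature matrix
#'
#' Features are the raw poststimulus voltages: the \[0, 350) ms window of
#' every channel, flattened channel-major / time-minor (column
#' `(c - 1) * 350 + t` holds channel `c` at poststimulus sample `t`), in
#' microvolts with no rescaling.  The `"frequency"` task selects the trials
#' of one stimulation modality and labels them by tone frequency (4
#' classes); the `"modality"` task uses all trials labeled by stimulation
#' modality (3 classes).
#'
#' @param ep an `eeg_epochs`
#' @param task `"frequency"` or `"modality"`
#' @param modality for the frequency task: `"left"`, `"right"` or
#'   `"binaural"`
#' @param min_per_class minimum trials required per class (defaults to 4,
#'   one per fold)
#' @return list of class `feature_matrix` with `X` (trials x features), `y`
#'   (factor), `channels`, `n_time`, `task`, `modality`.
#' @export
build_feature_matrix <- function(ep, task = c("frequency", "modality"),
                                 modality = NULL, min_per_class = 4) {
  task <- match.arg(task)
  stopifnot(inherits(ep, "eeg_epochs"))
  post <- ep$time_ms >= 0 & ep$time_ms < 350
  if (task == "frequency") {
    stopifnot(!is.null(modality))
    idx <- which(ep$labels$modality == modality)
    if (length(idx) == 0) stop("no trials for modality ", modality)
    y <- factor(ep$labels$frequency_hz[idx],
                levels = c(250, 500, 1000, 2000))
  } else {
    idx <- seq_len(n_trials(ep))
    y <- factor(ep$labels$modality[idx],
                levels = c("left", "right", "binaural"))
  }
  y <- droplevels(y)
  if (any(table(y) < min_per_class))
    stop("each class needs at least ", min_per_class, " trials")
  d <- ep$data[idx, , post, drop = FALSE]
  nt <- dim(d)[1]; nc <- dim(d)[2]; ns <- dim(d)[3]
  # channel-major, time-minor flattening
  X <- matrix(aperm(d, c(1, 3, 2)), nrow = nt, ncol = nc * ns)
  structure(list(X = X, y = y, channels = ep$channels, n_time = ns,
                 task = task, modality = modality),
            class = "feature_matrix")
}

# ---- one-vs-one linear SVM on a precomputed Gram matrix ------------------

# fit/predict every class pair by kernlab C-svc on kernel sub-blocks;
# majority vote, ties broken by lowest class index (factor level order)
.ovo_predict_kernel <- function(K, y, Kte, C = 1, tol = 1e-3) {
  lev <- levels(y)
  stopifnot(length(lev) >= 2)
  nte <- nrow(Kte)
  votes <- matrix(0L, nte, length(lev))
  for (a in seq_along(lev)[-length(lev)]) {
    for (b in (a + 1):length(lev)) {
      idx <- which(y == lev[a] | y == lev[b])
      ysub <- factor(as.character(y[idx]), levels = c(lev[a], lev[b]))
      fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K[idx, idx,
                                                      drop = FALSE]),
                           ysub, type = "C-svc", C = C, tol = tol)
      sv <- kernlab::SVindex(fit)
      pred <- kernlab::predict(fit,
                               kernlab::as.kernelMatrix(
                                 Kte[, idx[sv], drop = FALSE]))
      pa <- pred == lev[a]
      votes[, a] <- votes[, a] + pa
      votes[, b] <- votes[, b] + !pa
    }
  }
  factor(lev[apply(votes, 1, which.max)], levels = lev)
}

#' Fit a one-vs-one linear SVM and predict test labels
#'
#' All class pairs get a binary soft-margin linear SVM (SMO-type solver via
#' kernlab, gradient tolerance `tol`, cost `C`); a test trial's label is the
#' majority vote over the pairwise classifiers, with ties broken in favour
#' of the lowest class index.
#'
#' @param X_train,y_train training trials (matrix rows) and labels (factor
#'   or coercible)
#' @param X_test test trials
#' @param C cost parameter, default 1
#' @param tol SMO gradient tolerance, default 1e-3
#' @return factor of predicted labels, one per test row.
#' @export
svm_ovo_fit_predict <- function(X_train, y_train, X_test, C = 1,
                                tol = 1e-3) {
  y_train <- droplevels(as.factor(y_train))
  if (nlevels(y_train) < 2) stop("training data contains a single class")
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  K <- tcrossprod(X_train)
  Kte <- X_test %*% t(X_train)
  .ovo_predict_kernel(K, y_train, Kte, C = C, tol = tol)
}

# one repetition of the random equal-size 4-fold scheme on a Gram matrix;
# returns per-fold accuracies and pooled per-class (correct, total) counts
.cv_one_rep <- function(K, y, n_folds, C, tol) {
  n <- length(y)
  keep <- sample.int(n)  # random permutation; remainder dropped
  n_use <- n - n %% n_folds
  keep <- keep[seq_len(n_use)]
  fold_of <- rep(seq_len(n_folds), each = n_use / n_folds)
  lev <- levels(y)
  acc <- numeric(n_folds)
  cls_correct <- stats::setNames(numeric(length(lev)), lev)
  cls_total <- stats::setNames(numeric(length(lev)), lev)
  for (f in seq_len(n_folds)) {
    te <- keep[fold_of == f]
    tr <- keep[fold_of != f]
    ytr <- droplevels(y[tr])
    pred <- .ovo_predict_kernel(K[tr, tr, drop = FALSE], ytr,
                                K[te, tr, drop = FALSE], C = C, tol = tol)
    pred <- factor(as.character(pred), levels = lev)
    ok <- pred == y[te]
    acc[f] <- mean(ok)
    for (l in lev) {
      sel <- y[te] == l
      cls_correct[l] <- cls_correct[l] + sum(ok[sel])
      cls_total[l] <- cls_total[l] + sum(sel)
    }
  }
  list(accuracy = mean(acc), fold_accuracies = acc,
       per_class = ifelse(cls_total > 0, cls_correct / cls_total, NA_real_))
}

#' Repeated random 4-fold cross-validated accuracy
#'
#' Implements the repeated cross-validation scheme: in each repetition the
#' trials are randomly permuted and split into `n_folds` groups of equal
#' size (the `n mod n_folds` remainder is dropped at random that
#' repetition); each group serves once as the test set with the remaining
#' trials as training; the repetition accuracy is the mean of the fold
#' accuracies; the global accuracy is the mean over repetitions.  Per-class
#' accuracy is the class recall pooled over the folds of a repetition,
#' averaged over repetitions.
#'
#' @param fm a `feature_matrix` (or list with `X`, `y`)
#' @param cfg a [cv_config()]
#' @param gram optional precomputed linear Gram matrix `tcrossprod(fm$X)`
#' @return list of class `cv_result`: `global_accuracy`,
#'   `per_class_accuracy`, `per_repetition` (data.frame), `n_trials_used`,
#'   `chance_level`.
#' @export
cross_validated_accuracy <- function(fm, cfg = cv_config(profile = "test"),
                                     gram = NULL) {
  y <- fm$y
  K <- if (is.null(gram)) tcrossprod(fm$X) else gram
  res <- withr::with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_repetitions), function(r)
      .cv_one_rep(K, y, cfg$n_folds, cfg$C, cfg$svm_tolerance))
  })
  accs <- vapply(res, `[[`, numeric(1), "accuracy")
  percls <- do.call(rbind, lapply(res, `[[`, "per_class"))
  structure(list(global_accuracy = mean(accs),
                 per_class_accuracy = colMeans(percls, na.rm = TRUE),
                 per_repetition = data.frame(repetition =
                                               seq_along(accs),
                                             accuracy = accs),
                 n_trials_used = length(y) - length(y) %% cfg$n_folds,
                 chance_level = 1 / nlevels(y)),
            class = "cv_result")
}

#' Permutation-test p-value for a cross-validated accuracy
#'
#' For each permutation the class labels are shuffled uniformly and the
#' cross-validated accuracy recomputed with a single CV repetition; the
#' p-value is the fraction of null accuracies at or above the observed one
#' (`k / n`, which can be exactly 0; the `(k + 1) / (n + 1)` variant is also
#' reported).  Per-class p-values are computed analogously from the null
#' per-class recalls.
#'
#' @param fm a `feature_matrix`
#' @param observed observed global accuracy (from
#'   [cross_validated_accuracy()])
#' @param cfg a [cv_config()]
#' @param observed_per_class optional named vector of observed per-class
#'   recalls
#' @param gram optional precomputed Gram matrix
#' @return list with `p_value`, `p_value_plus1`, `null_accuracies`,
#'   `p_per_class`, `null_per_class`.
#' @export
permutation_pvalue <- function(fm, observed,
                               cfg = cv_config(profile = "test"),
                               observed_per_class = NULL, gram = NULL) {
  y <- fm$y
  K <- if (is.null(gram)) tcrossprod(fm$X) else gram
  res <- withr::with_seed(cfg$seed + 1L, {
    lapply(seq_len(cfg$n_permutations), function(r) {
      yp <- factor(sample(as.character(y)), levels = levels(y))
      .cv_one_rep(K, yp, cfg$n_folds, cfg$C, cfg$svm_tolerance)
    })
  })
  null_acc <- vapply(res, `[[`, numeric(1), "accuracy")
  null_cls <- do.call(rbind, lapply(res, `[[`, "per_class"))
  p <- mean(null_acc >= observed)
  p_per_class <- NULL
  if (!is.null(observed_per_class)) {
    p_per_class <- vapply(names(observed_per_class), function(l)
      mean(null_cls[, l] >= observed_per_class[[l]]), numeric(1))
  }
  list(p_value = p,
       p_value_plus1 = (sum(null_acc >= observed) + 1) /
         (length(null_acc) + 1),
       null_accuracies = null_acc,
       p_per_class = p_per_class,
       null_per_class = null_cls)
}

#' Run the full classification suite on one subject's epochs
#'
#' Four decoding tasks: stimulation modality (3 classes, all trials) and
#' tone frequency within each stimulation modality (4 classes each).  Each
#' task yields global and per-class cross-validated accuracies with
#' permutation p-values; significance is flagged at the 1% level.  Task
#' failures are caught and recorded so the remaining tasks still run.
#'
#' @param ep an `eeg_epochs` with all relevant conditions present
#' @param cfg a [cv_config()]
#' @param alpha significance level for flagging (default 0.01)
#' @param tasks character subset of
#'   `c("modality", "frequency_left", "frequency_right",
#'   "frequency_binaural")`
#' @return named list of `classification_outcome` objects (or `error`
#'   entries).
#' @export
run_classification_suite <- function(ep, cfg = cv_config(profile = "test"),
                                     alpha = 0.01,
                                     tasks = c("modality", "frequency_left",
                                               "frequency_right",
                                               "frequency_binaural")) {
  run1 <- function(task, modality) {
    fm <- if (task == "modality")
      build_feature_matrix(ep, "modality")
    else build_feature_matrix(ep, "frequency", modality = modality)
    gram <- tcrossprod(fm$X)
    cv <- cross_validated_accuracy(fm, cfg, gram = gram)
    pt <- permutation_pvalue(fm, cv$global_accuracy, cfg,
                             observed_per_class = cv$per_class_accuracy,
                             gram = gram)
    structure(list(task = task, modality = modality,
                   global_accuracy = cv$global_accuracy,
                   per_class_accuracy = cv$per_class_accuracy,
                   p_global = pt$p_value,
                   p_global_plus1 = pt$p_value_plus1,
                   p_per_class = pt$p_per_class,
                   n_trials_used = cv$n_trials_used,
                   chance_level = cv$chance_level,
                   significant = pt$p_value < alpha,
                   alpha = alpha,
                   n_repetitions = cfg$n_repetitions,
                   n_permutations = cfg$n_permutations),
              class = "classification_outcome")
  }
  out <- list()
  for (task in tasks) {
    modality <- sub("^frequency_", "", task)
    if (task == "modality") modality <- NA_character_
    out[[task]] <- tryCatch(run1(if (task == "modality") "modality"
                                 else "frequency", modality),
                            error = function(e)
                              structure(list(task = task,
                                             error = conditionMessage(e)),
                                        class = "classification_error"))
  }
  out
}

#' @export
print.classification_outcome <- function(x, ...) {
  lab <- if (x$task == "modality") "modality (3-class)"
  else sprintf("frequency (4-class, %s)", x$modality)
  cat(sprintf("<classification_outcome> %s: accuracy %.4f (chance %.3f), p = %.4g%s\n",
              lab, x$global_accuracy, x$chance_level, x$p_global,
              if (x$significant) " *" else ""))
  if (!is.null(x$per_class_accuracy)) {
    pc <- paste(sprintf("%s: %.3f (p %.3g)", names(x$per_class_accuracy),
                        x$per_class_accuracy, x$p_per_class),
                collapse = ", ")
    cat("  per class: ", pc, "\n", sep = "")
  }
  invisible(x)
}
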