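#' Per-trial population features
#'
#' Builds the trial-by-neuron feature matrix used for decoding: each entry
#' is a neuron's mean dF/F over one trial's stimulus window.
#'
#' @param dataset A `calcium_dataset`.
#' @param neurons Optional integer vector of neuron indices (e.g. the
#'   responsive union); defaults to all neurons, order preserved.
#' @return An object of class `trial_features`: list with `x` (n_trials x
#'   n_neurons matrix) and `labels` (orientation per trial, degrees).
#' @export
trial_features <- function(dataset, neurons = NULL) {
  if (is.null(neurons)) neurons <- seq_len(nrow(dataset$traces))
  neurons <- if (is.logical(neurons)) which(neurons) else as.integer(neurons)
  if (length(neurons) == 0) stop("empty neuron subset")
  sched <- dataset$schedule
  dur <- attr(sched, "stim_duration")
  rate <- dataset$frame_rate
  x <- t(vapply(seq_len(nrow(sched)), function(t) {
    fr <- stim_frames(sched$onset[t], dur, rate)
    rowMeans(dataset$traces[neurons, fr, drop = FALSE])
  }, numeric(length(neurons))))
  dim(x) <- c(nrow(sched), length(neurons))
  structure(list(x = x, labels = sched$orientation),
            class = "trial_features")
}

#' Orientation decoding accuracy by cross-validated linear SVM
#'
#' Stratified k-fold cross-validation of a one-vs-rest linear-kernel
#' support-vector machine (default regularization). Features are z-scored
#' per fold using training-set statistics only. Accuracy is the pooled
#' ratio of correctly classified held-out trials to all trials.
#'
#' @param features A [trial_features()] object.
#' @param folds Number of folds (default 4).
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `decoding_result`: list with `accuracy`,
#'   `fold_accuracy`, `confusion` (classes x classes count matrix, rows =
#'   truth), `n_correct`, `n_total`.
#' @examples
#' p <- session_params(n_neurons = 30, kappa = 10, noise_sd = 0.05,
#'                     responsive_fraction = 1)
#' ds <- simulate_session(p, build_schedule(p, seed = 2), make_atlas(4),
#'                        seed = 2)
#' decoding_accuracy(trial_features(ds), folds = 4, seed = 1)$accuracy
#' @export
decoding_accuracy <- function(features, folds = 4L, seed = 1L) {
  stopifnot(inherits(features, "trial_features"))
  x <- features$x
  lab <- factor(features$labels)
  classes <- levels(lab)
  if (any(table(lab) < folds))
    stop("each class needs at least `folds` trials for stratification")
  set.seed(seed)
  fold_id <- integer(length(lab))
  for (cl in classes) {
    idx <- sample(which(lab == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes, predicted = classes))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    if (length(unique(lab[tr])) < length(classes))
      stop("a class is absent from a training fold")
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdv, `/`)
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sdv, `/`)
    scores <- vapply(classes, function(cl) {
      y <- factor(ifelse(lab[tr] == cl, "pos", "neg"),
                  levels = c("pos", "neg"))
      m <- e1071::svm(xtr, y, kernel = "linear", scale = FALSE)
      dv <- attr(stats::predict(m, xte, decision.values = TRUE),
                 "decision.values")[, 1]
      if (m$labels[1] == 2) dv <- -dv   # orient so positive favours `cl`
      dv
    }, numeric(sum(te)))
    dim(scores) <- c(sum(te), length(classes))
    pred <- classes[max.col(scores, ties.method = "first")]
    fold_acc[f] <- mean(pred == as.character(lab[te]))
    confusion <- confusion + table(factor(lab[te], levels = classes),
                                   factor(pred, levels = classes))
  }
  n_total <- length(lab)
  n_correct <- sum(diag(confusion))
  structure(list(accuracy = n_correct / n_total, fold_accuracy = fold_acc,
                 confusion = confusion, n_correct = n_correct,
                 n_total = n_total),
            class = "decoding_result")
}

#' Linear discriminant embedding of trial features
#'
#' Projects trial population vectors onto the low-dimensional discriminant
#' space separating the stimulus orientations. Uses the standard LDA fit;
#' when the within-class scatter is singular (e.g. more neurons than trials,
#' or constant features) a ridge-shrunken Fisher solver is used instead and
#' flagged in the result.
#'
#' @param features A [trial_features()] object.
#' @param n_dims Number of discriminant dimensions (<= n_classes - 1).
#' @return List with `coords` (n_trials x n_dims), `centroids` (class means
#'   in the embedding), `labels`, and `shrinkage` (logical).
#' @export
lda_embedding <- function(features, n_dims = 3L) {
  stopifnot(inherits(features, "trial_features"))
  lab <- factor(features$labels)
  k <- nlevels(lab)
  if (n_dims > k - 1)
    stop(sprintf("n_dims must be <= %d (n_classes - 1)", k - 1))
  x <- features$x
  res <- tryCatch({
    fit <- MASS::lda(x, grouping = lab)
    sc <- stats::predict(fit, x)$x[, seq_len(n_dims), drop = FALSE]
    list(coords = sc, shrinkage = FALSE)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(res)) {
    res <- list(coords = fisher_shrunk(x, lab, n_dims), shrinkage = TRUE)
  }
  centroids <- apply(res$coords, 2, function(col) tapply(col, lab, mean))
  dim(centroids) <- c(k, n_dims)
  rownames(centroids) <- levels(lab)
  list(coords = res$coords, centroids = centroids, labels = lab,
       shrinkage = res$shrinkage)
}

# Fisher discriminant with ridge-regularized within-class scatter
fisher_shrunk <- function(x, lab, n_dims) {
  p <- ncol(x)
  mu <- colMeans(x)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (cl in levels(lab)) {
    xi <- x[lab == cl, , drop = FALSE]
    mi <- colMeans(xi)
    xc <- sweep(xi, 2, mi)
    Sw <- Sw + crossprod(xc)
    Sb <- Sb + nrow(xi) * tcrossprod(mi - mu)
  }
  lambda <- max(mean(diag(Sw)), 1) * 1e-4
  W <- Sw + lambda * diag(p)
  e <- eigen(solve(W, Sb))
  v <- Re(e$vectors[, seq_len(n_dims), drop = FALSE])
  x %*% v
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> Acc = %.3f (%d / %d trials)\n",
              x$accuracy, x$n_correct, x$n_total))
  invisible(x)
}
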