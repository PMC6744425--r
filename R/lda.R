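#' Fit a regularized two-class linear discriminant
#'
#' Computes `w = Sigma_hat^{-1} (mu1 - mu0)` with the shrinkage estimator
#' `Sigma_hat = (1 - lambda) * S_pooled + lambda * (tr(S_pooled)/p) * I`, and a
#' bias placing the boundary at the class-mean midpoint (equal priors). With
#' `shrinkage = "lw"` (default) the intensity `lambda` is the Ledoit-Wolf
#' analytic estimate, which keeps the fit well-posed in the
#' features >> samples regime typical of 100-voxel searchlight neighborhoods.
#'
#' @param x Numeric matrix `[sample x feature]`, all finite.
#' @param y Two-class labels (factor or coercible); the second factor level is
#'   the positive class (positive signed distance).
#' @param shrinkage `"lw"` or a number in `[0, 1]` (`0` = plain pooled
#'   covariance, `1` = spherical).
#' @return An object of class `ndba_lda` with elements `w`, `b`, `class_means`,
#'   `classes`, `lambda`, `n`, `pooled_condition`.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' fit <- fit_lda(x, rep(c("a", "b"), each = 20), shrinkage = 0)
#' mean(predict(fit, x) == rep(c("a", "b"), each = 20))
#' @export
fit_lda <- function(x, y, shrinkage = "lw") {
  x <- as.matrix(x)
  if (!all(is.finite(x))) ndba_abort("Features must be finite.", "ndba_invalid_input")
  y <- factor(y)
  if (nlevels(y) != 2 || any(table(y) == 0)) {
    ndba_abort("`y` must contain exactly two classes, both present.",
               "ndba_invalid_argument")
  }
  if (!identical(shrinkage, "lw") &&
      (!is.numeric(shrinkage) || length(shrinkage) != 1 ||
       shrinkage < 0 || shrinkage > 1)) {
    ndba_abort("`shrinkage` must be \"lw\" or a single number in [0, 1].",
               "ndba_invalid_argument")
  }
  n <- nrow(x); p <- ncol(x)
  i1 <- as.integer(y) == 2L
  mu0 <- colMeans(x[!i1, , drop = FALSE])
  mu1 <- colMeans(x[i1, , drop = FALSE])
  xc <- x
  xc[!i1, ] <- sweep(x[!i1, , drop = FALSE], 2, mu0)
  xc[i1, ] <- sweep(x[i1, , drop = FALSE], 2, mu1)
  df <- max(n - 2L, 1L)
  s_pooled <- crossprod(xc) / df

  lambda <- if (identical(shrinkage, "lw")) ledoit_wolf_lambda(xc) else shrinkage
  m <- mean(diag(s_pooled))
  sigma <- (1 - lambda) * s_pooled
  diag(sigma) <- diag(sigma) + lambda * m
  w <- tryCatch(drop(solve(sigma, mu1 - mu0)),
                error = function(e) ndba_abort(
                  paste0("Covariance solve failed: ", conditionMessage(e)),
                  "ndba_degenerate_model"))
  structure(list(
    w = w,
    b = -sum(w * (mu0 + mu1) / 2),
    class_means = rbind(mu0, mu1),
    classes = levels(y),
    lambda = lambda,
    n = c(table(y)),
    pooled_condition = kappa(sigma, exact = FALSE)
  ), class = "ndba_lda")
}

# Ledoit-Wolf analytic shrinkage intensity toward (tr(S)/p) I, computed on
# (class-)centered rows.
ledoit_wolf_lambda <- function(xc) {
  n <- nrow(xc); p <- ncol(xc)
  s_n <- crossprod(xc) / n
  m <- mean(diag(s_n))
  d2 <- sum((s_n - diag(m, p))^2) / p
  if (d2 <= 0) return(0)
  row_norms4 <- rowSums(xc^2)^2
  b2 <- (mean(row_norms4) - sum(s_n^2)) / (n * p)
  max(0, min(1, b2 / d2))
}

#' @export
print.ndba_lda <- function(x, ...) {
  cat(sprintf("<ndba_lda> %d features, classes %s/%s, lambda = %.3g\n",
              length(x$w), x$classes[1], x$classes[2], x$lambda))
  invisible(x)
}

#' @export
predict.ndba_lda <- function(object, newdata, ...) {
  d <- signed_distance(object, newdata)
  factor(object$classes[ifelse(d > 0, 2L, 1L)], levels = object$classes)
}

#' Signed distance from the decision boundary
#'
#' The geometric distance `d(x) = (w . x + b) / ||w||`, positive toward the
#' second class. When true labels are supplied the sign is re-expressed as
#' "correct-side": positive when the sample lies on its own class's side
#' (misclassified samples get negative distance), which is the quantity the
#' distance-to-bound analysis correlates with behavior. Invariant to rescaling
#' `(w, b)` by any positive constant.
#'
#' @param model An [fit_lda()] model.
#' @param x Matrix (or vector) of samples with matching feature count.
#' @param y Optional true labels for the correct-side convention.
#' @return Numeric vector of distances.
#' @export
signed_distance <- function(model, x, y = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$w)) {
    ndba_abort("Feature count does not match the model.", "ndba_invalid_argument")
  }
  nw <- sqrt(sum(model$w^2))
  if (nw == 0) ndba_abort("Degenerate model: ||w|| = 0.", "ndba_degenerate_model")
  d <- drop(x %*% model$w + model$b) / nw
  if (!is.null(y)) {
    y <- factor(y, levels = model$classes)
    if (anyNA(y)) ndba_abort("Labels outside the model's classes.",
                             "ndba_invalid_argument")
    d <- d * ifelse(as.integer(y) == 2L, 1, -1)
  }
  d
}

# Stratified k-fold assignment over samples: folds balanced within every
# (run, class) cell; every sample is tested exactly once.
make_folds <- function(run, y, k = 5, seed = 1L) {
  fold <- integer(length(run))
  withr::with_seed(seed, {
    for (cell in split(seq_along(run), list(run, y), drop = TRUE)) {
      fold[sample(cell)] <- rep_len(sample(k), length(cell))
    }
  })
  fold
}

#' Fold-averaged signed distances per stimulus
#'
#' Implements the distance proxy of the distance-to-bound analysis: samples
#' are split into `k` folds (default 5, i.e. a 4/5 train-test split),
#' stratified by class and run; for each fold a discriminant is fit on the
#' training samples and correct-side signed distances are computed for the
#' held-out samples; each stimulus's distances are then averaged over all of
#' its held-out samples.
#'
#' @param subject An `ndba_patterns` object (one subject of
#'   [generate_patterns()]).
#' @param labels Per-stimulus two-class labels (length = number of stimuli),
#'   e.g. `task_labels(design, "animacy")`.
#' @param voxels Optional voxel indices restricting the feature set (an ROI).
#' @param k Number of folds.
#' @param shrinkage Passed to [fit_lda()].
#' @param seed Seed for the stratified fold assignment.
#' @return A tibble `(stimulus_id, distance, n_samples)` of class
#'   `ndba_distances`, with the per-sample held-out distance matrix
#'   `[stimulus x sample]` in `attr(, "sample_distances")`.
#' @export
crossval_distances <- function(subject, labels, voxels = NULL, k = 5,
                               shrinkage = "lw", seed = 1L) {
  fl <- flatten_patterns(subject, voxels)
  S <- dim(subject$values)[1]
  y <- factor(labels)[fl$info$stimulus]
  fold <- make_folds(fl$info$run, y, k = k, seed = seed)
  if (length(unique(fold)) < 2 || !all(seq_len(S) %in% fl$info$stimulus)) {
    ndba_abort("Fold scheme must hold out every stimulus at least once.",
               "ndba_invalid_scheme")
  }
  d_sample <- rep(NA_real_, nrow(fl$x))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    fit <- fit_lda(fl$x[tr, , drop = FALSE], y[tr], shrinkage = shrinkage)
    d_sample[!tr] <- signed_distance(fit, fl$x[!tr, , drop = FALSE], y[!tr])
  }
  mat <- matrix(d_sample, nrow = S, byrow = TRUE)  # samples vary fastest per stimulus
  out <- tibble::tibble(
    stimulus_id = subject$stimulus_id,
    distance = rowMeans(mat),
    n_samples = rowSums(!is.na(mat))
  )
  attr(out, "sample_distances") <- mat
  attr(out, "sample_info") <- subject$sample_info
  class(out) <- c("ndba_distances", class(out))
  out
}

#' Cross-validated decoding accuracy
#'
#' Leave-one-run-out by default: for each run, a discriminant is fit on the
#' remaining runs' samples and evaluated on the held-out run. Accuracy is the
#' pooled proportion of correct held-out predictions.
#'
#' @inheritParams crossval_distances
#' @return A list with `accuracy` (pooled) and `per_fold` (tibble: fold,
#'   n_test, accuracy).
#' @export
crossval_accuracy <- function(subject, labels, voxels = NULL, shrinkage = "lw") {
  fl <- flatten_patterns(subject, voxels)
  y <- factor(labels)[fl$info$stimulus]
  folds <- fl$info$run
  per_fold <- purrr::map_dfr(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- fit_lda(fl$x[tr, , drop = FALSE], y[tr], shrinkage = shrinkage)
    pred <- predict(fit, fl$x[!tr, , drop = FALSE])
    tibble::tibble(fold = f, n_test = sum(!tr),
                   accuracy = mean(pred == y[!tr]))
  })
  list(accuracy = sum(per_fold$accuracy * per_fold$n_test) / sum(per_fold$n_test),
       per_fold = per_fold)
}

#' Cross-decoding across matched cluster pairs
#'
#' Pattern-level analogue of [crossdecode_descriptors()]: train on the two
#' clusters matched on the orthogonal dimension, test on the complementary
#' pair, both directions. Isolates signal that generalizes across exemplar
#' clusters.
#'
#' @inheritParams crossval_distances
#' @param design The stimulus design tibble.
#' @param dimension `"animacy"` or `"shape"`.
#' @return A tibble with one row per fold plus pooled accuracy attribute.
#' @export
cross_decode <- function(subject, design, dimension = c("animacy", "shape"),
                         voxels = NULL, shrinkage = "lw") {
  dimension <- match.arg(dimension)
  fl <- flatten_patterns(subject, voxels)
  labels <- task_labels(design, dimension)
  y <- labels[fl$info$stimulus]
  cluster <- design$cluster[fl$info$stimulus]
  pairs <- crossdecode_pairs(design, dimension)
  out <- purrr::imap_dfr(pairs, function(train_clusters, pair_name) {
    tr <- cluster %in% train_clusters
    fit <- fit_lda(fl$x[tr, , drop = FALSE], y[tr], shrinkage = shrinkage)
    pred <- predict(fit, fl$x[!tr, , drop = FALSE])
    tibble::tibble(fold = match(pair_name, names(pairs)),
                   train_clusters = paste(train_clusters, collapse = "+"),
                   n_test = sum(!tr),
                   accuracy = mean(pred == y[!tr]))
  })
  attr(out, "mean_accuracy") <- mean(out$accuracy)
  out
}

#' @export
tidy.ndba_lda <- function(x, ...) {
  tibble::tibble(term = if (!is.null(names(x$w))) names(x$w)
                        else sprintf("f%04d", seq_along(x$w)),
                 weight = unname(x$w))
}

#' @export
glance.ndba_lda <- function(x, ...) {
  tibble::tibble(n = sum(x$n), p = length(x$w), lambda = x$lambda,
                 bias = x$b, pooled_condition = x$pooled_condition)
}
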