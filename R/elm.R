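# Extreme Learning Machine regression: random fixed hidden layer, output
# weights by minimum-norm least squares. Used to invert biomass from
# selected-band reflectance.

#' Split a labelled dataset into training and test sets
#'
#' Seeded random partition; the training set takes `round(ratio * n)` samples.
#'
#' @param ds labelled [spectral_dataset()].
#' @param ratio training fraction in (0, 1); default 0.7 (the 7:3 protocol).
#' @param seed shuffle seed.
#' @return list with elements `train` and `test` (spectral datasets) and the
#'   index vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(ds, ratio = 0.7, seed = 1L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.null(ds$y)) stop_("split_dataset: dataset has no labels")
  n <- nrow(ds$X)
  if (n < 5) stop_("split_dataset: need at least 5 samples (got %d)", n)
  if (ratio <= 0 || ratio >= 1) stop_("split_dataset: ratio must be in (0, 1)")
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(ratio * n)
  train_idx <- sort(idx[seq_len(n_train)])
  test_idx <- sort(idx[-seq_len(n_train)])
  list(train = ds[train_idx], test = ds[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

act_fun <- function(name) {
  switch(name,
    sigmoid = stats::plogis,
    tanh = base::tanh,
    linear = identity,
    stop_("elm: unknown activation '%s'", name)
  )
}

#' Train an extreme learning machine regressor
#'
#' Inputs are min-max scaled per feature to `[-1, 1]` (parameters stored in
#' the model). Hidden weights and biases are drawn node-by-node from a seeded
#' Uniform(-1, 1) — so growing `n_hidden` appends nodes without changing
#' existing ones — and the output weights solve the minimum-norm least-squares
#' problem `H beta = y` via SVD with a rank cut at `1e-10` of the largest
#' singular value (set `ridge > 0` for a ridge solution instead).
#'
#' @param x feature matrix (rows = samples) or a labelled
#'   [spectral_dataset()] (optionally subset via `bands`).
#' @param y numeric targets (ignored when `x` is a labelled dataset).
#' @param n_hidden number of hidden nodes (default 50).
#' @param activation `"sigmoid"` (default), `"tanh"` or `"linear"`.
#' @param seed seed for the hidden layer.
#' @param ridge optional ridge penalty on the output weights.
#' @param bands optional band indices (or a `band_selection`) selecting
#'   feature columns; recorded in the model.
#' @return object of class `elm`.
#' @export
#' @examples
#' ds <- generate_inversion_dataset(60, seed = 3)
#' sel <- c(5, 40, 80, 120, 160)
#' m <- elm_train(ds, bands = sel, n_hidden = 30, seed = 1)
#' compute_metrics(ds$y, predict(m, ds$X[, sel]))
elm_train <- function(x, y = NULL, n_hidden = 50L, activation = "sigmoid",
                      seed = 1L, ridge = 0, bands = NULL) {
  if (inherits(bands, "band_selection")) bands <- bands$order
  if (inherits(x, "spectral_dataset")) {
    if (is.null(x$y)) stop_("elm_train: dataset has no labels")
    y <- x$y
    x <- if (is.null(bands)) x$X else x$X[, bands, drop = FALSE]
  } else if (!is.null(bands)) {
    x <- as.matrix(x)[, bands, drop = FALSE]
  }
  X <- as.matrix(x)
  if (!all(is.finite(X))) stop_("elm_train: non-finite features")
  if (length(y) != nrow(X)) stop_("elm_train: length(y) != nrow(x)")
  n_hidden <- as.integer(n_hidden)
  if (n_hidden < 1L) stop_("elm_train: n_hidden must be >= 1")
  p <- ncol(X)
  xmin <- apply(X, 2, min)
  xmax <- apply(X, 2, max)
  Xs <- scale_minmax(X, xmin, xmax)
  draws <- with_seed(seed, stats::runif(n_hidden * (p + 1L), -1, 1))
  M <- matrix(draws, nrow = n_hidden, byrow = TRUE)  # row i = node i
  W <- M[, seq_len(p), drop = FALSE]
  b <- M[, p + 1L]
  H <- act_fun(activation)(Xs %*% t(W) + matrix(b, nrow(Xs), n_hidden, byrow = TRUE))
  if (!all(is.finite(H))) {
    stop_("elm_train: non-finite hidden activations under activation '%s'", activation)
  }
  beta <- if (ridge > 0) {
    solve(crossprod(H) + diag(ridge, n_hidden), crossprod(H, y))
  } else {
    pinv_solve(H, y)
  }
  model <- structure(list(
    input_weights = W, hidden_bias = b, output_weights = as.numeric(beta),
    activation = activation, seed = as.integer(seed), ridge = ridge,
    n_hidden = n_hidden, xmin = as.numeric(xmin), xmax = as.numeric(xmax),
    feature_indices = if (is.null(bands)) seq_len(p) else as.integer(bands)
  ), class = "elm")
  model
}

scale_minmax <- function(X, xmin, xmax) {
  rng <- xmax - xmin
  rng[rng == 0] <- 1  # constant feature maps to -1; harmless
  sweep(sweep(X, 2, xmin), 2, rng, "/") * 2 - 1
}

# Minimum-norm least squares via SVD, rank cut at tol * max singular value.
pinv_solve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("<elm> %d features -> %d hidden (%s) -> 1, seed %d\n",
              length(x$xmin), x$n_hidden, x$activation, x$seed))
  invisible(x)
}

#' Predict biomass from an ELM model
#'
#' Applies the stored min-max scaling, hidden layer and output weights.
#' Deterministic; independent of row order.
#'
#' @param object an [elm_train()] model.
#' @param newdata feature matrix with the model's feature count (already
#'   band-subset), or a [spectral_dataset()] from which the model's
#'   `feature_indices` are taken.
#' @param ... unused.
#' @return numeric predictions (t/ha).
#' @export
predict.elm <- function(object, newdata, ...) {
  if (inherits(newdata, "spectral_dataset")) {
    newdata <- newdata$X[, object$feature_indices, drop = FALSE]
  }
  X <- as.matrix(newdata)
  p <- length(object$xmin)
  if (ncol(X) != p) {
    stop_("predict.elm: expected %d features, got %d", p, ncol(X))
  }
  Xs <- scale_minmax(X, object$xmin, object$xmax)
  H <- act_fun(object$activation)(
    Xs %*% t(object$input_weights) +
      matrix(object$hidden_bias, nrow(Xs), object$n_hidden, byrow = TRUE))
  drop(H %*% object$output_weights)
}

#' Regression accuracy metrics
#'
#' Coefficient of determination `R2 = 1 - RSS/TSS` and
#' `RMSE = sqrt(mean((pred - meas)^2))`, the standard inversion scores.
#'
#' @param meas measured values.
#' @param pred predicted values (same length, n >= 2).
#' @param split optional label ("train"/"test") carried in the report.
#' @return object of class `regression_report` with `r2`, `rmse`, `n`, `split`.
#' @export
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 2, 2))  # R2 = 0, RMSE = sqrt(2/3)
compute_metrics <- function(meas, pred, split = NA_character_) {
  if (length(meas) != length(pred)) {
    stop_("compute_metrics: lengths differ (%d vs %d)", length(meas), length(pred))
  }
  n <- length(meas)
  if (n < 2) stop_("compute_metrics: need n >= 2")
  tss <- sum((meas - mean(meas))^2)
  if (tss <= 0) stop_("compute_metrics: measured values are constant; R2 undefined")
  rss <- sum((meas - pred)^2)
  structure(list(
    r2 = 1 - rss / tss,
    rmse = sqrt(rss / n),
    n = n,
    split = split
  ), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report>%s n = %d, R2 = %.3f, RMSE = %.4f\n",
              if (is.na(x$split)) "" else paste0(" [", x$split, "]"),
              x$n, x$r2, x$rmse))
  invisible(x)
}

## ---- serialization ----------------------------------------------------------

#' @rdname paddydose-io
#' @export
write_elm_json <- function(x, path) {
  stopifnot(inherits(x, "elm"))
  jsonlite::write_json(list(
    input_weights = x$input_weights, hidden_bias = x$hidden_bias,
    output_weights = x$output_weights, activation = x$activation,
    seed = x$seed, ridge = x$ridge, n_hidden = x$n_hidden,
    xmin = x$xmin, xmax = x$xmax, feature_indices = x$feature_indices
  ), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname paddydose-io
#' @export
read_elm_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    input_weights = matrix(j$input_weights, nrow = j$n_hidden),
    hidden_bias = as.numeric(j$hidden_bias),
    output_weights = as.numeric(j$output_weights),
    activation = j$activation, seed = as.integer(j$seed), ridge = j$ridge,
    n_hidden = as.integer(j$n_hidden), xmin = as.numeric(j$xmin),
    xmax = as.numeric(j$xmax), feature_indices = as.integer(j$feature_indices)
  ), class = "elm")
}
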