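# Successive Projections Algorithm (SPA) feature-band selection and the
# cross-validated choice of band count (RMSECV).

#' Successive Projections Algorithm band selection
#'
#' Greedy forward selector for minimally collinear wavelength subsets.
#' Starting from band `k0`, each iteration orthogonalizes every remaining
#' candidate column of the working matrix against the most recently selected
#' column and picks the candidate with the largest residual norm. Because the
#' working columns are residualized in place, the residual at step n is the
#' projection of the original column onto the orthogonal complement of the
#' span of all previously selected columns.
#'
#' @param X reflectance matrix, rows = samples, columns = candidate bands.
#' @param k0 initial band index (1-based).
#' @param n_bands number of bands to select, `1 <= n_bands <= min(nrow, ncol)`.
#' @param center mean-center each column before projecting (default `TRUE`;
#'   removes the offset that otherwise dominates the first norms).
#' @return integer vector of selected band indices, `k0` first, in selection
#'   order. Ties in the norm criterion go to the lowest index.
#' @export
#' @examples
#' X <- matrix(rnorm(60), 10, 6)
#' spa_select(X, k0 = 2, n_bands = 3)
spa_select <- function(X, k0, n_bands, center = TRUE) {
  X <- as.matrix(X)
  J <- ncol(X)
  if (n_bands < 1 || n_bands > min(nrow(X), J)) {
    stop_("spa_select: n_bands must lie in [1, %d]", min(nrow(X), J))
  }
  if (k0 < 1 || k0 > J) stop_("spa_select: k0 = %s out of range [1, %d]", k0, J)
  W <- if (center) sweep(X, 2, colMeans(X)) else X
  sel <- integer(n_bands)
  sel[1] <- as.integer(k0)
  cand <- setdiff(seq_len(J), k0)
  if (n_bands == 1L) return(sel)
  for (n in 2:n_bands) {
    xi <- W[, sel[n - 1L]]
    nrm2 <- sum(xi^2)
    if (nrm2 < 1e-24) {
      stop_("spa_select: degenerate rank at iteration %d (selected column has zero norm)", n)
    }
    # rank-1 residualization of all remaining candidates against xi
    coef <- crossprod(W[, cand, drop = FALSE], xi) / nrm2
    W[, cand] <- W[, cand, drop = FALSE] - xi %*% t(coef)
    norms <- sqrt(colSums(W[, cand, drop = FALSE]^2))
    if (max(norms) < 1e-12) {
      stop_("spa_select: degenerate rank at iteration %d (all residual norms < 1e-12)", n)
    }
    pick <- cand[which.max(norms)]  # which.max -> first (lowest index) on ties
    sel[n] <- pick
    cand <- setdiff(cand, pick)
  }
  sel
}

# SPA chains are prefix-nested in n_bands, so one chain of length n_max per
# start band serves every smaller count. Returns a list of integer vectors
# (one chain per k0); chains that hit rank degeneracy are truncated.
spa_chains <- function(X, n_max, center = TRUE) {
  lapply(seq_len(ncol(X)), function(k0) {
    tryCatch(spa_select(X, k0, n_max, center = center),
             error = function(e) {
               # salvage the longest achievable chain
               n <- n_max - 1L
               while (n >= 1L) {
                 out <- tryCatch(spa_select(X, k0, n, center = center),
                                 error = function(e2) NULL)
                 if (!is.null(out)) return(out)
                 n <- n - 1L
               }
               integer(0)
             })
  })
}

# Cross-validated RMSE of an ordinary least-squares fit on the given bands.
# Used to score candidate start bands k0 (fast inner criterion).
cv_rmse_linear <- function(X, y, bands, folds) {
  press <- 0
  for (te in folds) {
    tr <- setdiff(seq_len(nrow(X)), te)
    Xtr <- cbind(1, X[tr, bands, drop = FALSE])
    fit <- stats::lm.fit(Xtr, y[tr])
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pred <- cbind(1, X[te, bands, drop = FALSE]) %*% beta
    press <- press + sum((y[te] - pred)^2)
  }
  sqrt(press / nrow(X))
}

# Cross-validated RMSE of the ELM inversion on the given bands (the RMSECV
# reported in the trace).
cv_rmse_elm <- function(X, y, bands, folds, n_hidden, activation, seed) {
  press <- 0
  for (te in folds) {
    tr <- setdiff(seq_len(nrow(X)), te)
    m <- elm_train(X[tr, bands, drop = FALSE], y[tr], n_hidden = n_hidden,
                   activation = activation, seed = seed)
    pred <- predict(m, X[te, bands, drop = FALSE])
    press <- press + sum((y[te] - pred)^2)
  }
  sqrt(press / nrow(X))
}

#' Select the band count by cross-validated RMSE (RMSECV)
#'
#' For every candidate count `N` in `[n_min, n_max]`, runs SPA (all start
#' bands `k0`, unless one is fixed), scores the start bands by k-fold
#' linear-regression RMSE, then records the k-fold RMSECV of the ELM inversion
#' on the winning subset. The returned selection minimizes the RMSECV trace;
#' ties break toward the smaller count.
#'
#' @param ds labelled [spectral_dataset()].
#' @param n_min,n_max band-count search range (default 5--30).
#' @param folds number of CV folds (default 5).
#' @param seed seed for fold shuffling and the ELM hidden layer.
#' @param k0 optional fixed start band (fast mode); `NULL` scans all bands.
#' @param n_hidden,activation ELM settings used for the RMSECV trace.
#' @param center mean-center columns inside SPA.
#' @return object of class `band_selection` with fields `order` (selected
#'   indices in selection order), `n_selected`, `k0`, `rmsecv_trace` (named by
#'   band count), `wavelengths_nm` and `grid`.
#' @export
rmsecv_scan <- function(ds, n_min = 5L, n_max = 30L, folds = 5L, seed = 1L,
                        k0 = NULL, n_hidden = 50L, activation = "sigmoid",
                        center = TRUE) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.null(ds$y)) stop_("rmsecv_scan: dataset has no biomass labels")
  if (n_min > n_max) stop_("rmsecv_scan: n_min (%d) > n_max (%d)", n_min, n_max)
  n <- nrow(ds$X)
  if (n_min < 1 || n_max > min(n, ncol(ds$X))) {
    stop_("rmsecv_scan: band-count range must lie in [1, %d]", min(n, ncol(ds$X)))
  }
  fold_idx <- make_folds(n, folds, seed = derive_seed(seed, 11L))
  chains <- if (is.null(k0)) {
    spa_chains(ds$X, n_max, center = center)
  } else {
    list(spa_select(ds$X, k0, n_max, center = center))
  }
  counts <- n_min:n_max
  trace <- stats::setNames(rep(NA_real_, length(counts)), counts)
  orders <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    N <- counts[i]
    usable <- Filter(function(ch) length(ch) >= N, chains)
    if (length(usable) == 0) next
    scores <- vapply(usable, function(ch) {
      cv_rmse_linear(ds$X, ds$y, ch[seq_len(N)], fold_idx)
    }, numeric(1))
    best <- usable[[which.min(scores)]][seq_len(N)]
    orders[[i]] <- best
    trace[i] <- cv_rmse_elm(ds$X, ds$y, best, fold_idx, n_hidden, activation,
                            seed = derive_seed(seed, 13L))
  }
  if (all(is.na(trace))) stop_("rmsecv_scan: no usable SPA chain of any length")
  pick <- which.min(trace)  # first minimum -> smaller N on ties
  order <- orders[[pick]]
  structure(list(
    order = order,
    n_selected = length(order),
    k0 = order[1],
    rmsecv_trace = trace,
    wavelengths_nm = ds$grid[order],
    grid = ds$grid
  ), class = "band_selection")
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("<band_selection> %d bands (RMSECV %.4f)\n", x$n_selected,
              min(x$rmsecv_trace, na.rm = TRUE)))
  cat("  wavelengths (nm):", paste(round(x$wavelengths_nm), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname paddydose-io
#' @export
write_selection_json <- function(x, path) {
  stopifnot(inherits(x, "band_selection"))
  jsonlite::write_json(list(
    order = x$order, n_selected = x$n_selected, k0 = x$k0,
    rmsecv_trace = as.list(x$rmsecv_trace),
    wavelengths_nm = x$wavelengths_nm, grid = x$grid
  ), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname paddydose-io
#' @export
read_selection_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    order = as.integer(j$order), n_selected = as.integer(j$n_selected),
    k0 = as.integer(j$k0),
    rmsecv_trace = stats::setNames(unlist(j$rmsecv_trace),
                                   names(j$rmsecv_trace)),
    wavelengths_nm = as.numeric(j$wavelengths_nm), grid = as.numeric(j$grid)
  ), class = "band_selection")
}
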