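# Independent oracles and small fixtures shared across tests.

# From-scratch Gram-Schmidt SPA oracle: at every step the residual of each
# candidate is recomputed against the span of ALL previously selected columns
# (QR projection), unlike the package's in-place rank-1 recursion.
spa_oracle <- function(X, k0, n_bands, center = TRUE) {
  W <- if (center) sweep(X, 2, colMeans(X)) else X
  sel <- as.integer(k0)
  while (length(sel) < n_bands) {
    cand <- setdiff(seq_len(ncol(W)), sel)
    Q <- qr.Q(qr(W[, sel, drop = FALSE]))
    norms <- vapply(cand, function(j) {
      r <- W[, j] - Q %*% crossprod(Q, W[, j])
      sqrt(sum(r^2))
    }, numeric(1))
    sel <- c(sel, cand[which.max(norms)])
  }
  sel
}

# Replays the SPA recursion while recording, after each iteration, the inner
# products between every remaining residual column and the just-selected
# working column (the orthogonality the projection must enforce).
spa_trace_orthogonality <- function(X, k0, n_bands, center = TRUE) {
  W <- if (center) sweep(X, 2, colMeans(X)) else X
  sel <- as.integer(k0)
  cand <- setdiff(seq_len(ncol(W)), k0)
  worst <- numeric(0)
  for (n in seq_len(n_bands - 1L)) {
    xi <- W[, sel[length(sel)]]
    coef <- crossprod(W[, cand, drop = FALSE], xi) / sum(xi^2)
    W[, cand] <- W[, cand, drop = FALSE] - xi %*% t(coef)
    worst <- c(worst, max(abs(crossprod(W[, cand, drop = FALSE], xi))))
    pick <- cand[which.max(sqrt(colSums(W[, cand, drop = FALSE]^2)))]
    sel <- c(sel, pick)
    cand <- setdiff(cand, pick)
  }
  worst
}

# Rebuild the hidden-layer matrix of an ELM model from its stored fields
# (used by the normal-equations oracle).
elm_hidden <- function(model, X) {
  rng <- model$xmax - model$xmin
  rng[rng == 0] <- 1
  Xs <- sweep(sweep(as.matrix(X), 2, model$xmin), 2, rng, "/") * 2 - 1
  act <- switch(model$activation, sigmoid = stats::plogis, tanh = base::tanh,
                linear = identity)
  act(Xs %*% t(model$input_weights) +
        matrix(model$hidden_bias, nrow(Xs), model$n_hidden, byrow = TRUE))
}

# Small shared season fixture: 100 days is enough to reach maturity with the
# default phenology.
demo_weather <- function(n_days = 130, seed = 1) {
  generate_weather("2021-05-19", n_days, seed = seed)
}

demo_schedule <- function(gradient = "N3", tillering_n = 60, weather = demo_weather()) {
  build_schedule(gradient, tillering_n = tillering_n,
                 dates = schedule_dates(weather))
}
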