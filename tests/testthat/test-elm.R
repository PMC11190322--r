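test_that("split_dataset partitions exactly at the requested ratio", {
  ds <- generate_inversion_dataset(100, seed = 1)
  sp <- split_dataset(ds, ratio = 0.7, seed = 2)
  expect_equal(nrow(sp$train$X), 70)
  expect_equal(nrow(sp$test$X), 30)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(100))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  sp2 <- split_dataset(ds, ratio = 0.7, seed = 2)
  expect_identical(sp$train_idx, sp2$train_idx)

  tiny <- generate_inversion_dataset(10, seed = 1)[1:4]
  expect_error(split_dataset(tiny), "at least 5")
  expect_error(split_dataset(ds, ratio = 1.2), "ratio")
})

test_that("elm_train reproduces targets that live in its hidden-layer span", {
  set.seed(7)
  X <- matrix(runif(80), 20, 4)
  m0 <- elm_train(X, rnorm(20), n_hidden = 10, seed = 3)
  beta_true <- rnorm(10)
  m_star <- m0
  m_star$output_weights <- beta_true
  y <- predict(m_star, X)
  m <- elm_train(X, y, n_hidden = 10, seed = 3)
  expect_lt(sqrt(mean((predict(m, X) - y)^2)), 1e-8)
})

test_that("output weights agree with a normal-equations oracle", {
  set.seed(8)
  X <- matrix(runif(30 * 5), 30, 5)
  y <- X %*% runif(5) + rnorm(30, 0, 0.1)
  m <- elm_train(X, y, n_hidden = 8, seed = 4)
  H <- elm_hidden(m, X)
  expect_gt(rcond(crossprod(H)), 1e-10)  # well-conditioned case only
  beta_ne <- solve(crossprod(H), crossprod(H, y))
  expect_lt(max(abs(m$output_weights - beta_ne)), 1e-6)
})

test_that("elm predictions are deterministic and row-order invariant", {
  set.seed(9)
  X <- matrix(runif(60), 15, 4)
  X[2, ] <- X[1, ]  # duplicate row
  y <- rnorm(15)
  m <- elm_train(X, y, n_hidden = 12, seed = 5)
  p <- predict(m, X)
  expect_equal(p[1], p[2])
  ord <- sample(15)
  expect_equal(predict(m, X[ord, ]), p[ord])
  expect_error(predict(m, X[, 1:3]), "expected 4 features")
})

test_that("training error never rises as seed-nested hidden nodes are added", {
  set.seed(10)
  X <- matrix(runif(100), 25, 4)
  y <- sin(3 * X[, 1]) + X[, 2]^2 + rnorm(25, 0, 0.05)
  rmse <- vapply(c(5, 10, 20, 40), function(h) {
    m <- elm_train(X, y, n_hidden = h, seed = 6)
    sqrt(mean((predict(m, X) - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("elm models round-trip through JSON exactly", {
  ds <- generate_inversion_dataset(40, seed = 11)
  bands <- c(10, 60, 110, 160)
  m <- elm_train(ds, bands = bands, n_hidden = 15, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  write_elm_json(m, f)
  back <- read_elm_json(f)
  expect_identical(back$feature_indices, m$feature_indices)
  expect_identical(predict(back, ds$X[, bands]), predict(m, ds$X[, bands]))
})

test_that("compute_metrics evaluates the R2 and RMSE formulas exactly", {
  perfect <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)

  # RSS = (1-2)^2 + 0 + (3-2)^2 = 2 = TSS -> R2 = 0, RMSE = sqrt(2/3)
  flat <- compute_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_identical(flat$r2, 0)
  expect_identical(flat$rmse, sqrt(2 / 3))

  shifted <- compute_metrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shifted$rmse, 1)
  expect_lt(shifted$r2, 1)

  expect_error(compute_metrics(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(compute_metrics(1:3, 1:4), "lengths")
  expect_error(compute_metrics(1, 1), "n >= 2")
})

test_that("selected-band ELM inversion reaches the expected accuracy regime", {
  ds <- generate_inversion_dataset(300, seed = 21)
  sp <- split_dataset(ds, ratio = 0.7, seed = 5)
  sel <- rmsecv_scan(ds, n_min = 5, n_max = 10, folds = 5, seed = 3, k0 = 30)
  m <- elm_train(sp$train, bands = sel, seed = 6)
  rep_te <- compute_metrics(sp$test$y, predict(m, sp$test), "test")
  expect_gt(rep_te$r2, 0.85)
  expect_lt(rep_te$rmse, 0.15)
})
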