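test_that("enkf_analysis recovers the Kalman update from ensemble statistics", {
  set.seed(1)
  ens <- rbind(a = rnorm(5000, 5, 1), b = rnorm(5000, 3, 0.5))
  ens["b", ] <- ens["b", ] + 0.4 * (ens["a", ] - 5)  # correlated components
  obs <- observation("2021-06-01", 7, 0.5)

  # deterministic-mean mode obeys the update identity exactly
  a <- enkf_analysis(ens, obs, h = "a", perturb_obs = FALSE)
  hx <- ens["a", ]
  K <- drop((ens - rowMeans(ens)) %*% (hx - mean(hx))) / (ncol(ens) - 1) /
    (obs$var + var(hx))
  expect_lt(max(abs(rowMeans(a) -
                      (rowMeans(ens) + K * (obs$value - mean(hx))))), 1e-8)
  # analysis variance of the observed component never exceeds the forecast's
  expect_lte(var(a["a", ]), var(hx))
  # the unobserved component moves through the cross-covariance
  expect_gt(mean(a["b", ]), mean(ens["b", ]))
})

test_that("enkf_analysis limits: vanishing gain and zero spread", {
  set.seed(2)
  ens <- matrix(rnorm(2000, 10, 2), 1)
  obs_far <- observation("2021-06-01", 12, 1e12 * var(drop(ens)))
  a <- enkf_analysis(ens, obs_far, h = 1, seed = 3)
  expect_lt(abs(mean(a) - mean(ens)) / abs(mean(ens)), 1e-4)

  flat <- matrix(10, 1, 50)
  expect_warning(a0 <- enkf_analysis(flat, observation("2021-06-01", 12, 1)),
                 "zero ensemble spread")
  expect_identical(a0, flat)

  expect_error(observation("2021-06-01", 12, 0), "variance")
})

test_that("the filter without observations tracks the open-loop run", {
  w <- demo_weather()
  p <- crop_params()
  sch <- demo_schedule("N3", 60, w)
  open <- run(p, w, sch)
  tr <- enkf_assimilate(p, w, sch, obs_list = NULL, M = 150, seed = 4)
  # ensemble mean stays within Monte-Carlo error of the open loop
  expect_lt(abs(final_yield(tr) - final_yield(open)) / final_yield(open), 0.05)
  expect_identical(as.data.frame(tr),
                   as.data.frame(enkf_assimilate(p, w, sch, NULL, M = 150,
                                                 seed = 4)))

  early <- data.frame(date = w$date[1] - 5, value = 500, var = 100)
  expect_error(enkf_assimilate(p, w, sch, early), "precedes")
})

test_that("fourdvar_cost evaluates the quadratic form as printed", {
  # 1-D hand case: identity model, B = 1, R = 1, xb = 0, y = 2, x0 = 1
  prob <- var_problem(xb = c(x = 0), B = matrix(1),
                      obs = data.frame(value = 2, var = 1),
                      forward = function(x0) unname(x0))
  expect_equal(fourdvar_cost(c(x = 1), prob), 0.5 + 0.5)
  expect_equal(fourdvar_cost(c(x = 0), prob), 2)  # pure observation term

  none <- var_problem(xb = c(x = 0.7), B = matrix(1),
                      obs = data.frame(value = numeric(), var = numeric()),
                      forward = function(x0) numeric(0))
  expect_equal(fourdvar_cost(c(x = 0.7), none), 0)

  # perfect background: observations equal the background forecast
  w <- demo_weather()
  p <- crop_params()
  sch <- demo_schedule("N3", 60, w)
  tr <- run(p, w, sch)
  obs <- data.frame(date = tr$date[30], value = tr$tagp[30], var = 100)
  cprob <- make_var_problem(p, w, sch, obs)
  expect_lt(fourdvar_cost(cprob$xb, cprob), 1e-12)
})

test_that("fourdvar_solve matches closed forms on linear-Gaussian problems", {
  # prior-only: the minimum is the background
  prob0 <- var_problem(xb = c(a = 1, b = 2),
                       B = matrix(c(0.5, 0.1, 0.1, 0.4), 2),
                       obs = data.frame(value = numeric(), var = numeric()),
                       forward = function(x0) numeric(0))
  expect_equal(fourdvar_solve(prob0)$x0_opt, c(a = 1, b = 2), tolerance = 1e-6)

  # flat prior, identity model, obs {9, 11} -> sample mean 10
  flat <- var_problem(xb = c(x = 5), B = matrix(1e12),
                      obs = data.frame(value = c(9, 11), var = c(1, 1)),
                      forward = function(x0) rep(unname(x0), 2))
  expect_equal(unname(fourdvar_solve(flat)$x0_opt), 10, tolerance = 1e-3)

  # full vector case vs the normal-equations solution
  A <- matrix(c(0.9, 0.2, -0.1, 0.8), 2, 2)
  H <- matrix(c(1, 0), 1, 2)
  xb <- c(a = 1, b = 2)
  B <- matrix(c(0.5, 0.1, 0.1, 0.4), 2, 2)
  obs <- data.frame(value = c(2.0, 1.5), var = c(0.3, 0.5))
  prob <- var_problem(xb, B, obs,
                      forward = function(x0) c(H %*% (A %*% x0),
                                               H %*% (A %*% (A %*% x0))))
  sol <- fourdvar_solve(prob)
  G <- rbind(H %*% A, H %*% A %*% A)
  Binv <- solve(B)
  xstar <- solve(Binv + t(G) %*% diag(1 / obs$var) %*% G,
                 Binv %*% xb + t(G) %*% (obs$value / obs$var))
  expect_lt(max(abs(sol$x0_opt - xstar) / abs(xstar)), 1e-4)
  expect_lte(sol$cost, sol$cost_b)  # J(x0_opt) <= J(xb)
})

test_that("var_problem rejects a non-SPD background covariance", {
  expect_error(var_problem(c(a = 1), matrix(-1), NULL, identity), "positive definite")
  expect_error(var_problem(c(a = 1, b = 2), diag(2) * c(1, 0), NULL, identity),
               "positive definite")
})

test_that("both schemes cut twin-experiment yield error against the open loop", {
  w <- demo_weather()
  p <- crop_params()
  sch <- demo_schedule("N3", 60, w)
  obs_date <- schedule_dates(w)[["tillering"]]
  # truth: a more vigorous transplant (initial biomass and leaf area +30%)
  truth <- crop_params(lai0 = p$lai0 * 1.3, tagp0 = p$tagp0 * 1.3)
  tr_true <- run(truth, w, sch)
  y_true <- final_yield(tr_true)
  tagp_obs <- state_at(tr_true, obs_date)$tagp
  obs <- data.frame(date = obs_date, value = tagp_obs,
                    var = (0.05 * tagp_obs)^2)
  err_open <- abs(final_yield(run(p, w, sch)) - y_true)

  tr_e <- enkf_assimilate(p, w, sch, obs, M = 100, seed = 7)
  tr_v <- fourdvar_assimilate(p, w, sch, obs)
  expect_lt(abs(final_yield(tr_e) - y_true), 0.5 * err_open)
  expect_lt(abs(final_yield(tr_v) - y_true), 0.5 * err_open)
})
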