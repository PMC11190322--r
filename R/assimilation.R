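# State assimilation of observed aboveground biomass (TAGP) into the crop
# engine: stochastic ensemble Kalman filter and windowed 4D-Var over the
# initial state.

#' Construct a biomass observation
#'
#' @param date observation date.
#' @param value observed TAGP, kg/ha (>= 0).
#' @param var observation error variance, (kg/ha)^2 (> 0).
#' @return object of class `observation`.
#' @export
observation <- function(date, value, var) {
  if (value < 0) stop_("observation: value must be >= 0")
  if (var <= 0) stop_("observation: error variance must be > 0")
  structure(list(date = as.Date(date), value = value, var = var),
            class = "observation")
}

#' Ensemble Kalman analysis step
#'
#' Updates a forecast ensemble with one scalar observation. Cross-covariances
#' `P^F H^T` and the scalar `H P^F H^T` are sample statistics of the ensemble
#' anomalies; the gain is `K = P^F H^T / (R + H P^F H^T)`. Each member is
#' updated against an independently perturbed observation `y + eta`,
#' `eta ~ N(0, R)` (the stochastic EnKF); set `perturb_obs = FALSE` for the
#' deterministic-mean variant used in diagnostics.
#'
#' @param forecast numeric matrix, rows = state components, columns = ensemble
#'   members (M >= 2). A plain numeric vector is treated as a 1 x M matrix.
#' @param obs an [observation()] (or list with `value` and `var`).
#' @param h observed component: a row name or row index (default `"tagp"`
#'   if present, else row 1).
#' @param seed seed for the observation perturbations.
#' @param perturb_obs draw perturbed observations per member (default `TRUE`).
#' @return the analysis ensemble, same shape as `forecast`. With zero
#'   ensemble spread in the observed component the forecast is returned
#'   unchanged with a warning (gain 0).
#' @export
#' @examples
#' ens <- matrix(rnorm(1000, 10, 2), 1)
#' a <- enkf_analysis(ens, observation(Sys.Date(), 12, 1), h = 1, seed = 1)
#' mean(a)  # pulled toward the observation
enkf_analysis <- function(forecast, obs, h = NULL, seed = NULL,
                          perturb_obs = TRUE) {
  if (is.null(dim(forecast))) forecast <- matrix(forecast, nrow = 1)
  M <- ncol(forecast)
  if (M < 2) stop_("enkf_analysis: need an ensemble of at least 2 members")
  if (!all(is.finite(forecast))) stop_("enkf_analysis: non-finite ensemble")
  if (obs$var <= 0) stop_("enkf_analysis: observation variance must be > 0")
  if (is.null(h)) {
    h <- if (!is.null(rownames(forecast)) && "tagp" %in% rownames(forecast)) {
      "tagp"
    } else 1L
  }
  hx <- forecast[h, ]
  hp <- stats::var(hx)
  if (hp == 0) {
    warn_("enkf_analysis: zero ensemble spread in the observed component; gain = 0")
    return(forecast)
  }
  xbar <- rowMeans(forecast)
  anom <- forecast - xbar
  pfht <- drop(anom %*% (hx - mean(hx))) / (M - 1)
  gain <- pfht / (obs$var + hp)
  y <- if (perturb_obs) {
    obs$value + with_seed(seed, stats::rnorm(M, 0, sqrt(obs$var)))
  } else {
    rep(obs$value, M)
  }
  forecast + outer(gain, y - hx)
}

#' Sequential EnKF assimilation over a season
#'
#' Initializes an ensemble by perturbing the initial state components
#' (`lai0`, `tagp0`, `soil_n0`) with multiplicative lognormal noise,
#' propagates it daily through the crop engine, and at each observation date
#' applies [enkf_analysis()] jointly to (LAI, TAGP, soil N) via the sample
#' cross-covariance with TAGP — the model state "jumps" to the analysis and
#' integration continues. Negative post-analysis components are clamped to 0
#' (count recorded).
#'
#' @param params [crop_params()].
#' @param weather,schedule season inputs as in [run()].
#' @param obs_list data frame (`date`, `value`, `var`) of TAGP observations
#'   (kg/ha), or a list of [observation()]s.
#' @param M ensemble size (>= 20 for the full filter).
#' @param perturb named CVs for the initial-state perturbation
#'   (default 0.25 for `lai0`/`tagp0`, 0.25 for `soil_n0`).
#' @param seed master seed (initial perturbations and observation draws).
#' @return a `crop_trajectory` of daily ensemble means with extra columns
#'   `tagp_sd` and `yield_sd`; attributes `final_yield` (ensemble mean),
#'   `final_yield_sd`, `n_clamped` and `method = "enkf"`.
#' @export
enkf_assimilate <- function(params, weather, schedule, obs_list, M = 100L,
                            perturb = c(lai0 = 0.25, tagp0 = 0.25, soil_n0 = 0.25),
                            seed = 1L) {
  obs <- normalize_obs(obs_list)
  if (M < 2) stop_("enkf_assimilate: ensemble size must be >= 2")
  start <- weather$date[1]
  if (nrow(obs) && any(obs$date < start)) {
    stop_("enkf_assimilate: observation on %s precedes the assimilation window",
          as.character(min(obs$date)))
  }
  if (nrow(obs) && any(obs$date > max(weather$date))) {
    stop_("enkf_assimilate: observation after the weather range")
  }
  # lognormal multiplicative perturbations, unit mean
  pert <- with_seed(derive_seed(seed, 1L), {
    sapply(c("lai0", "tagp0", "soil_n0"), function(nm) {
      cv <- perturb[[nm]] %||% 0.25
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(M, -sdlog^2 / 2, sdlog)
    })
  })
  state <- crop_state(start - 1L, dvs = rep(0, M),
                      lai = params$lai0 * pert[, "lai0"],
                      tagp = params$tagp0 * pert[, "tagp0"],
                      soil_n = params$soil_n0 * pert[, "soil_n0"],
                      yield_so_far = rep(0, M))
  n <- nrow(weather)
  traj <- data.frame(date = weather$date, dvs = NA_real_, lai = NA_real_,
                     tagp = NA_real_, soil_n = NA_real_, yield = NA_real_,
                     tagp_sd = NA_real_, yield_sd = NA_real_)
  n_clamped <- 0L
  last <- 0L
  tmin <- weather$tmin; tmax <- weather$tmax; rad <- weather$rad
  for (i in seq_len(n)) {
    fert <- schedule_dose_on(schedule, weather$date[i])
    state <- step(state, params,
                  list(tmin = tmin[i], tmax = tmax[i], rad = rad[i]),
                  fert_today = fert)
    oi <- which(obs$date == weather$date[i])
    for (k in oi) {
      X <- rbind(lai = state$lai, tagp = state$tagp, soil_n = state$soil_n)
      A <- enkf_analysis(X, observation(obs$date[k], obs$value[k], obs$var[k]),
                         h = "tagp", seed = derive_seed(seed, 100L + k))
      n_clamped <- n_clamped + sum(A < 0)
      A[A < 0] <- 0
      state$lai <- A["lai", ]
      state$tagp <- A["tagp", ]
      state$soil_n <- A["soil_n", ]
    }
    traj[i, -1] <- c(state$dvs[1], mean(state$lai), mean(state$tagp),
                     mean(state$soil_n), mean(state$yield_so_far),
                     stats::sd(state$tagp), stats::sd(state$yield_so_far))
    last <- i
    if (all(state$dvs >= 2)) break
  }
  traj <- traj[seq_len(last), , drop = FALSE]
  structure(traj, class = c("crop_trajectory", "data.frame"),
            final_yield = mean(state$yield_so_far),
            final_yield_sd = stats::sd(state$yield_so_far),
            final_state = state, params = params,
            n_clamped = n_clamped, method = "enkf")
}

normalize_obs <- function(obs_list) {
  if (is.data.frame(obs_list)) {
    stopifnot(all(c("date", "value", "var") %in% names(obs_list)))
    data.frame(date = as.Date(obs_list$date), value = obs_list$value,
               var = obs_list$var)
  } else if (is.null(obs_list) || length(obs_list) == 0) {
    data.frame(date = as.Date(character()), value = numeric(), var = numeric())
  } else {
    do.call(rbind, lapply(obs_list, function(o) {
      data.frame(date = as.Date(o$date), value = o$value, var = o$var)
    }))
  }
}

## ---- 4D-Var -----------------------------------------------------------------

#' Define a windowed 4D-Var problem
#'
#' The control vector is the state at the window start; the forward map runs
#' the model across the window and returns the observed quantity at each
#' observation time. For the crop engine use [make_var_problem()]; custom
#' problems (e.g. linear toys) can supply their own `forward`.
#'
#' @param xb background (prior) control vector, named.
#' @param B background error covariance (SPD matrix).
#' @param obs data frame (`value`, `var`), one row per observation, aligned
#'   with the rows of `forward(x0)`.
#' @param forward function `x0 -> numeric` of length `nrow(obs)`: the
#'   model-equivalent of each observation.
#' @param lower,upper optional bounds on the control vector.
#' @param rerun optional function `x0 -> crop_trajectory` producing the
#'   full-season rerun from the analysed control.
#' @return object of class `var_problem`.
#' @export
var_problem <- function(xb, B, obs, forward, lower = NULL, upper = NULL,
                        rerun = NULL) {
  xb <- unlist(xb)
  B <- as.matrix(B)
  if (!isTRUE(all.equal(B, t(B))) || any(eigen(B, symmetric = TRUE,
                                               only.values = TRUE)$values <= 0)) {
    stop_("var_problem: B must be symmetric positive definite")
  }
  if (nrow(B) != length(xb)) stop_("var_problem: dim(B) does not match xb")
  structure(list(xb = xb, B = B, Binv = solve(B), obs = obs, forward = forward,
                 lower = lower, upper = upper, rerun = rerun),
            class = "var_problem")
}

#' 4D-Var cost function
#'
#' `J(x0) = 1/2 (x0 - xb)' B^-1 (x0 - xb) + 1/2 sum_t (h_t(x_t) - y_t)^2 / R_t`
#' where the model states `x_t` are generated by running the forward map from
#' `x0` across the window.
#'
#' @param x0 control vector.
#' @param prob a [var_problem()].
#' @return scalar cost (>= 0).
#' @export
fourdvar_cost <- function(x0, prob) {
  stopifnot(inherits(prob, "var_problem"))
  d <- x0 - prob$xb
  j_b <- 0.5 * drop(t(d) %*% prob$Binv %*% d)
  j_o <- 0
  if (!is.null(prob$obs) && nrow(prob$obs) > 0) {
    hx <- prob$forward(x0)
    if (length(hx) != nrow(prob$obs)) {
      stop_("fourdvar_cost: forward map returned %d values for %d observations",
            length(hx), nrow(prob$obs))
    }
    j_o <- 0.5 * sum((hx - prob$obs$value)^2 / prob$obs$var)
  }
  j_b + j_o
}

#' Minimize the 4D-Var cost
#'
#' Bounded quasi-Newton (`L-BFGS-B`) with finite-difference gradients,
#' started from the background. Non-convergence warns and returns the best
#' iterate.
#'
#' @param prob a [var_problem()].
#' @param control passed to [stats::optim()].
#' @return list with `x0_opt`, `cost` (J at the optimum), `cost_b` (J at the
#'   background), `convergence`, and `trajectory` (full-season rerun from
#'   `x0_opt` when the problem defines `rerun`, else `NULL`).
#' @export
fourdvar_solve <- function(prob, control = list()) {
  stopifnot(inherits(prob, "var_problem"))
  ctl <- utils::modifyList(list(maxit = 200, factr = 1e4), control)
  lower <- prob$lower %||% rep(-Inf, length(prob$xb))
  upper <- prob$upper %||% rep(Inf, length(prob$xb))
  # parscale keeps FD steps proportionate across components of very
  # different magnitude (LAI ~ 0.05, TAGP ~ 50)
  ctl$parscale <- pmax(abs(prob$xb), 1e-3)
  opt <- stats::optim(prob$xb, fourdvar_cost, prob = prob,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = ctl)
  # L-BFGS-B reports an abnormal line search when it stalls on an already
  # stationary point (e.g. a prior-only problem started at xb); that is a
  # converged state, not a failure
  stalled <- grepl("LNSRCH", opt$message %||% "")
  if (opt$convergence != 0 && !stalled) {
    warn_("fourdvar_solve: optimizer code %d (%s); returning best iterate",
          opt$convergence, opt$message %||% "")
  }
  traj <- if (!is.null(prob$rerun)) prob$rerun(opt$par) else NULL
  if (!is.null(traj)) attr(traj, "method") <- "4dvar"
  list(x0_opt = opt$par, cost = opt$value,
       cost_b = fourdvar_cost(prob$xb, prob),
       convergence = opt$convergence, trajectory = traj)
}

#' Build the crop-engine 4D-Var problem
#'
#' Control vector `(lai0, tagp0, soil_n0)` at the season start; the window
#' runs to the last observation; observations are TAGP (kg/ha). `B` defaults
#' to a diagonal with (20% of the background)^2 per component.
#'
#' @param params [crop_params()] supplying the background initial state.
#' @param weather,schedule season inputs as in [run()].
#' @param obs_list TAGP observations as in [enkf_assimilate()].
#' @param B optional background covariance (3 x 3).
#' @return a [var_problem()] whose `rerun` yields the full-season trajectory.
#' @export
make_var_problem <- function(params, weather, schedule, obs_list, B = NULL) {
  obs <- normalize_obs(obs_list)
  if (nrow(obs) && any(obs$date > max(weather$date))) {
    stop_("make_var_problem: observation after the weather range")
  }
  xb <- c(lai0 = params$lai0, tagp0 = params$tagp0, soil_n0 = params$soil_n0)
  if (is.null(B)) B <- diag((0.2 * xb)^2, 3)
  run_from <- function(x0) {
    p <- params
    p$lai0 <- x0[["lai0"]]; p$tagp0 <- x0[["tagp0"]]; p$soil_n0 <- x0[["soil_n0"]]
    run(p, weather, schedule)
  }
  forward <- function(x0) {
    tr <- run_from(x0)
    i <- match(obs$date, tr$date)
    if (anyNA(i)) stop_("4dvar forward: observation date not simulated")
    tr$tagp[i]
  }
  var_problem(xb, B, obs[, c("value", "var")], forward,
              lower = rep(0, 3), upper = xb * 10 + 1,
              rerun = run_from)
}

#' Windowed 4D-Var assimilation over a season
#'
#' Convenience wrapper: builds the crop [make_var_problem()], solves it and
#' returns the full-season trajectory rerun from the analysed initial state.
#'
#' @inheritParams make_var_problem
#' @param control optimizer control, see [fourdvar_solve()].
#' @return a `crop_trajectory` with attributes `x0_opt`, `cost` and
#'   `method = "4dvar"`.
#' @export
fourdvar_assimilate <- function(params, weather, schedule, obs_list, B = NULL,
                                control = list()) {
  prob <- make_var_problem(params, weather, schedule, obs_list, B = B)
  sol <- fourdvar_solve(prob, control = control)
  traj <- sol$trajectory
  attr(traj, "x0_opt") <- sol$x0_opt
  attr(traj, "cost") <- sol$cost
  attr(traj, "method") <- "4dvar"
  traj
}
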