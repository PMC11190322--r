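# Daily-step nitrogen-limited crop growth engine (reduced WOFOST-style causal
# chain: fertilization -> soil N -> growth -> partitioning -> yield), plus
# parameter calibration ("localization") against an LAI series and a yield
# target, and the split-fertilization schedule builder.

#' Crop, soil and initial-state parameters
#'
#' Engineering defaults for a mid-late japonica paddy crop, tuned so that
#' standard N3 management (200 kg N/ha split base/tillering/panicle) yields on
#' the order of 8--10 t/ha grain dry matter. Units: degree-days use `tbase_C`;
#' `rue` is radiation-use efficiency in g DM per MJ intercepted PAR (converted
#' internally to kg/ha via the factor 10); `sla` is ha leaf per kg leaf;
#' `n_conc_target` is kg N per kg new dry matter; `n_recovery` is the
#' fertilizer fraction reaching the crop-available soil pool.
#'
#' @param ... named overrides of any default (see source for the full list).
#' @return object of class `crop_params`.
#' @export
#' @examples
#' p <- crop_params(rue = 2.8)
#' p$rue
crop_params <- function(...) {
  p <- list(
    tbase_C = 8, tsum1 = 900, tsum2 = 950,
    rue = 3.0, k_ext = 0.6, sla = 0.0018,
    leaf_frac0 = 0.55, grain_frac = 0.8, r_sen = 0.006,
    n_conc_target = 0.009, n_recovery = 0.65,
    lai0 = 0.012, tagp0 = 50, soil_n0 = 28
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop_("crop_params: unknown parameter(s) %s",
                           paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_crop_params(p)
  structure(p, class = "crop_params")
}

validate_crop_params <- function(p) {
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                logical(1))
  if (!all(num)) stop_("crop_params: all parameters must be finite scalars")
  if (any(unlist(p[c("tsum1", "tsum2", "rue", "sla", "n_conc_target")]) <= 0)) {
    stop_("crop_params: tsum1, tsum2, rue, sla, n_conc_target must be positive")
  }
  frac <- unlist(p[c("leaf_frac0", "grain_frac", "n_recovery")])
  if (any(frac <= 0 | frac > 1)) {
    stop_("crop_params: partition/recovery fractions must lie in (0, 1]")
  }
  if (p$k_ext <= 0 || p$k_ext >= 1.2) stop_("crop_params: k_ext must lie in (0, 1.2)")
  if (p$r_sen < 0 || p$r_sen >= 1) stop_("crop_params: r_sen must lie in [0, 1)")
  if (any(unlist(p[c("lai0", "tagp0", "soil_n0")]) < 0)) {
    stop_("crop_params: initial states must be non-negative")
  }
  invisible(p)
}

#' @export
print.crop_params <- function(x, ...) {
  cat("<crop_params>\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Initial crop state
#'
#' @param date simulation date.
#' @param dvs development stage (0 emergence, 1 anthesis, 2 maturity).
#' @param lai leaf area index.
#' @param tagp total aboveground dry production, kg/ha.
#' @param soil_n crop-available mineral N, kg/ha.
#' @param yield_so_far accumulated grain dry matter, kg/ha.
#' @return object of class `crop_state` (a named list; fields may be equal
#'   length vectors, which the engine propagates element-wise).
#' @export
crop_state <- function(date, dvs = 0, lai, tagp, soil_n, yield_so_far = 0) {
  structure(list(date = as.Date(date), dvs = dvs, lai = lai, tagp = tagp,
                 soil_n = soil_n, yield_so_far = yield_so_far),
            class = "crop_state")
}

initial_state <- function(params, date) {
  crop_state(date, dvs = 0, lai = params$lai0, tagp = params$tagp0,
             soil_n = params$soil_n0, yield_so_far = 0)
}

#' Advance the crop state by one day
#'
#' Fixed update order: (1) fertilizer enters the soil pool at recovery
#' fraction; (2) phenology advances by thermal time (`tsum1` to anthesis,
#' `tsum2` to maturity, capped at DVS 2); (3) potential growth is
#' `rue * PAR * (1 - exp(-k_ext * lai))` with `PAR = 0.5 * rad`; (4) nitrogen
#' demand `n_conc_target * dW_pot` is met from soil N, defining the stress
#' factor `f_N = uptake / demand`; (5) realized growth `dW = f_N * dW_pot`
#' accrues to TAGP; (6) pre-anthesis, leaves expand at
#' `sla * leaf_frac0 * (1 - dvs) * dW`; post-anthesis the canopy senesces at
#' `r_sen` per day and grain gains `grain_frac * dW`.
#'
#' State fields may be vectors (an ensemble); weather is scalar per day.
#'
#' @param state a [crop_state()].
#' @param params [crop_params()].
#' @param day one-row weather record (`tmin`, `tmax`, `rad`).
#' @param fert_today nitrogen applied this day, kg N/ha.
#' @return the next day's `crop_state`.
#' @export
step <- function(state, params, day, fert_today = 0) {
  p <- params
  soil_n <- state$soil_n + fert_today * p$n_recovery
  tmean <- (day$tmin + day$tmax) / 2
  dtt <- max(0, tmean - p$tbase_C)
  dvs <- ifelse(state$dvs < 1,
                state$dvs + dtt / p$tsum1,
                state$dvs + dtt / p$tsum2)
  dvs <- pmin(dvs, 2)
  par <- 0.5 * day$rad
  dw_pot <- p$rue * 10 * par * (1 - exp(-p$k_ext * state$lai))  # kg DM/ha
  demand <- p$n_conc_target * dw_pot
  uptake <- pmin(demand, soil_n)
  f_n <- ifelse(demand <= 0, 1, uptake / demand)
  soil_n <- soil_n - uptake
  dw <- dw_pot * f_n
  tagp <- state$tagp + dw
  pre <- dvs < 1
  lai <- ifelse(pre,
                state$lai + p$sla * p$leaf_frac0 * pmax(0, 1 - dvs) * dw,
                state$lai * (1 - p$r_sen))
  yield <- ifelse(pre, state$yield_so_far,
                  state$yield_so_far + p$grain_frac * dw)
  crop_state(state$date + 1L, dvs = dvs, lai = lai, tagp = tagp,
             soil_n = soil_n, yield_so_far = yield)
}

schedule_dose_on <- function(schedule, date) {
  if (is.null(schedule) || nrow(schedule) == 0) return(0)
  sum(schedule$n_kg_ha[schedule$date == date])
}

#' Run the crop engine over a season
#'
#' Iterates [step()] daily from the initial state until DVS reaches 2
#' (maturity) or the weather series ends. Rows of the returned trajectory are
#' end-of-day states.
#'
#' @param params [crop_params()].
#' @param weather a `weather_series` covering the season.
#' @param schedule fertilizer schedule data frame (`date`, `n_kg_ha`,
#'   `label`), e.g. from [build_schedule()]; `NULL` for no fertilization.
#' @param init_state optional starting [crop_state()] (default: the initial
#'   state implied by `params` at the first weather date).
#' @param start_date first day to simulate (default: first weather date, or
#'   the day after `init_state$date` when a state is given).
#' @return object of class `crop_trajectory`: a data frame with columns
#'   `date`, `dvs`, `lai`, `tagp`, `soil_n`, `yield`, with the final yield in
#'   `attr(, "final_yield")`.
#' @export
#' @examples
#' w <- generate_weather("2021-05-19", 130, seed = 1)
#' sch <- build_schedule("N3", tillering_n = 60,
#'                       dates = schedule_dates(w))
#' tr <- run(crop_params(), w, sch)
#' final_yield(tr)
run <- function(params, weather, schedule = NULL, init_state = NULL,
                start_date = NULL) {
  stopifnot(is.data.frame(weather))
  if (is.null(start_date)) {
    start_date <- if (is.null(init_state)) weather$date[1] else init_state$date + 1L
  }
  start_date <- as.Date(start_date)
  if (!is.null(schedule) && nrow(schedule) > 0) {
    sched_dates <- as.Date(schedule$date)
    # events before a mid-season restart are treated as already applied, but a
    # full-season run must cover every event
    bad <- sched_dates > max(weather$date) |
      (is.null(init_state) & sched_dates < weather$date[1])
    if (any(bad)) {
      stop_("run: schedule event on %s lies outside the weather range",
            as.character(sched_dates[which(bad)[1]]))
    }
  }
  if (is.null(init_state)) init_state <- initial_state(params, start_date - 1L)
  days <- weather[weather$date >= start_date, , drop = FALSE]
  if (nrow(days) == 0) stop_("run: no weather on/after %s", as.character(start_date))
  state <- init_state
  n <- nrow(days)
  tmin <- days$tmin; tmax <- days$tmax; rad <- days$rad
  fert_by_day <- numeric(n)
  if (!is.null(schedule) && nrow(schedule) > 0) {
    j <- match(as.Date(schedule$date), days$date)
    for (r in seq_along(j)) {
      if (!is.na(j[r])) fert_by_day[j[r]] <- fert_by_day[j[r]] + schedule$n_kg_ha[r]
    }
  }
  traj <- data.frame(date = days$date, dvs = NA_real_, lai = NA_real_,
                     tagp = NA_real_, soil_n = NA_real_, yield = NA_real_)
  last <- 0L
  for (i in seq_len(n)) {
    state <- step(state, params,
                  list(tmin = tmin[i], tmax = tmax[i], rad = rad[i]),
                  fert_today = fert_by_day[i])
    traj[i, -1] <- c(state$dvs[1], mean(state$lai), mean(state$tagp),
                     mean(state$soil_n), mean(state$yield_so_far))
    last <- i
    if (all(state$dvs >= 2)) break
  }
  traj <- traj[seq_len(last), , drop = FALSE]
  structure(traj,
            class = c("crop_trajectory", "data.frame"),
            final_yield = mean(state$yield_so_far),
            final_state = state,
            params = params)
}

#' Final grain yield of a trajectory
#' @param traj a `crop_trajectory`.
#' @return final grain dry matter, kg/ha.
#' @export
final_yield <- function(traj) attr(traj, "final_yield")

#' State of a trajectory at a given date
#' @param traj a `crop_trajectory`.
#' @param date date of interest (must be a simulated day).
#' @return a [crop_state()].
#' @export
state_at <- function(traj, date) {
  date <- as.Date(date)
  i <- match(date, traj$date)
  if (is.na(i)) stop_("state_at: %s is not a simulated day", as.character(date))
  crop_state(date, dvs = traj$dvs[i], lai = traj$lai[i], tagp = traj$tagp[i],
             soil_n = traj$soil_n[i], yield_so_far = traj$yield[i])
}

#' @export
print.crop_trajectory <- function(x, ...) {
  cat(sprintf("<crop_trajectory> %d days (%s to %s), final yield %.0f kg/ha\n",
              nrow(x), as.character(x$date[1]), as.character(x$date[nrow(x)]),
              attr(x, "final_yield")))
  invisible(x)
}

#' @export
plot.crop_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$date, x$lai, type = "l", ylab = "LAI", xlab = "", ...)
  graphics::plot(x$date, x$tagp / 1000, type = "l", ylab = "TAGP (t/ha)",
                 xlab = "", ...)
  graphics::lines(x$date, x$yield / 1000, lty = 2)
  invisible(x)
}

## ---- fertilizer schedules ---------------------------------------------------

gradient_rates <- c(N0 = 0, N1 = 100, N2 = 150, N3 = 200, N4 = 250)

#' Default split-fertilization dates for a weather series
#'
#' Base dressing on the first day, tillering topdress 30 days in, panicle
#' dressing 70 days in (clipped to the season).
#'
#' @param weather a `weather_series`.
#' @return named `Date` vector (`base`, `tillering`, `panicle`).
#' @export
schedule_dates <- function(weather) {
  d0 <- weather$date[1]
  n <- nrow(weather)
  c(base = d0, tillering = d0 + min(30L, n - 1L), panicle = d0 + min(70L, n - 1L))
}

#' Build a split nitrogen schedule for a gradient treatment
#'
#' Base dressing is 50% of the gradient's seasonal rate (N0 = 0, N1 = 100,
#' N2 = 150, N3 = 200, N4 = 250 kg N/ha); the panicle dressing is 20% of the
#' local standard rate; the tillering dose is caller-supplied (it is the
#' decision variable).
#'
#' @param gradient one of `"N0".."N4"`.
#' @param tillering_n tillering dose, kg N/ha.
#' @param dates named dates (`base`, `tillering`, `panicle`), e.g. from
#'   [schedule_dates()].
#' @param standard_n local standard seasonal rate, kg N/ha (default 200).
#' @return schedule data frame (`date`, `n_kg_ha`, `label`).
#' @export
#' @examples
#' w <- generate_weather("2021-05-19", 130, seed = 1)
#' build_schedule("N3", tillering_n = 60, dates = schedule_dates(w))
build_schedule <- function(gradient, tillering_n, dates, standard_n = 200) {
  if (!gradient %in% names(gradient_rates)) {
    stop_("build_schedule: unknown gradient '%s'", gradient)
  }
  stopifnot(all(c("base", "tillering", "panicle") %in% names(dates)),
            tillering_n >= 0)
  data.frame(
    date = as.Date(dates[c("base", "tillering", "panicle")]),
    n_kg_ha = c(0.5 * gradient_rates[[gradient]], tillering_n, 0.2 * standard_n),
    label = c("base", "tillering", "panicle"),
    row.names = NULL
  )
}

## ---- calibration ("localization") -------------------------------------------

#' Calibrate unmeasurable crop parameters against LAI and yield
#'
#' Minimizes
#' `sum((lai_sim - lai_obs)^2) / var(lai_obs) + ((yield_sim - target)/target)^2`
#' over the named free parameters by Nelder-Mead on a logistic bound
#' transform (derivative-free; the day-stepped model makes finite-difference
#' gradients unreliable at phenology breakpoints).
#'
#' @param params0 starting [crop_params()].
#' @param free_names names of parameters to optimize.
#' @param lai_obs data frame (`date`, `lai`) of observed LAI.
#' @param target_yield yield target, kg/ha (default 9000, the variety mean).
#' @param weather,schedule season inputs as in [run()].
#' @param bounds list with named numeric vectors `lower` and `upper` covering
#'   `free_names`.
#' @param control passed to [stats::optim()] (Nelder-Mead).
#' @return calibrated `crop_params` with attributes `cost` (final value),
#'   `cost_trace` and `convergence`. Non-convergence warns and returns the
#'   best iterate.
#' @export
calibrate <- function(params0, free_names, lai_obs, target_yield = 9000,
                      weather, schedule, bounds, control = list()) {
  stopifnot(all(free_names %in% names(params0)))
  lower <- bounds$lower[free_names]
  upper <- bounds$upper[free_names]
  if (anyNA(lower) || anyNA(upper) || any(!is.finite(c(lower, upper)))) {
    stop_("calibrate: finite lower/upper bounds required for all free parameters")
  }
  lai_obs$date <- as.Date(lai_obs$date)
  v_lai <- stats::var(lai_obs$lai)
  if (!is.finite(v_lai) || v_lai <= 0) v_lai <- 1
  trace <- numeric(0)

  cost_of <- function(vals) {
    p <- params0
    p[free_names] <- as.list(vals)
    tr <- run(p, weather, schedule)
    i <- match(lai_obs$date, tr$date)
    lai_sim <- ifelse(is.na(i), 0, tr$lai[i])
    c_lai <- sum((lai_sim - lai_obs$lai)^2) / v_lai
    c_yld <- ((final_yield(tr) - target_yield) / target_yield)^2
    c_lai + c_yld
  }

  to_z <- function(v) stats::qlogis(pmin(pmax((v - lower) / (upper - lower),
                                              1e-9), 1 - 1e-9))
  to_v <- function(z) lower + (upper - lower) * stats::plogis(z)

  obj <- function(z) {
    val <- cost_of(to_v(z))
    trace <<- c(trace, val)
    val
  }
  ctl <- utils::modifyList(list(maxit = 800, reltol = 1e-12), control)
  if (length(free_names) == 1L) {
    # 1-D: golden-section/parabolic search on the raw bounded scale
    raw_obj <- function(v) {
      val <- cost_of(v)
      trace <<- c(trace, val)
      val
    }
    opt <- stats::optim(unlist(params0[free_names]), raw_obj, method = "Brent",
                        lower = lower, upper = upper)
    opt$par <- to_z(opt$par)
  } else {
    z0 <- to_z(unlist(params0[free_names]))
    opt <- stats::optim(z0, obj, method = "Nelder-Mead", control = ctl)
    # one restart from the incumbent tightens simplex-collapse finishes
    opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead", control = ctl)
    if (opt2$value < opt$value) opt <- opt2
  }
  if (opt$convergence != 0) {
    warn_("calibrate: optimizer did not converge (code %d); returning best iterate",
          opt$convergence)
  }
  out <- params0
  out[free_names] <- as.list(to_v(opt$par))
  validate_crop_params(out)
  structure(out, class = "crop_params", cost = opt$value, cost_trace = trace,
            convergence = opt$convergence)
}
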