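# Tillering-stage nitrogen dose search and variable-rate prescription maps.

#' Decision settings
#'
#' @param target_yield yield target, kg/ha (default 9000, the variety mean).
#' @param tolerance acceptable shortfall below the target, kg/ha (default 50).
#' @param dose_cap maximum tillering dose, kg N/ha (default 150).
#' @param dose_step search grid spacing, kg N/ha (default 5; bisection then
#'   refines to `dose_step / 10`).
#' @param tillering_date date of the tillering topdress (defaults to the day
#'   after the corrected state when omitted).
#' @return object of class `decision_config`.
#' @export
decision_config <- function(target_yield = 9000, tolerance = 50,
                            dose_cap = 150, dose_step = 5,
                            tillering_date = NULL) {
  stopifnot(target_yield > 0, tolerance >= 0, dose_step > 0,
            dose_step <= dose_cap)
  structure(list(target_yield = target_yield, tolerance = tolerance,
                 dose_cap = dose_cap, dose_step = dose_step,
                 tillering_date = if (is.null(tillering_date)) NULL
                                  else as.Date(tillering_date)),
            class = "decision_config")
}

#' Simulated yield as a function of the tillering dose
#'
#' Inserts a tillering event of the given dose and integrates the engine from
#' the (assimilation-corrected) state to maturity. Deterministic in all
#' arguments.
#'
#' @param state corrected [crop_state()] at the tillering decision date.
#' @param params [crop_params()].
#' @param weather season weather (must cover the remaining season).
#' @param schedule_rest remaining schedule after the decision date (e.g. the
#'   panicle dressing); the tillering event is added by this function.
#' @param dose tillering nitrogen dose, kg N/ha (>= 0).
#' @param tillering_date date of the topdress (default: day after `state`).
#' @return final grain yield, kg/ha.
#' @export
yield_response <- function(state, params, weather, schedule_rest, dose,
                           tillering_date = NULL) {
  if (dose < 0) stop_("yield_response: dose must be >= 0")
  if (is.null(tillering_date)) tillering_date <- state$date + 1L
  till <- data.frame(date = as.Date(tillering_date), n_kg_ha = dose,
                     label = "tillering")
  sched <- if (is.null(schedule_rest) || nrow(schedule_rest) == 0) {
    till
  } else {
    rbind(till, schedule_rest[, c("date", "n_kg_ha", "label")])
  }
  tr <- run(params, weather, sched, init_state = state)
  final_yield(tr)
}

#' Decide the tillering nitrogen dose
#'
#' Finds the smallest dose whose predicted yield reaches
#' `target_yield - tolerance`. If the zero dose already suffices, returns 0;
#' if even the cap falls short, returns the cap with `shortfall = TRUE`.
#' Otherwise the dose grid (`dose_step`) is scanned upward and the bracketing
#' step is refined by bisection to `dose_step / 10` resolution.
#'
#' @param state,params,weather,schedule_rest as in [yield_response()]
#'   (ignored when `response_fn` is supplied).
#' @param cfg a [decision_config()].
#' @param response_fn optional function `dose -> yield` replacing the engine
#'   response (used for testing and for precomputed responses).
#' @return list with `dose` (kg N/ha), `predicted_yield` (kg/ha) and
#'   `shortfall` flag.
#' @export
decide_dose <- function(state = NULL, params = NULL, weather = NULL,
                        schedule_rest = NULL, cfg = decision_config(),
                        response_fn = NULL) {
  f <- response_fn %||% function(d) {
    yield_response(state, params, weather, schedule_rest, d,
                   tillering_date = cfg$tillering_date)
  }
  thr <- cfg$target_yield - cfg$tolerance
  y0 <- f(0)
  if (y0 >= thr) {
    return(list(dose = 0, predicted_yield = y0, shortfall = FALSE))
  }
  ycap <- f(cfg$dose_cap)
  if (ycap < thr) {
    return(list(dose = cfg$dose_cap, predicted_yield = ycap, shortfall = TRUE))
  }
  grid <- seq(cfg$dose_step, cfg$dose_cap, by = cfg$dose_step)
  lo <- 0
  hi <- cfg$dose_cap
  for (d in grid) {
    if (f(d) >= thr) { hi <- d; break }
    lo <- d
  }
  while (hi - lo > cfg$dose_step / 10) {
    mid <- (lo + hi) / 2
    if (f(mid) >= thr) hi <- mid else lo <- mid
  }
  list(dose = hi, predicted_yield = f(hi), shortfall = FALSE)
}

#' Per-zone prescription map
#'
#' Runs [decide_dose()] for every zone of the layout from its
#' assimilation-corrected state and converts the nitrogen dose to a urea
#' rate (urea is 46% N; rounded to 1 kg/ha). Zones whose gradient is listed
#' in `exclude_gradients` (default the unfertilized N0 controls) are carried
#' with `excluded = TRUE` and no dose.
#'
#' @param layout a [make_gradient_layout()] / [read_layout_geojson()] layout.
#' @param zone_states named list (by `zone_id`) of lists with elements
#'   `state` (a [crop_state()]) and `method` (`"enkf"` or `"4dvar"`).
#' @param params,weather cropping inputs as in [yield_response()].
#' @param schedule_rest remaining schedule events (per zone: a named list by
#'   zone_id, or one data frame shared by all zones).
#' @param cfg a [decision_config()].
#' @param exclude_gradients gradient labels to skip (default `"N0"`).
#' @return object of class `prescription_map`: a data frame with one row per
#'   zone (`zone_id`, `plot_id`, `gradient`, `method`, `n_dose_kg_ha`,
#'   `urea_kg_ha`, `predicted_yield_kg_ha`, `shortfall`, `excluded`) and the
#'   layout stored as an attribute.
#' @export
prescribe <- function(layout, zone_states, params, weather, schedule_rest,
                      cfg = decision_config(), exclude_gradients = "N0") {
  stopifnot(inherits(layout, "plot_layout"))
  rows <- lapply(layout$zones, function(z) {
    excluded <- z$gradient %in% exclude_gradients
    if (excluded) {
      return(data.frame(zone_id = z$zone_id, plot_id = z$plot_id,
                        gradient = z$gradient, method = NA_character_,
                        n_dose_kg_ha = NA_real_, urea_kg_ha = NA_real_,
                        predicted_yield_kg_ha = NA_real_, shortfall = FALSE,
                        excluded = TRUE))
    }
    zs <- zone_states[[z$zone_id]]
    if (is.null(zs)) {
      stop_("prescribe: no corrected state for zone %s", z$zone_id)
    }
    rest <- if (is.data.frame(schedule_rest)) schedule_rest
            else schedule_rest[[z$zone_id]]
    dec <- decide_dose(zs$state, params, weather, rest, cfg)
    data.frame(zone_id = z$zone_id, plot_id = z$plot_id, gradient = z$gradient,
               method = zs$method, n_dose_kg_ha = dec$dose,
               urea_kg_ha = round(dec$dose / 0.46),
               predicted_yield_kg_ha = dec$predicted_yield,
               shortfall = dec$shortfall, excluded = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("prescription_map", "data.frame"), layout = layout)
}

#' @export
print.prescription_map <- function(x, ...) {
  act <- x[!x$excluded, , drop = FALSE]
  cat(sprintf("<prescription_map> %d zones (%d prescribed, %d excluded)\n",
              nrow(x), nrow(act), sum(x$excluded)))
  if (nrow(act)) {
    cat(sprintf("  N dose: %.1f-%.1f kg/ha (mean %.1f), urea mean %.0f kg/ha\n",
                min(act$n_dose_kg_ha), max(act$n_dose_kg_ha),
                mean(act$n_dose_kg_ha), mean(act$urea_kg_ha)))
  }
  invisible(x)
}

#' Compare EnKF- and 4D-Var-based prescriptions
#'
#' Reports per-zone and mean dose differences (4D-Var minus EnKF) and each
#' method's total as a percentage of the standard fixed scheme (the standard
#' tillering dose applied uniformly to the same zones).
#'
#' @param map_enkf,map_4dvar [prescribe()] maps over the same zones.
#' @param standard_tillering_n the standard uniform tillering dose, kg N/ha
#'   (default 60 = the 200 kg/ha scheme minus its base and panicle splits).
#' @return list with `table` (per-zone doses and differences),
#'   `mean_difference_kg_ha`, `total_enkf_kg_ha`, `total_4dvar_kg_ha`,
#'   `pct_of_standard_enkf`, `pct_of_standard_4dvar` and
#'   `saving_enkf_vs_standard_pct`.
#' @export
compare_methods <- function(map_enkf, map_4dvar, standard_tillering_n = 60) {
  a <- map_enkf[!map_enkf$excluded, , drop = FALSE]
  b <- map_4dvar[!map_4dvar$excluded, , drop = FALSE]
  if (!identical(sort(a$zone_id), sort(b$zone_id))) {
    stop_("compare_methods: the two maps cover different zones")
  }
  b <- b[match(a$zone_id, b$zone_id), , drop = FALSE]
  diff <- b$n_dose_kg_ha - a$n_dose_kg_ha
  tab <- data.frame(zone_id = a$zone_id, gradient = a$gradient,
                    dose_enkf = a$n_dose_kg_ha, dose_4dvar = b$n_dose_kg_ha,
                    difference = diff)
  tot_std <- standard_tillering_n * nrow(a)
  list(
    table = tab,
    mean_difference_kg_ha = mean(diff),
    total_enkf_kg_ha = sum(a$n_dose_kg_ha),
    total_4dvar_kg_ha = sum(b$n_dose_kg_ha),
    pct_of_standard_enkf = 100 * sum(a$n_dose_kg_ha) / tot_std,
    pct_of_standard_4dvar = 100 * sum(b$n_dose_kg_ha) / tot_std,
    saving_enkf_vs_standard_pct = 100 * (1 - sum(a$n_dose_kg_ha) / tot_std)
  )
}

#' @rdname paddydose-io
#' @export
write_prescription_geojson <- function(x, path) {
  stopifnot(inherits(x, "prescription_map"))
  layout <- attr(x, "layout")
  zone_of <- stats::setNames(layout$zones,
                             vapply(layout$zones, `[[`, "", "zone_id"))
  feats <- lapply(seq_len(nrow(x)), function(i) {
    z <- zone_of[[x$zone_id[i]]]
    ring <- rbind(z$coords, z$coords[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(
        zone_id = x$zone_id[i], plot_id = x$plot_id[i],
        gradient = x$gradient[i], method = x$method[i],
        n_kg_ha = x$n_dose_kg_ha[i], urea_kg_ha = x$urea_kg_ha[i],
        predicted_yield_kg_ha = x$predicted_yield_kg_ha[i],
        shortfall = x$shortfall[i], excluded = x$excluded[i]
      ),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(j) as.numeric(ring[j, ]))))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname paddydose-io
#' @export
read_prescription_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  zones <- list()
  rows <- lapply(gj$features, function(f) {
    p <- f$properties
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring <- ring[-nrow(ring), , drop = FALSE]
    colnames(ring) <- c("x", "y")
    zones[[length(zones) + 1L]] <<- list(zone_id = p$zone_id,
                                         plot_id = p$plot_id,
                                         gradient = p$gradient, coords = ring)
    data.frame(zone_id = p$zone_id, plot_id = p$plot_id, gradient = p$gradient,
               method = p$method %||% NA_character_,
               n_dose_kg_ha = p$n_kg_ha %||% NA_real_,
               urea_kg_ha = p$urea_kg_ha %||% NA_real_,
               predicted_yield_kg_ha = p$predicted_yield_kg_ha %||% NA_real_,
               shortfall = isTRUE(p$shortfall), excluded = isTRUE(p$excluded))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("prescription_map", "data.frame"),
            layout = structure(list(zones = zones), class = "plot_layout"))
}
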