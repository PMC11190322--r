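test_that("yield_response continues the season deterministically from a state", {
  w <- demo_weather()
  p <- crop_params()
  dates <- schedule_dates(w)
  sch_base <- build_schedule("N2", 0, dates)[1, ]  # base dressing only
  tr <- run(p, w, sch_base)
  st <- state_at(tr, dates[["tillering"]])
  rest <- build_schedule("N2", 0, dates)[3, ]      # panicle dressing remains

  # dose 0 equals a plain continuation without a tillering event
  y0 <- yield_response(st, p, w, rest, dose = 0)
  cont <- run(p, w, rest, init_state = st)
  expect_equal(y0, final_yield(cont))
  expect_equal(y0, yield_response(st, p, w, rest, dose = 0))

  # non-decreasing over a dose scan
  ys <- vapply(seq(0, 150, by = 30), function(d) {
    yield_response(st, p, w, rest, dose = d)
  }, numeric(1))
  expect_true(all(diff(ys) >= 0))
  expect_error(yield_response(st, p, w, rest, dose = -5), ">= 0")
})

test_that("decide_dose matches an exhaustive fine-grid oracle", {
  # synthetic saturating response, exactly solvable
  resp <- function(d) 6000 + 40 * pmin(d, 300) * (1 - pmin(d, 300) / 300)
  cfg <- decision_config(target_yield = 9000, tolerance = 50,
                         dose_cap = 150, dose_step = 5)
  dec <- decide_dose(cfg = cfg, response_fn = resp)

  grid <- seq(0, 150, by = 0.5)
  oracle <- grid[which(vapply(grid, resp, numeric(1)) >= 9000 - 50)[1]]
  expect_lt(abs(dec$dose - oracle), 0.5)
  expect_false(dec$shortfall)
  expect_gte(dec$predicted_yield, 9000 - 50)
})

test_that("decide_dose shortcut and shortfall branches trigger correctly", {
  cfg <- decision_config(target_yield = 9000, tolerance = 50, dose_cap = 150)
  rich <- decide_dose(cfg = cfg, response_fn = function(d) 9500)
  expect_equal(rich$dose, 0)
  expect_false(rich$shortfall)

  poor <- decide_dose(cfg = cfg, response_fn = function(d) 7000 + d)
  expect_equal(poor$dose, 150)
  expect_true(poor$shortfall)
  expect_equal(poor$predicted_yield, 7150)
})

test_that("the decided dose is monotone in the target and in crop status", {
  resp <- function(d) 6000 + 40 * pmin(d, 300) * (1 - pmin(d, 300) / 300)
  doses <- vapply(c(7000, 8000, 9000), function(ty) {
    decide_dose(cfg = decision_config(target_yield = ty, tolerance = 50),
                response_fn = resp)$dose
  }, numeric(1))
  expect_true(all(diff(doses) >= 0))

  # a zone with more residual soil N never receives a larger dose
  w <- demo_weather()
  p <- crop_params()
  dates <- schedule_dates(w)
  rest <- build_schedule("N2", 0, dates)[3, ]
  tr <- run(p, w, build_schedule("N2", 0, dates)[1, ])
  st <- state_at(tr, dates[["tillering"]])
  st_rich <- st
  st_rich$soil_n <- st$soil_n + 30
  cfg <- decision_config(tillering_date = dates[["tillering"]] + 1)
  d_poor <- decide_dose(st, p, w, rest, cfg)$dose
  d_rich <- decide_dose(st_rich, p, w, rest, cfg)$dose
  expect_lte(d_rich, d_poor)
})

test_that("prescribe converts doses to urea and round-trips GeoJSON", {
  w <- demo_weather()
  p <- crop_params()
  dates <- schedule_dates(w)
  lay <- make_gradient_layout(5)
  rest <- data.frame(date = dates[["panicle"]], n_kg_ha = 40, label = "panicle")
  states <- list()
  for (z in lay$zones) {
    if (z$gradient == "N0") next
    sch_base <- build_schedule(z$gradient, 0, dates)[1, ]
    tr <- run(p, w, sch_base)
    states[[z$zone_id]] <- list(state = state_at(tr, dates[["tillering"]]),
                                method = if (grepl("A$", z$zone_id)) "enkf"
                                         else "4dvar")
  }
  cfg <- decision_config(dose_step = 10, tillering_date = dates[["tillering"]] + 1)
  map <- prescribe(lay, states, p, w, rest, cfg)
  expect_s3_class(map, "prescription_map")
  expect_equal(nrow(map), 10)
  expect_equal(sum(map$excluded), 2)  # the N0 plot's two halves
  act <- map[!map$excluded, ]
  expect_equal(act$urea_kg_ha, round(act$n_dose_kg_ha / 0.46))

  f <- withr::local_tempfile(fileext = ".geojson")
  write_prescription_geojson(map, f)
  back <- read_prescription_geojson(f)
  expect_equal(back$n_dose_kg_ha, map$n_dose_kg_ha)
  expect_equal(back$urea_kg_ha, map$urea_kg_ha)
  expect_equal(back$zone_id, map$zone_id)
  expect_equal(back$shortfall, map$shortfall)

  # a missing state is reported with its zone id
  states2 <- states
  states2[["P02A"]] <- NULL
  expect_error(prescribe(lay, states2, p, w, rest, cfg), "P02A")
})

test_that("compare_methods reports per-zone and aggregate differences", {
  w <- demo_weather()
  p <- crop_params()
  dates <- schedule_dates(w)
  lay <- make_gradient_layout(5)
  rest <- data.frame(date = dates[["panicle"]], n_kg_ha = 40, label = "panicle")
  states <- list()
  for (z in lay$zones) {
    if (z$gradient == "N0") next
    tr <- run(p, w, build_schedule(z$gradient, 0, dates)[1, ])
    states[[z$zone_id]] <- list(state = state_at(tr, dates[["tillering"]]),
                                method = "enkf")
  }
  cfg <- decision_config(dose_step = 10, tillering_date = dates[["tillering"]] + 1)
  map <- prescribe(lay, states, p, w, rest, cfg)
  cmp <- compare_methods(map, map)
  expect_equal(cmp$mean_difference_kg_ha, 0)
  expect_true(all(cmp$table$difference == 0))
  expect_equal(cmp$mean_difference_kg_ha, mean(cmp$table$difference))
  expect_equal(cmp$pct_of_standard_enkf, cmp$pct_of_standard_4dvar)

  other <- map[map$zone_id != "P02A", ]
  attr(other, "layout") <- attr(map, "layout")
  expect_error(compare_methods(map, other), "different zones")
})
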