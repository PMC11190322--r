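test_that("step responds correctly to light and nitrogen limitation", {
  p <- crop_params()
  s0 <- crop_state("2021-06-01", dvs = 0.3, lai = 2, tagp = 1500,
                   soil_n = 10, yield_so_far = 0)

  dark <- step(s0, p, list(tmin = 18, tmax = 26, rad = 0))
  expect_equal(dark$tagp, s0$tagp)
  expect_equal(dark$yield_so_far, 0)
  expect_gt(dark$dvs, s0$dvs)  # phenology still advances

  starved <- crop_state("2021-06-01", dvs = 0.3, lai = 2, tagp = 1500,
                        soil_n = 0, yield_so_far = 0)
  after <- step(starved, p, list(tmin = 18, tmax = 26, rad = 18))
  expect_equal(after$tagp, starved$tagp)  # f_N = 0 -> no growth
  expect_equal(after$soil_n, 0)
})

test_that("season runs are deterministic and respect the engine invariants", {
  w <- demo_weather()
  p <- crop_params()
  sch <- demo_schedule("N3", 60, w)
  tr <- run(p, w, sch)
  expect_identical(as.data.frame(tr), as.data.frame(run(p, w, sch)))

  expect_true(all(diff(tr$tagp) >= 0))
  expect_true(all(diff(tr$dvs) >= 0))
  expect_true(all(tr$yield <= tr$tagp))
  # grain only accumulates after anthesis
  expect_true(all(tr$yield[tr$dvs < 1] == 0))
  expect_gt(final_yield(tr), 0)

  # soil N conservation: uptake is n_conc_target per realized kg DM, so
  # soil_n(t+1) - soil_n(t) = recovery*fert - n_conc_target*dTAGP
  fert <- numeric(nrow(tr))
  fert[match(as.Date(sch$date), tr$date)] <- sch$n_kg_ha
  prev_n <- c(p$soil_n0, tr$soil_n[-nrow(tr)])
  prev_t <- c(p$tagp0, tr$tagp[-nrow(tr)])
  lhs <- tr$soil_n - prev_n
  rhs <- p$n_recovery * fert - p$n_conc_target * (tr$tagp - prev_t)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("a crop below base temperature never develops", {
  w <- demo_weather(40)
  w$tmin[] <- 8
  w$tmax[] <- 8
  tr <- run(crop_params(), w, NULL)
  expect_equal(nrow(tr), 40)  # runs to the weather end
  expect_true(all(tr$dvs == 0))
})

test_that("yield and biomass respond monotonically to inputs", {
  w <- demo_weather()
  p <- crop_params()
  dates <- schedule_dates(w)
  # larger base dose -> at least as much biomass
  y <- vapply(c("N1", "N2", "N3", "N4"), function(g) {
    tail(run(p, w, build_schedule(g, 60, dates))$tagp, 1)
  }, numeric(1))
  expect_true(all(diff(y) >= 0))

  # doubling RUE with N non-limiting strictly raises biomass
  rich <- crop_params(soil_n0 = 1e6)
  rich2 <- crop_params(soil_n0 = 1e6, rue = 2 * rich$rue)
  expect_gt(tail(run(rich2, w, NULL)$tagp, 1), tail(run(rich, w, NULL)$tagp, 1))

  # tillering dose response is non-decreasing up to the cap
  doses <- seq(0, 150, by = 25)
  yd <- vapply(doses, function(d) {
    final_yield(run(p, w, build_schedule("N2", d, dates)))
  }, numeric(1))
  expect_true(all(diff(yd) >= 0))
})

test_that("schedules follow the split-dressing arithmetic", {
  w <- demo_weather(90)
  dates <- schedule_dates(w)
  n3 <- build_schedule("N3", tillering_n = 60, dates = dates)
  expect_equal(n3$n_kg_ha, c(100, 60, 40))  # 50% of 200; caller; 20% of 200
  expect_equal(build_schedule("N0", 0, dates)$n_kg_ha[1], 0)
  expect_equal(build_schedule("N4", 0, dates)$n_kg_ha[1], 125)
  expect_error(build_schedule("N9", 0, dates), "unknown gradient")

  late <- data.frame(date = max(w$date) + 10, n_kg_ha = 50, label = "base")
  expect_error(run(crop_params(), w, late), "outside the weather range")
})

test_that("calibration sits at a zero-cost fixed point on self-generated data", {
  w <- demo_weather()
  sch <- demo_schedule("N3", 60, w)
  p0 <- crop_params()
  tr <- run(p0, w, sch)
  obs <- data.frame(date = tr$date[seq(10, nrow(tr), by = 10)],
                    lai = tr$lai[seq(10, nrow(tr), by = 10)])
  cal <- calibrate(p0, c("tsum1", "rue"), obs, target_yield = final_yield(tr),
                   weather = w, schedule = sch,
                   bounds = list(lower = c(tsum1 = 700, rue = 2),
                                 upper = c(tsum1 = 1300, rue = 4)),
                   control = list(maxit = 200))
  expect_lt(attr(cal, "cost"), 1e-6)
  expect_s3_class(cal, "crop_params")
})

test_that("calibration warns instead of failing when iterations run out", {
  w <- demo_weather(60)
  sch <- demo_schedule("N3", 60, w)
  p0 <- crop_params(rue = 3.5, tsum1 = 1000)
  tr <- run(crop_params(), w, sch)
  obs <- data.frame(date = tr$date[c(20, 40)], lai = tr$lai[c(20, 40)])
  expect_warning(
    calibrate(p0, c("rue", "tsum1"), obs, target_yield = 9000,
              weather = w, schedule = sch,
              bounds = list(lower = c(rue = 2, tsum1 = 700),
                            upper = c(rue = 4, tsum1 = 1300)),
              control = list(maxit = 2)),
    "converge")
})
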