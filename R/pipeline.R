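# End-to-end orchestration: synthesize/ingest -> select bands -> train the
# inversion -> invert plot spectra into observations -> assimilate (EnKF on
# one half-plot, 4D-Var on the other) -> decide doses -> prescription map.

#' Default pipeline configuration
#'
#' A self-contained demo scenario: synthetic weather, a ten-plot gradient
#' layout, an endmember-mixing training set, per-plot "true" crops whose
#' tillering-date spectra are inverted into the assimilated observations.
#' Every stage has its own seed derived from `seed`.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed.
#' @return nested configuration list (class `run_config`).
#' @export
default_config <- function(out_dir = tempfile("paddydose_run_"), seed = 1L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    synth = list(
      enabled = TRUE,
      start_date = "2021-05-19", n_days = 130L,
      n_train = 200L, noise_sd = 0.01,
      n_plots = 10L,
      soil_fertility_cv = 0.3,   # per-plot lognormal spread on soil_n0
      vigor_cv = 0.2             # per-plot lognormal spread on lai0/tagp0
    ),
    paths = list(weather = NULL, spectra = NULL, layout = NULL),
    selection = list(n_min = 5L, n_max = 30L, folds = 5L),
    elm = list(ratio = 0.7, n_hidden = 50L, activation = "sigmoid"),
    engine = crop_params(),
    assimilation = list(M = 100L, obs_rel_sd = 0.08),
    decision = list(target_yield = 9000, tolerance = 50,
                    dose_cap = 150, dose_step = 5),
    standard_n = 200
  ), class = "run_config")
}

validate_config <- function(cfg) {
  if (!isTRUE(cfg$synth$enabled)) {
    for (nm in c("weather", "spectra", "layout")) {
      p <- cfg$paths[[nm]]
      if (is.null(p)) stop_("config: paths$%s is required when synth is disabled", nm)
      if (!file.exists(p)) stop_("config: missing input file '%s' (paths$%s)", p, nm)
    }
  }
  if (!is.numeric(cfg$seed)) stop_("config: seed must be an integer")
  invisible(cfg)
}

#' Run the full fertilization-decision pipeline
#'
#' Executes every stage in order and writes all intermediates to
#' `cfg$out_dir`: `weather.csv`, `spectra.csv`, `layout.geojson` (when
#' synthesized), `selection.json`, `model.json`, `report.json`, `obs.csv`,
#' `traj_enkf.csv`, `traj_4dvar.csv`, `rx.geojson`, `summary.json` and
#' `manifest.json` (config hash + seeds). A failing stage aborts with the
#' stage name; artifacts written so far are preserved.
#'
#' @param cfg a [default_config()] list (possibly edited).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the main in-memory results (`selection`,
#'   `model`, `report`, `obs`, `maps`, `summary`, `manifest`).
#' @export
run_pipeline <- function(cfg = default_config(), quiet = FALSE) {
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  art <- function(name) file.path(cfg$out_dir, name)
  params <- if (inherits(cfg$engine, "crop_params")) cfg$engine
            else do.call(crop_params, cfg$engine)

  ## stage 1: inputs ----------------------------------------------------------
  inputs <- stage("synth", {
    if (isTRUE(cfg$synth$enabled)) {
      w <- generate_weather(cfg$synth$start_date, cfg$synth$n_days,
                            seed = derive_seed(cfg$seed, 1L))
      lay <- make_gradient_layout(cfg$synth$n_plots,
                                  seed = derive_seed(cfg$seed, 2L))
      ds <- generate_inversion_dataset(cfg$synth$n_train,
                                       seed = derive_seed(cfg$seed, 3L),
                                       noise_sd = cfg$synth$noise_sd)
      write_weather_csv(w, art("weather.csv"))
      write_layout_geojson(lay, art("layout.geojson"))
      write_spectra_csv(ds, art("spectra.csv"))
      list(weather = w, layout = lay, train = ds)
    } else {
      list(weather = read_weather_csv(cfg$paths$weather),
           layout = read_layout_geojson(cfg$paths$layout),
           train = read_spectra_csv(cfg$paths$spectra))
    }
  })
  say("inputs ready (%d weather days, %d zones, %d training spectra)",
      nrow(inputs$weather), length(inputs$layout$zones), nrow(inputs$train$X))

  ## stage 2: band selection --------------------------------------------------
  sel <- stage("select_bands", {
    s <- rmsecv_scan(inputs$train, n_min = cfg$selection$n_min,
                     n_max = cfg$selection$n_max, folds = cfg$selection$folds,
                     seed = derive_seed(cfg$seed, 4L),
                     n_hidden = cfg$elm$n_hidden,
                     activation = cfg$elm$activation)
    write_selection_json(s, art("selection.json"))
    s
  })
  say("selected %d bands: %s nm", sel$n_selected,
      paste(round(sel$wavelengths_nm), collapse = ", "))

  ## stage 3: inversion model -------------------------------------------------
  inv <- stage("train_inversion", {
    sp <- split_dataset(inputs$train, ratio = cfg$elm$ratio,
                        seed = derive_seed(cfg$seed, 5L))
    m <- elm_train(sp$train, bands = sel, n_hidden = cfg$elm$n_hidden,
                   activation = cfg$elm$activation,
                   seed = derive_seed(cfg$seed, 6L))
    rep_tr <- compute_metrics(sp$train$y, predict(m, sp$train), "train")
    rep_te <- compute_metrics(sp$test$y, predict(m, sp$test), "test")
    write_elm_json(m, art("model.json"))
    jsonlite::write_json(list(
      train = list(r2 = rep_tr$r2, rmse_t_ha = rep_tr$rmse, n = rep_tr$n),
      test = list(r2 = rep_te$r2, rmse_t_ha = rep_te$rmse, n = rep_te$n)
    ), art("report.json"), auto_unbox = TRUE, digits = I(17))
    list(model = m, train = rep_tr, test = rep_te)
  })
  say("inversion R2 train %.3f / test %.3f, RMSE test %.3f t/ha",
      inv$train$r2, inv$test$r2, inv$test$rmse)

  ## stage 4: per-plot truths and inverted observations -----------------------
  sdates <- schedule_dates(inputs$weather)
  obs_date <- sdates[["tillering"]]
  zones_df <- as.data.frame(inputs$layout)
  plots <- unique(zones_df[, c("plot_id", "gradient")])
  field <- stage("observe", {
    n_p <- nrow(plots)
    mult <- with_seed(derive_seed(cfg$seed, 7L), {
      cvf <- cfg$synth$soil_fertility_cv
      cvv <- cfg$synth$vigor_cv
      sdf <- sqrt(log(1 + cvf^2)); sdv <- sqrt(log(1 + cvv^2))
      data.frame(
        plot_id = plots$plot_id,
        fert = stats::rlnorm(n_p, -sdf^2 / 2, sdf),
        vigor = stats::rlnorm(n_p, -sdv^2 / 2, sdv)
      )
    })
    rows <- list()
    for (i in seq_len(nrow(plots))) {
      pid <- plots$plot_id[i]
      g <- plots$gradient[i]
      p_true <- params
      p_true$soil_n0 <- params$soil_n0 * mult$fert[i]
      p_true$lai0 <- params$lai0 * mult$vigor[i]
      p_true$tagp0 <- params$tagp0 * mult$vigor[i]
      # assimilation-window schedule: base dressing only (tillering undecided)
      sch_base <- data.frame(date = sdates[["base"]],
                             n_kg_ha = 0.5 * gradient_rates[[g]],
                             label = "base")
      tr_true <- run(p_true, inputs$weather, sch_base)
      tagp_true <- state_at(tr_true, obs_date)$tagp
      spec <- simulate_spectrum(tagp_true / 1000, grid = inputs$train$grid,
                                noise_sd = cfg$synth$noise_sd,
                                seed = derive_seed(cfg$seed, 20L + i))
      inv_t_ha <- predict(inv$model,
                          matrix(spec[sel$order], nrow = 1))
      inv_t_ha <- max(inv_t_ha, 0)
      rows[[i]] <- data.frame(
        plot_id = pid, gradient = g, date = obs_date,
        tagp_true_kg_ha = tagp_true,
        tagp_obs_kg_ha = 1000 * inv_t_ha,  # t/ha -> kg/ha before assimilation
        sd_kg_ha = cfg$assimilation$obs_rel_sd * 1000 * inv_t_ha
      )
    }
    obs <- do.call(rbind, rows)
    utils::write.csv(
      data.frame(PLOT_ID = obs$plot_id, DATE = as.character(obs$date),
                 TAGP_T_HA = obs$tagp_obs_kg_ha / 1000,
                 SD = obs$sd_kg_ha / 1000),
      art("obs.csv"), row.names = FALSE, quote = FALSE)
    obs
  })
  say("inverted biomass observations for %d plots on %s",
      nrow(field), as.character(obs_date))

  ## stage 5: assimilation ----------------------------------------------------
  active <- field[field$gradient != "N0", , drop = FALSE]
  assim <- stage("assimilate", {
    res <- list()
    for (i in seq_len(nrow(active))) {
      pid <- active$plot_id[i]
      g <- active$gradient[i]
      sch_base <- data.frame(date = sdates[["base"]],
                             n_kg_ha = 0.5 * gradient_rates[[g]],
                             label = "base")
      obs_df <- data.frame(date = active$date[i],
                           value = active$tagp_obs_kg_ha[i],
                           var = pmax(active$sd_kg_ha[i], 1)^2)
      tr_e <- enkf_assimilate(params, inputs$weather, sch_base, obs_df,
                              M = cfg$assimilation$M,
                              seed = derive_seed(cfg$seed, 40L + i))
      tr_v <- fourdvar_assimilate(params, inputs$weather, sch_base, obs_df)
      res[[pid]] <- list(enkf = tr_e, fourdvar = tr_v)
    }
    res
  })
  stage("write_trajectories", {
    bind_traj <- function(which) {
      do.call(rbind, lapply(names(assim), function(pid) {
        tr <- assim[[pid]][[which]]
        data.frame(PLOT_ID = pid, DATE = as.character(tr$date), DVS = tr$dvs,
                   LAI = tr$lai, TAGP = tr$tagp, SOIL_N = tr$soil_n,
                   YIELD = tr$yield)
      }))
    }
    utils::write.csv(bind_traj("enkf"), art("traj_enkf.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(bind_traj("fourdvar"), art("traj_4dvar.csv"),
                     row.names = FALSE, quote = FALSE)
  })
  say("assimilated %d plots (EnKF M = %d; 4D-Var window to %s)",
      length(assim), cfg$assimilation$M, as.character(obs_date))

  ## stage 6: dose decisions and prescription ---------------------------------
  dcfg <- decision_config(target_yield = cfg$decision$target_yield,
                          tolerance = cfg$decision$tolerance,
                          dose_cap = cfg$decision$dose_cap,
                          dose_step = cfg$decision$dose_step,
                          tillering_date = obs_date + 1L)
  sch_rest <- data.frame(date = sdates[["panicle"]],
                         n_kg_ha = 0.2 * cfg$standard_n, label = "panicle")
  maps <- stage("decide", {
    mk_states <- function(method_of) {
      st <- list()
      for (z in inputs$layout$zones) {
        if (z$gradient == "N0") next
        meth <- method_of(z$zone_id)
        tr <- assim[[z$plot_id]][[if (meth == "enkf") "enkf" else "fourdvar"]]
        st[[z$zone_id]] <- list(state = state_at(tr, obs_date), method = meth)
      }
      st
    }
    # field design: half A corrected by EnKF, half B by 4D-Var
    states_mixed <- mk_states(function(zid) {
      if (grepl("A$", zid)) "enkf" else "4dvar"
    })
    states_enkf <- mk_states(function(zid) "enkf")
    states_4dvar <- mk_states(function(zid) "4dvar")
    map_mixed <- prescribe(inputs$layout, states_mixed, params,
                           inputs$weather, sch_rest, dcfg)
    map_enkf <- prescribe(inputs$layout, states_enkf, params,
                          inputs$weather, sch_rest, dcfg)
    map_4dvar <- prescribe(inputs$layout, states_4dvar, params,
                           inputs$weather, sch_rest, dcfg)
    write_prescription_geojson(map_mixed, art("rx.geojson"))
    list(mixed = map_mixed, enkf = map_enkf, fourdvar = map_4dvar)
  })
  say("prescription written (%d zones)", nrow(maps$mixed))

  ## stage 7: summary + manifest ----------------------------------------------
  cmp <- stage("summarize", {
    std_till <- cfg$standard_n - 0.5 * gradient_rates[["N3"]] -
      0.2 * cfg$standard_n
    s <- compare_methods(maps$enkf, maps$fourdvar,
                         standard_tillering_n = std_till)
    jsonlite::write_json(list(
      obs_date = as.character(obs_date),
      per_zone = s$table,
      mean_difference_4dvar_minus_enkf_kg_ha = s$mean_difference_kg_ha,
      total_enkf_kg_ha = s$total_enkf_kg_ha,
      total_4dvar_kg_ha = s$total_4dvar_kg_ha,
      pct_of_standard_enkf = s$pct_of_standard_enkf,
      pct_of_standard_4dvar = s$pct_of_standard_4dvar,
      saving_enkf_vs_standard_pct = s$saving_enkf_vs_standard_pct
    ), art("summary.json"), auto_unbox = TRUE, digits = I(17))
    s
  })
  manifest <- stage("manifest", {
    man <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                package_version = as.character(utils::packageVersion("paddydose")),
                artifacts = c("selection.json", "model.json", "report.json",
                              "obs.csv", "traj_enkf.csv", "traj_4dvar.csv",
                              "rx.geojson", "summary.json", "manifest.json"))
    jsonlite::write_json(man, art("manifest.json"), auto_unbox = TRUE)
    man
  })
  say("done: %s", cfg$out_dir)
  invisible(list(selection = sel, model = inv$model,
                 report = list(train = inv$train, test = inv$test),
                 obs = field, assim = assim, maps = maps, summary = cmp,
                 manifest = manifest))
}

# md5 of the canonical (JSON-serialized) configuration
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg$out_dir <- NULL  # location does not affect results
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = I(17), force = TRUE)
  unname(tools::md5sum(tmp))
}
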