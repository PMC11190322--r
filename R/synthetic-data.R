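# Synthetic-data generators: weather, canopy spectra, inversion training sets
# and gradient plot layouts. Everything downstream (band selection, inversion,
# assimilation, prescription) can be exercised on these fixtures alone.

#' Default hyperspectral wavelength grid
#'
#' Band centers of the emulated canopy imager: 170 bands spanning 400--1000 nm,
#' evenly spaced.
#'
#' @param n_bands number of bands (default 170).
#' @param from,to grid end points in nm.
#' @return numeric vector of strictly increasing band centers (nm).
#' @export
#' @examples
#' wl <- wavelength_grid()
#' range(wl); length(wl)
wavelength_grid <- function(n_bands = 170L, from = 400, to = 1000) {
  stopifnot(n_bands >= 2, from < to, from >= 400, to <= 1000)
  seq(from, to, length.out = n_bands)
}

#' Synthetic daily weather series
#'
#' Sinusoidal seasonal cycle (temperate monsoon paddy region) plus seeded
#' day-to-day noise. Temperatures are built as a daily mean and a positive
#' half-range, so `tmax >= tmin` holds by construction.
#'
#' @param start_date first day (`Date` or ISO string).
#' @param n_days number of consecutive days (>= 1).
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @return a `weather_series` data frame with columns `date`, `tmin`, `tmax`
#'   (deg C), `rad` (global radiation, MJ m-2 d-1) and `rain` (mm).
#' @export
#' @examples
#' w <- generate_weather("2021-05-19", 130, seed = 1)
#' summary(w$tmax - w$tmin)
generate_weather <- function(start_date, n_days, seed = 1L) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) {
    stop_("generate_weather: n_days must be a positive integer (got %s)", n_days)
  }
  start_date <- as.Date(start_date)
  dates <- start_date + seq_len(n_days) - 1L
  doy <- as.POSIXlt(dates)$yday + 1
  phase <- 2 * pi * (doy - 105) / 365
  with_seed(seed, {
    tmean <- 16 + 9 * sin(phase) + stats::rnorm(n_days, 0, 1.5)
    half <- pmax(0.5, 4 + stats::rnorm(n_days, 0, 1))
    rad <- pmax(1, 17 + 7 * sin(phase) + stats::rnorm(n_days, 0, 3))
    wet <- stats::rbinom(n_days, 1, 0.35)
    rain <- round(wet * stats::rgamma(n_days, shape = 0.8, scale = 10), 2)
  })
  out <- data.frame(
    date = dates,
    tmin = round(tmean - half, 2),
    tmax = round(tmean + half, 2),
    rad = round(rad, 2),
    rain = rain
  )
  class(out) <- c("weather_series", "data.frame")
  out
}

# Built-in endmembers: green vegetation (chlorophyll bump at 550 nm, red
# absorption trough near 670 nm, logistic red edge to a NIR plateau) and a
# bare-soil ramp that rises gently with wavelength.
vegetation_endmember <- function(wl) {
  vis <- 0.05 + 0.07 * exp(-((wl - 550) / 30)^2) - 0.03 * exp(-((wl - 670) / 25)^2)
  s <- stats::plogis((wl - 715) / 12)
  (1 - s) * vis + s * 0.50
}

soil_endmember <- function(wl) {
  0.08 + 0.25 * (wl - 400) / 600
}

#' Simulate a canopy reflectance spectrum from biomass
#'
#' Linear endmember mixing: `r = w * veg + (1 - w) * soil + noise` with
#' vegetation cover fraction `w = 1 - exp(-c * biomass)` (mixing coefficient
#' `c = 3` per t/ha, so cover spans roughly 0.03--0.98 across the tillering
#' biomass range). Output is clipped to `[0, 1]`.
#'
#' @param biomass_t_ha aboveground dry biomass, t/ha (>= 0).
#' @param grid wavelength grid (nm), default [wavelength_grid()].
#' @param noise_sd additive Gaussian noise sd in reflectance units (>= 0);
#'   default 0.01, a sensor-scale level.
#' @param seed seed for the noise draw (`NULL` for the current stream).
#' @param mixing_c mixing coefficient per t/ha.
#' @return reflectance vector, one value per band.
#' @export
#' @examples
#' r <- simulate_spectrum(0.4, noise_sd = 0)
#' plot(wavelength_grid(), r, type = "l", xlab = "nm", ylab = "reflectance")
simulate_spectrum <- function(biomass_t_ha, grid = wavelength_grid(),
                              noise_sd = 0.01, seed = NULL, mixing_c = 3.0) {
  if (!is.finite(biomass_t_ha) || biomass_t_ha < 0) {
    stop_("simulate_spectrum: biomass must be non-negative (got %s)", biomass_t_ha)
  }
  if (noise_sd < 0) stop_("simulate_spectrum: noise_sd must be >= 0")
  w <- 1 - exp(-mixing_c * biomass_t_ha)
  r <- w * vegetation_endmember(grid) + (1 - w) * soil_endmember(grid)
  if (noise_sd > 0) {
    r <- r + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  }
  pmin(pmax(r, 0), 1)
}

#' Spectral dataset container
#'
#' Bundles a reflectance matrix with its wavelength grid and (optionally)
#' paired biomass labels.
#'
#' @param X reflectance matrix, rows = samples, columns = bands.
#' @param grid wavelength grid matching `ncol(X)`.
#' @param y optional biomass labels (t/ha), length `nrow(X)`.
#' @return object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(X, grid = wavelength_grid(ncol(X)), y = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != length(grid)) {
    stop_("spectral_dataset: ncol(X) = %d does not match grid length %d",
          ncol(X), length(grid))
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_("spectral_dataset: wavelength grid must be strictly increasing")
  }
  if (!is.null(y) && length(y) != nrow(X)) {
    stop_("spectral_dataset: length(y) = %d does not match nrow(X) = %d",
          length(y), nrow(X))
  }
  structure(list(X = X, grid = as.numeric(grid), y = y),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d samples x %d bands (%.0f-%.0f nm)%s\n",
              nrow(x$X), ncol(x$X), min(x$grid), max(x$grid),
              if (is.null(x$y)) "" else ", labelled"))
  invisible(x)
}

#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  spectral_dataset(x$X[i, , drop = FALSE], x$grid,
                   if (is.null(x$y)) NULL else x$y[i])
}

#' Generate a labelled inversion training set
#'
#' Biomass is drawn right-skewed on the tillering range 0.009--1.34 t/ha
#' (Beta(1.2, 3.2) rescaled; marginal mean ~0.37 t/ha, matching field
#' statistics for tillering-stage paddies), and each sample gets a paired
#' endmember-mixing spectrum via [simulate_spectrum()].
#'
#' @param n number of samples (>= 10).
#' @param seed integer seed.
#' @param noise_sd spectral noise sd (reflectance), default 0.01.
#' @param grid wavelength grid.
#' @return labelled [spectral_dataset()].
#' @export
#' @examples
#' ds <- generate_inversion_dataset(100, seed = 7)
#' range(ds$y)
generate_inversion_dataset <- function(n, seed = 1L, noise_sd = 0.01,
                                       grid = wavelength_grid()) {
  n <- as.integer(n)
  if (is.na(n) || n < 10L) stop_("generate_inversion_dataset: n must be >= 10")
  with_seed(seed, {
    b <- 0.009 + (1.34 - 0.009) * stats::rbeta(n, 1.2, 3.2)
    noise <- matrix(stats::rnorm(n * length(grid), 0, noise_sd), nrow = n)
  })
  w <- 1 - exp(-3.0 * b)
  veg <- vegetation_endmember(grid)
  soil <- soil_endmember(grid)
  X <- outer(w, veg) + outer(1 - w, soil) + noise
  X <- pmin(pmax(X, 0), 1)
  spectral_dataset(X, grid, y = b)
}

#' Gradient plot layout with half-plot management zones
#'
#' Rectangular plots in a row, each assigned one of the five base-fertilizer
#' nitrogen gradients N0--N4 (0/100/150/200/250 kg N/ha applied at 50% as base
#' dressing) cyclically, and each split into two equal-area halves ("A"/"B") —
#' the management zones that later receive independent assimilation-based
#' prescriptions. Coordinates are planar metres around a local origin.
#'
#' @param n_plots number of plots (>= 5 so every gradient occurs).
#' @param seed seed for the gradient-order permutation; `NULL` keeps the
#'   canonical N0..N4 cycle.
#' @param plot_w,plot_h plot width and height in metres.
#' @return object of class `plot_layout`: list of zones, each with `zone_id`,
#'   `plot_id`, `gradient` and a `coords` matrix (closed handled at I/O).
#' @export
#' @examples
#' lay <- make_gradient_layout(10)
#' length(lay$zones)
make_gradient_layout <- function(n_plots, seed = NULL, plot_w = 10, plot_h = 30) {
  n_plots <- as.integer(n_plots)
  if (is.na(n_plots) || n_plots < 5L) {
    stop_("make_gradient_layout: n_plots must be >= 5")
  }
  grads <- c("N0", "N1", "N2", "N3", "N4")
  if (!is.null(seed)) grads <- with_seed(seed, sample(grads))
  zones <- list()
  for (i in seq_len(n_plots)) {
    x0 <- (i - 1) * (plot_w + 2)  # 2 m ridge between plots
    g <- grads[(i - 1) %% 5 + 1]
    pid <- sprintf("P%02d", i)
    halves <- list(
      A = cbind(x = c(x0, x0 + plot_w, x0 + plot_w, x0),
                y = c(0, 0, plot_h / 2, plot_h / 2)),
      B = cbind(x = c(x0, x0 + plot_w, x0 + plot_w, x0),
                y = c(plot_h / 2, plot_h / 2, plot_h, plot_h))
    )
    for (h in names(halves)) {
      zones[[length(zones) + 1L]] <- list(
        zone_id = paste0(pid, h), plot_id = pid, gradient = g,
        coords = halves[[h]]
      )
    }
  }
  structure(list(zones = zones), class = "plot_layout")
}

#' @export
print.plot_layout <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<plot_layout> %d zones over %d plots\n",
              nrow(df), length(unique(df$plot_id))))
  print(utils::head(df, 6))
  invisible(x)
}

#' @export
as.data.frame.plot_layout <- function(x, ...) {
  do.call(rbind, lapply(x$zones, function(z) {
    data.frame(zone_id = z$zone_id, plot_id = z$plot_id, gradient = z$gradient,
               area_m2 = polygon_area(z$coords))
  }))
}

## ---- plain-text writers / readers -------------------------------------------

#' Read and write the package's file formats
#'
#' Weather CSV uses columns `DATE,TMIN,TMAX,RAD,RAIN`; spectra CSV has the
#' wavelength grid as its header (plus an optional trailing `BIOMASS` column);
#' plot layouts are GeoJSON FeatureCollections of planar polygons with
#' `zone_id`, `plot_id` and `gradient` properties.
#'
#' @param x object to write.
#' @param path file path.
#' @return readers return the corresponding object; writers return `path`
#'   invisibly.
#' @name paddydose-io
NULL

#' @rdname paddydose-io
#' @export
write_weather_csv <- function(x, path) {
  stopifnot(inherits(x, "weather_series") || is.data.frame(x))
  df <- data.frame(DATE = as.character(x$date), TMIN = x$tmin, TMAX = x$tmax,
                   RAD = x$rad, RAIN = x$rain)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname paddydose-io
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("DATE", "TMIN", "TMAX", "RAD", "RAIN")
  if (!all(need %in% names(df))) {
    stop_("read_weather_csv: %s lacks columns %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- data.frame(date = as.Date(df$DATE), tmin = df$TMIN, tmax = df$TMAX,
                    rad = df$RAD, rain = df$RAIN)
  class(out) <- c("weather_series", "data.frame")
  out
}

#' @rdname paddydose-io
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectral_dataset"))
  df <- as.data.frame(x$X)
  names(df) <- formatC(x$grid, digits = 15, format = "g")
  if (!is.null(x$y)) df$BIOMASS <- x$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname paddydose-io
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  y <- NULL
  if ("BIOMASS" %in% names(df)) {
    y <- df$BIOMASS
    df$BIOMASS <- NULL
  }
  grid <- as.numeric(names(df))
  if (anyNA(grid)) stop_("read_spectra_csv: header of %s is not a wavelength grid", path)
  spectral_dataset(as.matrix(df), grid, y)
}

#' @rdname paddydose-io
#' @export
write_layout_geojson <- function(x, path) {
  stopifnot(inherits(x, "plot_layout"))
  feats <- lapply(x$zones, function(z) {
    ring <- rbind(z$coords, z$coords[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(zone_id = z$zone_id, plot_id = z$plot_id,
                        gradient = z$gradient),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(i) as.numeric(ring[i, ]))))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname paddydose-io
#' @export
read_layout_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop_("read_layout_geojson: %s is not a FeatureCollection", path)
  }
  zones <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    colnames(ring) <- c("x", "y")
    list(zone_id = f$properties$zone_id, plot_id = f$properties$plot_id,
         gradient = f$properties$gradient, coords = ring)
  })
  structure(list(zones = zones), class = "plot_layout")
}
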