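#' Landscape configuration
#'
#' Describes a synthetic dynamic landscape: a gridded world with a latitudinal
#' temperature gradient whose steepness changes through time, an additive
#' global temperature anomaly curve, a static random elevation field corrected
#' by a lapse rate, and a subtropical arid belt. Temperature and aridity are
#' later standardized to \[0, 1\] jointly over all time steps, so the global
#' temperature curve survives standardization.
#'
#' @param n_rows,n_cols grid dimensions (rows are latitudinal bands).
#' @param cell_size_km cell edge length in km (default 220).
#' @param n_steps number of time steps.
#' @param dt_kyr duration of one step in kyr (default 170).
#' @param equator_pole_gradient gradient steepness per step: degrees of
#'   cooling between the equator and the edge rows; length `n_steps` or
#'   shorter (linearly interpolated onto the steps). Steepening cools high
#'   latitudes while the tropics stay near `equatorial_temp`.
#' @param global_anomaly additive global temperature offsets (degrees) per
#'   step; recycled/interpolated like `equator_pole_gradient`.
#' @param equatorial_temp baseline equatorial temperature in degrees
#'   (default 28).
#' @param lapse_rate temperature decrease in degrees per km of elevation
#'   (default 6.5).
#' @param lat_span_deg total latitude span covered by the rows (default 140,
#'   i.e. rows run from +70 to -70); sets how steep the per-row temperature
#'   steps are relative to the cell size.
#' @param arid_belt_rows integer rows receiving nonzero aridity (default: the
#'   subtropical bands at roughly 15--35 degrees absolute latitude).
#' @param arid_amplitude per-step amplitude of the arid belt (scalar or
#'   vector; default 1).
#' @param zonal_wave_amp amplitude (degrees) of the stationary zonal
#'   temperature wave that breaks the east-west symmetry of the isotherms
#'   (continentality / ocean-current asymmetry); 0 disables it.
#' @param zonal_wavenumber number of warm/cold sectors around a latitude
#'   circle.
#' @param zonal_drift_cycles how many full phase rotations the wave drifts
#'   through over the whole run; a slow drift repeatedly forms and breaks
#'   thermal barriers.
#' @param ocean_widths integer widths (cells) of the meridional ocean
#'   channels separating full-height continental strips (default
#'   c(2, 3, 5)). Graded widths provide dispersal barriers that are
#'   effective across the whole range of kernel scales: a channel isolates
#'   populations whose contact distance it exceeds, while still being
#'   crossed occasionally, which is what turns it into a speciation pump.
#'   `NULL` gives an all-land world. Static through time (no plate
#'   tectonics).
#' @param coast_roughness fraction of land cells eroded by coastal noise
#'   (bays, fjords, offshore gaps; default 0.08).
#' @param elevation_seed integer seed for the static elevation field.
#' @param terrain_roughness maximum elevation in km of the random terrain
#'   (0 gives a flat world).
#' @param rng_seed seed controlling any remaining stochastic structure.
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 18L, n_cols = 36L, cell_size_km = 220,
                             n_steps = 120L, dt_kyr = 170,
                             equator_pole_gradient = seq(22, 44, length.out = n_steps),
                             global_anomaly = default_anomaly(n_steps),
                             equatorial_temp = 28,
                             lapse_rate = 6.5,
                             lat_span_deg = 100,
                             arid_belt_rows = default_arid_rows(n_rows, lat_span_deg),
                             arid_amplitude = 1,
                             zonal_wave_amp = 3,
                             zonal_wavenumber = 2L,
                             zonal_drift_cycles = 2,
                             ocean_widths = default_ocean_widths(n_cols),
                             coast_roughness = 0.08,
                             elevation_seed = 42L,
                             terrain_roughness = 0.8,
                             rng_seed = 1L) {
  stopifnot(coast_roughness >= 0, coast_roughness < 1)
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size_km > 0, n_steps >= 1,
            lapse_rate >= 0, dt_kyr > 0)
  if (any(!is.finite(equator_pole_gradient)) || any(!is.finite(global_anomaly)))
    stop("non-finite values in gradient/anomaly series")
  if (length(equator_pole_gradient) > n_steps || length(global_anomaly) > n_steps)
    stop("gradient/anomaly series longer than n_steps")
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              cell_size_km = cell_size_km, n_steps = as.integer(n_steps),
              dt_kyr = dt_kyr,
              equator_pole_gradient = interp_to_length(equator_pole_gradient, n_steps),
              global_anomaly = interp_to_length(global_anomaly, n_steps),
              equatorial_temp = equatorial_temp,
              lapse_rate = lapse_rate,
              lat_span_deg = lat_span_deg,
              arid_belt_rows = as.integer(arid_belt_rows),
              arid_amplitude = rep_len(arid_amplitude, n_steps),
              zonal_wave_amp = zonal_wave_amp,
              zonal_wavenumber = as.integer(zonal_wavenumber),
              zonal_drift_cycles = zonal_drift_cycles,
              ocean_widths = as.integer(ocean_widths),
              coast_roughness = coast_roughness,
              elevation_seed = as.integer(elevation_seed),
              terrain_roughness = terrain_roughness,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "landscape_config"
  cfg
}

# Cenozoic-style trend: a mild global decline with multi-scale oscillations
# slow enough for niches to track by drift and range shifts.
default_anomaly <- function(n_steps) {
  t <- seq(0, 1, length.out = max(n_steps, 2L))[seq_len(n_steps)]
  2 * (1 - t) + 0.8 * sin(2 * pi * t * 3) + 0.5 * sin(2 * pi * t * 7.3)
}

# as many graded channels as the grid can afford
default_ocean_widths <- function(n_cols) {
  full <- c(2L, 3L, 4L, 5L)
  for (k in rev(seq_along(full))) {
    w <- full[seq_len(k)]
    if (n_cols - sum(w) >= 4L * (k + 1L)) return(w)
  }
  NULL
}

default_arid_rows <- function(n_rows, lat_span_deg = 140) {
  lat <- row_latitudes(n_rows, lat_span_deg)
  which(abs(lat) >= 15 & abs(lat) <= 35)
}

#' @keywords internal
row_latitudes <- function(n_rows, lat_span_deg = 140) {
  h <- (lat_span_deg / 2) / n_rows
  seq(lat_span_deg / 2 - h, -(lat_span_deg / 2 - h), length.out = n_rows)
}

interp_to_length <- function(x, n) {
  if (length(x) == n) return(as.numeric(x))
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  stats::approx(seq(0, 1, length.out = length(x)), x,
                xout = seq(0, 1, length.out = n))$y
}

#' Standardize a field of layers to \[0, 1\]
#'
#' Affine map `(x - min)/(max - min)` with min/max taken jointly over all
#' supplied values (all time steps), so relative temporal variation is
#' preserved. A constant field maps to 0.5 everywhere by convention.
#'
#' @param x numeric array (any shape); `NA` entries pass through.
#' @return array of the same shape with finite values in \[0, 1\].
#' @export
standardize01 <- function(x) {
  v <- x[is.finite(x)]
  if (length(v) == 0L) stop("standardize01: no finite values")
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    x[is.finite(x)] <- 0.5
    return(x)
  }
  out <- (x - lo) / (hi - lo)
  out
}

# smoothed uniform noise field in [0, 1], used for terrain and continents
smooth_noise <- function(n_rows, n_cols, passes, seed) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  z <- matrix(stats::runif(n_rows * n_cols), n_rows, n_cols)
  for (i in seq_len(passes)) {
    zp <- z
    z <- (zp +
          zp[c(1, seq_len(n_rows - 1)), ] + zp[c(seq_len(n_rows - 1) + 1, n_rows), ] +
          zp[, c(1, seq_len(n_cols - 1))] + zp[, c(seq_len(n_cols - 1) + 1, n_cols)]) / 5
  }
  z <- z - min(z)
  z / max(z)
}

# Continental ladder: full-height meridional land strips separated by
# oceans of the given widths, with sinuous coasts and noise erosion.
# Every strip spans all rows, so species can track latitudinal climate
# shifts within their landmass; the graded channel widths supply
# divergence-generating barriers for small through large dispersal kernels.
make_land_mask <- function(n_rows, n_cols, ocean_widths, coast_roughness,
                           seed) {
  if (length(ocean_widths) == 0L) return(matrix(TRUE, n_rows, n_cols))
  n_strips <- length(ocean_widths) + 1L
  total_land <- n_cols - sum(ocean_widths)
  if (total_land < n_strips) stop("ocean widths leave no room for land")
  w <- rep(total_land %/% n_strips, n_strips)
  extra <- total_land - sum(w)
  if (extra > 0) w[seq_len(extra)] <- w[seq_len(extra)] + 1L
  starts <- cumsum(c(1L, w[-n_strips] + ocean_widths))
  old_rs <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_rs)) assign(".Random.seed", old_rs, envir = globalenv()))
  set.seed(seed)
  land <- matrix(FALSE, n_rows, n_cols)
  for (k in seq_len(n_strips)) {
    off <- round(cumsum(stats::rnorm(n_rows, 0, 0.5)))
    off <- off - round(mean(off))
    for (r in seq_len(n_rows)) {
      cs <- starts[k] + off[r] + seq_len(w[k]) - 1L
      cs <- cs[cs >= 1 & cs <= n_cols]
      land[r, cs] <- TRUE
    }
  }
  if (coast_roughness > 0) {
    z <- smooth_noise(n_rows, n_cols, 1L, seed + 1L)
    land[z < stats::quantile(z, coast_roughness)] <- FALSE
  }
  land
}

# Static random elevation: smoothed positive noise, scaled to [0, roughness] km.
make_elevation <- function(n_rows, n_cols, roughness, seed) {
  if (roughness <= 0) return(matrix(0, n_rows, n_cols))
  z <- smooth_noise(n_rows, n_cols, 2L, seed)
  # sharpen so high mountains are sparse ridges, lowlands common
  roughness * z^2
}

#' Raw (pre-standardization) temperature for one step
#'
#' Exposed so the lapse-rate and gradient structure can be inspected in
#' physical degrees before the \[0, 1\] standardization.
#'
#' @param config a [landscape_config()].
#' @param step time-step index.
#' @param elevation_km optional elevation matrix overriding the generated one.
#' @return matrix (row x col) of raw temperatures in degrees.
#' @export
raw_temperature <- function(config, step = 1L, elevation_km = NULL) {
  lat <- row_latitudes(config$n_rows, config$lat_span_deg)
  # latitudinal band shape in [0, 1]: 0 at the equator, 1 at the edge rows,
  # so gradient(t) is exactly the equator-to-edge temperature difference
  shape <- (1 - cos(lat * pi / 180)) /
    (1 - cos(config$lat_span_deg / 2 * pi / 180))
  if (is.null(elevation_km))
    elevation_km <- make_elevation(config$n_rows, config$n_cols,
                                   config$terrain_roughness, config$elevation_seed)
  wamp <- if (is.null(config$zonal_wave_amp)) 0 else config$zonal_wave_amp
  wave <- 0
  if (wamp > 0) {
    phase <- 2 * pi * config$zonal_drift_cycles * (step - 1) / max(config$n_steps - 1, 1)
    wave <- outer(rep(1, config$n_rows),
                  wamp * cos(2 * pi * config$zonal_wavenumber *
                             (seq_len(config$n_cols) - 1) / config$n_cols + phase))
  }
  config$equatorial_temp + config$global_anomaly[step] -
    outer(shape * config$equator_pole_gradient[step], rep(1, config$n_cols)) -
    config$lapse_rate * elevation_km + wave
}

#' Generate a synthetic dynamic landscape
#'
#' Raw temperature at a cell is `band(lat) * gradient(t) + anomaly(t) -
#' lapse_rate * elevation_km`, where `band(lat) = cos(lat)` so the raw
#' equator-to-pole difference at step `t` equals `gradient(t)`. Raw
#' temperature is then standardized to \[0, 1\] with bounds computed jointly
#' over all steps. Aridity is `arid_amplitude(t)` inside the arid belt rows
#' and 0 elsewhere, standardized the same way.
#'
#' @param config a [landscape_config()].
#' @return an object of class `landscape_series` with elements
#'   `temperature01`, `aridity01`, `habitable` (arrays step x row x col),
#'   `elevation_km` (matrix), `latitude_deg`, `step_times_kyr`,
#'   `cell_size_km`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$n_rows; nc <- config$n_cols; ns <- config$n_steps
  lat <- row_latitudes(nr, config$lat_span_deg)
  elev <- make_elevation(nr, nc, config$terrain_roughness, config$elevation_seed)
  land <- make_land_mask(nr, nc, config$ocean_widths,
                         config$coast_roughness, config$rng_seed)
  temp <- array(NA_real_, dim = c(ns, nr, nc))
  arid <- array(0, dim = c(ns, nr, nc))
  hab <- array(NA, dim = c(ns, nr, nc))
  for (s in seq_len(ns)) {
    temp[s, , ] <- raw_temperature(config, s, elev)
    if (length(config$arid_belt_rows))
      arid[s, config$arid_belt_rows, ] <- config$arid_amplitude[s]
    hab[s, , ] <- land
  }
  if (any(!is.finite(temp))) stop("non-finite raw temperature")
  # standardize over habitable cells only; sea cells carry the NA sentinel
  if (!all(land)) {
    sea <- !hab
    temp[sea] <- NA_real_
    arid[sea] <- NA_real_
  }
  structure(list(
    temperature01 = standardize01(temp),
    aridity01 = standardize01(arid),
    elevation_km = elev,
    habitable = hab,
    latitude_deg = lat,
    step_times_kyr = (seq_len(ns) - 1) * config$dt_kyr,
    cell_size_km = config$cell_size_km
  ), class = "landscape_series")
}

#' @export
print.landscape_series <- function(x, ...) {
  d <- dim(x$temperature01)
  cat(sprintf("landscape_series: %d steps, %d x %d grid, cell %g km\n",
              d[1], d[2], d[3], x$cell_size_km))
  invisible(x)
}

n_steps <- function(series) dim(series$temperature01)[1]

#' Linearly interpolate a landscape series onto more time steps
#'
#' Per-cell linear interpolation in time; the endpoint layers are preserved
#' exactly. Habitability is taken from the nearest original step.
#'
#' @param series a `landscape_series`.
#' @param target_n desired number of steps (>= current, >= 2).
#' @return a `landscape_series` with `target_n` steps.
#' @export
interpolate_timesteps <- function(series, target_n) {
  ns <- n_steps(series)
  if (target_n < 2) stop("target_n must be >= 2")
  if (ns < 2) stop("need at least 2 steps to interpolate")
  if (target_n < ns) stop("target_n must be >= current number of steps")
  if (target_n == ns) return(series)
  d <- dim(series$temperature01)
  xin <- seq(0, 1, length.out = ns)
  xout <- seq(0, 1, length.out = target_n)
  interp_arr <- function(a) {
    out <- array(NA_real_, dim = c(target_n, d[2], d[3]))
    for (r in seq_len(d[2])) for (cc in seq_len(d[3]))
      out[, r, cc] <- stats::approx(xin, a[, r, cc], xout = xout)$y
    out
  }
  nearest <- pmax(1L, pmin(ns, round(stats::approx(xin, seq_len(ns), xout = xout)$y)))
  out <- series
  out$temperature01 <- interp_arr(series$temperature01)
  out$aridity01 <- interp_arr(series$aridity01)
  out$habitable <- series$habitable[nearest, , , drop = FALSE]
  out$step_times_kyr <- stats::approx(xin, series$step_times_kyr, xout = xout)$y
  out
}

#' Write / read a landscape series as plain-text CSV grids
#'
#' The on-disk format is a directory holding `manifest.json` plus one
#' row-major CSV grid per layer per step (`temperature01_0001.csv`, ...),
#' `elevation_km.csv`, and `habitable_0001.csv` (0/1). Values are written
#' with 17 significant digits so the round trip is exact.
#'
#' @param series a `landscape_series`.
#' @param path directory to create/read.
#' @rdname landscape_io
#' @export
write_landscape <- function(series, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(series$temperature01)
  man <- list(n_steps = d[1], n_rows = d[2], n_cols = d[3],
              cell_size_km = series$cell_size_km,
              latitude_deg = series$latitude_deg,
              step_times_kyr = series$step_times_kyr)
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  wgrid <- function(m, f)
    utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                       file.path(path, f), sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  wgrid(series$elevation_km, "elevation_km.csv")
  for (s in seq_len(d[1])) {
    wgrid(series$temperature01[s, , ], sprintf("temperature01_%04d.csv", s))
    wgrid(series$aridity01[s, , ], sprintf("aridity01_%04d.csv", s))
    wgrid(series$habitable[s, , ] * 1L, sprintf("habitable_%04d.csv", s))
  }
  invisible(path)
}

#' @rdname landscape_io
#' @export
read_landscape <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("read_landscape: missing manifest.json in ", path)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  ns <- man$n_steps; nr <- man$n_rows; nc <- man$n_cols
  rgrid <- function(f, what) {
    p <- file.path(path, f)
    if (!file.exists(p)) return(NULL)
    m <- as.matrix(utils::read.table(p, sep = ",", header = FALSE))
    if (!all(dim(m) == c(nr, nc)))
      stop(sprintf("read_landscape: layer %s has shape %dx%d, expected %dx%d",
                   f, nrow(m), ncol(m), nr, nc))
    if (any(is.nan(m) | is.infinite(m)))
      stop("read_landscape: non-numeric values in ", f)
    unname(m)
  }
  temp <- array(NA_real_, c(ns, nr, nc)); arid <- temp
  hab <- array(TRUE, c(ns, nr, nc))
  miss_hab <- FALSE
  for (s in seq_len(ns)) {
    temp[s, , ] <- rgrid(sprintf("temperature01_%04d.csv", s), "temperature01")
    arid[s, , ] <- rgrid(sprintf("aridity01_%04d.csv", s), "aridity01")
    h <- rgrid(sprintf("habitable_%04d.csv", s), "habitable")
    if (is.null(h)) miss_hab <- TRUE else hab[s, , ] <- h > 0
  }
  if (miss_hab) warning("habitability layer(s) missing; defaulting to all-habitable")
  structure(list(temperature01 = temp, aridity01 = arid,
                 elevation_km = rgrid("elevation_km.csv", "elevation_km"),
                 habitable = hab,
                 latitude_deg = as.numeric(man$latitude_deg),
                 step_times_kyr = as.numeric(man$step_times_kyr),
                 cell_size_km = man$cell_size_km),
            class = "landscape_series")
}
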