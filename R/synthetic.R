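# Synthetic-data generators: toy calibration curves, landscapes, date
# tables from constant-speed radial expansions, and closed-form arrival
# rasters. Every stage of the pipeline can be exercised against known
# ground truth with these.

#' Identity ("toy") calibration curve
#'
#' A curve with `c14_age(t) = t` and constant curve error, so calibrated
#' densities are analytic Gaussians and back-calibration is the identity.
#'
#' @param cal_range `c(min, max)` calendar range in cal BP.
#' @param curve_sigma Constant curve 1-sigma error in years.
#' @return A [cal_curve].
#' @export
toy_curve <- function(cal_range = c(0, 6000), curve_sigma = 0) {
  if (diff(cal_range) <= 0) stop("empty calendar range", call. = FALSE)
  grid <- seq(cal_range[1], cal_range[2], length.out = 2L)
  cal_curve(grid, grid, curve_sigma)
}

#' Generate a synthetic suitability landscape
#'
#' Three kinds: `uniform` (constant value), `gradient` (strictly monotone
#' along columns from 0.05 to 0.95), and `smooth` (seeded low-frequency
#' random field: coarse uniform noise bilinearly interpolated and rescaled
#' to [0, 1]).
#'
#' @param n_rows,n_cols Grid dimensions (>= 10).
#' @param kind One of "uniform", "gradient", "smooth".
#' @param value Constant suitability for `kind = "uniform"`.
#' @param threshold Settleability threshold of the returned grid.
#' @param seed Optional integer seed (used by `smooth`).
#' @param center `c(lon, lat)` the grid is centred on; ties the equal-area
#'   plane to geographic coordinates for [grid_locate].
#' @param cell_km Cell side in km.
#' @return A `suit_grid`.
#' @export
synth_landscape <- function(n_rows, n_cols,
                            kind = c("uniform", "gradient", "smooth"),
                            value = 0.7, threshold = 0.5, seed = NULL,
                            center = c(-60, -5), cell_km = 10) {
  kind <- match.arg(kind)
  if (n_rows < 10 || n_cols < 10) stop("grid must be at least 10 x 10",
                                       call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- switch(kind,
    uniform = matrix(value, n_rows, n_cols),
    gradient = matrix(rep(seq(0.05, 0.95, length.out = n_cols),
                          each = n_rows), n_rows, n_cols),
    smooth = {
      k <- 8L
      coarse <- matrix(stats::runif(k * k), k, k)
      ri <- seq(1, k, length.out = n_rows)
      ci <- seq(1, k, length.out = n_cols)
      r0 <- pmin(floor(ri), k - 1L); c0 <- pmin(floor(ci), k - 1L)
      fr <- ri - r0; fc <- ci - c0
      f <- matrix(0, n_rows, n_cols)
      for (j in seq_len(n_cols)) {
        a <- coarse[cbind(r0, c0[j])] * (1 - fr) +
          coarse[cbind(r0 + 1L, c0[j])] * fr
        b <- coarse[cbind(r0, c0[j] + 1L)] * (1 - fr) +
          coarse[cbind(r0 + 1L, c0[j] + 1L)] * fr
        f[, j] <- a * (1 - fc[j]) + b * fc[j]
      }
      (f - min(f)) / (max(f) - min(f))
    })
  pj <- list(lon0 = center[1], lat0 = center[2], lat1 = center[2] - 15,
             lat2 = center[2] + 15)
  ctr <- project_albers(center[1], center[2], lon0 = pj$lon0,
                        lat0 = pj$lat0, lat1 = pj$lat1, lat2 = pj$lat2)
  suit_grid(m, threshold = threshold, cell_km = cell_km,
            xll = ctr[1] - n_cols * cell_km / 2,
            yll = ctr[2] - n_rows * cell_km / 2, proj = pj)
}

#' Specification of a synthetic constant-speed expansion
#'
#' @param origin `c(lon, lat)` of the true origin.
#' @param speed Front speed, km/yr (> 0).
#' @param start Start date, cal BP (> 500).
#' @param n_sites Number of dated sites (>= 5).
#' @param max_distance_km Largest site distance from the origin.
#' @param lab_sigma 1-sigma lab error applied to back-calibrated ages, yr.
#' @param seed Integer seed.
#' @param placement "distance" places sites uniformly in distance (keeps
#'   all bins populated); "area" uniformly in area.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(origin = c(-60, -5), speed = 1, start = 3000,
                       n_sites = 40, max_distance_km = 1000, lab_sigma = 60,
                       seed = 1, placement = c("distance", "area")) {
  if (speed <= 0) stop("speed must be > 0", call. = FALSE)
  if (start <= 500) stop("start must exceed 500 BP", call. = FALSE)
  if (n_sites < 5) stop("need at least 5 sites", call. = FALSE)
  structure(list(origin = origin, speed = speed, start = start,
                 n_sites = n_sites, max_distance_km = max_distance_km,
                 lab_sigma = lab_sigma, seed = seed,
                 placement = match.arg(placement)),
            class = "synth_spec")
}

#' Synthesise a radiocarbon date table from a constant-speed expansion
#'
#' Sites are placed at seeded-random bearings and distances from the origin
#' (the first site sits at the origin itself); the true arrival year at
#' distance d is `start - d/speed`. Each recorded age is the calibration
#' curve evaluated at the true year plus Gaussian lab noise, rounded to the
#' year - the minimal generative model consistent with the calibration
#' model. Reported sigma is `lab_sigma` (floored at 1 yr to keep the
#' determination invariants valid in the noise-free case).
#'
#' @param spec A [synth_spec].
#' @param curve A [cal_curve] used for back-calibration.
#' @return A date table with the standard columns plus `true_calbp` and
#'   `dist_km`.
#' @export
synth_dates <- function(spec, curve) {
  stopifnot(inherits(spec, "synth_spec"), inherits(curve, "cal_curve"))
  set.seed(spec$seed)
  n <- spec$n_sites
  u <- stats::runif(n - 1)
  d <- c(0, if (spec$placement == "distance") u * spec$max_distance_km
         else sqrt(u) * spec$max_distance_km)
  brg <- stats::runif(n, 0, 360)
  pos <- geosphere::destPoint(spec$origin, brg, d * 1000, r = 6371000)
  t_true <- round(spec$start - d / spec$speed)
  if (any(t_true < min(curve$cal_bp)))
    stop("expansion runs off the calendar range of the curve; increase ",
         "start or curve range", call. = FALSE)
  mu <- .curve_at(curve, t_true)$mu
  age <- round(mu + stats::rnorm(n, 0, spec$lab_sigma))
  data.frame(site_id = sprintf("S%03d", seq_len(n)),
             lon = pos[, 1], lat = pos[, 2],
             age_bp = age, sigma = max(spec$lab_sigma, 1),
             culture = "synthetic", reliable = TRUE, note = "",
             true_calbp = t_true, dist_km = d)
}

#' Synthesise a date table from an arrival raster
#'
#' Samples settled cells stratified by distance from the origin (one site
#' near each of `n_sites` evenly spaced target distances) and emits a date
#' table whose ages are the arrival years, for use with an identity
#' calibration curve. This closes the loop between the simulator and the
#' regression stage: the recovered front speed can be compared with the
#' raster's realized speed.
#'
#' @param arrival Arrival-year matrix (sim BP; NA = unreached).
#' @param grid The `suit_grid` the raster lives on.
#' @param origin_cell `c(row, col)` of the expansion origin.
#' @param n_sites Number of sites to sample.
#' @param sigma Reported lab error for every record, yr.
#' @param seed Optional integer seed.
#' @return A date table with the standard columns plus `dist_km`.
#' @export
dates_from_arrival <- function(arrival, grid, origin_cell, n_sites = 40,
                               sigma = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- which(!is.na(arrival))
  if (length(idx) < n_sites)
    stop("fewer settled cells than requested sites", call. = FALSE)
  nr <- grid$nrow
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  d <- sqrt((rr - origin_cell[1])^2 + (cc - origin_cell[2])^2) * grid$cell_km
  targets <- seq(0, max(d), length.out = n_sites)
  pick <- integer(n_sites)
  avail <- rep(TRUE, length(idx))
  for (k in seq_len(n_sites)) {
    j <- which(avail)[which.min(abs(d[avail] - targets[k]))]
    pick[k] <- j
    avail[j] <- FALSE
  }
  pj <- grid$proj
  xy <- vapply(pick, function(j) cell_center(rr[j], cc[j], grid), numeric(2))
  ll <- if (is.null(pj)) project_albers_inv(xy[1, ], xy[2, ])
  else project_albers_inv(xy[1, ], xy[2, ], lon0 = pj$lon0, lat0 = pj$lat0,
                          lat1 = pj$lat1, lat2 = pj$lat2)
  data.frame(site_id = sprintf("C%03d", seq_len(n_sites)),
             lon = ll[, 1], lat = ll[, 2],
             age_bp = round(arrival[idx[pick]]), sigma = sigma,
             culture = "simulated", reliable = TRUE, note = "",
             dist_km = d[pick])
}

#' Closed-form arrival raster for a constant-speed expansion
#'
#' `arrival(cell) = start - distance(cell, origin)/speed` on settleable
#' cells (NA elsewhere), with distances Euclidean on the grid plane. Lets
#' the fitness stage be tested independently of the simulator.
#'
#' @param grid A `suit_grid`.
#' @param origin_cell `c(row, col)`.
#' @param speed Front speed, km/yr (> 0).
#' @param start Start year (BP) at the origin.
#' @return Matrix of arrival years (NA on unsettleable cells).
#' @export
synth_arrival <- function(grid, origin_cell, speed, start) {
  if (speed <= 0) stop("speed must be > 0", call. = FALSE)
  rr <- matrix(seq_len(grid$nrow), grid$nrow, grid$ncol)
  cc <- matrix(seq_len(grid$ncol), grid$nrow, grid$ncol, byrow = TRUE)
  d <- sqrt((rr - origin_cell[1])^2 + (cc - origin_cell[2])^2) * grid$cell_km
  arr <- start - d / speed
  arr[!grid$settleable] <- NA_real_
  arr
}
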