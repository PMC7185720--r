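# Radiocarbon calibration: curve handling, probabilistic calibration,
# medians and single-year draws from calibrated densities.

#' Construct a calibration curve object
#'
#' A calibration curve maps calendar years (cal BP) to conventional
#' radiocarbon ages (14C yr BP) with a 1-sigma curve uncertainty. The grid
#' must be strictly monotone in cal BP; linear interpolation is used between
#' knots.
#'
#' @param cal_bp Numeric vector of calendar years BP (strictly monotone).
#' @param c14_age Numeric vector of 14C ages BP at those calendar years.
#' @param sigma Numeric vector (or scalar) of 1-sigma curve errors in years.
#' @return An object of class `cal_curve` with elements `cal_bp`, `c14_age`,
#'   `sigma`, sorted by increasing cal BP.
#' @export
cal_curve <- function(cal_bp, c14_age, sigma) {
  if (length(cal_bp) < 2L)
    stop("calibration curve needs at least two knots", call. = FALSE)
  if (length(c14_age) != length(cal_bp))
    stop("cal_bp and c14_age lengths differ", call. = FALSE)
  sigma <- rep_len(sigma, length(cal_bp))
  d <- diff(cal_bp)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop("cal_bp grid is not strictly monotone", call. = FALSE)
  if (any(sigma < 0)) stop("curve sigma must be >= 0", call. = FALSE)
  ord <- order(cal_bp)
  structure(
    list(cal_bp = as.numeric(cal_bp[ord]),
         c14_age = as.numeric(c14_age[ord]),
         sigma = as.numeric(sigma[ord])),
    class = "cal_curve")
}

#' Read a calibration curve in IntCal/ShCal text format
#'
#' Expects the standard three-column dialect (cal BP, 14C age BP, 1-sigma
#' error), comma or whitespace separated, with `#` comment lines tolerated.
#' Extra columns beyond the third are ignored.
#'
#' @param path Path to a `.14c`-style text file.
#' @return A [cal_curve] object.
#' @export
load_curve <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("curve file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "[,[:space:]]+")
  ncols <- vapply(fields, length, integer(1))
  if (any(ncols < 3L))
    stop("curve file must have at least three columns (cal BP, 14C age, sigma)",
         call. = FALSE)
  m <- t(vapply(fields, function(f) as.numeric(f[1:3]), numeric(3)))
  if (anyNA(m)) stop("non-numeric values in curve file", call. = FALSE)
  cal_curve(m[, 1], m[, 2], m[, 3])
}

#' Write a calibration curve in IntCal/ShCal text format
#'
#' @param curve A [cal_curve] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "cal_curve"))
  # write in decreasing cal BP, the convention of published curve files
  ord <- order(curve$cal_bp, decreasing = TRUE)
  lines <- c("# cal BP, 14C age BP, sigma",
             sprintf("%g,%g,%g", curve$cal_bp[ord], curve$c14_age[ord],
                     curve$sigma[ord]))
  writeLines(lines, path)
  invisible(path)
}

# interpolate curve mean and sigma at (integer) calendar years
.curve_at <- function(curve, years) {
  list(mu = stats::approx(curve$cal_bp, curve$c14_age, xout = years,
                          rule = 1)$y,
       sig = stats::approx(curve$cal_bp, curve$sigma, xout = years,
                           rule = 1)$y)
}

#' Calibrate a radiocarbon determination
#'
#' Computes the probability mass function over integer calendar years implied
#' by an uncalibrated age and its lab error. At each calendar year t the
#' unnormalised mass is the normal density of `age - c14_age(t)` with variance
#' `sigma^2 + curve_sigma(t)^2`; the result is normalised to sum to one and
#' truncated where the cumulative mass in either tail is below `1e-6`.
#'
#' @param age Uncalibrated 14C age, yr BP.
#' @param sigma 1-sigma lab error, yr (> 0).
#' @param curve A [cal_curve] object.
#' @return An object of class `cal_density`: list with integer `years`
#'   (increasing cal BP) and `mass` summing to 1.
#' @export
calibrate <- function(age, sigma, curve) {
  stopifnot(inherits(curve, "cal_curve"))
  if (!is.finite(age) || !is.finite(sigma) || sigma <= 0)
    stop("age must be finite and sigma > 0", call. = FALSE)
  rng <- range(curve$c14_age)
  if (age < rng[1] - 5 * sigma || age > rng[2] + 5 * sigma)
    stop("age ", age, " outside curve 14C coverage [", rng[1], ", ", rng[2],
         "] +/- 5 sigma", call. = FALSE)
  years <- seq.int(ceiling(min(curve$cal_bp)), floor(max(curve$cal_bp)))
  at <- .curve_at(curve, years)
  w <- stats::dnorm(age, mean = at$mu, sd = sqrt(sigma^2 + at$sig^2))
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop("calibration produced zero mass; age outside curve coverage",
         call. = FALSE)
  mass <- w / s
  cum <- cumsum(mass)
  lo <- which(cum > 1e-6)[1]
  hi <- which(cum >= 1 - 1e-6)[1]
  years <- years[lo:hi]
  mass <- mass[lo:hi]
  mass <- mass / sum(mass)
  structure(list(years = years, mass = mass), class = "cal_density")
}

#' Construct a calibrated density directly from years and weights
#'
#' Mostly useful for tests and for degenerate densities.
#'
#' @param years Integer calendar years (cal BP).
#' @param mass Nonnegative weights; normalised to sum to 1.
#' @return A `cal_density` object.
#' @export
cal_density <- function(years, mass) {
  if (length(years) != length(mass) || !length(years))
    stop("years and mass must be nonempty and of equal length", call. = FALSE)
  if (any(mass < 0) || sum(mass) <= 0)
    stop("mass must be nonnegative with positive sum", call. = FALSE)
  ord <- order(years)
  structure(list(years = as.integer(years[ord]),
                 mass = mass[ord] / sum(mass)),
            class = "cal_density")
}

#' Median of a calibrated density
#'
#' Cumulates mass from the older (larger cal BP) end and returns the first
#' year at which the cumulative mass reaches 0.5. For a symmetric density
#' this is the centre; for the tied two-point density \{3000: 0.5, 2000: 0.5\}
#' it is 3000.
#'
#' @param d A `cal_density` object.
#' @return Integer calendar year (cal BP).
#' @export
median_year <- function(d) {
  stopifnot(inherits(d, "cal_density"))
  ord <- order(d$years, decreasing = TRUE)
  cum <- cumsum(d$mass[ord])
  d$years[ord][which(cum >= 0.5 - 1e-12)[1]]
}

#' Draw single calendar years from a calibrated density
#'
#' Samples years with probability given by the calibrated distribution, the
#' resampling unit of the bootstrap regression. Uses the current RNG stream;
#' call `set.seed()` for reproducibility.
#'
#' @param d A `cal_density` object.
#' @param n Number of draws.
#' @return Integer vector of length `n`.
#' @export
sample_year <- function(d, n = 1L) {
  stopifnot(inherits(d, "cal_density"))
  if (length(d$years) == 1L) return(rep(d$years, n))
  d$years[sample.int(length(d$years), n, replace = TRUE, prob = d$mass)]
}

#' @export
print.cal_curve <- function(x, ...) {
  cat("Calibration curve:", length(x$cal_bp), "knots,",
      min(x$cal_bp), "-", max(x$cal_bp), "cal BP\n")
  invisible(x)
}

#' @export
print.cal_density <- function(x, ...) {
  cat("Calibrated density on", length(x$years), "years,",
      min(x$years), "-", max(x$years), "cal BP; median",
      median_year(x), "\n")
  invisible(x)
}
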