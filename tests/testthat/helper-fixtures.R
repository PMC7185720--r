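# Shared fixtures, built in code at test time.

# identity calibration curve over 0-6000 cal BP with zero curve error
identity_curve <- function(sigma = 0) toy_curve(c(0, 6000), sigma)

# a small date table with known structure
tiny_dates <- function() {
  data.frame(
    site_id = c("A", "A", "B", "C", "C"),
    lon = c(-60, -60, -61, -62, -62),
    lat = c(-5, -5, -5.5, -6, -6),
    age_bp = c(2400, 1800, 2000, 2600, 2600),
    sigma = c(40, 30, 50, 80, 40),
    culture = "t",
    reliable = TRUE,
    note = "")
}

# independent haversine evaluation (oracle for great_circle_km)
brute_haversine <- function(lon1, lat1, lon2, lat2, R = 6371) {
  r <- pi / 180
  dphi <- (lat2 - lat1) * r
  dlam <- (lon2 - lon1) * r
  a <- sin(dphi / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin(dlam / 2)^2
  2 * R * asin(sqrt(pmin(1, a)))
}

# independent reduced-major-axis evaluation from the defining sums
# (oracle for rma)
brute_rma <- function(x, y) {
  xm <- sum(x) / length(x)
  ym <- sum(y) / length(y)
  sxx <- sum((x - xm)^2)
  syy <- sum((y - ym)^2)
  sxy <- sum((x - xm) * (y - ym))
  r <- sxy / sqrt(sxx * syy)
  slope <- sign(r) * sqrt(syy / sxx)
  list(slope = slope, intercept = ym - slope * xm, r = r)
}
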