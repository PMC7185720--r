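# Equal-area gridded world: suitability raster, settleability mask,
# site-to-cell mapping, and a small net-primary-productivity utility.

#' Construct a suitability grid
#'
#' The grid lives on an equal-area plane in km: square cells of side
#' `cell_km` (default 10 km, i.e. 100 km^2 per cell), row 1 at the top
#' (largest y). `suitability` values are in [0, 1] with NA for no-data; cells
#' are settleable when suitability >= `threshold`.
#'
#' @param suitability Numeric matrix in [0, 1] (NA = no-data).
#' @param threshold Settleability threshold in [0, 1].
#' @param cell_km Cell side in km.
#' @param xll,yll Coordinates (km) of the lower-left corner of the grid.
#' @param proj Optional list of Albers projection parameters
#'   (`lon0`, `lat0`, `lat1`, `lat2`) tying the plane to lon/lat; defaults
#'   to the [project_albers] defaults when NULL.
#' @return An object of class `suit_grid`.
#' @export
suit_grid <- function(suitability, threshold = 0.5, cell_km = 10,
                      xll = 0, yll = 0, proj = NULL) {
  if (!is.matrix(suitability)) stop("suitability must be a matrix",
                                    call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  v <- suitability[is.finite(suitability)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("suitability values must be in [0, 1]", call. = FALSE)
  settle <- is.finite(suitability) & suitability >= threshold
  structure(list(suitability = suitability, settleable = settle,
                 threshold = threshold, cell_km = cell_km,
                 nrow = nrow(suitability), ncol = ncol(suitability),
                 xll = xll, yll = yll, proj = proj),
            class = "suit_grid")
}

#' @export
print.suit_grid <- function(x, ...) {
  cat("Suitability grid ", x$nrow, " x ", x$ncol, " cells of ", x$cell_km,
      " km; ", sum(x$settleable), " settleable (threshold ", x$threshold,
      ")\n", sep = "")
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to an `.asc` file.
#' @return List with `values` matrix (row 1 = top), `cellsize`, `xll`, `yll`,
#'   `nodata`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) == 2L && is.na(suppressWarnings(as.numeric(tok[1])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header must define ncols, nrows and cellsize",
         call. = FALSE)
  if (!("xllcorner" %in% names(hdr)) || !("yllcorner" %in% names(hdr)))
    stop("ASCII grid header must define xllcorner and yllcorner (missing ",
         "georeferencing)", call. = FALSE)
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values; expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else NA
  if (!is.na(nodata)) m[m == nodata] <- NA
  list(values = m, cellsize = hdr$cellsize, xll = hdr$xllcorner,
       yll = hdr$yllcorner, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param values Numeric matrix (row 1 = top).
#' @param path Output path.
#' @param cellsize Cell side (same units as `xll`/`yll`).
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata No-data sentinel written in place of NA.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, path, cellsize = 10, xll = 0, yll = 0,
                             nodata = -9999) {
  hdr <- c(paste("ncols", ncol(values)), paste("nrows", nrow(values)),
           paste("xllcorner", xll), paste("yllcorner", yll),
           paste("cellsize", cellsize), paste("NODATA_value", nodata))
  v <- values
  v[!is.finite(v)] <- nodata
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Load a suitability raster and derive the settleability mask
#'
#' Reads an ESRI ASCII grid already expressed in an equal-area projection
#' with square cells (the package validates but does not reproject). Values
#' must be in [0, 1]; no-data cells are unsettleable.
#'
#' @param path Path to an `.asc` raster. GeoTIFF input is not supported;
#'   convert to ESRI ASCII first.
#' @param threshold Settleability threshold in [0, 1], e.g. the maximum
#'   training sensitivity plus specificity cut-point of the niche model that
#'   produced the raster.
#' @param cell_km Expected cell size in km (default 10); used to validate the
#'   raster resolution when its cellsize is expressed in metres or km.
#' @return A `suit_grid`.
#' @export
load_suitability <- function(path, threshold, cell_km = 10) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF input is not supported; export the raster as an ESRI ",
         "ASCII grid (equal-area, square cells)", call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  g <- read_ascii_grid(path)
  cs_km <- if (g$cellsize > 1000) g$cellsize / 1000 else g$cellsize
  xll <- if (g$cellsize > 1000) g$xll / 1000 else g$xll
  yll <- if (g$cellsize > 1000) g$yll / 1000 else g$yll
  if (abs(cs_km - cell_km) > 1e-6)
    stop("raster cell size ", cs_km, " km does not match expected ",
         cell_km, " km", call. = FALSE)
  suit_grid(g$values, threshold = threshold, cell_km = cs_km,
            xll = xll, yll = yll)
}

#' Spherical Albers equal-area conic projection
#'
#' Forward projection of lon/lat (degrees) to x/y in km on a sphere of
#' radius 6371 km. Defaults are the standard parallels and origin commonly
#' used for South American equal-area mapping.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param lon0,lat0 Projection origin (degrees).
#' @param lat1,lat2 Standard parallels (degrees).
#' @return A two-column matrix of x, y in km.
#' @export
project_albers <- function(lon, lat, lon0 = -60, lat0 = -32,
                           lat1 = -5, lat2 = -42) {
  R <- 6371
  rad <- pi / 180
  phi <- lat * rad; phi0 <- lat0 * rad
  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  n <- (sin(phi1) + sin(phi2)) / 2
  C <- cos(phi1)^2 + 2 * n * sin(phi1)
  rho <- R * sqrt(C - 2 * n * sin(phi)) / n
  rho0 <- R * sqrt(C - 2 * n * sin(phi0)) / n
  theta <- n * (lon - lon0) * rad
  cbind(x = rho * sin(theta), y = rho0 - rho * cos(theta))
}

#' Map projected coordinates to a grid cell
#'
#' @param x,y Coordinates in km on the grid's equal-area plane.
#' @param grid A `suit_grid`.
#' @return Integer vector `c(row, col)` of the containing cell.
#' @export
site_to_cell <- function(x, y, grid) {
  col <- floor((x - grid$xll) / grid$cell_km) + 1L
  row <- grid$nrow - floor((y - grid$yll) / grid$cell_km)
  if (any(col < 1L | col > grid$ncol | row < 1L | row > grid$nrow))
    stop("location (", x, ", ", y, ") falls outside the grid", call. = FALSE)
  c(row = as.integer(row), col = as.integer(col))
}

#' Centre coordinates of a grid cell
#'
#' Inverse of [site_to_cell] up to within-cell position.
#'
#' @param row,col Cell indices.
#' @param grid A `suit_grid`.
#' @return Numeric `c(x, y)` in km.
#' @export
cell_center <- function(row, col, grid) {
  c(x = grid$xll + (col - 0.5) * grid$cell_km,
    y = grid$yll + (grid$nrow - row + 0.5) * grid$cell_km)
}

#' Inverse spherical Albers equal-area conic projection
#'
#' Maps x/y in km on the projection plane back to lon/lat degrees.
#'
#' @param x,y Plane coordinates in km.
#' @inheritParams project_albers
#' @return A two-column matrix of lon, lat in degrees.
#' @export
project_albers_inv <- function(x, y, lon0 = -60, lat0 = -32,
                               lat1 = -5, lat2 = -42) {
  R <- 6371
  rad <- pi / 180
  phi1 <- lat1 * rad; phi2 <- lat2 * rad; phi0 <- lat0 * rad
  n <- (sin(phi1) + sin(phi2)) / 2
  C <- cos(phi1)^2 + 2 * n * sin(phi1)
  rho0 <- R * sqrt(C - 2 * n * sin(phi0)) / n
  s <- sign(n)   # southern-aspect cones have n < 0
  rho <- sqrt(x^2 + (rho0 - y)^2) * s
  theta <- atan2(s * x, s * (rho0 - y))
  phi <- asin((C - (rho * n / R)^2) / (2 * n))
  cbind(lon = lon0 + theta / (n * rad), lat = phi / rad)
}

#' Locate a lon/lat site on a grid
#'
#' Projects the coordinates onto the grid's equal-area plane (using the
#' grid's `proj` parameters, or the [project_albers] defaults) and returns
#' the containing cell.
#'
#' @param lon,lat Site coordinates, decimal degrees.
#' @param grid A `suit_grid`.
#' @return Integer `c(row, col)`.
#' @export
grid_locate <- function(lon, lat, grid) {
  pj <- grid$proj
  xy <- if (is.null(pj)) project_albers(lon, lat)
  else project_albers(lon, lat, lon0 = pj$lon0, lat0 = pj$lat0,
                      lat1 = pj$lat1, lat2 = pj$lat2)
  site_to_cell(xy[1], xy[2], grid)
}

#' Miami-model net primary productivity
#'
#' Empirical NPP (g m^-2 yr^-1) as the minimum of a temperature-limited and a
#' precipitation-limited term, both saturating at 3000.
#'
#' @param temp_c Mean annual temperature, degrees C.
#' @param precip_mm Annual precipitation, mm.
#' @return NPP in g m^-2 yr^-1.
#' @export
miami_npp <- function(temp_c, precip_mm) {
  pmin(3000 / (1 + exp(1.315 - 0.119 * temp_c)),
       3000 * (1 - exp(-0.000664 * precip_mm)))
}
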