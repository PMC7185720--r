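# Date-table handling: reading the compilation CSV, reliability/error
# filtering and reduction to the earliest determination per site.

.DATE_COLS <- c("site_id", "lon", "lat", "age_bp", "sigma", "culture",
                "reliable", "note")

#' Read a radiocarbon date table
#'
#' The table has one row per determination with columns
#' `site_id,lon,lat,age_bp,sigma,culture,reliable,note`. Coordinates are
#' decimal degrees WGS84, ages uncalibrated 14C yr BP.
#'
#' @param path CSV file path.
#' @return A data.frame of determinations.
#' @export
read_dates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dates(df)
}

#' Validate a date table
#'
#' Checks the column schema and the row invariants (positive age and error,
#' coordinates on the globe). `reliable` is coerced to logical.
#'
#' @param df A data.frame of determinations.
#' @return The validated data.frame.
#' @export
validate_dates <- function(df) {
  miss <- setdiff(setdiff(.DATE_COLS, "note"), names(df))
  if (length(miss))
    stop("date table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"note" %in% names(df)) df$note <- ""
  df$reliable <- as.logical(df$reliable)
  if (anyNA(df$reliable))
    stop("reliable column must be TRUE/FALSE", call. = FALSE)
  bad <- !is.finite(df$sigma) | df$sigma <= 0 | !is.finite(df$age_bp) |
    df$age_bp <= 0 | abs(df$lat) > 90 | abs(df$lon) > 180
  if (any(bad))
    stop(sum(bad), " row(s) violate invariants (sigma > 0, age > 0, ",
         "lat in [-90, 90], lon in [-180, 180])", call. = FALSE)
  df
}

#' Write a date table
#'
#' @param df A data.frame of determinations.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dates <- function(df, path) {
  utils::write.csv(df[, intersect(.DATE_COLS, names(df))], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Filter a date table by lab error and reliability
#'
#' Drops determinations with standard errors larger than `max_sigma`
#' (strictly larger; the default 200 yr keeps older legacy dates that would
#' otherwise be lost) and determinations flagged unreliable. Input order is
#' preserved; the number dropped per reason is reported via `message()` and
#' attached as attribute `"dropped"`.
#'
#' @param records A date table (data.frame).
#' @param max_sigma Maximum admissible 1-sigma lab error in years.
#' @param quiet Suppress the message.
#' @return The filtered data.frame.
#' @export
filter_records <- function(records, max_sigma = 200, quiet = FALSE) {
  records <- validate_dates(records)
  big <- records$sigma > max_sigma
  unrel <- !records$reliable
  keep <- !(big | unrel)
  out <- records[keep, , drop = FALSE]
  dropped <- c(error = sum(big), unreliable = sum(unrel & !big))
  if (!quiet)
    message("filter_records: dropped ", dropped[["error"]],
            " with sigma > ", max_sigma, " and ", dropped[["unreliable"]],
            " flagged unreliable; ", nrow(out), " retained")
  attr(out, "dropped") <- dropped
  out
}

# calibrated medians for each row, computed once and cached in the table
.with_medians <- function(records, curve) {
  if (is.null(records$median_calbp)) {
    records$median_calbp <- vapply(
      seq_len(nrow(records)),
      function(i) as.numeric(median_year(
        calibrate(records$age_bp[i], records$sigma[i], curve))),
      numeric(1))
  }
  records
}

#' Keep the earliest determination per site
#'
#' "Earliest" is judged on the median of the calibrated density: per site the
#' record with the largest median calibrated age is kept, ties broken by
#' smaller lab error and then input order. Using a single date per site
#' avoids the distortion caused when long-lived sites also carry many recent
#' dates.
#'
#' @param records A date table.
#' @param curve A [cal_curve] used to calibrate each determination.
#' @return One row per `site_id`, in order of first appearance, with a
#'   `median_calbp` column added.
#' @export
earliest_per_site <- function(records, curve) {
  records <- .with_medians(validate_dates(records), curve)
  if (!nrow(records)) return(records)
  idx <- seq_len(nrow(records))
  pick <- vapply(split(idx, factor(records$site_id,
                                   levels = unique(records$site_id))),
                 function(i) {
                   o <- order(-records$median_calbp[i], records$sigma[i], i)
                   i[o[1]]
                 }, integer(1))
  out <- records[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}
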