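#' Read a long-format daily temperature series
#'
#' Expects delimited text with columns `cell_id`, `doy`, `tmin`, `tmax`
#' (optionally `lat`, `lon`, `year`).
#'
#' @param path CSV path.
#' @return Data frame, validated for `tmin <= tmax`.
#' @export
read_daily_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "doy", "tmin", "tmax")
  if (!all(need %in% names(d))) {
    stop("daily series must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  assert_daily_series(d)
  d
}

#' Write a long-format daily temperature series
#'
#' @param series Data frame as read by [read_daily_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(series, path) {
  assert_daily_series(series)
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Daily climatology over years
#'
#' Per cell and day-of-year, averages `tmin` and `tmax` across the years of
#' a multi-year daily series, after dropping leap days (`doy` 366). Every
#' (cell, year) must supply all 365 days; gaps are a hard error listing the
#' missing combinations.
#'
#' @param multi_year Data frame with columns `cell_id`, `year`, `doy`,
#'   `tmin`, `tmax`.
#' @return Data frame (`cell_id`, `doy`, `tmin`, `tmax`) with one
#'   365-day climatological year per cell.
#' @export
build_climatology <- function(multi_year) {
  need <- c("cell_id", "year", "doy", "tmin", "tmax")
  if (!all(need %in% names(multi_year))) {
    stop("multi-year series must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  d <- multi_year[multi_year$doy <= 365, , drop = FALSE]
  counts <- stats::aggregate(doy ~ cell_id + year, data = d, FUN = length)
  bad <- counts[counts$doy != 365, , drop = FALSE]
  if (nrow(bad)) {
    stop("incomplete cell-years (need 365 days each): ",
         paste(sprintf("%s/%s (%d days)", bad$cell_id, bad$year, bad$doy),
               collapse = ", "), call. = FALSE)
  }
  out <- stats::aggregate(cbind(tmin, tmax) ~ cell_id + doy, data = d,
                          FUN = mean)
  out <- out[order(out$cell_id, out$doy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean annual temperature per cell
#'
#' Defined as the mean over days of the daily midpoint `(tmin + tmax) / 2`.
#'
#' @param series Data frame with columns `cell_id`, `tmin`, `tmax`.
#' @return Data frame with columns `cell_id`, `tmean`.
#' @export
annual_mean_temperature <- function(series) {
  assert_daily_series(series)
  mids <- (series$tmin + series$tmax) / 2
  out <- stats::aggregate(list(tmean = mids),
                          by = list(cell_id = series$cell_id), FUN = mean)
  out[order(out$cell_id), , drop = FALSE]
}

#' Delta-change warming scenario
#'
#' Computes per-cell warming offsets as the difference between future and
#' current mean annual temperatures. When several model projections of the
#' future field are supplied, their per-cell mean (the consensus
#' projection) is used.
#'
#' @param current Data frame (`cell_id`, `tmean`) of current mean annual
#'   temperature.
#' @param future The same for the future period, or a list of such data
#'   frames (one per climate-model projection).
#' @param label Scenario label.
#' @return Object of class `warming_scenario`: data frame (`cell_id`,
#'   `delta_t`) with attribute `label`.
#' @export
compute_delta <- function(current, future, label = "future") {
  if (is.data.frame(future)) future <- list(future)
  for (f in future) {
    if (!setequal(f$cell_id, current$cell_id)) {
      stop("current and future fields must cover the same cells",
           call. = FALSE)
    }
  }
  cur <- current[order(current$cell_id), ]
  fut <- vapply(future, function(f) {
    f <- f[order(f$cell_id), ]
    f$tmean
  }, numeric(nrow(cur)))
  consensus <- rowMeans(as.matrix(fut))
  delta <- consensus - cur$tmean
  if (any(!is.finite(delta))) stop("deltas must be finite", call. = FALSE)
  structure(data.frame(cell_id = cur$cell_id, delta_t = delta),
            label = label, class = c("warming_scenario", "data.frame"))
}

#' Shift a daily series by a warming scenario
#'
#' Adds each cell's `delta_t` to both `tmin` and `tmax` (the ordering
#' `tmin <= tmax` is preserved by a uniform shift).
#'
#' @param series Long-format daily series with `cell_id`.
#' @param scenario A [compute_delta()] result, or a single number applied
#'   to every cell.
#' @return The shifted series.
#' @export
apply_delta <- function(series, scenario) {
  assert_daily_series(series)
  if (is.numeric(scenario) && length(scenario) == 1) {
    series$tmin <- series$tmin + scenario
    series$tmax <- series$tmax + scenario
    return(series)
  }
  stopifnot(inherits(scenario, "warming_scenario"))
  i <- match(series$cell_id, scenario$cell_id)
  if (any(is.na(i))) {
    stop("scenario lacks deltas for cell(s): ",
         paste(unique(series$cell_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  series$tmin <- series$tmin + scenario$delta_t[i]
  series$tmax <- series$tmax + scenario$delta_t[i]
  series
}
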