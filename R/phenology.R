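assert_daily_series <- function(series) {
  need <- c("doy", "tmin", "tmax")
  if (!is.data.frame(series) || !all(need %in% names(series))) {
    stop("a daily climate series needs columns doy, tmin, tmax",
         call. = FALSE)
  }
  if (any(series$tmin > series$tmax)) {
    stop("tmin must be <= tmax on every day", call. = FALSE)
  }
  invisible(series)
}

assert_complete_year <- function(series) {
  assert_daily_series(series)
  if (nrow(series) != 365 || !setequal(series$doy, 1:365)) {
    stop("series must cover exactly days 1..365 (one climatological year)",
         call. = FALSE)
  }
  invisible(series[order(series$doy), , drop = FALSE])
}

#' Daily development rate from minimum and maximum temperature
#'
#' The daily rate is the average of the rates evaluated at the day's
#' minimum and maximum air temperatures.
#'
#' @param params A [model_params()] object.
#' @param tmin,tmax Numeric vectors (degrees C), elementwise `tmin <= tmax`.
#' @return Numeric vector of daily development rates (d^-1).
#' @export
daily_rate <- function(params, tmin, tmax) {
  if (length(tmin) != length(tmax)) {
    stop("tmin and tmax must have equal length", call. = FALSE)
  }
  if (any(tmin > tmax)) stop("tmin must be <= tmax", call. = FALSE)
  (evaluate_rate(params, tmin) + evaluate_rate(params, tmax)) / 2
}

#' Annual generations from daily development accumulation
#'
#' Accumulates [daily_rate()] from day 1 with an empty accumulator; each
#' time cumulative development reaches 1 a generation is completed on that
#' day and the overshoot carries into the next generation. The annual
#' number of generations is the completed count plus the final residual
#' fraction, which by the carry construction equals the plain sum of the
#' daily rates.
#'
#' @param series Data frame with columns `doy` (1..365), `tmin`, `tmax`.
#' @param params A [model_params()] object.
#' @param scenario Scenario label attached to the result.
#' @return Object of class `voltinism_result`: list with `generations`,
#'   `completion_days` (day-of-year of each completed generation),
#'   `daily_rates` and `scenario`.
#' @export
annual_generations <- function(series, params, scenario = "current") {
  series <- assert_complete_year(series)
  r <- daily_rate(params, series$tmin, series$tmax)
  cum <- cumsum(r)
  total <- cum[length(cum)]
  n_complete <- floor(total + 1e-12)
  completion_days <- if (n_complete >= 1) {
    series$doy[findInterval(seq_len(n_complete) - 1e-12, cum) + 1L]
  } else integer(0)
  structure(list(generations = total,
                 completion_days = as.integer(completion_days),
                 daily_rates = r, scenario = scenario,
                 cell_id = if (!is.null(series$cell_id)) series$cell_id[1]
                           else NA),
            class = "voltinism_result")
}

#' @export
print.voltinism_result <- function(x, ...) {
  cat("<voltinism_result>", sprintf("%.2f generations (%d complete), scenario '%s'\n",
      x$generations, length(x$completion_days), x$scenario))
  invisible(x)
}

#' Percentage difference between current and future generation numbers
#'
#' @param current,future Generations per year; `current` must be positive
#'   for the percentage to be defined.
#' @return `(future - current) / current * 100`; `NA` with a warning when
#'   `current` is zero.
#' @export
percent_difference <- function(current, future) {
  if (any(current < 0, na.rm = TRUE)) {
    stop("current generations must be >= 0", call. = FALSE)
  }
  out <- (future - current) / current * 100
  if (any(current == 0, na.rm = TRUE)) {
    warning("percent difference undefined where current = 0", call. = FALSE)
    out[current == 0] <- NA_real_
  }
  out
}

#' Days per year beyond the thermal thresholds
#'
#' Counts days with daily minimum temperature strictly below the lower
#' threshold, and days with daily maximum temperature reaching or
#' exceeding the upper threshold.
#'
#' @param series Data frame with columns `doy`, `tmin`, `tmax` for one
#'   cell-year.
#' @param thresholds A [thermal_thresholds()] object with at least one of
#'   `t_l`, `t_h` defined.
#' @param scenario Scenario label.
#' @return List with integer `days_below_tl` and `days_above_th`
#'   (`NA` for an undefined threshold) and `scenario`.
#' @export
count_exceedance <- function(series, thresholds, scenario = "current") {
  assert_daily_series(series)
  stopifnot(inherits(thresholds, "thermal_thresholds"))
  if (!is.finite(thresholds$t_l) && !is.finite(thresholds$t_h)) {
    stop("neither t_l nor t_h is defined", call. = FALSE)
  }
  list(
    days_below_tl = if (is.finite(thresholds$t_l))
      sum(series$tmin < thresholds$t_l) else NA_integer_,
    days_above_th = if (is.finite(thresholds$t_h))
      sum(series$tmax >= thresholds$t_h) else NA_integer_,
    scenario = scenario)
}

#' Voltinism over a grid of daily climate series
#'
#' Applies [annual_generations()] (and, when `thresholds` is supplied,
#' [count_exceedance()]) to every cell of a long-format grid.
#'
#' @param grid Data frame with columns `cell_id`, `doy`, `tmin`, `tmax`.
#' @param params A [model_params()] object.
#' @param scenario Scenario label.
#' @param thresholds Optional [thermal_thresholds()] for exceedance counts.
#' @return Data frame with one row per cell: `cell_id`, `scenario`,
#'   `generations`, `n_complete`, and when thresholds are supplied
#'   `days_below_tl`, `days_above_th`. Cells whose computation fails are
#'   kept with `ok = FALSE` and an error message, never dropped silently.
#' @export
voltinism_map <- function(grid, params, scenario = "current",
                          thresholds = NULL) {
  if (!all(c("cell_id", "doy", "tmin", "tmax") %in% names(grid))) {
    stop("grid needs columns cell_id, doy, tmin, tmax", call. = FALSE)
  }
  cells <- split(grid, grid$cell_id)
  rows <- lapply(cells, function(s) {
    res <- tryCatch({
      v <- annual_generations(s, params, scenario)
      row <- data.frame(cell_id = s$cell_id[1], scenario = scenario,
                        generations = v$generations,
                        n_complete = length(v$completion_days),
                        ok = TRUE, error = NA_character_,
                        stringsAsFactors = FALSE)
      if (!is.null(thresholds)) {
        ex <- count_exceedance(s, thresholds, scenario)
        row$days_below_tl <- ex$days_below_tl
        row$days_above_th <- ex$days_above_th
      }
      row
    }, error = function(e) {
      row <- data.frame(cell_id = s$cell_id[1], scenario = scenario,
                        generations = NA_real_, n_complete = NA_integer_,
                        ok = FALSE, error = conditionMessage(e),
                        stringsAsFactors = FALSE)
      if (!is.null(thresholds)) {
        row$days_below_tl <- NA_integer_
        row$days_above_th <- NA_integer_
      }
      row
    })
    res
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (any(!out$ok)) {
    warning(sum(!out$ok), " cell(s) failed; see the error column",
            call. = FALSE)
  }
  out
}
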