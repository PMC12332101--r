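# Synthetic data generators. These emulate the study's two data sources:
# constant-temperature development trials (five chambers, 20 replicates)
# and the gridded daily min/max air-temperature climatology of the study
# region (cold highlands to warm lowlands). Cells are independent; no
# spatial correlation is simulated.

#' Simulate a constant-temperature development trial
#'
#' Draws replicate development times around the true curve of a chosen
#' model: time = (1/rate) * (1 + eps) with eps ~ Normal(0, cv), i.e.
#' multiplicative Gaussian noise on development TIME, matching how such
#' trials are measured. Temperatures where the true rate is non-positive
#' yield no emergence and are excluded from the returned rates (kept in the
#' `censored` attribute).
#'
#' @param params True [model_params()] generating the data.
#' @param temperatures Test temperatures (degrees C); default the five
#'   chamber temperatures of the study design.
#' @param replicates Replicates per temperature.
#' @param cv Coefficient of variation of the time noise (default 0.05,
#'   loosely calibrated to the reported standard errors, 1-5% of means).
#' @param seed Integer seed.
#' @param species Label for the returned dataset.
#' @return A [development_dataset()] of per-temperature mean times and
#'   standard errors, with attributes `replicates` (long data frame of all
#'   simulated times) and `censored` (temperatures with no development).
#' @export
gen_dev_data <- function(params, temperatures = c(15, 20, 25, 30, 35),
                         replicates = 20, cv = 0.05, seed = 1L,
                         species = "synthetic") {
  stopifnot(inherits(params, "model_params"), cv >= 0, replicates >= 1)
  set.seed(seed)
  true_rate <- evaluate_rate(params, temperatures)
  censored <- temperatures[true_rate <= 0]
  keep <- true_rate > 0
  reps <- lapply(which(keep), function(i) {
    t0 <- 1 / true_rate[i]
    times <- t0 * (1 + stats::rnorm(replicates, 0, cv))
    times <- pmax(times, t0 * 1e-3) # guard: times must stay positive
    data.frame(temperature = temperatures[i], dev_time_days = times)
  })
  reps <- do.call(rbind, reps)
  agg_mean <- tapply(reps$dev_time_days, reps$temperature, mean)
  agg_se <- tapply(reps$dev_time_days, reps$temperature,
                   function(x) stats::sd(x) / sqrt(length(x)))
  out <- development_dataset(
    temperature = as.numeric(names(agg_mean)),
    dev_time_days = as.numeric(agg_mean),
    se = as.numeric(agg_se), n = replicates,
    species = species, stage = "egg-adult")
  attr(out, "replicates") <- reps
  attr(out, "censored") <- censored
  attr(out, "true_model") <- params
  out
}

#' Simulate a grid of daily min/max temperature series
#'
#' Per cell, the daily midpoint temperature follows a seasonal sinusoid
#' around a cell-specific annual mean with day-to-day Gaussian noise:
#' `tmid(d) = mean + amplitude * cos(2*pi*(d - peak_day)/365) + noise`;
#' `tmin`/`tmax` sit half the diurnal range below/above the midpoint.
#' Defaults emulate the study region: annual means spanning cold highlands
#' (12 C) to the warm northwest (24 C), seasonal amplitude 6 C, diurnal
#' range 10 C, noise sd 1.5 C, and a southern-hemisphere phase with the
#' warmest day near mid-January (day 15).
#'
#' @param n_cells Number of grid cells.
#' @param mean_range Length-2 range from which per-cell annual means are
#'   drawn uniformly (degrees C); a length-`n_cells` vector fixes them.
#' @param amplitude Seasonal amplitude (degrees C, >= 0).
#' @param diurnal_range Daily tmax - tmin (degrees C, >= 0).
#' @param noise_sd Day-to-day noise standard deviation (degrees C).
#' @param peak_day Day of year of the seasonal maximum.
#' @param seed Integer seed.
#' @return Long data frame (`cell_id`, `doy`, `tmin`, `tmax`) with 365 days
#'   per cell and attribute `cells` (data frame of per-cell configured
#'   means).
#' @export
gen_climate_grid <- function(n_cells = 10, mean_range = c(12, 24),
                             amplitude = 6, diurnal_range = 10,
                             noise_sd = 1.5, peak_day = 15, seed = 1L) {
  stopifnot(n_cells >= 1, amplitude >= 0, diurnal_range >= 0, noise_sd >= 0)
  set.seed(seed)
  means <- if (length(mean_range) == n_cells) mean_range
           else stats::runif(n_cells, mean_range[1], mean_range[2])
  doy <- 1:365
  season <- amplitude * cos(2 * pi * (doy - peak_day) / 365)
  out <- lapply(seq_len(n_cells), function(i) {
    tmid <- means[i] + season + stats::rnorm(365, 0, noise_sd)
    data.frame(cell_id = sprintf("cell_%03d", i), doy = doy,
               tmin = tmid - diurnal_range / 2,
               tmax = tmid + diurnal_range / 2,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(grid, "cells") <- data.frame(
    cell_id = sprintf("cell_%03d", seq_len(n_cells)), mean = means)
  grid
}

#' Simulate a multi-year daily series for climatology tests
#'
#' Stacks `n_years` independent draws of [gen_climate_grid()] with a `year`
#' column, sharing the per-cell means.
#'
#' @param n_years Number of years.
#' @inheritParams gen_climate_grid
#' @return Long data frame with columns `cell_id`, `year`, `doy`, `tmin`,
#'   `tmax`.
#' @export
gen_multi_year_grid <- function(n_cells = 5, n_years = 20,
                                mean_range = c(12, 24), amplitude = 6,
                                diurnal_range = 10, noise_sd = 1.5,
                                peak_day = 15, seed = 1L) {
  set.seed(seed)
  means <- stats::runif(n_cells, mean_range[1], mean_range[2])
  years <- lapply(seq_len(n_years), function(y) {
    g <- gen_climate_grid(n_cells, mean_range = means,
                          amplitude = amplitude,
                          diurnal_range = diurnal_range,
                          noise_sd = noise_sd, peak_day = peak_day,
                          seed = seed + 1000L + y)
    g$year <- 2000L + y
    g
  })
  do.call(rbind, c(years, list(make.row.names = FALSE)))
}
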