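# Shared fixtures built in code.

# Published mean egg-adult development of Te. remus (five chamber
# temperatures); identical to the shipped CSV but constructed here so the
# oracle tests do not depend on file reading.
remus_fixture <- function() {
  development_dataset(
    temperature = c(15, 20, 25, 30, 35),
    dev_time_days = c(52.70, 21.09, 12.49, 8.26, 8.10),
    se = c(0.41, 0.11, 0.03, 0.02, 0.03), n = 20,
    species = "Telenomus remus")
}

# Constant-temperature 365-day series (tmin = tmax = t).
constant_series <- function(t, cell_id = "c1") {
  data.frame(cell_id = cell_id, doy = 1:365, tmin = t, tmax = t,
             stringsAsFactors = FALSE)
}

# Sinusoidal single-cell year without noise.
sinusoid_series <- function(mean = 18, amplitude = 6, diurnal = 10,
                            peak_day = 15, cell_id = "c1") {
  tmid <- mean + amplitude * cos(2 * pi * ((1:365) - peak_day) / 365)
  data.frame(cell_id = cell_id, doy = 1:365, tmin = tmid - diurnal / 2,
             tmax = tmid + diurnal / 2, stringsAsFactors = FALSE)
}

# Brute-force grid argmax oracle for the optimum temperature.
topt_oracle <- function(params, lo = -20, hi = 60, step = 1e-3) {
  v <- params$values
  if (!is.null(v$t_l)) lo <- v$t_l
  if (!is.null(v$t_h)) hi <- v$t_h
  grid <- seq(lo, hi, by = step)
  grid[which.max(evaluate_rate(params, grid))]
}

# The published accuracy-mark pattern (rows: model; per species the marks
# for t_l, t_opt, t_h; "+" plausible, "-" implausible, "." not estimated).
table5_marks <- function(species) {
  m <- switch(species,
    te_remus = rbind(
      linear = c("+", ".", "."), beta16 = c("-", "+", "-"),
      beta_type = c(".", "+", "-"), briere1 = c("+", "+", "-"),
      briere2 = c("+", "+", "+"), kontodimas = c("+", "+", "-"),
      lactin1 = c(".", "+", "-"), lactin2 = c("-", "+", "-"),
      logan6 = c(".", "+", "-"), performance2 = c("+", "+", "+"),
      shi = c("+", "+", "+"), taylor = c("+", "+", ".")),
    t_foersteri = rbind(
      linear = c("+", ".", "."), beta16 = c("+", "+", "-"),
      beta_type = c(".", "+", "-"), briere1 = c("+", "+", "-"),
      briere2 = c("+", "+", "+"), kontodimas = c("+", "+", "-"),
      lactin1 = c(".", "+", "-"), lactin2 = c("+", "+", "-"),
      logan6 = c(".", "+", "-"), performance2 = c("+", "+", "+"),
      shi = c("+", "+", "+"), taylor = c("+", "+", ".")))
  colnames(m) <- c("t_l", "t_opt", "t_h")
  m
}
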