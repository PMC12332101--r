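#' Development-time dataset at constant temperatures
#'
#' The fitting substrate: mean egg-to-adult development times observed at a
#' series of constant temperatures, with the derived development rates
#' (1/time, d^-1).
#'
#' @param temperature Numeric vector of constant rearing temperatures
#'   (degrees C), strictly increasing, at least two distinct values.
#' @param dev_time_days Positive mean development times (days), one per
#'   temperature.
#' @param species,stage Labels.
#' @param se,n Optional standard errors of the mean times and replicate
#'   counts.
#' @return Object of class `development_dataset` with elements
#'   `observations` (data frame: temperature, dev_time_days, se, n) and
#'   `rates` (data frame: temperature, rate).
#' @export
development_dataset <- function(temperature, dev_time_days,
                                species = "unknown", stage = "egg-adult",
                                se = NA_real_, n = NA_integer_) {
  if (length(temperature) != length(dev_time_days)) {
    stop("temperature and dev_time_days must have equal length", call. = FALSE)
  }
  if (length(temperature) < 2 || anyDuplicated(temperature)) {
    stop("need at least 2 distinct temperatures", call. = FALSE)
  }
  if (is.unsorted(temperature, strictly = TRUE)) {
    ord <- order(temperature)
    temperature <- temperature[ord]
    dev_time_days <- dev_time_days[ord]
    se <- rep_len(se, length(temperature))[ord]
    n <- rep_len(n, length(temperature))[ord]
  }
  if (any(dev_time_days <= 0)) {
    stop("development times must be > 0", call. = FALSE)
  }
  obs <- data.frame(temperature = temperature,
                    dev_time_days = dev_time_days,
                    se = rep_len(se, length(temperature)),
                    n = rep_len(n, length(temperature)))
  structure(list(species = species, stage = stage, observations = obs,
                 rates = data.frame(temperature = temperature,
                                    rate = 1 / dev_time_days)),
            class = "development_dataset")
}

#' @export
print.development_dataset <- function(x, ...) {
  cat("<development_dataset>", x$species, "|", x$stage, "|",
      nrow(x$observations), "temperatures\n")
  print(cbind(x$observations, rate = x$rates$rate), row.names = FALSE)
  invisible(x)
}

#' Read a development dataset from delimited text
#'
#' Expects columns `temperature` and `dev_time_days`, optionally `species`,
#' `stage`, `se` and `n`.
#'
#' @param path Path to a CSV file.
#' @return A [development_dataset()].
#' @export
read_development_data <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature", "dev_time_days")
  if (!all(need %in% names(d))) {
    stop("development data must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(d) == 0) stop("empty development data file: ", path, call. = FALSE)
  development_dataset(
    temperature = d$temperature, dev_time_days = d$dev_time_days,
    species = if ("species" %in% names(d)) d$species[1] else "unknown",
    stage = if ("stage" %in% names(d)) d$stage[1] else "egg-adult",
    se = if ("se" %in% names(d)) d$se else NA_real_,
    n = if ("n" %in% names(d)) d$n else NA_integer_)
}

#' Mean egg-to-adult development of Telenomus remus
#'
#' The published mean development times of *Telenomus remus* on
#' *Spodoptera frugiperda* eggs at 15, 20, 25, 30 and 35 degrees C
#' (20 replicates per temperature), shipped with the package.
#'
#' @return A [development_dataset()].
#' @export
remus_development <- function() {
  read_development_data(system.file("extdata",
    "telenomus_remus_development.csv", package = "phenotherm",
    mustWork = TRUE))
}

#' Published model parameter sets
#'
#' Reads the parameter sets (and the thermal thresholds as reported) of the
#' twelve development-rate models fitted to the egg-to-adult development of
#' *Telenomus remus* and *Trichogramma foersteri*.
#'
#' @param species `"te_remus"` or `"t_foersteri"`.
#' @param model Optional model name; when given, returns a single
#'   [model_params()] object, otherwise a named list over all models.
#' @return A `model_params` object or a named list of them; each carries
#'   attributes `thresholds` (reported threshold values as a
#'   [thermal_thresholds()] object) and `species`.
#' @export
published_params <- function(species = c("te_remus", "t_foersteri"),
                             model = NULL) {
  species <- match.arg(species)
  cfg <- read_params_config(system.file("extdata", "published_params.yaml",
    package = "phenotherm", mustWork = TRUE))[[species]]
  if (!is.null(model)) {
    if (!model %in% names(cfg)) {
      stop("no published parameters for model '", model, "'", call. = FALSE)
    }
    return(cfg[[model]])
  }
  cfg
}

#' Read a model-parameter configuration file
#'
#' Parses a YAML configuration holding, per species and model, the fitted
#' parameter values and optionally the reported thresholds and thermal
#' constant. Round-trips files written by [write_params_config()].
#'
#' @param path Path to a YAML file.
#' @return Nested named list: species -> model -> [model_params()] with
#'   attributes `thresholds` and `species`.
#' @export
read_params_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(stats::setNames(names(raw), names(raw)), function(sp) {
    models <- raw[[sp]]
    lapply(stats::setNames(names(models), names(models)), function(m) {
      entry <- models[[m]]
      p <- model_params(m, entry$params)
      th <- entry$thresholds
      get_th <- function(f) if (!is.null(th[[f]])) th[[f]] else NA_real_
      attr(p, "thresholds") <- thermal_thresholds(
        t_l = get_th("t_l"), t_opt = get_th("t_opt"), t_h = get_th("t_h"),
        k = if (!is.null(entry$k)) entry$k else NA_real_)
      attr(p, "species") <- sp
      p
    })
  })
}

#' Write a model-parameter configuration file
#'
#' @param config Nested named list: species -> model -> [model_params()]
#'   (optionally carrying a `thresholds` attribute).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(config, path) {
  out <- lapply(config, function(models) {
    lapply(models, function(p) {
      entry <- list(params = p$values)
      th <- attr(p, "thresholds")
      if (!is.null(th)) {
        vals <- Filter(is.finite, list(t_l = th$t_l, t_opt = th$t_opt,
                                       t_h = th$t_h))
        if (length(vals)) entry$thresholds <- vals
        if (is.finite(th$k)) entry$k <- th$k
      }
      entry
    })
  })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Species-specific plausibility ranges for thermal thresholds
#'
#' Acceptance windows (degrees C) used to judge whether a model's estimated
#' thresholds are biologically realistic for each parasitoid, based on the
#' observed laboratory development and the species' known distribution.
#'
#' @return Named list per species with numeric length-2 ranges `t_l`,
#'   `t_opt` and `t_h`.
#' @export
plausibility_ranges <- function() {
  list(
    te_remus = list(t_l = c(6, 15), t_opt = c(32, 34), t_h = c(34, 36)),
    t_foersteri = list(t_l = c(8, 15), t_opt = c(30, 32), t_h = c(32, 33))
  )
}
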