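# Catalog of temperature-dependent development-rate models.
#
# Each entry defines the raw rate function r(T) in d^-1 (T in degrees C),
# its free parameters, which thermal thresholds are explicit parameters of
# the functional form, and how the remaining thresholds are obtained
# ("root" = numerical zero of the raw rate on that side of T_opt,
#  "none" = the form has no finite zero on that side).
.model_catalog <- list(
  linear = list(
    parameter_names = c("a", "b"),
    positive = character(0),
    explicit = character(0),
    lower = "closed_form", upper = "none", opt = "none",
    fun = function(p, t) p[["a"]] + p[["b"]] * t
  ),
  beta16 = list(
    # canonical beta rate function: peak cm at t_opt, zeros at t_l and t_h
    parameter_names = c("cm", "t_l", "t_h", "t_opt"),
    positive = "cm",
    explicit = c("t_l", "t_h", "t_opt"),
    lower = "explicit", upper = "explicit", opt = "explicit",
    fun = function(p, t) {
      ex <- (p[["t_opt"]] - p[["t_l"]]) / (p[["t_h"]] - p[["t_opt"]])
      p[["cm"]] * ((p[["t_h"]] - t) / (p[["t_h"]] - p[["t_opt"]])) *
        ((t - p[["t_l"]]) / (p[["t_opt"]] - p[["t_l"]]))^ex
    }
  ),
  beta_type = list(
    parameter_names = c("rho", "a", "beta"),
    positive = c("rho", "a"),
    explicit = character(0),
    lower = "none", upper = "root", opt = "numeric",
    fun = function(p, t) p[["rho"]] * (p[["a"]] - t / 10) * (t / 10)^p[["beta"]]
  ),
  briere1 = list(
    parameter_names = c("a", "t_l", "t_h"),
    positive = "a",
    explicit = c("t_l", "t_h"),
    lower = "explicit", upper = "explicit", opt = "numeric",
    fun = function(p, t) p[["a"]] * t * (t - p[["t_l"]]) * (p[["t_h"]] - t)^(1 / 2)
  ),
  briere2 = list(
    parameter_names = c("a", "m", "t_l", "t_h"),
    positive = c("a", "m"),
    explicit = c("t_l", "t_h"),
    lower = "explicit", upper = "explicit", opt = "numeric",
    fun = function(p, t) p[["a"]] * t * (t - p[["t_l"]]) * (p[["t_h"]] - t)^(1 / p[["m"]])
  ),
  kontodimas = list(
    parameter_names = c("alpha", "t_l", "t_h"),
    positive = "alpha",
    explicit = c("t_l", "t_h"),
    lower = "explicit", upper = "explicit", opt = "numeric",
    fun = function(p, t) p[["alpha"]] * (t - p[["t_l"]])^2 * (p[["t_h"]] - t)
  ),
  lactin1 = list(
    # single zero exactly at t_h; no finite lower zero
    parameter_names = c("rho", "delta", "t_h"),
    positive = c("rho", "delta"),
    explicit = "t_h",
    lower = "none", upper = "explicit", opt = "numeric",
    fun = function(p, t)
      exp(p[["rho"]] * t) - exp(p[["rho"]] * p[["t_h"]] - (p[["t_h"]] - t) / p[["delta"]])
  ),
  lactin2 = list(
    parameter_names = c("rho", "delta", "lambda", "t_h"),
    positive = c("rho", "delta"),
    explicit = "t_h",
    lower = "root", upper = "explicit", opt = "numeric",
    fun = function(p, t)
      exp(p[["rho"]] * t) - exp(p[["rho"]] * p[["t_h"]] - (p[["t_h"]] - t) / p[["delta"]]) +
        p[["lambda"]]
  ),
  logan6 = list(
    parameter_names = c("rho", "delta", "phi", "t_h"),
    positive = c("rho", "delta", "phi"),
    explicit = "t_h",
    lower = "none", upper = "explicit", opt = "numeric",
    fun = function(p, t)
      p[["phi"]] * (exp(p[["rho"]] * t) -
        exp(p[["rho"]] * p[["t_h"]] - (p[["t_h"]] - t) / p[["delta"]]))
  ),
  performance2 = list(
    parameter_names = c("c", "k", "t_l", "t_h"),
    positive = c("c", "k"),
    explicit = c("t_l", "t_h"),
    lower = "explicit", upper = "explicit", opt = "numeric",
    fun = function(p, t)
      p[["c"]] * (t - p[["t_l"]]) * (1 - exp(p[["k"]] * (t - p[["t_h"]])))
  ),
  shi = list(
    parameter_names = c("c", "k1", "k2", "t_l", "t_h"),
    positive = c("c", "k1", "k2"),
    explicit = c("t_l", "t_h"),
    lower = "explicit", upper = "explicit", opt = "numeric",
    fun = function(p, t)
      p[["c"]] * (1 - exp(-p[["k1"]] * (t - p[["t_l"]]))) *
        (1 - exp(p[["k2"]] * (t - p[["t_h"]])))
  ),
  taylor = list(
    # Gaussian thermal response: t_sigma is a spread, not a developmental zero
    parameter_names = c("rm", "t_opt", "t_sigma"),
    positive = c("rm", "t_sigma"),
    explicit = "t_opt",
    lower = "none", upper = "none", opt = "explicit",
    fun = function(p, t) p[["rm"]] * exp(-0.5 * ((t - p[["t_opt"]]) / p[["t_sigma"]])^2)
  )
)

#' Names of the available development-rate models
#'
#' @return Character vector with the twelve model names: the degree-day
#'   linear model and eleven nonlinear thermal performance curves.
#' @export
model_names <- function() names(.model_catalog)

#' Model specification
#'
#' Describes one of the twelve development-rate models: its parameter names,
#' which thermal thresholds (`t_l`, `t_opt`, `t_h`) appear as explicit
#' parameters of the functional form, and its parameter count.
#'
#' @param name Model name, one of [model_names()].
#' @return An object of class `model_spec` with elements `name`,
#'   `parameter_names`, `explicit_thresholds` and `k` (number of fitted
#'   parameters).
#' @export
model_spec <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% names(.model_catalog)) {
    stop("unknown model name: ", paste(name, collapse = ", "),
         "; see model_names()", call. = FALSE)
  }
  entry <- .model_catalog[[name]]
  explicit <- intersect(c("t_l", "t_opt", "t_h"),
                        c(entry$explicit))
  structure(
    list(name = name,
         parameter_names = entry$parameter_names,
         explicit_thresholds = explicit,
         k = length(entry$parameter_names)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name, "\n",
      " parameters:", paste(x$parameter_names, collapse = ", "), "\n",
      " explicit thresholds:",
      if (length(x$explicit_thresholds)) paste(x$explicit_thresholds, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Parameterised development-rate model
#'
#' Binds a complete named parameter vector to a model specification.
#' Temperatures are degrees Celsius and rates are d^-1 throughout.
#'
#' @param name Model name, one of [model_names()].
#' @param values Named numeric vector or list covering every parameter of
#'   the model (see `model_spec(name)$parameter_names`).
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params("briere2", c(a = 1.69e-4, m = 14.22, t_l = 8.72, t_h = 35.04))
#' evaluate_rate(p, 25)
#' @export
model_params <- function(name, values) {
  spec <- model_spec(name)
  values <- unlist(values)
  if (is.null(names(values)) || !all(spec$parameter_names %in% names(values))) {
    missing <- setdiff(spec$parameter_names, names(values))
    stop("missing parameter(s) for model '", name, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  values <- values[spec$parameter_names]
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("parameter values must be finite numerics", call. = FALSE)
  }
  pos <- .model_catalog[[name]]$positive
  bad <- pos[values[pos] <= 0]
  if (length(bad)) {
    stop("parameter(s) must be > 0 for model '", name, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  v <- as.list(values)
  if (all(c("t_l", "t_h") %in% names(v)) && v$t_l >= v$t_h) {
    stop("t_l must be below t_h", call. = FALSE)
  }
  if (all(c("t_l", "t_opt") %in% names(v)) && v$t_l >= v$t_opt) {
    stop("t_l must be below t_opt", call. = FALSE)
  }
  if (all(c("t_opt", "t_h") %in% names(v)) && v$t_opt >= v$t_h) {
    stop("t_opt must be below t_h", call. = FALSE)
  }
  structure(list(spec = spec, values = v), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>", x$spec$name, "\n")
  print(unlist(x$values))
  invisible(x)
}

# Raw (unclamped) model formula value; may be negative, NaN or infinite.
rate_raw <- function(params, t) {
  stopifnot(inherits(params, "model_params"))
  suppressWarnings(.model_catalog[[params$spec$name]]$fun(params$values, t))
}

#' Evaluate a development rate
#'
#' Evaluates the model formula elementwise over `t` and clamps it to the
#' biologically meaningful domain: the returned rate is exactly 0 wherever
#' the raw formula is negative or undefined (complex/NaN), and wherever `t`
#' lies below an explicit lower threshold or above an explicit upper
#' threshold of the form. This totalises the rate over any temperature
#' input, which the daily accumulation of development requires.
#'
#' @param params A [model_params()] object.
#' @param t Numeric vector of temperatures (degrees C).
#' @return Numeric vector of non-negative development rates (d^-1).
#' @export
evaluate_rate <- function(params, t) {
  if (!inherits(params, "model_params")) {
    stop("params must be a model_params object", call. = FALSE)
  }
  if (!is.numeric(t)) stop("t must be numeric", call. = FALSE)
  r <- rate_raw(params, t)
  r[!is.finite(r) | r < 0] <- 0
  v <- params$values
  if (!is.null(v$t_l)) r[t < v$t_l] <- 0
  if (!is.null(v$t_h)) r[t > v$t_h] <- 0
  pmax(r, 0)
}

#' Optimum development temperature
#'
#' Finds the temperature maximising [evaluate_rate()]. When the optimum is
#' an explicit parameter of the form (beta and Taylor families) it is passed
#' through; otherwise the maximum is located by a dense grid scan (step
#' `step` degrees C) followed by local refinement with [stats::optimize()].
#'
#' @param params A [model_params()] object.
#' @param step Grid step in degrees C for the initial scan.
#' @param search Numeric length-2 vector; scan interval used for the sides
#'   on which the model has no explicit threshold.
#' @return Optimum temperature in degrees C.
#' @export
derive_topt <- function(params, step = 0.01, search = c(-20, 60)) {
  stopifnot(inherits(params, "model_params"))
  entry <- .model_catalog[[params$spec$name]]
  if (entry$opt == "explicit") return(params$values$t_opt)
  if (entry$opt == "none") {
    stop("degenerate optimum: model '", params$spec$name,
         "' has no interior maximum", call. = FALSE)
  }
  v <- params$values
  lo <- if (!is.null(v$t_l)) v$t_l else search[1]
  hi <- if (!is.null(v$t_h)) v$t_h else search[2]
  grid <- seq(lo, hi, by = step)
  rates <- evaluate_rate(params, grid)
  i <- which.max(rates)
  if (rates[i] <= 0) {
    stop("degenerate optimum: rate is non-positive over the search domain",
         call. = FALSE)
  }
  if (i == 1L || i == length(grid)) {
    stop("degenerate optimum: maximum on the domain boundary", call. = FALSE)
  }
  stats::optimize(function(x) evaluate_rate(params, x),
                  lower = grid[i - 1L], upper = grid[i + 1L],
                  maximum = TRUE, tol = 1e-8)$maximum
}

#' Thermal thresholds of a parameterised model
#'
#' Returns the lower threshold `t_l`, optimum `t_opt`, upper threshold
#' `t_h` and (for the linear model) the thermal constant `k` in
#' degree-days, together with the provenance of each value:
#' `"explicit-parameter"`, `"derived-numerically"` or
#' `"undefined-by-model"`. Derived thresholds are the zeros of the raw rate
#' nearest below/above the optimum, found by a bracketed root search; the
#' linear model uses the x-axis intersection `t_l = -a/b` and `k = 1/b`.
#' A failed bracket yields an undefined threshold, not an error.
#'
#' @param params A [model_params()] object.
#' @param search Numeric length-2 vector bounding the root search.
#' @return An object of class `thermal_thresholds`: list with numeric
#'   fields `t_l`, `t_opt`, `t_h`, `k` (NA when undefined) and a character
#'   vector `provenance`.
#' @export
derive_thresholds <- function(params, search = c(-60, 80)) {
  stopifnot(inherits(params, "model_params"))
  name <- params$spec$name
  entry <- .model_catalog[[name]]
  v <- params$values
  out <- list(t_l = NA_real_, t_opt = NA_real_, t_h = NA_real_, k = NA_real_)
  prov <- c(t_l = "undefined-by-model", t_opt = "undefined-by-model",
            t_h = "undefined-by-model")

  if (name == "linear") {
    if (v$b > 0) {
      out$t_l <- -v$a / v$b
      out$k <- 1 / v$b
      prov["t_l"] <- "derived-numerically"
    }
    return(structure(c(out, list(provenance = prov)),
                     class = "thermal_thresholds"))
  }

  t_opt <- tryCatch(derive_topt(params), error = function(e) NA_real_)
  if (entry$opt == "explicit") {
    out$t_opt <- v$t_opt
    prov["t_opt"] <- "explicit-parameter"
  } else if (is.finite(t_opt)) {
    out$t_opt <- t_opt
    prov["t_opt"] <- "derived-numerically"
  }

  f <- function(x) rate_raw(params, x)
  root_below <- function(from) {
    grid <- seq(from, search[1], by = -0.25)
    vals <- f(grid)
    ok <- is.finite(vals)
    sgn <- sign(vals[ok])
    flip <- which(diff(sgn) != 0)
    if (!length(flip)) return(NA_real_)
    g <- grid[ok]
    stats::uniroot(f, c(g[flip[1] + 1L], g[flip[1]]), tol = 1e-9)$root
  }
  root_above <- function(from) {
    grid <- seq(from, search[2], by = 0.25)
    vals <- f(grid)
    ok <- is.finite(vals)
    sgn <- sign(vals[ok])
    flip <- which(diff(sgn) != 0)
    if (!length(flip)) return(NA_real_)
    g <- grid[ok]
    stats::uniroot(f, c(g[flip[1]], g[flip[1] + 1L]), tol = 1e-9)$root
  }

  if (entry$lower == "explicit") {
    out$t_l <- v$t_l
    prov["t_l"] <- "explicit-parameter"
  } else if (entry$lower == "root" && is.finite(out$t_opt)) {
    r <- root_below(out$t_opt)
    if (is.finite(r)) {
      out$t_l <- r
      prov["t_l"] <- "derived-numerically"
    }
  }
  if (entry$upper == "explicit") {
    out$t_h <- v$t_h
    prov["t_h"] <- "explicit-parameter"
  } else if (entry$upper == "root" && is.finite(out$t_opt)) {
    r <- root_above(out$t_opt)
    if (is.finite(r)) {
      out$t_h <- r
      prov["t_h"] <- "derived-numerically"
    }
  }
  structure(c(out, list(provenance = prov)), class = "thermal_thresholds")
}

#' Construct thermal thresholds directly from known values
#'
#' Convenience constructor used when threshold values are taken from a
#' published table rather than derived from a parameterised curve (e.g. to
#' screen reported thresholds for plausibility).
#'
#' @param t_l,t_opt,t_h,k Numeric or NA.
#' @return A `thermal_thresholds` object; provenance is
#'   `"explicit-parameter"` for supplied values.
#' @export
thermal_thresholds <- function(t_l = NA_real_, t_opt = NA_real_,
                               t_h = NA_real_, k = NA_real_) {
  def <- c(t_l = t_l, t_opt = t_opt, t_h = t_h)
  def <- def[is.finite(def)]
  if (length(def) > 1 && any(diff(def[order(match(names(def),
      c("t_l", "t_opt", "t_h")))]) <= 0)) {
    stop("thresholds must satisfy t_l < t_opt < t_h where defined",
         call. = FALSE)
  }
  prov <- vapply(c(t_l = t_l, t_opt = t_opt, t_h = t_h),
                 function(x) if (is.finite(x)) "explicit-parameter"
                             else "undefined-by-model",
                 character(1))
  structure(list(t_l = t_l, t_opt = t_opt, t_h = t_h, k = k,
                 provenance = prov),
            class = "thermal_thresholds")
}

#' @export
print.thermal_thresholds <- function(x, digits = 2, ...) {
  fmt <- function(v) if (is.finite(v)) format(round(v, digits)) else "undefined"
  cat("<thermal_thresholds> t_l:", fmt(x$t_l),
      " t_opt:", fmt(x$t_opt),
      " t_h:", fmt(x$t_h), "\n")
  if (is.finite(x$k)) cat("  thermal constant k:", fmt(x$k), "degree-days\n")
  invisible(x)
}
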