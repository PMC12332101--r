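#' Fit statistics for a development-rate model
#'
#' The regression standard error is `s = sqrt(sse / (n - k))` (undefined
#' when `n <= k`), and the information criteria follow the least-squares
#' convention with the error variance counted as a parameter:
#' `aic = n * log(sse / n) + 2 * (k + 1)` and
#' `bic = n * log(sse / n) + (k + 1) * log(n)`. Only differences between
#' models fitted to the same data are meaningful; [compare_models()] adds
#' `delta_aic` / `delta_bic` against the per-set minimum.
#'
#' @param sse Residual sum of squares.
#' @param n Number of observations.
#' @param k Number of fitted parameters.
#' @return List with `sse`, `n`, `k`, `s`, `aic`, `bic`.
#' @export
fit_statistics <- function(sse, n, k) {
  stopifnot(sse >= 0, n >= 1, k >= 1)
  s <- if (n > k) sqrt(sse / (n - k)) else NA_real_
  if (n >= k) {
    ll_term <- n * log(sse / n) # -Inf when a model interpolates exactly
    aic <- ll_term + 2 * (k + 1)
    bic <- ll_term + (k + 1) * log(n)
  } else {
    aic <- bic <- NA_real_
  }
  list(sse = sse, n = n, k = k, s = s, aic = aic, bic = bic)
}

new_fitted_model <- function(data, spec, values, sse, convergence) {
  params <- model_params(spec$name, values)
  structure(
    list(data = data, spec = spec, params = params,
         stats = fit_statistics(sse, nrow(data$rates), spec$k),
         thresholds = derive_thresholds(params),
         convergence = convergence),
    class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("<fitted_model>", x$spec$name, "on", x$data$species, "\n ")
  print(unlist(x$params$values))
  with(x$stats, cat(sprintf(
    " n = %d, k = %d, SSE = %.4g, S = %s, AIC = %.2f\n", n, k, sse,
    ifelse(is.na(s), "undef.", sprintf("%.4g", s)), aic)))
  print(x$thresholds)
  invisible(x)
}

#' Fit the linear degree-day model
#'
#' Ordinary least squares of development rate on temperature over all
#' supplied points. The lower threshold is the x-axis intersection
#' `t_l = -a/b` and the thermal constant `k = 1/b` degree-days.
#'
#' @param data A [development_dataset()].
#' @return A `fitted_model`; with only two points the regression standard
#'   error is undefined (reported NA). A non-positive slope leaves the
#'   thresholds undefined.
#' @export
fit_linear <- function(data) {
  stopifnot(inherits(data, "development_dataset"))
  r <- data$rates
  if (nrow(r) < 2) stop("insufficient data: need >= 2 points", call. = FALSE)
  fit <- stats::lm(rate ~ temperature, data = r)
  cf <- stats::coef(fit)
  out <- new_fitted_model(data, model_spec("linear"),
                          c(a = unname(cf[1]), b = unname(cf[2])),
                          sum(stats::resid(fit)^2),
                          list(converged = TRUE, method = "ols"))
  out
}

# Default multi-start sampling boxes per model: thresholds t_l in [-20, 20]
# and t_h in [30, 50]; shape and rate parameters in wide positive boxes.
default_bounds <- function(name) {
  switch(name,
    beta16 = list(lower = c(cm = 1e-3, t_l = -20, t_h = 30, t_opt = 20),
                  upper = c(cm = 1, t_l = 20, t_h = 50, t_opt = 38)),
    beta_type = list(lower = c(rho = 1e-5, a = 0.5, beta = 0.1),
                     upper = c(rho = 1, a = 10, beta = 20)),
    briere1 = list(lower = c(a = 1e-7, t_l = -20, t_h = 30),
                   upper = c(a = 1e-2, t_l = 20, t_h = 50)),
    briere2 = list(lower = c(a = 1e-6, m = 1, t_l = -20, t_h = 30),
                   upper = c(a = 1e-2, m = 50, t_l = 20, t_h = 50)),
    kontodimas = list(lower = c(alpha = 1e-8, t_l = -20, t_h = 30),
                      upper = c(alpha = 1e-3, t_l = 20, t_h = 50)),
    lactin1 = list(lower = c(rho = 1e-3, delta = 0.1, t_h = 30),
                   upper = c(rho = 1, delta = 20, t_h = 50)),
    lactin2 = list(lower = c(rho = 1e-3, delta = 0.1, lambda = -5, t_h = 30),
                   upper = c(rho = 1, delta = 20, lambda = 5, t_h = 50)),
    logan6 = list(lower = c(rho = 1e-3, delta = 0.1, phi = 1e-4, t_h = 30),
                  upper = c(rho = 1, delta = 20, phi = 10, t_h = 50)),
    performance2 = list(lower = c(c = 1e-5, k = 1e-3, t_l = -20, t_h = 30),
                        upper = c(c = 1, k = 20, t_l = 20, t_h = 50)),
    shi = list(lower = c(c = 1e-3, k1 = 1e-4, k2 = 1e-4, t_l = -20, t_h = 30),
               upper = c(c = 50, k1 = 5, k2 = 20, t_l = 20, t_h = 50)),
    taylor = list(lower = c(rm = 1e-3, t_opt = 20, t_sigma = 0.5),
                  upper = c(rm = 1, t_opt = 40, t_sigma = 30)),
    stop("no default bounds for model '", name, "'", call. = FALSE)
  )
}

# Published parameter sets reused as literature-informed anchor starts.
# The Lactin/Logan family additionally gets structural anchors with
# rho = 1/delta: near that ridge the two exponentials almost cancel and the
# curve attains realistic rate magnitudes, a region Latin-hypercube draws
# practically never hit.
anchor_starts <- function(name, lower, upper) {
  anchors <- lapply(c("te_remus", "t_foersteri"), function(sp) {
    p <- tryCatch(published_params(sp, name), error = function(e) NULL)
    if (is.null(p)) return(NULL)
    unlist(p$values)
  })
  anchors <- Filter(Negate(is.null), anchors)
  if (name %in% c("lactin1", "lactin2", "logan6")) {
    grid <- expand.grid(delta = seq(3, 12, by = 1.5), t_h = c(33, 36, 39, 42))
    anchors <- c(anchors, lapply(seq_len(nrow(grid)), function(i) {
      d <- grid$delta[i]
      c(rho = 1 / d, delta = d, lambda = -0.01, phi = 0.01,
        t_h = grid$t_h[i])[names(lower)]
    }))
  }
  lapply(anchors, function(a) pmin(pmax(a[names(lower)], lower + 1e-9),
                                   upper - 1e-9))
}

#' Fit a nonlinear development-rate model by seeded multi-start
#' Levenberg-Marquardt
#'
#' Runs bounded Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]) from every start of a seeded Latin-hypercube
#' sample of the bounding box, plus literature-informed anchor starts
#' (the shipped published parameter sets, when available for the model),
#' and returns the converged fit with the smallest residual sum of squares.
#'
#' @param data A [development_dataset()].
#' @param model Model name, one of [model_names()] except `"linear"`
#'   (use [fit_linear()]).
#' @param n_starts Number of Latin-hypercube starting points (>= 1).
#' @param bounds List with named numeric vectors `lower` and `upper`;
#'   defaults to [default_bounds()] for the model.
#' @param anchors Optional list of additional named start vectors.
#' @param seed Integer seed for the Latin-hypercube draw.
#' @return A `fitted_model` with a `convergence` element recording the
#'   number of converged starts and the index of the winning start.
#' @export
fit_nonlinear <- function(data, model, n_starts = 200, bounds = NULL,
                          anchors = NULL, seed = 1L) {
  stopifnot(inherits(data, "development_dataset"))
  spec <- model_spec(model)
  if (model == "linear") stop("use fit_linear() for the linear model",
                              call. = FALSE)
  if (is.null(bounds)) bounds <- default_bounds(model)
  lower <- bounds$lower[spec$parameter_names]
  upper <- bounds$upper[spec$parameter_names]
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite and cover every parameter", call. = FALSE)
  }
  tt <- data$rates$temperature
  rr <- data$rates$rate

  set.seed(seed)
  u <- lhs::randomLHS(n_starts, spec$k)
  starts <- sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  colnames(starts) <- spec$parameter_names
  extra <- c(anchor_starts(model, lower, upper), anchors)
  starts <- rbind(starts, do.call(rbind, lapply(extra, function(a)
    a[spec$parameter_names])))

  # Least squares on the raw formula: negative values stay (clamping them
  # flattens the gradient and traps the optimizer, e.g. in the Lactin
  # family's rho ~ 1/delta valley); temperatures outside the formula's real
  # domain predict rate 0.
  fun <- .model_catalog[[model]]$fun
  resid_fn <- function(p) {
    names(p) <- spec$parameter_names
    v <- suppressWarnings(fun(as.list(p), tt))
    v[!is.finite(v)] <- 0
    v - rr
  }
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300))),
      error = function(e) NULL)
    if (is.null(o)) next
    p <- stats::setNames(as.numeric(o$par), spec$parameter_names)
    valid <- tryCatch({model_params(model, p); TRUE},
                      error = function(e) FALSE)
    if (!valid) next
    n_conv <- n_conv + 1L
    sse <- sum(o$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-15) {
      best <- list(sse = sse, par = p, start = i, info = o$info)
    }
  }
  if (is.null(best)) {
    stop("fit failure for model '", model, "': no start converged to a ",
         "valid parameter set (", nrow(starts), " starts tried)",
         call. = FALSE)
  }
  new_fitted_model(data, spec, best$par, best$sse,
                   list(converged = TRUE, n_converged = n_conv,
                        n_starts = nrow(starts), winning_start = best$start,
                        lm_info = best$info, seed = seed))
}

#' Fit all requested models to one dataset
#'
#' @param data A [development_dataset()].
#' @param models Character vector of model names (default: all twelve).
#' @param n_starts,seed Passed to [fit_nonlinear()]; each model uses
#'   `seed + <model index>` so draws differ between models but are
#'   reproducible.
#' @return Named list of `fitted_model` objects; models whose fit fails are
#'   dropped with a warning.
#' @export
fit_all_models <- function(data, models = model_names(), n_starts = 200,
                           seed = 1L) {
  fits <- list()
  for (i in seq_along(models)) {
    m <- models[i]
    f <- tryCatch(
      if (m == "linear") fit_linear(data)
      else fit_nonlinear(data, m, n_starts = n_starts, seed = seed + i),
      error = function(e) {
        warning("model '", m, "' failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(f)) fits[[m]] <- f
  }
  fits
}

#' Screen thermal thresholds for biological plausibility
#'
#' Marks each threshold `"+"` if defined and inside the closed
#' species-specific acceptance range, `"-"` if defined and outside, and
#' `"."` if the model does not estimate it.
#'
#' @param thresholds A [thermal_thresholds()] object.
#' @param ranges Named list of length-2 ranges `t_l`, `t_opt`, `t_h`
#'   (degrees C), e.g. one element of [plausibility_ranges()].
#' @param species Optional species label used to index `ranges` when it is
#'   the full per-species list.
#' @return Named character vector of marks for `t_l`, `t_opt`, `t_h`.
#' @export
screen_plausibility <- function(thresholds, ranges = plausibility_ranges(),
                                species = NULL) {
  stopifnot(inherits(thresholds, "thermal_thresholds"))
  if (!is.null(species)) {
    if (!species %in% names(ranges)) {
      stop("no plausibility ranges for species '", species, "'",
           call. = FALSE)
    }
    ranges <- ranges[[species]]
  }
  if (!all(c("t_l", "t_opt", "t_h") %in% names(ranges))) {
    stop("ranges must define t_l, t_opt and t_h (or pass species=)",
         call. = FALSE)
  }
  vapply(c("t_l", "t_opt", "t_h"), function(f) {
    v <- thresholds[[f]]
    if (!is.finite(v)) return(".")
    rg <- ranges[[f]]
    if (v >= rg[1] && v <= rg[2]) "+" else "-"
  }, character(1))
}

#' Compare fitted models
#'
#' Builds the model-comparison table: fit statistics with `delta_aic` /
#' `delta_bic` against the minimum over the supplied set, the thermal
#' thresholds derived from each fit, and (when `species` has plausibility
#' ranges) the accuracy marks and their count.
#'
#' @param fits Non-empty named list of `fitted_model` objects sharing one
#'   dataset.
#' @param species Species key into `ranges` (default: none, no marks).
#' @param ranges Per-species plausibility ranges, as
#'   [plausibility_ranges()].
#' @return Object of class `model_comparison`: a data frame with one row
#'   per model (model, k, sse, s, aic, bic, delta_aic, delta_bic, t_l,
#'   t_opt, t_h, mark_t_l, mark_t_opt, mark_t_h, n_plausible,
#'   n_thresholds).
#' @export
compare_models <- function(fits, species = NULL,
                           ranges = plausibility_ranges()) {
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "fitted_model")))
  rows <- lapply(fits, function(f) {
    th <- f$thresholds
    data.frame(model = f$spec$name, k = f$stats$k, n = f$stats$n,
               sse = f$stats$sse, s = f$stats$s, aic = f$stats$aic,
               bic = f$stats$bic, t_l = th$t_l, t_opt = th$t_opt,
               t_h = th$t_h, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  tab$delta_bic <- tab$bic - min(tab$bic, na.rm = TRUE)
  marks <- t(vapply(fits, function(f) {
    if (is.null(species)) rep(NA_character_, 3)
    else screen_plausibility(f$thresholds, ranges, species)
  }, character(3)))
  tab$mark_t_l <- marks[, 1]
  tab$mark_t_opt <- marks[, 2]
  tab$mark_t_h <- marks[, 3]
  tab$n_plausible <- rowSums(marks == "+", na.rm = TRUE)
  tab$n_thresholds <- rowSums(cbind(is.finite(tab$t_l), is.finite(tab$t_opt),
                                    is.finite(tab$t_h)))
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' Select the best model from a comparison
#'
#' Deterministic lexicographic rule: maximise the number of plausible
#' (`"+"`) thresholds; break ties by minimal `delta_aic`; then by minimal
#' parameter count `k`; finally alphabetically.
#'
#' @param comparison A [compare_models()] result.
#' @return The selected model name.
#' @export
select_best <- function(comparison) {
  stopifnot(inherits(comparison, "model_comparison"),
            nrow(comparison) >= 1)
  d_aic <- ifelse(is.na(comparison$delta_aic), Inf, comparison$delta_aic)
  ord <- order(-comparison$n_plausible, d_aic, comparison$k,
               comparison$model)
  comparison$model[ord[1]]
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat("<model_comparison>", nrow(x), "models\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
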