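# Bounded nonlinear least-squares estimation of (eta_c, a_star_um, alpha)
# from (diameter, apparent relative viscosity) series.  The loss is the sum
# of squared RELATIVE residuals, consistent with the multiplicative 10-20%
# error structure of in-vitro tube viscometry.

#' Viscosity-diameter dataset
#'
#' Validates a set of `(diameter_um, eta_app_rel)` observations for
#' fitting.  At least three rows are required (the model has three free
#' parameters); diameters need not be sorted or unique.
#'
#' @param diameter_um Tube diameters in micrometres, all `> 0`.
#' @param eta_app_rel Observed apparent relative viscosities, all `>= 1`.
#' @param weight Optional positive per-row weights (relative residuals are
#'   scaled by `sqrt(weight)`).
#' @param label Free-text label carried through to summaries.
#' @return An object of class `fl_dataset`: a `data.frame` with columns
#'   `diameter_um`, `eta_app_rel` and optionally `weight`.
#' @export
viscosity_dataset <- function(diameter_um, eta_app_rel, weight = NULL,
                              label = "") {
  if (length(diameter_um) != length(eta_app_rel))
    stop("`diameter_um` and `eta_app_rel` must have equal length", call. = FALSE)
  if (length(diameter_um) < 3)
    stop("need at least 3 observations to constrain 3 parameters", call. = FALSE)
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0))
    stop("all diameters must be finite and > 0", call. = FALSE)
  if (any(!is.finite(eta_app_rel)) || any(eta_app_rel < 1))
    stop("all apparent relative viscosities must be finite and >= 1",
         call. = FALSE)
  out <- data.frame(diameter_um = diameter_um, eta_app_rel = eta_app_rel)
  if (!is.null(weight)) {
    if (length(weight) != length(diameter_um) || any(!is.finite(weight)) ||
        any(weight <= 0))
      stop("`weight` must be positive and match the dataset length",
           call. = FALSE)
    out$weight <- weight
  }
  attr(out, "label") <- label
  class(out) <- c("fl_dataset", "data.frame")
  out
}

#' Parameter bounds for fitting
#'
#' Box constraints for [fit_parameters()].  The defaults encode the
#' physically acceptable ranges for human blood: the exclusion
#' half-thickness is about half an RBC disk thickness (1--1.5 um), the
#' marginal viscosity fraction typically does not exceed 0.15, and the core
#' relative viscosity must exceed 1 (bulk blood is more viscous than
#' plasma).  All are overridable, e.g. `a_star_um` near 0.8 um for rat
#' blood, whose cells are 25--30% smaller, or `eta_c` above 6 for
#' high-hematocrit samples.
#'
#' @param eta_c Length-2 interval for the core relative viscosity.
#' @param alpha Length-2 interval for the marginal viscosity fraction.
#' @param a_star_um Length-2 interval (micrometres) for the exclusion
#'   half-thickness.
#' @return An object of class `fl_bounds`: a named list of intervals.
#' @export
fit_bounds <- function(eta_c = c(1.001, 10), alpha = c(0, 0.15),
                       a_star_um = c(1.0, 1.5)) {
  b <- list(eta_c = eta_c, alpha = alpha, a_star_um = a_star_um)
  for (nm in names(b)) {
    iv <- b[[nm]]
    if (length(iv) != 2 || any(!is.finite(iv)) || iv[1] > iv[2])
      stop(sprintf("`%s` bound must be a finite interval c(lower, upper)", nm),
           call. = FALSE)
  }
  if (b$eta_c[1] <= 1) stop("`eta_c` lower bound must exceed 1", call. = FALSE)
  if (b$alpha[1] < 0 || b$alpha[2] > 1)
    stop("`alpha` bounds must lie in [0, 1]", call. = FALSE)
  if (b$a_star_um[1] <= 0)
    stop("`a_star_um` lower bound must be positive", call. = FALSE)
  structure(b, class = "fl_bounds")
}

# Relative residual vector for a raw parameter triple.  Diameters at or
# below the exclusion gap 2 a* get a large *finite* penalty so that
# bounded optimizers can back out of an infeasible corner instead of
# aborting on an exception.
.residuals_raw <- function(dataset, eta_c, alpha, a_star_um,
                           penalty = 1e6) {
  d <- dataset$diameter_um
  obs <- dataset$eta_app_rel
  res <- rep(penalty, length(d))
  ok <- d > 2 * a_star_um
  if (any(ok)) {
    s0 <- 1 - 2 * a_star_um / d[ok]
    eta_A <- annulus_viscosity(eta_c, alpha)
    s_inf <- core_radius_closed_form(s0, eta_c, eta_A)
    pred <- apparent_relative_viscosity(s_inf, eta_c, eta_A)
    res[ok] <- (pred - obs[ok]) / obs[ok]
  }
  if (!is.null(dataset$weight)) res <- res * sqrt(dataset$weight)
  res
}

#' Per-observation relative residuals of the core-annulus model
#'
#' `residual_i = (predicted eta_app(D_i) - observed_i) / observed_i`,
#' scaled by `sqrt(weight)` when the dataset carries weights.  During a
#' bounded search, diameters at or below the exclusion gap `2 a_star_um`
#' receive a large finite penalty rather than raising an error.
#'
#' @param dataset A [viscosity_dataset()].
#' @param params A [model_params()] object.
#' @return Numeric vector of relative residuals, one per dataset row.
#' @export
model_residuals <- function(dataset, params) {
  stopifnot(inherits(dataset, "fl_dataset"), inherits(params, "fl_params"))
  .residuals_raw(dataset, params$eta_c, params$alpha, params$a_star_um)
}

#' Fit the core-annulus model to a viscosity-diameter dataset
#'
#' Estimates `(eta_c, a_star_um, alpha)` by bounded Levenberg-Marquardt
#' least squares ([minpack.lm::nls.lm()]) on the relative residuals,
#' restarted from a deterministic `3 x 3 x 3` grid of interior points of
#' the bounds (fewer dimensions when parameters are fixed).  The best local
#' optimum is returned; ties in the loss are broken by the
#' lexicographically smallest `(eta_c, a_star_um, alpha)`, so the result is
#' deterministic for identical inputs.
#'
#' @param dataset A [viscosity_dataset()].
#' @param bounds A [fit_bounds()] object.
#' @param fixed Optional named numeric vector fixing a subset of
#'   `c("eta_c", "alpha", "a_star_um")` at given values (each inside its
#'   bound); only the remaining parameters are fitted.  Sharing `a_star_um`
#'   across series fitted separately is the typical use.
#' @param n_starts Number of multistart points per free parameter
#'   (default 3).
#' @return An object of class `fl_fit`: a list with `params` (a
#'   [model_params()] object), `loss` (sum of squared relative residuals),
#'   `residuals`, `converged`, `n_starts` (total starts attempted) and
#'   `bounds_active` (names of parameters sitting on a bound).
#' @examples
#' p <- model_params(eta_c = 3.3, alpha = 0.1, a_star_um = 1.2)
#' d <- viscosity_curve(seq(40, 600, length.out = 20), p)
#' fit <- fit_parameters(viscosity_dataset(d$diameter_um, d$eta_app_rel))
#' fit$params
#' @export
fit_parameters <- function(dataset, bounds = fit_bounds(), fixed = NULL,
                           n_starts = 3) {
  stopifnot(inherits(dataset, "fl_dataset"), inherits(bounds, "fl_bounds"))
  par_names <- c("eta_c", "a_star_um", "alpha")
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% par_names))
      stop("`fixed` must be a named vector over eta_c, alpha, a_star_um",
           call. = FALSE)
    for (nm in names(fixed)) {
      iv <- bounds[[nm]]
      if (fixed[[nm]] < iv[1] || fixed[[nm]] > iv[2])
        stop(sprintf("fixed `%s` = %g lies outside its bounds [%g, %g]",
                     nm, fixed[[nm]], iv[1], iv[2]), call. = FALSE)
    }
  }
  free <- setdiff(par_names, names(fixed))
  if (length(free) == 0) stop("no free parameters to fit", call. = FALSE)

  full <- function(theta) {
    th <- as.list(c(theta, fixed))
    th[par_names]
  }
  resid_fun <- function(theta) {
    th <- full(theta)
    .residuals_raw(dataset, th$eta_c, th$alpha, th$a_star_um)
  }

  lower <- vapply(free, function(nm) bounds[[nm]][1], numeric(1))
  upper <- vapply(free, function(nm) bounds[[nm]][2], numeric(1))
  # deterministic interior multistart grid over the box
  fracs <- seq(0.5 / n_starts, 1 - 0.5 / n_starts, length.out = n_starts)
  grid <- as.matrix(expand.grid(lapply(seq_along(free), function(i)
    lower[i] + fracs * (upper[i] - lower[i]))))
  colnames(grid) <- free

  best <- NULL
  n_attempted <- nrow(grid)
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = grid[i, ], lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cand <- list(par = setNames(pmin(pmax(fit$par, lower), upper), free),
                 loss = sum(resid_fun(fit$par)^2),
                 converged = fit$info %in% 1:4)
    if (is.null(best) || cand$loss < best$loss - 1e-15 ||
        (abs(cand$loss - best$loss) <= 1e-15 &&
         .lex_less(full(cand$par), full(best$par)))) {
      best <- cand
    }
  }
  if (is.null(best) || !best$converged) {
    th <- if (is.null(best)) full(setNames((lower + upper) / 2, free))
          else full(best$par)
    return(structure(list(
      params = model_params(eta_c = th$eta_c, alpha = th$alpha,
                            a_star_um = th$a_star_um),
      loss = if (is.null(best)) NA_real_ else best$loss,
      residuals = rep(NA_real_, nrow(dataset)),
      converged = FALSE, n_starts = n_attempted,
      bounds_active = character(0)), class = "fl_fit"))
  }

  th <- full(best$par)
  params <- model_params(eta_c = th$eta_c, alpha = th$alpha,
                         a_star_um = th$a_star_um)
  res <- model_residuals(dataset, params)
  tol <- 1e-8
  active <- free[vapply(free, function(nm) {
    v <- best$par[[nm]]
    iv <- bounds[[nm]]
    (v - iv[1]) <= tol * max(1, abs(iv[1])) ||
      (iv[2] - v) <= tol * max(1, abs(iv[2]))
  }, logical(1))]
  structure(list(params = params, loss = sum(res^2), residuals = res,
                 converged = TRUE, n_starts = n_attempted,
                 bounds_active = active),
            class = "fl_fit")
}

.lex_less <- function(a, b) {
  for (nm in c("eta_c", "a_star_um", "alpha")) {
    if (a[[nm]] < b[[nm]] - 1e-12) return(TRUE)
    if (a[[nm]] > b[[nm]] + 1e-12) return(FALSE)
  }
  FALSE
}

#' @export
print.fl_fit <- function(x, ...) {
  cat("Core-annulus model fit\n")
  if (!x$converged) {
    cat("  DID NOT CONVERGE from any start\n")
    return(invisible(x))
  }
  cat(sprintf("  eta_c = %.6g, a_star_um = %.6g um, alpha = %.6g\n",
              x$params$eta_c, x$params$a_star_um, x$params$alpha))
  cat(sprintf("  loss (sum sq. rel. residuals) = %.6g over %d points\n",
              x$loss, length(x$residuals)))
  if (length(x$bounds_active))
    cat("  on bound:", paste(x$bounds_active, collapse = ", "), "\n")
  invisible(x)
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Repeats generate-then-fit over independent noisy replicates of a known
#' truth and summarizes per-parameter bias and root-mean-square error.
#' Deterministic given the seed: replicate `i` uses seed `seed + i`.
#'
#' @param truth A [model_params()] object, the data-generating parameters.
#' @param diameters Tube diameters (micrometres) of each synthetic dataset.
#' @param rel_noise_sd Relative noise standard deviation (see
#'   [generate_dataset()]).
#' @param n_replicates Number of independent datasets.
#' @param seed Integer base seed.
#' @param bounds A [fit_bounds()] object passed to [fit_parameters()].
#' @param fixed Optional fixed parameters passed to [fit_parameters()].
#' @return An object of class `fl_recovery`: a list with the `estimates`
#'   matrix (one row per replicate), per-parameter `bias` and `rmse`, the
#'   number of converged replicates `n_converged`, and the design fields.
#' @export
recovery_experiment <- function(truth, diameters, rel_noise_sd = 0.1,
                                n_replicates = 20, seed = 1,
                                bounds = fit_bounds(), fixed = NULL) {
  stopifnot(inherits(truth, "fl_params"), n_replicates >= 1)
  est <- matrix(NA_real_, nrow = n_replicates, ncol = 3,
                dimnames = list(NULL, c("eta_c", "a_star_um", "alpha")))
  for (i in seq_len(n_replicates)) {
    ds <- generate_dataset(truth, diameters, rel_noise_sd, seed = seed + i)
    fit <- fit_parameters(ds, bounds = bounds, fixed = fixed)
    if (fit$converged)
      est[i, ] <- c(fit$params$eta_c, fit$params$a_star_um, fit$params$alpha)
  }
  tru <- c(eta_c = truth$eta_c, a_star_um = truth$a_star_um,
           alpha = truth$alpha)
  ok <- stats::complete.cases(est)
  bias <- colMeans(est[ok, , drop = FALSE]) - tru
  rmse <- sqrt(colMeans((est[ok, , drop = FALSE] -
                           rep(tru, each = sum(ok)))^2))
  structure(list(estimates = est, bias = bias, rmse = rmse,
                 n_converged = sum(ok), truth = tru,
                 rel_noise_sd = rel_noise_sd, n_per_dataset = length(diameters),
                 seed = seed),
            class = "fl_recovery")
}

#' @export
print.fl_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d/%d replicates converged, noise sd %.3g, n = %d\n",
              x$n_converged, nrow(x$estimates), x$rel_noise_sd,
              x$n_per_dataset))
  print(round(rbind(truth = x$truth, bias = x$bias, rmse = x$rmse), 5))
  invisible(x)
}
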