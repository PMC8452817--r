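# Core-annulus two-fluid Poiseuille model: asymptotic core radius,
# velocity profile, apparent relative viscosity, marginal-layer thickness.
# Lengths are micrometres at the interface; the solver itself works with
# the radius-normalized dimensionless variables r, s0, s_inf in [0, 1].

#' Model parameter set for the core-annulus model
#'
#' Bundles the three model parameters: the core relative viscosity `eta_c`
#' (dimensionless, `> 1`; also the large-diameter "bulk" limit of the
#' apparent viscosity), the marginal viscosity fraction `alpha` in `[0, 1]`
#' (the annulus viscosity is `1 + alpha * (eta_c - 1)`; `alpha = 0` is the
#' Haynes cell-free-layer limit), and the red-blood-cell exclusion
#' half-thickness `a_star_um` (micrometres; cell centres cannot approach
#' the wall closer than this at the inlet, about half the RBC disk
#' thickness, 1--1.5 um for human blood).
#'
#' `eta_c` may instead be derived from a discharge hematocrit `phi` through
#' the Charm-Kurland correlation; the route taken is recorded in the
#' `eta_c_source` field.
#'
#' @param eta_c Core relative viscosity, `> 1`.  Exactly one of `eta_c` and
#'   `phi` must be given.
#' @param alpha Marginal viscosity fraction in `[0, 1]` (typically below
#'   0.15).
#' @param a_star_um RBC exclusion half-thickness in micrometres, `> 0`.
#' @param phi Optional discharge hematocrit; when given, `eta_c` is set to
#'   [charm_kurland_relative_viscosity()]`(phi)`.
#' @param eta_p_mPas Optional plasma viscosity scale in mPa s; when set,
#'   [predict_vessel()] also reports the dimensional apparent viscosity.
#' @return An object of class `fl_params`: a list with fields `eta_c`,
#'   `alpha`, `a_star_um`, `eta_p_mPas`, `eta_c_source`.
#' @examples
#' model_params(eta_c = 3.3, alpha = 0.1, a_star_um = 1.2)
#' model_params(phi = 0.45, alpha = 0.1, a_star_um = 1.2)  # eta_c = 2.05
#' @export
model_params <- function(eta_c = NULL, alpha, a_star_um, phi = NULL,
                         eta_p_mPas = NULL) {
  if (is.null(eta_c) == is.null(phi))
    stop("give exactly one of `eta_c` and `phi`", call. = FALSE)
  source <- "direct"
  if (!is.null(phi)) {
    eta_c <- charm_kurland_relative_viscosity(phi)
    source <- "phi"
  }
  stopifnot(length(eta_c) == 1, length(alpha) == 1, length(a_star_um) == 1)
  if (!is.finite(eta_c) || eta_c <= 1)
    stop("`eta_c` must be > 1 (the core is more viscous than plasma)",
         call. = FALSE)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (!is.finite(a_star_um) || a_star_um <= 0)
    stop("`a_star_um` must be a positive length in micrometres", call. = FALSE)
  if (!is.null(eta_p_mPas) && (!is.finite(eta_p_mPas) || eta_p_mPas <= 0))
    stop("`eta_p_mPas` must be positive when provided", call. = FALSE)
  structure(list(eta_c = eta_c, alpha = alpha, a_star_um = a_star_um,
                 eta_p_mPas = eta_p_mPas, eta_c_source = source),
            class = "fl_params")
}

#' @export
print.fl_params <- function(x, ...) {
  cat("Core-annulus model parameters\n")
  cat(sprintf("  eta_c     : %.6g  (%s)\n", x$eta_c,
              if (x$eta_c_source == "phi") "from hematocrit via Charm-Kurland"
              else "supplied directly"))
  cat(sprintf("  alpha     : %.6g\n", x$alpha))
  cat(sprintf("  a_star_um : %.6g um\n", x$a_star_um))
  if (!is.null(x$eta_p_mPas))
    cat(sprintf("  eta_p     : %.6g mPa s\n", x$eta_p_mPas))
  invisible(x)
}

#' Inlet core radius from size exclusion
#'
#' At the vessel entrance, finite cell size keeps red-blood-cell centres at
#' least `a_star_um` from the wall, so the cell-rich core starts at
#' dimensionless radius `s0 = 1 - 2 a_star_um / D_um`.
#'
#' @param D_um Vessel diameter in micrometres; must exceed `2 * a_star_um`.
#'   Vectorized.
#' @param a_star_um RBC exclusion half-thickness in micrometres.
#' @return Dimensionless inlet core radius `s0` in `(0, 1]`.
#' @export
inlet_core_radius <- function(D_um, a_star_um) {
  if (any(!is.finite(D_um)) || any(!is.finite(a_star_um)) || any(a_star_um < 0))
    stop("diameters and `a_star_um` must be finite, `a_star_um` >= 0",
         call. = FALSE)
  if (any(D_um <= 2 * a_star_um))
    stop("`D_um` must exceed 2 * a_star_um: continuum core-annulus geometry ",
         "is undefined for vessels narrower than the exclusion gap",
         call. = FALSE)
  1 - 2 * a_star_um / D_um
}

#' Annulus relative viscosity
#'
#' Viscosity of the cell-poor marginal layer, interpolated between plasma
#' (`1`) and core (`eta_c`) by the marginal viscosity fraction:
#' `eta_A = 1 + alpha * (eta_c - 1)`.
#'
#' @param eta_c Core relative viscosity, `> 1`.
#' @param alpha Marginal viscosity fraction in `[0, 1]`.
#' @return Annulus relative viscosity in `[1, eta_c]`.
#' @export
annulus_viscosity <- function(eta_c, alpha) {
  if (any(eta_c <= 1)) stop("`eta_c` must be > 1", call. = FALSE)
  if (any(alpha < 0) || any(alpha > 1))
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  1 + alpha * (eta_c - 1)
}

.check_core_inputs <- function(s0, eta_c, eta_A) {
  if (any(s0 <= 0) || any(s0 > 1))
    stop("`s0` must lie in (0, 1]", call. = FALSE)
  if (any(eta_A < 1) || any(eta_A > eta_c))
    stop("need 1 <= eta_A <= eta_c", call. = FALSE)
  invisible(NULL)
}

#' Asymptotic core radius (closed form)
#'
#' Axial migration in the entrance region thins the cell-rich core from its
#' inlet radius `s0` to the asymptotic value
#' \deqn{s_\infty = \frac{s_0}{\sqrt{1 + \sqrt{(1 - s_0^2)
#'   \big[1 - s_0^2 (1 - \eta_A/\eta_c)\big]}}},}
#' the unique physically admissible root of the quartic mass-conservation
#' equation solved numerically by [core_radius_numeric()].
#'
#' @param s0 Dimensionless inlet core radius in `(0, 1]`.
#' @param eta_c Core relative viscosity.
#' @param eta_A Annulus relative viscosity, `1 <= eta_A <= eta_c`.
#' @return `s_inf` in `(0, s0]`; equals `s0` only when `s0 = 1`.
#' @export
core_radius_closed_form <- function(s0, eta_c, eta_A) {
  .check_core_inputs(s0, eta_c, eta_A)
  s0 / sqrt(1 + sqrt((1 - s0^2) * (1 - s0^2 * (1 - eta_A / eta_c))))
}

#' Asymptotic core radius (bracketed bisection oracle)
#'
#' Solves the quartic mass-conservation equation
#' \deqn{s_0^2 = \frac{s_\infty^4 (1/\eta_c - 2/\eta_A) +
#'   2 s_\infty^2/\eta_A}{s_\infty^4 (1/\eta_c - 1/\eta_A) + 1/\eta_A}}
#' for \eqn{x = s_\infty^2 \in (0, 1)} by bracketed root search to absolute
#' tolerance `1e-14`.  Kept as an independent numerical check of (and
#' fallback for) [core_radius_closed_form()].
#'
#' @inheritParams core_radius_closed_form
#' @return `s_inf` in `(0, s0]`.
#' @export
core_radius_numeric <- function(s0, eta_c, eta_A) {
  .check_core_inputs(s0, eta_c, eta_A)
  solve1 <- function(s0, eta_c, eta_A) {
    if (s0 == 1) return(1)
    # residual of the quartic, cleared of its denominator (positive on (0,1))
    f <- function(x)
      s0^2 * (x^2 * (1 / eta_c - 1 / eta_A) + 1 / eta_A) -
        (x^2 * (1 / eta_c - 2 / eta_A) + 2 * x / eta_A)
    # f(0) = s0^2/eta_A > 0, f(1) = (s0^2 - 1)/eta_c < 0: bracket guaranteed
    root <- uniroot(f, lower = 0, upper = 1, tol = 1e-15,
                    f.lower = s0^2 / eta_A, f.upper = (s0^2 - 1) / eta_c)
    sqrt(root$root)
  }
  mapply(solve1, s0, eta_c, eta_A)
}

#' Asymptotic two-region axial velocity profile
#'
#' Dimensionless fully developed axial velocity of the core-annulus flow,
#' normalized to unit cross-sectional mean speed:
#' \deqn{v_\infty(r) = \frac{2}{s_\infty^4/\eta_c + (1 - s_\infty^4)/\eta_A}
#'   \times \begin{cases}
#'     (s_\infty^2 - r^2)/\eta_c + (1 - s_\infty^2)/\eta_A, & 0 \le r \le s_\infty,\\
#'     (1 - r^2)/\eta_A, & s_\infty \le r \le 1.
#'   \end{cases}}
#' The profile is continuous at the core interface, vanishes at the wall,
#' and satisfies the flux normalization \eqn{2\int_0^1 v\,r\,dr = 1} for any
#' `s_inf`; when `s_inf` solves the mass-conservation quartic, the core flux
#' \eqn{2\int_0^{s_\infty} v\,r\,dr} equals the inlet core area \eqn{s_0^2}.
#'
#' @inheritParams core_radius_closed_form
#' @param s_inf Dimensionless asymptotic core radius in `(0, 1)`.
#' @return An object of class `fl_velocity_profile`: a function of the
#'   dimensionless radius `r` in `[0, 1]` (evaluation outside is an error)
#'   with the knot `s_inf` and the viscosities attached as attributes.
#' @export
velocity_profile <- function(s_inf, eta_c, eta_A) {
  if (s_inf <= 0 || s_inf >= 1) stop("`s_inf` must lie in (0, 1)", call. = FALSE)
  if (eta_A < 1 || eta_A > eta_c) stop("need 1 <= eta_A <= eta_c", call. = FALSE)
  pre <- 2 / (s_inf^4 / eta_c + (1 - s_inf^4) / eta_A)
  f <- function(r) {
    if (any(r < 0) || any(r > 1))
      stop("velocity profile is defined on r in [0, 1]", call. = FALSE)
    core <- (s_inf^2 - r^2) / eta_c + (1 - s_inf^2) / eta_A
    annulus <- (1 - r^2) / eta_A
    pre * ifelse(r <= s_inf, core, annulus)
  }
  structure(f, class = c("fl_velocity_profile", "function"),
            s_inf = s_inf, eta_c = eta_c, eta_A = eta_A, prefactor = pre)
}

#' @export
print.fl_velocity_profile <- function(x, ...) {
  cat("Core-annulus velocity profile v(r), r in [0, 1]\n")
  cat(sprintf("  s_inf = %.6g, eta_c = %.6g, eta_A = %.6g\n",
              attr(x, "s_inf"), attr(x, "eta_c"), attr(x, "eta_A")))
  cat(sprintf("  centreline v(0) = %.6g, mean speed 1 (flux-normalized)\n",
              x(0)))
  invisible(x)
}

#' Apparent relative viscosity of the core-annulus flow
#'
#' Viscosity of the homogeneous Newtonian fluid that would carry the same
#' discharge under the same pressure gradient, relative to plasma:
#' \deqn{\eta_{app} = \left[s_\infty^4\left(\frac{1}{\eta_c} -
#'   \frac{1}{\eta_A}\right) + \frac{1}{\eta_A}\right]^{-1}.}
#' Interpolates between `eta_A` (no core) and `eta_c` (core filling the
#' vessel).
#'
#' @inheritParams velocity_profile
#' @param s_inf Dimensionless asymptotic core radius in `[0, 1]`.
#' @return Apparent relative viscosity in `[eta_A, eta_c]`.
#' @export
apparent_relative_viscosity <- function(s_inf, eta_c, eta_A) {
  if (any(s_inf < 0) || any(s_inf > 1))
    stop("`s_inf` must lie in [0, 1]", call. = FALSE)
  if (any(eta_A < 1) || any(eta_A > eta_c))
    stop("need 1 <= eta_A <= eta_c", call. = FALSE)
  1 / (s_inf^4 * (1 / eta_c - 1 / eta_A) + 1 / eta_A)
}

#' Apparent viscosity by direct two-fluid Poiseuille quadrature
#'
#' Independent verification path for [apparent_relative_viscosity()] that
#' never uses the closed-form discharge formula.  For a unit pressure
#' gradient the shear stress is \eqn{\tau(r) = r/2}; integrating
#' \eqn{dv/dr = -\tau/\eta(r)} with the piecewise-constant viscosity gives
#' the velocity by quadrature, a second quadrature gives the flux, and the
#' apparent viscosity is that of the homogeneous Poiseuille flow with the
#' same flux and gradient.
#'
#' @inheritParams velocity_profile
#' @param rel_tol Relative tolerance passed to the adaptive quadrature.
#' @return Apparent relative viscosity, dimensionless.
#' @export
apparent_viscosity_poiseuille_oracle <- function(s_inf, eta_c, eta_A,
                                                 rel_tol = 1e-11) {
  if (s_inf < 0 || s_inf > 1) stop("`s_inf` must lie in [0, 1]", call. = FALSE)
  if (eta_A < 1 || eta_A > eta_c) stop("need 1 <= eta_A <= eta_c", call. = FALSE)
  visc <- function(r) ifelse(r <= s_inf, eta_c, eta_A)
  # quadrature panels are split at the core interface: the integrands are
  # only piecewise smooth there
  quad <- function(f, a, b) {
    cuts <- sort(unique(c(a, min(max(s_inf, a), b), b)))
    sum(vapply(seq_len(length(cuts) - 1), function(k)
      if (cuts[k] == cuts[k + 1]) 0
      else integrate(f, cuts[k], cuts[k + 1], rel.tol = rel_tol,
                     subdivisions = 500L)$value, numeric(1)))
  }
  v <- function(r)  # no-slip at r = 1; dv/dr = -r / (2 eta(r))
    quad(function(rho) rho / (2 * visc(rho)), r, 1)
  flux <- quad(function(r) vapply(r, function(ri) ri * v(ri), numeric(1)),
               0, 1)
  # homogeneous flow with gradient 1 and viscosity eta has int r v dr = 1/(16 eta)
  1 / (16 * flux)
}

#' Per-vessel core-annulus prediction
#'
#' Composes the model chain for one vessel: inlet core radius from size
#' exclusion, annulus viscosity, asymptotic core radius (closed form),
#' apparent relative viscosity, and the asymptotic marginal-layer thickness
#' `(D_um / 2) * (1 - s_inf)`.
#'
#' The continuum description loses fidelity once the vessel is only a few
#' cell diameters wide; a warning (never an error) is emitted below
#' `continuum_warn_um`.
#'
#' @param D_um Vessel diameter in micrometres; must exceed
#'   `2 * params$a_star_um`.
#' @param params A [model_params()] object.
#' @param continuum_warn_um Diameter (micrometres) below which a
#'   continuum-validity warning is emitted; set to `0` to disable.
#' @return An object of class `fl_solution`: a one-row `data.frame` with
#'   columns `D_um`, `s0`, `s_inf`, `eta_A`, `eta_app`, `layer_thickness_um`
#'   and, when `params$eta_p_mPas` is set, `eta_app_mPas`.
#' @examples
#' p <- model_params(eta_c = 3.3, alpha = 0.1, a_star_um = 1.2)
#' predict_vessel(100, p)
#' @export
predict_vessel <- function(D_um, params, continuum_warn_um = 30) {
  stopifnot(inherits(params, "fl_params"), length(D_um) == 1)
  if (D_um < continuum_warn_um)
    warning(sprintf(paste0("D_um = %g um is below the continuum-validity ",
                           "threshold (%g um); treat predictions as ",
                           "extrapolation"), D_um, continuum_warn_um),
            call. = FALSE)
  s0 <- inlet_core_radius(D_um, params$a_star_um)
  eta_A <- annulus_viscosity(params$eta_c, params$alpha)
  s_inf <- core_radius_closed_form(s0, params$eta_c, eta_A)
  eta_app <- apparent_relative_viscosity(s_inf, params$eta_c, eta_A)
  out <- data.frame(D_um = D_um, s0 = s0, s_inf = s_inf, eta_A = eta_A,
                    eta_app = eta_app,
                    layer_thickness_um = (D_um / 2) * (1 - s_inf))
  if (!is.null(params$eta_p_mPas))
    out$eta_app_mPas <- eta_app * params$eta_p_mPas
  class(out) <- c("fl_solution", "data.frame")
  out
}

#' Apparent viscosity and layer thickness along a diameter grid
#'
#' Vectorized [predict_vessel()]: evaluates the model on a grid of vessel
#' diameters, preserving the input order.  For fixed parameters with
#' `alpha < 1` the apparent viscosity and the marginal-layer thickness are
#' both strictly increasing in the diameter.
#'
#' @param D_um Vector of vessel diameters in micrometres.
#' @inheritParams predict_vessel
#' @return An object of class `fl_curve`: a `data.frame` with columns
#'   `diameter_um`, `eta_app_rel`, `layer_thickness_um`.
#' @examples
#' p <- model_params(eta_c = 3.3, alpha = 0.1, a_star_um = 1.2)
#' viscosity_curve(c(50, 100, 500), p)
#' @export
viscosity_curve <- function(D_um, params, continuum_warn_um = 30) {
  stopifnot(inherits(params, "fl_params"))
  bad <- which(!is.finite(D_um) | D_um <= 2 * params$a_star_um)
  if (length(bad))
    stop(sprintf("invalid diameter at position %d (D_um = %g): must exceed 2 * a_star_um = %g um",
                 bad[1], D_um[bad[1]], 2 * params$a_star_um), call. = FALSE)
  if (any(D_um < continuum_warn_um))
    warning(sprintf(paste0("%d diameter(s) below the continuum-validity ",
                           "threshold (%g um)"),
                    sum(D_um < continuum_warn_um), continuum_warn_um),
            call. = FALSE)
  s0 <- inlet_core_radius(D_um, params$a_star_um)
  eta_A <- annulus_viscosity(params$eta_c, params$alpha)
  s_inf <- core_radius_closed_form(s0, params$eta_c, eta_A)
  out <- data.frame(diameter_um = D_um,
                    eta_app_rel = apparent_relative_viscosity(s_inf, params$eta_c, eta_A),
                    layer_thickness_um = (D_um / 2) * (1 - s_inf))
  class(out) <- c("fl_curve", "data.frame")
  out
}

#' @export
print.fl_solution <- function(x, ...) {
  cat("Core-annulus solution\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
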