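# Empirical viscosity laws: Charm-Kurland (hematocrit -> relative
# viscosity), Pries and Secomb (diameter + hematocrit -> apparent relative
# viscosity). Diameters are in micrometres throughout; no unit detection.

# Upper guard for the Charm-Kurland hematocrit domain.  The bracket
# 1 - phi * f(phi) crosses zero near phi ~ 0.78; 0.7 keeps a safety margin
# while admitting the largest hematocrit used in practice (~0.66).
.CK_PHI_MAX <- 0.7

.check_phi <- function(phi, upper = .CK_PHI_MAX) {
  if (!is.numeric(phi) || anyNA(phi))
    stop("hematocrit `phi` must be numeric and non-missing", call. = FALSE)
  if (any(phi < 0) || any(phi >= upper))
    stop(sprintf("hematocrit `phi` must lie in [0, %g)", upper), call. = FALSE)
  invisible(phi)
}

.check_diameter <- function(d, min = 0) {
  if (!is.numeric(d) || anyNA(d))
    stop("diameter `d_um` must be numeric and non-missing", call. = FALSE)
  if (any(d <= min))
    stop(sprintf("diameter `d_um` must exceed %g micrometres", min),
         call. = FALSE)
  invisible(d)
}

#' Charm-Kurland relative viscosity of blood
#'
#' Relative (plasma-normalized) viscosity of a well-mixed red-blood-cell
#' suspension as a function of discharge hematocrit,
#' \deqn{\eta_{CK}(\phi) = \left[1 - \phi\,0.07
#'   \exp\!\big(2.49\phi + \tfrac{1107}{310} e^{-1.69\phi}\big)\right]^{-1}.}
#' The constant 1107/310 is kept as an exact rational.  The correlation is
#' valid at high shear rates, where blood behaves as a Newtonian suspension;
#' the bracket turns non-positive (infinite viscosity) near
#' \eqn{\phi \approx 0.78}, so the domain is guarded at \eqn{[0, 0.7)}.
#'
#' @param phi Discharge hematocrit, a volume fraction in `[0, 0.7)`.
#'   Vectorized.
#' @return Relative viscosity, dimensionless, `>= 1`; `1` at `phi = 0`.
#' @examples
#' charm_kurland_relative_viscosity(c(0, 0.45))
#' @seealso [charm_kurland_inverse()] for the inverse map.
#' @export
charm_kurland_relative_viscosity <- function(phi) {
  .check_phi(phi)
  bracket <- 1 - phi * (0.07 * exp(2.49 * phi + (1107 / 310) * exp(-1.69 * phi)))
  if (any(bracket <= 0))
    stop("Charm-Kurland bracket non-positive: hematocrit too high", call. = FALSE)
  1 / bracket
}

#' Hematocrit from a Charm-Kurland relative viscosity
#'
#' Inverts [charm_kurland_relative_viscosity()] by bracketed root search.
#' The forward map is strictly increasing on its domain, so the root is
#' unique; it is located to absolute tolerance `1e-10`.
#'
#' @param eta Relative viscosity, `>= 1`, at most the value attained at the
#'   upper end of the hematocrit domain. Vectorized.
#' @return Hematocrit `phi` with `charm_kurland_relative_viscosity(phi) == eta`.
#' @examples
#' charm_kurland_inverse(2.05)
#' @export
charm_kurland_inverse <- function(eta) {
  if (!is.numeric(eta) || anyNA(eta))
    stop("`eta` must be numeric and non-missing", call. = FALSE)
  if (any(eta < 1))
    stop("relative viscosity `eta` must be >= 1", call. = FALSE)
  upper <- .CK_PHI_MAX - 1e-9
  eta_max <- charm_kurland_relative_viscosity(upper)
  if (any(eta > eta_max))
    stop(sprintf("`eta` exceeds the attainable Charm-Kurland range (max %.4f)",
                 eta_max), call. = FALSE)
  vapply(eta, function(e) {
    if (e == 1) return(0)
    uniroot(function(p) charm_kurland_relative_viscosity(p) - e,
            lower = 0, upper = upper, tol = 1e-12)$root
  }, numeric(1))
}

#' Pries reference viscosity at hematocrit 0.45
#'
#' In-vitro apparent relative viscosity of blood at discharge hematocrit
#' 0.45 as a function of tube diameter (micrometres):
#' \deqn{\eta_{0.45}^{(P)}(d) = 220 e^{-1.3 d} + 3.2 - 2.44 e^{-0.06 d^{0.645}}.}
#' Tends to the bulk value 3.2 as \eqn{d \to \infty}.
#'
#' @param d_um Tube diameter in micrometres, `> 0`. Vectorized.
#' @return Apparent relative viscosity, dimensionless.
#' @export
pries_reference_viscosity_45 <- function(d_um) {
  .check_diameter(d_um)
  220 * exp(-1.3 * d_um) + 3.2 - 2.44 * exp(-0.06 * d_um^0.645)
}

#' Pries shape exponent C(d)
#'
#' Diameter-dependent exponent controlling the hematocrit dependence of the
#' Pries and Secomb laws:
#' \deqn{C(d) = (0.8 + e^{-0.075 d})\left(\frac{1}{1 + 10^{-11} d^{12}} - 1\right)
#'   + \frac{1}{1 + 10^{-11} d^{12}}.}
#' Equals 1 in the small-diameter limit and tends to -0.8 for large vessels.
#'
#' @inheritParams pries_reference_viscosity_45
#' @return The exponent `C`, dimensionless.
#' @export
pries_shape_exponent <- function(d_um) {
  .check_diameter(d_um)
  t <- 1 / (1 + 1e-11 * d_um^12)
  (0.8 + exp(-0.075 * d_um)) * (t - 1) + t
}

# ((1-phi)^C - 1) / ((1-0.45)^C - 1), continuously extended at C = 0 by
# l'Hopital in the exponent: ratio -> log(1-phi)/log(0.55).
.hematocrit_ratio <- function(phi, C) {
  ifelse(abs(C) < 1e-12,
         log1p(-phi) / log(0.55),
         ((1 - phi)^C - 1) / (0.55^C - 1))
}

#' Pries apparent viscosity law
#'
#' In-vitro apparent relative viscosity of blood in a tube of diameter
#' `d_um` (micrometres) at discharge hematocrit `phi`:
#' \deqn{\eta^{(P)}(d,\phi) = 1 + (\eta_{0.45}^{(P)}(d) - 1)\,
#'   \frac{(1-\phi)^{C(d)} - 1}{(1-0.45)^{C(d)} - 1}.}
#' At `phi = 0.45` this reduces exactly to
#' [pries_reference_viscosity_45()]; the removable `C = 0` degeneracy is
#' resolved by continuous extension of the hematocrit ratio.
#'
#' @inheritParams pries_reference_viscosity_45
#' @param phi Discharge hematocrit in `[0, 1)`. Vectorized (recycled
#'   against `d_um`).
#' @return Apparent relative viscosity, dimensionless.
#' @export
pries_apparent_viscosity <- function(d_um, phi) {
  .check_diameter(d_um)
  .check_phi(phi, upper = 1)
  1 + (pries_reference_viscosity_45(d_um) - 1) *
    .hematocrit_ratio(phi, pries_shape_exponent(d_um))
}

#' Secomb reference viscosity at hematocrit 0.45
#'
#' \deqn{\eta_{0.45}^{(S)}(d) = 3.2 - 2.44 e^{-0.06 d^{0.645}} + 6 e^{-0.085 d}.}
#' Tends to 3.2 as \eqn{d \to \infty} and to 6.76 as \eqn{d \to 0^+}.
#'
#' @inheritParams pries_reference_viscosity_45
#' @return Apparent relative viscosity, dimensionless.
#' @export
secomb_reference_viscosity_45 <- function(d_um) {
  .check_diameter(d_um)
  3.2 - 2.44 * exp(-0.06 * d_um^0.645) + 6 * exp(-0.085 * d_um)
}

#' Secomb apparent viscosity law
#'
#' \deqn{\eta^{(S)}(d,\phi) = \frac{d^2}{(d-1.1)^2}\left(
#'   \frac{d^2\,(\eta_{0.45}^{(S)}(d) - 1)\,((1-\phi)^{C(d)} - 1)}
#'        {(d-1.1)^2\,(0.55^{C(d)} - 1)} + 1\right),}
#' with `C(d)` the [pries_shape_exponent()].  The squared factor accounts
#' for the effective lumen reduction by the near-wall exclusion; it is
#' singular at `d = 1.1`, so the law requires `d_um > 1.1`.
#'
#' @inheritParams pries_apparent_viscosity
#' @return Apparent relative viscosity, dimensionless.
#' @export
secomb_apparent_viscosity <- function(d_um, phi) {
  .check_diameter(d_um, min = 1.1)
  .check_phi(phi, upper = 1)
  C <- pries_shape_exponent(d_um)
  f <- d_um^2 / (d_um - 1.1)^2
  f * (f * (secomb_reference_viscosity_45(d_um) - 1) *
         .hematocrit_ratio(phi, C) + 1)
}

#' Evaluate an empirical viscosity law by name
#'
#' Dispatch helper used by the comparison CLI: evaluates one of the bundled
#' empirical laws, or this package's core-annulus model, on a diameter grid.
#'
#' @param law One of `"model"`, `"pries"`, `"secomb"`.
#' @param d_um Diameters in micrometres.
#' @param phi Discharge hematocrit (used directly by the empirical laws;
#'   routed through [charm_kurland_relative_viscosity()] to set `eta_c` for
#'   the model).
#' @param params A [model_params()] object for `law = "model"`; when `NULL`,
#'   `eta_c` is derived from `phi` and defaults `alpha = 0.1`,
#'   `a_star_um = 1.2` are used.
#' @return Numeric vector of apparent relative viscosities.
#' @export
empirical_law <- function(law = c("model", "pries", "secomb"), d_um, phi,
                          params = NULL) {
  law <- match.arg(law)
  switch(law,
    pries  = pries_apparent_viscosity(d_um, phi),
    secomb = secomb_apparent_viscosity(d_um, phi),
    model  = {
      if (is.null(params))
        params <- model_params(phi = phi, alpha = 0.1, a_star_um = 1.2)
      viscosity_curve(d_um, params, continuum_warn_um = 0)$eta_app_rel
    })
}
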