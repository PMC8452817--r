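# Synthetic viscosity-diameter series and packaged reference
# configurations.  In-vitro tube viscometry carries multiplicative
# experimental errors of roughly 10-20%, so the generator applies
# truncated-Gaussian relative noise to the exact model curve.

#' Generate a synthetic viscosity-diameter dataset
#'
#' `observed_i = eta_app(D_i; truth) * (1 + eps_i)` with
#' `eps_i ~ Normal(0, rel_noise_sd)` truncated at three standard
#' deviations (out-of-range draws are rejected and redrawn), which keeps
#' observations physical at realistic noise levels.  The same integer seed
#' always yields the bit-identical dataset; sampling uses R's default
#' Mersenne-Twister generator via [withr::with_seed()], so the global RNG
#' state is left untouched.
#'
#' @param truth A [model_params()] object, the data-generating parameters.
#' @param diameters Tube diameters in micrometres, all `> 2 * a_star_um`.
#' @param rel_noise_sd Relative noise standard deviation in `[0, 0.5]`;
#'   realistic tube-viscometry levels are 0.10--0.20.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @return A [viscosity_dataset()] whose label records the truth, noise
#'   level and seed.
#' @examples
#' p <- model_params(eta_c = 3.3, alpha = 0.1, a_star_um = 1.2)
#' generate_dataset(p, c(50, 100, 200), rel_noise_sd = 0.1, seed = 42)
#' @export
generate_dataset <- function(truth, diameters, rel_noise_sd = 0.1,
                             seed = NULL) {
  stopifnot(inherits(truth, "fl_params"))
  if (!is.numeric(rel_noise_sd) || rel_noise_sd < 0 || rel_noise_sd > 0.5)
    stop("`rel_noise_sd` must lie in [0, 0.5]", call. = FALSE)
  if (any(!is.finite(diameters)) || any(diameters <= 2 * truth$a_star_um))
    stop("all diameters must exceed 2 * a_star_um", call. = FALSE)
  curve <- viscosity_curve(diameters, truth, continuum_warn_um = 0)
  draw <- function() {
    eps <- rnorm(length(diameters), 0, rel_noise_sd)
    while (any(bad <- abs(eps) > 3 * rel_noise_sd))
      eps[bad] <- rnorm(sum(bad), 0, rel_noise_sd)
    eps
  }
  eps <- if (rel_noise_sd == 0) {
    numeric(length(diameters))
  } else if (is.null(seed)) {
    draw()
  } else {
    withr::with_seed(as.integer(seed), draw())
  }
  viscosity_dataset(diameters, curve$eta_app_rel * (1 + eps),
                    label = sprintf(
                      "synthetic: eta_c=%g a*=%g alpha=%g noise=%g seed=%s",
                      truth$eta_c, truth$a_star_um, truth$alpha,
                      rel_noise_sd, if (is.null(seed)) "NA" else seed))
}

#' Packaged reference configurations
#'
#' Machine-readable transcriptions of published reference configurations
#' bundled with the package as plain CSV under `inst/extdata/`:
#' \describe{
#'   \item{`table1_maeda`}{Marginal-layer thickness in 30 um tubes, human
#'     blood at hematocrit 0.08--0.45 (measurements by Maeda and
#'     co-workers), with the Charm-Kurland viscosity and the reported
#'     measured/theoretical thickness columns; model inputs `a* = 1.2` um,
#'     `alpha = 0.1`.}
#'   \item{`table2_kim`}{Marginal-layer thickness in 30--73 um tubes, rat
#'     blood at hematocrit 0.41--0.42 (measurements by Kim and
#'     co-workers); `a* = 0.8` um (rat RBCs are 25--30% smaller),
#'     `alpha = 0.1`.}
#'   \item{`table3_zilow`}{Fitted `(eta_c, a_star_um, alpha)` for adult and
#'     infant blood at hematocrit 0.2--0.6 (data of Zilow and
#'     Linderkamp).}
#'   \item{`fig2_config`}{The reference illustration configuration:
#'     `eta_c = 3.3`, `a* = 1.2` um, `alpha` in 0.05/0.10/0.15 over
#'     diameters 10--1000 um.}
#' }
#'
#' @param id One of `"table1_maeda"`, `"table2_kim"`, `"table3_zilow"`,
#'   `"fig2_config"`.
#' @return A `data.frame` of the transcribed values, with a `citation`
#'   attribute naming the original data source.
#' @examples
#' fl_fixture("table3_zilow")
#' @export
fl_fixture <- function(id = c("table1_maeda", "table2_kim", "table3_zilow",
                              "fig2_config")) {
  id <- match.arg(id)
  path <- system.file("extdata", paste0(id, ".csv"), package = "flvisc",
                      mustWork = TRUE)
  first <- readLines(path, n = 1)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(tab, "citation") <- sub("^#\\s*", "", first)
  tab
}
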