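#' Simulation parameter set
#'
#' Bundles the six varied parameters of the diversification model together
#' with the fixed constants. `model` selects how the per-step genetic
#' divergence increment between isolated population clusters is computed:
#' `"M0"` time-only (a constant rate drawn once per simulation from
#' U(0.01, 1)), `"M1"` temperature-dependent, `"M2"` body-size-dependent,
#' `"M3"` both.
#'
#' @param model one of "M0", "M1", "M2", "M3".
#' @param S divergence threshold at which isolated clusters become species
#'   (range 2--10).
#' @param lambda divergence-rate exponent for M1--M3 (range 2--5).
#' @param omega environmental-filter width of the Gaussian thermal
#'   suitability, in standardized temperature units (range 0.01--0.035).
#' @param sigma_B,sigma_T per-step Brownian rates of body-size and
#'   temperature-niche evolution (ranges 0.001--0.02 and 0.001--0.015).
#' @param phi Weibull dispersal scale in km (range 330--880).
#' @param psi Weibull dispersal shape (fixed 2.5).
#' @param Kc maximum carrying capacity per cell (fixed 30000 individuals).
#' @param mu_t extirpation population-size threshold (individuals).
#' @param mu_d extirpation decay rate.
#' @param g0 M0 per-step divergence increment; `NA` means draw once per
#'   simulation from U(0.01, 1).
#' @param m0_draw `"per_simulation"` (default) or `"per_step"`; how often the
#'   M0 uniform rate is redrawn.
#' @param contact_distance cluster-connectivity distance in km; default the
#'   dispersal-kernel mean `phi * gamma(1 + 1/psi)`.
#' @param merge_rule divergence bookkeeping when coalesced clusters merge:
#'   third-party divergence is the "mean" (default), "max" or "min" of the
#'   constituents' values.
#' @param boundary trait boundary handling, "reflect" (default) or "truncate".
#' @param seed integer RNG seed for the run.
#' @return an object of class `parameter_set`.
#' @export
parameter_set <- function(model = c("M0", "M1", "M2", "M3"),
                          S = 6, lambda = 3.5, omega = 0.02,
                          sigma_B = 0.01, sigma_T = 0.008,
                          phi = 600, psi = 2.5, Kc = 30000,
                          mu_t = 500, mu_d = 0.01,
                          g0 = NA_real_,
                          m0_draw = c("per_simulation", "per_step"),
                          contact_distance = NULL,
                          merge_rule = c("mean", "max", "min"),
                          boundary = c("reflect", "truncate"),
                          seed = 1L) {
  model <- match.arg(model)
  m0_draw <- match.arg(m0_draw)
  merge_rule <- match.arg(merge_rule)
  boundary <- match.arg(boundary)
  stopifnot(S > 0, lambda >= 1, omega > 0, sigma_B >= 0, sigma_T >= 0,
            phi > 0, psi > 0, Kc > 0, mu_d > 0, mu_t >= 0)
  if (is.null(contact_distance)) contact_distance <- phi * gamma(1 + 1 / psi)
  stopifnot(contact_distance > 0)
  structure(list(model = model, S = S, lambda = lambda, omega = omega,
                 sigma_B = sigma_B, sigma_T = sigma_T, phi = phi, psi = psi,
                 Kc = Kc, mu_t = mu_t, mu_d = mu_d, g0 = g0,
                 m0_draw = m0_draw, contact_distance = contact_distance,
                 merge_rule = merge_rule, boundary = boundary,
                 seed = as.integer(seed)),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(paste0("parameter_set %s: S=%.3g lambda=%.3g omega=%.4g ",
                     "sigma_B=%.4g sigma_T=%.4g phi=%.3g (psi=%.2g, Kc=%g)\n"),
              x$model, x$S, x$lambda, x$omega, x$sigma_B, x$sigma_T,
              x$phi, x$psi, x$Kc))
  invisible(x)
}
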