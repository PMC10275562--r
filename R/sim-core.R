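#' Site carrying capacity
#'
#' `K = Kc * exp(-A)`: capacity declines exponentially with the standardized
#' aridity index of the site, on the assumption that water availability
#' limits productivity and hence the number of individuals a cell supports.
#'
#' @param A_j standardized aridity in \[0, 1\] (vectorized).
#' @param Kc maximum carrying capacity at zero aridity.
#' @return carrying capacity in individuals.
#' @export
carrying_capacity <- function(A_j, Kc = 30000) {
  if (any(A_j < 0 | A_j > 1)) stop("aridity must lie in [0, 1]")
  Kc * exp(-A_j)
}

#' Thermal suitability abundance
#'
#' Gaussian environmental filtering: `N = K * exp(-((T_i - T_j)/omega)^2)`.
#' A population perfectly adapted to its site (`T_i == T_j`) attains the full
#' carrying capacity in the absence of competitors; smaller `omega` gives a
#' sharper decline away from the optimum.
#'
#' @param T_i population temperature optimum in \[0, 1\] (vectorized).
#' @param T_j site temperature in \[0, 1\].
#' @param omega filter width (> 0).
#' @param K site carrying capacity.
#' @return abundance in individuals.
#' @export
suitability_abundance <- function(T_i, T_j, omega, K) {
  if (any(omega <= 0)) stop("omega must be > 0")
  K * exp(-((T_i - T_j) / omega)^2)
}

#' Zero-sum reapportionment of site abundances
#'
#' When the summed abundance of all species in a site exceeds the site's
#' capacity, every population is scaled by `min(N_j, K)/N_j` so the total
#' equals `K` while relative proportions are preserved.
#'
#' @param N_vector per-species abundances in one site (>= 0).
#' @param K site carrying capacity.
#' @return adjusted abundances.
#' @export
reapportion <- function(N_vector, K) {
  if (any(N_vector < 0)) stop("negative abundances")
  Nj <- sum(N_vector)
  if (Nj == 0) return(N_vector)
  N_vector * min(Nj, K) / Nj
}

#' Stochastic extirpation probability
#'
#' Sigmoid in adjusted abundance: `p = 1/(1 + exp(-mu_d * (mu_t - N)))`.
#' Populations well above the threshold `mu_t` are near-immune; populations
#' below it are at risk, with `mu_d` setting how sharp the transition is.
#' A population with adjusted abundance exactly 0 is removed
#' deterministically before this draw is ever made.
#'
#' @param N_hat adjusted abundance (>= 0, vectorized).
#' @param mu_t population-size threshold.
#' @param mu_d decay rate (> 0).
#' @return extirpation probability in (0, 1).
#' @export
extirpation_probability <- function(N_hat, mu_t, mu_d) {
  stopifnot(mu_d > 0)
  if (any(N_hat < 0)) stop("negative abundance")
  stats::plogis(mu_d * (mu_t - N_hat))
}

#' Bounded Brownian trait evolution
#'
#' Adds an independent `Normal(0, sigma)` deviate to each value and maps the
#' result back into \[0, 1\] by reflection at the boundaries (default) or by
#' truncation. Reflection preserves the step-size distribution near the
#' bounds.
#'
#' @param values trait values in \[0, 1\].
#' @param sigma per-step standard deviation (>= 0).
#' @param boundary "reflect" or "truncate".
#' @return updated values in \[0, 1\].
#' @export
evolve_traits <- function(values, sigma, boundary = "reflect") {
  stopifnot(sigma >= 0)
  if (sigma == 0 || length(values) == 0L) return(values)
  x <- values + stats::rnorm(length(values), 0, sigma)
  if (boundary == "truncate") return(pmin(1, pmax(0, x)))
  reflect01(x)
}

# fold the real line into [0, 1] (period-2 triangular map)
reflect01 <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

#' Per-step divergence increment between two population clusters
#'
#' The rate at which two geographically isolated clusters of a species
#' accumulate genetic divergence, per time step:
#' \itemize{
#'   \item M0: a constant `g0` (time-only null);
#'   \item M1: `((Tbar_i + Tbar_k)/2)^lambda` -- faster in warmer ranges;
#'   \item M2: `(((1-Bbar_i) + (1-Bbar_k))/2)^lambda` -- faster for smaller
#'     bodies (faster life histories);
#'   \item M3: `((BT_i + BT_k)/2)^lambda` with `BT = ((1-Bbar) + Tbar)/2` per
#'     cluster -- both effects combined.
#' }
#' All inputs are standardized to \[0, 1\], so `g` is bounded by 1 per step.
#'
#' @param model "M0".."M3".
#' @param Tbar_i,Tbar_k mean standardized temperature across each cluster's
#'   occupied cells.
#' @param Bbar_i,Bbar_k mean standardized body size of each cluster.
#' @param lambda exponent (>= 1).
#' @param g0 the M0 constant.
#' @return divergence increment in \[0, 1\] (vectorized over pairs).
#' @export
divergence_increment <- function(model, Tbar_i, Tbar_k, Bbar_i, Bbar_k,
                                 lambda, g0 = NA_real_) {
  switch(model,
    M0 = rep_len(g0, max(length(Tbar_i), 1L)),
    M1 = ((Tbar_i + Tbar_k) / 2)^lambda,
    M2 = (((1 - Bbar_i) + (1 - Bbar_k)) / 2)^lambda,
    M3 = {
      bt_i <- ((1 - Bbar_i) + Tbar_i) / 2
      bt_k <- ((1 - Bbar_k) + Tbar_k) / 2
      ((bt_i + bt_k) / 2)^lambda
    },
    stop("unknown divergence model: ", model)
  )
}
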