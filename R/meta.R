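# Traditional correlative test: per-clade Spearman coefficients are
# Fisher-transformed to the z scale, pooled across clades with a
# random-effects model (REML tau^2 through metafor, DerSimonian-Laird as
# the fallback), and back-transformed for reporting.

#' Fisher z-transformation of a Spearman coefficient
#'
#' `z = atanh(rho)`, sampling variance `1/(n - 3)`, 95% CI
#' `z +/- 1.959964 sqrt(var)` (back-transformable with `tanh`).
#' Coefficients at exactly +/-1 are clipped to +/-(1 - 1e-6) with a
#' warning, since atanh diverges there.
#'
#' @param rho correlation in \[-1, 1\].
#' @param n number of paired observations (> 3).
#' @return list: z, var, ci95 (z scale), ci95_rho.
#' @export
fisher_transform <- function(rho, n) {
  if (n <= 3) stop("need n > 3 for the Fisher variance 1/(n-3)")
  if (abs(rho) > 1) stop("|rho| > 1")
  if (abs(rho) == 1) {
    warning("|rho| = 1 clipped to 1 - 1e-6 before transformation")
    rho <- sign(rho) * (1 - 1e-6)
  }
  z <- atanh(rho)
  v <- 1 / (n - 3)
  ci <- z + c(-1, 1) * 1.959964 * sqrt(v)
  list(z = z, var = v, ci95 = ci, ci95_rho = tanh(ci))
}

#' Random-effects pooling of per-clade effects
#'
#' Pools Fisher-z effects across clades with a random-effects model:
#' between-clade variance tau^2 by REML (convergence tolerance 1e-10, at
#' most 100 iterations), inverse-variance weights `1/(v_i + tau^2)`,
#' pooled effect `beta = sum(w z)/sum(w)`, `se = 1/sqrt(sum(w))`, two-sided
#' normal p-value. If REML fails to converge the DerSimonian-Laird
#' estimator is used with a warning. Pooling happens on the z scale; the
#' back-transformed `beta_rho = tanh(beta)` is reported alongside.
#'
#' @param records data.frame with columns rho and n (and optionally clade).
#' @param method "REML" (default) or "DL".
#' @return list: beta, beta_rho, se, z_stat, p_value, tau2, k.
#' @export
random_effects_pool <- function(records, method = c("REML", "DL")) {
  method <- match.arg(method)
  stopifnot(nrow(records) >= 2, all(records$n > 3))
  ft <- lapply(seq_len(nrow(records)),
               function(i) fisher_transform(records$rho[i], records$n[i]))
  yi <- vapply(ft, `[[`, numeric(1), "z")
  vi <- vapply(ft, `[[`, numeric(1), "var")
  fit <- tryCatch(
    metafor::rma(yi = yi, vi = vi, method = method,
                 control = list(threshold = 1e-10, maxiter = 100)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) && method == "REML") {
    warning("REML did not converge; falling back to DerSimonian-Laird")
    fit <- metafor::rma(yi = yi, vi = vi, method = "DL")
  }
  beta <- as.numeric(fit$beta)
  list(beta = beta, beta_rho = tanh(beta), se = fit$se,
       z_stat = as.numeric(fit$zval), p_value = as.numeric(fit$pval),
       tau2 = fit$tau2, k = length(yi))
}

#' Pooled key correlations across clade bundles
#'
#' For every bundle with more than `min_species` species, computes the four
#' key Spearman coefficients -- richness ~ |latitude| and
#' richness ~ temperature across occupied cells, DR ~ body size and
#' DR ~ temperature niche across species -- and pools each across clades
#' with [random_effects_pool()].
#'
#' @param bundles list of `clade_bundle`s.
#' @param min_species clade-size threshold (default 20, exclusive).
#' @param method tau^2 estimator passed through.
#' @return list with `records` (long data.frame: clade, statistic, rho, n)
#'   and `pooled` (data.frame: statistic, k, beta_z, beta_rho, se, Z, p,
#'   tau2).
#' @export
key_correlation_battery <- function(bundles, min_species = 20L,
                                    method = "REML") {
  recs <- list()
  for (ci in seq_along(bundles)) {
    b <- bundles[[ci]]
    if (ape::Ntip(b$tree) <= min_species) {
      message("clade ", ci, " excluded (<= ", min_species, " species)")
      next
    }
    ctemp <- stats::setNames(b$cells$temperature, b$cells$cell)
    clat <- stats::setNames(b$cells$latitude, b$cells$cell)
    occ_cells <- sort(unique(b$occupancy$cell))
    rich <- lengths(split(b$occupancy$species, b$occupancy$cell)[occ_cells])
    tm <- tip_metrics(b$tree)
    spt <- species_spatial_traits(b$occupancy, ctemp)
    tm <- tm[match(spt$species, tm$tip), ]
    bs <- b$body_size[spt$species]
    add <- function(stat, rho, n)
      recs[[length(recs) + 1L]] <<- data.frame(clade = ci, statistic = stat,
                                               rho = rho, n = n)
    add("richness_abslat", spearman(rich, abs(clat[occ_cells])), length(rich))
    add("richness_temperature", spearman(rich, ctemp[occ_cells]), length(rich))
    add("DR_bodysize", spearman(tm$DR, bs), nrow(spt))
    add("DR_temperature", spearman(tm$DR, spt$mean_range_temperature), nrow(spt))
  }
  if (!length(recs)) stop("no clade passed the species threshold")
  records <- do.call(rbind, recs)
  records <- records[is.finite(records$rho) & records$n > 3, ]
  pooled <- do.call(rbind, lapply(split(records, records$statistic), function(d) {
    if (nrow(d) < 2) return(NULL)
    p <- random_effects_pool(d, method = method)
    data.frame(statistic = d$statistic[1], k = p$k, beta_z = p$beta,
               beta_rho = p$beta_rho, se = p$se, Z = p$z_stat,
               p = p$p_value, tau2 = p$tau2)
  }))
  rownames(pooled) <- NULL
  list(records = records, pooled = pooled)
}
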