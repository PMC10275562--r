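# Quasi-random experiment design. The six-dimensional Sobol sequence is
# generated from the standard Joe-Kuo direction numbers with Gray-code
# ordering; generation starts at sequence index 1 (the index-0 point is the
# all-zeros corner), so every returned coordinate is strictly inside (0, 1).

# primitive polynomial degree s, coefficient a, initial direction numbers m
.joe_kuo <- list(
  list(s = 1, a = 0, m = c(1)),
  list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3))
)

#' Sobol low-discrepancy sequence
#'
#' @param n number of points.
#' @param d dimension (1..6 supported).
#' @return n x d matrix of points in (0, 1).
#' @export
sobol_points <- function(n, d) {
  stopifnot(n >= 1, d >= 1, d <= 6)
  nbits <- 30L
  scale <- 2^nbits
  V <- matrix(0L, nbits, d)
  V[, 1] <- as.integer(2^(nbits - seq_len(nbits)))   # van der Corput
  if (d > 1) for (j in 2:d) {
    p <- .joe_kuo[[j - 1L]]
    s <- p$s; m <- p$m
    for (k in seq_len(min(s, nbits)))
      V[k, j] <- as.integer(m[k] * 2^(nbits - k))
    if (nbits > s) for (k in (s + 1L):nbits) {
      vk <- bitwXor(V[k - s, j], bitwShiftR(V[k - s, j], s))
      if (s > 1) for (i in seq_len(s - 1L)) {
        if (bitwAnd(bitwShiftR(p$a, s - 1L - i), 1L) == 1L)
          vk <- bitwXor(vk, V[k - i, j])
      }
      V[k, j] <- vk
    }
  }
  x <- integer(d)
  out <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    # Gray-code step: flip direction c = lowest zero bit of (i - 1)
    cbit <- 1L
    ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); cbit <- cbit + 1L }
    x <- bitwXor(x, V[cbit, ])
    out[i, ] <- x / scale
  }
  out
}

#' Sobol-sampled simulation parameter sets
#'
#' Maps the first `n_samples` Sobol points (six dimensions) affinely into
#' the parameter ranges of the simulation campaign.
#'
#' @param n_samples number of parameter sets.
#' @param ranges named list of c(lo, hi) for S, lambda, omega, sigma_B,
#'   sigma_T, phi.
#' @param ... fixed arguments passed to every [parameter_set()] (e.g.
#'   mu_t, mu_d, contact_distance).
#' @return data.frame with param_id and the six columns.
#' @export
sobol_parameters <- function(n_samples,
                             ranges = list(S = c(2, 10), lambda = c(2, 5),
                                           omega = c(0.01, 0.035),
                                           sigma_B = c(0.001, 0.02),
                                           sigma_T = c(0.001, 0.015),
                                           phi = c(330, 880)),
                             ...) {
  need <- c("S", "lambda", "omega", "sigma_B", "sigma_T", "phi")
  stopifnot(n_samples >= 1, all(need %in% names(ranges)))
  u <- sobol_points(n_samples, 6)
  out <- data.frame(param_id = seq_len(n_samples))
  for (j in seq_along(need)) {
    r <- ranges[[need[j]]]
    out[[need[j]]] <- r[1] + u[, j] * (r[2] - r[1])
  }
  out
}

#' Stable per-run seed derivation
#'
#' A documented multiplicative hash (no language-default hashing):
#' `(base * 2654435 + param_id * 9973 + model_index * 7919) mod (2^31 - 1)`,
#' with 0 mapped to 1. Exact in double precision for base < 2^31.
#'
#' @param base_seed integer base seed.
#' @param param_id parameter-set id.
#' @param model model label "M0".."M3".
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(base_seed, param_id, model) {
  mi <- match(model, c("M0", "M1", "M2", "M3"))
  if (is.na(mi)) stop("unknown model label: ", model)
  h <- (as.numeric(base_seed) %% 2147483647) * 2654435 +
    as.numeric(param_id) * 9973 + mi * 7919
  h <- h %% 2147483647
  as.integer(if (h == 0) 1 else h)
}

#' Run a simulation ensemble over parameter sets x models
#'
#' Executes [run_simulation()] and [summarize_clade()] for every
#' (parameter set, model) combination, with per-run seeds from
#' [derive_seed()] (checked for collisions). When `out_dir` is given each
#' finished run is written as a one-row CSV and re-runs skip rows already
#' present, making long campaigns restartable.
#'
#' @param params data.frame from [sobol_parameters()].
#' @param models character subset of c("M0","M1","M2","M3").
#' @param landscape a `landscape_series` (one realization shared by the
#'   whole campaign).
#' @param base_seed campaign base seed.
#' @param richness_window completion window passed to [run_simulation()].
#' @param out_dir optional directory for restartable per-run rows.
#' @param ... fixed arguments forwarded to [parameter_set()].
#' @return data.frame (class `ensemble_table`): param_id, model, completed,
#'   reason, n_species, then one column per summary statistic (NA for
#'   incomplete runs).
#' @export
run_ensemble <- function(params, models = c("M0", "M1", "M2", "M3"),
                         landscape, base_seed = 1L,
                         richness_window = c(20, 6000), out_dir = NULL,
                         ...) {
  combos <- expand.grid(param_id = params$param_id, model = models,
                        stringsAsFactors = FALSE)
  seeds <- mapply(derive_seed, base_seed, combos$param_id, combos$model)
  if (anyDuplicated(seeds)) stop("derived seed collision in ensemble")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(combos))
  stat_names <- NULL
  for (i in seq_len(nrow(combos))) {
    pid <- combos$param_id[i]; mod <- combos$model[i]
    f <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("run_p%04d_%s.csv", pid, mod)) else NULL
    if (!is.null(f) && file.exists(f)) {
      rows[[i]] <- utils::read.csv(f, check.names = FALSE)
      next
    }
    pr <- params[params$param_id == pid, ]
    ps <- parameter_set(model = mod, S = pr$S, lambda = pr$lambda,
                        omega = pr$omega, sigma_B = pr$sigma_B,
                        sigma_T = pr$sigma_T, phi = pr$phi,
                        seed = seeds[i], ...)
    res <- run_simulation(ps, landscape, richness_window = richness_window)
    row <- data.frame(param_id = pid, model = mod,
                      completed = res$completed, reason = res$reason,
                      n_species = length(res$species))
    if (res$completed) {
      b <- bundle_from_result(res)
      if (!is.null(b)) {
        sv <- summarize_clade(b)
        row <- cbind(row, as.data.frame(as.list(sv), check.names = FALSE))
      } else {
        row$completed <- FALSE; row$reason <- "no tree"
      }
    }
    rows[[i]] <- row
    if (!is.null(f)) utils::write.csv(row, f, row.names = FALSE)
    if (is.null(stat_names) && ncol(row) > 5) stat_names <- names(row)[-(1:5)]
  }
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    miss <- setdiff(all_names, names(r))
    for (m in miss) r[[m]] <- NA
    r[all_names]
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ensemble_table", class(out))
  out
}

#' Keep only parameter sets complete under every model
#'
#' The classifier compares models on equal footing: a parameter set whose
#' run failed under any model is excluded entirely, so class counts are
#' equal afterwards. Invariant to input row order.
#'
#' @param table an `ensemble_table`.
#' @param models the model labels that must all be complete.
#' @return the filtered table (complete rows only), sorted by
#'   (param_id, model).
#' @export
completeness_filter <- function(table, models = c("M0", "M1", "M2", "M3")) {
  stopifnot(nrow(table) > 0)
  tab <- table[table$model %in% models & table$completed, , drop = FALSE]
  cnt <- table(tab$param_id)
  good <- names(cnt)[cnt == length(models)]
  out <- tab[as.character(tab$param_id) %in% good, , drop = FALSE]
  out <- out[order(out$param_id, out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}
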