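# One eco-evolutionary time step, applied in a fixed documented order:
# (1) bounded Brownian trait evolution, (2) Weibull dispersal,
# (3) contact clustering, (4) divergence accrual / coalescence,
# (5) speciation at threshold S, (6) abundance via suitability, capacity and
# zero-sum reapportionment, (7) deterministic + stochastic extirpation,
# (8) extinction cleanup and logging.

#' Accrue or coalesce pairwise divergence after (re)clustering
#'
#' Old clusters spanning several spatial components are split (fragments
#' start at divergence 0 from each other and inherit the parent's divergence
#' to third clusters). Cluster pairs now sharing a component are in secondary
#' contact: their divergence drops by 1 per step, floored at 0, and pairs
#' reaching 0 merge (third-party divergence combined by `merge_rule`). Pairs
#' in different components accrue the model-specific increment `g`.
#'
#' @param sp species state (`sites`, `topt`, `bsize`, `clus`, `D`,
#'   `next_cl`).
#' @param comp integer spatial component per site (from
#'   [cluster_populations()]).
#' @param temp_site standardized temperature at each occupied site.
#' @param params a [parameter_set()].
#' @param g0 the M0 constant for this simulation/step.
#' @return updated species state.
#' @export
update_divergence <- function(sp, comp, temp_site, params, g0 = NA_real_) {
  lab <- sp$clus
  D <- sp$D
  # --- split old clusters that now span several components
  for (L in unique(lab)) {
    in_L <- lab == L
    comps <- sort(unique(comp[in_L]))
    if (length(comps) <= 1L) next
    Lc <- as.character(L)
    for (cc in comps[-1L]) {
      newid <- sp$next_cl; sp$next_cl <- sp$next_cl + 1L
      lab[in_L & comp == cc] <- newid
      nc <- as.character(newid)
      D <- rbind(cbind(D, D[, Lc, drop = FALSE]), 0)
      rownames(D)[nrow(D)] <- nc; colnames(D)[ncol(D)] <- nc
      D[nc, ] <- D[, nc] <- D[Lc, ]
      D[nc, Lc] <- D[Lc, nc] <- 0
      D[nc, nc] <- 0
    }
  }
  ids <- sort(unique(lab))
  k <- length(ids)
  if (k >= 2L) {
    key <- as.character(ids)
    D <- D[key, key, drop = FALSE]
    cl_comp <- vapply(ids, function(L) comp[match(TRUE, lab == L)], integer(1))
    Tbar <- vapply(ids, function(L) mean(temp_site[lab == L]), numeric(1))
    Bbar <- vapply(ids, function(L) mean(sp$bsize[lab == L]), numeric(1))
    merge_a <- integer(0); merge_b <- integer(0)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (cl_comp[i] == cl_comp[j]) {
        D[i, j] <- D[j, i] <- max(0, D[i, j] - 1)
        if (D[i, j] == 0) { merge_a <- c(merge_a, i); merge_b <- c(merge_b, j) }
      } else {
        g <- divergence_increment(params$model, Tbar[i], Tbar[j],
                                  Bbar[i], Bbar[j], params$lambda, g0)
        D[i, j] <- D[j, i] <- D[i, j] + g
      }
    }
    if (length(merge_a)) {
      grp <- seq_len(k)
      for (e in seq_along(merge_a)) {
        ga <- grp[merge_a[e]]; gb <- grp[merge_b[e]]
        if (ga != gb) grp[grp == gb] <- ga
      }
      gids <- unique(grp)
      newD <- matrix(0, length(gids), length(gids))
      newids <- vapply(gids, function(g) min(ids[grp == g]), integer(1))
      for (a in seq_along(gids)) for (b in seq_along(gids)) {
        if (a == b) next
        block <- D[grp == gids[a], grp == gids[b], drop = FALSE]
        newD[a, b] <- mean_or(block, params$merge_rule)
      }
      dimnames(newD) <- list(as.character(newids), as.character(newids))
      relab <- newids[match(grp, gids)]
      lab <- relab[match(lab, ids)]
      D <- newD
      ids <- sort(newids)
      D <- D[as.character(ids), as.character(ids), drop = FALSE]
    }
  } else {
    D <- matrix(0, 1, 1, dimnames = list(as.character(ids), as.character(ids)))
  }
  sp$clus <- lab
  sp$D <- D
  sp
}

mean_or <- function(block, rule) {
  switch(rule, mean = mean(block), max = max(block), min = min(block))
}

#' Split a species at the divergence threshold
#'
#' Builds the graph over the species' clusters with an edge wherever the
#' accumulated divergence is below `S`; each connected component becomes one
#' species. The component with the largest occupied-cell count (ties: the
#' one containing the lowest cluster label) keeps the parent identity;
#' the others become children. Divergence sub-matrices are carried over.
#'
#' @param sp species state.
#' @param S divergence threshold (> 0).
#' @return list of species states (length 1 when no split occurs); children
#'   carry `id = NA`, to be assigned by the caller.
#' @export
speciate <- function(sp, S) {
  ids <- as.integer(rownames(sp$D))
  k <- length(ids)
  if (k <= 1L) return(list(sp))
  adj <- sp$D < S
  grp <- seq_len(k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (adj[i, j]) {
      gi <- grp[i]; gj <- grp[j]
      if (gi != gj) grp[grp == gj] <- gi
    }
  }
  gids <- unique(grp)
  if (length(gids) == 1L) return(list(sp))
  sizes <- vapply(gids, function(g)
    sum(sp$clus %in% ids[grp == g]), integer(1))
  minlab <- vapply(gids, function(g) min(ids[grp == g]), integer(1))
  parent_g <- gids[order(-sizes, minlab)][1L]
  out <- vector("list", length(gids))
  ord <- c(parent_g, setdiff(gids, parent_g))
  for (n in seq_along(ord)) {
    g <- ord[n]
    members <- ids[grp == g]
    in_g <- sp$clus %in% members
    key <- as.character(sort(members))
    out[[n]] <- list(id = if (n == 1L) sp$id else NA_integer_,
                     sites = sp$sites[in_g],
                     topt = sp$topt[in_g], bsize = sp$bsize[in_g],
                     clus = sp$clus[in_g],
                     D = sp$D[key, key, drop = FALSE],
                     next_cl = sp$next_cl)
  }
  out
}

#' Advance the world by one time step
#'
#' Applies the eight phases in their fixed order (see the file header) to
#' every species, in increasing species-id order, drawing all randomness
#' from the current R RNG stream so runs are reproducible from the seed.
#'
#' @param world simulation world state (see [run_simulation()]).
#' @param land landscape layers for this step: list with `temp`, `arid`,
#'   `hab` matrices.
#' @param t current time (steps from the start).
#' @return updated world.
#' @export
sim_step <- function(world, land, t) {
  p <- world$params
  nr <- world$n_rows
  if (length(world$species) == 0L) return(world)
  if (p$model == "M0" && p$m0_draw == "per_step")
    world$g0 <- stats::runif(1, 0.01, 1)

  for (i in seq_along(world$species)) {
    sp <- world$species[[i]]
    # (1) trait evolution; the evolving unit is the population cluster:
    # gene flow homogenizes traits within a cluster, so members share the
    # cluster mean and each cluster receives one Brownian kick per step
    uc <- sort(unique(sp$clus))
    pos <- match(sp$clus, uc)
    cnt <- tabulate(pos, length(uc))
    tmean <- as.numeric(rowsum(sp$topt, pos)) / cnt
    bmean <- as.numeric(rowsum(sp$bsize, pos)) / cnt
    sp$topt <- evolve_traits(tmean, p$sigma_T, p$boundary)[pos]
    sp$bsize <- evolve_traits(bmean, p$sigma_B, p$boundary)[pos]
    # (2) dispersal
    sp <- disperse(sp, land$hab, nr, world$cell_size_km, p$phi, p$psi)
    # (3) clustering + (4) divergence; the contact distance is floored at
    # the diagonal neighbor distance -- populations in adjacent cells are
    # always in contact at the grid resolution
    d_c <- max(p$contact_distance, sqrt(2) * world$cell_size_km + 1e-9)
    comp <- cluster_populations(sp$sites, nr, world$cell_size_km, d_c)
    sp <- update_divergence(sp, comp, land$temp[sp$sites], p, world$g0)
    world$species[[i]] <- sp
  }

  # (5) speciation
  newsp <- list()
  for (i in seq_along(world$species)) {
    parts <- speciate(world$species[[i]], p$S)
    world$species[[i]] <- parts[[1L]]
    for (ch in parts[-1L]) {
      ch$id <- world$next_sp
      world$next_sp <- world$next_sp + 1L
      world$events <- log_event(world$events, t, "speciation", ch$id,
                                parts[[1L]]$id)
      newsp[[length(newsp) + 1L]] <- ch
    }
  }
  world$species <- c(world$species, newsp)

  # (6) abundance: suitability x capacity, zero-sum reapportionment per site
  n_per <- vapply(world$species, function(s) length(s$sites), integer(1))
  all_sites <- unlist(lapply(world$species, `[[`, "sites"), use.names = FALSE)
  all_topt <- unlist(lapply(world$species, `[[`, "topt"), use.names = FALSE)
  spi <- rep(seq_along(world$species), n_per)
  K_site <- carrying_capacity(land$arid[all_sites], p$Kc)
  N <- suitability_abundance(all_topt, land$temp[all_sites], p$omega, K_site)
  N[!land$hab[all_sites]] <- 0
  u <- sort(unique(all_sites))
  grp <- match(all_sites, u)
  tot <- rowsum(N, grp)[grp]
  scale <- ifelse(tot > 0, pmin(tot, K_site) / tot, 0)
  Nhat <- N * scale

  # (7) extirpation
  pr <- extirpation_probability(Nhat, p$mu_t, p$mu_d)
  dead <- Nhat == 0 | stats::runif(length(Nhat)) < pr

  # (8) apply removals, drop empty clusters, log extinctions
  survivors <- list()
  for (i in seq_along(world$species)) {
    sp <- world$species[[i]]
    keep <- !dead[spi == i]
    if (!any(keep)) {
      world$events <- log_event(world$events, t, "extinction", sp$id)
      next
    }
    sp$sites <- sp$sites[keep]; sp$topt <- sp$topt[keep]
    sp$bsize <- sp$bsize[keep]; sp$clus <- sp$clus[keep]
    live <- as.character(sort(unique(sp$clus)))
    if (length(live) < nrow(sp$D)) sp$D <- sp$D[live, live, drop = FALSE]
    survivors[[length(survivors) + 1L]] <- sp
  }
  world$species <- survivors
  world
}

#' Run a full eco-evolutionary simulation
#'
#' Iterates [sim_step()] over every landscape step, starting from a single
#' ancestral species. The run is flagged complete iff it reaches the final
#' step with an extant richness inside `richness_window`; global extinction
#' or exceeding the window's upper bound stop the run early with an
#' incomplete flag (never an error). Fully reproducible from
#' `params$seed` and the landscape.
#'
#' @param params a [parameter_set()].
#' @param landscape a `landscape_series`.
#' @param init list: `cell` (index; default the warmest habitable cell at
#'   step 1), `topt` (default that cell's temperature), `B` (default 0.2, a small-bodied founder).
#' @param richness_window completion window for final extant richness
#'   (default c(20, 6000)).
#' @return an object of class `simulation_result`: `events`, `species`
#'   (final states), `richness_by_cell`, `per_species` table, `params`,
#'   `completed`, `reason`, `final_time`, `n_rows`, `n_cols`,
#'   `latitude_deg`, `temperature_final`.
#' @export
run_simulation <- function(params, landscape, init = list(),
                           richness_window = c(20, 6000)) {
  stopifnot(inherits(params, "parameter_set"),
            inherits(landscape, "landscape_series"))
  set.seed(params$seed)
  ns <- dim(landscape$temperature01)[1]
  nr <- dim(landscape$temperature01)[2]
  nc <- dim(landscape$temperature01)[3]

  g0 <- params$g0
  if (params$model == "M0" && is.na(g0) && params$m0_draw == "per_simulation")
    g0 <- stats::runif(1, 0.01, 1)

  t1 <- landscape$temperature01[1, , ]
  h1 <- landscape$habitable[1, , ]
  cell <- init$cell
  if (is.null(cell)) {
    # the ancestor is an established species, not a single propagule: it
    # seeds the warm band of the largest landmass (up to 20 cells closest
    # to the 0.8 temperature quantile -- not the absolute maximum, which is
    # the first climate to disappear as the world cools). A one-cell start
    # makes early survival a pure lottery against the trait random walk.
    land_cells <- which(h1)
    comp <- cluster_populations(land_cells, nr, landscape$cell_size_km,
                                1.5 * landscape$cell_size_km)
    main <- land_cells[comp == which.max(tabulate(comp))]
    target <- stats::quantile(t1[main], 0.8, na.rm = TRUE)
    cell <- main[order(abs(t1[main] - target))]
    cell <- cell[seq_len(min(20L, length(cell)))]
    cell <- cell[abs(t1[cell] - target) <= 0.03]
  }
  topt0 <- if (!is.null(init$topt)) init$topt else t1[cell]
  # small-bodied ancestor: radiations typically start from fast-life-history
  # founders, and a mid-scale start would make body-size-dependent
  # divergence unobservably slow on short landscapes
  B0 <- if (!is.null(init$B)) init$B else 0.2
  cell <- as.integer(cell)

  world <- list(
    species = list(list(id = 1L, sites = cell,
                        topt = rep_len(topt0, length(cell)),
                        bsize = rep_len(B0, length(cell)),
                        clus = rep_len(1L, length(cell)),
                        D = matrix(0, 1, 1, dimnames = list("1", "1")),
                        next_cl = 2L)),
    next_sp = 2L, events = empty_log(), params = params, g0 = g0,
    n_rows = nr, cell_size_km = landscape$cell_size_km
  )

  completed <- TRUE; reason <- "complete"; t_end <- ns
  for (s in seq_len(ns)) {
    land <- list(temp = landscape$temperature01[s, , ],
                 arid = landscape$aridity01[s, , ],
                 hab = landscape$habitable[s, , ])
    world <- sim_step(world, land, s)
    rich <- length(world$species)
    if (rich == 0L) {
      completed <- FALSE; reason <- "extinct"; t_end <- s; break
    }
    if (rich > richness_window[2]) {
      completed <- FALSE
      reason <- sprintf("above maximum of %d", richness_window[2])
      t_end <- s; break
    }
  }
  world$events <- finalize_log(world$events)
  rich <- length(world$species)
  if (completed && rich < richness_window[1]) {
    completed <- FALSE
    reason <- sprintf("below minimum of %d", richness_window[1])
  }

  tf <- landscape$temperature01[min(t_end, ns), , ]
  richness <- matrix(0L, nr, nc)
  per <- data.frame(species_id = integer(0), range_size_cells = integer(0),
                    mean_range_temperature = numeric(0),
                    mean_body_size = numeric(0))
  for (sp in world$species) {
    richness[sp$sites] <- richness[sp$sites] + 1L
    per <- rbind(per, data.frame(
      species_id = sp$id, range_size_cells = length(sp$sites),
      mean_range_temperature = mean(tf[sp$sites]),
      mean_body_size = mean(sp$bsize)))
  }
  structure(list(events = world$events, species = world$species,
                 richness_by_cell = richness, per_species = per,
                 params = params, g0 = g0, completed = completed,
                 reason = reason, final_time = t_end,
                 n_rows = nr, n_cols = nc,
                 latitude_deg = landscape$latitude_deg,
                 temperature_final = tf),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result [%s]: %d extant species, %d events, %s\n",
              x$params$model, length(x$species), nrow(x$events),
              if (x$completed) "complete" else paste0("incomplete (", x$reason, ")")))
  invisible(x)
}

#' Extant (or full) tree of a simulation result
#'
#' @param result a `simulation_result`.
#' @param drop_extinct keep only extant tips (default TRUE).
#' @return `phylo` or `NULL` (fewer than two tips).
#' @export
result_tree <- function(result, drop_extinct = TRUE) {
  phylo_from_log(result$events, result$final_time, drop_extinct)
}
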