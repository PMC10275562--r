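# Grid geometry: cells are indexed like R matrix entries (row-major position
# idx = row + (col - 1) * n_rows); centroids sit on a planar equal-area grid
# with spacing cell_size_km. Distances are planar Euclidean, no wraparound.

cell_rc <- function(idx, n_rows) {
  cbind(row = (idx - 1L) %% n_rows + 1L, col = (idx - 1L) %/% n_rows + 1L)
}

# offsets (dr, dc, dist_km) with 0 < dist <= radius_km, cached per geometry
.offset_cache <- new.env(parent = emptyenv())

radius_offsets <- function(radius_km, cell_size_km) {
  key <- sprintf("%.6g_%.6g", radius_km, cell_size_km)
  hit <- get0(key, envir = .offset_cache)
  if (!is.null(hit)) return(hit)
  m <- floor(radius_km / cell_size_km)
  dr <- rep(-m:m, times = 2 * m + 1)
  dc <- rep(-m:m, each = 2 * m + 1)
  d <- cell_size_km * sqrt(dr^2 + dc^2)
  keep <- d <= radius_km & d > 0
  out <- list(dr = dr[keep], dc = dc[keep], dist = d[keep])
  assign(key, out, envir = .offset_cache)
  out
}

#' Partition occupied sites into contact clusters
#'
#' Population clusters are the connected components of the graph on a
#' species' occupied cells, with an edge between two cells whenever their
#' planar centroid distance is at most `contact_distance`. Components are
#' numbered deterministically in order of their smallest member cell index.
#'
#' @param sites integer cell indices (any order; duplicates not allowed).
#' @param n_rows grid rows.
#' @param cell_size_km cell edge length in km.
#' @param contact_distance connectivity distance in km (> 0).
#' @return integer component label per site (parallel to `sites`).
#' @export
cluster_populations <- function(sites, n_rows, cell_size_km, contact_distance) {
  stopifnot(contact_distance > 0)
  n <- length(sites)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  max_col <- max((sites - 1L) %/% n_rows) + 1L
  off <- radius_offsets(contact_distance, cell_size_km)
  cpp_components(as.integer(sites), as.integer(n_rows), as.integer(max_col),
                 as.integer(off$dr), as.integer(off$dc))
}

#' Weibull dispersal into unoccupied habitable cells
#'
#' For every candidate target cell (habitable, not yet occupied by the
#' species, and within the capped search radius -- the 0.999 quantile of the
#' dispersal kernel), a dispersal distance is drawn from
#' `Weibull(shape = psi, scale = phi)`; the cell is colonized iff the draw is
#' at least the planar distance to the species' nearest occupied cell.
#' Founders inherit the traits and current cluster label of that nearest
#' source population.
#'
#' @param sp species state: list with `sites`, `topt`, `bsize`, `clus`.
#' @param habitable logical matrix (rows x cols) for the current step.
#' @param n_rows,cell_size_km grid geometry.
#' @param phi,psi Weibull scale (km) and shape.
#' @return the species state with colonized cells appended (sites sorted).
#' @export
disperse <- function(sp, habitable, n_rows, cell_size_km, phi, psi) {
  if (length(sp$sites) == 0L) return(sp)
  r_cap <- phi * log(1000)^(1 / psi)   # 0.999 kernel quantile
  off <- radius_offsets(r_cap, cell_size_km)
  n_cols <- length(habitable) %/% n_rows
  ncell <- n_rows * n_cols
  ns <- cpp_nearest_source(as.integer(sp$sites), as.integer(n_rows),
                           as.integer(n_cols), as.integer(off$dr),
                           as.integer(off$dc), off$dist)
  dmin <- ns$dmin
  src <- ns$src
  dmin[sp$sites] <- Inf                      # cannot colonize itself
  cand <- which(is.finite(dmin) & as.vector(habitable))
  if (length(cand) == 0L) return(sp)
  draw <- stats::rweibull(length(cand), shape = psi, scale = phi)
  win <- draw >= dmin[cand]
  if (!any(win)) return(sp)
  new_sites <- cand[win]
  s_idx <- src[new_sites]
  ord <- order(c(sp$sites, new_sites))
  sp$sites <- c(sp$sites, new_sites)[ord]
  sp$topt <- c(sp$topt, sp$topt[s_idx])[ord]
  sp$bsize <- c(sp$bsize, sp$bsize[s_idx])[ord]
  sp$clus <- c(sp$clus, sp$clus[s_idx])[ord]
  sp
}
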