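#' Clade bundle: tree + ranges + traits + cell environment
#'
#' The unit of analysis for the summary-statistic suite: a rooted phylogeny
#' with branch lengths, a species-by-cell occupancy table, per-species body
#' size, and per-cell temperature and latitude. Species not shared by the
#' tree, the occupancy table and the trait table are pruned (with a
#' message).
#'
#' @param tree `phylo`.
#' @param occupancy data.frame with columns species, cell.
#' @param body_size named numeric (names = species).
#' @param cells data.frame with columns cell, temperature, latitude.
#' @return object of class `clade_bundle`.
#' @export
clade_bundle <- function(tree, occupancy, body_size, cells) {
  stopifnot(inherits(tree, "phylo"),
            all(c("species", "cell") %in% names(occupancy)),
            all(c("cell", "temperature", "latitude") %in% names(cells)))
  occupancy$species <- as.character(occupancy$species)
  occupancy$cell <- as.character(occupancy$cell)
  cells$cell <- as.character(cells$cell)
  common <- Reduce(intersect, list(tree$tip.label, unique(occupancy$species),
                                   names(body_size)))
  dropped <- setdiff(unique(c(tree$tip.label, occupancy$species,
                              names(body_size))), common)
  if (length(dropped))
    message("clade_bundle: pruning ", length(dropped),
            " species without matching tree/range/trait data")
  if (length(common) < 2L) stop("fewer than 2 species with complete data")
  if (length(setdiff(tree$tip.label, common)))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, common))
  structure(list(tree = tree,
                 occupancy = occupancy[occupancy$species %in% common, ],
                 body_size = body_size[common],
                 cells = cells),
            class = "clade_bundle")
}

#' @export
print.clade_bundle <- function(x, ...) {
  cat(sprintf("clade_bundle: %d species, %d cells, %d occupancy records\n",
              ape::Ntip(x$tree), nrow(x$cells), nrow(x$occupancy)))
  invisible(x)
}

#' Build a clade bundle from a simulation result
#'
#' Uses the extant tree, final occupancy, per-species mean body size, and
#' the final-step temperature field. Returns `NULL` when fewer than two
#' extant species exist (no tree).
#'
#' @param result a `simulation_result`.
#' @return a `clade_bundle` or `NULL`.
#' @export
bundle_from_result <- function(result) {
  tree <- result_tree(result, drop_extinct = TRUE)
  if (is.null(tree)) return(NULL)
  occ <- do.call(rbind, lapply(result$species, function(sp)
    data.frame(species = paste0("s", sp$id), cell = as.character(sp$sites),
               stringsAsFactors = FALSE)))
  bs <- vapply(result$species, function(sp) mean(sp$bsize), numeric(1))
  names(bs) <- paste0("s", vapply(result$species, `[[`, integer(1), "id"))
  ncell <- result$n_rows * result$n_cols
  idx <- which(is.finite(as.vector(result$temperature_final)))  # land cells
  if (!length(idx)) idx <- seq_len(ncell)
  rows <- (idx - 1L) %% result$n_rows + 1L
  cells <- data.frame(cell = as.character(idx),
                      temperature = as.vector(result$temperature_final)[idx],
                      latitude = result$latitude_deg[rows])
  suppressMessages(clade_bundle(tree, occ, bs, cells))
}

#' Summary-statistic vector of a clade
#'
#' Assembles the clade's named feature vector across the four statistic
#' categories used by the classifier:
#' \itemize{
#'   \item `phylo_corr`: Spearman correlations of tip metrics (ES, DR, ED,
#'     MRD) with species-level range size, mean range temperature, and body
#'     size (across species);
#'   \item `spatial_corr`: Spearman correlations of cell-level richness, PD,
#'     MPD, MNTD and body-size moments with absolute latitude and
#'     temperature (across cells);
#'   \item `trait_dist`: moments of the body-size, temperature-niche and
#'     range-size distributions, plus species-level trait correlations;
#'   \item `tree_shape`: gamma, Sackin, clade size.
#' }
#' Cells with fewer than `min_cell_species` species contribute NA to
#' divergence-based cell metrics (pairwise exclusion). Statistics that
#' cannot be computed are NA, never an error.
#'
#' @param bundle a `clade_bundle`.
#' @param min_cell_species minimum species per cell for MPD/MNTD/SD (2).
#' @return named numeric vector with attributes `category` (named character)
#'   and `n_species`.
#' @export
summarize_clade <- function(bundle, min_cell_species = 2L) {
  stopifnot(inherits(bundle, "clade_bundle"))
  tree <- bundle$tree
  tm <- tip_metrics(tree)
  occ <- bundle$occupancy
  cells <- bundle$cells
  ctemp <- stats::setNames(cells$temperature, cells$cell)
  clat <- stats::setNames(cells$latitude, cells$cell)
  spt <- species_spatial_traits(occ, ctemp)
  rownames(spt) <- spt$species
  tm <- tm[order(match(tm$tip, spt$species)), ]
  stopifnot(all(tm$tip == spt$species))
  bs <- bundle$body_size[spt$species]

  # per-occupied-cell assemblage table
  dmat <- ape::cophenetic.phylo(tree)
  occ_cells <- sort(unique(occ$cell))
  by_cell <- split(occ$species, occ$cell)[occ_cells]
  am <- t(vapply(by_cell, function(spp)
    assemblage_metrics(tree, spp, bundle$body_size, dmat), numeric(6)))
  cell_lat <- abs(clat[occ_cells])
  cell_tmp <- ctemp[occ_cells]

  v <- c()
  cat_tag <- c()
  add <- function(name, value, category) {
    v[[name]] <<- as.numeric(value)
    cat_tag[[name]] <<- category
  }

  for (met in c("ES", "DR", "ED", "MRD")) {
    add(paste0("cor_", met, "_rangesize"), spearman(tm[[met]], spt$range_size), "phylo_corr")
    add(paste0("cor_", met, "_temperature"), spearman(tm[[met]], spt$mean_range_temperature), "phylo_corr")
    add(paste0("cor_", met, "_bodysize"), spearman(tm[[met]], bs), "phylo_corr")
  }
  for (met in c("richness", "PD", "MPD", "MNTD", "mean_body_size", "sd_body_size")) {
    add(paste0("cor_", met, "_abslat"), spearman(am[, met], cell_lat), "spatial_corr")
    add(paste0("cor_", met, "_celltemp"), spearman(am[, met], cell_tmp), "spatial_corr")
  }
  # |latitude| centroid of the cell-mean speciation rate (DR) field: low
  # values mean high speciation rates concentrate toward the equator
  drmap <- vapply(by_cell, function(spp) {
    dr <- tm$DR[match(spp, tm$tip)]
    mean(dr[is.finite(dr)])
  }, numeric(1))
  okc <- is.finite(drmap) & drmap > 0
  add("dr_abslat_centroid",
      if (any(okc)) sum(cell_lat[okc] * drmap[okc]) / sum(drmap[okc]) else NA_real_,
      "spatial_corr")
  bm <- trait_distribution_stats(bs)
  nm <- trait_distribution_stats(spt$mean_range_temperature)
  rm_ <- trait_distribution_stats(spt$range_size)
  for (s in c("mean", "sd", "skewness", "kurtosis", "range"))
    add(paste0("bodysize_", s), bm[[s]], "trait_dist")
  for (s in c("mean", "sd", "skewness", "kurtosis", "range"))
    add(paste0("tempniche_", s), nm[[s]], "trait_dist")
  for (s in c("mean", "sd", "skewness"))
    add(paste0("rangesize_", s), rm_[[s]], "trait_dist")
  sp_abslat <- vapply(split(abs(clat[occ$cell]), occ$species)[spt$species],
                      mean, numeric(1))
  add("cor_bodysize_temperature", spearman(bs, spt$mean_range_temperature), "trait_dist")
  add("cor_rangesize_temperature", spearman(spt$range_size, spt$mean_range_temperature), "trait_dist")
  add("cor_rangesize_abslat", spearman(spt$range_size, sp_abslat), "trait_dist")
  ts <- tree_shape(tree)
  add("gamma", ts[["gamma"]], "tree_shape")
  add("sackin", ts[["sackin"]], "tree_shape")
  add("clade_size", ts[["clade_size"]], "tree_shape")

  out <- unlist(v)
  attr(out, "category") <- unlist(cat_tag)
  attr(out, "n_species") <- nrow(spt)
  out
}

#' Write / read a clade bundle as plain-text files
#'
#' Directory dialect: `tree.nwk` (Newick), `occupancy.csv`
#' (species_id, cell_row, cell_col), `traits.csv` (species_id, body_size),
#' `cells.csv` (cell_row, cell_col, temperature, latitude). Cell ids are
#' reconstructed as `row + (col-1) * n_rows`.
#'
#' @param bundle a `clade_bundle`; `n_rows` grid rows used to encode cell
#'   ids as (row, col).
#' @param path directory.
#' @rdname bundle_io
#' @export
write_bundle <- function(bundle, path, n_rows) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(bundle$tree, file.path(path, "tree.nwk"))
  occ <- bundle$occupancy
  idx <- as.integer(occ$cell)
  utils::write.csv(data.frame(species_id = occ$species,
                              cell_row = (idx - 1L) %% n_rows + 1L,
                              cell_col = (idx - 1L) %/% n_rows + 1L),
                   file.path(path, "occupancy.csv"), row.names = FALSE)
  utils::write.csv(data.frame(species_id = names(bundle$body_size),
                              body_size = unname(bundle$body_size)),
                   file.path(path, "traits.csv"), row.names = FALSE)
  cidx <- as.integer(bundle$cells$cell)
  utils::write.csv(data.frame(cell_row = (cidx - 1L) %% n_rows + 1L,
                              cell_col = (cidx - 1L) %/% n_rows + 1L,
                              temperature = bundle$cells$temperature,
                              latitude = bundle$cells$latitude),
                   file.path(path, "cells.csv"), row.names = FALSE)
  writeLines(as.character(n_rows), file.path(path, "n_rows.txt"))
  invisible(path)
}

#' @rdname bundle_io
#' @export
read_bundle <- function(path) {
  n_rows <- as.integer(readLines(file.path(path, "n_rows.txt"))[1])
  tree <- ape::read.tree(file.path(path, "tree.nwk"))
  occ <- utils::read.csv(file.path(path, "occupancy.csv"))
  traits <- utils::read.csv(file.path(path, "traits.csv"))
  cells <- utils::read.csv(file.path(path, "cells.csv"))
  mkcell <- function(r, cc) as.character(r + (cc - 1L) * n_rows)
  clade_bundle(
    tree,
    data.frame(species = traits_chr(occ$species_id),
               cell = mkcell(occ$cell_row, occ$cell_col)),
    stats::setNames(traits$body_size, traits_chr(traits$species_id)),
    data.frame(cell = mkcell(cells$cell_row, cells$cell_col),
               temperature = cells$temperature, latitude = cells$latitude))
}

traits_chr <- function(x) as.character(x)

#' Export a completed simulation as a pseudo-empirical clade bundle
#'
#' Writes the extant tree and matching range/trait/cell tables so the
#' model-selection path can be exercised without any external data.
#' Extinct tips are excluded.
#'
#' @param result a completed `simulation_result`.
#' @param path output directory.
#' @return the path, invisibly; errors if the result has < 2 extant species.
#' @export
export_pseudo_empirical <- function(result, path) {
  b <- bundle_from_result(result)
  if (is.null(b)) stop("result has fewer than 2 extant species")
  write_bundle(b, path, result$n_rows)
}
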