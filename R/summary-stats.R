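# Clade-level biodiversity summary statistics: per-tip phylogenetic rate
# metrics (ES, DR, ED, MRD), grid-cell assemblage metrics (richness, PD,
# MPD, MNTD, body-size moments), tree-shape statistics (gamma, Sackin,
# clade size), species-level spatial/trait summaries, and the Spearman
# correlation suite that turns them into the classifier feature vector.

#' Per-tip phylogenetic rate metrics
#'
#' \describe{
#'   \item{ES}{equal splits: walking from the tip to the root, the pendant
#'     edge counts fully and each successive edge is halved again
#'     (divisors 1, 2, 4, ...).}
#'   \item{DR}{the diversification-rate statistic, `1/ES`; flagged missing
#'     (NA) when a zero-length pendant path makes it infinite.}
#'   \item{ED}{evolutionary distinctiveness by fair proportion: each edge's
#'     length divided equally among its descendant tips, summed along the
#'     root-to-tip path.}
#'   \item{MRD}{mean-root-distance contribution: the number of edges
#'     (equivalently ancestral nodes, root included) on the root-to-tip
#'     path.}
#' }
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return data.frame with columns tip, ES, DR, ED, MRD.
#' @export
tip_metrics <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  parent <- integer(nn); plen <- numeric(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  root <- nt + 1L
  # descendant-tip counts: accumulate over edges, deepest children first
  ntips_below <- integer(nn)
  ntips_below[seq_len(nt)] <- 1L
  tr <- ape::reorder.phylo(tree, "cladewise")
  depth <- integer(nn)
  for (e in seq_len(nrow(tr$edge)))
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + 1L
  for (e in order(-depth[tree$edge[, 2]])) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    ntips_below[a] <- ntips_below[a] + ntips_below[b]
  }
  ES <- DR <- ED <- numeric(nt); MRD <- integer(nt)
  for (tip in seq_len(nt)) {
    v <- tip; div <- 1; es <- 0; ed <- 0; m <- 0L
    while (v != root) {
      es <- es + plen[v] / div
      ed <- ed + plen[v] / ntips_below[v]
      div <- div * 2
      m <- m + 1L
      v <- parent[v]
    }
    ES[tip] <- es; ED[tip] <- ed; MRD[tip] <- m
    DR[tip] <- if (es > 0) 1 / es else NA_real_
  }
  data.frame(tip = tree$tip.label, ES = ES, DR = DR, ED = ED, MRD = MRD,
             stringsAsFactors = FALSE)
}

# cladewise depth ordering is guaranteed after reorder; ensure it
node_depths_edgewise <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  depth <- integer(nn)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge)))
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + 1L
  depth
}

#' Assemblage metrics for one cell
#'
#' @param tree the clade tree (`phylo`).
#' @param present character vector of tip labels present in the cell.
#' @param body_size named numeric of body sizes (names = tip labels).
#' @param dist_mat optional precomputed patristic distance matrix.
#' @return named numeric: richness, PD, MPD, MNTD, mean_body_size,
#'   sd_body_size (divergence metrics NA below 2 species).
#' @export
assemblage_metrics <- function(tree, present, body_size, dist_mat = NULL) {
  present <- intersect(present, tree$tip.label)
  n <- length(present)
  out <- c(richness = n, PD = NA_real_, MPD = NA_real_, MNTD = NA_real_,
           mean_body_size = NA_real_, sd_body_size = NA_real_)
  if (n == 0L) return(out)
  out["mean_body_size"] <- mean(body_size[present])
  out["PD"] <- pd_rooted(tree, present)
  if (n >= 2L) {
    if (is.null(dist_mat)) dist_mat <- ape::cophenetic.phylo(tree)
    dm <- dist_mat[present, present, drop = FALSE]
    out["MPD"] <- mean(dm[upper.tri(dm)])
    diag(dm) <- Inf
    out["MNTD"] <- mean(apply(dm, 1, min))
    out["sd_body_size"] <- stats::sd(body_size[present])
  }
  out
}

# total branch length of the minimal spanning subtree connecting the present
# tips to the root (single species: its root-to-tip path length)
pd_rooted <- function(tree, present) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  parent <- integer(nn); plen <- numeric(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  root <- nt + 1L
  used <- logical(nn)
  for (tip in match(present, tree$tip.label)) {
    v <- tip
    while (v != root && !used[v]) { used[v] <- TRUE; v <- parent[v] }
  }
  sum(plen[used])
}

#' Tree shape statistics
#'
#' `gamma` is the Pybus--Harvey statistic computed from ordered internode
#' intervals of the (ultrametric) tree; on a non-ultrametric tree it is
#' computed from node heights with `attr(,"nonultrametric") = TRUE`. Sackin
#' is the sum of tip depths (node counts) divided by the number of tips;
#' `clade_size` the number of tips.
#'
#' @param tree a `phylo`.
#' @return named numeric: gamma, sackin, clade_size.
#' @export
tree_shape <- function(tree) {
  nt <- ape::Ntip(tree)
  depth <- node_depths_edgewise(tree)
  sackin <- sum(depth[seq_len(nt)]) / nt
  g <- if (nt >= 3L) gamma_statistic(tree) else NA_real_
  c(gamma = g, sackin = sackin, clade_size = nt)
}

#' Pybus--Harvey gamma from branching times
#' @param tree ultrametric `phylo` with >= 3 tips.
#' @return the gamma statistic.
#' @export
gamma_statistic <- function(tree) {
  n <- ape::Ntip(tree)
  if (n < 3L) return(NA_real_)
  # node heights above root
  nn <- n + tree$Nnode
  h <- numeric(nn)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge)))
    h[tr$edge[e, 2]] <- h[tr$edge[e, 1]] + tr$edge.length[e]
  total <- max(h[seq_len(n)])
  # branching times from the root: root at height 0, then internal nodes
  btimes <- sort(h[(n + 1L):nn])
  g_int <- diff(c(btimes, total))          # g_2..g_n: interval with k lineages
  k <- 2:n
  Tsum <- sum(k * g_int)
  cumT <- cumsum(k * g_int)
  inner <- sum(cumT[seq_len(n - 2L)])
  (inner / (n - 2L) - Tsum / 2) / (Tsum * sqrt(1 / (12 * (n - 2L))))
}

#' Species-level spatial and trait summaries
#'
#' @param occupancy data.frame with columns species, cell (cell ids).
#' @param cell_temperature named numeric per cell.
#' @return data.frame: species, range_size, mean_range_temperature.
#' @export
species_spatial_traits <- function(occupancy, cell_temperature) {
  spl <- split(as.character(occupancy$cell), occupancy$species)
  data.frame(
    species = names(spl),
    range_size = lengths(spl),
    mean_range_temperature = vapply(spl, function(cells)
      mean(cell_temperature[cells]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Moment statistics of a trait distribution
#'
#' Mean, SD, adjusted Fisher--Pearson skewness
#' `g1 * sqrt(n(n-1))/(n-2)`, excess kurtosis with the standard
#' bias-corrected estimator, and range. Degenerate (zero-variance) inputs
#' give NA skewness/kurtosis.
#'
#' @param values numeric vector.
#' @return named numeric: mean, sd, skewness, kurtosis, range.
#' @export
trait_distribution_stats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  m <- mean(values); s <- stats::sd(values)
  skew <- kurt <- NA_real_
  if (n >= 3L && s > 0) {
    g1 <- mean((values - m)^3) / (mean((values - m)^2))^(3 / 2)
    skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  if (n >= 4L && s > 0) {
    g2 <- mean((values - m)^4) / (mean((values - m)^2))^2 - 3
    kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  c(mean = m, sd = s, skewness = skew, kurtosis = kurt,
    range = if (n) diff(range(values)) else NA_real_)
}

#' Spearman correlation with missing-pair handling
#'
#' Average-rank Spearman over complete pairs; NA (with < 3 complete pairs)
#' rather than an error.
#' @param x,y numeric vectors.
#' @return correlation in \[-1, 1\] or NA.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
}

#' Greedy collinearity pruning
#'
#' Repeatedly finds the pair of columns with the largest absolute Pearson
#' correlation above `threshold` and drops the member with the larger mean
#' absolute correlation to all remaining columns (ties broken
#' alphabetically), until no pair exceeds the threshold. Constant columns
#' are dropped first.
#'
#' @param mat numeric matrix/data.frame (rows = simulations, columns =
#'   statistics, named).
#' @param threshold absolute-correlation threshold in (0, 1\] (default 0.90).
#' @return character vector of retained column names (original order).
#' @export
collinearity_filter <- function(mat, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  mat <- as.matrix(mat)
  stopifnot(!is.null(colnames(mat)), ncol(mat) >= 2, nrow(mat) >= 3)
  sds <- apply(mat, 2, stats::sd, na.rm = TRUE)
  const <- colnames(mat)[!is.finite(sds) | sds == 0]
  if (length(const)) {
    message("dropping constant/degenerate columns: ",
            paste(const, collapse = ", "))
    mat <- mat[, setdiff(colnames(mat), const), drop = FALSE]
  }
  keep <- colnames(mat)
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(suppressWarnings(stats::cor(mat[, keep, drop = FALSE],
                                          use = "pairwise.complete.obs")))
    diag(cm) <- 0
    cm[!is.finite(cm)] <- 0
    if (max(cm) <= threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)
    pair <- sort(c(rownames(cm)[idx[1, 1]], colnames(cm)[idx[1, 2]]))
    mean_abs <- rowMeans(cm)
    a <- pair[1]; b <- pair[2]
    drop <- if (mean_abs[a] > mean_abs[b]) a
            else if (mean_abs[b] > mean_abs[a]) b
            else sort(c(a, b))[2]
    keep <- setdiff(keep, drop)
  }
  keep
}
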