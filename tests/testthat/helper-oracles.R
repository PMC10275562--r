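# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own traversal code: paths come from ape::nodepath()
# and metrics are computed by direct enumeration.

oracle_tip_metrics <- function(tree) {
  nt <- ape::Ntip(tree)
  plen <- numeric(nt + tree$Nnode)
  plen[tree$edge[, 2]] <- tree$edge.length
  # tips below each node by enumeration
  tips_below <- function(node) {
    if (node <= nt) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  out <- data.frame(tip = tree$tip.label, ES = NA_real_, DR = NA_real_,
                    ED = NA_real_, MRD = NA_integer_)
  for (i in seq_len(nt)) {
    path <- ape::nodepath(tree, from = nt + 1L, to = i)   # root ... tip
    edges_on_path <- path[-1]                              # child end of each edge
    # ES: pendant edge divisor 1, doubling toward the root
    divs <- 2^(rev(seq_along(edges_on_path)) - 1)
    out$ES[i] <- sum(plen[edges_on_path] / divs)
    out$DR[i] <- if (out$ES[i] > 0) 1 / out$ES[i] else NA_real_
    out$ED[i] <- sum(vapply(edges_on_path, function(nd)
      plen[nd] / length(tips_below(nd)), numeric(1)))
    out$MRD[i] <- length(edges_on_path)
  }
  out
}

oracle_patristic <- function(tree) {
  nt <- ape::Ntip(tree)
  plen <- numeric(nt + tree$Nnode)
  plen[tree$edge[, 2]] <- tree$edge.length
  d <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    pi <- ape::nodepath(tree, nt + 1L, i)
    pj <- ape::nodepath(tree, nt + 1L, j)
    shared <- intersect(pi, pj)
    d[i, j] <- d[j, i] <- sum(plen[setdiff(pi[-1], shared)]) +
      sum(plen[setdiff(pj[-1], shared)])
  }
  d
}

oracle_pd <- function(tree, present) {
  nt <- ape::Ntip(tree)
  plen <- numeric(nt + tree$Nnode)
  plen[tree$edge[, 2]] <- tree$edge.length
  nodes <- unique(unlist(lapply(match(present, tree$tip.label), function(i)
    ape::nodepath(tree, nt + 1L, i)[-1])))
  sum(plen[nodes])
}

oracle_sackin <- function(tree) {
  nt <- ape::Ntip(tree)
  sum(vapply(seq_len(nt), function(i)
    length(ape::nodepath(tree, nt + 1L, i)) - 1L, integer(1)))
}

# transitive-closure connected components on a boolean adjacency matrix
oracle_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ])
  comp <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      nxt <- nxt + 1L
      comp[reach[i, ]] <- nxt
    }
  }
  comp
}

# minimal landscape_series constructed directly for simulator tests
toy_landscape <- function(temp, n_steps = 10, arid = NULL, cell_km = 220) {
  nr <- nrow(temp); nc <- ncol(temp)
  if (is.null(arid)) arid <- matrix(0, nr, nc)
  t3 <- array(NA_real_, c(n_steps, nr, nc))
  a3 <- array(NA_real_, c(n_steps, nr, nc))
  h3 <- array(NA, c(n_steps, nr, nc))
  hab <- is.finite(temp)
  for (s in seq_len(n_steps)) {
    t3[s, , ] <- temp
    a3[s, , ] <- ifelse(hab, arid, NA)
    h3[s, , ] <- hab
  }
  structure(list(temperature01 = t3, aridity01 = a3,
                 elevation_km = matrix(0, nr, nc), habitable = h3,
                 latitude_deg = seq(50, -50, length.out = nr),
                 step_times_kyr = (seq_len(n_steps) - 1) * 170,
                 cell_size_km = cell_km),
            class = "landscape_series")
}

# labeled Gaussian classification fixture: 4 classes at the corners of a
# square of half-width `sep`, unit spherical noise
gaussian4_fixture <- function(n_per, sep = 1.5, seed = 1) {
  set.seed(seed)
  mu <- rbind(c(-sep, -sep), c(-sep, sep), c(sep, -sep), c(sep, sep))
  X <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(n_per, mu[k, 1]), rnorm(n_per, mu[k, 2]))))
  data.frame(model = rep(c("M0", "M1", "M2", "M3"), each = n_per),
             f1 = X[, 1], f2 = X[, 2])
}
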