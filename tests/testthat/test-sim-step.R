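# two-cluster species state on a toy geometry, used by several tests
two_cluster_species <- function(D0 = 0, sites = c(1L, 181L)) {
  list(id = 1L, sites = sites, topt = c(0.5, 0.5), bsize = c(0.5, 0.5),
       clus = c(1L, 2L),
       D = matrix(c(0, D0, D0, 0), 2, 2, dimnames = list(c("1", "2"), c("1", "2"))),
       next_cl = 3L)
}

test_that("isolated clusters accumulate g per step; contact coalesces by 1", {
  p <- parameter_set("M0", g0 = 0.3, contact_distance = 300)
  sp <- two_cluster_species()
  # sites 1 and 181 on a 18-row grid are 10 columns apart -> two components
  for (i in 1:4)
    sp <- update_divergence(sp, comp = c(1L, 2L), temp_site = c(0.5, 0.5),
                            params = p, g0 = 0.3)
  expect_equal(sp$D["1", "2"], 1.2)

  # secondary contact: D = 2.5 -> 1.5 after one step
  sp <- two_cluster_species(D0 = 2.5)
  sp <- update_divergence(sp, comp = c(1L, 1L), temp_site = c(0.5, 0.5),
                          params = p)
  expect_equal(sp$D["1", "2"], 1.5)

  # D = 0.4 floors at 0 and the pair merges into one cluster
  sp <- two_cluster_species(D0 = 0.4)
  sp <- update_divergence(sp, comp = c(1L, 1L), temp_site = c(0.5, 0.5),
                          params = p)
  expect_equal(nrow(sp$D), 1L)
  expect_equal(unique(sp$clus), 1L)
})

test_that("cluster splitting inherits divergence to third clusters", {
  p <- parameter_set("M0", g0 = 0.2)
  sp <- two_cluster_species(D0 = 1.5)
  # cluster 2 now spans two spatial components -> fragments at D 0 from
  # each other, both at 1.5 from cluster 1 (then one step of accrual)
  sp$sites <- c(1L, 181L, 361L)
  sp$topt <- rep(0.5, 3); sp$bsize <- rep(0.5, 3)
  sp$clus <- c(1L, 2L, 2L)
  sp <- update_divergence(sp, comp = c(1L, 2L, 3L), temp_site = rep(0.5, 3),
                          params = p, g0 = 0.2)
  expect_equal(dim(sp$D), c(3L, 3L))
  frag <- setdiff(rownames(sp$D), c("1", "2"))
  expect_equal(sp$D["2", frag], 0.2)          # started at 0, one accrual
  expect_equal(sp$D["1", frag], 1.7)          # inherited 1.5 + one accrual
})

test_that("speciation partitions clusters exactly like exhaustive search", {
  mk <- function(D, S) {
    k <- nrow(D)
    dimnames(D) <- list(as.character(1:k), as.character(1:k))
    sp <- list(id = 1L, sites = seq_len(k), topt = rep(0.5, k),
               bsize = rep(0.5, k), clus = seq_len(k), D = D, next_cl = k + 1L)
    speciate(sp, S)
  }
  # below threshold everywhere -> no split
  D <- matrix(1, 3, 3); diag(D) <- 0
  expect_length(mk(D, S = 2), 1L)
  # one pair over threshold -> two species
  D <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_length(mk(D, S = 2), 2L)
  # chained components: D(1,2) < S, D(2,3) < S, D(1,3) >= S -> one species
  D <- matrix(c(0, 1, 9, 1, 0, 1, 9, 1, 0), 3, 3)
  expect_length(mk(D, S = 2), 1L)

  set.seed(9)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    D <- matrix(0, k, k)
    D[upper.tri(D)] <- runif(k * (k - 1) / 2, 0, 10)
    D <- D + t(D)
    S <- runif(1, 1, 9)
    parts <- mk(D, S)
    want <- oracle_components(D < S & !diag(TRUE, k))
    got <- integer(k)
    for (pi in seq_along(parts))
      got[as.integer(rownames(parts[[pi]]$D))] <- pi
    expect_identical(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("an empty world passes through a step unchanged", {
  p <- parameter_set("M1")
  world <- list(species = list(), next_sp = 1L, events = evospeed:::empty_log(),
                params = p, g0 = NA, n_rows = 3, cell_size_km = 220)
  land <- list(temp = matrix(0.5, 3, 3), arid = matrix(0, 3, 3),
               hab = matrix(TRUE, 3, 3))
  expect_identical(sim_step(world, land, 1), world)
})

test_that("a single connected cluster never speciates", {
  ls <- toy_landscape(matrix(0.5, 5, 5), n_steps = 30)
  p <- parameter_set("M1", sigma_T = 0, sigma_B = 0, phi = 600, seed = 5)
  res <- run_simulation(p, ls, richness_window = c(1, 6000))
  expect_equal(length(res$species), 1L)
  expect_equal(nrow(res$events), 0L)
})

test_that("two permanently disconnected islands under M0 speciate at step 4", {
  # islands 12 cells apart; g0 = 0.5 and S = 2 -> D crosses 2 at step 4
  temp <- matrix(NA_real_, 3, 15)
  temp[2, 1] <- temp[2, 13] <- 0.5
  ls <- toy_landscape(temp, n_steps = 8)
  p <- parameter_set("M0", S = 2, g0 = 0.5, sigma_T = 0, sigma_B = 0,
                     phi = 300, seed = 3)
  res <- run_simulation(p, ls, richness_window = c(1, 6000),
                        init = list(cell = which(!is.na(temp))))
  spec <- res$events[res$events$event == "speciation", ]
  expect_equal(nrow(spec), 1L)
  expect_equal(spec$time, 4)
})

test_that("identical seeds give identical results; richness window is enforced", {
  cfg <- landscape_config(n_steps = 25)
  ls <- generate_landscape(cfg)
  p <- parameter_set("M1", seed = 13)
  r1 <- run_simulation(p, ls)
  r2 <- run_simulation(p, ls)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$per_species, r2$per_species)
  expect_identical(r1$richness_by_cell, r2$richness_by_cell)
  # 25 steps cannot reach 20 species here
  expect_false(r1$completed)
  expect_match(r1$reason, "below minimum of 20|extinct")
})

test_that("phylogeny bookkeeping balances and the tree is time-consistent", {
  cfg <- landscape_config(n_steps = 60)
  ls <- generate_landscape(cfg)
  p <- parameter_set("M1", S = 3, seed = 8)
  res <- run_simulation(p, ls, richness_window = c(2, 6000))
  nspec <- sum(res$events$event == "speciation")
  next_ <- sum(res$events$event == "extinction")
  expect_equal(nspec - next_ + 1L, length(res$species))
  expect_gt(nspec, 0)

  # every divergence matrix stays symmetric, nonnegative, zero-diagonal
  for (sp in res$species) {
    expect_identical(sp$D, t(sp$D))
    expect_true(all(sp$D >= 0))
    expect_true(all(diag(sp$D) == 0))
    expect_setequal(rownames(sp$D), as.character(unique(sp$clus)))
  }

  full <- result_tree(res, drop_extinct = FALSE)
  expect_s3_class(full, "phylo")
  depths <- ape::node.depth.edgelength(full)[seq_len(ape::Ntip(full))]
  extinct <- paste0("s", res$events$sp[res$events$event == "extinction"])
  extant <- setdiff(full$tip.label, extinct)
  for (tp in extant) {
    i <- match(tp, full$tip.label)
    expect_equal(depths[i] + full$root.edge, res$final_time, tolerance = 1e-10)
  }
  # Newick text round-trips through ape
  txt <- ape::write.tree(full)
  expect_s3_class(ape::read.tree(text = txt), "phylo")
  # extant tree holds exactly the extant species
  ext_tree <- result_tree(res, drop_extinct = TRUE)
  expect_setequal(ext_tree$tip.label,
                  paste0("s", vapply(res$species, `[[`, integer(1), "id")))
})

test_that("per-site abundance never exceeds K after reapportionment", {
  # direct contract check on a crowded site
  N <- runif(8, 0, 2e4)
  expect_lte(sum(reapportion(N, 30000)), 30000 + 1e-9)
  expect_lte(sum(reapportion(N, 1000)), 1000 + 1e-9)
})

test_that("monotone model behavior: warmer ranges diverge faster under M1,
           larger bodies slower under M2", {
  lam <- 3
  temps <- seq(0.2, 1, by = 0.2)
  g1 <- divergence_increment("M1", temps, temps, 0.5, 0.5, lam)
  expect_false(is.unsorted(g1))
  sizes <- seq(0, 1, by = 0.25)
  g2 <- divergence_increment("M2", 0.5, 0.5, sizes, sizes, lam)
  expect_false(is.unsorted(rev(g2)))
})
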