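test_that("Fisher transformation matches its closed form and inverts cleanly", {
  f0 <- fisher_transform(0, 50)
  expect_equal(f0$z, 0)
  expect_equal(f0$ci95, -rev(f0$ci95))
  f <- fisher_transform(0.5, 103)
  expect_equal(f$z, atanh(0.5))
  expect_equal(f$var, 0.01)
  expect_equal(f$ci95, atanh(0.5) + c(-1, 1) * 1.959964 * 0.1)
  for (r in c(-0.9, -0.3, 0.4, 0.99))
    expect_equal(tanh(fisher_transform(r, 30)$z), r, tolerance = 1e-12)
  expect_error(fisher_transform(0.5, 3), "n > 3")
  expect_warning(fisher_transform(1, 30), "clipped")
})

# independent oracle: profile the restricted likelihood over a tau^2 grid
grid_reml_tau2 <- function(yi, vi, upper = 2, n_grid = 40001) {
  restricted_ll <- function(t2) {
    w <- 1 / (vi + t2)
    beta <- sum(w * yi) / sum(w)
    -0.5 * sum(log(vi + t2)) - 0.5 * log(sum(w)) -
      0.5 * sum(w * (yi - beta)^2)
  }
  grid <- seq(0, upper, length.out = n_grid)
  grid[which.max(vapply(grid, restricted_ll, numeric(1)))]
}

test_that("random-effects pooling matches a grid-search REML oracle", {
  rec <- data.frame(rho = c(0.2, 0.4), n = rep(103, 2))
  out <- random_effects_pool(rec)
  expect_equal(out$beta, mean(atanh(c(0.2, 0.4))), tolerance = 1e-6)
  expect_equal(out$beta_rho, tanh(out$beta))
  expect_equal(out$z_stat, out$beta / out$se, tolerance = 1e-10)
  t2 <- grid_reml_tau2(atanh(c(0.2, 0.4)), rep(0.01, 2))
  expect_equal(out$tau2, t2, tolerance = 5e-4)

  set.seed(31)
  rho <- tanh(rnorm(12, 0.3, 0.25))
  n <- sample(50:200, 12)
  out2 <- random_effects_pool(data.frame(rho = rho, n = n))
  t2b <- grid_reml_tau2(atanh(rho), 1 / (n - 3))
  expect_equal(out2$tau2, t2b, tolerance = 1e-3)
  expect_gte(out2$tau2, 0)
  expect_true(out2$beta >= min(atanh(rho)) && out2$beta <= max(atanh(rho)))
})

test_that("homogeneous effects pool to the common value with tau2 = 0", {
  rec <- data.frame(rho = rep(0.35, 5), n = rep(80, 5))
  out <- random_effects_pool(rec)
  expect_equal(out$beta, atanh(0.35), tolerance = 1e-10)
  expect_equal(out$tau2, 0, tolerance = 1e-8)
})

test_that("a clade with negligible weight leaves the pooled effect unchanged", {
  rec <- data.frame(rho = c(0.2, 0.4, 0.9), n = c(103, 103, 4))
  # n = 4 gives variance 1; inflate it further by duplicating tiny weight
  full <- random_effects_pool(rec, method = "DL")
  reduced <- random_effects_pool(rec[1:2, ], method = "DL")
  expect_lt(abs(full$beta - reduced$beta), 0.05)
})

test_that("REML and DerSimonian-Laird agree on moderate heterogeneity", {
  set.seed(77)
  k <- 25
  true_z <- rnorm(k, 0.3, 0.1)
  n <- sample(80:300, k, replace = TRUE)
  rho <- tanh(rnorm(k, true_z, sqrt(1 / (n - 3))))
  rec <- data.frame(rho = rho, n = n)
  reml <- random_effects_pool(rec, "REML")
  dl <- random_effects_pool(rec, "DL")
  expect_lt(abs(reml$tau2 - dl$tau2), 0.1 * max(reml$tau2, dl$tau2, 0.005))
})

test_that("the key-correlation battery pools across clades and filters small ones", {
  set.seed(41)
  mk_big_bundle <- function(seed) {
    set.seed(seed)
    n <- 25; ncell <- 30
    tr <- ape::rtree(n)
    occ <- unique(data.frame(
      species = sample(tr$tip.label, 5 * ncell, replace = TRUE),
      cell = as.character(rep(seq_len(ncell), 5))))
    cells <- data.frame(cell = as.character(seq_len(ncell)),
                        temperature = runif(ncell),
                        latitude = seq(-60, 60, length.out = ncell))
    suppressMessages(clade_bundle(tr, occ, setNames(runif(n), tr$tip.label),
                                  cells))
  }
  b1 <- mk_big_bundle(1)
  out <- key_correlation_battery(list(b1, b1), min_species = 20)
  expect_setequal(unique(out$records$statistic),
                  c("richness_abslat", "richness_temperature",
                    "DR_bodysize", "DR_temperature"))
  # two identical clades: pooled beta equals the single-clade z
  z1 <- atanh(out$records$rho[out$records$statistic == "richness_abslat"][1])
  row <- out$pooled[out$pooled$statistic == "richness_abslat", ]
  expect_equal(row$beta_z, z1, tolerance = 1e-6)

  # a 10-species clade is excluded with a message, leaving k unchanged
  tr10 <- ape::rtree(10)
  occ10 <- data.frame(species = tr10$tip.label, cell = as.character(1:10))
  cells10 <- data.frame(cell = as.character(1:10), temperature = runif(10),
                        latitude = 1:10)
  small <- suppressMessages(clade_bundle(tr10, occ10,
                                         setNames(runif(10), tr10$tip.label),
                                         cells10))
  expect_message(out2 <- key_correlation_battery(list(b1, b1, small),
                                                 min_species = 20),
                 "excluded")
  expect_equal(out2$pooled$k, out$pooled$k)
})

test_that("clades simulated under temperature-dependent divergence show a
           positive richness-temperature correlation", {
  cfg <- landscape_config(n_steps = 60)
  ls <- generate_landscape(cfg)
  rhos <- c()
  for (sd in c(5, 9)) {
    res <- run_simulation(parameter_set("M1", S = 3, seed = sd), ls,
                          richness_window = c(2, 6000))
    b <- bundle_from_result(res)
    if (is.null(b)) next
    ctemp <- setNames(b$cells$temperature, b$cells$cell)
    occ_cells <- sort(unique(b$occupancy$cell))
    rich <- lengths(split(b$occupancy$species, b$occupancy$cell)[occ_cells])
    rhos <- c(rhos, spearman(rich, ctemp[occ_cells]))
  }
  expect_gt(mean(rhos), 0)
})
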