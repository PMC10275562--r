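random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- round(tr$edge.length, 6) + 0.01
  tr
}

test_that("tip metrics reproduce hand-computed small-tree values", {
  two <- ape::read.tree(text = "(a:1.5,b:1.5);")
  tm <- tip_metrics(two)
  expect_equal(tm$ES, c(1.5, 1.5))
  expect_equal(tm$DR, c(1 / 1.5, 1 / 1.5))
  expect_equal(tm$ED, c(1.5, 1.5))
  expect_equal(tm$MRD, c(1L, 1L))

  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  tm <- tip_metrics(bal)
  expect_equal(tm$ES, rep(1.5, 4))       # 1 + 1/2
  expect_equal(tm$DR, rep(2 / 3, 4))
  expect_equal(tm$ED, rep(1.5, 4))       # 1 + 1/2 under fair proportion
  expect_equal(tm$MRD, rep(2L, 4))
  expect_equal(sum(tm$ED), sum(bal$edge.length))
})

test_that("tip metrics match the path-enumeration oracle and picante", {
  skip_if_not_installed("picante")
  set.seed(5)
  for (i in 1:25) {
    tr <- random_tree(sample(4:12, 1))
    got <- tip_metrics(tr)
    want <- oracle_tip_metrics(tr)
    expect_equal(got$ES, want$ES, tolerance = 1e-10)
    expect_equal(got$ED, want$ED, tolerance = 1e-10)
    expect_equal(got$MRD, want$MRD)
    ok <- is.finite(got$DR)
    expect_equal(got$DR[ok], 1 / got$ES[ok], tolerance = 1e-12)
  }
  tr <- random_tree(10)
  es <- picante::evol.distinct(tr, type = "equal.splits")
  fp <- picante::evol.distinct(tr, type = "fair.proportion")
  got <- tip_metrics(tr)
  expect_equal(got$ES, es$w[match(got$tip, es$Species)], tolerance = 1e-10)
  expect_equal(got$ED, fp$w[match(got$tip, fp$Species)], tolerance = 1e-10)
})

test_that("assemblage metrics match brute-force patristic computations", {
  set.seed(6)
  for (i in 1:10) {
    tr <- random_tree(sample(4:10, 1))
    dm <- oracle_patristic(tr)
    present <- sample(tr$tip.label, 3)
    got <- assemblage_metrics(tr, present, setNames(runif(ape::Ntip(tr)),
                                                   tr$tip.label))
    sub <- dm[present, present]
    expect_equal(got[["MPD"]], mean(sub[upper.tri(sub)]), tolerance = 1e-10)
    diag(sub) <- Inf
    expect_equal(got[["MNTD"]], mean(apply(sub, 1, min)), tolerance = 1e-10)
    expect_equal(got[["PD"]], oracle_pd(tr, present), tolerance = 1e-10)
  }
  tr <- random_tree(8)
  bs <- setNames(runif(8), tr$tip.label)
  all_m <- assemblage_metrics(tr, tr$tip.label, bs)
  expect_equal(all_m[["PD"]], sum(tr$edge.length), tolerance = 1e-10)
  one <- assemblage_metrics(tr, tr$tip.label[1], bs)
  expect_equal(one[["richness"]], 1)
  expect_true(is.na(one[["MPD"]]) && is.na(one[["MNTD"]]))
  expect_equal(one[["PD"]],
               ape::node.depth.edgelength(tr)[1], tolerance = 1e-10)
})

test_that("gamma matches ape and Sackin counts tip depths", {
  skip_if_not_installed("picante")
  set.seed(8)
  for (i in 1:10) {
    tr <- ape::rcoal(sample(4:12, 1))
    expect_equal(gamma_statistic(tr), ape::gammaStat(tr), tolerance = 1e-8)
  }
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(tree_shape(bal)[["sackin"]] * 4, 8)
  cat4 <- ape::read.tree(text = "(a:3,(b:2,(c:1,d:1):1):1);")
  expect_equal(tree_shape(cat4)[["sackin"]] * 4, oracle_sackin(cat4))
  expect_equal(oracle_sackin(cat4), 9)   # depths 1+2+3+3
  expect_gt(tree_shape(cat4)[["sackin"]], tree_shape(bal)[["sackin"]])
})

test_that("species spatial traits are simple bookkeeping", {
  occ <- data.frame(species = c("a", "b", "b"), cell = c("1", "1", "2"))
  ct <- c(`1` = 0.2, `2` = 0.4)
  spt <- species_spatial_traits(occ, ct)
  expect_equal(spt$range_size, c(1L, 2L))
  expect_equal(spt$mean_range_temperature, c(0.2, 0.3))
  expect_equal(sum(spt$range_size), nrow(occ))
})

test_that("trait moments match direct computation and flag degenerate input", {
  s <- trait_distribution_stats(c(1, 2, 3))
  expect_equal(s[["skewness"]], 0)
  expect_gt(trait_distribution_stats(c(0, 0, 0, 1))[["skewness"]], 0)
  x <- c(2.3, 5.1, 0.4, 9.9, 3.3, 2.2, 7.1, 0.1, 4.4, 6.0)
  expect_equal(trait_distribution_stats(x)[["skewness"]],
               e1071::skewness(x, type = 2), tolerance = 1e-12)
  expect_equal(trait_distribution_stats(x)[["kurtosis"]],
               e1071::kurtosis(x, type = 2), tolerance = 1e-12)
  expect_true(is.na(trait_distribution_stats(rep(3, 6))[["skewness"]]))
})

test_that("spearman handles monotone, antitone and independent inputs", {
  x <- runif(30)
  expect_equal(spearman(x, exp(x)), 1)
  expect_equal(spearman(x, -x^3), -1)
  set.seed(10)
  m <- replicate(1000, spearman(1:20, sample(20)))
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m)), 3 * se + 1e-3)
  expect_true(is.na(spearman(c(1, 2), c(3, 4))))
})

make_bundle <- function(seed = 1, n = 8, ncell = 12) {
  set.seed(seed)
  tr <- random_tree(n)
  occ <- data.frame(species = sample(tr$tip.label, 3 * ncell, replace = TRUE),
                    cell = as.character(rep(seq_len(ncell), 3)))
  occ <- unique(occ)
  cells <- data.frame(cell = as.character(seq_len(ncell)),
                      temperature = runif(ncell),
                      latitude = seq(-50, 50, length.out = ncell))
  suppressMessages(clade_bundle(tr, occ, setNames(runif(n), tr$tip.label), cells))
}

test_that("the summary vector spans four categories with >= 30 statistics", {
  b <- make_bundle()
  v <- summarize_clade(b)
  expect_gte(length(v), 30)
  expect_setequal(unique(attr(v, "category")),
                  c("phylo_corr", "spatial_corr", "trait_dist", "tree_shape"))
  expect_equal(attr(v, "n_species"), 8)
  cors <- v[startsWith(names(v), "cor_")]
  cors <- cors[is.finite(cors)]
  expect_true(all(cors >= -1 & cors <= 1))
})

test_that("the summary vector is invariant to row ordering of the inputs", {
  b <- make_bundle(seed = 3)
  v1 <- summarize_clade(b)
  b2 <- b
  set.seed(99)
  b2$occupancy <- b2$occupancy[sample(nrow(b2$occupancy)), ]
  b2$body_size <- b2$body_size[sample(names(b2$body_size))]
  b2$cells <- b2$cells[sample(nrow(b2$cells)), ]
  v2 <- summarize_clade(b2)
  expect_equal(v1, v2)
  expect_equal(summarize_clade(b), v1)   # determinism
})

test_that("a two-species clade flags species-level correlations as missing", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  occ <- data.frame(species = c("a", "b", "b"), cell = c("1", "1", "2"))
  cells <- data.frame(cell = c("1", "2"), temperature = c(0.3, 0.6),
                      latitude = c(0, 20))
  b <- suppressMessages(clade_bundle(tr, occ, c(a = 0.4, b = 0.6), cells))
  v <- summarize_clade(b)
  expect_true(is.na(v[["cor_ES_bodysize"]]))
  expect_equal(v[["clade_size"]], 2)
})

test_that("collinearity pruning is greedy, deterministic and subset-optimal", {
  set.seed(12)
  n <- 40
  a <- rnorm(n); b <- rnorm(n); cc <- rnorm(n)
  m <- cbind(s_a = a, s_b = b, s_c = cc, s_dup = a + rnorm(n, 0, 1e-4))
  kept <- collinearity_filter(m, 0.90)
  expect_length(kept, 3)
  # exhaustive-subset oracle: largest subset with no |r| > 0.90
  best <- 0
  for (k in 1:4) for (s in combn(4, k, simplify = FALSE)) {
    cm <- abs(cor(m[, s, drop = FALSE])); diag(cm) <- 0
    if (max(cm) <= 0.90) best <- max(best, k)
  }
  expect_equal(length(kept), best)

  expect_length(collinearity_filter(cbind(x = a, y = a), 0.9), 1)
  ortho <- cbind(u = a, v = b, w = cc)
  expect_length(collinearity_filter(ortho, 0.9), 3)
  expect_message(collinearity_filter(cbind(m, s_const = rep(1, n)), 0.9),
                 "constant")
})
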