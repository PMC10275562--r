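test_that("Cohen's kappa follows the marginal-chance-corrected formula", {
  expect_equal(cohen_kappa(diag(c(10, 20, 5))), 1)
  expect_equal(cohen_kappa(matrix(25, 2, 2)), 0)
  expect_equal(cohen_kappa(matrix(c(20, 10, 5, 15), 2, 2)), 0.4)
  expect_true(is.na(suppressWarnings(
    cohen_kappa(matrix(c(5, 0, 0, 0), 2, 2)))))
})

test_that("kappa-weighted support averages probabilities correctly", {
  p1 <- c(M0 = 1, M1 = 0, M2 = 0, M3 = 0)
  p2 <- c(M0 = 0, M1 = 1, M2 = 0, M3 = 0)
  s <- kappa_weighted_support(list(p1, p2), c(0.5, 0.25))
  expect_equal(unname(s$support), c(2 / 3, 1 / 3, 0, 0))
  expect_equal(s$best, "M0")
  # equal weights = plain average; single algorithm = identity
  s2 <- kappa_weighted_support(list(p1, p2), c(0.4, 0.4))
  expect_equal(unname(s2$support), c(0.5, 0.5, 0, 0))
  expect_equal(kappa_weighted_support(list(p1), 0.7)$support, p1)
  # invariant to algorithm ordering
  s3 <- kappa_weighted_support(list(p2, p1), c(0.25, 0.5))
  expect_equal(s3$support, s$support)
  # negative kappas floored; all-zero weights fall back with a warning
  s4 <- kappa_weighted_support(list(p1, p2), c(0.5, -3))
  expect_equal(unname(s4$support), c(1, 0, 0, 0))
  expect_warning(s5 <- kappa_weighted_support(list(p1, p2), c(0, -1)),
                 "unweighted")
  expect_equal(unname(s5$support), c(0.5, 0.5, 0, 0))
  expect_equal(sum(s$support), 1, tolerance = 1e-9)
})

test_that("every algorithm separates a trivially separable fixture", {
  tab <- gaussian4_fixture(40, sep = 12, seed = 2)
  fit <- train_classifiers(tab, c("f1", "f2"),
                           algorithms = c("lda", "cart", "rf", "xgb",
                                          "nb", "svm", "nnet"),
                           folds = 5, repeats = 1, seed = 3)
  for (a in names(fit$fits)) {
    expect_equal(fit$fits[[a]]$accuracy, 1, info = a)
    expect_equal(fit$fits[[a]]$kappa, 1, info = a)
  }
})

test_that("label-permuted data yields kappa near zero", {
  set.seed(4)
  tab <- data.frame(model = sample(rep(c("M0", "M1", "M2", "M3"), 250)),
                    f1 = rnorm(1000), f2 = rnorm(1000), f3 = rnorm(1000))
  fit <- train_classifiers(tab, c("f1", "f2", "f3"),
                           algorithms = c("lda", "nb"),
                           folds = 5, repeats = 1, seed = 5)
  for (a in names(fit$fits))
    expect_lt(abs(fit$fits[[a]]$kappa), 0.1)
})

test_that("training is deterministic given the seed", {
  tab <- gaussian4_fixture(30, sep = 2, seed = 6)
  f1 <- train_classifiers(tab, c("f1", "f2"), algorithms = c("rf", "nnet"),
                          folds = 5, repeats = 2, seed = 11)
  f2 <- train_classifiers(tab, c("f1", "f2"), algorithms = c("rf", "nnet"),
                          folds = 5, repeats = 2, seed = 11)
  expect_identical(f1$test_idx, f2$test_idx)
  for (a in names(f1$fits)) {
    expect_equal(f1$fits[[a]]$accuracy, f2$fits[[a]]$accuracy)
    expect_equal(f1$fits[[a]]$confusion, f2$fits[[a]]$confusion)
  }
})

test_that("holdout accuracy approaches the analytic Bayes rate on Gaussians", {
  # four unit Gaussians at corners (+-1.5, +-1.5): the Bayes rule is the
  # nearest mean, with accuracy pnorm(1.5)^2
  tab <- gaussian4_fixture(300, sep = 1.5, seed = 7)
  fit <- train_classifiers(tab, c("f1", "f2"),
                           algorithms = c("lda", "nb", "svm"),
                           folds = 5, repeats = 1, seed = 8)
  bayes <- pnorm(1.5)^2
  best <- max(vapply(fit$fits, function(f) f$accuracy, numeric(1)))
  expect_lt(abs(best - bayes), 0.05)
})

test_that("per-class sensitivity and specificity come from the confusion matrix", {
  tab <- gaussian4_fixture(40, sep = 12, seed = 9)
  fit <- train_classifiers(tab, c("f1", "f2"), algorithms = "lda",
                           folds = 5, repeats = 1, seed = 2)
  bc <- fit$fits$lda$by_class
  expect_equal(unname(bc[, "sensitivity"]), rep(1, 4))
  expect_equal(unname(bc[, "specificity"]), rep(1, 4))
})

test_that("permutation importance ranks the informative feature first", {
  set.seed(10)
  n <- 400
  y <- rep(c("M0", "M1", "M2", "M3"), n / 4)
  tab <- data.frame(model = y,
                    signal = as.integer(factor(y)) * 2 + rnorm(n, 0, 0.3),
                    noise = rnorm(n))
  fit <- train_classifiers(tab, c("signal", "noise"),
                           algorithms = c("lda", "rf"),
                           folds = 5, repeats = 1, seed = 12)
  imp <- variable_importance(fit, tab, n_perm = 3, seed = 1)
  expect_equal(names(imp)[1], "signal")
  expect_true(all(imp >= 0 & imp <= 100))
  expect_equal(unname(imp["signal"]), 100)
})

test_that("clade classification recombines per-algorithm probabilities", {
  tab <- gaussian4_fixture(40, sep = 6, seed = 13)
  fit <- train_classifiers(tab, c("f1", "f2"),
                           algorithms = c("lda", "nb"),
                           folds = 5, repeats = 1, seed = 14)
  v <- c(f1 = -6, f2 = -6)   # deep inside class M0 territory
  s <- classify_clade(fit, v)
  expect_equal(s$best, "M0")
  expect_equal(sum(s$support), 1, tolerance = 1e-9)
  # recomputation oracle: kappa-weighted mean of the returned per-algorithm rows
  kap <- pmax(0, vapply(fit$fits, function(f) f$kappa, numeric(1)))
  want <- colSums(s$per_algorithm * kap) / sum(kap)
  expect_equal(unname(s$support), unname(want / sum(want)), tolerance = 1e-12)
  # a mostly-missing vector is refused
  expect_error(classify_clade(fit, c(bogus = 1)), "missing")
})
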