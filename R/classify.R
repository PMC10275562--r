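# Supervised model selection. Seven classifier families (linear
# discriminant, single decision tree, bagged trees/random forest, boosted
# trees, naive Bayes, kernel SVM, feed-forward network) are fitted through
# their native packages behind a uniform fit/predict-probability interface;
# hyperparameters are tuned by repeated stratified k-fold cross-validation
# on a two-thirds training split, final metrics come from the untouched
# test third, and per-clade class probabilities are combined across
# algorithms weighted by each algorithm's holdout Cohen's kappa.

algo_registry <- function() {
  list(
    lda = list(
      grid = list(list()),
      fit = function(X, y, par) MASS::lda(X, grouping = y),
      prob = function(m, X) stats::predict(m, X)$posterior),
    cart = list(
      grid = lapply(c(0.001, 0.01), function(cp) list(cp = cp)),
      fit = function(X, y, par) {
        d <- data.frame(X, .y = y, check.names = FALSE)
        rpart::rpart(.y ~ ., data = d, method = "class",
                     control = rpart::rpart.control(cp = par$cp, xval = 0))
      },
      prob = function(m, X)
        stats::predict(m, data.frame(X, check.names = FALSE), type = "prob")),
    rf = list(
      grid = lapply(c(0.5, 1), function(f) list(mtry_frac = f)),
      fit = function(X, y, par) {
        mtry <- max(1L, round(par$mtry_frac * floor(sqrt(ncol(X)))))
        randomForest::randomForest(X, y, ntree = 300, mtry = mtry)
      },
      prob = function(m, X) stats::predict(m, X, type = "prob")),
    xgb = list(
      grid = lapply(c(60, 150), function(n) list(nrounds = n)),
      fit = function(X, y, par) {
        dtrain <- xgboost::xgb.DMatrix(as.matrix(X),
                                       label = as.integer(y) - 1L)
        m <- xgboost::xgb.train(
          params = list(objective = "multi:softprob",
                        num_class = nlevels(y), max_depth = 3,
                        eta = 0.3, nthread = 1, tree_method = "exact"),
          data = dtrain, nrounds = par$nrounds, verbose = 0)
        attr(m, "levels") <- levels(y)
        m
      },
      prob = function(m, X) {
        p <- stats::predict(m, xgboost::xgb.DMatrix(as.matrix(X)))
        if (!is.matrix(p))
          p <- matrix(p, ncol = length(attr(m, "levels")), byrow = TRUE)
        colnames(p) <- attr(m, "levels")
        p
      }),
    nb = list(
      grid = list(list()),
      fit = function(X, y, par) e1071::naiveBayes(X, y),
      prob = function(m, X) stats::predict(m, X, type = "raw")),
    svm = list(
      grid = lapply(c(1, 10), function(cc) list(cost = cc)),
      fit = function(X, y, par)
        e1071::svm(X, y, kernel = "radial", cost = par$cost,
                   probability = TRUE),
      prob = function(m, X) {
        p <- attr(stats::predict(m, X, probability = TRUE), "probabilities")
        p[, levels(m$fitted), drop = FALSE]
      }),
    nnet = list(
      grid = lapply(c(0.01, 0.1), function(dec) list(decay = dec)),
      fit = function(X, y, par)
        nnet::nnet(X, nnet::class.ind(y), size = 6, decay = par$decay,
                   maxit = 250, softmax = TRUE, trace = FALSE,
                   MaxNWts = 5000),
      prob = function(m, X) stats::predict(m, X))
  )
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` (the
#' accuracy) and chance agreement `p_e` from the products of row and column
#' marginals. Degenerate marginals (`p_e = 1`) give NA.
#'
#' @param cm square nonnegative confusion matrix (same class order on both
#'   axes), any orientation.
#' @return kappa in \[-1, 1\] or NA.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0), sum(cm) > 0)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

confusion <- function(pred, truth, lev) {
  table(factor(pred, levels = lev), factor(truth, levels = lev))
}

class_sens_spec <- function(cm) {
  lev <- rownames(cm)
  t(vapply(lev, function(l) {
    tp <- cm[l, l]; fn <- sum(cm[, l]) - tp
    fp <- sum(cm[l, ]) - tp; tn <- sum(cm) - tp - fn - fp
    c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
  }, numeric(2)))
}

# preprocessing fitted on the training split only
fit_preproc <- function(X) {
  med <- vapply(X, stats::median, numeric(1), na.rm = TRUE)
  mu <- vapply(X, mean, numeric(1), na.rm = TRUE)
  sg <- vapply(X, stats::sd, numeric(1), na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(median = med, mean = mu, sd = sg, features = names(X))
}

apply_preproc <- function(pp, X) {
  X <- X[pp$features]
  for (j in seq_along(X)) {
    xj <- X[[j]]
    xj[!is.finite(xj)] <- pp$median[j]
    X[[j]] <- (xj - pp$mean[j]) / pp$sd[j]
  }
  X
}

stratified_split <- function(y, frac, seed_offset = 0L) {
  idx <- unlist(lapply(levels(y), function(l) {
    members <- which(y == l)
    sample(members, round(length(members) * frac))
  }))
  sort(idx)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (l in levels(y)) {
    members <- sample(which(y == l))
    fold[members] <- rep_len(seq_len(k), length(members))
  }
  fold
}

#' Train the classifier ensemble on labeled summary vectors
#'
#' Stratified two-thirds/one-third split; per-algorithm hyperparameters are
#' tuned by `repeats` x stratified `folds`-fold cross-validation on the
#' training split (mean accuracy); final confusion matrix, accuracy,
#' Cohen's kappa and per-class sensitivity/specificity are computed on the
#' untouched test third. Missing feature values are imputed with
#' training-split medians; features are centered and scaled with
#' training-split statistics.
#'
#' @param table `ensemble_table` (or any data.frame) with a `model` label
#'   column and feature columns.
#' @param features character vector of feature column names.
#' @param algorithms subset of c("lda","cart","rf","xgb","nb","svm","nnet").
#' @param folds,repeats cross-validation design (default 10 x 10).
#' @param split_frac training fraction (default 2/3).
#' @param holdout optional integer row indices to use as the test set
#'   (overrides the random split); used e.g. to rotate the holdout third
#'   over outer folds so every row is predicted out-of-sample once.
#' @param seed RNG seed; identical seeds give identical splits and metrics.
#' @return object of class `trained_ensemble`: per-algorithm fits and
#'   holdout metrics, the preprocessing parameters, feature and class lists,
#'   and the holdout row indices.
#' @export
train_classifiers <- function(table, features,
                              algorithms = c("lda", "cart", "rf", "xgb",
                                             "nb", "svm", "nnet"),
                              folds = 10L, repeats = 10L,
                              split_frac = 2 / 3, holdout = NULL,
                              seed = 1L) {
  reg <- algo_registry()
  stopifnot(all(algorithms %in% names(reg)),
            all(features %in% names(table)))
  y <- factor(table$model)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  small <- table(y) < folds
  if (any(small))
    stop("class(es) with fewer members than folds: ",
         paste(names(which(small)), collapse = ", "))
  X <- as.data.frame(table[, features, drop = FALSE])

  set.seed(seed)
  if (is.null(holdout)) {
    tr_idx <- stratified_split(y, split_frac)
    te_idx <- setdiff(seq_along(y), tr_idx)
  } else {
    te_idx <- sort(as.integer(holdout))
    tr_idx <- setdiff(seq_along(y), te_idx)
  }
  pp <- fit_preproc(X[tr_idx, , drop = FALSE])
  Xtr <- apply_preproc(pp, X[tr_idx, , drop = FALSE])
  Xte <- apply_preproc(pp, X[te_idx, , drop = FALSE])
  ytr <- y[tr_idx]; yte <- y[te_idx]

  fits <- list()
  for (a in algorithms) {
    spec <- reg[[a]]
    cv_acc <- rep(0, length(spec$grid))
    if (length(spec$grid) > 1L) {
      for (r in seq_len(repeats)) {
        fold <- stratified_folds(ytr, folds)
        for (f in seq_len(folds)) {
          hold <- fold == f
          if (!any(hold) || length(unique(ytr[!hold])) < nlevels(y)) next
          for (gi in seq_along(spec$grid)) {
            m <- spec$fit(Xtr[!hold, , drop = FALSE], droplevels(ytr[!hold]),
                          spec$grid[[gi]])
            p <- spec$prob(m, Xtr[hold, , drop = FALSE])
            pred <- colnames(p)[max.col(p, ties.method = "first")]
            cv_acc[gi] <- cv_acc[gi] + mean(pred == as.character(ytr[hold]))
          }
        }
      }
      best <- which.max(cv_acc)
    } else best <- 1L
    model <- spec$fit(Xtr, ytr, spec$grid[[best]])
    pte <- spec$prob(model, Xte)
    pte <- pte[, levels(y), drop = FALSE]
    pred <- colnames(pte)[max.col(pte, ties.method = "first")]
    cm <- confusion(pred, yte, levels(y))
    fits[[a]] <- list(model = model, par = spec$grid[[best]],
                      confusion = cm,
                      accuracy = sum(diag(cm)) / sum(cm),
                      kappa = cohen_kappa(cm),
                      by_class = class_sens_spec(cm),
                      test_prob = pte)
  }
  structure(list(fits = fits, preproc = pp, features = features,
                 classes = levels(y), algorithms = algorithms,
                 test_idx = te_idx, test_labels = yte,
                 folds = folds, repeats = repeats, seed = seed),
            class = "trained_ensemble")
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat("trained_ensemble on", length(x$features), "features,",
      length(x$test_labels), "holdout rows\n")
  for (a in names(x$fits))
    cat(sprintf("  %-5s accuracy %.3f kappa %.3f\n", a,
                x$fits[[a]]$accuracy, x$fits[[a]]$kappa))
  invisible(x)
}

#' Kappa-weighted model-averaged support
#'
#' `support(class) = sum_a kappa_a p_a(class) / sum_a kappa_a`, with
#' negative kappas floored at 0 (an algorithm worse than chance should not
#' invert support); if every kappa is 0 the unweighted mean is used with a
#' warning. The result is renormalized to sum to 1; the best model is the
#' argmax with ties broken toward the lower class index.
#'
#' @param probs list (or matrix rows) of per-algorithm class-probability
#'   vectors, each summing to 1 over the same classes.
#' @param kappas per-algorithm Cohen's kappa values.
#' @return object of class `support_profile`: `support` (named, sums to 1),
#'   `best`, `weights`, `per_algorithm`.
#' @export
kappa_weighted_support <- function(probs, kappas) {
  if (is.matrix(probs)) probs <- asplit(probs, 1)
  stopifnot(length(probs) == length(kappas))
  P <- do.call(rbind, probs)
  if (any(abs(rowSums(P) - 1) > 1e-6)) stop("probabilities must sum to 1")
  w <- pmax(0, ifelse(is.finite(kappas), kappas, 0))
  if (sum(w) == 0) {
    warning("all kappa weights are 0; using the unweighted mean")
    w <- rep(1, length(w))
  }
  s <- colSums(P * w) / sum(w)
  s <- s / sum(s)
  structure(list(support = s,
                 best = names(s)[which.max(s)],
                 weights = w, per_algorithm = P),
            class = "support_profile")
}

#' @export
print.support_profile <- function(x, ...) {
  cat("support:", paste(sprintf("%s=%.3f", names(x$support), x$support),
                        collapse = " "), "| best:", x$best, "\n")
  invisible(x)
}

#' Kappa-weighted permutation variable importance
#'
#' Permutation importance is the common currency across the heterogeneous
#' algorithm families: for each algorithm, the drop in holdout accuracy
#' when one feature column is permuted (averaged over `n_perm`
#' permutations), scaled to \[0, 100\] within the algorithm, then averaged
#' across algorithms with kappa weights.
#'
#' @param ensemble a `trained_ensemble`.
#' @param table the table used in training (holdout rows are re-used).
#' @param n_perm permutations per feature (default 5).
#' @param seed RNG seed for the permutations.
#' @return named numeric scores in \[0, 100\], sorted decreasing.
#' @export
variable_importance <- function(ensemble, table, n_perm = 5L, seed = 1L) {
  reg <- algo_registry()
  X <- as.data.frame(table[, ensemble$features, drop = FALSE])
  Xte <- apply_preproc(ensemble$preproc, X[ensemble$test_idx, , drop = FALSE])
  yte <- ensemble$test_labels
  set.seed(seed)
  imp <- matrix(0, length(ensemble$features), length(ensemble$fits),
                dimnames = list(ensemble$features, names(ensemble$fits)))
  for (a in names(ensemble$fits)) {
    spec <- reg[[a]]
    fit <- ensemble$fits[[a]]
    base <- fit$accuracy
    for (f in ensemble$features) {
      drop_acc <- 0
      for (r in seq_len(n_perm)) {
        Xp <- Xte
        Xp[[f]] <- sample(Xp[[f]])
        p <- spec$prob(fit$model, Xp)
        p <- p[, ensemble$classes, drop = FALSE]
        pred <- colnames(p)[max.col(p, ties.method = "first")]
        drop_acc <- drop_acc + (base - mean(pred == as.character(yte)))
      }
      imp[f, a] <- max(0, drop_acc / n_perm)
    }
    mx <- max(imp[, a])
    if (mx > 0) imp[, a] <- 100 * imp[, a] / mx
  }
  kap <- vapply(ensemble$fits, function(f) f$kappa, numeric(1))
  w <- pmax(0, ifelse(is.finite(kap), kap, 0))
  if (sum(w) == 0) w <- rep(1, length(w))
  sort(drop(imp %*% w) / sum(w), decreasing = TRUE)
}

#' Classify a clade's summary vector
#'
#' Applies the stored preprocessing (training-median imputation for missing
#' statistics, refused when more than half are missing), queries every
#' algorithm for class probabilities, and combines them with kappa weights.
#'
#' @param ensemble a `trained_ensemble`.
#' @param vector named numeric summary vector (e.g. from
#'   [summarize_clade()]).
#' @return a `support_profile`.
#' @export
classify_clade <- function(ensemble, vector) {
  reg <- algo_registry()
  x <- stats::setNames(rep(NA_real_, length(ensemble$features)),
                       ensemble$features)
  have <- intersect(names(vector), ensemble$features)
  x[have] <- vector[have]
  if (mean(is.finite(x)) < 0.5)
    stop("summary vector is missing more than 50% of the model's features")
  X <- apply_preproc(ensemble$preproc, as.data.frame(as.list(x)))
  probs <- lapply(names(ensemble$fits), function(a) {
    p <- reg[[a]]$prob(ensemble$fits[[a]]$model, X)
    drop(as.matrix(p)[, ensemble$classes])
  })
  kap <- vapply(ensemble$fits, function(f) f$kappa, numeric(1))
  kappa_weighted_support(probs, kap)
}

#' Principal-component projection of summary statistics
#'
#' Convenience utility for inspecting multivariate overlap between
#' simulated and pseudo-empirical summary vectors.
#'
#' @param mat rows = clades/simulations, columns = statistics.
#' @param k number of components.
#' @return list with `scores` and `sdev`.
#' @export
project_pca <- function(mat, k = 2L) {
  mat <- as.matrix(mat)
  keep <- apply(mat, 2, function(x) all(is.finite(x)) && stats::sd(x) > 0)
  p <- stats::prcomp(mat[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  list(scores = p$x[, seq_len(min(k, ncol(p$x))), drop = FALSE],
       sdev = p$sdev)
}
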