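test_that("peak counting handles maxima, plateaus and prominence", {
  expect_identical(count_peaks(c(0, 1, 0, 1, 0)), 2L)
  expect_identical(count_peaks(1:10), 0L)
  expect_identical(count_peaks(10:1), 0L)
  expect_identical(count_peaks(c(0, 1, 1, 0)), 1L)  # plateau collapses
  expect_identical(count_peaks(c(0, 1, 1, 2, 0)), 1L)
  expect_identical(count_peaks(c(0, 5, 4, 4.9, 0), prominence = 1), 1L)
  expect_identical(count_peaks(c(0, 5, 4, 4.9, 0), prominence = 0.5), 2L)
  expect_warning(n <- count_peaks(c(0, 1, NA, 0, 1, 0)), "missing")
  expect_identical(n, 2L)
  # brute-force enumeration oracle on random walks
  set.seed(12)
  for (rep in 1:10) {
    x <- cumsum(rnorm(50))
    y <- rle(x)$values
    brute <- sum(vapply(2:(length(y) - 1), function(i)
      y[i] > y[i - 1] && y[i] > y[i + 1], logical(1)))
    expect_identical(count_peaks(x), as.integer(brute))
  }
})

test_that("aggregation yields exactly the named 26 features", {
  set.seed(13)
  meas <- list(speed = runif(100), curvature = runif(100),
               torsion = c(runif(95), rep(NA, 5)),
               shape_change_rate = runif(11), E_xy = runif(12),
               E_xz = runif(12))
  f <- suppressWarnings(aggregate_features(meas))
  expect_length(f, 26L)
  expect_identical(names(f), feature_names())
  # order-statistic oracle: sort-based quantiles and raw MAD
  x <- meas$speed
  expect_equal(unname(f["speed_median"]), median(x))
  expect_equal(unname(f["speed_mad"]), median(abs(x - median(x))))
  expect_equal(unname(f["speed_p25"]), unname(quantile(x, 0.25)))
  expect_equal(unname(f["speed_p75"]), unname(quantile(x, 0.75)))
  expect_true(f["speed_p25"] <= f["speed_median"] &&
                f["speed_median"] <= f["speed_p75"])
  # constant speed collapses its order statistics
  meas$speed <- rep(3, 100)
  f2 <- suppressWarnings(aggregate_features(meas))
  expect_equal(unname(f2[c("speed_median", "speed_p25", "speed_p75")]),
               c(3, 3, 3))
  expect_equal(unname(f2["speed_mad"]), 0)
  # inclusion rule: fewer than 6 shape time points is refused
  meas$E_xy <- runif(5)
  expect_error(suppressWarnings(aggregate_features(meas)), "excluded")
})

test_that("feature tables standardize to zero mean, unit sd, invertibly", {
  set.seed(14)
  x <- matrix(rnorm(60, mean = 5, sd = 3), 10, 6,
              dimnames = list(NULL, letters[1:6]))
  ft <- standardize_table(x)
  expect_equal(unname(colMeans(ft$features)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(ft$features, 2, sd)), rep(1, 6),
               tolerance = 1e-9)
  back <- sweep(sweep(ft$features, 2, ft$scale, `*`), 2, ft$center, `+`)
  expect_equal(unname(back), unname(x), tolerance = 1e-12)
  # hand-computed z-scores on a 3 x 2 toy table
  toy <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  zt <- standardize_table(toy)
  expect_equal(unname(zt$features[, "a"]), c(-1, 0, 1))
  expect_equal(unname(zt$features[, "b"]),
               (c(10, 20, 60) - 30) / sd(c(10, 20, 60)))
  # constant columns are dropped with a warning
  expect_warning(d <- standardize_table(cbind(a = 1:5, b = rep(2, 5))),
                 "constant")
  expect_identical(colnames(d$features), "a")
  expect_error(standardize_table(x[1, , drop = FALSE]), "2 rows")
})

test_that("Kendall matrix is tie-corrected and matches pair counting", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
             c = c(5, 4, 3, 2, 1), d = c(2, 1, 4, 3, 5))
  K <- kendall_matrix(x)
  expect_equal(dim(K), c(4L, 4L))
  expect_equal(unname(diag(K)), rep(1, 4))
  expect_equal(K, t(K))
  expect_equal(K["a", "b"], 1)
  expect_equal(K["a", "c"], -1)
  # brute-force tau-b oracle with ties
  tau_b <- function(u, v) {
    s <- 0; n <- length(u)
    tx <- 0; ty <- 0; n0 <- choose(n, 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      du <- sign(u[j] - u[i]); dv <- sign(v[j] - v[i])
      s <- s + du * dv
      if (du == 0) tx <- tx + 1
      if (dv == 0) ty <- ty + 1
    }
    s / sqrt((n0 - tx) * (n0 - ty))
  }
  set.seed(15)
  for (rep in 1:10) {
    u <- sample(1:4, 8, replace = TRUE)
    v <- sample(1:4, 8, replace = TRUE)
    if (sd(u) == 0 || sd(v) == 0) next
    expect_equal(unname(kendall_matrix(cbind(u, v, w = rnorm(8)))[1, 2]),
                 tau_b(u, v), tolerance = 1e-12)
  }
})

test_that("the 2D embedding separates separated classes reproducibly", {
  set.seed(16)
  X <- rbind(matrix(rnorm(30 * 5), 30, 5),
             matrix(rnorm(30 * 5, mean = 8), 30, 5))
  lab <- rep(1:2, each = 30)
  emb <- embed_2d(X, n_neighbors = 10L, seed = 42L)
  expect_equal(dim(emb), c(60L, 2L))
  expect_identical(attr(emb, "seed"), 42L)
  emb2 <- embed_2d(X, n_neighbors = 10L, seed = 42L)
  expect_identical(emb, emb2)
  # silhouette of the two blobs in embedding space
  D <- as.matrix(dist(emb))
  sil <- vapply(1:60, function(i) {
    a <- mean(D[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(D[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_error(embed_2d(X[1:5, ], n_neighbors = 10L), "parameter error")
})

test_that("stratified KNN cross-validation scores as expected", {
  set.seed(17)
  X <- rbind(matrix(rnorm(40 * 3), 40, 3),
             matrix(rnorm(40 * 3, mean = 10), 40, 3))
  lab <- rep(c("a", "b"), each = 40)
  res <- knn_cv(X, lab, k = c(3L, 5L), folds = 10L, seed = 1L)
  expect_equal(mean(res$accuracy), 1)
  # fold sizes differ by <= 1 and preserve class ratios within 1
  fold <- attr(res, "folds")
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  per_class <- table(fold, lab)
  expect_lte(max(per_class) - min(per_class), 1)
  # chance level for random labels, averaged over seeds
  accs <- vapply(1:8, function(s) {
    set.seed(100 + s)
    mean(knn_cv(matrix(rnorm(60 * 4), 60, 4),
                sample(rep(c("a", "b"), each = 30)),
                k = 5L, folds = 10L, seed = s)$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
  expect_error(knn_cv(X[1:12, ], lab[c(1:6, 41:46)], folds = 10L),
               "stratification")
})

test_that("paired accuracy t-tests match the textbook formula", {
  expect_warning(r0 <- paired_accuracy_ttest(rep(0.8, 10), rep(0.8, 10)),
                 "zero-variance")
  expect_equal(r0$mean_difference, 0)
  expect_equal(r0$statistic, 0)
  expect_true(is.na(r0$p_value))
  set.seed(18)
  a <- runif(10, 0.7, 0.9); b <- a - 0.1 + rnorm(10, sd = 0.02)
  r <- paired_accuracy_ttest(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(r$statistic, t_manual, tolerance = 1e-12)
  expect_equal(r$df, 9)
  expect_equal(r$p_value, 2 * pt(-abs(t_manual), df = 9),
               tolerance = 1e-12)
  # symmetric differences: small statistic
  r2 <- paired_accuracy_ttest(c(0.8, 0.9, 0.8, 0.9), c(0.9, 0.8, 0.9, 0.8))
  expect_lt(abs(r2$statistic), 1)
})

test_that("permutation importance isolates predictive features", {
  set.seed(19)
  n <- 60L
  lab <- rep(c("a", "b"), each = n / 2)
  X <- cbind(signal = ifelse(lab == "a", 0, 5) + rnorm(n, sd = 0.3),
             noise = rnorm(n), flat = rep(1, n))
  tr <- c(1:20, 31:50); te <- setdiff(1:n, tr)
  imp <- permutation_importance(X[tr, ], lab[tr], X[te, ], lab[te],
                                k = 3L, n_repeats = 20L, seed = 1L)
  expect_equal(unname(imp["flat"]), 0)
  expect_gt(imp["signal"], 0.3)           # ~ accuracy - chance
  expect_lt(abs(imp["noise"]), 0.1)
  imp2 <- permutation_importance(X[tr, ], lab[tr], X[te, ], lab[te],
                                 k = 3L, n_repeats = 20L, seed = 1L)
  expect_identical(imp, imp2)
})
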