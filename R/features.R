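# Per-cell feature aggregation and the downstream statistical battery:
# robust order statistics of the six shape-movement quantities, peak
# counts, column standardization, Kendall correlation, 2D embedding,
# stratified KNN cross-validation, paired accuracy t-test and permutation
# importance.

.FEATURE_QUANTITIES <- c("speed", "curvature", "torsion",
                         "shape_change_rate", "E_xy", "E_xz")

#' Canonical names of the 26 per-cell features
#'
#' Four order statistics (median, raw MAD, 25th and 75th percentile) of
#' each of speed, curvature, torsion, shape-change rate, `E_xy` and
#' `E_xz`, plus the number of peaks in the curvature and torsion series:
#' 4 x 6 + 2 = 26.
#'
#' @return character vector of length 26.
#' @export
feature_names <- function() {
  c(as.vector(t(outer(.FEATURE_QUANTITIES,
                      c("median", "mad", "p25", "p75"), paste, sep = "_"))),
    "n_peaks_curvature", "n_peaks_torsion")
}

#' Count peaks in a series
#'
#' Interior strict local maxima after collapsing runs of equal values
#' (a flat-topped peak counts once), keeping only peaks whose prominence
#' (height above the higher of the two bounding valleys, measured to the
#' nearest higher point or series end) exceeds `prominence`. Missing
#' values are dropped with a warning.
#'
#' @param series numeric vector, length >= 3.
#' @param prominence non-negative threshold; 0 (default) keeps every
#'   strict local maximum.
#' @return non-negative integer count.
#' @examples
#' count_peaks(c(0, 1, 0, 1, 0))  # 2
#' count_peaks(c(0, 1, 1, 0))     # 1 (plateau collapses)
#' @export
count_peaks <- function(series, prominence = 0) {
  if (anyNA(series)) {
    warning("missing values dropped in count_peaks")
    series <- series[!is.na(series)]
  }
  if (length(series) < 3L) stop("need at least 3 points")
  y <- rle(series)$values
  n <- length(y)
  if (n < 3L) return(0L)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  if (prominence <= 0) return(length(idx))
  keep <- vapply(idx, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1)]
    hi <- which(left > h)
    lbase <- min(left[seq(from = if (length(hi)) max(hi) else 1L,
                          to = p - 1L)])
    right <- y[(p + 1L):n]
    hi <- which(right > h)
    rbase <- min(right[seq_len(if (length(hi)) min(hi) else length(right))])
    (h - max(lbase, rbase)) > prominence
  }, logical(1))
  sum(keep)
}

.mad_raw <- function(x) stats::median(abs(x - stats::median(x)))

#' Aggregate per-time measures of one cell into the 26-feature vector
#'
#' Computes the median, raw median absolute deviation (no consistency
#' factor), and the 25th and 75th percentiles (linear interpolation,
#' `quantile` type 7) of each of the six quantities, plus the peak counts
#' of the curvature and torsion series. Missing values (e.g. torsion on
#' near-straight segments) are ignored in the order statistics.
#'
#' @param measures named list with numeric vectors `speed`, `curvature`,
#'   `torsion`, `shape_change_rate`, `E_xy`, `E_xz`. The vectors may have
#'   different lengths (movement quantities are typically sampled on the
#'   dense smoothed grid, shape quantities only at observed mesh times).
#' @param min_timepoints minimum number of observed shape time points
#'   (length of `E_xy`); cells below it are refused, mirroring the
#'   minimal-six-consecutive-time-points inclusion rule.
#' @return named numeric vector of length 26 (see [feature_names()]).
#' @export
aggregate_features <- function(measures, min_timepoints = 6L) {
  miss <- setdiff(.FEATURE_QUANTITIES, names(measures))
  if (length(miss)) stop("missing measures: ", paste(miss, collapse = ", "))
  if (length(measures$E_xy) < min_timepoints)
    stop("cell excluded: ", length(measures$E_xy),
         " shape time points < required ", min_timepoints)
  out <- numeric(0)
  for (q in .FEATURE_QUANTITIES) {
    x <- measures[[q]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) stop("no non-missing values for ", q)
    qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    out <- c(out, stats::median(x), .mad_raw(x), qs[1], qs[2])
  }
  out <- c(out,
           suppressWarnings(count_peaks(measures$curvature)),
           suppressWarnings(count_peaks(measures$torsion)))
  stats::setNames(out, feature_names())
}

#' Standardize a feature table to zero mean, unit sd columns
#'
#' @param table numeric matrix or data.frame (rows = cells), >= 2 rows.
#'   Constant columns are dropped with a warning.
#' @return object of class `feature_table`: `features` (standardized
#'   matrix), `center`, `scale` (named constants for inversion),
#'   `dropped` (names of removed constant columns).
#' @export
standardize_table <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 2L) stop("need at least 2 rows to standardize")
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped))
    warning("constant columns dropped: ", paste(dropped, collapse = ", "))
  x <- x[, sds > 0, drop = FALSE]
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  z <- scale(x, center = ctr, scale = scl)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  structure(list(features = z, center = ctr, scale = scl, dropped = dropped),
            class = "feature_table")
}

.feature_matrix <- function(x) {
  if (inherits(x, "feature_table")) x$features else as.matrix(x)
}

#' Kendall rank correlation matrix of a feature table
#'
#' Tie-corrected (tau-b) Kendall correlations between all feature columns.
#'
#' @param table a `feature_table` or numeric matrix with >= 3 rows.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
kendall_matrix <- function(table) {
  x <- .feature_matrix(table)
  if (nrow(x) < 3L) stop("need at least 3 rows")
  stats::cor(x, method = "kendall")
}

# smooth-knn bandwidth calibration: find sigma with
# sum_j exp(-max(0, d_j - rho) / sigma) = log2(k)
.smooth_knn_sigma <- function(d, rho, target) {
  lo <- 0; hi <- Inf; mid <- 1
  for (iter in 1:64) {
    val <- sum(exp(-pmax(0, d - rho) / mid))
    if (abs(val - target) < 1e-5) break
    if (val > target) { hi <- mid; mid <- (lo + hi) / 2 }
    else { lo <- mid; mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2 }
  }
  mid
}

.umap_ab <- function(min_dist, spread = 1) {
  d <- seq(0, spread * 3, length.out = 300)[-1]
  target <- ifelse(d <= min_dist, 1, exp(-(d - min_dist) / spread))
  fit <- tryCatch(
    stats::nls(target ~ 1 / (1 + a * d^(2 * b)),
               start = list(a = 1.5, b = 0.9)),
    error = function(e) NULL)
  if (is.null(fit)) return(c(a = 1.577, b = 0.8951))
  stats::setNames(stats::coef(fit), c("a", "b"))
}

#' Embed a feature table in 2D (UMAP-style)
#'
#' Uniform-manifold-style nonlinear embedding: a fuzzy k-nearest-neighbour
#' graph with smooth-knn bandwidth calibration and probabilistic-union
#' symmetrization, a spectral (normalized graph Laplacian) initialization,
#' and stochastic gradient refinement with negative sampling of the usual
#' `1 / (1 + a d^(2b))` low-dimensional kernel, with `a`, `b` fitted from
#' `min_dist`. Deterministic for a fixed `seed`.
#'
#' @param table a `feature_table` or numeric matrix (rows = cells).
#' @param n_neighbors neighbourhood size (default 20; must be < rows).
#' @param min_dist minimum embedding distance parameter (default 0.1).
#' @param metric only `"euclidean"` is implemented.
#' @param n_epochs gradient epochs (default 200).
#' @param seed integer RNG seed (recorded in the result).
#' @return `n x 2` matrix with attribute `seed`.
#' @export
embed_2d <- function(table, n_neighbors = 20L, min_dist = 0.1,
                     metric = "euclidean", n_epochs = 200L, seed = 1L) {
  metric <- match.arg(metric)
  X <- .feature_matrix(table)
  n <- nrow(X)
  if (n <= n_neighbors)
    stop("parameter error: need more rows (", n, ") than n_neighbors (",
         n_neighbors, ")")
  set.seed(seed)
  D <- as.matrix(stats::dist(X))
  P <- matrix(0, n, n)
  target <- log2(n_neighbors)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    nb <- setdiff(ord, i)[seq_len(n_neighbors)]
    d <- D[i, nb]
    rho <- min(d[d > 0], Inf)
    if (!is.finite(rho)) rho <- 0
    sig <- .smooth_knn_sigma(d, rho, target)
    P[i, nb] <- exp(-pmax(0, d - rho) / sig)
  }
  P <- P + t(P) - P * t(P)

  # spectral initialization from the symmetric normalized Laplacian
  deg <- pmax(rowSums(P), 1e-12)
  Lsym <- diag(n) - (P / sqrt(deg)) / rep(sqrt(deg), each = n)
  eig <- eigen(Lsym, symmetric = TRUE)
  emb <- eig$vectors[, c(n - 1L, n - 2L), drop = FALSE]
  emb <- emb / max(abs(emb)) * 10
  emb <- emb + matrix(stats::rnorm(2 * n, sd = 1e-4), n, 2L)

  ab <- .umap_ab(min_dist)
  a <- ab["a"]; b <- ab["b"]
  ut <- which(upper.tri(P) & P > 0, arr.ind = TRUE)
  w <- P[ut]
  eps <- max(w) / n_epochs
  keep <- w >= eps
  ut <- ut[keep, , drop = FALSE]; w <- w[keep]
  eps_per <- max(w) / w  # epochs between updates of each edge
  next_due <- eps_per
  neg_rate <- 5L
  for (epoch in seq_len(n_epochs)) {
    alpha <- 1 - (epoch - 1) / n_epochs
    due <- which(next_due <= epoch)
    for (e in due) {
      i <- ut[e, 1]; j <- ut[e, 2]
      diff <- emb[i, ] - emb[j, ]
      d2 <- sum(diff^2)
      if (d2 > 0) {
        g <- (-2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
        gv <- pmin(4, pmax(-4, g * diff))
        emb[i, ] <- emb[i, ] + alpha * gv
        emb[j, ] <- emb[j, ] - alpha * gv
      }
      for (s in seq_len(neg_rate)) {
        k <- sample.int(n, 1L)
        if (k == i) next
        diff <- emb[i, ] - emb[k, ]
        d2 <- sum(diff^2)
        g <- (2 * b) / ((0.001 + d2) * (1 + a * d2^b))
        gv <- pmin(4, pmax(-4, g * diff))
        emb[i, ] <- emb[i, ] + alpha * gv
      }
      next_due[e] <- next_due[e] + eps_per[e]
    }
  }
  dimnames(emb) <- list(rownames(X), c("dim1", "dim2"))
  attr(emb, "seed") <- seed
  emb
}

.stratified_folds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  if (any(table(labels) < folds))
    stop("stratification error: every class needs >= ", folds, " members")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated KNN accuracy
#'
#' K-nearest-neighbour classification accuracy (fraction of correct
#' classifications) per fold and per `k`, with folds stratified by class
#' and seeded for reproducibility.
#'
#' @param table a `feature_table` or numeric matrix.
#' @param labels class labels (one per row; every class needs >= `folds`
#'   members).
#' @param k integer vector of neighbour counts (default
#'   `c(3, 5, 10, 15, 20, 25)`).
#' @param folds number of folds (default 10).
#' @param seed RNG seed controlling the fold partition and tie breaking.
#' @return data.frame with columns `k`, `fold`, `accuracy`; attribute
#'   `folds` stores the fold assignment so a paired comparison can reuse
#'   the identical partition.
#' @export
knn_cv <- function(table, labels, k = c(3L, 5L, 10L, 15L, 20L, 25L),
                   folds = 10L, seed = 1L) {
  x <- .feature_matrix(table)
  labels <- as.factor(labels)
  stopifnot(nrow(x) == length(labels))
  fold <- .stratified_folds(labels, folds, seed)
  res <- expand.grid(k = k, fold = seq_len(folds))
  res$accuracy <- NA_real_
  for (r in seq_len(nrow(res))) {
    te <- fold == res$fold[r]
    if (res$k[r] >= sum(!te)) {
      warning("k = ", res$k[r], " >= training size; fold skipped")
      next
    }
    set.seed(seed + res$fold[r])  # deterministic tie breaking
    pred <- class::knn(x[!te, , drop = FALSE], x[te, , drop = FALSE],
                       labels[!te], k = res$k[r])
    res$accuracy[r] <- mean(pred == labels[te])
  }
  attr(res, "folds") <- fold
  attr(res, "seed") <- seed
  res
}

#' One-sample t-test on paired per-fold accuracy differences
#'
#' Tests whether the per-fold accuracy difference between two classifiers
#' (evaluated on the same fold partition) differs from zero; two-sided.
#'
#' @param acc_a,acc_b numeric accuracy vectors of equal length >= 2.
#' @return list with `mean_difference`, `statistic`, `df`, `p_value`.
#' @export
paired_accuracy_ttest <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 2L)
  d <- acc_a - acc_b
  if (stats::sd(d) == 0) {
    warning("zero-variance accuracy differences; p-value undefined")
    return(list(mean_difference = mean(d), statistic = if (mean(d) == 0) 0
                else sign(mean(d)) * Inf, df = length(d) - 1L,
                p_value = NA_real_))
  }
  tt <- stats::t.test(d, mu = 0)
  list(mean_difference = unname(tt$estimate), statistic = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value)
}

#' Permutation importance of features for a KNN classifier
#'
#' Importance of a feature is the mean drop in held-out accuracy when that
#' feature column of the held-out set is shuffled, over `n_repeats`
#' seeded shuffles.
#'
#' @param train,test numeric feature matrices.
#' @param train_labels,test_labels class labels.
#' @param k KNN neighbour count (default 5).
#' @param n_repeats shuffles per feature (default 10).
#' @param seed RNG seed.
#' @return named numeric vector of importances (baseline accuracy stored
#'   in attribute `baseline`).
#' @export
permutation_importance <- function(train, train_labels, test, test_labels,
                                   k = 5L, n_repeats = 10L, seed = 1L) {
  train <- as.matrix(train); test <- as.matrix(test)
  train_labels <- as.factor(train_labels)
  test_labels <- factor(test_labels, levels = levels(train_labels))
  set.seed(seed)
  base_acc <- mean(class::knn(train, test, train_labels, k = k) == test_labels)
  imp <- numeric(ncol(test))
  for (j in seq_len(ncol(test))) {
    accs <- vapply(seq_len(n_repeats), function(r) {
      perm <- test
      perm[, j] <- sample(perm[, j])
      mean(class::knn(train, perm, train_labels, k = k) == test_labels)
    }, numeric(1))
    imp[j] <- base_acc - mean(accs)
  }
  stats::setNames(imp, colnames(test))
  structure(stats::setNames(imp, colnames(test)), baseline = base_acc)
}
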