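# End-to-end orchestration: a mesh time series in, joint shape-movement
# quantification out. fit_cell() is the central fitting function; its
# result behaves like a fitted model object (print, summary, coef,
# predict, plot, residuals). run_cohort() maps fit_cell over cells and
# runs the downstream statistics.

.identity_frame <- function(origin) {
  list(T = c(1, 0, 0), N = c(0, 1, 0), B = c(0, 0, 1), origin = origin)
}

#' Fit the joint shape-movement model to one cell
#'
#' Runs the full pipeline on a time series of closed genus-0 meshes:
#' mass-center extraction, GP trajectory smoothing, parallel-transport
#' moving frames, reorientation of each mesh into its frame (so the
#' direction of motion becomes the x-axis), volume normalization,
#' mean-curvature-flow spherical parameterization, least-squares real
#' spherical-harmonic fitting, eccentricity indices, shape-change rates,
#' movement features (speed, curvature, torsion) and the aggregated
#' 26-feature vector.
#'
#' Meshes that are not closed genus-0 are excluded with a warning; at
#' least `min_timepoints` valid meshes are required.
#'
#' @param meshes list of [triangle_mesh()] objects, time-ordered.
#' @param times numeric time stamps (default: the meshes' `time_index`).
#' @param basis `"moving"` (parallel-transport frames) or `"standard"`
#'   (identity frames at the mesh mass centers, i.e. no realignment).
#' @param gp a [gp_config()].
#' @param l_max spherical-harmonic expansion degree (default 6).
#' @param mcf_step,mcf_max_iters,mcf_tol passed to
#'   [mcf_spherical_parameterization()].
#' @param normal0 initial-normal rule passed to
#'   [parallel_transport_frames()].
#' @param min_timepoints minimum usable time points (default 6).
#' @param cell_id identifier carried into outputs.
#' @return An object of class `cell_fit` with components `raw`, `smooth`,
#'   `movement` (dense data.frame), `frames`, `coefficients` (list of
#'   `sh_coefficients`), `per_time` (data.frame of per-observation
#'   measures), `features` (named length-26 vector), `excluded`
#'   (data.frame of skipped meshes) and metadata.
#' @seealso [run_cohort()], [generate_dataset()]
#' @export
fit_cell <- function(meshes, times = NULL,
                     basis = c("moving", "standard"),
                     gp = gp_config(), l_max = 6L,
                     mcf_step = NULL, mcf_max_iters = 500L, mcf_tol = 0.02,
                     normal0 = "acceleration",
                     min_timepoints = 6L, cell_id = "cell") {
  basis <- match.arg(basis)
  if (is.null(times))
    times <- vapply(meshes, function(m) as.numeric(m$time_index), numeric(1))
  stopifnot(length(times) == length(meshes))
  ord <- order(times)
  meshes <- meshes[ord]; times <- times[ord]

  ok <- vapply(meshes, check_spherical_topology, logical(1))
  excluded <- data.frame(time = times[!ok],
                         reason = rep("not closed genus-0", sum(!ok)))
  if (any(!ok))
    warning(cell_id, ": excluded ", sum(!ok),
            " mesh(es) failing the spherical-topology requirement")
  meshes <- meshes[ok]; times <- times[ok]
  if (length(meshes) < min_timepoints)
    stop(cell_id, " excluded: ", length(meshes), " usable time points < ",
         min_timepoints)

  centers <- t(vapply(meshes, mass_center, numeric(3)))
  raw <- raw_trajectory(times, centers)
  smooth <- smooth_trajectory(raw, gp)
  movement <- movement_features(smooth)
  frames <- if (basis == "moving")
    parallel_transport_frames(smooth, normal0 = normal0) else NULL

  basis_obj <- sh_basis(l_max)
  coefs <- vector("list", length(meshes))
  ecc <- matrix(NA_real_, length(meshes), 3L,
                dimnames = list(NULL, c("E_xy", "E_xz", "E_yz")))
  sphericity <- numeric(length(meshes))
  for (i in seq_along(meshes)) {
    fr <- if (basis == "moving") frame_at(frames, times[i])
    else .identity_frame(centers[i, ])
    m <- reorient_mesh(meshes[[i]], fr)
    m <- normalize_volume(m)
    map <- mcf_spherical_parameterization(m, step = mcf_step,
                                          max_iters = mcf_max_iters,
                                          tol = mcf_tol)
    coefs[[i]] <- fit_coefficients(map, basis_obj)
    ecc[i, ] <- eccentricities(coefs[[i]])
    sphericity[i] <- map$sphericity
  }
  rates <- shape_change_rate(coefs)

  obs_idx <- match(round(times, 9), round(smooth$times, 9))
  per_time <- data.frame(time = times,
                         speed = movement$speed[obs_idx],
                         curvature = movement$curvature[obs_idx],
                         torsion = movement$torsion[obs_idx],
                         E_xy = ecc[, 1], E_xz = ecc[, 2], E_yz = ecc[, 3],
                         shape_change_rate = c(rates, NA_real_),
                         mcf_sphericity = sphericity)

  features <- aggregate_features(
    list(speed = movement$speed, curvature = movement$curvature,
         torsion = movement$torsion, shape_change_rate = rates,
         E_xy = ecc[, 1], E_xz = ecc[, 2]),
    min_timepoints = min_timepoints)

  structure(list(cell_id = cell_id, basis = basis, times = times,
                 excluded = excluded, raw = raw, smooth = smooth,
                 movement = movement, frames = frames,
                 coefficients = coefs, per_time = per_time,
                 features = features, l_max = l_max,
                 call = match.call()),
            class = "cell_fit")
}

#' @export
print.cell_fit <- function(x, ...) {
  cat(sprintf("cell_fit '%s' (%s basis): %d time points, l_max = %d\n",
              x$cell_id, x$basis, length(x$times), x$l_max))
  cat(sprintf("  median speed %.3g, median E_xy %.3g, median E_xz %.3g\n",
              x$features["speed_median"], x$features["E_xy_median"],
              x$features["E_xz_median"]))
  if (nrow(x$excluded)) cat("  excluded time points:",
                            paste(x$excluded$time, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cell_fit <- function(object, ...) {
  out <- list(cell_id = object$cell_id, basis = object$basis,
              n_timepoints = length(object$times),
              excluded = object$excluded,
              gp_sigma2 = object$smooth$sigma2,
              features = object$features,
              per_time = object$per_time)
  class(out) <- "summary.cell_fit"
  out
}

#' @export
print.summary.cell_fit <- function(x, ...) {
  cat(sprintf("Joint shape-movement fit for '%s' (%s basis)\n", x$cell_id,
              x$basis))
  cat(sprintf("  %d time points; GP noise variance %.3g\n", x$n_timepoints,
              x$gp_sigma2))
  cat("\nPer-cell features (26):\n")
  print(round(x$features, 4))
  invisible(x)
}

#' Shape descriptors of a fitted cell
#'
#' @param object a `cell_fit`.
#' @param ... unused.
#' @return numeric matrix, one row per observed time point, columns the
#'   concatenated descriptor `C = (C_x, C_y, C_z)`.
#' @export
coef.cell_fit <- function(object, ...) {
  mat <- t(vapply(object$coefficients, sh_descriptor,
                  numeric(3 * (object$l_max + 1)^2)))
  rownames(mat) <- object$times
  mat
}

#' Evaluate the smoothed trajectory of a fitted cell
#'
#' @param object a `cell_fit`.
#' @param times numeric times (default: the dense grid).
#' @param ... unused.
#' @return numeric `length(times) x 3` matrix of positions.
#' @export
predict.cell_fit <- function(object, times = object$smooth$times, ...) {
  object$smooth$predict(times)
}

#' Spherical-harmonic fit residuals of a fitted cell
#'
#' @param object a `cell_fit`.
#' @param ... unused.
#' @return matrix (time points x 3) of per-coordinate RMS reconstruction
#'   residuals of the SH expansion.
#' @export
residuals.cell_fit <- function(object, ...) {
  out <- t(vapply(object$coefficients, `[[`, numeric(3), "rms_residual"))
  rownames(out) <- object$times
  out
}

#' Plot the shape-movement time courses of a fitted cell
#'
#' Panels: speed, curvature and torsion on the dense smoothed grid, and
#' the eccentricity indices and shape-change rate at the observed times.
#'
#' @param x a `cell_fit`.
#' @param ... passed to `matplot`/`plot`.
#' @export
plot.cell_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  mv <- x$movement
  graphics::plot(mv$time, mv$speed, type = "l", xlab = "t", ylab = "speed",
                 main = "speed", ...)
  graphics::plot(mv$time, mv$curvature, type = "l", xlab = "t",
                 ylab = "curvature", main = "curvature", ...)
  graphics::plot(mv$time, mv$torsion, type = "l", xlab = "t",
                 ylab = "torsion", main = "torsion", ...)
  pt <- x$per_time
  graphics::plot(pt$time, pt$E_xy, type = "b", xlab = "t", ylab = "E_xy",
                 main = "E_xy", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::plot(pt$time, pt$E_xz, type = "b", xlab = "t", ylab = "E_xz",
                 main = "E_xz", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::plot(pt$time[-nrow(pt)], pt$shape_change_rate[-nrow(pt)],
                 type = "b", xlab = "t", ylab = "d(t, t+1)",
                 main = "shape-change rate", ...)
  invisible(x)
}

#' Analyse a cohort of cells in moving-frame and standard bases
#'
#' Fits every cell in both bases (the runs differ only in the
#' reorientation step), assembles the two 26-feature tables, and runs the
#' statistical battery: column standardization, Kendall correlation, 2D
#' embedding, stratified tenfold KNN cross-validation per basis on
#' identical fold partitions, paired one-sample t-tests of the per-fold
#' accuracy differences, and KNN permutation importance on the
#' moving-frame features.
#'
#' @param cells list; each element either a list with `meshes` (and
#'   optionally `times`), e.g. a [generate_dataset()] result, or a plain
#'   list of meshes.
#' @param labels group labels, one per cell; `NULL` skips the
#'   classification steps.
#' @param k KNN neighbour counts (values too large for the training folds
#'   are dropped with a message).
#' @param folds cross-validation folds (default 10).
#' @param seed seed for folds, embedding and permutations.
#' @param n_neighbors embedding neighbourhood size (reduced to
#'   `n cells - 1` when necessary).
#' @param ... passed on to [fit_cell()].
#' @return object of class `cohort_analysis`: `features_moving`,
#'   `features_standard` (raw feature matrices), `tables` (standardized
#'   `feature_table`s), `kendall`, `embedding`, `cv` (per-basis
#'   [knn_cv()] results), `ttests` (per-k paired tests), `importance`,
#'   `labels`, `seed`, `status` (per-cell fit status).
#' @export
run_cohort <- function(cells, labels = NULL,
                       k = c(3L, 5L, 10L, 15L, 20L, 25L), folds = 10L,
                       seed = 1L, n_neighbors = 20L, ...) {
  n <- length(cells)
  fits_m <- vector("list", n); fits_s <- vector("list", n)
  status <- data.frame(cell = seq_len(n), ok = TRUE, note = "")
  for (i in seq_len(n)) {
    cl <- cells[[i]]
    meshes <- if (!is.null(cl$meshes)) cl$meshes else cl
    id <- sprintf("cell%03d", i)
    res <- tryCatch({
      fits_m[[i]] <- fit_cell(meshes, basis = "moving", cell_id = id, ...)
      fits_s[[i]] <- fit_cell(meshes, basis = "standard", cell_id = id, ...)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      status$ok[i] <- FALSE; status$note[i] <- res
      message("cell ", i, " skipped: ", res)
    }
  }
  keep <- status$ok
  if (!is.null(labels)) labels <- factor(labels[keep])
  fm <- do.call(rbind, lapply(fits_m[keep], `[[`, "features"))
  fs <- do.call(rbind, lapply(fits_s[keep], `[[`, "features"))
  rownames(fm) <- rownames(fs) <-
    vapply(fits_m[keep], `[[`, character(1), "cell_id")

  tab_m <- standardize_table(fm)
  tab_s <- standardize_table(fs)
  kend <- kendall_matrix(tab_m)
  nn <- min(n_neighbors, nrow(fm) - 1L)
  emb_m <- embed_2d(tab_m, n_neighbors = nn, seed = seed)
  emb_s <- embed_2d(tab_s, n_neighbors = nn, seed = seed)

  cv <- ttests <- imp <- NULL
  if (!is.null(labels) && nlevels(labels) >= 2L) {
    kk <- k[k < nrow(fm) * (folds - 1) / folds]
    if (length(kk) < length(k))
      message("dropping k > training-fold size: ",
              paste(setdiff(k, kk), collapse = ", "))
    cv_m <- knn_cv(tab_m, labels, k = kk, folds = folds, seed = seed)
    cv_s <- knn_cv(tab_s, labels, k = kk, folds = folds, seed = seed)
    cv <- list(moving = cv_m, standard = cv_s)
    ttests <- lapply(stats::setNames(kk, paste0("k", kk)), function(ki) {
      a <- cv_m$accuracy[cv_m$k == ki]
      b <- cv_s$accuracy[cv_s$k == ki]
      paired_accuracy_ttest(a, b)
    })
    # permutation importance on a stratified 70/30 split
    set.seed(seed)
    te <- unlist(lapply(levels(labels), function(cl) {
      idx <- sample(which(labels == cl))
      idx[seq_len(max(1L, floor(0.3 * length(idx))))]
    }))
    tr <- setdiff(seq_len(nrow(fm)), te)
    imp <- permutation_importance(tab_m$features[tr, , drop = FALSE],
                                  labels[tr],
                                  tab_m$features[te, , drop = FALSE],
                                  labels[te],
                                  k = min(5L, length(tr) - 1L), seed = seed)
  }

  structure(list(features_moving = fm, features_standard = fs,
                 tables = list(moving = tab_m, standard = tab_s),
                 kendall = kend,
                 embedding = list(moving = emb_m, standard = emb_s),
                 cv = cv, ttests = ttests, importance = imp,
                 labels = labels, seed = seed, status = status,
                 fits = list(moving = fits_m[keep],
                             standard = fits_s[keep])),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("cohort_analysis: %d cells (%d skipped), seed %d\n",
              nrow(x$features_moving), sum(!x$status$ok), x$seed))
  if (!is.null(x$cv)) {
    for (b in names(x$cv)) {
      agg <- tapply(x$cv[[b]]$accuracy, x$cv[[b]]$k, mean, na.rm = TRUE)
      cat(sprintf("  mean KNN CV accuracy (%s): %s\n", b,
                  paste(sprintf("k=%s %.3f", names(agg), agg),
                        collapse = ", ")))
    }
  }
  invisible(x)
}

#' Write a cohort feature table to CSV
#'
#' Columns: `cell_id`, `group` (if labelled), then the 26 canonical
#' features of the chosen basis.
#'
#' @param cohort a `cohort_analysis`.
#' @param path output path.
#' @param basis `"moving"` or `"standard"`.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(cohort, path, basis = c("moving", "standard")) {
  basis <- match.arg(basis)
  fm <- if (basis == "moving") cohort$features_moving
  else cohort$features_standard
  df <- data.frame(cell_id = rownames(fm))
  if (!is.null(cohort$labels)) df$group <- cohort$labels
  df <- cbind(df, as.data.frame(fm))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
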