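#' Raw mass-center trajectory
#'
#' @param times strictly increasing numeric time stamps.
#' @param positions numeric `n x 3` matrix of mass centers at `times`.
#' @return An object of class `raw_trajectory`.
#' @export
raw_trajectory <- function(times, positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be n x 3")
  if (length(times) != nrow(positions)) stop("times/positions length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), positions = positions),
            class = "raw_trajectory")
}

#' Gaussian-process smoothing configuration
#'
#' The mass-center sequence of each coordinate is modelled as a zero-mean
#' Gaussian process with squared-exponential kernel
#' `k(t, t') = v * exp(-(t - t')^2 / (2 l^2))` plus i.i.d. Gaussian
#' observation noise of variance `sigma^2`, fitted on the standardized
#' sequence. Defaults follow the kernel used throughout this package:
#' length scale `exp(1)` and signal variance 1, with the length scale
#' expressed in units of the median sampling interval (`time_scale =
#' "interval"`); `"none"` uses raw time units.
#'
#' @param kernel_length_scale positive; SE length scale.
#' @param kernel_variance positive; SE signal variance.
#' @param noise_variance positive numeric, or `"optimize"` to maximize the
#'   marginal likelihood over `sigma^2` with the kernel parameters fixed.
#'   When optimized inside [smooth_trajectory()], a single `sigma^2` is
#'   shared by the three coordinate axes, which keeps the smoother exactly
#'   equivariant under rigid motions of the scene.
#' @param interpolation_factor integer >= 1; number of subintervals each
#'   original sampling interval is split into on the dense output grid
#'   (1 = no interpolation).
#' @param time_scale `"interval"` or `"none"` (see above).
#' @return A list of class `gp_config`.
#' @export
gp_config <- function(kernel_length_scale = exp(1), kernel_variance = 1,
                      noise_variance = "optimize",
                      interpolation_factor = 10L,
                      time_scale = c("interval", "none")) {
  stopifnot(kernel_length_scale > 0, kernel_variance > 0,
            interpolation_factor >= 1L)
  if (is.numeric(noise_variance) && noise_variance <= 0)
    stop("noise_variance must be positive or \"optimize\"")
  structure(list(kernel_length_scale = kernel_length_scale,
                 kernel_variance = kernel_variance,
                 noise_variance = noise_variance,
                 interpolation_factor = as.integer(interpolation_factor),
                 time_scale = match.arg(time_scale)),
            class = "gp_config")
}

#' Standardize a sequence to zero mean and unit standard deviation
#'
#' Uses the sample standard deviation (divide by `n - 1`), the same
#' convention as the feature-table standardization; the stored constants
#' make the choice exactly invertible either way. A constant sequence
#' cannot be standardized; a condition of class
#' `"degenerate_axis_error"` is signalled so the caller can substitute the
#' constant and skip GP fitting for that axis.
#'
#' @param values numeric vector, length >= 2.
#' @return list with `values` (standardized), `mean`, `sd`.
#' @export
standardize_sequence <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  mu <- mean(values)
  sd_pop <- stats::sd(values)
  if (sd_pop == 0)
    stop(structure(class = c("degenerate_axis_error", "error", "condition"),
                   list(message = "constant sequence: standard deviation is zero",
                        call = sys.call(-1))))
  list(values = (values - mu) / sd_pop, mean = mu, sd = sd_pop)
}

#' Invert [standardize_sequence()]
#'
#' @param values standardized numeric vector.
#' @param mean,sd constants returned by [standardize_sequence()].
#' @return numeric vector on the original scale.
#' @export
destandardize_sequence <- function(values, mean, sd) values * sd + mean

.se_kernel <- function(t1, t2, l, v) {
  v * exp(-outer(t1, t2, `-`)^2 / (2 * l^2))
}

# Cholesky with escalating jitter; the SE kernel is near-singular for
# closely spaced inputs.
.chol_jitter <- function(K) {
  jit <- 0
  for (e in c(0, 10^(-10:-4))) {
    R <- tryCatch(chol(K + diag(e * mean(diag(K)), nrow(K))),
                  error = function(err) NULL)
    if (!is.null(R)) {
      if (e > 0) message("GP kernel matrix ill-conditioned; jitter ", e, " added")
      return(R)
    }
  }
  stop("numeric error: kernel matrix singular even after jitter")
}

.gp_loglik <- function(y, K, sigma2) {
  n <- length(y)
  R <- .chol_jitter(K + diag(sigma2, n))
  alpha <- backsolve(R, forwardsolve(t(R), y))
  -0.5 * sum(y * alpha) - sum(log(diag(R))) - 0.5 * n * log(2 * pi)
}

.optimize_sigma2 <- function(ys, K) {
  # ys: list of standardized sequences sharing one kernel matrix
  obj <- function(ls2) -sum(vapply(ys, .gp_loglik, numeric(1),
                                   K = K, sigma2 = exp(ls2)))
  opt <- stats::optimize(obj, interval = c(log(1e-8), log(2)))
  exp(opt$minimum)
}

#' Fit a zero-mean GP posterior mean to a standardized sequence
#'
#' @param times numeric inputs (distinct).
#' @param values standardized observations at `times`.
#' @param config a [gp_config()]. `time_scale` is ignored here: `times`
#'   are used as given.
#' @return A function `f(t)` evaluating the GP posterior mean at arbitrary
#'   inputs, with attributes `sigma2` (noise variance used) and
#'   `loglik` (marginal log-likelihood at that `sigma2`).
#' @export
fit_gp <- function(times, values, config = gp_config()) {
  stopifnot(length(times) == length(values))
  if (anyDuplicated(times)) stop("times must be distinct")
  l <- config$kernel_length_scale; v <- config$kernel_variance
  K <- .se_kernel(times, times, l, v)
  sigma2 <- if (identical(config$noise_variance, "optimize"))
    .optimize_sigma2(list(values), K) else config$noise_variance
  R <- .chol_jitter(K + diag(sigma2, length(times)))
  alpha <- backsolve(R, forwardsolve(t(R), values))
  f <- function(t) drop(.se_kernel(t, times, l, v) %*% alpha)
  attr(f, "sigma2") <- sigma2
  attr(f, "loglik") <- .gp_loglik(values, K, sigma2)
  f
}

#' Smooth a mass-center trajectory with per-axis GP regression
#'
#' Each coordinate sequence is standardized (zero mean, unit sd), fitted
#' with a zero-mean squared-exponential GP, evaluated on a dense grid (the
#' original times plus `interpolation_factor - 1` equally spaced points per
#' interval), and destandardized by multiplying by the stored sd and adding
#' back the mean. A constant axis is carried through unchanged (GP
#' skipped). When `noise_variance = "optimize"` a single noise variance is
#' chosen for all three axes by maximizing the summed marginal likelihood.
#'
#' @param raw a [raw_trajectory()] (>= 2 samples; >= 6 for downstream
#'   moving-frame analysis).
#' @param config a [gp_config()].
#' @return An object of class `smooth_trajectory`: `times` (dense grid),
#'   `points` (dense n x 3), `sample_times`, `standardization` (3 x 2),
#'   `sigma2`, `predict(t)` closure evaluating the smooth curve anywhere.
#' @export
smooth_trajectory <- function(raw, config = gp_config()) {
  stopifnot(inherits(raw, "raw_trajectory"))
  t_obs <- raw$times
  scale_t <- if (config$time_scale == "interval")
    stats::median(diff(t_obs)) else 1
  u_obs <- t_obs / scale_t

  std <- vector("list", 3L)
  for (i in 1:3) {
    std[[i]] <- tryCatch(standardize_sequence(raw$positions[, i]),
                         degenerate_axis_error = function(e)
                           list(values = NULL,
                                mean = raw$positions[1, i], sd = 0))
  }
  live <- which(vapply(std, function(s) s$sd > 0, logical(1)))
  if (length(live) == 0L) stop("stationary trajectory: all axes constant")

  l <- config$kernel_length_scale; v <- config$kernel_variance
  K <- .se_kernel(u_obs, u_obs, l, v)
  # The shared noise variance is estimated from the centered sequences
  # scaled by one common factor (the root-mean per-axis variance): the
  # summed Gaussian marginal likelihood then depends on the data only
  # through Y Y^T, so the estimate -- and with it the whole smoother --
  # is exactly invariant under rigid motions of the scene.
  sigma2 <- if (identical(config$noise_variance, "optimize")) {
    s_common <- sqrt(mean(vapply(std[live], function(s) s$sd^2, numeric(1))))
    ys <- lapply(std[live], function(s) s$values * s$sd / s_common)
    .optimize_sigma2(ys, K)
  } else config$noise_variance
  cfg_fixed <- config
  cfg_fixed$noise_variance <- sigma2
  fs <- lapply(std, function(s) {
    if (s$sd == 0) return(NULL)
    fit_gp(u_obs, s$values, cfg_fixed)
  })

  F_ <- config$interpolation_factor
  dense <- unlist(lapply(seq_len(length(t_obs) - 1L), function(i) {
    t_obs[i] + (t_obs[i + 1L] - t_obs[i]) * (seq_len(F_) - 1L) / F_
  }))
  dense <- c(dense, t_obs[length(t_obs)])

  pred <- function(t) {
    out <- matrix(NA_real_, length(t), 3L)
    for (i in 1:3) {
      out[, i] <- if (is.null(fs[[i]])) rep(std[[i]]$mean, length(t))
      else destandardize_sequence(fs[[i]](t / scale_t),
                                  std[[i]]$mean, std[[i]]$sd)
    }
    colnames(out) <- c("x", "y", "z")
    out
  }

  structure(list(times = dense, points = pred(dense),
                 sample_times = t_obs,
                 standardization = cbind(
                   mean = vapply(std, `[[`, numeric(1), "mean"),
                   sd = vapply(std, `[[`, numeric(1), "sd")),
                 sigma2 = sigma2, config = config, predict = pred),
            class = "smooth_trajectory")
}

#' @export
print.smooth_trajectory <- function(x, ...) {
  cat(sprintf(paste0("smooth_trajectory: %d samples -> %d dense points, ",
                     "sigma2 = %.3g\n"),
              length(x$sample_times), length(x$times), x$sigma2))
  invisible(x)
}

# second-order finite-difference gradient on a (possibly non-uniform)
# grid; one-sided three-point formulas keep the ends second-order too
.fd_gradient <- function(y, x) {
  n <- length(x)
  g <- numeric(n)
  hs <- diff(x)
  if (n < 2L) return(g)
  if (n == 2L) {
    g[] <- (y[2] - y[1]) / hs[1]
    return(g)
  }
  h1 <- hs[1]; h2 <- hs[2]
  g[1] <- -(2 * h1 + h2) / (h1 * (h1 + h2)) * y[1] +
    (h1 + h2) / (h1 * h2) * y[2] - h1 / (h2 * (h1 + h2)) * y[3]
  h1 <- hs[n - 2L]; h2 <- hs[n - 1L]
  g[n] <- h2 / (h1 * (h1 + h2)) * y[n - 2L] -
    (h1 + h2) / (h1 * h2) * y[n - 1L] +
    (h1 + 2 * h2) / (h2 * (h1 + h2)) * y[n]
  i <- 2:(n - 1)
  h1 <- hs[i - 1]; h2 <- hs[i]
  g[i] <- (h1^2 * y[i + 1] - (h1^2 - h2^2) * y[i] - h2^2 * y[i - 1]) /
    (h1 * h2 * (h1 + h2))
  g
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Speed, curvature and torsion of a smooth trajectory
#'
#' Speed is the distance travelled per unit time, `|r'|`; curvature
#' `kappa = |r' x r''| / |r'|^3` measures deviation from a straight line;
#' torsion `tau = (r' x r'') . r''' / |r' x r''|^2` measures deviation
#' from a planar curve. Derivatives are central finite differences on the
#' dense grid (one-sided at the ends). Where the speed is numerically zero
#' the curvature and torsion are reported `NA`; torsion is also `NA` where
#' `|r' x r''| < 1e-8 * |r'|^3` (near-straight segments, where torsion is
#' not identifiable).
#'
#' @param smooth a [smooth_trajectory()] with >= 5 dense points.
#' @return data.frame with columns `time`, `speed`, `curvature`, `torsion`.
#' @export
movement_features <- function(smooth) {
  stopifnot(inherits(smooth, "smooth_trajectory"))
  x <- smooth$times
  if (length(x) < 5L) stop("need at least 5 dense points")
  r <- smooth$points
  d1 <- apply(r, 2L, .fd_gradient, x = x)
  d2 <- apply(d1, 2L, .fd_gradient, x = x)
  d3 <- apply(d2, 2L, .fd_gradient, x = x)
  speed <- sqrt(rowSums(d1^2))
  cr <- .cross3(d1, d2)
  ncr <- sqrt(rowSums(cr^2))
  kappa <- ncr / speed^3
  tau <- rowSums(cr * d3) / ncr^2
  still <- speed < 1e-12
  kappa[still] <- NA_real_
  speed[still] <- 0
  tau[still | ncr < 1e-8 * pmax(speed, 1e-300)^3] <- NA_real_
  data.frame(time = x, speed = speed, curvature = kappa, torsion = tau)
}

#' Write a smooth trajectory (with movement features) to CSV
#'
#' Columns: `cell_id`, `t`, `x`, `y`, `z`, `speed`, `curvature`, `torsion`.
#'
#' @param smooth a [smooth_trajectory()].
#' @param path output CSV path.
#' @param cell_id identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(smooth, path, cell_id = "cell") {
  mf <- movement_features(smooth)
  df <- data.frame(cell_id = cell_id, t = smooth$times,
                   x = smooth$points[, 1], y = smooth$points[, 2],
                   z = smooth$points[, 3],
                   speed = mf$speed, curvature = mf$curvature,
                   torsion = mf$torsion)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a raw trajectory from CSV
#'
#' Expects header columns `t`, `x`, `y`, `z` (a `cell_id` column, if
#' present, must contain a single id).
#'
#' @param path CSV path.
#' @return A [raw_trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t", "x", "y", "z") %in% names(df)))
    stop("trajectory CSV must have columns t, x, y, z")
  if ("cell_id" %in% names(df) && length(unique(df$cell_id)) > 1L)
    stop("trajectory CSV contains multiple cell ids")
  df <- df[order(df$t), , drop = FALSE]
  raw_trajectory(df$t, as.matrix(df[, c("x", "y", "z")]))
}
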