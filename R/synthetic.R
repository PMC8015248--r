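# Synthetic moving-cell generator.
# Emulates a near-spherical cell of unit volume moving along a smooth 3D
# path with an accelerate-decelerate-accelerate-decelerate speed profile,
# protruding a pseudopod along the direction of motion while accelerating
# and relaxing back toward a sphere while decelerating. Every emitted
# quantity has known ground truth, so each pipeline stage can be validated
# without external data.

#' Synthetic cell configuration
#'
#' Defaults encode the reference simulation: 250 unit-spaced time points
#' of which `t = 1, 10, 20, ..., 250` (26 points) are observed; a two-bump
#' speed profile (accelerate-decelerate twice); one smooth change of
#' heading between t = 100 and t = 130; a velocity-locked pseudopod whose
#' protrusion length is `pseudopod_amplitude * speed / max speed` cell
#' radii; low-order spherical-harmonic surface noise of amplitude 0.02;
#' meshes of unit volume.
#'
#' @param n_timepoints number of ground-truth time points (default 250).
#' @param observed_times subset of `1:n_timepoints` emitted as meshes
#'   (default `c(1, seq(10, 250, 10))`, 26 points).
#' @param base_speed baseline speed, cell radii per time unit.
#' @param bump_amplitudes,bump_centers,bump_widths two-bump Gaussian speed
#'   profile parameters.
#' @param turn_angle total heading change (radians) of the mid-course
#'   direction change.
#' @param turn_center,turn_width centre and width (time units) of the
#'   direction change.
#' @param elevation_amplitude amplitude (radians) of the slow out-of-plane
#'   heading oscillation (gives the path nonzero torsion).
#' @param pseudopod_amplitude maximum protrusion length in cell radii
#'   (default 0.6).
#' @param pseudopod_cap angular radius (radians) of the protruding cap
#'   around the motion direction.
#' @param subdivisions icosphere subdivision level of emitted meshes.
#' @param noise_amplitude radial surface-noise amplitude (relative).
#' @param heading initial heading: length-3 direction or `"random"` (one
#'   seeded random direction per cell).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of class `synthetic_cell_config`.
#' @export
synthetic_cell_config <- function(n_timepoints = 250L,
                                  observed_times = c(1L, seq(10L, 250L, 10L)),
                                  base_speed = 0.2,
                                  bump_amplitudes = c(0.8, 0.8),
                                  bump_centers = c(65, 190),
                                  bump_widths = c(28, 28),
                                  turn_angle = 2.0,
                                  turn_center = 115,
                                  turn_width = 12,
                                  elevation_amplitude = 0.35,
                                  pseudopod_amplitude = 0.6,
                                  pseudopod_cap = pi / 3,
                                  subdivisions = 3L,
                                  noise_amplitude = 0.02,
                                  heading = c(1, 0, 0),
                                  seed = 1L) {
  observed_times <- as.integer(observed_times)
  if (!all(observed_times %in% seq_len(n_timepoints)))
    stop("observed_times must be a subset of 1..n_timepoints")
  structure(as.list(environment()), class = "synthetic_cell_config")
}

.smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

#' True speed profile of a synthetic cell
#'
#' @param t numeric times.
#' @param config a [synthetic_cell_config()].
#' @return numeric speeds (cell radii per time unit).
#' @export
synthetic_speed <- function(t, config) {
  v <- rep(config$base_speed, length(t))
  for (b in seq_along(config$bump_amplitudes))
    v <- v + config$bump_amplitudes[b] *
      exp(-(t - config$bump_centers[b])^2 / (2 * config$bump_widths[b]^2))
  v
}

# heading direction (unit) as a function of time, before the initial-
# heading rotation: the azimuth drifts slowly and both azimuth and
# elevation take one smooth turn around turn_center, so the single
# mid-course direction change is fully three-dimensional and produces a
# curvature peak and a torsion peak there (the osculating plane rotates
# through the turn)
.synthetic_heading_base <- function(t, config) {
  n <- config$n_timepoints
  s <- .smoothstep((t - config$turn_center + 1.5 * config$turn_width) /
                     (3 * config$turn_width))
  psi <- 0.3 * sin(2 * pi * t / (2.5 * n)) + config$turn_angle * s
  eta <- config$elevation_amplitude * s
  cbind(cos(eta) * cos(psi), cos(eta) * sin(psi), sin(eta))
}

# rotation aligning the base path's initial heading with config$heading
.heading_rotation <- function(config) {
  h <- config$heading
  if (identical(h, "random")) {
    set.seed(config$seed)
    h <- stats::rnorm(3)
  }
  h <- h / sqrt(sum(h^2))
  d0 <- .synthetic_heading_base(1, config)[1, ]
  ax <- drop(.cross3(rbind(d0), rbind(h)))
  na <- sqrt(sum(ax^2))
  if (na > 1e-12)
    rotation_matrix(ax / na, acos(max(-1, min(1, sum(d0 * h)))))
  else if (sum(d0 * h) < 0) rotation_matrix(initial_normal(d0), pi)
  else diag(3)
}

.synthetic_fine_grid <- function(config) seq(1, config$n_timepoints, by = 0.1)

.make_path_fine <- function(config) {
  tfine <- .synthetic_fine_grid(config)
  dir <- .synthetic_heading_base(tfine, config)
  vel <- dir * synthetic_speed(tfine, config)
  dt <- diff(tfine)
  steps <- (vel[-1, , drop = FALSE] + vel[-nrow(vel), , drop = FALSE]) / 2 * dt
  pos <- rbind(0, apply(steps, 2L, cumsum))
  pos %*% t(.heading_rotation(config))
}

#' Ground-truth path of a synthetic cell
#'
#' Integrates the heading direction times the speed profile on a fine grid
#' (trapezoidal rule), yielding a C2 space curve whose speed matches
#' [synthetic_speed()] and whose heading changes smoothly by `turn_angle`
#' radians around `turn_center`, rotated so the initial heading is
#' `config$heading`.
#'
#' @param config a [synthetic_cell_config()].
#' @param times evaluation times within `[1, n_timepoints]`
#'   (default `1:n_timepoints`).
#' @return numeric `length(times) x 3` matrix of positions.
#' @export
make_path <- function(config, times = seq_len(config$n_timepoints)) {
  tfine <- .synthetic_fine_grid(config)
  pos <- .make_path_fine(config)
  idx <- vapply(times, function(tt) which.min(abs(tfine - tt)), integer(1))
  if (max(abs(tfine[idx] - times)) > 0.05 + 1e-9)
    stop("degenerate spec: requested times outside the simulated range")
  pos[idx, , drop = FALSE]
}

#' Build one synthetic cell mesh
#'
#' A subdivided icosphere whose vertices within an angular cap around the
#' motion direction are displaced radially outward by a smooth bump scaled
#' by the velocity-locked protrusion law, with seeded low-order
#' spherical-harmonic radial surface noise, rescaled to unit enclosed
#' volume and translated to `center`.
#'
#' @param center length-3 position of the mass center.
#' @param direction unit length-3 motion direction.
#' @param speed instantaneous speed.
#' @param max_speed maximum speed over the track (protrusion normalizer).
#' @param config a [synthetic_cell_config()].
#' @param noise_coeffs optional precomputed degree 1..4 SH noise
#'   coefficients (one fresh draw per mesh when `NULL`).
#' @param time_index time stamp attached to the mesh.
#' @return A unit-volume [triangle_mesh()] whose vertex mean is exactly
#'   `center`.
#' @export
make_cell_mesh <- function(center, direction, speed, max_speed, config,
                           noise_coeffs = NULL, time_index = NA_integer_) {
  direction <- direction / sqrt(sum(direction^2))
  m <- icosphere(config$subdivisions)
  u <- m$vertices  # unit vectors
  protrusion <- config$pseudopod_amplitude * speed / max_speed
  ang <- acos(pmin(1, pmax(-1, u %*% direction)))
  bump <- ifelse(ang < config$pseudopod_cap,
                 cos(pi * ang / (2 * config$pseudopod_cap))^2, 0)
  r <- 1 + protrusion * drop(bump)
  if (config$noise_amplitude > 0) {
    if (is.null(noise_coeffs))
      noise_coeffs <- stats::rnorm(sh_basis(4L)$k - 1)
    angs <- sphere_angles(u)
    Y <- sh_design_matrix(angs$theta, angs$phi, sh_basis(4L))
    noise <- drop(Y[, -1, drop = FALSE] %*% noise_coeffs)
    r <- r * (1 + config$noise_amplitude * noise / max(abs(noise)))
  }
  v <- u * r
  mesh <- normalize_volume(triangle_mesh(v, m$faces, time_index))
  v <- sweep(mesh$vertices, 2L, colMeans(mesh$vertices))
  triangle_mesh(sweep(v, 2L, center, `+`), m$faces, time_index)
}

#' Generate a synthetic moving-cell dataset with ground truth
#'
#' Emits meshes at the observed time points and the full ground truth
#' (positions, speed, heading, curvature and torsion of the true path at
#' every time point). Deterministic for a fixed `config$seed`; two seeds
#' share the same path skeleton (for equal non-random parameters) but
#' differ in surface noise.
#'
#' @param config a [synthetic_cell_config()].
#' @param dir optional output directory; when given, meshes are written as
#'   OBJ (`<cell_id>_t<index>.obj`) together with `manifest.csv` and
#'   `ground_truth.csv`.
#' @param cell_id identifier used in file names and the manifest.
#' @return list with `meshes` (list of [triangle_mesh()] at
#'   `observed_times`), `observed_times`, `truth` (data.frame with `t`,
#'   `x`, `y`, `z`, `speed`, `curvature`, `torsion`, heading columns) and
#'   `config`.
#' @export
generate_dataset <- function(config = synthetic_cell_config(), dir = NULL,
                             cell_id = "cell") {
  all_t <- seq_len(config$n_timepoints)
  path <- make_path(config, all_t)
  colnames(path) <- c("x", "y", "z")
  speed <- synthetic_speed(all_t, config)
  heading <- .synthetic_heading_base(all_t, config) %*%
    t(.heading_rotation(config))

  # true curvature/torsion by finite differences on the fine analytic path
  tfine <- .synthetic_fine_grid(config)
  fine <- .make_path_fine(config)
  d1 <- apply(fine, 2L, .fd_gradient, x = tfine)
  d2 <- apply(d1, 2L, .fd_gradient, x = tfine)
  d3 <- apply(d2, 2L, .fd_gradient, x = tfine)
  sp_f <- sqrt(rowSums(d1^2))
  cr <- .cross3(d1, d2)
  ncr <- sqrt(rowSums(cr^2))
  kap <- ncr / sp_f^3
  tau <- rowSums(cr * d3) / ncr^2
  idx <- vapply(all_t, function(tt) which.min(abs(tfine - tt)), integer(1))
  truth <- data.frame(t = all_t, path, speed = speed,
                      curvature = kap[idx], torsion = tau[idx],
                      hx = heading[, 1], hy = heading[, 2],
                      hz = heading[, 3])

  set.seed(config$seed)
  max_speed <- max(speed)
  meshes <- lapply(config$observed_times, function(tt) {
    nz <- stats::rnorm(sh_basis(4L)$k - 1)
    make_cell_mesh(path[tt, ], heading[tt, ], speed[tt], max_speed, config,
                   noise_coeffs = nz, time_index = tt)
  })

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(seq_along(meshes), function(i) {
      p <- file.path(dir, sprintf("%s_t%03d.obj", cell_id,
                                  config$observed_times[i]))
      write_mesh(meshes[[i]], p)
      p
    }, character(1))
    utils::write.csv(data.frame(cell_id = cell_id,
                                time_index = config$observed_times,
                                path = paths),
                     file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(meshes = meshes, observed_times = config$observed_times,
       truth = truth, config = config)
}

#' Mean squared error between a smooth trajectory and the ground truth
#'
#' Evaluates the smooth curve at every ground-truth time point and reports
#' both averaging conventions: `mse_point`, the mean over time points of
#' the squared Euclidean distance, and `mse_coordinate`, the mean over all
#' scalar coordinates (`mse_point / 3`).
#'
#' @param smooth a [smooth_trajectory()].
#' @param truth ground-truth data.frame with columns `t`, `x`, `y`, `z`
#'   (as from [generate_dataset()]).
#' @return list with `mse_point`, `mse_coordinate`, `per_axis` (named
#'   per-axis mean squared errors).
#' @export
evaluate_trajectory_mse <- function(smooth, truth) {
  if (min(truth$t) < min(smooth$sample_times) - 1e-9 ||
        max(truth$t) > max(smooth$sample_times) + 1e-9)
    stop("time misalignment: truth times extend beyond the smoothed range")
  pred <- smooth$predict(truth$t)
  err <- pred - as.matrix(truth[, c("x", "y", "z")])
  per_axis <- colMeans(err^2)
  list(mse_point = sum(per_axis), mse_coordinate = sum(per_axis) / 3,
       per_axis = stats::setNames(per_axis, c("x", "y", "z")))
}

#' Generate a two-group synthetic cohort
#'
#' Cells share the speed-profile family (movement features carry no group
#' signal) but differ between groups in the velocity-locked pseudopod
#' amplitude, so the group signal lives in the shape-movement coupling.
#' Each cell gets a seeded random 3D heading, so features measured in the
#' fixed laboratory basis are scrambled across cells while moving-frame
#' features are not.
#'
#' @param n_per_group cells per group (default 12).
#' @param amplitudes length-2 pseudopod amplitudes of the two groups.
#' @param subdivisions mesh subdivision level (default 2 for speed).
#' @param seed master seed; cell `i` of group `g` uses
#'   `seed + 1000 * g + i`.
#' @param ... further overrides passed to [synthetic_cell_config()].
#' @return list with `cells` (list of [generate_dataset()] results) and
#'   `labels` (factor of group names).
#' @export
generate_cohort <- function(n_per_group = 12L, amplitudes = c(0.25, 0.7),
                            subdivisions = 2L, seed = 1L, ...) {
  cells <- list(); labels <- character(0)
  for (g in 1:2) {
    for (i in seq_len(n_per_group)) {
      cfg <- synthetic_cell_config(pseudopod_amplitude = amplitudes[g],
                                   subdivisions = subdivisions,
                                   heading = "random",
                                   seed = seed + 1000L * g + i, ...)
      cells[[length(cells) + 1L]] <- generate_dataset(cfg)
      labels <- c(labels, paste0("group", g))
    }
  }
  list(cells = cells, labels = factor(labels))
}
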