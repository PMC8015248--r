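# Fixtures built in code: small meshes and trajectories with known
# analytic properties.

cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  # 12 outward-wound triangles
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  triangle_mesh(v, f)
}

# closed genus-1 torus mesh (Euler characteristic 0)
torus_mesh <- function(n = 12L, m = 8L, R = 1, r = 0.35) {
  u <- rep(seq(0, 2 * pi, length.out = n + 1)[-(n + 1)], each = m)
  w <- rep(seq(0, 2 * pi, length.out = m + 1)[-(m + 1)], times = n)
  v <- cbind((R + r * cos(w)) * cos(u), (R + r * cos(w)) * sin(u),
             r * sin(w))
  idx <- function(i, j) ((i - 1L) %% n) * m + ((j - 1L) %% m) + 1L
  f <- NULL
  for (i in seq_len(n)) for (j in seq_len(m)) {
    f <- rbind(f,
               c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L)),
               c(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  triangle_mesh(v, f)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_matrix(ax / sqrt(sum(ax^2)), stats::runif(1, 0, 2 * pi))
}

rigid_transform_mesh <- function(mesh, R, tr) {
  triangle_mesh(sweep(mesh$vertices %*% t(R), 2L, tr, `+`), mesh$faces,
                mesh$time_index)
}

helix_trajectory <- function(a = 1, b = 1, n = 400L, tmax = 6 * pi) {
  t <- seq(0, tmax, length.out = n)
  structure(list(times = t,
                 points = cbind(a * cos(t), a * sin(t), b * t),
                 sample_times = t),
            class = "smooth_trajectory")
}

circle_trajectory <- function(R = 2, n = 500L, plane = "xy") {
  t <- seq(0, 2 * pi, length.out = n)
  pts <- switch(plane,
                xy = cbind(R * cos(t), R * sin(t), 0 * t),
                xz = cbind(R * cos(t), 0 * t, R * sin(t)))
  structure(list(times = t, points = pts, sample_times = t),
            class = "smooth_trajectory")
}

# a short synthetic mesh series shared by pipeline-level tests (cheap:
# coarse meshes, 12 observed times)
small_cell_dataset <- function(seed = 3L, ...) {
  generate_dataset(synthetic_cell_config(
    n_timepoints = 120L, observed_times = c(1L, seq(10L, 120L, 10L)),
    bump_centers = c(40, 95), bump_widths = c(18, 18), turn_center = 60,
    turn_width = 9, subdivisions = 2L, seed = seed, ...))
}

fit_small_cell <- function(ds, ...) {
  suppressWarnings(fit_cell(ds$meshes, mcf_tol = 0.08, ...))
}
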