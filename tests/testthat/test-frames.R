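frame_invariants_ok <- function(fr) {
  n <- nrow(fr$T)
  units <- c(rowSums(fr$T^2), rowSums(fr$N^2), rowSums(fr$B^2))
  ortho <- c(abs(rowSums(fr$T * fr$N)), abs(rowSums(fr$T * fr$B)),
             abs(rowSums(fr$N * fr$B)))
  dets <- vapply(seq_len(n), function(i)
    det(cbind(fr$T[i, ], fr$N[i, ], fr$B[i, ])), numeric(1))
  max(abs(units - 1)) < 1e-9 && max(ortho) < 1e-9 &&
    max(abs(dets - 1)) < 1e-9
}

test_that("tangent vectors are unit, carry forward at rest, and follow lines", {
  t <- seq(0, 10, 0.5)
  line <- structure(list(times = t, points = cbind(t, 0 * t, 0 * t)),
                    class = "smooth_trajectory")
  Tm <- tangent_vectors(line)
  expect_equal(Tm, matrix(rep(c(1, 0, 0), each = length(t)), ncol = 3),
               ignore_attr = TRUE)

  circ <- circle_trajectory(R = 3)
  Tc <- tangent_vectors(circ)
  expect_equal(rowSums(Tc^2), rep(1, nrow(Tc)), tolerance = 1e-9)
  # analytic circle tangent (-sin, cos, 0) at interior samples
  interior <- seq(10, nrow(Tc) - 10)
  th <- circ$times[interior]
  expect_equal(Tc[interior, ], cbind(-sin(th), cos(th), 0 * th),
               tolerance = 1e-3)

  # a flat segment repeats the previous tangent
  t2 <- c(0, 1, 2, 3, 4)
  pts <- cbind(c(0, 1, 1, 1, 2), 0, 0)  # stationary between t=1..3
  still <- structure(list(times = t2, points = pts),
                     class = "smooth_trajectory")
  Ts <- tangent_vectors(still)
  expect_equal(Ts[3, ], Ts[2, ])

  allzero <- structure(list(times = t2, points = matrix(1, 5, 3)),
                       class = "smooth_trajectory")
  expect_error(tangent_vectors(allzero), "stationary")
})

test_that("initial_normal is deterministic, unit and orthogonal", {
  expect_equal(initial_normal(c(1, 0, 0)), c(0, 1, 0))
  n0 <- initial_normal(c(0, 0, 1))
  expect_equal(sum(n0 * c(0, 0, 1)), 0, tolerance = 1e-12)
  expect_equal(sum(n0^2), 1, tolerance = 1e-12)
  set.seed(2)
  for (rep in 1:10) {
    T0 <- rnorm(3); T0 <- T0 / sqrt(sum(T0^2))
    n <- initial_normal(T0)
    expect_equal(sum(n * T0), 0, tolerance = 1e-12)
    expect_equal(sum(n^2), 1, tolerance = 1e-12)
  }
  expect_error(initial_normal(c(0, 0, 0)), "unit")
})

test_that("Rodrigues rotation matrices behave as rotations", {
  expect_equal(rotation_matrix(c(0, 0, 1), 0), diag(3))
  expect_equal(drop(rotation_matrix(c(0, 0, 1), pi / 2) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:10) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2)); th <- runif(1, -pi, pi)
    R <- rotation_matrix(u, th)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(R %*% rotation_matrix(u, -th), diag(3), tolerance = 1e-12)
  }
})

test_that("parallel transport gives constant frames on straight lines", {
  t <- seq(0, 10, 0.1)
  line <- structure(list(times = t, points = cbind(t, t, 0 * t)),
                    class = "smooth_trajectory")
  fr <- parallel_transport_frames(line)
  expect_true(frame_invariants_ok(fr))
  expect_equal(fr$N, matrix(fr$N[1, ], nrow(fr$N), 3, byrow = TRUE))
  expect_equal(fr$B, matrix(fr$B[1, ], nrow(fr$B), 3, byrow = TRUE))
})

test_that("planar curves keep B constant and closed loops have no holonomy", {
  # planar but non-circular curve in the xy plane
  t <- seq(0, 2 * pi, length.out = 2000)
  pts <- cbind((2 + cos(3 * t)) * cos(t), (2 + cos(3 * t)) * sin(t), 0 * t)
  pl <- structure(list(times = t, points = pts),
                  class = "smooth_trajectory")
  fr <- parallel_transport_frames(pl)
  expect_true(frame_invariants_ok(fr))
  # N0 from the in-plane acceleration keeps N in the plane, so B is the
  # plane normal throughout
  expect_lt(max(abs(abs(fr$B[, 3]) - 1)), 1e-6)
  spread <- apply(fr$B, 2, function(col) max(col) - min(col))
  expect_lt(max(spread), 1e-6)

  # closed circular loop: planar PT has zero holonomy
  circ <- circle_trajectory(R = 2, n = 3000L)
  frc <- parallel_transport_frames(circ)
  expect_lt(sqrt(sum((frc$N[nrow(frc$N), ] - frc$N[1, ])^2)), 1e-3)
})

test_that("transport twist never exceeds the tangent turn angle", {
  sm <- helix_trajectory(a = 1, b = 0.5, n = 600L)
  fr <- parallel_transport_frames(sm)
  expect_true(frame_invariants_ok(fr))
  n <- nrow(fr$T)
  turn <- acos(pmin(1, pmax(-1, rowSums(fr$T[-n, ] * fr$T[-1, ]))))
  # rotation of N about T between consecutive samples: the angle between
  # N_i transported trivially and N_(i+1), projected on the plane
  # orthogonal to T_(i+1)
  for (i in seq(1, n - 1, by = 37)) {
    Np <- fr$N[i, ] - sum(fr$N[i, ] * fr$T[i + 1, ]) * fr$T[i + 1, ]
    Np <- Np / sqrt(sum(Np^2))
    twist <- acos(min(1, max(-1, sum(Np * fr$N[i + 1, ]))))
    expect_lte(twist, turn[i] + 1e-9)
  }
  # consecutive normals stay aligned when turning gently
  expect_true(all(rowSums(fr$N[-n, ] * fr$N[-1, ]) > 0))
})

test_that("frames refine stably with grid resolution", {
  sm1 <- helix_trajectory(a = 1, b = 1, n = 8000L)
  sm2 <- helix_trajectory(a = 1, b = 1, n = 16000L)
  f1 <- parallel_transport_frames(sm1)
  f2 <- parallel_transport_frames(sm2)
  expect_lt(sqrt(sum((f1$N[nrow(f1$N), ] - f2$N[nrow(f2$N), ])^2)), 1e-3)
})

test_that("reorientation is the rigid map sending motion to the x-axis", {
  m <- icosphere(1)
  id <- list(T = c(1, 0, 0), N = c(0, 1, 0), B = c(0, 0, 1),
             origin = c(0, 0, 0))
  expect_equal(reorient_mesh(m, id)$vertices, m$vertices)

  set.seed(4)
  fr <- list(T = NULL, N = NULL, B = NULL, origin = rnorm(3))
  T0 <- rnorm(3); T0 <- T0 / sqrt(sum(T0^2))
  N0 <- initial_normal(T0)
  fr$T <- T0; fr$N <- N0; fr$B <- drop(morphodyn:::.cross3(rbind(T0),
                                                           rbind(N0)))
  out <- reorient_mesh(m, fr)
  # isometry about the origin
  expect_equal(sqrt(rowSums(out$vertices^2)),
               sqrt(rowSums(sweep(m$vertices, 2, fr$origin)^2)),
               tolerance = 1e-12)
  # a vertex sitting along T maps onto the +x axis
  probe <- triangle_mesh(rbind(fr$origin + 2 * T0, fr$origin + 0.5 * N0,
                               fr$origin), matrix(c(1L, 2L, 3L), 1))
  pv <- reorient_mesh(probe, fr)$vertices
  expect_equal(pv[1, ], c(2, 0, 0), tolerance = 1e-12)
  expect_equal(pv[2, ], c(0, 0.5, 0), tolerance = 1e-12)
})

test_that("jointly rotating mesh and frame leaves reoriented vertices fixed", {
  set.seed(5)
  m <- icosphere(1)
  T0 <- c(1, 0, 0); N0 <- c(0, 1, 0)
  fr <- list(T = T0, N = N0, B = c(0, 0, 1), origin = c(0.2, -0.1, 0.3))
  base <- reorient_mesh(m, fr)$vertices
  for (rep in 1:5) {
    R <- random_rotation(); tr <- rnorm(3)
    m2 <- rigid_transform_mesh(m, R, tr)
    fr2 <- list(T = drop(R %*% fr$T), N = drop(R %*% fr$N),
                B = drop(R %*% fr$B), origin = drop(R %*% fr$origin) + tr)
    expect_equal(reorient_mesh(m2, fr2)$vertices, base, tolerance = 1e-6)
  }
})
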