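test_that("the SH index map is the stated bijection", {
  expect_identical(sh_index(0, 0), 1L)
  expect_identical(sh_index(1, -1), 2L)
  expect_identical(sh_index(1, 0), 3L)
  expect_identical(sh_index(1, 1), 4L)
  expect_identical(sh_index(6, 6), 49L)
  b <- sh_basis(6)
  expect_identical(b$k, 49L)
  expect_identical(sort(sh_index(b$terms$l, b$terms$m)), 1:49)
  expect_error(sh_index(1, 2), "invalid order")
})

test_that("real harmonics match closed forms and are orthonormal", {
  th <- runif(20, 0, pi); ph <- runif(20, -pi, pi)
  expect_equal(real_sh(0, 0, th, ph), rep(1 / (2 * sqrt(pi)), 20))
  expect_equal(real_sh(1, 1, pi / 2, 0), sqrt(3 / (4 * pi)))
  # degree-1 harmonics are sqrt(3/4pi) times the direction components
  u <- angles_to_sphere(th, ph)
  K1 <- sqrt(3 / (4 * pi))
  expect_equal(real_sh(1, 1, th, ph), K1 * u[, 1], tolerance = 1e-12)
  expect_equal(real_sh(1, 0, th, ph), K1 * u[, 2], tolerance = 1e-12)
  expect_equal(real_sh(1, -1, th, ph), K1 * u[, 3], tolerance = 1e-12)

  # exact quadrature orthonormality oracle: Gauss-Legendre in cos(theta)
  # (Golub-Welsch nodes) x periodic trapezoid in phi integrates products
  # of degree <= 4 harmonics exactly
  ngl <- 20L
  beta <- (1:(ngl - 1)) / sqrt(4 * (1:(ngl - 1))^2 - 1)
  J <- diag(0, ngl); J[cbind(1:(ngl - 1), 2:ngl)] <- beta
  J[cbind(2:ngl, 1:(ngl - 1))] <- beta
  eig <- eigen(J, symmetric = TRUE)
  z <- eig$values; wz <- 2 * eig$vectors[1, ]^2
  nphi <- 40L
  phg <- seq(0, 2 * pi, length.out = nphi + 1)[-(nphi + 1)]
  grid <- expand.grid(z = z, phi = phg)
  w <- rep(wz, times = nphi) * (2 * pi / nphi)
  Y <- sh_design_matrix(acos(grid$z), grid$phi, sh_basis(4))
  G <- unname(crossprod(Y * sqrt(w)))
  expect_equal(G, diag(ncol(Y)), tolerance = 1e-10)
})

test_that("least-squares fitting recovers synthesized coefficients exactly", {
  set.seed(9)
  s <- icosphere(2)
  ang <- sphere_angles(s$vertices)
  b <- sh_basis(6)
  Y <- sh_design_matrix(ang$theta, ang$phi, b)
  truth <- matrix(rnorm(3 * b$k, sd = 0.2), b$k, 3)
  mesh <- triangle_mesh(Y %*% truth, s$faces)
  map <- structure(list(mesh = mesh, sphere_vertices = s$vertices,
                        theta = ang$theta, phi = ang$phi),
                   class = "spherical_map")
  cf <- fit_coefficients(map, b)
  expect_equal(unname(cf$c_x), truth[, 1], tolerance = 1e-8)
  expect_equal(unname(cf$c_y), truth[, 2], tolerance = 1e-8)
  expect_equal(unname(cf$c_z), truth[, 3], tolerance = 1e-8)
  expect_lt(max(cf$rms_residual), 1e-10)
})

test_that("a sphere map yields the perfect-sphere coefficient pattern", {
  map <- mcf_spherical_parameterization(
    normalize_volume(icosphere(3, radius = 0.7)))
  cf <- fit_coefficients(map)
  c1 <- c(cf$c_x[sh_index(1, 1)], cf$c_y[sh_index(1, 0)],
          cf$c_z[sh_index(1, -1)])
  expect_equal(unname(c1[2]), unname(c1[1]), tolerance = 1e-6)
  expect_equal(unname(c1[3]), unname(c1[1]), tolerance = 1e-6)
  others <- c(cf$c_x[-sh_index(1, 1)], cf$c_y[-sh_index(1, 0)],
              cf$c_z[-sh_index(1, -1)])
  expect_lt(max(abs(others)), 1e-6)
  ec <- eccentricities(cf)
  expect_equal(unname(ec), c(1, 1, 1), tolerance = 1e-3)
})

test_that("reconstruction residual is non-increasing in l_max", {
  cfg <- synthetic_cell_config(subdivisions = 2L, seed = 13L,
                               noise_amplitude = 0.05)
  m <- make_cell_mesh(c(0, 0, 0), c(1, 0, 0), 0.8, 1, cfg, time_index = 1L)
  map <- suppressWarnings(mcf_spherical_parameterization(m))
  rms <- vapply(c(2L, 4L, 6L), function(l)
    max(fit_coefficients(map, sh_basis(l))$rms_residual), numeric(1))
  expect_true(all(diff(rms) <= 1e-12))
})

test_that("ellipsoid eccentricities equal the semi-axis ratios within 2%", {
  for (ratio in c(0.5, 1, 2, 3)) {
    e <- ellipsoid_mesh(c(ratio, 1, 1), 3)
    map <- suppressWarnings(mcf_spherical_parameterization(e))
    ec <- eccentricities(fit_coefficients(map))
    expect_equal(unname(ec["E_xy"]), ratio, tolerance = 0.02)
    expect_equal(unname(ec["E_xz"]), ratio, tolerance = 0.02)
    expect_equal(unname(ec["E_yz"]), unname(ec["E_xz"] / ec["E_xy"]),
                 tolerance = 1e-9)
  }
  # y-elongated ellipsoid: E_xy = 0.5
  e <- ellipsoid_mesh(c(1, 2, 1), 3)
  ec <- eccentricities(fit_coefficients(
    suppressWarnings(mcf_spherical_parameterization(e))))
  expect_equal(unname(ec["E_xy"]), 0.5, tolerance = 0.02)
})

test_that("shape distance is the L2 norm with metric properties", {
  set.seed(10)
  mk <- function(seed) {
    set.seed(seed)
    b <- sh_basis(4)
    structure(list(c_x = rnorm(b$k), c_y = rnorm(b$k), c_z = rnorm(b$k),
                   l_max = 4L), class = "sh_coefficients")
  }
  a <- mk(1); b <- mk(2); c_ <- mk(3)
  expect_equal(shape_distance(a, a), 0)
  expect_equal(shape_distance(a, b), shape_distance(b, a))
  expect_lte(shape_distance(a, c_),
             shape_distance(a, b) + shape_distance(b, c_))
  # direct-summation oracle
  expect_equal(shape_distance(a, b),
               sqrt(sum((c(a$c_x, a$c_y, a$c_z) -
                           c(b$c_x, b$c_y, b$c_z))^2)))
  bad <- mk(4); bad$l_max <- 6L
  expect_error(shape_distance(a, bad), "incompatible")
})

test_that("shape-change rates are consecutive distances, linear in morphs", {
  mk_interp <- function(w, ca, cb) {
    structure(list(c_x = (1 - w) * ca$c_x + w * cb$c_x,
                   c_y = (1 - w) * ca$c_y + w * cb$c_y,
                   c_z = (1 - w) * ca$c_z + w * cb$c_z,
                   l_max = ca$l_max), class = "sh_coefficients")
  }
  set.seed(11)
  k <- sh_basis(3)$k
  ca <- structure(list(c_x = rnorm(k), c_y = rnorm(k), c_z = rnorm(k),
                       l_max = 3L), class = "sh_coefficients")
  cb <- structure(list(c_x = rnorm(k), c_y = rnorm(k), c_z = rnorm(k),
                       l_max = 3L), class = "sh_coefficients")
  series <- lapply(seq(0, 1, length.out = 5), mk_interp, ca = ca, cb = cb)
  rates <- shape_change_rate(series)
  expect_length(rates, 4L)
  expect_equal(rates, rep(rates[1], 4), tolerance = 0.05)
  # identical shapes: all-zero rates
  expect_equal(shape_change_rate(list(ca, ca, ca)), c(0, 0))
})

test_that("surfaces reconstruct from coefficients", {
  map <- mcf_spherical_parameterization(
    normalize_volume(icosphere(2, radius = 1.3)))
  cf <- fit_coefficients(map)
  rec <- reconstruct_surface(cf, icosphere(2))
  radii <- sqrt(rowSums(rec$vertices^2))
  expect_equal(radii, rep(mean(radii), length(radii)), tolerance = 1e-3)
  # radius of the source sphere mesh after unit-volume scaling, close to
  # the continuum value (3 / (4 pi))^(1/3) up to the faceting deficit
  r_src <- mean(sqrt(rowSums(
    normalize_volume(icosphere(2, radius = 1.3))$vertices^2)))
  expect_equal(mean(radii), r_src, tolerance = 1e-3)
  expect_equal(mean(radii), (3 / (4 * pi))^(1 / 3), tolerance = 2e-2)
  zero <- cf
  zero$c_x[] <- 0; zero$c_y[] <- 0; zero$c_z[] <- 0
  expect_equal(max(abs(reconstruct_surface(zero)$vertices)), 0)
})

test_that("translating the source mesh changes only the constant term", {
  e <- ellipsoid_mesh(c(1.5, 1, 1), 2)
  map <- suppressWarnings(mcf_spherical_parameterization(e))
  cf <- fit_coefficients(map)
  shifted <- map
  shifted$mesh <- triangle_mesh(sweep(e$vertices, 2, c(1, 2, 3), `+`),
                                e$faces)
  cf2 <- fit_coefficients(shifted)
  expect_equal(cf2$c_x[-1], cf$c_x[-1], tolerance = 1e-9)
  expect_equal(cf2$c_y[-1], cf$c_y[-1], tolerance = 1e-9)
  expect_equal(cf2$c_z[-1], cf$c_z[-1], tolerance = 1e-9)
  expect_gt(abs(cf2$c_x[1] - cf$c_x[1]), 0.1)
})
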