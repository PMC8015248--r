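# Spherical parameterization by conformalized mean-curvature flow.
# The flow drives a genus-0 mesh toward the round sphere while keeping the
# cotangent stiffness matrix frozen at the initial surface, which prevents
# the neck-pinch singularities of raw mean-curvature flow on non-convex
# shapes. The converged, radially projected vertex positions give each
# source vertex its (theta, phi) coordinates for spherical-harmonic
# fitting.

.face_corners <- function(v, f) {
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

.face_areas <- function(v, f) {
  co <- .face_corners(v, f)
  cr <- .cross3(co$b - co$a, co$c - co$a)
  sqrt(rowSums(cr^2)) / 2
}

#' Cotangent stiffness matrix of a triangle mesh
#'
#' Symmetric positive semi-definite `n x n` sparse matrix with
#' `L[i,j] = -(cot a + cot b)/2` over the two angles opposite edge `(i,j)`
#' and row sums zero (the P1 finite-element Laplace-Beltrami stiffness;
#' positive semi-definite even with the negative off-diagonal entries that
#' obtuse triangles produce). Only numerically degenerate triangles are
#' intervened on: their cotangents are clamped to `cot_cap` in magnitude,
#' with a warning.
#'
#' @param mesh a [triangle_mesh()].
#' @param cot_cap magnitude cap for cotangents of degenerate corners.
#' @return a sparse `Matrix` (n x n).
#' @export
cotangent_laplacian <- function(mesh, cot_cap = 1e8) {
  v <- mesh$vertices; f <- mesh$faces
  co <- .face_corners(v, f)
  cot_at <- function(p, q, r) {
    # cotangent of the angle at p between (q - p) and (r - p)
    u <- q - p; w <- r - p
    d <- rowSums(u * w)
    cr <- sqrt(rowSums(.cross3(u, w)^2))
    d / pmax(cr, .Machine$double.eps)
  }
  ca <- cot_at(co$a, co$b, co$c)  # opposite edge (b, c)
  cb <- cot_at(co$b, co$c, co$a)  # opposite edge (c, a)
  cc <- cot_at(co$c, co$a, co$b)  # opposite edge (a, b)
  cots <- c(ca, cb, cc)
  if (any(abs(cots) > cot_cap)) {
    warning("near-degenerate triangles: ", sum(abs(cots) > cot_cap),
            " cotangents clamped to magnitude ", cot_cap)
    cots <- pmin(cot_cap, pmax(-cot_cap, cots))
  }
  ii <- c(f[, 2], f[, 3], f[, 1])
  jj <- c(f[, 3], f[, 1], f[, 2])
  ww <- cots / 2
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(nrow(v), nrow(v)))
  Matrix::Diagonal(x = Matrix::rowSums(W)) - W
}

.lumped_mass <- function(v, f) {
  ar <- .face_areas(v, f) / 3
  m <- numeric(nrow(v))
  for (k in 1:3) {
    s <- tapply(ar, f[, k], sum)
    m[as.integer(names(s))] <- m[as.integer(names(s))] + s
  }
  Matrix::Diagonal(x = m)
}

.count_flipped <- function(s, f) {
  co <- .face_corners(s, f)
  sgn <- sign(rowSums(.cross3(co$a, co$b) * co$c))
  min(sum(sgn > 0), sum(sgn < 0))
}

#' Spherical angles of unit vectors (motion-frame convention)
#'
#' The polar axis is +y and the longitude is measured from +x toward +z:
#' `theta = acos(y)` in `[0, pi]`, `phi = atan2(z, x)` in `[-pi, pi)`.
#' With this convention the three degree-1 real harmonics pair with the
#' Cartesian coordinates as `x ~ Y(1,1)`, `y ~ Y(1,0)`, `z ~ Y(1,-1)`, so
#' the degree-1 coefficients of the three coordinate functions read off
#' elongation along x (the motion axis), y and z directly.
#'
#' @param s `n x 3` matrix of unit vectors.
#' @return list with numeric vectors `theta`, `phi`.
#' @export
sphere_angles <- function(s) {
  list(theta = acos(pmin(1, pmax(-1, s[, 2]))),
       phi = atan2(s[, 3], s[, 1]))
}

#' Unit vectors from spherical angles (inverse of [sphere_angles()])
#'
#' @param theta colatitude from +y, in `[0, pi]`.
#' @param phi longitude from +x toward +z.
#' @return `n x 3` matrix of unit vectors.
#' @export
angles_to_sphere <- function(theta, phi) {
  cbind(sin(theta) * cos(phi), cos(theta), sin(theta) * sin(phi))
}

#' Map a genus-0 mesh to the unit sphere by conformalized MCF
#'
#' Implicit-Euler steps `x <- (M_t + delta * L0)^(-1) M_t x` with the
#' cotangent stiffness `L0` frozen at the input mesh and the lumped mass
#' matrix `M_t` rebuilt from the current vertices each iteration. After
#' each step the vertices are re-centered on the mass center and rescaled
#' to unit mean radius. The flow stops when the sphericity (radius
#' coefficient of variation, sd/mean) drops below `tol`, when it stalls
#' (relative improvement below 1e-4 for 25 consecutive iterations: the
#' discrete flow has reached its equilibrium, whose residual sphericity
#' on coarse meshes of elongated shapes is above `tol`), or at
#' `max_iters`. A final sphericity above `tol` gives a warning, above
#' `fail_tol` an error. The vertices are then projected radially onto the
#' unit sphere and, by default, the parameterization is normalized to
#' first order ([sh_degree1_normalize()]) so that the degree-1
#' spherical-harmonic fit of the surface becomes self-consistent -- the
#' property that makes the degree-1 coefficients of an ellipsoid equal
#' its semi-axes (and hence the eccentricity indices equal the axis
#' ratios), and a sphere map to the identity parameterization.
#'
#' @param mesh a closed genus-0 [triangle_mesh()] (ideally volume
#'   normalized).
#' @param step implicit time step `delta`; default
#'   `(mean edge length)^2` of the input mesh.
#' @param max_iters iteration cap (default 500).
#' @param tol sphericity target (default 0.02).
#' @param fail_tol sphericity above which the flow is considered failed.
#' @param normalize_degree1 apply first-order parameter normalization
#'   (default TRUE).
#' @return An object of class `spherical_map`: `mesh` (source),
#'   `sphere_vertices` (`n x 3` unit vectors), `theta`, `phi`,
#'   `iterations`, `sphericity`, `flipped` (inconsistently oriented
#'   spherical triangles; 0 indicates a bijective map).
#' @export
mcf_spherical_parameterization <- function(mesh, step = NULL,
                                           max_iters = 500L, tol = 0.02,
                                           fail_tol = 0.15,
                                           normalize_degree1 = TRUE) {
  if (!check_spherical_topology(mesh))
    stop("mesh is not closed genus-0; spherical parameterization undefined")
  v <- mesh$vertices; f <- mesh$faces
  if (is.null(step)) {
    e <- .mesh_edges(f)
    el <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                          v[e[, 2], , drop = FALSE])^2))
    step <- mean(el)^2
  }
  L0 <- cotangent_laplacian(mesh)
  x <- sweep(v, 2L, colMeans(v))
  r <- sqrt(rowSums(x^2))
  x <- x / mean(r)
  spher <- stats::sd(r) / mean(r)
  it <- 0L; stall <- 0L
  while (spher >= tol && it < max_iters && stall < 25L) {
    M <- .lumped_mass(x, f)
    x <- as.matrix(Matrix::solve(M + step * L0, M %*% x))
    x <- sweep(x, 2L, colMeans(x))
    r <- sqrt(rowSums(x^2))
    x <- x / mean(r)
    new_spher <- stats::sd(r) / mean(r)
    stall <- if (spher - new_spher < 1e-4 * spher) stall + 1L else 0L
    spher <- new_spher
    it <- it + 1L
  }
  if (spher >= fail_tol)
    stop(sprintf(paste0("mean-curvature flow did not converge: sphericity ",
                        "%.4g after %d iterations (tol %.4g)"),
                 spher, it, tol))
  if (spher >= tol)
    warning(sprintf(paste0("mean-curvature flow stalled at sphericity %.4g ",
                           "(tol %.4g) after %d iterations; continuing"),
                    spher, tol, it))
  s <- x / sqrt(rowSums(x^2))
  ang <- sphere_angles(s)
  map <- structure(list(mesh = mesh, sphere_vertices = s,
                        theta = ang$theta, phi = ang$phi,
                        iterations = it, sphericity = spher,
                        flipped = .count_flipped(s, f)),
                   class = "spherical_map")
  if (normalize_degree1) map <- sh_degree1_normalize(map)
  map
}

#' First-order (degree-1) normalization of a spherical parameterization
#'
#' Iteratively reparameterizes a spherical map so that the degree <= 1
#' spherical-harmonic fit of the surface becomes self-consistent: fit the
#' constant offset `c0` and the 3 x 3 degree-1 coefficient matrix `B`
#' (columns: the x-, y- and z-direction harmonics), move each vertex to
#' `normalize(B^-1 (v - c0))`, and repeat until the sphere positions stop
#' changing. A surface that is exactly an affinely mapped sphere (any
#' ellipsoid) is a fixed point under its exact parameterization, so the
#' normalized map recovers degree-1 coefficients equal to the semi-axes;
#' for general shapes it removes the first-order distortion of the input
#' parameterization. The operation is equivariant under rotations of the
#' scene. If `B` becomes numerically singular the input map is returned
#' with a warning.
#'
#' @param map a `spherical_map`.
#' @param max_rounds iteration cap (default 50).
#' @param tol convergence threshold on the max sphere-position change.
#' @return A `spherical_map` with updated `sphere_vertices`, `theta`,
#'   `phi` and `flipped`.
#' @export
sh_degree1_normalize <- function(map, max_rounds = 50L, tol = 1e-8) {
  v <- map$mesh$vertices
  s <- map$sphere_vertices
  K1 <- sqrt(3 / (4 * pi))
  for (r in seq_len(max_rounds)) {
    ang <- sphere_angles(s)
    Y <- sh_design_matrix(ang$theta, ang$phi, sh_basis(1L))
    cf <- qr.coef(qr(Y), v)        # rows j: (0,0), (1,-1), (1,0), (1,1)
    c0 <- cf[1, ] * real_sh(0L, 0L, 0, 0)
    # v ~ c0 + B s: columns of B act on (s_x, s_y, s_z); in the +y-pole
    # convention j(1,1) carries s_x, j(1,0) s_y, j(1,-1) s_z
    B <- t(rbind(cf[4, ], cf[3, ], cf[2, ])) * K1
    if (!all(is.finite(B)) || abs(det(B)) < 1e-12 * max(abs(B))^3) {
      warning("degree-1 normalization skipped: singular coefficient matrix")
      return(map)
    }
    s_new <- t(solve(B, t(v) - c0))
    s_new <- s_new / sqrt(rowSums(s_new^2))
    delta <- max(abs(s_new - s))
    s <- s_new
    if (delta < tol) break
  }
  ang <- sphere_angles(s)
  map$sphere_vertices <- s
  map$theta <- ang$theta
  map$phi <- ang$phi
  map$flipped <- .count_flipped(s, map$mesh$faces)
  map
}

#' @export
print.spherical_map <- function(x, ...) {
  cat(sprintf(paste0("spherical_map: %d vertices, %d MCF iterations, ",
                     "sphericity %.3g, %d flipped triangles\n"),
              nrow(x$sphere_vertices), x$iterations, x$sphericity, x$flipped))
  invisible(x)
}

#' Spherical angles of a spherical map
#'
#' @param map a `spherical_map`.
#' @return list with `theta` (colatitude from +y) and `phi` (longitude
#'   from +x toward +z); see [sphere_angles()] for the convention.
#' @export
to_angles <- function(map) {
  stopifnot(inherits(map, "spherical_map"))
  list(theta = map$theta, phi = map$phi)
}

#' Debug dump of a spherical parameterization
#'
#' Writes a `(vertex_id, theta, phi)` CSV and, optionally, the spherical
#' mesh itself (unit-sphere vertices with the source connectivity).
#'
#' @param map a `spherical_map`.
#' @param path output CSV path.
#' @param mesh_path optional mesh output path (OBJ/OFF/PLY by extension).
#' @return `path`, invisibly.
#' @export
write_spherical_map_csv <- function(map, path, mesh_path = NULL) {
  utils::write.csv(data.frame(vertex_id = seq_along(map$theta),
                              theta = map$theta, phi = map$phi),
                   path, row.names = FALSE)
  if (!is.null(mesh_path))
    write_mesh(triangle_mesh(map$sphere_vertices, map$mesh$faces),
               mesh_path)
  invisible(path)
}
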