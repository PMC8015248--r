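# Real spherical-harmonic (SH) shape descriptor.
# Each Cartesian coordinate function on the parameterizing sphere is
# expanded in orthonormal real spherical harmonics up to degree l_max and
# the three coefficient vectors are concatenated into one descriptor
# C = (C_x, C_y, C_z) of length 3 * (l_max + 1)^2.

#' Linear index of a spherical-harmonic term
#'
#' Maps degree `l` and order `m` to the 1-based column index
#' `j = l^2 + l + m + 1`, a bijection onto `1..(l_max + 1)^2`.
#'
#' @param l degree, `l >= 0`.
#' @param m order, `-l <= m <= l`.
#' @return integer index.
#' @examples
#' sh_index(0, 0)   # 1
#' sh_index(1, -1)  # 2
#' sh_index(6, 6)   # 49
#' @export
sh_index <- function(l, m) {
  if (any(l < 0) || any(abs(m) > l)) stop("invalid order: need |m| <= l")
  as.integer(l^2 + l + m + 1)
}

#' Spherical-harmonic basis description
#'
#' @param l_max maximum expansion degree (default 6).
#' @return list of class `sh_basis` with `l_max`, `k = (l_max + 1)^2` and
#'   a data.frame `terms` of `(l, m)` in `j` order. Convention:
#'   orthonormal real SH, Condon-Shortley phase off.
#' @export
sh_basis <- function(l_max = 6L) {
  stopifnot(l_max >= 0L)
  l_max <- as.integer(l_max)
  terms <- do.call(rbind, lapply(0:l_max, function(l)
    data.frame(l = l, m = seq(-l, l))))
  terms$j <- sh_index(terms$l, terms$m)
  stopifnot(identical(terms$j, seq_len((l_max + 1L)^2)))
  structure(list(l_max = l_max, k = as.integer((l_max + 1L)^2),
                 terms = terms,
                 convention = "orthonormal real SH, Condon-Shortley off"),
            class = "sh_basis")
}

# associated Legendre P_l^m(x) without Condon-Shortley phase, standard
# three-term recurrences; fine in double precision for the small l used
# here
.assoc_legendre <- function(l, m, x) {
  stopifnot(m >= 0, m <= l)
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    for (i in seq_len(m)) pmm <- pmm * (2 * i - 1) * somx2
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

#' Evaluate an orthonormal real spherical harmonic
#'
#' `Y(l, m)` with the Condon-Shortley phase omitted:
#' `sqrt(2) K cos(m phi) P_l^m(cos theta)` for `m > 0`,
#' `sqrt(2) K sin(|m| phi) P_l^|m|(cos theta)` for `m < 0`, and
#' `K P_l^0(cos theta)` for `m = 0`, with
#' `K = sqrt((2l + 1) / (4 pi) * (l - |m|)! / (l + |m|)!)`.
#' The set is orthonormal under the surface measure of the unit sphere.
#'
#' @param l degree. @param m order.
#' @param theta colatitude in `[0, pi]` (from the +y polar axis in this
#'   package's convention; see [sphere_angles()]).
#' @param phi longitude.
#' @return numeric vector of values.
#' @export
real_sh <- function(l, m, theta, phi) {
  if (abs(m) > l) stop("invalid order: need |m| <= l")
  am <- abs(m)
  K <- sqrt((2 * l + 1) / (4 * pi) *
              exp(lfactorial(l - am) - lfactorial(l + am)))
  P <- .assoc_legendre(l, am, cos(theta))
  if (m > 0) sqrt(2) * K * cos(m * phi) * P
  else if (m < 0) sqrt(2) * K * sin(am * phi) * P
  else K * P
}

#' Spherical-harmonic design matrix
#'
#' `n x k` matrix with `Y[i, j] = real_sh(l_j, m_j, theta_i, phi_i)` and
#' columns in `j = l^2 + l + m + 1` order.
#'
#' @param theta,phi angle vectors of equal length.
#' @param basis an [sh_basis()] (or integer `l_max`).
#' @return numeric matrix.
#' @export
sh_design_matrix <- function(theta, phi, basis = sh_basis()) {
  if (is.numeric(basis)) basis <- sh_basis(basis)
  Y <- matrix(NA_real_, length(theta), basis$k)
  for (r in seq_len(nrow(basis$terms)))
    Y[, basis$terms$j[r]] <-
      real_sh(basis$terms$l[r], basis$terms$m[r], theta, phi)
  colnames(Y) <- sprintf("l%d_m%d", basis$terms$l, basis$terms$m)
  Y
}

#' Fit spherical-harmonic coefficients to a parameterized surface
#'
#' Solves, for each coordinate function, the least-squares problem
#' `min || Y c - coord ||_2` with the SH design matrix evaluated at the
#' vertex angles of the spherical map. Unweighted by default; vertex-area
#' weights may be supplied to counter parameterization area distortion.
#'
#' @param map a `spherical_map` (from
#'   [mcf_spherical_parameterization()]).
#' @param basis an [sh_basis()] or integer `l_max`.
#' @param weights optional non-negative per-vertex weights.
#' @return Object of class `sh_coefficients`: `c_x`, `c_y`, `c_z`
#'   (length-k named vectors), `l_max`, `rms_residual` (per coordinate),
#'   `n_vertices`.
#' @export
fit_coefficients <- function(map, basis = sh_basis(), weights = NULL) {
  if (is.numeric(basis)) basis <- sh_basis(basis)
  coords <- map$mesh$vertices
  n <- nrow(coords)
  if (n < basis$k)
    stop("underdetermined: ", n, " vertices < ", basis$k, " basis functions")
  Y <- sh_design_matrix(map$theta, map$phi, basis)
  if (!is.null(weights)) {
    w <- sqrt(weights)
    Yw <- Y * w
    cw <- coords * w
  } else {
    Yw <- Y; cw <- coords
  }
  qrY <- qr(Yw)
  if (qrY$rank < basis$k) {
    warning("rank-deficient SH design (rank ", qrY$rank,
            " < ", basis$k, "); minimum-norm solution used")
    sv <- svd(Yw)
    pos <- sv$d > max(sv$d) * 1e-12
    cf <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% cw) / sv$d[pos])
  } else {
    cf <- qr.coef(qrY, cw)
  }
  resid <- Y %*% cf - coords
  rms <- sqrt(colMeans(resid^2))
  nm <- colnames(Y)
  structure(list(c_x = stats::setNames(cf[, 1], nm),
                 c_y = stats::setNames(cf[, 2], nm),
                 c_z = stats::setNames(cf[, 3], nm),
                 l_max = basis$l_max,
                 rms_residual = stats::setNames(rms, c("x", "y", "z")),
                 n_vertices = n),
            class = "sh_coefficients")
}

#' @export
print.sh_coefficients <- function(x, ...) {
  cat(sprintf(paste0("sh_coefficients: l_max = %d (3 x %d values), ",
                     "fit RMS residual %.3g\n"),
              x$l_max, (x$l_max + 1)^2, max(x$rms_residual)))
  invisible(x)
}

#' Concatenated descriptor vector `C = (C_x, C_y, C_z)`
#'
#' @param coeffs an `sh_coefficients` object.
#' @return numeric vector of length `3 (l_max + 1)^2`.
#' @export
sh_descriptor <- function(coeffs) {
  c(cx = coeffs$c_x, cy = coeffs$c_y, cz = coeffs$c_z)
}

#' Eccentricity indices from degree-1 SH coefficients
#'
#' The degree-1 coefficients `C_x(1,1)`, `C_y(1,0)`, `C_z(1,-1)` capture
#' elongation along the x (motion), y and z axes. Their absolute ratios
#' `E_xy = |C_x(1,1)| / |C_y(1,0)|`, `E_xz = |C_x(1,1)| / |C_z(1,-1)|`
#' and `E_yz = E_xz / E_xy` measure how far the shape deviates from a
#' sphere in each coordinate plane; all three equal 1 for a perfect
#' sphere. Absolute values are used because the coefficient signs depend
#' only on the parameterization's pole alignment. `E_yz` is redundant
#' given the other two and is excluded from the downstream feature set.
#'
#' @param coeffs an `sh_coefficients` object.
#' @return named numeric vector `c(E_xy, E_xz, E_yz)`.
#' @export
eccentricities <- function(coeffs) {
  cx <- abs(coeffs$c_x[sh_index(1, 1)])
  cy <- abs(coeffs$c_y[sh_index(1, 0)])
  cz <- abs(coeffs$c_z[sh_index(1, -1)])
  if (min(cy, cz) < 1e-12)
    stop("degenerate shape: vanishing degree-1 coefficient")
  c(E_xy = unname(cx / cy), E_xz = unname(cx / cz), E_yz = unname(cy / cz))
}

#' L2 distance between two shape descriptors
#'
#' By default the full concatenated vector enters the distance,
#' including the degree-0 terms that carry residual translation;
#' `drop_degree0 = TRUE` removes them first.
#'
#' @param a,b `sh_coefficients` objects with the same `l_max`.
#' @param drop_degree0 exclude the three `l = 0` coefficients?
#' @return non-negative numeric.
#' @export
shape_distance <- function(a, b, drop_degree0 = FALSE) {
  if (a$l_max != b$l_max)
    stop("incompatible descriptors: l_max ", a$l_max, " vs ", b$l_max)
  d <- sh_descriptor(a) - sh_descriptor(b)
  if (drop_degree0) {
    k <- (a$l_max + 1)^2
    d <- d[-(1 + k * 0:2)]
  }
  sqrt(sum(d^2))
}

#' Shape-change rate of a coefficient time series
#'
#' The rate of shape change between consecutive observed time points is
#' the L2 descriptor distance `d(t, t+1)`.
#'
#' @param series list of `sh_coefficients`, time-ordered, length >= 2.
#' @return numeric vector of length `length(series) - 1`.
#' @export
shape_change_rate <- function(series) {
  if (length(series) < 2L) stop("need at least 2 time points")
  vapply(seq_len(length(series) - 1L),
         function(i) shape_distance(series[[i]], series[[i + 1L]]),
         numeric(1))
}

#' Reconstruct a surface from SH coefficients
#'
#' Evaluates the truncated expansions of the three coordinate functions on
#' a spherical grid (by default the vertices of an icosphere, which also
#' provides the triangulation). Intended for visualization and round-trip
#' checks.
#'
#' @param coeffs an `sh_coefficients` object.
#' @param grid_mesh a spherical [triangle_mesh()] whose unit vertices
#'   supply the evaluation angles (default `icosphere(3)`).
#' @return A [triangle_mesh()].
#' @export
reconstruct_surface <- function(coeffs, grid_mesh = icosphere(3L)) {
  s <- grid_mesh$vertices / sqrt(rowSums(grid_mesh$vertices^2))
  ang <- sphere_angles(s)
  Y <- sh_design_matrix(ang$theta, ang$phi, sh_basis(coeffs$l_max))
  v <- cbind(Y %*% coeffs$c_x, Y %*% coeffs$c_y, Y %*% coeffs$c_z)
  triangle_mesh(v, grid_mesh$faces)
}

#' Write a coefficient time series to CSV
#'
#' Columns: `cell_id`, `t`, then `cx_l_m`, `cy_l_m`, `cz_l_m` in `j`
#' order.
#'
#' @param series list of `sh_coefficients`.
#' @param times numeric time stamps, one per element.
#' @param path output path.
#' @param cell_id identifier column value.
#' @return `path`, invisibly.
#' @export
write_coefficients_csv <- function(series, times, path, cell_id = "cell") {
  stopifnot(length(series) == length(times))
  mat <- t(vapply(series, sh_descriptor,
                  numeric(3 * (series[[1]]$l_max + 1)^2)))
  colnames(mat) <- sub("^(c[xyz])\\.l(\\d+)_m(-?\\d+)$", "\\1_\\2_\\3",
                       colnames(mat))
  df <- data.frame(cell_id = cell_id, t = times, mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
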