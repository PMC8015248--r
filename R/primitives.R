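#' Regular icosahedron mesh
#'
#' Canonical 12-vertex, 20-face closed polyhedron with outward winding,
#' circumscribed by the unit sphere. Base shape for [icosphere()].
#'
#' @param time_index optional time stamp.
#' @return A [triangle_mesh()].
#' @export
icosahedron <- function(time_index = NA_integer_) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  triangle_mesh(v, f, time_index)
}

#' Subdivided icosphere mesh
#'
#' Loop-style midpoint subdivision of the icosahedron with radial
#' projection onto the sphere of radius `radius`. Subdivision level `s`
#' gives `10 * 4^s + 2` vertices (level 2: 162, level 3: 642).
#'
#' @param subdivisions non-negative integer subdivision level.
#' @param radius sphere radius.
#' @param time_index optional time stamp.
#' @return A [triangle_mesh()].
#' @examples
#' s <- icosphere(2)
#' nrow(s$vertices)  # 162
#' @export
icosphere <- function(subdivisions = 3L, radius = 1, time_index = NA_integer_) {
  m <- icosahedron()
  v <- m$vertices; f <- m$faces
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    ue <- .mesh_edges(f)
    key <- paste(ue[, 1], ue[, 2])
    uq <- !duplicated(key)
    edges <- ue[uq, , drop = FALSE]
    mid_id <- stats::setNames(nv + seq_len(nrow(edges)),
                              paste(edges[, 1], edges[, 2]))
    mids <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
    a <- f[, 1]; b <- f[, 2]; c_ <- f[, 3]
    ab <- mid_id[ekey(a, b)]; bc <- mid_id[ekey(b, c_)]; ca <- mid_id[ekey(c_, a)]
    f <- rbind(cbind(a, ab, ca), cbind(b, bc, ab),
               cbind(c_, ca, bc), cbind(ab, bc, ca))
    dimnames(f) <- NULL
  }
  triangle_mesh(v * radius, f, time_index)
}

#' Axis-aligned ellipsoid mesh
#'
#' Icosphere scaled anisotropically to the given semi-axes. With
#' `unit_volume = TRUE` the semi-axes are rescaled uniformly so the
#' enclosed mesh volume is exactly 1, preserving the axis ratios.
#'
#' @param semi_axes length-3 positive numeric (x, y, z semi-axes).
#' @param subdivisions icosphere subdivision level.
#' @param unit_volume rescale to unit enclosed volume?
#' @return A [triangle_mesh()].
#' @export
ellipsoid_mesh <- function(semi_axes = c(2, 1, 1), subdivisions = 3L,
                           unit_volume = TRUE) {
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0))
  m <- icosphere(subdivisions)
  v <- sweep(m$vertices, 2L, semi_axes, `*`)
  out <- triangle_mesh(v, m$faces)
  if (unit_volume) out <- normalize_volume(out)
  out
}
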