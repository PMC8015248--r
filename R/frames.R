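# Parallel-transport moving frames along the smooth trajectory.
# The frame (T, N, B) travels with the cell: T is the unit velocity, N is
# carried along the curve with minimal rotation about T (no spurious
# twist, unlike the Frenet frame), and B = T x N closes the right-handed
# triad. Reorienting each mesh into its frame makes the direction of
# motion the first shape axis.

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize the zero vector")
  v / n
}

#' Unit tangent vectors of a smooth trajectory
#'
#' Finite-difference velocity directions at every dense sample. Where the
#' speed is numerically zero the previous tangent is carried forward (a
#' momentarily stationary cell keeps its heading); leading zero-speed
#' samples take the first defined tangent.
#'
#' @param smooth a [smooth_trajectory()] (or any list with `times` and
#'   `points`).
#' @return numeric `n x 3` matrix of unit vectors.
#' @export
tangent_vectors <- function(smooth) {
  x <- smooth$times; r <- smooth$points
  if (length(x) < 2L) stop("need at least 2 points")
  d1 <- apply(r, 2L, .fd_gradient, x = x)
  sp <- sqrt(rowSums(d1^2))
  ok <- sp > 1e-12
  if (!any(ok))
    stop("stationary cell: velocity is zero along the whole trajectory, ",
         "no moving frame is definable")
  Tm <- d1 / sp
  dimnames(Tm) <- NULL
  first <- which(ok)[1]
  if (first > 1L) Tm[seq_len(first - 1L), ] <-
    matrix(Tm[first, ], first - 1L, 3L, byrow = TRUE)
  for (i in seq_along(sp)[-1]) if (!ok[i]) Tm[i, ] <- Tm[i - 1L, ]
  Tm
}

#' Deterministic normal perpendicular to a tangent
#'
#' Gram-Schmidt of the coordinate axis least aligned with `T0`. Used as a
#' reproducible fallback when the trajectory itself does not determine an
#' initial normal (straight initial segment); see
#' [parallel_transport_frames()] for the default, rotation-equivariant
#' choice.
#'
#' @param T0 unit length-3 vector.
#' @return unit length-3 vector orthogonal to `T0`.
#' @export
initial_normal <- function(T0) {
  if (abs(sqrt(sum(T0^2)) - 1) > 1e-6) stop("T0 must be a unit vector")
  axis <- diag(3)[, which.min(abs(T0))]
  .normalize(axis - sum(axis * T0) * T0)
}

#' Rodrigues rotation matrix
#'
#' @param axis unit length-3 rotation axis (normalized with a warning if
#'   off by less than 1e-6, an error otherwise).
#' @param angle rotation angle in radians.
#' @return 3 x 3 rotation matrix (determinant +1).
#' @export
rotation_matrix <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (abs(n - 1) > 1e-6) stop("axis must be a unit vector")
  if (n != 1) {
    if (abs(n - 1) > 1e-12) warning("axis renormalized (|axis| - 1 = ",
                                    format(n - 1), ")")
    axis <- axis / n
  }
  Kx <- matrix(c(0, axis[3], -axis[2],
                 -axis[3], 0, axis[1],
                 axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * Kx + (1 - cos(angle)) * (Kx %*% Kx)
}

#' Parallel-transport moving frames along a smooth trajectory
#'
#' Builds one orthonormal right-handed frame `(T, N, B)` per dense sample.
#' `N` is transported with minimal twist: between samples `i` and `i+1`,
#' with `U = T_i x T_(i+1)`, `N` is unchanged if `|U|` is below
#' `eps_parallel` (parallel tangents) and otherwise rotated about `U/|U|`
#' by `theta = acos(T_i . T_(i+1))`. Antiparallel consecutive tangents
#' (dot near -1) are handled by composing two half-turns about a
#' perpendicular axis, with a warning. `B = T x N` throughout.
#'
#' The initial normal defaults to the direction of the initial normal
#' acceleration (Gram-Schmidt of `r''(t_1)` against `T_1`), which rotates
#' with the scene and therefore makes every downstream shape descriptor
#' invariant under rigid motions of the whole scene. When the initial
#' acceleration is (numerically) tangential the deterministic axis rule of
#' [initial_normal()] is used instead (`normal0 = "axis"` forces it).
#'
#' @param smooth a [smooth_trajectory()].
#' @param normal0 `"acceleration"` (default) or `"axis"`, or a numeric
#'   length-3 vector to use directly (projected against `T_1`).
#' @param eps_parallel threshold on `|U|` for the parallel branch.
#' @return An object of class `frame_sequence`: list with `times`,
#'   `origins` (n x 3), and `T`, `N`, `B` (each n x 3).
#' @export
parallel_transport_frames <- function(smooth, normal0 = "acceleration",
                                      eps_parallel = 1e-10) {
  if (anyNA(smooth$points))
    stop("NaN in input trajectory at index ",
         which(apply(is.na(smooth$points), 1L, any))[1])
  Tm <- tangent_vectors(smooth)
  n <- nrow(Tm)
  Nm <- matrix(NA_real_, n, 3L)

  if (is.numeric(normal0)) {
    N0 <- normal0 - sum(normal0 * Tm[1, ]) * Tm[1, ]
    if (sqrt(sum(N0^2)) < 1e-8)
      stop("supplied normal0 is parallel to the initial tangent")
    N0 <- .normalize(N0)
  } else if (identical(normal0, "acceleration")) {
    d1 <- apply(smooth$points, 2L, .fd_gradient, x = smooth$times)
    d2 <- apply(d1, 2L, .fd_gradient, x = smooth$times)
    acc <- d2[1, ]
    perp <- acc - sum(acc * Tm[1, ]) * Tm[1, ]
    N0 <- if (sqrt(sum(perp^2)) > 1e-8 * max(sqrt(sum(acc^2)), 1e-12))
      .normalize(perp) else initial_normal(Tm[1, ])
  } else if (identical(normal0, "axis")) {
    N0 <- initial_normal(Tm[1, ])
  } else stop("invalid normal0")

  Nm[1, ] <- N0
  for (i in seq_len(n - 1L)) {
    U <- drop(.cross3(Tm[i, , drop = FALSE], Tm[i + 1L, , drop = FALSE]))
    nu <- sqrt(sum(U^2))
    dot <- sum(Tm[i, ] * Tm[i + 1L, ])
    if (nu < eps_parallel) {
      if (dot < 0) {
        # tangent reversal: no rotation axis is preferred; compose two
        # half-angle rotations about an arbitrary perpendicular axis
        warning("antiparallel consecutive tangents at sample ", i,
                "; frame continued through the reversal")
        axis <- initial_normal(Tm[i, ])
        R <- rotation_matrix(axis, pi / 2)
        Nm[i + 1L, ] <- drop(R %*% R %*% Nm[i, ])
      } else Nm[i + 1L, ] <- Nm[i, ]
    } else {
      theta <- acos(max(-1, min(1, dot)))
      Nm[i + 1L, ] <- drop(rotation_matrix(U / nu, theta) %*% Nm[i, ])
    }
    # re-orthogonalize against drift
    Nm[i + 1L, ] <- .normalize(Nm[i + 1L, ] -
                                 sum(Nm[i + 1L, ] * Tm[i + 1L, ]) * Tm[i + 1L, ])
  }
  Bm <- .cross3(Tm, Nm)
  structure(list(times = smooth$times, origins = smooth$points,
                 T = Tm, N = Nm, B = Bm),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("frame_sequence: %d frames on [%g, %g]\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Extract one frame from a frame sequence
#'
#' @param frames a `frame_sequence`.
#' @param time time stamp; must match a frame time exactly (within 1e-9).
#' @return list with `T`, `N`, `B` (unit vectors) and `origin`.
#' @export
frame_at <- function(frames, time) {
  i <- which(abs(frames$times - time) < 1e-9)
  if (length(i) != 1L) stop("no frame at time ", time)
  list(T = frames$T[i, ], N = frames$N[i, ], B = frames$B[i, ],
       origin = frames$origins[i, ])
}

#' Express mesh vertices in a moving-frame basis
#'
#' Each vertex `v` maps to `v* = M (v - origin)` where the rows of `M` are
#' `T`, `N`, `B`: the direction of motion becomes the new x-axis, and the
#' transform is a rigid motion (vertex norms relative to the origin are
#' preserved). Faces are untouched.
#'
#' @param mesh a [triangle_mesh()].
#' @param frame list with unit vectors `T`, `N`, `B` and `origin`
#'   (as from [frame_at()]).
#' @return A reoriented [triangle_mesh()].
#' @export
reorient_mesh <- function(mesh, frame) {
  M <- rbind(frame$T, frame$N, frame$B)
  if (max(abs(M %*% t(M) - diag(3))) > 1e-6)
    stop("invalid frame: T, N, B are not orthonormal")
  v <- sweep(mesh$vertices, 2L, frame$origin)
  triangle_mesh(v %*% t(M), mesh$faces, mesh$time_index)
}

#' Write a frame sequence to CSV
#'
#' Columns: `cell_id`, `t`, origin (`ox`,`oy`,`oz`) and the 9 frame
#' components `Tx..Bz`.
#'
#' @param frames a `frame_sequence`.
#' @param path output path.
#' @param cell_id identifier column value.
#' @return `path`, invisibly.
#' @export
write_frames_csv <- function(frames, path, cell_id = "cell") {
  df <- data.frame(cell_id = cell_id, t = frames$times,
                   ox = frames$origins[, 1], oy = frames$origins[, 2],
                   oz = frames$origins[, 3],
                   Tx = frames$T[, 1], Ty = frames$T[, 2], Tz = frames$T[, 3],
                   Nx = frames$N[, 1], Ny = frames$N[, 2], Nz = frames$N[, 3],
                   Bx = frames$B[, 1], By = frames$B[, 2], Bz = frames$B[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
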