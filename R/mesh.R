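#' Construct a triangle mesh
#'
#' A `triangle_mesh` is the shape observation at one time point: a closed,
#' genus-0 triangulated surface. Vertices are stored as an `n x 3` numeric
#' matrix (arbitrary length units), faces as an `m x 3` integer matrix of
#' 1-based vertex indices.
#'
#' @param vertices numeric matrix (or coercible) with 3 columns.
#' @param faces integer matrix (or coercible) with 3 columns of 1-based
#'   vertex indices; each face must reference 3 distinct, valid vertices.
#' @param time_index optional integer time stamp of the observation.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `time_index`.
#' @examples
#' m <- icosahedron()
#' nrow(m$vertices)  # 12
#' @export
triangle_mesh <- function(vertices, faces, time_index = NA_integer_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L || nrow(vertices) < 1L)
    stop("vertices must be a non-empty n x 3 matrix")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L)
    stop("faces must be an m x 3 matrix of vertex indices")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
              faces[, 1] == faces[, 3]))
      stop("degenerate face: repeated vertex index within a face")
  }
  structure(list(vertices = vertices, faces = faces,
                 time_index = as.integer(time_index)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (!is.na(x$time_index)) cat(sprintf(", t = %d", x$time_index))
  cat(sprintf("\n  closed genus-0: %s\n",
              if (check_spherical_topology(x)) "yes" else "NO"))
  invisible(x)
}

.mesh_format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("obj", "ply", "off"))
    stop("cannot infer mesh format from extension '", ext, "'")
  ext
}

#' Read a triangular surface mesh
#'
#' Supports Wavefront OBJ (ASCII), PLY (ASCII and binary little-endian) and
#' OFF. Vertices and faces are returned exactly as stored, with no
#' reordering. Non-triangular faces are refused: this package analyses
#' triangulated genus-0 surfaces only.
#'
#' @param path file path.
#' @param format `"auto"` (infer from extension), `"obj"`, `"ply"` or `"off"`.
#' @param time_index optional integer time stamp to attach.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply", "off"),
                      time_index = NA_integer_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .mesh_format_from_path(path)
  m <- switch(format,
              obj = .read_obj(path),
              off = .read_off(path),
              ply = .read_ply(path))
  triangle_mesh(m$vertices, m$faces, time_index)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) stop("OBJ parse failure: no vertices in ", path)
  vs <- t(vapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                 function(p) as.numeric(p[1:3]), numeric(3)))
  if (anyNA(vs)) stop("OBJ parse failure: malformed vertex line")
  fparts <- strsplit(trimws(sub("^f", "", flines)), "\\s+")
  if (any(lengths(fparts) != 3L))
    stop("unsupported topology: OBJ file contains non-triangular faces")
  fs <- t(vapply(fparts,
                 function(p) as.integer(sub("/.*$", "", p)), integer(3)))
  list(vertices = vs, faces = fs)
}

.read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (toupper(trimws(lines[1])) != "OFF") stop("OFF parse failure: missing header")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  body <- lines[-(1:2)]
  if (length(body) < nv + nf) stop("OFF parse failure: truncated file")
  vs <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                 function(p) as.numeric(p[1:3]), numeric(3)))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  sizes <- vapply(frows, function(p) as.integer(p[1]), integer(1))
  if (any(sizes != 3L))
    stop("unsupported topology: OFF file contains non-triangular faces")
  fs <- t(vapply(frows, function(p) as.integer(p[2:4]), integer(3))) + 1L
  list(vertices = vs, faces = fs)
}

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(con, type) {
  sz <- .ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1L, size = sz, endian = "little")
  else
    readBin(con, "integer", 1L, size = sz, endian = "little",
            signed = !(sz < 4L && grepl("^u", type)))
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("PLY parse failure: unterminated header")
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  if (trimws(header[1]) != "ply") stop("PLY parse failure: missing magic")
  fmt_line <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("PLY parse failure: unsupported format (big-endian)")
  # parse element/property declarations in order
  elements <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY parse failure: need vertex and face elements")

  vs <- NULL; fs <- NULL
  if (binary) {
    for (el in elements) {
      if (el$name == "vertex") {
        pnames <- vapply(el$props, `[[`, "", "name")
        rows <- matrix(NA_real_, el$count, length(el$props))
        for (i in seq_len(el$count))
          for (j in seq_along(el$props))
            rows[i, j] <- .ply_read_scalar(con, el$props[[j]]$type)
        vs <- rows[, match(c("x", "y", "z"), pnames), drop = FALSE]
      } else if (el$name == "face") {
        p <- el$props[[1]]
        fs <- matrix(NA_integer_, el$count, 3L)
        for (i in seq_len(el$count)) {
          n <- .ply_read_scalar(con, p$count_type)
          if (n != 3L)
            stop("unsupported topology: PLY file contains non-triangular faces")
          fs[i, ] <- vapply(1:3, function(k) .ply_read_scalar(con, p$type),
                            numeric(1))
        }
      } else {
        # skip unknown element payload (fixed-size properties only)
        for (i in seq_len(el$count))
          for (p in el$props) .ply_read_scalar(con, p$type)
      }
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    for (el in elements) {
      rows <- strsplit(trimws(body[pos + seq_len(el$count)]), "\\s+")
      pos <- pos + el$count
      if (el$name == "vertex") {
        pnames <- vapply(el$props, `[[`, "", "name")
        idx <- match(c("x", "y", "z"), pnames)
        vs <- t(vapply(rows, function(r) as.numeric(r[idx]), numeric(3)))
      } else if (el$name == "face") {
        sizes <- vapply(rows, function(r) as.integer(r[1]), integer(1))
        if (any(sizes != 3L))
          stop("unsupported topology: PLY file contains non-triangular faces")
        fs <- t(vapply(rows, function(r) as.integer(r[2:4]), integer(3)))
      }
    }
  }
  list(vertices = vs, faces = fs + 1L)
}

#' Write a mesh to OBJ, OFF or ASCII PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path; format inferred from the extension unless
#'   `format` is given.
#' @param format `"auto"`, `"obj"`, `"ply"` (ASCII) or `"off"`.
#' @param digits significant digits written (default 17: lossless
#'   round-trip for doubles).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply", "off"),
                       digits = 17L) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  if (format == "auto") format <- .mesh_format_from_path(path)
  v <- mesh$vertices; f <- mesh$faces
  fmtv <- function(row) paste(formatC(row, digits = digits, format = "g"),
                              collapse = " ")
  vtxt <- apply(v, 1L, fmtv)
  lines <- switch(format,
    obj = c(paste("v", vtxt),
            paste("f", f[, 1], f[, 2], f[, 3])),
    off = c("OFF", paste(nrow(v), nrow(f), 0L),
            vtxt,
            paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nrow(v)),
            "property double x", "property double y", "property double z",
            paste("element face", nrow(f)),
            "property list uchar int vertex_indices", "end_header",
            vtxt,
            paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)))
  writeLines(lines, path)
  invisible(path)
}

.mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Test whether a mesh is closed and topologically spherical
#'
#' Spherical-harmonic shape analysis requires a genus-0 surface: the mesh
#' must be closed (every undirected edge shared by exactly two faces, each
#' traversing it in opposite directions) and have Euler characteristic
#' V - E + F = 2. Meshes failing this check cannot be mapped to the sphere
#' and are excluded from analysis.
#'
#' @param mesh a [triangle_mesh()].
#' @return `TRUE` or `FALSE` (never an error for a structurally valid mesh).
#' @examples
#' check_spherical_topology(icosahedron())  # TRUE: 12 - 30 + 20 = 2
#' @export
check_spherical_topology <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  ue <- .mesh_edges(f)
  key <- paste(ue[, 1], ue[, 2])
  tab <- table(key)
  if (any(tab != 2L)) return(FALSE)
  # consistent orientation: each directed edge appears exactly once
  de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  if (anyDuplicated(paste(de[, 1], de[, 2]))) return(FALSE)
  V <- nrow(mesh$vertices); E <- length(tab); F <- nrow(f)
  (V - E + F) == 2L
}

#' Mass center of a mesh
#'
#' The trajectory of a moving cell is the time series of its mass centers,
#' defined as the unweighted arithmetic mean of the vertex coordinates
#' (`method = "vertex"`, the default). The volume-weighted centroid
#' (`method = "volumetric"`) is available as an alternative but is not used
#' by the default pipeline.
#'
#' @param mesh a [triangle_mesh()].
#' @param method `"vertex"` (arithmetic vertex mean) or `"volumetric"`.
#' @return numeric length-3 vector.
#' @export
mass_center <- function(mesh, method = c("vertex", "volumetric")) {
  method <- match.arg(method)
  v <- mesh$vertices
  if (nrow(v) == 0L) stop("invalid input: mesh has no vertices")
  if (method == "vertex") return(colMeans(v))
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  # signed tetrahedron volumes against the origin
  w <- (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
        a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  tot <- sum(w)
  if (abs(tot) < .Machine$double.eps * 100)
    stop("volumetric centroid undefined: near-zero enclosed volume")
  colSums((a + b + c_) / 4 * w) / tot
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedra spanned by each face and the
#' origin. Positive for outward-facing (counter-clockwise) winding.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric scalar.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Scale a mesh to unit enclosed volume
#'
#' Shapes are compared at a common scale by normalizing the enclosed volume
#' to one before spherical-harmonic decomposition. Vertices are scaled
#' uniformly about the mass center by `volume^(-1/3)`, which preserves all
#' shape ratios (eccentricity indices are invariant under this operation).
#'
#' @param mesh a closed [triangle_mesh()] with positive signed volume.
#' @return A [triangle_mesh()] with enclosed volume 1 (relative tolerance
#'   1e-6).
#' @export
normalize_volume <- function(mesh) {
  vol <- mesh_volume(mesh)
  if (!is.finite(vol) || vol <= 0)
    stop("orientation error: non-positive signed volume (",
         format(vol), "); face winding appears inward - flip face order")
  ctr <- mass_center(mesh)
  s <- vol^(-1 / 3)
  v <- sweep(mesh$vertices, 2L, ctr)
  v <- sweep(v * s, 2L, ctr, `+`)
  triangle_mesh(v, mesh$faces, mesh$time_index)
}

#' Read a manifest of per-time-point meshes for one or more cells
#'
#' The manifest is a CSV with header columns `cell_id`, `time_index`,
#' `path` (paths relative to the manifest location or absolute).
#'
#' @param manifest_path path to the manifest CSV.
#' @return A named list (one element per cell id) of lists of
#'   [triangle_mesh()] objects ordered by `time_index`.
#' @export
read_mesh_series <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_index", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  out <- list()
  for (cid in unique(man$cell_id)) {
    rows <- man[man$cell_id == cid, , drop = FALSE]
    rows <- rows[order(rows$time_index), , drop = FALSE]
    out[[as.character(cid)]] <- lapply(seq_len(nrow(rows)), function(i) {
      p <- rows$path[i]
      if (!file.exists(p)) p <- file.path(base, rows$path[i])
      read_mesh(p, time_index = rows$time_index[i])
    })
  }
  out
}
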