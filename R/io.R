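# Minimal readers/writers for the interchange formats used around vascular
# surface models: PLY (ascii and binary little-endian) for meshes and point
# clouds, OBJ for meshes, whitespace XYZ for clouds.

#' Write a point cloud to PLY
#'
#' @param points N x 3 numeric matrix.
#' @param path output file.
#' @param format `"ascii"` (default, text, reproducible byte-for-byte) or
#'   `"binary_little_endian"`.
#' @export
write_ply_cloud <- function(points, path, format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, all(is.finite(points)))
  header <- c("ply",
              paste("format", format, "1.0"),
              paste("element vertex", nrow(points)),
              "property float x", "property float y", "property float z",
              "end_header")
  if (format == "ascii") {
    body <- sprintf("%.6f %.6f %.6f", points[, 1], points[, 2], points[, 3])
    writeLines(c(header, body), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(points)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Write a triangle mesh to PLY (ascii)
#'
#' @param mesh a `surface_mesh`.
#' @param path output file.
#' @export
write_ply_mesh <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nrow(v)),
              "property float x", "property float y", "property float z",
              paste("element face", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  vb <- sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3])
  fb <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(header, vb, fb), path)
  invisible(path)
}

.parse_ply_header <- function(lines) {
  stopifnot(lines[1] == "ply")
  fmt <- sub("^format ", "", lines[grepl("^format ", lines)][1])
  fmt <- strsplit(fmt, " ")[[1]][1]
  elements <- list()
  cur <- NULL
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1L]] <- tok[-1]
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  list(format = fmt, elements = elements)
}

#' Read a PLY file
#'
#' Supports ascii and binary little-endian PLY with a `vertex` element
#' carrying `x`, `y`, `z` (float or double) and an optional `face` element
#' with an index list property.
#'
#' @param path PLY file.
#' @return a list with `points` (N x 3) and, when faces are present, a
#'   `surface_mesh` under `$mesh`.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header_lines <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unreadable PLY: no end_header in ", path, call. = FALSE)
    header_lines <- c(header_lines, ln)
    if (ln == "end_header") break
  }
  h <- .parse_ply_header(header_lines)
  ve <- h$elements[["vertex"]]
  if (is.null(ve)) stop("PLY without vertex element: ", path, call. = FALSE)
  fe <- h$elements[["face"]]
  nprop <- length(ve$props)
  if (h$format == "ascii") {
    txt <- readLines(con)
    vlines <- txt[seq_len(ve$count)]
    vals <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                   ncol = nprop, byrow = TRUE)
    pnames <- vapply(ve$props, function(p) p[length(p)], character(1))
    pts <- vals[, match(c("x", "y", "z"), pnames), drop = FALSE]
    faces <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      flines <- txt[ve$count + seq_len(fe$count)]
      fl <- strsplit(trimws(flines), "\\s+")
      faces <- t(vapply(fl, function(tok) as.integer(tok[2:4]) + 1L, integer(3)))
    }
  } else if (h$format == "binary_little_endian") {
    sizes <- vapply(ve$props, function(p) {
      switch(p[1], float = 4L, float32 = 4L, double = 8L, float64 = 8L,
             stop("unsupported PLY property type: ", p[1]))
    }, integer(1))
    if (length(unique(sizes)) != 1L) stop("mixed vertex property sizes unsupported")
    vals <- readBin(con, "numeric", n = ve$count * nprop, size = sizes[1],
                    endian = "little")
    vals <- matrix(vals, ncol = nprop, byrow = TRUE)
    pnames <- vapply(ve$props, function(p) p[length(p)], character(1))
    pts <- vals[, match(c("x", "y", "z"), pnames), drop = FALSE]
    faces <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      faces <- matrix(0L, fe$count, 3L)
      for (i in seq_len(fe$count)) {
        k <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
        idx <- readBin(con, "integer", n = k, size = 4L, endian = "little")
        faces[i, ] <- idx[1:3] + 1L
      }
    }
  } else {
    stop("unsupported PLY format: ", h$format, call. = FALSE)
  }
  out <- list(points = pts)
  if (!is.null(faces)) out$mesh <- new_surface_mesh(pts, faces)
  out
}

#' Read a Wavefront OBJ mesh
#' @param path OBJ file.
#' @return a `surface_mesh`.
#' @export
read_obj <- function(path) {
  txt <- readLines(path)
  vl <- txt[startsWith(txt, "v ")]
  fl <- txt[startsWith(txt, "f ")]
  verts <- matrix(as.numeric(unlist(strsplit(trimws(sub("^v ", "", vl)), "\\s+"))),
                  ncol = 3L, byrow = TRUE)
  faces <- t(vapply(strsplit(trimws(sub("^f ", "", fl)), "\\s+"), function(tok) {
    as.integer(vapply(strsplit(tok, "/"), `[[`, character(1), 1L))[1:3]
  }, integer(3)))
  new_surface_mesh(verts, faces)
}

#' Write a Wavefront OBJ mesh
#' @param mesh a `surface_mesh`.
#' @param path output file.
#' @export
write_obj <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}

#' Read / write whitespace-delimited XYZ point clouds
#' @param path file path.
#' @return `read_xyz`: N x 3 matrix.
#' @export
read_xyz <- function(path) {
  as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
}

#' @rdname read_xyz
#' @param points N x 3 matrix.
#' @export
write_xyz <- function(points, path) {
  writeLines(sprintf("%.6f %.6f %.6f", points[, 1], points[, 2], points[, 3]), path)
  invisible(path)
}
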