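#' Triangle surface mesh
#'
#' Validated container for a closed triangle mesh: an N x 3 vertex matrix in
#' millimetres and an F x 3 matrix of 0-based triangle vertex indices.
#'
#' @param vertices N x 3 numeric matrix.
#' @param faces F x 3 integer matrix of 0-based vertex indices.
#' @param validate if `TRUE` (default), reject out-of-range indices and
#'   degenerate (zero-area) triangles.
#' @return Object of class `"surface_mesh"`.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be N x 3")
  if (ncol(faces) != 3L) stop("faces must be F x 3")
  if (validate && nrow(faces) > 0L) {
    if (min(faces) < 0L || max(faces) >= nrow(vertices))
      stop("face indices out of range [0, N-1]")
    a <- vertices[faces[, 1L] + 1L, , drop = FALSE]
    e1 <- vertices[faces[, 2L] + 1L, , drop = FALSE] - a
    e2 <- vertices[faces[, 3L] + 1L, , drop = FALSE] - a
    cr <- .cross_rows(e1, e2)
    area2 <- sqrt(rowSums(cr^2))
    if (any(area2 <= .Machine$double.eps * 100))
      stop(sprintf("degenerate zero-area face(s): %s",
                   paste(which(area2 <= .Machine$double.eps * 100)[1:min(5, sum(area2 <= .Machine$double.eps * 100))] - 1L,
                         collapse = ", ")))
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

.cross_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Center a mesh at the origin
#'
#' Subtracts the vertex centroid (default) or the area-weighted face-centroid
#' center so that subsequent ray casting and normalized error metrics are
#' well posed.
#'
#' @param mesh a `"surface_mesh"`.
#' @param method `"vertex"` (unweighted vertex centroid, default) or
#'   `"area"` (triangle-area-weighted centroid of face barycenters).
#' @return The centered `"surface_mesh"`.
#' @export
center_mesh <- function(mesh, method = c("vertex", "area")) {
  stopifnot(inherits(mesh, "surface_mesh"))
  method <- match.arg(method)
  if (nrow(mesh$vertices) == 0L) stop("empty mesh cannot be centered")
  if (method == "vertex") {
    ctr <- colMeans(mesh$vertices)
  } else {
    v <- mesh$vertices
    f <- mesh$faces + 1L
    a <- v[f[, 1L], , drop = FALSE]
    b <- v[f[, 2L], , drop = FALSE]
    cc <- v[f[, 3L], , drop = FALSE]
    area <- 0.5 * sqrt(rowSums(.cross_rows(b - a, cc - a)^2))
    bary <- (a + b + cc) / 3
    ctr <- colSums(bary * area) / sum(area)
  }
  mesh$vertices <- sweep(mesh$vertices, 2L, ctr)
  mesh
}

#' Signed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes against the origin; the absolute value
#' is the enclosed volume for a consistently oriented watertight mesh.
#'
#' @param mesh a `"surface_mesh"`.
#' @return Numeric scalar volume.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces + 1L
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  abs(sum(rowSums(a * .cross_rows(b, cc))) / 6)
}

#' Read a triangle mesh from an ASCII mesh file
#'
#' Minimal readers for the ASCII variants of PLY, OBJ, OFF and STL. OBJ's
#' 1-based face indices are converted to the internal 0-based convention;
#' quad faces are fan-triangulated.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format one of `"ply"`, `"obj"`, `"off"`, `"stl"`, or `NULL` to
#'   infer from the file extension.
#' @return A `"surface_mesh"`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "obj", "off", "stl"))
  lines <- readLines(path, warn = FALSE)
  switch(format,
         ply = .read_ply(lines),
         obj = .read_obj(lines),
         off = .read_off(lines),
         stl = .read_stl(lines))
}

.split_fields <- function(x) strsplit(trimws(x), "[[:space:]]+")

.triangulate_fan <- function(idx_list) {
  do.call(rbind, lapply(idx_list, function(ix) {
    if (length(ix) < 3L) stop("face with fewer than 3 vertices")
    if (length(ix) == 3L) matrix(ix, 1L)
    else do.call(rbind, lapply(2:(length(ix) - 1L),
                               function(j) c(ix[1L], ix[j], ix[j + 1L])))
  }))
}

.read_ply <- function(lines) {
  if (!grepl("^ply", lines[1L])) stop("not a PLY file")
  if (!any(grepl("format[[:space:]]+ascii", lines)))
    stop("only ASCII PLY is supported")
  endh <- which(trimws(lines) == "end_header")[1L]
  header <- lines[seq_len(endh)]
  el <- grep("^element[[:space:]]", header, value = TRUE)
  counts <- stats::setNames(
    as.integer(vapply(.split_fields(el), `[`, "", 3L)),
    vapply(.split_fields(el), `[`, "", 2L))
  nv <- counts[["vertex"]]
  nf <- counts[["face"]]
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vparts <- .split_fields(body[seq_len(nv)])
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3L)))
  fparts <- .split_fields(body[nv + seq_len(nf)])
  faces <- .triangulate_fan(lapply(fparts, function(p) {
    k <- as.integer(p[1L])
    as.integer(p[1L + seq_len(k)])
  }))
  surface_mesh(verts, faces)
}

.read_obj <- function(lines) {
  parts <- .split_fields(lines)
  key <- vapply(parts, function(p) if (length(p)) p[1L] else "", "")
  vp <- parts[key == "v"]
  verts <- t(vapply(vp, function(p) as.numeric(p[2:4]), numeric(3L)))
  fp <- parts[key == "f"]
  faces <- .triangulate_fan(lapply(fp, function(p) {
    ix <- vapply(strsplit(p[-1L], "/"), `[`, "", 1L)
    as.integer(ix) - 1L            # OBJ is 1-based
  }))
  surface_mesh(verts, faces)
}

.read_off <- function(lines) {
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", trimws(lines))]
  if (trimws(lines[1L]) == "OFF") lines <- lines[-1L]
  hdr <- as.integer(.split_fields(lines[1L])[[1L]])
  nv <- hdr[1L]; nf <- hdr[2L]
  vparts <- .split_fields(lines[1L + seq_len(nv)])
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3L)))
  fparts <- .split_fields(lines[1L + nv + seq_len(nf)])
  faces <- .triangulate_fan(lapply(fparts, function(p) {
    k <- as.integer(p[1L])
    as.integer(p[1L + seq_len(k)])
  }))
  surface_mesh(verts, faces)
}

.read_stl <- function(lines) {
  vx <- grep("^[[:space:]]*vertex[[:space:]]", lines, value = TRUE)
  vm <- t(vapply(.split_fields(vx), function(p) as.numeric(p[2:4]), numeric(3L)))
  if (nrow(vm) %% 3L != 0L) stop("malformed ASCII STL")
  # weld duplicated corner vertices
  key <- apply(round(vm, 9L), 1L, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- vm[uk, , drop = FALSE]
  id <- match(key, key[uk]) - 1L
  faces <- matrix(id, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' Write a triangle mesh to an ASCII mesh file
#'
#' @param mesh a `"surface_mesh"`.
#' @param path output file path.
#' @param format one of `"ply"`, `"obj"`, `"off"`, `"stl"`, or `NULL` to
#'   infer from the extension. Vertex order is preserved exactly, so
#'   corresponded (icosphere-ordered) meshes stay corresponded on disk.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "obj", "off", "stl"))
  v <- mesh$vertices
  f <- mesh$faces
  fmt_v <- sprintf("%.10g %.10g %.10g", v[, 1L], v[, 2L], v[, 3L])
  lines <- switch(
    format,
    ply = c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(v)),
            "property float x", "property float y", "property float z",
            sprintf("element face %d", nrow(f)),
            "property list uchar int vertex_indices", "end_header",
            fmt_v,
            sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L])),
    obj = c(paste("v", fmt_v),
            sprintf("f %d %d %d", f[, 1L] + 1L, f[, 2L] + 1L, f[, 3L] + 1L)),
    off = c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)),
            fmt_v,
            sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L])),
    stl = {
      a <- v[f[, 1L] + 1L, , drop = FALSE]
      b <- v[f[, 2L] + 1L, , drop = FALSE]
      cc <- v[f[, 3L] + 1L, , drop = FALSE]
      n <- .cross_rows(b - a, cc - a)
      n <- n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
      tri <- function(p) sprintf("      vertex %.10g %.10g %.10g",
                                 p[, 1L], p[, 2L], p[, 3L])
      body <- character(0)
      chunks <- lapply(seq_len(nrow(f)), function(i) c(
        sprintf("  facet normal %.10g %.10g %.10g", n[i, 1L], n[i, 2L], n[i, 3L]),
        "    outer loop",
        tri(a[i, , drop = FALSE]), tri(b[i, , drop = FALSE]),
        tri(cc[i, , drop = FALSE]),
        "    endloop", "  endfacet"))
      c("solid mesh", unlist(chunks), "endsolid mesh")
    })
  writeLines(lines, path)
  invisible(path)
}
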