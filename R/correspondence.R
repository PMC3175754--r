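#' Build a Class-I geodesic icosphere
#'
#' Subdivides each edge of a regular icosahedron into `frequency` equal
#' segments, triangulates every face into `frequency^2` small triangles and
#' projects all vertices onto the unit sphere. The vertex count is
#' \eqn{W = 10 f^2 + 2} and the face count \eqn{20 f^2}; frequency 20 gives
#' the 4002-vertex tessellation typical for kidney-sized organs.
#'
#' @param frequency positive integer subdivision frequency `f`.
#' @return Object of class `"icosphere"` (also `"surface_mesh"`): unit-norm
#'   `vertices`, `faces`, plus `frequency` and `n_vertices`.
#' @examples
#' ico <- build_icosphere(2)
#' ico$n_vertices  # 42
#' @export
build_icosphere <- function(frequency) {
  frequency <- as.integer(frequency)
  if (length(frequency) != 1L || is.na(frequency) || frequency < 1L)
    stop("invalid frequency: must be a positive integer")
  t <- (1 + sqrt(5)) / 2
  base_v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  base_v <- base_v / sqrt(1 + t^2)
  base_f <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1)) + 1L

  f <- frequency
  verts <- list()
  faces <- list()
  vidx <- new.env(parent = emptyenv(), hash = TRUE)
  nvert <- 0L
  get_vertex <- function(p) {
    p <- p / sqrt(sum(p^2))
    key <- paste(sprintf("%.9f", p), collapse = ",")
    id <- vidx[[key]]
    if (is.null(id)) {
      nvert <<- nvert + 1L
      id <- nvert
      vidx[[key]] <- id
      verts[[id]] <<- p
    }
    id
  }
  for (tf in seq_len(nrow(base_f))) {
    v1 <- base_v[base_f[tf, 1L], ]
    v2 <- base_v[base_f[tf, 2L], ]
    v3 <- base_v[base_f[tf, 3L], ]
    # barycentric lattice rows i = 0..f (from v1 toward the v2-v3 edge)
    rows <- vector("list", f + 1L)
    for (i in 0:f) {
      rows[[i + 1L]] <- vapply(0:i, function(j) {
        p <- ((f - i) * v1 + (i - j) * v2 + j * v3) / f
        get_vertex(p)
      }, integer(1L))
    }
    for (i in 1:f) {
      up <- rows[[i]]
      lo <- rows[[i + 1L]]
      for (j in 0:(i - 1L)) {
        faces[[length(faces) + 1L]] <- c(lo[j + 1L], lo[j + 2L], up[j + 1L])
        if (j < i - 1L)
          faces[[length(faces) + 1L]] <- c(lo[j + 2L], up[j + 2L], up[j + 1L])
      }
    }
  }
  V <- do.call(rbind, verts)
  Fc <- do.call(rbind, faces) - 1L
  out <- surface_mesh(V, Fc)
  out$frequency <- f
  out$n_vertices <- nrow(V)
  class(out) <- c("icosphere", "surface_mesh")
  out
}

#' @export
print.icosphere <- function(x, ...) {
  cat(sprintf("Icosphere: frequency %d, %d vertices, %d faces\n",
              x$frequency, x$n_vertices, nrow(x$faces)))
  invisible(x)
}

#' Spherical parameterization of icosphere directions
#'
#' Maps the unit vertex directions to polar coordinates,
#' \eqn{\theta = \arccos z}, \eqn{\phi = \mathrm{atan2}(y, x)} wrapped into
#' `[0, 2*pi)`.
#'
#' @param sphere an `"icosphere"` (or any mesh with unit-norm vertices).
#' @return An [sh_parameterization()] in icosphere vertex order.
#' @export
sphere_directions_to_parameterization <- function(sphere) {
  v <- sphere$vertices
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("vertices must be unit vectors")
  theta <- acos(pmin(pmax(v[, 3L], -1), 1))
  phi <- atan2(v[, 2L], v[, 1L]) %% (2 * pi)
  sh_parameterization(theta, phi)
}

#' Resample a star-shaped mesh by ray casting onto icosphere directions
#'
#' For every icosphere vertex direction, casts a ray from the origin and
#' replaces it with the ray-surface intersection point, giving a resampled
#' mesh in icosphere vertex order. Applying this to every deformation of a
#' cohort with the same icosphere yields point-wise correspondence: vertex
#' k of every output lies on ray k.
#'
#' The input must be centered at the origin (see [center_mesh()]) and
#' star-shaped about it for a unique intersection per ray. With
#' `strict = TRUE` multiple intersections raise an error; otherwise the
#' intersection farthest from the origin is used and a warning names the
#' affected rays.
#'
#' @param mesh a centered `"surface_mesh"`.
#' @param sphere the target `"icosphere"`.
#' @param strict error on multiple intersections instead of taking the
#'   outermost one.
#' @return Object of class `"corresponded_surface"`: list with `mesh`
#'   (a `"surface_mesh"` with the icosphere's connectivity), `param`
#'   (the shared [sh_parameterization()]) and `frequency`.
#' @export
ray_cast_resample <- function(mesh, sphere, strict = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(sphere, "icosphere"))
  v <- mesh$vertices
  f <- mesh$faces + 1L
  A <- v[f[, 1L], , drop = FALSE]
  E1 <- v[f[, 2L], , drop = FALSE] - A
  E2 <- v[f[, 3L], , drop = FALSE] - A
  dirs <- sphere$vertices
  W <- nrow(dirs)
  out <- matrix(NA_real_, W, 3L)
  multi <- integer(0)
  btol <- 1e-9   # barycentric slack so rays through edges/vertices still hit
  for (k in seq_len(W)) {
    d <- dirs[k, ]
    ts <- .ray_triangle_ts(d, A, E1, E2, btol)
    if (length(ts) == 0L)
      stop(sprintf("missing intersection: ray %d hit no triangle", k))
    # hits on shared edges/vertices duplicate; collapse nearly equal depths
    ts <- sort(ts)
    ts <- ts[c(TRUE, diff(ts) > 1e-7 * max(ts))]
    if (length(ts) > 1L) {
      if (strict)
        stop(sprintf(
          "multiple intersections on ray %d (%d hits); surface not star-shaped",
          k, length(ts)))
      multi <- c(multi, k)
    }
    out[k, ] <- max(ts) * d
  }
  if (length(multi) > 0L)
    warning(sprintf(
      "%d ray(s) had multiple intersections; outermost point used (rays: %s%s)",
      length(multi), paste(utils::head(multi, 10L), collapse = ", "),
      if (length(multi) > 10L) ", ..." else ""))
  structure(list(mesh = surface_mesh(out, sphere$faces, validate = FALSE),
                 param = sphere_directions_to_parameterization(sphere),
                 frequency = sphere$frequency),
            class = "corresponded_surface")
}

# Moller-Trumbore over all triangles for a single ray from the origin;
# returns the positive ray depths t of all hits.
.ray_triangle_ts <- function(d, A, E1, E2, btol) {
  # h = d x E2
  h1 <- d[2L] * E2[, 3L] - d[3L] * E2[, 2L]
  h2 <- d[3L] * E2[, 1L] - d[1L] * E2[, 3L]
  h3 <- d[1L] * E2[, 2L] - d[2L] * E2[, 1L]
  det <- E1[, 1L] * h1 + E1[, 2L] * h2 + E1[, 3L] * h3
  ok <- abs(det) > 1e-14
  inv <- ifelse(ok, 1 / det, 0)
  # s = origin - A = -A
  u <- -(A[, 1L] * h1 + A[, 2L] * h2 + A[, 3L] * h3) * inv
  # q = s x E1 = (-A) x E1
  q1 <- -(A[, 2L] * E1[, 3L] - A[, 3L] * E1[, 2L])
  q2 <- -(A[, 3L] * E1[, 1L] - A[, 1L] * E1[, 3L])
  q3 <- -(A[, 1L] * E1[, 2L] - A[, 2L] * E1[, 1L])
  v <- (d[1L] * q1 + d[2L] * q2 + d[3L] * q3) * inv
  t <- (E2[, 1L] * q1 + E2[, 2L] * q2 + E2[, 3L] * q3) * inv
  hit <- ok & u >= -btol & v >= -btol & (u + v) <= 1 + btol & t > 1e-12
  t[hit]
}

#' @export
print.corresponded_surface <- function(x, ...) {
  cat(sprintf(
    "Corresponded surface: %d vertices on a frequency-%d icosphere\n",
    nrow(x$mesh$vertices), x$frequency))
  invisible(x)
}

#' Coordinates of a corresponded surface as a matrix
#'
#' @param surface a `"corresponded_surface"` or `"surface_mesh"`.
#' @return N x 3 numeric matrix of vertex coordinates.
#' @export
surface_coords <- function(surface) {
  if (inherits(surface, "corresponded_surface")) surface$mesh$vertices
  else if (inherits(surface, "surface_mesh")) surface$vertices
  else as.matrix(surface)
}
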