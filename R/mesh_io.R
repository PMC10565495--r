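#' Minimal triangle-mesh container and OBJ/STL I/O
#'
#' Meshes are lists with `vertices` (n x 3) and `faces` (m x 3, 1-based),
#' class `ls_mesh`. Only the plain-text Wavefront OBJ and ASCII STL subsets
#' needed for bone surfaces are supported.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of vertex indices.
#' @export
new_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "ls_mesh")
}

#' @rdname new_mesh
#' @param path file path; format chosen by extension (.obj, .stl).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") return(read_obj(path))
  if (ext == "stl") return(read_stl_ascii(path))
  stop("unsupported mesh format: ", ext)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    idx <- vapply(x[-1], function(tok)
      as.integer(strsplit(tok, "/")[[1]][1]), integer(1))
    if (length(idx) != 3L) stop("only triangular faces are supported")
    idx
  }))
  new_mesh(v, f)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("vertex", lines, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  if (nrow(v) %% 3L != 0L) stop("malformed ASCII STL")
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  new_mesh(v, f)
}

#' @rdname new_mesh
#' @param mesh an `ls_mesh`.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

# closest point on one triangle (a, b, c) to p (Ericson's algorithm)
closest_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * (d1 / (d1 - d3)))
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * (d2 / (d2 - d6)))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c - b) * ((d4 - d3) / ((d4 - d3) + (d5 - d6))))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

#' Nearest point on a triangle mesh
#'
#' Scans all triangles; ties at equal distance are broken by the first
#' triangle in face order.
#'
#' @param p length-3 point.
#' @param mesh an `ls_mesh`.
#' @return list with `point`, `distance`, `face`.
#' @export
mesh_nearest_point <- function(p, mesh) {
  if (!nrow(mesh$faces)) stop("empty mesh")
  best <- NULL; bestd <- Inf; bestf <- NA_integer_
  V <- mesh$vertices; Fc <- mesh$faces
  for (k in seq_len(nrow(Fc))) {
    q <- closest_point_triangle(p, V[Fc[k, 1], ], V[Fc[k, 2], ], V[Fc[k, 3], ])
    d <- sqrt(sum((p - q)^2))
    if (d < bestd - 1e-15) { bestd <- d; best <- q; bestf <- k }
  }
  list(point = best, distance = bestd, face = bestf)
}

# Moller-Trumbore segment-triangle intersection test
segment_hits_triangle <- function(p0, p1, a, b, c, eps = 1e-12) {
  dir <- p1 - p0
  e1 <- b - a; e2 <- c - a
  h <- cross3(dir, e2)
  det <- sum(e1 * h)
  if (abs(det) < eps) return(FALSE)
  f <- 1 / det
  s <- p0 - a
  u <- f * sum(s * h)
  if (u < -1e-9 || u > 1 + 1e-9) return(FALSE)
  q <- cross3(s, e1)
  v <- f * sum(dir * q)
  if (v < -1e-9 || u + v > 1 + 1e-9) return(FALSE)
  t <- f * sum(e2 * q)
  t > 1e-9 && t < 1 - 1e-9
}

#' Does a straight segment pierce a mesh?
#'
#' Used by the registration QA report to flag muscle path segments that cut
#' through bone.
#' @param p0,p1 segment endpoints.
#' @param mesh an `ls_mesh`.
#' @export
segment_pierces_mesh <- function(p0, p1, mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  for (k in seq_len(nrow(Fc))) {
    if (segment_hits_triangle(p0, p1, V[Fc[k, 1], ], V[Fc[k, 2], ],
                              V[Fc[k, 3], ])) return(TRUE)
  }
  FALSE
}

#' Parametric primitive meshes (box, ellipsoid)
#'
#' Small triangle meshes used for synthetic bones and registration tests.
#' @param center length-3 center.
#' @param half length-3 half-extents (box).
#' @export
mesh_box <- function(center = c(0, 0, 0), half = c(1, 1, 1)) {
  s <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  v <- sweep(sweep(s, 2, half, `*`), 2, center, `+`)
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  new_mesh(v, f)
}

#' @rdname mesh_box
#' @param radii length-3 semi-axes (ellipsoid).
#' @param n angular resolution.
#' @export
mesh_ellipsoid <- function(center = c(0, 0, 0), radii = c(1, 1, 1), n = 12L) {
  th <- seq(0, pi, length.out = n + 1L)[-c(1, n + 1L)]
  ph <- seq(0, 2 * pi, length.out = 2L * n + 1L)[-(2L * n + 1L)]
  grid <- expand.grid(th = th, ph = ph)
  v <- cbind(sin(grid$th) * cos(grid$ph), sin(grid$th) * sin(grid$ph),
             cos(grid$th))
  v <- rbind(c(0, 0, 1), v, c(0, 0, -1))
  v <- sweep(sweep(v, 2, radii, `*`), 2, center, `+`)
  nt <- length(th); np <- length(ph)
  id <- function(i, j) 1L + (((j - 1L) %% np) * nt + i)
  f <- list()
  for (j in seq_len(np)) {
    f[[length(f) + 1L]] <- c(1L, id(1L, j), id(1L, j + 1L))
    f[[length(f) + 1L]] <- c(nrow(v), id(nt, j + 1L), id(nt, j))
    for (i in seq_len(nt - 1L)) {
      f[[length(f) + 1L]] <- c(id(i, j), id(i + 1L, j), id(i, j + 1L))
      f[[length(f) + 1L]] <- c(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
    }
  }
  new_mesh(v, do.call(rbind, f))
}
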