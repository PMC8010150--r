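#' Triangle meshes
#'
#' A `triangle_mesh` is a triangulated surface in world mm: an n x 3 vertex
#' matrix and an m x 3 matrix of 1-based vertex indices with consistent
#' outward orientation. Surfaces produced by the reconstruction are closed
#' 2-manifolds with Euler characteristic 2.
#'
#' @param vertices n x 3 numeric matrix (world mm)
#' @param triangles m x 3 integer matrix of 1-based vertex indices
#' @return an object of class `triangle_mesh`
#' @export
triangle_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3 || ncol(triangles) != 3)
    stop("vertices and triangles must have 3 columns")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles, chi = %d\n",
              nrow(x$vertices), nrow(x$triangles),
              euler_characteristic(x)))
  invisible(x)
}

#' Unique undirected edges of a mesh
#' @param mesh a `triangle_mesh`
#' @return 2-column matrix of vertex index pairs (u < v), with attribute
#'   `count` giving the number of incident triangles per edge
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  n <- nrow(mesh$vertices)
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- as.numeric(e[, 1]) + (n + 1) * as.numeric(e[, 2])
  ord <- order(key)
  ks <- key[ord]
  first <- !duplicated(ks)
  counts <- as.integer(diff(c(which(first), length(ks) + 1L)))
  out <- e[ord[first], , drop = FALSE]
  attr(out, "count") <- counts
  out
}

#' Euler characteristic V - E + F
#' @param mesh a `triangle_mesh`
#' @return integer
#' @export
euler_characteristic <- function(mesh) {
  ne <- nrow(mesh_edges(mesh))
  nrow(mesh$vertices) - ne + nrow(mesh$triangles)
}

#' Check that a mesh is closed and manifold
#' @param mesh a `triangle_mesh`
#' @return logical; TRUE when every edge has exactly two incident triangles
#' @export
is_closed_manifold <- function(mesh) {
  e <- mesh_edges(mesh)
  all(attr(e, "count") == 2L)
}

#' Area-weighted unit vertex normals
#' @param mesh a `triangle_mesh`
#' @return n x 3 matrix of unit normals
#' @export
vertex_normals <- function(mesh) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  a <- V[Tm[, 2], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  b <- V[Tm[, 3], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # 2*area-weighted
  n <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    n[, 1] <- n[, 1] + unname(tapply_add(fn[, 1], Tm[, k], nrow(V)))
    n[, 2] <- n[, 2] + unname(tapply_add(fn[, 2], Tm[, k], nrow(V)))
    n[, 3] <- n[, 3] + unname(tapply_add(fn[, 3], Tm[, k], nrow(V)))
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-30] <- 1
  n / len
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh a `triangle_mesh` with outward orientation
#' @return volume in mm^3 (positive for outward-oriented closed meshes)
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  a <- V[Tm[, 1], , drop = FALSE]
  b <- V[Tm[, 2], , drop = FALSE]
  c <- V[Tm[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Sparse vertex adjacency matrix
#' @param mesh a `triangle_mesh`
#' @return symmetric sparse 0/1 Matrix
#' @export
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}

#' One step of uniform Laplacian smoothing
#' @param V vertex matrix
#' @param A adjacency Matrix (from [vertex_adjacency()])
#' @param lambda step in (0,1]; negative values inflate (Taubin mu step)
#' @return smoothed vertex matrix
#' @keywords internal
laplacian_step <- function(V, A, lambda) {
  deg <- Matrix::rowSums(A)
  mean_nb <- as.matrix(A %*% V) / deg
  V + lambda * (mean_nb - V)
}

#' Taubin lambda/mu smoothing (low-shrink)
#' @param mesh a `triangle_mesh`
#' @param iterations number of lambda+mu pairs
#' @param lambda positive smoothing step
#' @param mu negative inflation step
#' @return smoothed `triangle_mesh` with identical connectivity
#' @export
taubin_smooth <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  A <- vertex_adjacency(mesh)
  V <- mesh$vertices
  for (i in seq_len(iterations)) {
    V <- laplacian_step(V, A, lambda)
    V <- laplacian_step(V, A, mu)
  }
  triangle_mesh(V, mesh$triangles)
}

# ---------------------------------------------------------------- icosphere --

#' Subdivided icosahedron on the unit sphere
#'
#' `level` subdivisions give `20 * 4^level` triangles and
#' `10 * 4^level + 2` vertices, in a deterministic vertex order so that all
#' meshes resampled at the same level share connectivity.
#'
#' @param level integer >= 0
#' @return a `triangle_mesh` on the unit sphere
#' @export
icosphere <- function(level = 0) {
  stopifnot(level >= 0)
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  Fm <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    res <- subdivide_tris(V, Fm)
    V <- res$V
    Fm <- res$F
    V <- V / sqrt(rowSums(V^2))
  }
  triangle_mesh(V, Fm)
}

subdivide_tris <- function(V, Fm) {
  nv <- nrow(V)
  e <- rbind(Fm[, c(1, 2)], Fm[, c(2, 3)], Fm[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- e[, 1] + (nv + 1) * e[, 2]
  uk <- sort(unique(key))
  mid_id <- nv + match(key, uk)
  ue_i <- match(uk, key)
  mids <- (V[e[ue_i, 1], , drop = FALSE] + V[e[ue_i, 2], , drop = FALSE]) / 2
  V2 <- rbind(V, mids)
  m12 <- mid_id[seq_len(nrow(Fm))]
  m23 <- mid_id[nrow(Fm) + seq_len(nrow(Fm))]
  m31 <- mid_id[2 * nrow(Fm) + seq_len(nrow(Fm))]
  F2 <- rbind(cbind(Fm[, 1], m12, m31),
              cbind(Fm[, 2], m23, m12),
              cbind(Fm[, 3], m31, m23),
              cbind(m12, m23, m31))
  list(V = V2, F = F2)
}

# ------------------------------------------------------------------ OBJ I/O --

#' Write a surface (Wavefront OBJ), optionally with per-vertex scalars
#'
#' Scalars are written next to the mesh as a plain text file (one value per
#' vertex line) with suffix `.txt`, or to `scalar_path` when given.
#'
#' @param mesh a `triangle_mesh`
#' @param path output `.obj` path
#' @param scalars optional numeric vector, one value per vertex
#' @param scalar_path optional explicit path for the scalar file
#' @export
write_surface <- function(mesh, path, scalars = NULL, scalar_path = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!is.null(scalars) && length(scalars) != nrow(mesh$vertices))
    stop("scalar map length (", length(scalars),
         ") does not match vertex count (", nrow(mesh$vertices), ")")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
  if (!is.null(scalars)) {
    if (is.null(scalar_path))
      scalar_path <- paste0(sub("\\.obj$", "", path), ".txt")
    writeLines(sprintf("%.9g", scalars), scalar_path)
  }
  invisible(NULL)
}

#' Read a Wavefront OBJ surface
#' @param path `.obj` file
#' @return a `triangle_mesh`
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  V <- do.call(rbind, lapply(strsplit(vl, "[[:space:]]+"), function(x)
    as.numeric(x[2:4])))
  Fm <- do.call(rbind, lapply(strsplit(fl, "[[:space:]]+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  triangle_mesh(V, Fm)
}

#' Read a per-vertex scalar map (plain text, one value per line)
#' @param path text file
#' @return numeric vector
#' @export
read_scalar_map <- function(path) as.numeric(readLines(path))

# ---------------------------------------------------------------- QA checks --

#' Count exact triangle-triangle self-intersections
#'
#' Pairs of triangles sharing a vertex are excluded.
#' @param mesh a `triangle_mesh`
#' @return integer count of intersecting non-adjacent triangle pairs
#' @export
count_self_intersections <- function(mesh) {
  self_intersection_count_cpp(mesh$vertices, mesh$triangles)
}

#' Shortest distance from points to a mesh (exact point-to-triangle)
#' @param points n x 3 matrix of world mm coordinates
#' @param mesh a `triangle_mesh`
#' @return list with `distance`, `closest` points and `triangle` indices
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- to_xyz_matrix(points)
  point_mesh_dist_cpp(points, mesh$vertices, mesh$triangles)
}
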