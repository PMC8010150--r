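#' Extract a genus-zero mesh on the boundary of a binary mask
#'
#' Spherical topology is guaranteed by collapsing, in voxel space, a filled
#' ellipsoid enclosing the mask onto the mask: voxels outside the mask are
#' removed farthest-first, but only when removal is a simple-point operation
#' (object 26-connectivity, background 6-connectivity), so the result is
#' homotopic to the ellipsoid. Handles in the mask are plugged and cavities
#' filled. The collapsed set is then made well-composed by topology-
#' preserving voxel additions, its exact voxel-boundary surface is
#' triangulated, and the blocky surface is relaxed by low-shrink Taubin
#' smoothing.
#'
#' @param mask a binary `voxel_grid` (nonzero = object); the largest
#'   26-connected component is used
#' @param smooth_iterations Taubin smoothing pairs applied to the voxel
#'   boundary surface
#' @param ellipsoid_margin relative enlargement of the enclosing ellipsoid
#' @return a closed, manifold, genus-zero `triangle_mesh` in world mm
#' @export
extract_wm_mesh <- function(mask, smooth_iterations = 10,
                            ellipsoid_margin = 1.25) {
  stopifnot(inherits(mask, "voxel_grid"))
  m <- mask$data != 0
  if (!any(m)) stop("empty mask")
  dm <- dim(m)
  mi <- array(0L, dm)
  mi[m] <- 1L
  lab <- label_components_cpp(as.integer(mi), dm, 26L)
  ncomp <- attr(lab, "ncomp")
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0], ncomp)
    keep <- which.max(sizes)
    mi <- array(as.integer(lab == keep), dm)
  }
  # pad so the enclosing ellipsoid fits strictly inside the grid
  idx <- which(array(mi == 1L, dm))
  coord <- arrayInd(idx, dm)
  lo <- apply(coord, 2, min)
  hi <- apply(coord, 2, max)
  half <- (hi - lo) / 2 + 1
  need <- ceiling(half * (ellipsoid_margin - 1) + 4)
  pad <- as.integer(pmax(need - pmin(lo - 1, dm - hi), 2))
  pad <- max(pad)
  dmp <- dm + 2L * pad
  mp <- array(0L, dmp)
  mp[(pad + 1):(pad + dm[1]), (pad + 1):(pad + dm[2]),
     (pad + 1):(pad + dm[3])] <- mi
  ctr <- (lo + hi) / 2 + pad
  ax <- half * ellipsoid_margin + 3
  co <- grid_coords(dmp, 1)
  ell <- ((co$X + 1 - ctr[1]) / ax[1])^2 + ((co$Y + 1 - ctr[2]) / ax[2])^2 +
    ((co$Z + 1 - ctr[3]) / ax[3])^2 <= 1
  ell <- array(as.integer(ell | mp == 1L), dmp)
  rm(co)

  sp <- grid_spacing(mask)
  dist <- chamfer_distance_cpp(as.integer(mp), dmp, sp)
  collapsed <- collapse_to_mask_cpp(as.integer(ell), as.integer(mp), dmp, dist)
  wc <- well_compose_cpp(collapsed, dmp)
  bm <- boundary_mesh_cpp(wc, dmp)
  # voxel coords (0-based, padded frame) -> original frame -> world
  vox <- bm$vertices - pad
  mesh <- triangle_mesh(world_from_voxel(mask, vox, check_bounds = FALSE),
                        orient_triangles(bm$triangles, mask$affine))
  if (smooth_iterations > 0) mesh <- taubin_smooth(mesh, smooth_iterations)
  mesh
}

# flip winding when the affine is reflecting, so outward stays outward
orient_triangles <- function(tris, affine) {
  if (det(affine[1:3, 1:3]) < 0) tris[, c(1, 3, 2)] else tris
}

#' Coarsen a mesh by edge collapse
#'
#' Vertices are removed by merging the two vertices of an edge (shortest
#' first, midpoint placement). A collapse is performed only when it is
#' topologically valid (link condition) and does not flip any incident
#' triangle, so the output remains closed and manifold with the same Euler
#' characteristic.
#'
#' @param mesh a closed `triangle_mesh`
#' @param target_vertex_count desired vertex count
#' @return coarsened `triangle_mesh`; the achieved count is reported in the
#'   attribute `achieved` when the target could not be reached
#' @export
coarsen_mesh <- function(mesh, target_vertex_count) {
  nv <- nrow(mesh$vertices)
  if (target_vertex_count >= nv) return(mesh)
  res <- decimate_cpp(mesh$vertices, mesh$triangles,
                      as.integer(target_vertex_count))
  out <- triangle_mesh(res$vertices, res$triangles)
  if (res$achieved > target_vertex_count) {
    warning("decimation stopped early at ", res$achieved, " vertices")
    attr(out, "achieved") <- res$achieved
  }
  out
}

#' Inflate a genus-zero mesh to the unit sphere
#'
#' Iterative Laplacian smoothing until a convex blob is reached (convexity
#' proxy: fraction of vertices whose umbrella vector points inward), then
#' projection onto the centroid-centered unit sphere followed by tangential
#' relaxation until the spherical triangulation has no flipped (negative
#' signed area) triangles.
#'
#' @param mesh a closed genus-zero `triangle_mesh`
#' @param max_iterations smoothing iteration cap
#' @param convexity_threshold fraction of convex vertices that counts as
#'   converged
#' @param lambda smoothing step
#' @return a `sphere_map`: list with `sphere` (unit-sphere `triangle_mesh`)
#'   and `mesh` (the input mesh, vertex-matched)
#' @export
inflate_to_sphere <- function(mesh, max_iterations = 500,
                              convexity_threshold = 1.0, lambda = 0.6) {
  if (euler_characteristic(mesh) != 2L)
    stop("inflation requires a genus-zero mesh (Euler characteristic 2)")
  A <- vertex_adjacency(mesh)
  V <- mesh$vertices
  iters <- 0L
  for (i in seq_len(max_iterations)) {
    iters <- i
    ctr <- colMeans(V)
    Vc <- sweep(V, 2, ctr)
    deg <- Matrix::rowSums(A)
    umb <- as.matrix(A %*% Vc) / deg - Vc   # umbrella (discrete Laplacian)
    convex <- rowSums(umb * Vc) < 0         # neighbours' mean lies inside
    if (mean(convex) >= convexity_threshold && i > 1) break
    V <- V + lambda * (as.matrix(A %*% V) / deg - V)
  }
  ctr <- colMeans(V)
  S <- sweep(V, 2, ctr)
  S <- S / sqrt(rowSums(S^2))
  # tangential relaxation on the sphere until no flipped triangles
  for (i in seq_len(200)) {
    nf <- count_flipped_spherical(S, mesh$triangles)
    if (nf == 0L) break
    deg <- Matrix::rowSums(A)
    S <- as.matrix(A %*% S) / deg
    S <- S / sqrt(rowSums(S^2))
  }
  out <- list(sphere = triangle_mesh(S, mesh$triangles), mesh = mesh,
              iterations = iters,
              flipped = count_flipped_spherical(S, mesh$triangles))
  class(out) <- "sphere_map"
  out
}

#' Count flipped spherical triangles (negative signed volume with the origin)
#' @param S unit-sphere vertex matrix
#' @param tris triangle index matrix
#' @return integer count
#' @export
count_flipped_spherical <- function(S, tris) {
  a <- S[tris[, 1], , drop = FALSE]
  b <- S[tris[, 2], , drop = FALSE]
  c <- S[tris[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(det3 <= 0)
}

#' Resample a mesh onto a subdivided icosahedron
#'
#' Each vertex of the level-`level` icosphere (`20 * 4^level` triangles,
#' `10 * 4^level + 2` vertices; level 6 gives 81,920 triangles) is located in
#' the spherical triangulation of the inflated mesh and pulled back to
#' original space with its barycentric coordinates. All surfaces resampled at
#' the same level share vertex ordering and triangle connectivity, which
#' fixes vertex correspondence across subjects.
#'
#' @param mesh original-space `triangle_mesh` (vertex-matched to `sphere`)
#' @param sphere a `sphere_map` from [inflate_to_sphere()] (or a unit-sphere
#'   `triangle_mesh` with the same connectivity as `mesh`)
#' @param level icosahedron subdivision level (>= 0)
#' @return resampled `triangle_mesh` with icosahedral connectivity
#' @export
icosahedron_resample <- function(mesh, sphere, level = 6) {
  S <- if (inherits(sphere, "sphere_map")) sphere$sphere else sphere
  stopifnot(nrow(S$vertices) == nrow(mesh$vertices))
  ico <- icosphere(level)
  loc <- locate_on_sphere_cpp(S$vertices, S$triangles, ico$vertices)
  tris <- S$triangles[loc$triangle, , drop = FALSE]
  Vn <- loc$bary[, 1] * mesh$vertices[tris[, 1], , drop = FALSE] +
    loc$bary[, 2] * mesh$vertices[tris[, 2], , drop = FALSE] +
    loc$bary[, 3] * mesh$vertices[tris[, 3], , drop = FALSE]
  out <- triangle_mesh(Vn, ico$triangles)
  attr(out, "fallback_count") <- sum(!loc$exact)
  out
}

#' Push apart self-proximal parts of a mesh
#'
#' Non-adjacent parts of the surface closer than `min_separation` are
#' displaced apart along the line of closest approach, iteratively, until
#' separation is achieved and the exact triangle-triangle intersection count
#' is zero (or the iteration cap is hit, with a warning).
#'
#' @param mesh a `triangle_mesh`
#' @param min_separation minimum allowed distance (mm) between non-adjacent
#'   parts ("non-adjacent" = outside each vertex's `ring`-ring)
#' @param ring graph-ring radius treated as local (excluded from proximity)
#' @param max_iter iteration cap
#' @return a `triangle_mesh` with the same connectivity
#' @export
enforce_self_proximity <- function(mesh, min_separation = 0.25, ring = 3,
                                   max_iter = 15) {
  V <- mesh$vertices
  Fm <- mesh$triangles
  for (i in seq_len(max_iter)) {
    pr <- vertex_proximity_cpp(V, Fm, as.integer(ring), min_separation)
    close_v <- which(is.finite(pr$distance) & pr$distance < min_separation)
    if (length(close_v) == 0) break
    push <- (min_separation - pr$distance[close_v]) * 0.6 + 0.05
    V[close_v, ] <- V[close_v, ] + pr$direction[close_v, , drop = FALSE] * push
  }
  # stubborn crossings (typically coincident sheets in deep sulci): relax the
  # involved vertices toward their neighbourhood mean until they separate
  A <- NULL
  for (i in seq_len(max_iter)) {
    pairs <- self_intersection_pairs_cpp(V, Fm)
    if (nrow(pairs) == 0) break
    if (is.null(A)) A <- vertex_adjacency(triangle_mesh(V, Fm))
    vids <- unique(as.vector(Fm[as.vector(pairs), ]))
    deg <- Matrix::rowSums(A)
    mean_nb <- as.matrix(A %*% V) / deg
    V[vids, ] <- V[vids, , drop = FALSE] +
      0.5 * (mean_nb[vids, , drop = FALSE] - V[vids, , drop = FALSE])
  }
  out <- triangle_mesh(V, Fm)
  if (count_self_intersections(out) > 0)
    warning("self-intersections remain after proximity enforcement")
  out
}
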