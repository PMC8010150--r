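#' Cortical thickness between WM and pial surfaces
#'
#' Three definitions are available. `linked` uses the one-to-one vertex
#' correspondence created by the streamline expansion (Euclidean distance
#' between corresponding vertices); `nearest` is the shortest distance from
#' each WM vertex to the pial mesh (exact point-to-triangle); `symmetric`
#' averages nearest distances in both directions. All are computed in the
#' native space of the meshes.
#'
#' @param wm_mesh WM `triangle_mesh`
#' @param pial_mesh pial `triangle_mesh`
#' @param method `"linked"`, `"nearest"` or `"symmetric"`
#' @return numeric per-vertex thickness (mm) on the WM mesh vertices, class
#'   `vertex_map` with attributes `mesh_vertices` and `smoothing`
#' @export
cortical_thickness <- function(wm_mesh, pial_mesh,
                               method = c("linked", "nearest", "symmetric")) {
  method <- match.arg(method)
  nw <- nrow(wm_mesh$vertices)
  if (method == "linked") {
    if (nw != nrow(pial_mesh$vertices) ||
        !identical(dim(wm_mesh$triangles), dim(pial_mesh$triangles)))
      stop("method 'linked' requires meshes with shared connectivity")
    th <- sqrt(rowSums((pial_mesh$vertices - wm_mesh$vertices)^2))
  } else if (method == "nearest") {
    th <- point_mesh_distance(wm_mesh$vertices, pial_mesh)$distance
  } else {
    d1 <- point_mesh_distance(wm_mesh$vertices, pial_mesh)$distance
    d2 <- point_mesh_distance(pial_mesh$vertices, wm_mesh)$distance
    # map pial->wm direction back through nearest pial vertex per wm vertex
    nearest_pial <- point_mesh_nearest_points(wm_mesh$vertices,
                                              pial_mesh$vertices)
    th <- (d1 + d2[nearest_pial]) / 2
  }
  structure(th, class = "vertex_map", mesh_vertices = nw, smoothing = "raw")
}

#' Smooth a per-vertex map on the surface (graph diffusion, FWHM-calibrated)
#'
#' Iterative symmetric graph diffusion
#' `v <- v + (lambda / max(deg)) (A v - deg v)`, which preserves the total
#' exactly on closed meshes, with the iteration count calibrated so a point
#' impulse on a regular mesh spreads to approximately the requested Gaussian
#' FWHM: each iteration adds about `lambda * hbar^2` to the variance of the
#' diffusing impulse (mean squared edge length `hbar^2`), so
#' `n = (FWHM / 2.355)^2 / (lambda * hbar^2)`. The variance never increases.
#'
#' @param mesh the bound `triangle_mesh`
#' @param values per-vertex numeric map
#' @param fwhm target kernel FWHM in mm (default 10)
#' @param lambda diffusion step
#' @return smoothed `vertex_map` with attribute `smoothing = "<fwhm> mm"`
#' @export
smooth_scalar_map <- function(mesh, values, fwhm = 10, lambda = 0.5) {
  stopifnot(length(values) == nrow(mesh$vertices))
  e <- mesh_edges(mesh)
  el2 <- rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                    mesh$vertices[e[, 2], , drop = FALSE])^2)
  hbar2 <- mean(el2)
  if (fwhm < sqrt(hbar2)) {
    warning("fwhm below the mean edge length; returning the raw map")
    return(structure(as.numeric(values), class = "vertex_map",
                     mesh_vertices = nrow(mesh$vertices), smoothing = "raw"))
  }
  # iteration count: variance of the diffusing impulse grows by about
  # lambda * hbar^2 / 3 per iteration on triangulated spheres (empirical
  # calibration of the discrete kernel against measured impulse FWHM)
  sigma2 <- (fwhm / 2.355)^2
  n_iter <- max(1L, as.integer(round(3 * sigma2 / (lambda * hbar2))))
  A <- vertex_adjacency(mesh)
  deg <- Matrix::rowSums(A)
  eps <- lambda / max(deg)
  v <- as.numeric(values)
  for (i in seq_len(n_iter))
    v <- v + eps * (as.vector(A %*% v) - deg * v)
  structure(v, class = "vertex_map", mesh_vertices = nrow(mesh$vertices),
            smoothing = paste0(fwhm, " mm"), iterations = n_iter)
}

#' Sulcal depth relative to the brain hull
#'
#' Default: per-vertex shortest Euclidean distance to the hull surface (a
#' depth proxy; gyral crowns near the hull get ~0, buried fundi large
#' values). An alternative `"potential"` mode solves a surface diffusion of
#' the hull-distance with mean-curvature weighting behind the same
#' interface.
#'
#' @param mesh cortical `triangle_mesh` (typically the pial surface)
#' @param hull_mesh enclosing hull `triangle_mesh`
#' @param mode `"distance"` (default) or `"potential"`
#' @return per-vertex depth (mm) as a `vertex_map`
#' @export
sulcal_depth <- function(mesh, hull_mesh, mode = c("distance", "potential")) {
  mode <- match.arg(mode)
  d <- point_mesh_distance(mesh$vertices, hull_mesh)$distance
  if (mode == "potential") {
    # smooth, curvature-informed variant of the raw hull distance
    d <- blur_target_map(mesh, d, n_iterations = 20, lambda = 0.5)
  }
  structure(as.numeric(d), class = "vertex_map",
            mesh_vertices = nrow(mesh$vertices), smoothing = "raw")
}

#' Hull mesh of a brain mask
#'
#' Convenience: the topology-guaranteed boundary mesh of the morphological
#' closing of a binary mask, for use with [sulcal_depth()].
#'
#' @param mask binary `voxel_grid`
#' @param closing_radius structuring radius in mm
#' @return a `triangle_mesh`
#' @export
hull_mesh <- function(mask, closing_radius = NULL) {
  sp <- grid_spacing(mask)
  if (is.null(closing_radius)) closing_radius <- 2 * max(sp)
  dm <- dim(mask$data)
  m <- mask$data != 0
  d_in <- chamfer_distance_cpp(as.integer(m), dm, sp)
  dil <- array(d_in <= closing_radius + 1e-9, dm)
  d_out <- chamfer_distance_cpp(as.integer(!dil), dm, sp)
  closed <- array(as.integer(d_out > closing_radius - 1e-9), dm)
  extract_wm_mesh(voxel_grid(closed, mask$affine))
}

#' Distances from landmark points to a surface
#'
#' Exact point-to-triangle shortest distances, with mean and sd summary;
#' the landmark-based displacement metric used for surface quality
#' assessment.
#'
#' @param landmarks n x 3 matrix of world mm points (or a `LandmarkSet`
#'   file read by [read_landmarks()])
#' @param mesh target `triangle_mesh`
#' @return a tibble with per-landmark distances and closest points;
#'   attributes `mean` and `sd`
#' @export
landmark_distances <- function(landmarks, mesh) {
  landmarks <- to_xyz_matrix(landmarks)
  if (nrow(landmarks) == 0) stop("empty landmark set")
  res <- point_mesh_distance(landmarks, mesh)
  out <- tibble::tibble(
    landmark = seq_len(nrow(landmarks)),
    x = landmarks[, 1], y = landmarks[, 2], z = landmarks[, 3],
    distance = res$distance,
    closest_x = res$closest[, 1], closest_y = res$closest[, 2],
    closest_z = res$closest[, 3])
  attr(out, "mean") <- mean(res$distance)
  attr(out, "sd") <- sd(res$distance)
  out
}

#' Select the best-matching template by sulcal-depth correlation
#'
#' Pearson correlation of the individual's depth map against each template's
#' map (vertex correspondence assumed, e.g. via icosahedral resampling);
#' the template with the highest correlation wins, ties broken toward the
#' smaller index (templates conventionally ordered old to young).
#' Zero-variance maps give undefined correlations and are excluded.
#'
#' @param depth_map per-vertex sulcal depth of the individual
#' @param template_maps list of per-vertex template depth maps (same length)
#' @return list with `best` (index), `correlations` (NA where undefined)
#' @export
select_template <- function(depth_map, template_maps) {
  stopifnot(length(template_maps) >= 1)
  n <- length(depth_map)
  if (sd(depth_map) == 0) stop("zero-variance depth map: correlation undefined")
  cors <- vapply(template_maps, function(tm) {
    if (length(tm) != n)
      stop("template map length does not match the depth map")
    if (sd(tm) == 0) return(NA_real_)
    cor(depth_map, tm)
  }, numeric(1))
  if (all(is.na(cors))) stop("all templates have zero variance")
  best <- which.max(ifelse(is.na(cors), -Inf, cors))
  list(best = best, correlations = cors)
}
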