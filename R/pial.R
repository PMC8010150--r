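#' Estimate pure tissue intensity means from a segmentation
#'
#' Partial-volume voxels at tissue interfaces drag the naive per-label mean
#' toward the neighbouring tissue; the mean is therefore taken over the
#' eroded label mask (voxels whose six face neighbours share their label),
#' falling back to the full mask when the erosion is empty.
#'
#' @param labels label `voxel_grid`
#' @param intensity intensity `voxel_grid`
#' @return named numeric vector `(csf, gm, wm)` (NA where the tissue is
#'   absent)
#' @export
estimate_tissue_means <- function(labels, intensity) {
  out <- c(csf = NA_real_, gm = NA_real_, wm = NA_real_)
  codes <- c(csf = LABEL_CSF, gm = LABEL_GM, wm = LABEL_WM)
  for (nm in names(codes)) {
    m <- labels$data == codes[[nm]]
    if (!any(m)) next
    core <- m
    for (ax in 1:3)
      core <- core & shift_array_zero(m, 1, ax) & shift_array_zero(m, -1, ax)
    out[nm] <- mean(intensity$data[if (any(core)) core else m])
  }
  out
}

#' Solve the Laplace equation on the GM+CSF domain
#'
#' Gauss-Seidel/SOR iteration of the 6-neighbour discrete Laplace equation
#' with Dirichlet conditions: 0 on the WM side (WM voxels and, through them,
#' the internal border), 1 on the skeleton and hull. The solution is the
#' harmonic expansion potential whose streamlines carry WM vertices to the
#' skeleton without crossing.
#'
#' @param domain a `union_volume` (from [build_union()]) or a list with
#'   binary arrays `union`, `wm`, `hull` and fields `affine`, `spacing`
#' @param skeleton a `skeleton_voxels` object or binary array of potential-1
#'   voxels (the hull is always added)
#' @param tol maximum update residual for convergence
#' @param max_iter iteration cap
#' @param omega SOR relaxation factor
#' @return object of class `laplace_field`: `potential` (`voxel_grid`),
#'   `residual`, `residual_history`, plus the boundary masks
#' @export
solve_laplace <- function(domain, skeleton, tol = 1e-5, max_iter = 5000,
                          omega = 1.8) {
  skel <- if (inherits(skeleton, "skeleton_voxels")) skeleton$mask
  else skeleton != 0
  dm <- dim(domain$union)
  stopifnot(all(dim(skel) == dm))
  one <- skel | domain$hull
  code <- array(0L, dm)
  code[domain$union] <- 1L
  code[domain$wm] <- 2L            # Dirichlet 0
  code[one] <- 3L                  # Dirichlet 1
  if (!any(code == 1L)) {
    # degenerate all-boundary domain: potential equals the boundary values
    phi <- array(0, dm)
    phi[code == 3L] <- 1
    return(structure(list(potential = voxel_grid(phi, domain$affine),
                          residual = 0, residual_history = numeric(0),
                          zero_mask = code == 2L, one_mask = code == 3L),
                     class = "laplace_field"))
  }
  # solvable only if the interior touches both boundaries
  phi <- laplace_sor_cpp(code, dm, tol, as.integer(max_iter), omega)
  resid <- attr(phi, "residual")
  hist <- attr(phi, "residual_history")
  if (!is.finite(resid) || resid > tol)
    warning("Laplace solver stopped at residual ", signif(resid, 3))
  pot <- array(as.numeric(phi), dm)
  interior <- code == 1L
  if (any(interior) && diff(range(pot[interior])) < 1e-9)
    stop("no path between the WM boundary and the skeleton/hull")
  structure(list(potential = voxel_grid(pot, domain$affine),
                 residual = resid, residual_history = hist,
                 zero_mask = code == 2L, one_mask = code == 3L),
            class = "laplace_field")
}

#' Trace expansion streamlines from WM vertices to the skeleton
#'
#' Each WM vertex is advected along the normalized potential gradient (RK2,
#' step `step_frac` of a voxel) until the potential reaches `1 - eps` or a
#' stop voxel (skeleton, and optionally visible CSF) is entered. The arrival
#' points with the WM connectivity form the intermediate pial mesh; the
#' one-streamline-per-vertex construction gives a one-to-one WM-pial
#' correspondence and avoids topological errors. Vertices whose streamline
#' exceeds `max_length_mm` are flagged and assigned the nearest stop voxel.
#'
#' @param field a `laplace_field`
#' @param wm_mesh the WM `triangle_mesh`
#' @param stop_mask binary array: entering these voxels ends a streamline
#'   (typically skeleton, or skeleton | visible CSF)
#' @param eps arrival potential margin
#' @param step_frac integration step as a fraction of the voxel size
#' @param max_length_mm streamline length cap
#' @return list of class `streamline_map`: `pial` (intermediate pial
#'   `triangle_mesh`), `length` (mm per vertex), `flagged` (logical)
#' @export
trace_streamlines <- function(field, wm_mesh, stop_mask, eps = 0.02,
                              step_frac = 0.25, max_length_mm = 30) {
  grid <- field$potential
  dm <- dim(grid$data)
  sp <- grid_spacing(grid)
  starts <- voxel_from_world(grid, wm_mesh$vertices)
  step <- step_frac
  max_steps <- as.integer(ceiling(max_length_mm / (step * min(sp))))
  res <- trace_streamlines_cpp(as.numeric(grid$data),
                               as.integer(stop_mask != 0), dm, starts,
                               step, eps, max_steps)
  arrival <- res$arrival
  flagged <- res$flag != 0L
  if (any(flagged)) {
    # assign nearest stop voxel
    idx <- which(stop_mask != 0)
    if (length(idx) > 0) {
      coord <- arrayInd(idx, dm) - 1
      near <- point_mesh_nearest_points(arrival[flagged, , drop = FALSE],
                                        coord)
      arrival[flagged, ] <- coord[near, , drop = FALSE]
    }
  }
  Vw <- world_from_voxel(grid, arrival, check_bounds = FALSE)
  pot0 <- sample_volume(grid, wm_mesh$vertices)
  pot1 <- sample_volume(grid, Vw)
  structure(list(pial = triangle_mesh(Vw, wm_mesh$triangles),
                 length = res$length * min(sp), flagged = flagged,
                 potential_start = pot0, potential_end = pot1),
            class = "streamline_map")
}

# nearest row of `pts` for each query (small n; used only for flagged vertices)
point_mesh_nearest_points <- function(q, pts) {
  vapply(seq_len(nrow(q)), function(i) {
    which.min(colSums((t(pts) - q[i, ])^2))
  }, integer(1))
}

#' Build the pial surface
#'
#' Composes the stages: Laplacian field over the GM+CSF union (0 at WM, 1 at
#' skeleton and hull), streamline expansion of the WM mesh (stopping at the
#' skeleton or at visible CSF voxels) into the intermediate pial surface,
#' self-proximity enforcement, and short-range gradient refinement with the
#' skeleton as a barrier. WM-vertex correspondence is preserved throughout.
#'
#' @param wm_mesh refined WM `triangle_mesh`
#' @param labels label `voxel_grid`
#' @param intensity intensity `voxel_grid`
#' @param skeleton a `skeleton_voxels` object
#' @param union_volume optional prebuilt `union_volume` (rebuilt otherwise)
#' @param refine_distance half-range (mm) of the short refinement window
#' @param refine_step search step (mm) of the refinement
#' @param pparams profile parameters (sign/blur); default: falling edge for
#'   GM-above-CSF contrast chosen automatically from the label means
#' @param dparams deformation parameters (schedule is overridden by the
#'   short window)
#' @param stop_at_csf stop streamlines at visible CSF voxels (recommended)
#' @param backoff back-off of arrival points toward the WM vertex (mm);
#'   keeps opposing sulcal banks on their own side of the medial sheet
#' @param proximity_min self-proximity separation (mm; 0 disables)
#' @return list of class `pial_result`: `pial` (refined), `intermediate`,
#'   `streamlines`, `field`
#' @export
build_pial <- function(wm_mesh, labels, intensity, skeleton,
                       union_volume = NULL, refine_distance = 1.5,
                       refine_step = 0.25, pparams = NULL, dparams = NULL,
                       stop_at_csf = TRUE, backoff = 0.3,
                       proximity_min = 0.1) {
  uv <- if (is.null(union_volume)) build_union(labels) else union_volume
  field <- solve_laplace(uv, skeleton)
  stop_mask <- skeleton$mask
  if (stop_at_csf)
    stop_mask <- stop_mask | (labels$data == LABEL_CSF)
  sl <- trace_streamlines(field, wm_mesh, stop_mask)
  inter <- sl$pial
  if (backoff > 0) {
    dirv <- inter$vertices - wm_mesh$vertices
    len <- sqrt(rowSums(dirv^2))
    pull <- pmin(backoff, len / 2) / pmax(len, 1e-9)
    inter <- triangle_mesh(inter$vertices - dirv * pull, inter$triangles)
  }
  if (proximity_min > 0)
    inter <- enforce_self_proximity(inter, proximity_min)
  # observed pure-tissue means define the contrast polarity, the expected
  # boundary intensity (their midpoint) and the similarity bandwidth
  tm <- estimate_tissue_means(labels, intensity)
  mg <- tm[["gm"]]
  mc <- tm[["csf"]]
  if (!is.finite(mc)) mc <- mg  # no visible CSF anywhere
  if (is.null(pparams)) {
    sgn <- if (mc < mg) -1 else 1
    pparams <- profile_params(expected_sign = sgn)
  }
  if (is.null(dparams)) dparams <- deformation_params()
  dparams$resolution_schedule <- list(c(refine_distance, refine_step),
                                      c(refine_distance / 2, refine_step / 2))
  barrier <- voxel_grid(array(as.integer(skeleton$mask), dim(skeleton$mask)),
                        labels$affine)
  # edges are only accepted at the GM/CSF interface: GM voxels plus the CSF
  # layer touching GM (this excludes the unrelated CSF/background edge)
  gm <- labels$data == LABEL_GM
  csf <- labels$data == LABEL_CSF
  gm_dil <- gm
  for (ax in 1:3)
    gm_dil <- gm_dil | shift_array_zero(gm, 1, ax) | shift_array_zero(gm, -1, ax)
  region <- voxel_grid(array(as.integer(gm | (csf & gm_dil)), dim(gm)),
                       labels$affine)
  pial <- deform_to_edges(inter, intensity, pparams, dparams,
                          barrier = barrier, edge_region = region,
                          target_map = (mg + mc) / 2,
                          target_bw = max(abs(mg - mc) / 4, 1e-6),
                          proximity_min = proximity_min)
  structure(list(pial = pial, intermediate = sl$pial, streamlines = sl,
                 field = field),
            class = "pial_result")
}
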