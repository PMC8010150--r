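#' Separable Gaussian smoothing of a 3D array
#' @param arr 3D numeric array
#' @param sigma_mm kernel sd in mm (scalar)
#' @param spacing per-axis voxel size in mm
#' @return smoothed array
#' @export
gaussian_smooth_volume <- function(arr, sigma_mm, spacing = c(1, 1, 1)) {
  out <- arr * 1.0
  for (ax in 1:3) {
    sig_vox <- sigma_mm / spacing[ax]
    if (sig_vox <= 0) next
    K <- max(1L, ceiling(3 * sig_vox))
    w <- exp(-(seq(-K, K))^2 / (2 * sig_vox^2))
    w <- w / sum(w)
    acc <- array(0, dim(out))
    for (j in seq(-K, K))
      acc <- acc + w[j + K + 1] * shift_array(out, j, ax)
    out <- acc
  }
  out
}

# shift a 3D array by k along axis ax with edge replication
shift_array <- function(arr, k, ax) {
  if (k == 0) return(arr)
  d <- dim(arr)
  n <- d[ax]
  idx <- pmin(pmax(seq_len(n) - k, 1L), n)
  switch(ax,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

central_diff <- function(arr, ax, spacing) {
  (shift_array(arr, -1, ax) - shift_array(arr, 1, ax)) / (2 * spacing[ax])
}

#' Mean and Gaussian curvature of the implicit surface of a smoothed
#' indicator
#'
#' The binary indicator of the object is Gaussian-smoothed and the standard
#' implicit-surface formulas are evaluated from central-difference first and
#' second derivatives. The sign convention makes the mean curvature positive
#' on convex-outward boundaries (a ball of radius R has H = 1/R, K = 1/R^2
#' on its boundary). Voxels with vanishing gradient get H = K = 0 and are
#' flagged.
#'
#' @param mask binary 3D array (the object)
#' @param spacing per-axis voxel size (mm)
#' @param sigma_mm smoothing sd in mm
#' @return list with arrays `H` (1/mm), `K` (1/mm^2), logical `flagged`,
#'   and `boundary` (object voxels 6-adjacent to background)
#' @export
volume_curvature <- function(mask, spacing = c(1, 1, 1), sigma_mm = 1.5) {
  f <- gaussian_smooth_volume(mask * 1.0, sigma_mm, spacing)
  fx <- central_diff(f, 1, spacing)
  fy <- central_diff(f, 2, spacing)
  fz <- central_diff(f, 3, spacing)
  fxx <- central_diff(fx, 1, spacing)
  fyy <- central_diff(fy, 2, spacing)
  fzz <- central_diff(fz, 3, spacing)
  fxy <- central_diff(fx, 2, spacing)
  fxz <- central_diff(fx, 3, spacing)
  fyz <- central_diff(fy, 3, spacing)
  g2 <- fx^2 + fy^2 + fz^2
  # below ~1e-2/mm gradient the implicit surface is not locally defined and
  # the curvature quotient is numerical noise: flag and zero those voxels
  flagged <- g2 < 1e-4
  g2s <- ifelse(flagged, 1, g2)
  # the indicator increases inward, so the outward normal is -grad f /|grad f|;
  # with that orientation H = div(n)/2 takes the sign below
  H <- -(fx^2 * (fyy + fzz) + fy^2 * (fxx + fzz) + fz^2 * (fxx + fyy) -
           2 * (fx * fy * fxy + fx * fz * fxz + fy * fz * fyz)) /
    (2 * g2s^1.5)
  K <- (fx^2 * (fyy * fzz - fyz^2) + fy^2 * (fxx * fzz - fxz^2) +
          fz^2 * (fxx * fyy - fxy^2) +
          2 * (fx * fy * (fxz * fyz - fxy * fzz) +
                 fy * fz * (fxy * fxz - fyz * fxx) +
                 fx * fz * (fxy * fyz - fxz * fyy))) / g2s^2
  H[flagged] <- 0
  K[flagged] <- 0
  list(H = H, K = K, flagged = flagged,
       boundary = boundary_voxels(mask))
}

# object voxels 6-adjacent to background (volume border counts as background)
boundary_voxels <- function(mask) {
  m <- mask != 0
  inner <- m
  for (ax in 1:3) {
    inner <- inner & shift_array_zero(m, 1, ax) & shift_array_zero(m, -1, ax)
  }
  m & !inner
}

shift_array_zero <- function(arr, k, ax) {
  d <- dim(arr)
  out <- array(vector(typeof(arr), 1), d)
  n <- d[ax]
  src <- seq_len(n) - k
  ok <- src >= 1 & src <= n
  idx_to <- seq_len(n)[ok]
  idx_from <- src[ok]
  switch(ax,
         out[idx_to, , ] <- arr[idx_from, , , drop = FALSE],
         out[, idx_to, ] <- arr[, idx_from, , drop = FALSE],
         out[, , idx_to] <- arr[, , idx_from, drop = FALSE])
  out
}

#' Build the GM+CSF union with its hull and inner boundary
#'
#' The union is the set of GM and CSF voxels inside the brain mask. Its
#' external boundary is the hull of the (morphologically closed) brain mask;
#' hull voxels are pre-marked as skeleton members representing the gyral
#' interface. The internal border is the set of union voxels 6-adjacent to
#' WM.
#'
#' @param labels a label `voxel_grid` (codes 0-3)
#' @param brain_mask optional binary `voxel_grid`; default `labels > 0`
#' @param wm_mask optional binary `voxel_grid`; default `labels == 3`
#' @param closing_radius structuring radius (mm) of the closing used for
#'   the hull
#' @return object of class `union_volume`: list with binary arrays `union`,
#'   `hull`, `inner`, `wm`, plus the affine and spacing
#' @export
build_union <- function(labels, brain_mask = NULL, wm_mask = NULL,
                        closing_radius = NULL) {
  stopifnot(inherits(labels, "voxel_grid"))
  lab <- labels$data
  if (!any(lab == LABEL_GM)) stop("label volume has no GM voxels")
  sp <- grid_spacing(labels)
  if (is.null(closing_radius)) closing_radius <- 2 * max(sp)
  mask <- if (is.null(brain_mask)) lab > 0L else brain_mask$data != 0
  wm <- if (is.null(wm_mask)) lab == LABEL_WM else wm_mask$data != 0
  uni <- (lab == LABEL_GM | lab == LABEL_CSF) & mask
  dm <- dim(lab)

  # morphological closing of the brain mask via two chamfer thresholds
  d_in <- chamfer_distance_cpp(as.integer(mask), dm, sp)
  dil <- array(d_in <= closing_radius + 1e-9, dm)
  d_out <- chamfer_distance_cpp(as.integer(!dil), dm, sp)
  closed <- array(d_out > closing_radius - 1e-9, dm)
  # the union extends to the hull: voxels the closing added (bridged sulcal
  # mouths, rounded corners) count as virtual CSF inside the hull
  uni <- uni | (closed & !mask)
  hull <- boundary_voxels(closed) & uni

  inner <- uni & (shift_array_zero(wm, 1, 1) | shift_array_zero(wm, -1, 1) |
                    shift_array_zero(wm, 1, 2) | shift_array_zero(wm, -1, 2) |
                    shift_array_zero(wm, 1, 3) | shift_array_zero(wm, -1, 3))
  structure(list(union = uni, hull = hull, inner = inner, wm = wm,
                 affine = labels$affine, spacing = sp),
            class = "union_volume")
}

#' Curvature field of the union boundaries
#'
#' Computes mean/Gaussian curvature both for the WM object (whose boundary
#' is the internal border of the union, where catchment-basin seeds are
#' detected: sulcal fundi are concave trenches of the WM surface, H < 0) and
#' for the union object itself (used to gate the erosion).
#'
#' @param union_volume from [build_union()]
#' @param smoothing_sigma Gaussian sd in mm for the implicit surface
#' @return list of class `curvature_field` with `inner` and `union` curvature
#'   components (each as returned by [volume_curvature()])
#' @export
boundary_curvature <- function(union_volume, smoothing_sigma = 1.5) {
  stopifnot(inherits(union_volume, "union_volume"))
  structure(list(
    inner = volume_curvature(union_volume$wm, union_volume$spacing,
                             smoothing_sigma),
    union = volume_curvature(union_volume$union, union_volume$spacing,
                             smoothing_sigma)),
    class = "curvature_field")
}

#' Seed catchment basins at sulcal fundi
#'
#' Seeds are internal-border voxels whose WM-surface curvature indicates a
#' sulcal fundus. Two criteria are available: `"mean"` (H below `-h_seed`;
#' detects trench-like fundi, including straight sulci whose Gaussian
#' curvature vanishes) and `"gaussian"` (K above `k_threshold` with H < 0;
#' detects bowl-like pits only). Each 26-connected seed cluster becomes one
#' catchment basin.
#'
#' @param union_volume from [build_union()]
#' @param curv from [boundary_curvature()]
#' @param mode `"mean"` or `"gaussian"`
#' @param h_seed trench threshold (1/mm) for mode "mean"; the default 0.15
#'   targets fundic trenches (mean curvature radius below ~3 mm) while flat
#'   cortex and sulcal walls stay below it
#' @param k_threshold pit threshold (1/mm^2) for mode "gaussian"
#' @return integer array of basin labels (0 = not a seed), with attribute
#'   `n_basins`
#' @export
seed_catchment_basins <- function(union_volume, curv,
                                  mode = c("mean", "gaussian"),
                                  h_seed = 0.15, k_threshold = 0.05) {
  mode <- match.arg(mode)
  H <- curv$inner$H
  K <- curv$inner$K
  sel <- if (mode == "mean") H < -h_seed else (K > k_threshold & H < 0)
  seeds <- union_volume$inner & sel
  dm <- dim(seeds)
  basins <- label_components_cpp(as.integer(seeds), dm, 26L)
  n <- attr(basins, "ncomp")
  if (n == 0) warning("no catchment-basin seeds found; skeleton will be hull-only")
  out <- array(as.integer(basins), dm)
  attr(out, "n_basins") <- n
  out
}

#' Homotopic erosion of the union with embedded watershed
#'
#' Ordered thinning of the GM+CSF union: boundary voxels are removed one at
#' a time in increasing distance from the internal (WM-adjacent) border,
#' provided removal preserves topology (simple point, object-26/background-6),
#' the voxel is erodible by the mean-curvature gate, and the voxel is not a
#' hull voxel, a seed, or a watershed ridge (a voxel whose removal would
#' merge water from two distinct basins is frozen as ridge). Fronts advancing
#' from opposing sulcal banks meet at the inter-bank midline, where voxels
#' become non-simple and persist: the medial surface.
#'
#' @param union_volume from [build_union()]
#' @param seeds basin label array from [seed_catchment_basins()]
#' @param curv from [boundary_curvature()]
#' @param h_threshold erosion gate (1/mm): only voxels with union-boundary
#'   mean curvature below this are erodible
#' @return object of class `skeleton_voxels`: list with logical `mask`,
#'   integer `state` (0 removed, 1 retained, 2 frozen), integer `classes`
#'   (Malandain-Bertrand codes 1-9), the removal `order` (linear indices),
#'   and the affine
#' @export
homotopic_erode <- function(union_volume, seeds, curv, h_threshold = 1.0) {
  stopifnot(inherits(union_volume, "union_volume"))
  dm <- dim(union_volume$union)
  frozen <- union_volume$hull | seeds > 0L
  dist <- chamfer_distance_cpp(as.integer(union_volume$inner), dm,
                               union_volume$spacing)
  state <- skeletonize_cpp(as.integer(union_volume$union),
                           as.integer(frozen), as.numeric(dist),
                           as.numeric(curv$union$H), h_threshold,
                           as.integer(seeds), dm)
  ord <- attr(state, "order")
  mask <- array(state > 0L, dm)
  cls <- array(classify_voxels_cpp(as.integer(mask), dm), dm)
  structure(list(mask = mask, state = array(as.integer(state), dm),
                 classes = cls, order = ord, affine = union_volume$affine,
                 hull = union_volume$hull, seeds = seeds),
            class = "skeleton_voxels")
}

#' Topological class names
#' @return character vector indexed by class code 1-9
#' @export
topo_class_names <- function() {
  c("interior", "isolated", "border", "curve", "curves",
    "surface", "surface-curve", "surfaces", "surfaces-curve")
}

#' Classify voxels of a binary object into the nine topological categories
#'
#' Computes the topological numbers C* (26-components of the object in the
#' 26-neighbourhood) and Cbar (6-components of the background in the
#' 18-neighbourhood that touch the center) and maps them to the nine classes:
#' interior (Cbar=0), isolated (C*=0), border (1,1), curve (2,1), curves
#' (>2,1), surface (1,2), surface-curve (>=2,2), surfaces (1,>2),
#' surfaces-curve (>=2,>2).
#'
#' @param ijk n x 3 matrix of 0-based voxel indices (or NULL for all object
#'   voxels)
#' @param object binary 3D array
#' @return if `ijk` is given, a character vector of class names (with the
#'   numeric codes and topological numbers as attributes); otherwise an
#'   integer code array over the full grid
#' @export
classify_topology <- function(ijk, object) {
  obj <- as.integer(object != 0)
  dm <- dim(object)
  if (is.null(ijk)) return(array(classify_voxels_cpp(obj, dm), dm))
  ijk <- matrix(as.integer(round(to_xyz_matrix(ijk))), ncol = 3)
  tn <- topo_numbers_grid(obj, dm, ijk)
  codes <- mapply(function(cs, cb) {
    if (cb == 0) 1L
    else if (cs == 0) 2L
    else if (cb == 1) { if (cs == 1) 3L else if (cs == 2) 4L else 5L }
    else if (cb == 2) { if (cs == 1) 6L else 7L }
    else { if (cs == 1) 8L else 9L }
  }, tn[, 1], tn[, 2])
  out <- topo_class_names()[codes]
  attr(out, "code") <- codes
  attr(out, "topo_numbers") <- tn
  out
}

#' Prune deletable-class voxels from a skeleton
#'
#' Iteratively removes voxels whose topological class is deletable,
#' re-classifying after each pass, until a fixed point. Surface-type classes
#' (surface, surface-curve, surfaces, surfaces-curve) are never deletable.
#' The default deletable set removes isolated voxels and curve-type branches
#' (the redundant secondary branches left by over-seeded basins) while
#' keeping sheet borders, so medial sheets are not nibbled from their free
#' edges; border voxels can be added to the set by the user.
#'
#' @param skel a `skeleton_voxels` object (or binary array)
#' @param deletable_classes character vector among
#'   `c("isolated", "border", "curve", "curves")`
#' @param protect optional logical array of voxels never deleted (defaults
#'   to the skeleton's hull and seeds when available)
#' @param max_pass pass cap
#' @return pruned object of the same type
#' @export
prune_skeleton <- function(skel,
                           deletable_classes = c("isolated", "curve", "curves"),
                           protect = NULL, max_pass = 100) {
  allowed <- c("isolated", "border", "curve", "curves")
  bad <- setdiff(deletable_classes, allowed)
  if (length(bad) > 0)
    stop("not deletable: ", paste(bad, collapse = ", "),
         " (surface-type classes are undeletable)")
  del_codes <- match(deletable_classes, topo_class_names())
  is_obj <- inherits(skel, "skeleton_voxels")
  mask <- if (is_obj) skel$mask else skel != 0
  if (is.null(protect) && is_obj) protect <- skel$hull | skel$seeds > 0L
  if (is.null(protect)) protect <- array(FALSE, dim(mask))
  dm <- dim(mask)
  for (i in seq_len(max_pass)) {
    cls <- array(classify_voxels_cpp(as.integer(mask), dm), dm)
    del <- mask & !protect & array(cls %in% del_codes, dm)
    if (!any(del)) break
    mask[del] <- FALSE
  }
  if (!is_obj) return(mask)
  skel$mask <- mask
  skel$state[!mask] <- 0L
  skel$classes <- array(classify_voxels_cpp(as.integer(mask), dm), dm)
  skel
}

#' Euler characteristic of a voxel set (cubical complex)
#'
#' Counts vertices, edges, faces and cubes of the voxel complex:
#' chi = V - E + F - C. Used as the independent audit of homotopy
#' preservation during erosion.
#'
#' @param mask binary 3D array
#' @return integer Euler characteristic
#' @export
euler_voxel_complex <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  # presence of a voxel at offset (dx,dy,dz) relative to each lattice point
  vox <- function(dx, dy, dz) {
    q <- array(FALSE, d + 1L)
    xs <- seq_len(d[1]) + dx
    ys <- seq_len(d[2]) + dy
    zs <- seq_len(d[3]) + dz
    q[xs, ys, zs] <- m
    q
  }
  o <- list(vox(0, 0, 0), vox(1, 0, 0), vox(0, 1, 0), vox(0, 0, 1),
            vox(1, 1, 0), vox(1, 0, 1), vox(0, 1, 1), vox(1, 1, 1))
  Vn <- sum(o[[1]] | o[[2]] | o[[3]] | o[[4]] | o[[5]] | o[[6]] | o[[7]] |
              o[[8]])
  Ex <- sum(o[[1]] | o[[3]] | o[[4]] | o[[7]])  # edges along x
  Ey <- sum(o[[1]] | o[[2]] | o[[4]] | o[[6]])  # edges along y
  Ez <- sum(o[[1]] | o[[2]] | o[[3]] | o[[5]])  # edges along z
  Fxy <- sum(o[[1]] | o[[4]])  # faces normal to z
  Fxz <- sum(o[[1]] | o[[3]])  # faces normal to y
  Fyz <- sum(o[[1]] | o[[2]])  # faces normal to x
  Cn <- sum(m)
  Vn - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - Cn
}

#' Count 26-connected components of a voxel set
#' @param mask binary 3D array
#' @param connectivity 26 (object) or 6 (background)
#' @return integer count
#' @export
count_components <- function(mask, connectivity = 26) {
  lab <- label_components_cpp(as.integer(mask != 0), dim(mask),
                              as.integer(connectivity))
  attr(lab, "ncomp")
}

#' Write a skeleton as a labelled NIfTI volume (class codes 1-9)
#' @param skel a `skeleton_voxels` object
#' @param path output NIfTI path
#' @export
write_skeleton <- function(skel, path) {
  arr <- skel$classes
  storage.mode(arr) <- "integer"
  write_volume(voxel_grid(arr, skel$affine), path)
}
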