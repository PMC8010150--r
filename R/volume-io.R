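#' Voxel grids
#'
#' A `voxel_grid` is a 3D scalar field (intensities, tissue labels, masks or
#' potentials) together with a 4x4 voxel-index-to-world-mm affine. Voxel
#' indices are 0-based and refer to voxel centers; all world coordinates are
#' in mm. Conversion between the two goes through the affine only.
#'
#' @param data 3D numeric or integer array.
#' @param affine 4x4 voxel-to-world transform (0-based voxel centers).
#' @return An object of class `voxel_grid` with elements `data` and `affine`.
#' @export
voxel_grid <- function(data, affine = NULL) {
  if (length(dim(data)) != 3L || any(dim(data) <= 0L))
    stop("voxel_grid data must be a 3D array with positive dimensions")
  if (is.null(affine)) affine <- diag(4)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  det_a <- det(affine[1:3, 1:3])
  if (!is.finite(det_a) || abs(det_a) < 1e-12)
    stop("affine is not invertible")
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(sp <= 0)) stop("voxel spacing must be positive")
  structure(list(data = data, affine = affine), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  sp <- grid_spacing(x)
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  invisible(x)
}

#' Per-axis voxel size in mm
#' @param grid a `voxel_grid`
#' @return length-3 numeric vector
#' @export
grid_spacing <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' Convert voxel indices to world coordinates
#'
#' Applies the grid affine to 0-based voxel indices (voxel-center
#' convention).
#'
#' @param grid a `voxel_grid`
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed.
#' @param check_bounds reject out-of-bounds integer indices
#' @return n x 3 matrix of world mm coordinates
#' @export
world_from_voxel <- function(grid, ijk, check_bounds = TRUE) {
  ijk <- to_xyz_matrix(ijk)
  if (check_bounds) {
    d <- dim(grid$data)
    if (any(ijk < -0.5) || any(t(t(ijk) - (d - 0.5)) > 0))
      stop("voxel index out of bounds")
  }
  h <- cbind(ijk, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

#' Convert world coordinates to (fractional) voxel indices
#' @inheritParams world_from_voxel
#' @param xyz n x 3 matrix of world mm coordinates
#' @return n x 3 matrix of 0-based fractional voxel indices
#' @export
voxel_from_world <- function(grid, xyz) {
  xyz <- to_xyz_matrix(xyz)
  h <- cbind(xyz, 1) %*% t(solve(grid$affine))
  h[, 1:3, drop = FALSE]
}

to_xyz_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop("coordinates must have 3 columns")
  x
}

#' Read a 3D volume (NIfTI-1/2)
#'
#' The affine is taken from the file header (sform/qform as stored; no forced
#' reorientation). Tissue label volumes may be remapped to the project label
#' convention \{0 background, 1 CSF, 2 GM, 3 WM\} with `label_map`.
#'
#' @param path NIfTI file
#' @param label_map optional named integer vector remapping foreign label
#'   codes, e.g. `c("10" = 2, "50" = 3)`.
#' @return a `voxel_grid`
#' @export
read_volume <- function(path, label_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4L) {
    if (dm[4] == 1L) dm <- dm[1:3]
    else stop("4D input not supported: ", path)
  }
  if (length(dm) != 3L) stop("input is not a 3D volume: ", path)
  arr <- array(as.vector(img)[seq_len(prod(dm))], dm)  # strip nifti attributes
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  if (!is.null(label_map)) {
    out <- arr
    for (code in names(label_map)) out[arr == as.numeric(code)] <- label_map[[code]]
    arr <- out
  }
  if (isTRUE(all(arr == round(arr))) && max(abs(arr)) < 2^31)
    storage.mode(arr) <- "integer"
  voxel_grid(arr, aff)
}

#' Write a volume to NIfTI
#'
#' Integer data round-trips bit-exactly (int16/int32 storage); float data is
#' stored as float64.
#'
#' @param grid a `voxel_grid`
#' @param path output path (`.nii` or `.nii.gz`)
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  arr <- grid$data
  dt <- if (is.integer(arr)) {
    if (max(abs(range(arr))) < 32767) "int16" else "int32"
  } else "double"
  img <- RNifti::asNifti(arr)
  # sform only: the qform quaternion cannot represent shear or anisotropic
  # scale and would take precedence when set last
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(NULL)
}

#' Resample a grid to isotropic voxel size
#'
#' Intensities are resampled trilinearly, labels (integer data) by nearest
#' neighbour. The world extent is preserved within one voxel.
#'
#' @param grid a `voxel_grid`
#' @param target_spacing isotropic voxel size in mm
#' @param method `"auto"` (trilinear for float, nearest for integer),
#'   `"linear"` or `"nearest"`
#' @return a `voxel_grid` at the requested spacing
#' @export
resample_isotropic <- function(grid, target_spacing,
                               method = c("auto", "linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(target_spacing > 0)
  d <- dim(grid$data)
  if (any(d < 2L)) stop("degenerate (single-slice) input cannot be resampled")
  sp <- grid_spacing(grid)
  if (method == "auto")
    method <- if (is.integer(grid$data)) "nearest" else "linear"
  scale <- target_spacing / sp
  if (all(abs(scale - 1) < 1e-12)) return(grid)
  nd <- pmax(2L, as.integer(ceiling(d * sp / target_spacing)))
  # fractional source index for each target index (voxel centers)
  ax <- lapply(1:3, function(k) (seq_len(nd[k]) - 1) * scale[k])
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  if (method == "nearest") {
    idx <- round(pts)
    for (k in 1:3) idx[, k] <- pmin(pmax(idx[, k], 0), d[k] - 1)
    vals <- grid$data[1 + idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3])]
  } else {
    pts_cl <- pts
    for (k in 1:3) pts_cl[, k] <- pmin(pmax(pts_cl[, k], 0), d[k] - 1)
    vals <- trilinear_cpp(as.numeric(grid$data), d, pts_cl)
  }
  arr <- array(vals, nd)
  if (method == "nearest" && is.integer(grid$data)) storage.mode(arr) <- "integer"
  new_aff <- grid$affine %*% diag(c(scale, 1))
  voxel_grid(arr, new_aff)
}

#' Sample a volume at world coordinates (trilinear)
#' @param grid a `voxel_grid`
#' @param xyz n x 3 world mm coordinates
#' @return numeric vector; `NA` for samples outside the volume
#' @export
sample_volume <- function(grid, xyz) {
  pts <- voxel_from_world(grid, xyz)
  trilinear_cpp(as.numeric(grid$data), dim(grid$data), pts)
}

#' Read plain-text landmarks (one `x y z` per line, world mm)
#' @param path text file
#' @return n x 3 matrix
#' @export
read_landmarks <- function(path) {
  m <- as.matrix(utils::read.table(path))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Validate a tissue label volume
#'
#' Checks that only codes \{0,1,2,3\} occur and that WM and GM are nonempty.
#' @param labels a `voxel_grid` with integer codes
#' @return the grid, invisibly; errors otherwise
#' @export
validate_labels <- function(labels) {
  codes <- sort(unique(as.vector(labels$data)))
  if (!all(codes %in% 0:3))
    stop("label volume contains codes outside {0,1,2,3}: ",
         paste(setdiff(codes, 0:3), collapse = ", "))
  if (!any(labels$data == LABEL_WM)) stop("label volume has no WM voxels")
  if (!any(labels$data == LABEL_GM)) stop("label volume has no GM voxels")
  invisible(labels)
}
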