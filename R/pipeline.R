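#' Split a WM mask into hemispheres at the midsagittal plane
#'
#' Geometric stand-in for a corpus-callosum-based split: the WM bounding box
#' is cut at its world-x midplane and every 26-connected WM component is
#' assigned to the side containing its centroid; voxels of components that
#' straddle the plane are split by the plane itself.
#'
#' @param wm_mask binary `voxel_grid`
#' @return list with `left` and `right` binary `voxel_grid`s (either may be
#'   empty when the WM lies entirely on one side: single-hemisphere mode)
#' @export
split_hemispheres <- function(wm_mask) {
  m <- wm_mask$data != 0
  if (!any(m)) stop("empty WM mask")
  dm <- dim(m)
  idx <- which(m)
  coord <- arrayInd(idx, dm) - 1
  wx <- world_from_voxel(wm_mask, coord)[, 1]
  mid <- (min(wx) + max(wx)) / 2
  lab <- label_components_cpp(as.integer(m), dm, 26L)
  ncomp <- attr(lab, "ncomp")
  side <- numeric(length(idx))  # -1 left, +1 right
  labv <- lab[idx]
  for (k in seq_len(ncomp)) {
    sel <- labv == k
    cx <- mean(wx[sel])
    rng <- range(wx[sel])
    if (rng[1] < mid && rng[2] > mid && abs(cx - mid) < diff(rng) / 4) {
      side[sel] <- ifelse(wx[sel] < mid, -1, 1)  # straddling: cut by plane
    } else {
      side[sel] <- ifelse(cx < mid, -1, 1)
    }
  }
  left <- array(0L, dm); right <- array(0L, dm)
  left[idx[side < 0]] <- 1L
  right[idx[side > 0]] <- 1L
  list(left = voxel_grid(left, wm_mask$affine),
       right = voxel_grid(right, wm_mask$affine))
}

#' Pipeline configuration
#'
#' @param phantom a `phantom_spec` (or NULL when reading files)
#' @param labels_path,intensity_path NIfTI inputs (ignored with a phantom)
#' @param hemisphere_mode `"whole"` (closed phantoms) or `"split"`
#' @param level icosahedron subdivision level
#' @param coarsen_target decimation target before inflation
#' @param wm_refine,pial_refine lists of overrides for the gradient
#'   refinement (`search_distance`, `step_size`, ...)
#' @param thickness_method see [cortical_thickness()]
#' @param fwhm surface smoothing kernel (mm)
#' @param seed RNG seed (phantom noise etc.)
#' @param out_dir output directory (NULL = keep results in memory only)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(phantom = NULL, labels_path = NULL,
                            intensity_path = NULL,
                            hemisphere_mode = c("whole", "split"),
                            level = 4, coarsen_target = 30000,
                            wm_refine = list(), pial_refine = list(),
                            thickness_method = "linked", fwhm = 10,
                            seed = 1L, out_dir = NULL) {
  hemisphere_mode <- match.arg(hemisphere_mode)
  if (is.null(phantom) &&
      (is.null(labels_path) || is.null(intensity_path)))
    stop("either a phantom spec or labels/intensity paths are required")
  for (p in c(labels_path, intensity_path))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(list(phantom = phantom, labels_path = labels_path,
                 intensity_path = intensity_path,
                 hemisphere_mode = hemisphere_mode, level = level,
                 coarsen_target = coarsen_target, wm_refine = wm_refine,
                 pial_refine = pial_refine,
                 thickness_method = thickness_method, fwhm = fwhm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror [pipeline_config()], with an optional
#'   `phantom:` block passed to [phantom_spec()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$phantom)) y$phantom <- do.call(phantom_spec, y$phantom)
  do.call(pipeline_config, y)
}

#' Run the surface reconstruction pipeline
#'
#' Executes, per hemisphere when requested: WM mesh extraction, coarsening,
#' inflation, icosahedral resampling, gradient refinement of the WM surface,
#' GM+CSF skeletonization, Laplacian streamline expansion with short-range
#' pial refinement, and morphometry (linked thickness with surface
#' smoothing, sulcal depth, QA metrics). All artifacts are returned and,
#' when `out_dir` is set, written to disk together with a JSON run manifest.
#' Identical config and seed give identical outputs.
#'
#' @param config a `pipeline_config`
#' @return list of class `pipeline_result`: per-hemisphere surfaces and
#'   maps, plus `manifest`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  t_start <- Sys.time()
  stages <- list()
  timing <- c()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  if (!is.null(config$phantom)) {
    ph <- make_phantom(config$phantom)
    labels <- ph$labels; intensity <- ph$intensity
    truth <- ph$truth
  } else {
    labels <- read_volume(config$labels_path)
    intensity <- read_volume(config$intensity_path)
    truth <- NULL
  }
  validate_labels(labels)
  timing["inputs"] <- toc(t0)

  wm_all <- array(as.integer(labels$data == LABEL_WM), dim(labels$data))
  hemis <- if (config$hemisphere_mode == "split") {
    hs <- split_hemispheres(voxel_grid(wm_all, labels$affine))
    Filter(function(g) any(g$data != 0), hs)
  } else {
    list(whole = voxel_grid(wm_all, labels$affine))
  }

  # contrast polarity for the WM fit, from the observed pure-tissue means
  tmeans <- estimate_tissue_means(labels, intensity)
  wm_sign <- if (tmeans[["gm"]] > tmeans[["wm"]]) 1 else -1

  results <- list()
  for (hn in names(hemis)) {
    res <- list()
    t0 <- tic()
    mesh0 <- extract_wm_mesh(hemis[[hn]])
    timing[paste0(hn, ".wm_extract")] <- toc(t0)

    t0 <- tic()
    coarse <- coarsen_mesh(mesh0, config$coarsen_target)
    sm <- inflate_to_sphere(coarse)
    wm_mesh <- icosahedron_resample(coarse, sm, config$level)
    timing[paste0(hn, ".resample")] <- toc(t0)

    t0 <- tic()
    wm_pp <- profile_params(expected_sign = wm_sign)
    wm_dp <- do.call(deformation_params, config$wm_refine)
    wm_ref <- deform_to_edges(wm_mesh, intensity, wm_pp, wm_dp)
    wm_ref <- enforce_self_proximity(wm_ref)
    timing[paste0(hn, ".wm_refine")] <- toc(t0)

    t0 <- tic()
    uv <- build_union(labels, wm_mask = hemis[[hn]])
    cv <- boundary_curvature(uv)
    seeds <- seed_catchment_basins(uv, cv)
    skel <- prune_skeleton(homotopic_erode(uv, seeds, cv))
    timing[paste0(hn, ".skeleton")] <- toc(t0)

    t0 <- tic()
    pial_args <- config$pial_refine
    pial_args$wm_mesh <- wm_ref
    pial_args$labels <- labels
    pial_args$intensity <- intensity
    pial_args$skeleton <- skel
    pial_args$union_volume <- uv
    pr <- do.call(build_pial, pial_args)
    timing[paste0(hn, ".pial")] <- toc(t0)

    t0 <- tic()
    th <- cortical_thickness(wm_ref, pr$pial, config$thickness_method)
    th_s <- smooth_scalar_map(pr$pial, th, config$fwhm)
    hm <- hull_mesh(voxel_grid(array(as.integer(labels$data > 0),
                                     dim(labels$data)), labels$affine))
    depth <- sulcal_depth(pr$pial, hm)
    timing[paste0(hn, ".morphometry")] <- toc(t0)

    res$wm_initial <- mesh0
    res$wm_surface <- wm_ref
    res$skeleton <- skel
    res$intermediate_pial <- pr$intermediate
    res$pial_surface <- pr$pial
    res$thickness <- th
    res$thickness_smoothed <- th_s
    res$sulcal_depth <- depth
    res$hull <- hm
    res$qa <- tibble::tibble(
      stage = c("wm_extract", "wm_refine", "pial"),
      euler = c(euler_characteristic(mesh0), euler_characteristic(wm_ref),
                euler_characteristic(pr$pial)),
      self_intersections = c(NA_integer_,
                             count_self_intersections(wm_ref),
                             count_self_intersections(pr$pial)),
      vertices = c(nrow(mesh0$vertices), nrow(wm_ref$vertices),
                   nrow(pr$pial$vertices)))
    res$laplace_residual <- pr$field$residual
    results[[hn]] <- res
  }

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("neosurf")),
    config_hash = digest_config(cfg_for_hash),
    seed = config$seed,
    hemisphere_mode = config$hemisphere_mode,
    level = config$level,
    timing_sec = as.list(round(timing, 3)),
    qa = lapply(results, function(r)
      list(euler = r$qa$euler, self_intersections = r$qa$self_intersections,
           vertices = r$qa$vertices,
           laplace_residual = r$laplace_residual,
           mean_thickness_mm = mean(r$thickness))))

  out <- list(hemis = results, labels = labels, intensity = intensity,
              truth = truth, manifest = manifest, config = config)
  class(out) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

# order-stable structural hash of the config (no external digest dependency)
digest_config <- function(x) {
  s <- paste(utils::capture.output(dput(x)), collapse = "")
  # 31-bit polynomial rolling hash over the deparsed config
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(result$labels, file.path(out_dir, "labels.nii.gz"))
  write_volume(result$intensity, file.path(out_dir, "intensity.nii.gz"))
  for (hn in names(result$hemis)) {
    r <- result$hemis[[hn]]
    pfx <- function(nm) file.path(out_dir, paste0(hn, "_", nm))
    write_surface(r$wm_surface, pfx("wm.obj"))
    write_surface(r$intermediate_pial, pfx("pial_intermediate.obj"))
    write_surface(r$pial_surface, pfx("pial.obj"),
                  scalars = r$thickness_smoothed,
                  scalar_path = pfx("thickness.txt"))
    writeLines(sprintf("%.9g", r$sulcal_depth), pfx("sulcal_depth.txt"))
    write_skeleton(r$skeleton, pfx("skeleton.nii.gz"))
  }
  # manifest last, written atomically
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(result$manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", length(x$hemis), "hemisphere(s)\n")
  for (hn in names(x$hemis)) {
    r <- x$hemis[[hn]]
    cat(sprintf("  %s: %d vertices, mean thickness %.2f mm, chi %d\n",
                hn, nrow(r$pial_surface$vertices), mean(r$thickness),
                euler_characteristic(r$pial_surface)))
  }
  invisible(x)
}
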