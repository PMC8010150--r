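#' Phantom specification
#'
#' Describes a synthetic brain-like object with analytic ground truth. Three
#' kinds are available:
#' \describe{
#'   \item{shell}{WM ball of radius `r1`, GM shell `r1..r2`, a 2 mm CSF
#'     shell outside, background beyond. Ground-truth thickness is
#'     `r2 - r1` everywhere.}
#'   \item{folded_slab}{a WM block whose top carries periodic sulci with
#'     parallel banks: each sulcus is a slot of exact width `sulcal_gap`
#'     (CSF) flanked by GM banks of the nominal cortical thickness, built
#'     from a capsule signed-distance rule so that gap and depth are exact
#'     parameters. `fold_wavelength` is the sulcus period and
#'     `fold_amplitude` the sulcal depth. When `sulcal_gap` is below the
#'     voxel size the rasterized labels contain no pure-CSF voxel inside the
#'     sulci: the invisible-CSF condition of small neonatal brains.}
#'   \item{folded_sphere}{a closed shell whose inner radius is modulated
#'     sinusoidally with latitude; exercises closed-topology code paths.}
#' }
#'
#' @param kind one of `"shell"`, `"folded_slab"`, `"folded_sphere"`
#' @param r1,r2 inner/outer radii in mm (shell kinds); `r2 - r1` is the
#'   cortical thickness. For the slab, `r2 - r1` is also used as the bank
#'   thickness.
#' @param fold_amplitude sulcal depth in mm (folded kinds)
#' @param fold_wavelength sulcus period in mm (folded kinds)
#' @param sulcal_gap CSF width between opposing banks at the fundi, mm
#' @param tissue_means length-3 named intensity means `(csf, gm, wm)` in
#'   arbitrary units; see [tissue_preset()]
#' @param noise_sd additive Gaussian noise sd (a.u.)
#' @param spacing output voxel size in mm (isotropic)
#' @param supersample integer >= 1; labels and partial-volume intensities are
#'   synthesized on a grid this many times finer
#' @param seed RNG seed for the noise
#' @param dim output grid dimensions (auto for shells)
#' @param thickness_variation relative amplitude of a smooth sinusoidal
#'   thickness modulation along the slab (0 = constant thickness)
#' @param csf_thickness thickness (mm) of the outer CSF jacket; large values
#'   make the GM/CSF interface the only edge within a profile's reach (a
#'   clean step-edge phantom)
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(kind = c("shell", "folded_slab", "folded_sphere"),
                         r1 = 20, r2 = 22, fold_amplitude = 10,
                         fold_wavelength = 16, sulcal_gap = 0.5,
                         tissue_means = tissue_preset("neonatal"),
                         noise_sd = 0, spacing = 1, supersample = 4L,
                         seed = 1L, dim = NULL, thickness_variation = 0,
                         csf_thickness = 2) {
  kind <- match.arg(kind)
  stopifnot(r2 > r1, r1 > 0, spacing > 0, supersample >= 1)
  if (kind != "shell" && fold_amplitude >= fold_wavelength)
    stop("fold_amplitude >= fold_wavelength gives self-intersecting folds")
  if (is.null(dim)) {
    dim <- if (kind == "folded_slab") rep(ceiling(64 / spacing), 3)
    else rep(ceiling((2 * (r2 + csf_thickness) + 8) / spacing), 3)
  }
  if (length(dim) == 1) dim <- rep(dim, 3)
  structure(list(kind = kind, r1 = r1, r2 = r2,
                 fold_amplitude = fold_amplitude,
                 fold_wavelength = fold_wavelength, sulcal_gap = sulcal_gap,
                 tissue_means = tissue_means, noise_sd = noise_sd,
                 spacing = spacing, supersample = as.integer(supersample),
                 seed = as.integer(seed), dim = as.integer(dim),
                 thickness_variation = thickness_variation,
                 csf_thickness = csf_thickness),
            class = "phantom_spec")
}

#' Tissue intensity presets
#'
#' `"neonatal"` has low WM-GM contrast with the unmyelinated-WM polarity
#' (GM brighter than WM on T1-like contrast) and CSF close to WM, the
#' combination that makes neonatal surface extraction hard. `"adult"` has
#' conventional bright WM and dark CSF.
#'
#' @param name `"neonatal"` or `"adult"`
#' @return named numeric vector `(csf, gm, wm)`
#' @export
tissue_preset <- function(name = c("neonatal", "adult")) {
  name <- match.arg(name)
  switch(name,
         neonatal = c(csf = 45, gm = 85, wm = 55),
         adult = c(csf = 30, gm = 70, wm = 110))
}

# signed distance to an axis-aligned box given lo/hi corners
box_signed_distance <- function(X, Y, Z, lo, hi) {
  cx <- (lo + hi) / 2
  hw <- (hi - lo) / 2
  qx <- abs(X - cx[1]) - hw[1]
  qy <- abs(Y - cx[2]) - hw[2]
  qz <- abs(Z - cx[3]) - hw[3]
  inside <- pmin(pmax(qx, pmax(qy, qz)), 0)
  ox <- pmax(qx, 0); oy <- pmax(qy, 0); oz <- pmax(qz, 0)
  inside + sqrt(ox^2 + oy^2 + oz^2)
}

# geometry parameters shared by the slab rule and its truth helpers
slab_geometry <- function(spec) {
  ext <- spec$dim * spec$spacing
  t0 <- spec$r2 - spec$r1
  csf <- spec$csf_thickness
  margin <- 5
  z_bottom <- margin
  z_top_room <- t0 + csf + 3
  z_w <- ext[3] - margin - z_top_room       # WM top face
  z_out <- z_w + t0                         # outer flat surface
  lo <- c(margin + t0 + csf, margin + t0 + csf, z_bottom + t0 + csf)
  hi <- c(ext[1] - margin - t0 - csf, ext[2] - margin - t0 - csf, z_w)
  usable <- hi[1] - lo[1]
  K <- max(0L, floor(usable / spec$fold_wavelength))
  xc <- (lo[1] + hi[1]) / 2
  x_k <- if (K > 0) xc + (seq_len(K) - (K + 1) / 2) * spec$fold_wavelength
         else numeric(0)
  z_f <- z_out - spec$fold_amplitude + spec$sulcal_gap / 2  # capsule bottom
  list(lo = lo, hi = hi, z_w = z_w, z_out = z_out, x_k = x_k, z_f = z_f,
       t0 = t0, ext = ext)
}

# "inner-surface" scalar: s <= 0 WM, 0 < s <= t GM, t < s <= t+csf CSF
slab_s_field <- function(X, Y, Z, spec, g) {
  s <- box_signed_distance(X, Y, Z, g$lo, g$hi)
  if (spec$fold_amplitude > 0 && length(g$x_k) > 0) {
    carve_reach <- spec$sulcal_gap / 2 + g$t0
    for (xk in g$x_k) {
      dx <- abs(X - xk)
      d <- ifelse(Z >= g$z_f, dx, sqrt(dx^2 + (Z - g$z_f)^2))
      s <- pmax(s, carve_reach - d)
    }
  }
  s
}

local_thickness <- function(Y, spec, g) {
  if (spec$thickness_variation == 0) return(g$t0)
  g$t0 * (1 + spec$thickness_variation *
            sin(2 * pi * Y / (g$ext[2] / 2)))
}

# analytic label rule at world points; returns integer codes
phantom_label_rule <- function(spec, X, Y, Z) {
  csf <- spec$csf_thickness
  if (spec$kind == "shell") {
    ctr <- spec$dim * spec$spacing / 2
    r <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2)
    s <- r - spec$r1
    t <- spec$r2 - spec$r1
  } else if (spec$kind == "folded_slab") {
    g <- slab_geometry(spec)
    s <- slab_s_field(X, Y, Z, spec, g)
    t <- local_thickness(Y, spec, g)
  } else {  # folded_sphere
    ctr <- spec$dim * spec$spacing / 2
    dx <- X - ctr[1]; dy <- Y - ctr[2]; dz <- Z - ctr[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    theta <- acos(pmin(pmax(ifelse(r > 0, dz / pmax(r, 1e-12), 1), -1), 1))
    nfold <- max(2, round(2 * pi * spec$r1 / spec$fold_wavelength))
    rin <- spec$r1 + spec$fold_amplitude * sin(nfold * theta)
    s <- r - rin
    t <- spec$r2 - spec$r1
  }
  lab <- integer(length(s))
  lab[s <= 0] <- LABEL_WM
  lab[s > 0 & s <= t] <- LABEL_GM
  lab[s > t & s <= t + csf] <- LABEL_CSF
  lab
}

# coordinate arrays (world mm) for a grid of given dim/spacing
grid_coords <- function(dm, spacing) {
  x <- (seq_len(dm[1]) - 1) * spacing
  y <- (seq_len(dm[2]) - 1) * spacing
  z <- (seq_len(dm[3]) - 1) * spacing
  list(X = array(rep(x, times = dm[2] * dm[3]), dm),
       Y = array(rep(rep(y, each = dm[1]), times = dm[3]), dm),
       Z = array(rep(z, each = dm[1] * dm[2]), dm))
}

# mean-downsample a supersampled array by integer factor f per axis
box_downsample <- function(arr, f) {
  if (f == 1) return(arr)
  # reduce the leading axis, then rotate axes; three rounds restore order
  for (ax in 1:3) {
    d <- dim(arr)
    arr <- array(colMeans(array(arr, c(f, d[1] %/% f, d[2], d[3])), dims = 1),
                 c(d[1] %/% f, d[2], d[3]))
    arr <- aperm(arr, c(2, 3, 1))
  }
  arr
}

#' Generate a phantom
#'
#' Produces the intensity volume, the rasterized tissue labels and the
#' analytic ground truth for a [phantom_spec()]. Labels are assigned by
#' majority vote over a supersampled grid (emulating a segmenter under
#' partial volume), which realises the invisible-CSF condition exactly:
#' sulcal slots narrower than a voxel never win the vote.
#'
#' @param spec a `phantom_spec`
#' @return list with elements `intensity` (`voxel_grid`), `labels`
#'   (`voxel_grid`, integer codes 0-3), `brain_mask` (`voxel_grid`), and
#'   `truth` (a `phantom_truth`)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- spec$supersample
  dm <- spec$dim
  t0 <- spec$r2 - spec$r1
  if (t0 < spec$spacing)
    warning("cortical shell thinner than a voxel; expect heavy partial volume")
  sp_hi <- spec$spacing / f
  dm_hi <- dm * f
  co <- grid_coords(dm_hi, sp_hi)
  # hi-res grid voxel centers offset so that block means align with coarse
  # voxel centers: coarse center c = mean of its f^3 fine centers
  off <- (sp_hi - spec$spacing) / 2
  lab_hi <- phantom_label_rule(spec, co$X + off, co$Y + off, co$Z + off)
  lab_hi <- array(lab_hi, dm_hi)
  rm(co)

  # majority-vote labels at the output grid (ties toward the higher code)
  counts <- lapply(0:3, function(code)
    box_downsample((lab_hi == code) * 1, f))
  lab <- array(0L, dm)
  best <- counts[[1]]
  for (code in 1:3) {
    take <- counts[[code + 1]] >= best
    lab[take] <- code
    best[take] <- counts[[code + 1]][take]
  }
  affine <- diag(c(rep(spec$spacing, 3), 1))
  labels <- voxel_grid(lab, affine)

  lab_hi_grid <- voxel_grid(lab_hi, diag(c(rep(sp_hi, 3), 1)))
  intensity <- synthesize_intensity(lab_hi_grid, spec)

  truth <- phantom_truth(spec)
  mask <- lab > 0L
  storage.mode(mask) <- "integer"
  list(intensity = intensity, labels = labels,
       brain_mask = voxel_grid(mask, affine), truth = truth)
}

#' @rdname make_phantom
#' @export
make_shell_phantom <- function(spec) {
  stopifnot(spec$kind == "shell")
  make_phantom(spec)
}

#' @rdname make_phantom
#' @export
make_folded_phantom <- function(spec) {
  stopifnot(spec$kind %in% c("folded_slab", "folded_sphere"))
  make_phantom(spec)
}

#' Synthesize a partial-volume intensity volume from supersampled labels
#'
#' Assigns the tissue means on the fine grid, box-averages down to the
#' output grid (creating partial-volume mixtures at tissue boundaries) and
#' adds Gaussian noise with the spec seed.
#'
#' @param labels_hi supersampled label `voxel_grid`
#' @param spec the `phantom_spec` (tissue means, noise, seed, supersample)
#' @return intensity `voxel_grid` at the output resolution
#' @export
synthesize_intensity <- function(labels_hi, spec) {
  f <- spec$supersample
  means <- c(0, spec$tissue_means[["csf"]], spec$tissue_means[["gm"]],
             spec$tissue_means[["wm"]])
  img_hi <- array(means[labels_hi$data + 1L], dim(labels_hi$data))
  img <- box_downsample(img_hi, f)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- img + rnorm(length(img), sd = spec$noise_sd)
  }
  voxel_grid(img, diag(c(rep(spec$spacing, 3), 1)))
}

#' Analytic phantom ground truth
#'
#' Bundles the analytic surface/thickness description of a phantom:
#' distances to the true inner (WM/GM) and outer (GM/CSF) surfaces,
#' the ground-truth thickness, sulcal-region membership and distance to the
#' inter-bank medial surface (folded_slab), and a deterministic sampler of
#' points on the outer surface for landmark-style QA.
#'
#' @param spec a `phantom_spec`
#' @return object of class `phantom_truth`: a list of closures over the
#'   analytic geometry (see Details in the package vignette)
#' @export
phantom_truth <- function(spec) {
  t0 <- spec$r2 - spec$r1
  obj <- list(spec = spec, thickness = t0)
  if (spec$kind == "shell" || spec$kind == "folded_sphere") {
    ctr <- spec$dim * spec$spacing / 2
    obj$inner_distance <- function(xyz) {
      xyz <- to_xyz_matrix(xyz)
      abs(sqrt(rowSums(sweep(xyz, 2, ctr)^2)) - spec$r1)
    }
    obj$outer_distance <- function(xyz) {
      xyz <- to_xyz_matrix(xyz)
      abs(sqrt(rowSums(sweep(xyz, 2, ctr)^2)) - spec$r2)
    }
    obj$sample_outer <- function(n, seed = 1) {
      set.seed(seed)
      u <- matrix(rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      sweep(u * spec$r2, 2, ctr, "+")
    }
    if (spec$kind == "folded_sphere") {
      # radial surfaces: distances along the radius (proxy near-exact for
      # shallow folds)
      nfold <- max(2, round(2 * pi * spec$r1 / spec$fold_wavelength))
      rad_in <- function(xyz) {
        d <- sweep(to_xyz_matrix(xyz), 2, ctr)
        r <- sqrt(rowSums(d^2))
        th <- acos(pmin(pmax(ifelse(r > 0, d[, 3] / pmax(r, 1e-12), 1),
                             -1), 1))
        spec$r1 + spec$fold_amplitude * sin(nfold * th)
      }
      obj$inner_distance <- function(xyz) {
        d <- sweep(to_xyz_matrix(xyz), 2, ctr)
        abs(sqrt(rowSums(d^2)) - rad_in(xyz))
      }
      obj$outer_distance <- function(xyz) {
        d <- sweep(to_xyz_matrix(xyz), 2, ctr)
        abs(sqrt(rowSums(d^2)) - (rad_in(xyz) + t0))
      }
      obj$sample_outer <- function(n, seed = 1) {
        set.seed(seed)
        u <- matrix(rnorm(3 * n), n, 3)
        u <- u / sqrt(rowSums(u^2))
        th <- acos(pmin(pmax(u[, 3], -1), 1))
        r <- spec$r1 + spec$fold_amplitude * sin(nfold * th) + t0
        sweep(u * r, 2, ctr, "+")
      }
    }
  } else {  # folded_slab
    g <- slab_geometry(spec)
    obj$geometry <- g
    sfun <- function(xyz) {
      xyz <- to_xyz_matrix(xyz)
      slab_s_field(xyz[, 1], xyz[, 2], xyz[, 3], spec, g)
    }
    obj$inner_distance <- function(xyz) abs(sfun(xyz))
    obj$outer_distance <- function(xyz) abs(sfun(xyz) - t0)
    # distance to the inter-bank medial surface (plane x = x_k above the
    # capsule bottom, axis line below), for points inside sulcal regions
    obj$medial_distance <- function(xyz) {
      xyz <- to_xyz_matrix(xyz)
      if (length(g$x_k) == 0) return(rep(Inf, nrow(xyz)))
      d <- rep(Inf, nrow(xyz))
      for (xk in g$x_k) {
        dx <- abs(xyz[, 1] - xk)
        dk <- ifelse(xyz[, 3] >= g$z_f, dx,
                     sqrt(dx^2 + (xyz[, 3] - g$z_f)^2))
        d <- pmin(d, dk)
      }
      d
    }
    # sulcal interior: within the bank zone of some sulcus and below the
    # mouth by depth_frac of the sulcal depth
    obj$sulcal_interior <- function(xyz, depth_frac = 0.5, reach = NULL) {
      xyz <- to_xyz_matrix(xyz)
      if (length(g$x_k) == 0) return(rep(FALSE, nrow(xyz)))
      if (is.null(reach)) reach <- spec$sulcal_gap / 2 + t0
      zcut <- g$z_out - depth_frac * spec$fold_amplitude
      inx <- rep(FALSE, nrow(xyz))
      for (xk in g$x_k)
        inx <- inx | abs(xyz[, 1] - xk) <= reach
      inx & xyz[, 3] <= zcut & xyz[, 3] >= g$z_f &
        xyz[, 2] >= g$lo[2] & xyz[, 2] <= g$hi[2]
    }
    # CSF slot interior (strictly inside the analytic sulcal CSF)
    obj$slot_interior <- function(xyz, depth_frac = 0.5) {
      xyz <- to_xyz_matrix(xyz)
      if (length(g$x_k) == 0) return(rep(FALSE, nrow(xyz)))
      zcut <- g$z_out - depth_frac * spec$fold_amplitude
      inx <- rep(FALSE, nrow(xyz))
      for (xk in g$x_k)
        inx <- inx | abs(xyz[, 1] - xk) < spec$sulcal_gap / 2
      inx & xyz[, 3] <= zcut & xyz[, 3] >= g$z_f &
        xyz[, 2] >= g$lo[2] & xyz[, 2] <= g$hi[2]
    }
    obj$fundus_lines <- cbind(x = g$x_k, z = g$z_f - spec$sulcal_gap / 2)
    obj$sample_outer <- function(n, seed = 1) {
      set.seed(seed)
      pts <- matrix(NA_real_, n, 3)
      gap2 <- spec$sulcal_gap / 2
      wall_h <- max(g$z_out - g$z_f, 0)
      # area weights: flat top vs bank walls (two per sulcus)
      flat_w <- (g$hi[1] - g$lo[1]) - length(g$x_k) * 2 * gap2
      walls_w <- length(g$x_k) * 2 * wall_h
      for (i in seq_len(n)) {
        y <- stats::runif(1, g$lo[2] + 1, g$hi[2] - 1)
        if (stats::runif(1) < flat_w / (flat_w + walls_w) ||
            length(g$x_k) == 0) {
          repeat {
            x <- stats::runif(1, g$lo[1] + 1, g$hi[1] - 1)
            if (length(g$x_k) == 0 || min(abs(x - g$x_k)) > gap2 + 0.25)
              break
          }
          pts[i, ] <- c(x, y, g$z_out)
        } else {
          xk <- sample(g$x_k, 1)
          side <- sample(c(-1, 1), 1)
          z <- stats::runif(1, g$z_f + 0.25, g$z_out - 0.25)
          pts[i, ] <- c(xk + side * gap2, y, z)
        }
      }
      pts
    }
  }
  # per-point ground-truth thickness (constant unless modulated)
  obj$thickness_at <- function(xyz) {
    xyz <- to_xyz_matrix(xyz)
    if (spec$kind == "folded_slab") {
      g <- slab_geometry(spec)
      local_thickness(xyz[, 2], spec, g)
    } else rep(t0, nrow(xyz))
  }
  class(obj) <- "phantom_truth"
  obj
}
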