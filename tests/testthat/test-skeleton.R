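# fixtures shared across skeleton tests
slab_union <- function() fixture("slab_union", function() {
  ph <- slab_phantom_invisible()
  uv <- build_union(ph$labels)
  cv <- boundary_curvature(uv)
  seeds <- seed_catchment_basins(uv, cv)
  list(ph = ph, uv = uv, cv = cv, seeds = seeds)
})

slab_skeleton <- function() fixture("slab_skeleton", function() {
  su <- slab_union()
  sk <- homotopic_erode(su$uv, su$seeds, su$cv)
  list(su = su, sk = sk, pruned = prune_skeleton(sk))
})

test_that("the union, hull and inner boundary match the shell geometry", {
  ph <- shell_phantom_small()
  uv <- build_union(ph$labels)
  sp <- ph$truth$spec
  ctr <- sp$dim * sp$spacing / 2
  dm <- dim(uv$union)
  idx <- which(uv$inner)
  r_in <- sqrt(rowSums(sweep(arrayInd(idx, dm) - 1, 2, ctr)^2))
  expect_lt(max(abs(r_in - sp$r1)), 1.8)  # one-voxel shell at r1
  idxh <- which(uv$hull)
  r_h <- sqrt(rowSums(sweep(arrayInd(idxh, dm) - 1, 2, ctr)^2))
  expect_gt(min(r_h), sp$r2)  # hull lies outside the pial surface
  expect_true(all(uv$hull[uv$hull] %in% TRUE))
  # no CSF at all: union = GM still valid
  lab2 <- ph$labels
  lab2$data[lab2$data == 1L] <- 0L
  uv2 <- build_union(lab2)
  expect_gt(sum(uv2$union), 0)
})

test_that("implicit-surface curvature matches the analytic sphere", {
  ball <- digital_ball(10, dim = rep(30L, 3))$data
  cv <- volume_curvature(ball, c(1, 1, 1), 1.5)
  bd <- cv$boundary
  expect_lt(abs(mean(cv$H[bd]) - 1 / 10) / (1 / 10), 0.25)
  expect_lt(abs(mean(cv$K[bd]) - 1 / 100) / (1 / 100), 0.40)
  # flat slab face: both curvatures at least 5x below the ball's
  slab <- array(0L, rep(30L, 3)); slab[5:25, 5:25, 10:20] <- 1L
  cvs <- volume_curvature(slab, c(1, 1, 1), 1.5)
  face <- array(FALSE, rep(30L, 3)); face[10:20, 10:20, 20] <- TRUE
  expect_lt(mean(abs(cvs$H[face])), (1 / 10) / 5)
  expect_lt(mean(abs(cvs$K[face])), (1 / 100) / 5)
})

test_that("saddle points at sulcal walls have negative Gaussian curvature", {
  su <- slab_union()
  g <- su$ph$truth$geometry
  # points on the fundus arc of the WM surface (concave trench): H < 0
  K <- su$cv$inner$K
  H <- su$cv$inner$H
  dm <- dim(H)
  fl <- su$ph$truth$fundus_lines
  for (k in seq_len(nrow(fl))) {
    sel <- array(FALSE, dm)
    xs <- round(fl[k, "x"]) + 1
    zs <- round(g$z_f) + 1 - 2  # just below the capsule bottom, on WM surface
    sel[xs, seq(round(g$lo[2]) + 3, round(g$hi[2]) - 3), zs + 0:1] <- TRUE
    expect_lt(mean(H[sel & su$cv$inner$boundary | sel]), 0)
  }
})

test_that("catchment basins appear at fundi and only at fundi", {
  # shell: no folds, no seeds
  ph <- shell_phantom_small()
  uv <- build_union(ph$labels)
  cv <- boundary_curvature(uv)
  expect_warning(s0 <- seed_catchment_basins(uv, cv), "no catchment")
  expect_equal(attr(s0, "n_basins"), 0L)
  # slab: one basin per sulcus, all seeds within 2 voxels of a fundus line
  su <- slab_union()
  g <- su$ph$truth$geometry
  expect_gte(attr(su$seeds, "n_basins"), length(g$x_k))
  idx <- which(su$seeds > 0)
  co <- arrayInd(idx, dim(su$seeds)) - 1
  fl <- su$ph$truth$fundus_lines
  fundus_dist <- function(pts) {
    dmin <- rep(Inf, nrow(pts))
    for (k in seq_len(nrow(fl)))
      dmin <- pmin(dmin, sqrt((pts[, 1] - fl[k, "x"])^2 +
                                (pts[, 3] - fl[k, "z"])^2))
    dmin
  }
  # each basin sits on a fundus line; no stray seeds far from any fundus
  for (b in seq_len(attr(su$seeds, "n_basins"))) {
    centroid <- colMeans(co[su$seeds[idx] == b, , drop = FALSE])
    expect_lt(fundus_dist(rbind(centroid)), 2)
  }
  expect_lt(max(fundus_dist(co)), 4.5)
  # an absurd threshold finds nothing
  expect_warning(sInf <- seed_catchment_basins(su$uv, su$cv,
                                               mode = "gaussian",
                                               k_threshold = 1e6))
  expect_equal(attr(sInf, "n_basins"), 0L)
})

test_that("erosion is idempotent on a one-voxel-thick sheet", {
  sheet <- digital_sheet()
  dm <- dim(sheet)
  uv <- structure(list(union = sheet == 1L,
                       hull = array(FALSE, dm),
                       inner = array(FALSE, dm),
                       wm = array(FALSE, dm),
                       affine = diag(4), spacing = c(1, 1, 1)),
                  class = "union_volume")
  cv <- list(union = volume_curvature(sheet, c(1, 1, 1), 1.5))
  sk <- homotopic_erode(uv, array(0L, dm), cv)
  # no front can reach a free sheet with no internal border: output = input
  expect_identical(sk$mask, sheet == 1L)
})

test_that("homotopic erosion preserves components and Euler number throughout", {
  ss <- slab_skeleton()
  uni <- ss$su$uv$union
  ord <- ss$sk$order
  chi0 <- euler_voxel_complex(uni)
  comp0 <- count_components(uni)
  m <- uni
  checkpoints <- unique(round(seq(1, length(ord), length.out = 6)))[-1]
  prev <- 0
  for (s in checkpoints) {
    m[ord[(prev + 1):s]] <- FALSE
    prev <- s
    expect_equal(euler_voxel_complex(m), chi0)
    expect_equal(count_components(m), comp0)
  }
})

test_that("the skeleton sheet tracks the inter-bank medial surface", {
  ss <- slab_skeleton()
  ph <- ss$su$ph
  sk2 <- ss$pruned
  dm <- dim(sk2$mask)
  idx <- which(sk2$mask & !sk2$hull)
  w <- world_from_voxel(ph$labels, arrayInd(idx, dm) - 1)
  insul <- ph$truth$sulcal_interior(w, depth_frac = 0.3)
  expect_gt(sum(insul), 200)
  md <- ph$truth$medial_distance(w)
  expect_gte(mean(md[insul] <= 1), 0.9)
  # structural invariants: skeleton within union, hull kept, thin
  expect_true(all(sk2$mask[!ss$su$uv$union] == FALSE))
  expect_true(all(sk2$mask[ss$su$uv$hull]))
  # thinness: interior-class voxels occur only as rare triple-junction
  # artifacts where sheet, hull and side fronts meet (< 0.5% of the skeleton)
  expect_lt(sum(sk2$classes == 1L) / sum(sk2$mask), 0.005)
})

test_that("pruning removes branches but never sheets", {
  dm <- rep(16L, 3)
  sheet <- digital_sheet(dim = dm)
  withbranch <- sheet
  withbranch[9:14, 8, 8] <- 1L  # dangling curve branch off the sheet
  pruned <- prune_skeleton(withbranch)
  expect_identical(which(pruned), which(sheet == 1L))
  # pure sheet unchanged
  expect_identical(which(prune_skeleton(sheet)), which(sheet == 1L))
  # empty deletable set = identity
  same <- prune_skeleton(withbranch, deletable_classes = character(0))
  expect_identical(which(same), which(withbranch == 1L))
  expect_error(prune_skeleton(sheet, deletable_classes = "surface"),
               "undeletable")
})
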