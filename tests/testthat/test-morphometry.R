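test_that("thickness definitions agree with the analytic shell", {
  tm <- shell_truth_meshes()
  for (method in c("linked", "nearest", "symmetric")) {
    th <- cortical_thickness(tm$wm, tm$pial, method)
    expect_true(all(abs(th - (tm$r2 - tm$r1)) < 0.25), label = method)
  }
  # identical meshes: zero thickness
  th0 <- cortical_thickness(tm$wm, tm$wm)
  expect_true(all(th0 == 0))
  # nearest is a minimum: never exceeds the linked distance
  thl <- cortical_thickness(tm$wm, tm$pial, "linked")
  thn <- cortical_thickness(tm$wm, tm$pial, "nearest")
  expect_true(all(thn <= thl + 1e-9))
  # linked requires shared connectivity
  other <- icosphere(2)
  expect_error(cortical_thickness(tm$wm, other, "linked"), "connectivity")
})

test_that("surface smoothing hits the requested FWHM and conserves the mean", {
  mesh <- icosphere(4)
  n <- nrow(mesh$vertices)
  const <- rep(2, n)
  expect_equal(as.numeric(smooth_scalar_map(mesh, const, fwhm = 0.5)),
               const)  # impulse-free fixed point (after edge-length warning)
  # impulse response: empirical FWHM within 20% of request
  v <- rep(0, n); v[1] <- 1
  fwhm_req <- 0.5  # on the unit sphere, mean edge ~0.07
  sm <- smooth_scalar_map(mesh, v, fwhm = fwhm_req)
  expect_lt(abs(mean(sm) - mean(v)) / mean(v), 0.001)
  expect_lt(var(sm), var(v))
  # geodesic spread: distance at which the response halves relative to max
  d <- sqrt(rowSums(sweep(mesh$vertices, 2,
                          mesh$vertices[1, ])^2))
  peak <- max(sm)
  half_r <- max(d[sm >= peak / 2])
  expect_lt(abs(2 * half_r - fwhm_req) / fwhm_req, 0.2)
})

test_that("smoothing warns and returns raw below the edge length", {
  mesh <- icosphere(2)
  v <- rnorm(nrow(mesh$vertices))
  expect_warning(out <- smooth_scalar_map(mesh, v, fwhm = 0.01), "edge")
  expect_equal(as.numeric(out), v)
})

test_that("sulcal depth is zero on the hull and recovers fold depth", {
  s <- icosphere(3)
  sphere <- triangle_mesh(s$vertices * 30, s$triangles)
  d0 <- sulcal_depth(sphere, sphere)
  expect_lt(max(d0), 1e-6)
  expect_true(all(d0 >= 0))
  ph <- slab_phantom_invisible()
  g <- ph$truth$geometry
  # depth of analytic points on the bank walls, measured to the hull mesh
  hm <- hull_mesh(voxel_grid(array(as.integer(ph$labels$data > 0),
                                   dim(ph$labels$data)),
                             ph$labels$affine))
  deep_pts <- cbind(g$x_k[1] + ph$truth$spec$sulcal_gap / 2,
                    seq(g$lo[2] + 5, g$hi[2] - 5, length.out = 9),
                    g$z_f + 0.5)
  mesh_pts <- triangle_mesh(rbind(deep_pts,
                                  deep_pts + c(0, 0.01, 0),
                                  deep_pts + c(0, 0, 0.01)),
                            cbind(1:9, 10:18, 19:27))
  dd <- sulcal_depth(mesh_pts, hm)[1:9]
  # wall points near the fundus are buried by ~the fold amplitude
  expect_true(all(dd > 0.6 * ph$truth$spec$fold_amplitude))
  # monotone along the wall: deeper points have larger depth
  zs <- seq(g$z_f + 0.5, g$z_out - 0.5, length.out = 7)
  wall <- cbind(g$x_k[1] + ph$truth$spec$sulcal_gap / 2, 30, zs)
  wall_mesh <- triangle_mesh(rbind(wall, wall + c(0, 0.01, 0),
                                   wall + c(0, 0, 0.01)),
                             cbind(1:7, 8:14, 15:21))
  dw <- sulcal_depth(wall_mesh, hm)[1:7]
  expect_true(all(diff(dw) < 0.5))  # shallower toward the mouth
  expect_gt(dw[1], dw[7])
})

test_that("landmark distances are exact point-to-triangle distances", {
  tm <- shell_truth_meshes()
  # a landmark on a vertex has distance zero
  lm0 <- tm$pial$vertices[5, , drop = FALSE]
  d0 <- landmark_distances(lm0, tm$pial)
  expect_lt(d0$distance[1], 1e-9)
  # 1 mm along a face normal from a face centroid
  tri <- tm$pial$triangles[10, ]
  cen <- colMeans(tm$pial$vertices[tri, ])
  a <- tm$pial$vertices[tri[1], ]; b <- tm$pial$vertices[tri[2], ]
  cc <- tm$pial$vertices[tri[3], ]
  nrm <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
           (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
           (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  d1 <- landmark_distances(rbind(cen + nrm), tm$pial)
  expect_lt(abs(d1$distance[1] - 1), 1e-6)
  expect_error(landmark_distances(matrix(0, 0, 3), tm$pial), "empty")
  expect_s3_class(d1, "tbl_df")
})

test_that("template selection is exact, noise-robust and scale-invariant", {
  set.seed(3)
  n <- 642
  base <- blur_target_map(icosphere(3), rnorm(n), 5)
  templates <- lapply(1:4, function(i)
    blur_target_map(icosphere(3), rnorm(n), 5))
  templates[[2]] <- base
  sel <- select_template(base, templates)
  expect_equal(sel$best, 2L)
  expect_equal(sel$correlations[2], 1.0)
  # affine rescaling leaves the choice unchanged (Pearson invariance)
  sel2 <- select_template(3.5 * base + 10, templates)
  expect_equal(sel2$best, 2L)
  expect_equal(sel2$correlations[2], 1.0, tolerance = 1e-12)
  # 50 seeded noisy trials at noise sd = 0.2 * signal sd: always correct
  hits <- vapply(1:50, function(i) {
    set.seed(100 + i)
    noisy <- base + rnorm(n, sd = 0.2 * sd(base))
    select_template(noisy, templates)$best == 2L
  }, logical(1))
  expect_true(all(hits))
  # degenerate maps are rejected or excluded
  expect_error(select_template(rep(1, n), templates), "zero-variance")
  t2 <- templates
  t2[[3]] <- rep(0, n)
  sel3 <- select_template(base, t2)
  expect_true(is.na(sel3$correlations[3]))
  expect_equal(sel3$best, 2L)
})
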