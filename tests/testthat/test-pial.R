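# concentric-shell harmonic fixture: WM ball r1=20, domain to r2=25,
# synthetic skeleton shell just outside r2
concentric_fixture <- function() fixture("concentric", function() {
  dm <- rep(56L, 3)
  co <- neosurf:::grid_coords(dm, 1)
  ctr <- rep(27.5, 3)
  r <- sqrt((co$X - ctr[1])^2 + (co$Y - ctr[2])^2 + (co$Z - ctr[3])^2)
  list(dm = dm, ctr = ctr, r = r,
       uni = r > 20 & r <= 26.5,
       wm = r <= 20,
       skel = r > 25 & r <= 26.5)
})

concentric_domain <- function(fx) {
  structure(list(union = fx$uni, wm = fx$wm,
                 hull = array(FALSE, fx$dm),
                 inner = fx$uni & fx$r <= 21,
                 affine = diag(4), spacing = c(1, 1, 1)),
            class = "union_volume")
}

test_that("the Laplace solution matches the analytic radial harmonic", {
  fx <- concentric_fixture()
  lf <- solve_laplace(concentric_domain(fx), fx$skel, tol = 1e-6)
  inside <- fx$uni & fx$r > 21 & fx$r < 24
  analytic <- (1 / 20 - 1 / fx$r[inside]) / (1 / 20 - 1 / 25)
  err <- abs(lf$potential$data[inside] - analytic)
  expect_lt(mean(err), 0.02)
  expect_true(all(lf$potential$data >= -1e-9 &
                    lf$potential$data <= 1 + 1e-9))
  # residual decays steadily to convergence
  hist <- lf$residual_history
  expect_lt(tail(hist, 1), head(hist, 1) / 1e3)
  expect_lt(cor(seq_along(hist), log(hist)), -0.9)
  # interior values are discrete-harmonic: each equals its 6-neighbour mean
  pot <- lf$potential$data
  nb_mean <- array(0, fx$dm)
  for (ax in 1:3)
    nb_mean <- nb_mean + neosurf:::shift_array_zero(pot, 1, ax) +
      neosurf:::shift_array_zero(pot, -1, ax)
  nb_mean <- nb_mean / 6
  deep <- fx$uni & fx$r > 22 & fx$r < 23.5
  expect_lt(max(abs(pot[deep] - nb_mean[deep])), 1e-4)
})

test_that("an all-boundary domain keeps its boundary values exactly", {
  dm <- rep(12L, 3)
  sheet <- array(FALSE, dm)
  sheet[6, 3:9, 3:9] <- TRUE
  dom <- structure(list(union = sheet, wm = array(FALSE, dm),
                        hull = array(FALSE, dm), inner = array(FALSE, dm),
                        affine = diag(4), spacing = c(1, 1, 1)),
                   class = "union_volume")
  lf <- solve_laplace(dom, sheet)
  expect_true(all(lf$potential$data[sheet] == 1))
  expect_true(all(lf$potential$data[!sheet] == 0))
})

test_that("streamlines are radial on concentric shells and arrive at r2", {
  fx <- concentric_fixture()
  lf <- solve_laplace(concentric_domain(fx), fx$skel, tol = 1e-6)
  ico <- icosphere(3)
  wm_mesh <- triangle_mesh(sweep(ico$vertices * 20, 2, fx$ctr, "+"),
                           ico$triangles)
  sl <- trace_streamlines(lf, wm_mesh, fx$skel)
  rr <- sqrt(rowSums(sweep(sl$pial$vertices, 2, fx$ctr)^2))
  expect_lt(abs(mean(rr) - 25), 0.5)
  expect_gt(mean(abs(rr - 25) <= 0.5), 0.9)
  # potential is nondecreasing start to arrival
  expect_true(all(sl$potential_end >= sl$potential_start - 1e-6,
                  na.rm = TRUE))
  # a vertex already on the skeleton does not move
  on_skel <- triangle_mesh(sweep(ico$vertices * 25.8, 2, fx$ctr, "+"),
                           ico$triangles)
  sl2 <- trace_streamlines(lf, on_skel, fx$skel)
  expect_lt(max(sl2$length), 1e-9)
})

test_that("the intermediate pial surface penetrates every invisible sulcus", {
  ph <- slab_phantom_invisible()
  labels <- ph$labels
  wm <- voxel_grid(array(as.integer(labels$data == 3L), dim(labels$data)),
                   labels$affine)
  mesh <- coarsen_mesh(extract_wm_mesh(wm), 6000)
  uv <- build_union(labels)
  cv <- boundary_curvature(uv)
  seeds <- seed_catchment_basins(uv, cv)
  skel <- prune_skeleton(homotopic_erode(uv, seeds, cv))
  field <- solve_laplace(uv, skel)
  sl <- trace_streamlines(field, mesh,
                          skel$mask | (labels$data == 1L))
  g <- ph$truth$geometry
  P <- sl$pial$vertices
  for (xk in g$x_k) {
    insl <- abs(P[, 1] - xk) <= 1.5 & P[, 2] > g$lo[2] + 2 &
      P[, 2] < g$hi[2] - 2 & P[, 3] > g$lo[3] + 3
    pen <- g$z_out - min(P[insl, 3])
    expect_gte(pen, 0.8 * ph$truth$spec$fold_amplitude)
  }
})

test_that("build_pial recovers the shell's outer surface with shared connectivity", {
  ph <- shell_phantom_small()
  labels <- ph$labels
  sp <- ph$truth$spec
  ctr <- sp$dim * sp$spacing / 2
  wm <- voxel_grid(array(as.integer(labels$data == 3L), dim(labels$data)),
                   labels$affine)
  m0 <- coarsen_mesh(extract_wm_mesh(wm), 20000)
  sm <- inflate_to_sphere(m0)
  wmesh <- icosahedron_resample(m0, sm, 3)
  wref <- deform_to_edges(wmesh, ph$intensity,
                          profile_params(expected_sign = 1),
                          deformation_params())
  uv <- build_union(labels)
  cv <- boundary_curvature(uv)
  seeds <- suppressWarnings(seed_catchment_basins(uv, cv))
  skel <- prune_skeleton(homotopic_erode(uv, seeds, cv))
  pr <- build_pial(wref, labels, ph$intensity, skel, union_volume = uv)
  rr <- radial_distance(pr$pial, ctr)
  expect_lt(mean(abs(rr - sp$r2)), 0.25)
  expect_identical(pr$pial$triangles, wref$triangles)
  # outward motion: pial never crosses the WM surface
  disp <- pr$pial$vertices - wref$vertices
  nrm <- vertex_normals(wref)
  expect_gt(mean(rowSums(disp * nrm) > -0.05), 0.99)
  # refinement improves on the intermediate surface
  d_ref <- mean(ph$truth$outer_distance(pr$pial$vertices))
  d_int <- mean(ph$truth$outer_distance(pr$intermediate$vertices))
  expect_lt(d_ref, d_int)
})
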