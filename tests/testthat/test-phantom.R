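test_that("shell phantom matches its analytic geometry", {
  ph <- shell_phantom_small()
  sp <- ph$truth$spec
  expect_equal(ph$truth$thickness, 2)
  wm_vol <- sum(ph$labels$data == 3) * sp$spacing^3
  expect_lt(abs(wm_vol - 4 / 3 * pi * sp$r1^3) / (4 / 3 * pi * sp$r1^3), 0.03)
  expect_true(all(sort(unique(as.vector(ph$labels$data))) == 0:3))
})

test_that("phantom generation is deterministic under a fixed seed", {
  sp <- phantom_spec("shell", r1 = 10, r2 = 12, noise_sd = 5, seed = 11,
                     supersample = 2)
  a <- make_shell_phantom(sp)
  b <- make_shell_phantom(sp)
  expect_identical(a$intensity$data, b$intensity$data)
  expect_identical(a$labels$data, b$labels$data)
})

test_that("sub-voxel sulcal gaps leave no CSF voxel inside sulci", {
  ph <- slab_phantom_invisible()
  dm <- dim(ph$labels$data)
  co <- neosurf:::grid_coords(dm, 1)
  pts <- cbind(as.vector(co$X), as.vector(co$Y), as.vector(co$Z))
  inside <- ph$truth$slot_interior(pts)
  expect_gt(sum(inside), 100)
  expect_equal(sum(ph$labels$data[inside] == 1L), 0L)
})

test_that("wide sulcal gaps put CSF in every sulcus", {
  ph <- make_folded_phantom(phantom_spec("folded_slab", r1 = 20, r2 = 22,
                                         sulcal_gap = 3, fold_amplitude = 10,
                                         fold_wavelength = 16, dim = 64,
                                         supersample = 2))
  g <- ph$truth$geometry
  dm <- dim(ph$labels$data)
  co <- neosurf:::grid_coords(dm, 1)
  for (xk in g$x_k) {
    sel <- abs(co$X - xk) < 1 & co$Z > g$z_f & co$Z < g$z_out &
      co$Y > g$lo[2] & co$Y < g$hi[2]
    expect_gt(sum(ph$labels$data[sel] == 1L), 0)
  }
})

test_that("zero fold amplitude degenerates to a plain slab", {
  ph <- make_folded_phantom(phantom_spec("folded_slab", r1 = 20, r2 = 22,
                                         fold_amplitude = 0, dim = 48,
                                         supersample = 2))
  expect_equal(length(ph$truth$geometry$x_k) * 0, 0)  # geometry still valid
  # no CSF below the outer flat surface other than the jacket
  g <- ph$truth$geometry
  co <- neosurf:::grid_coords(dim(ph$labels$data), 1)
  interior <- co$Z < g$z_w & co$Z > g$lo[3] & co$X > g$lo[1] &
    co$X < g$hi[1] & co$Y > g$lo[2] & co$Y < g$hi[2]
  expect_equal(sum(ph$labels$data[interior] == 1L), 0L)
  pts <- ph$truth$sample_outer(50, seed = 3)
  expect_true(all(abs(ph$truth$outer_distance(pts)) < 1e-9))
})

test_that("self-intersecting fold geometry is rejected", {
  expect_error(phantom_spec("folded_slab", fold_amplitude = 20,
                            fold_wavelength = 16), "self-intersecting")
})

test_that("intensity synthesis models partial volume by box averaging", {
  # supersample 1, no noise: exactly the pure tissue values
  sp1 <- phantom_spec("shell", r1 = 8, r2 = 10, supersample = 1,
                      noise_sd = 0, dim = 26)
  ph1 <- make_shell_phantom(sp1)
  vals <- sort(unique(as.vector(ph1$intensity$data)))
  expect_true(all(vals %in% c(0, sp1$tissue_means)))

  # supersample 4: boundary voxels strictly between adjacent tissue means
  sp4 <- phantom_spec("shell", r1 = 8, r2 = 10, supersample = 4,
                      noise_sd = 0, dim = 26)
  ph4 <- make_shell_phantom(sp4)
  mixed <- ph4$intensity$data[ph4$intensity$data > 0 &
                                ph4$intensity$data <
                                  min(sp4$tissue_means)]
  expect_gt(length(mixed), 0)
  expect_true(all(mixed > 0 & mixed < max(sp4$tissue_means)))

  # noise statistics on pure WM voxels
  spn <- phantom_spec("shell", r1 = 8, r2 = 10, supersample = 2,
                      noise_sd = 3, seed = 5, dim = 26)
  phn <- make_shell_phantom(spn)
  core <- phn$labels$data == 3
  for (ax in 1:3)
    core <- core & neosurf:::shift_array_zero(phn$labels$data == 3, 1, ax) &
      neosurf:::shift_array_zero(phn$labels$data == 3, -1, ax)
  wm_vals <- phn$intensity$data[core]
  expect_lt(abs(mean(wm_vals) - spn$tissue_means[["wm"]]),
            2 * 3 / sqrt(length(wm_vals)) + 0.5)
})

test_that("rasterized volumes converge to analytic volume with supersampling", {
  va <- 4 / 3 * pi * 10^3
  err <- vapply(c(1, 4), function(f) {
    ph <- make_shell_phantom(phantom_spec("shell", r1 = 10, r2 = 12,
                                          supersample = f, dim = 32))
    abs(sum(ph$labels$data == 3) - va) / va
  }, numeric(1))
  expect_lte(err[2], err[1] + 1e-9)
})

test_that("optional thickness modulation changes the truth field smoothly", {
  sp <- phantom_spec("folded_slab", r1 = 20, r2 = 22, fold_amplitude = 0,
                     dim = 48, supersample = 2, thickness_variation = 0.2)
  ph <- make_folded_phantom(sp)
  pts <- cbind(30, seq(12, 36, length.out = 20), 30)
  tt <- ph$truth$thickness_at(pts)
  expect_gt(diff(range(tt)), 0.3)
  expect_true(all(tt > 0))
})
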