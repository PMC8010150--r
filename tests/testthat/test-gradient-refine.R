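test_that("profiles sample the volume along normals as specified", {
  # constant image: constant profile, zero gradient everywhere
  g <- voxel_grid(array(7, c(20, 20, 20)), diag(4))
  ico <- icosphere(1)
  mesh <- triangle_mesh(ico$vertices * 5 + 9.5, ico$triangles)
  pp <- profile_params(search_step = 0.5, search_distance = 3)
  prof <- sample_profiles(mesh, g, pp)
  expect_equal(ncol(prof), 13L)
  expect_true(all(abs(prof - 7) < 1e-9))
  fe <- find_edges(prof, pp)
  expect_true(all(!fe$defined))
  expect_true(all(fe$offset == 0))

  # linear ramp: profile linear in offset, gradient constant
  co <- neosurf:::grid_coords(c(20, 20, 20), 1)
  ramp <- voxel_grid(co$X * 2, diag(4))
  vert <- matrix(c(9.5, 9.5, 9.5), 1)
  m1 <- triangle_mesh(rbind(vert, vert + c(0, 1, 0), vert + c(0, 0, 1)),
                      matrix(c(1, 2, 3), 1))
  # single triangle with normal along +x
  pp0 <- profile_params(search_step = 0.5, search_distance = 3,
                        profile_blur_sigma = 0)
  p1 <- sample_profile(m1, 1, ramp, pp0)
  off <- attr(p1, "offsets")
  fit <- lm(p1 ~ off)
  expect_lt(abs(coef(fit)[2] - 2), 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("profile crosses the GM/CSF step near the analytic shell edge", {
  ph <- shell_phantom_small()
  sp <- ph$truth$spec
  ctr <- sp$dim * sp$spacing / 2
  ico <- icosphere(2)
  mesh <- triangle_mesh(sweep(ico$vertices * 21, 2, ctr, "+"), ico$triangles)
  pp <- profile_params(search_step = 0.5, search_distance = 5,
                       expected_sign = -1)
  prof <- sample_profiles(mesh, ph$intensity, pp)
  off <- attr(prof, "offsets")
  # the profile crosses the GM/CSF midpoint intensity near offset r2 - 21 = 1
  mid <- mean(c(sp$tissue_means[["gm"]], sp$tissue_means[["csf"]]))
  crossing <- apply(prof, 1, function(pr) {
    k <- which(pr[-length(pr)] >= mid & pr[-1] < mid)[1]
    if (is.na(k)) return(NA_real_)
    off[k] + (pr[k] - mid) / (pr[k] - pr[k + 1]) * 0.5
  })
  expect_lt(abs(median(crossing, na.rm = TRUE) - (sp$r2 - 21)), 0.5)
})

test_that("edge finding brackets steps, honors sign, rejects flat profiles", {
  off <- seq(-2.5, 2.5, by = 0.5)
  pp <- profile_params(search_step = 0.5, search_distance = 2.5,
                       profile_blur_sigma = 0)
  step_prof <- structure(c(rep(0, 5), rep(10, 6)), offsets = off)
  fe <- find_edge(step_prof, pp)
  expect_true(fe$defined)
  expect_gte(fe$offset, -0.5)   # true edge between -0.5 and 0
  expect_lte(fe$offset, 0)
  # double step: rising at -1, falling at +1; sign selects
  dbl <- structure(c(0, 0, 5, 10, 10, 10, 10, 5, 0, 0, 0), offsets = off)
  up <- find_edge(dbl, profile_params(0.5, 2.5, 0, expected_sign = 1))
  dn <- find_edge(dbl, profile_params(0.5, 2.5, 0, expected_sign = -1))
  expect_lt(up$offset, 0)
  expect_gt(dn$offset, 0)
  flat <- structure(rep(4, 11), offsets = off)
  ff <- find_edge(flat, pp)
  expect_false(ff$defined)
  expect_equal(ff$offset, 0)
})

test_that("surface diffusion blurring is mean-preserving and kills outliers", {
  mesh <- icosphere(4)  # 2562 vertices
  const <- rep(3, nrow(mesh$vertices))
  expect_equal(blur_target_map(mesh, const, 10), const)
  big <- icosphere(6)  # 40,962 vertices
  v <- rep(0, nrow(big$vertices))
  v[100] <- 100
  b <- blur_target_map(big, v, 10)
  expect_lt(max(b), 6)        # >94% attenuation of the outlier
  expect_lt(abs(mean(b) - mean(v)), 1e-9)
  # NA vertices are filled from neighbours before blurring
  v2 <- rep(1, nrow(mesh$vertices))
  v2[c(5, 50, 500)] <- NA
  expect_true(all(abs(blur_target_map(mesh, v2, 3) - 1) < 1e-9))
})

test_that("deformation is a fixed point on a surface already at the edge", {
  ph <- make_shell_phantom(phantom_spec("shell", r1 = 15, r2 = 17,
                                        csf_thickness = 8, noise_sd = 0))
  sp <- ph$truth$spec
  ctr <- sp$dim * sp$spacing / 2
  ico <- icosphere(3)
  at_edge <- triangle_mesh(sweep(ico$vertices * sp$r2, 2, ctr, "+"),
                           ico$triangles)
  out <- deform_to_edges(at_edge, ph$intensity,
                         profile_params(expected_sign = -1),
                         deformation_params(resolution_schedule =
                                              list(c(1.5, 0.25))))
  moved <- sqrt(rowSums((out$vertices - at_edge$vertices)^2))
  expect_lt(mean(moved), 0.15)
})

test_that("a mesh 2 mm inside a clean step edge converges onto it", {
  ph <- make_shell_phantom(phantom_spec("shell", r1 = 20, r2 = 25,
                                        csf_thickness = 8, noise_sd = 0))
  sp <- ph$truth$spec
  ctr <- sp$dim * sp$spacing / 2
  ico <- icosphere(3)
  start <- triangle_mesh(sweep(ico$vertices * (sp$r2 - 2), 2, ctr, "+"),
                         ico$triangles)
  ref <- deform_to_edges(start, ph$intensity,
                         profile_params(expected_sign = -1),
                         deformation_params())
  rr <- radial_distance(ref, ctr)
  expect_lt(mean(abs(rr - sp$r2)), 0.25)
  expect_identical(ref$triangles, start$triangles)
  expect_equal(euler_characteristic(ref), 2L)
})

test_that("refinement still converges under 10% contrast noise", {
  ph <- make_shell_phantom(phantom_spec("shell", r1 = 20, r2 = 25,
                                        csf_thickness = 8, noise_sd = 4,
                                        seed = 21))
  sp <- ph$truth$spec
  ctr <- sp$dim * sp$spacing / 2
  ico <- icosphere(3)
  start <- triangle_mesh(sweep(ico$vertices * (sp$r2 - 2), 2, ctr, "+"),
                         ico$triangles)
  ref <- deform_to_edges(start, ph$intensity,
                         profile_params(expected_sign = -1),
                         deformation_params())
  rr <- radial_distance(ref, ctr)
  expect_lt(mean(abs(rr - sp$r2)), 0.25)
})

test_that("the same machinery fits both contrast polarities", {
  for (preset in c("neonatal", "adult")) {
    ph <- make_shell_phantom(phantom_spec("shell", r1 = 14, r2 = 16,
                                          tissue_means = tissue_preset(preset),
                                          noise_sd = 0, supersample = 2))
    sp <- ph$truth$spec
    ctr <- sp$dim * sp$spacing / 2
    ico <- icosphere(3)
    start <- triangle_mesh(sweep(ico$vertices * (sp$r1 - 1.5), 2, ctr, "+"),
                           ico$triangles)
    # fit the WM/GM interface with sign auto
    ref <- deform_to_edges(start, ph$intensity,
                           profile_params(expected_sign = "auto"),
                           deformation_params(resolution_schedule =
                                                list(c(3, 0.5),
                                                     c(1.5, 0.25))))
    rr <- radial_distance(ref, ctr)
    expect_lt(abs(mean(rr) - sp$r1), 0.4, label = preset)
  }
})
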