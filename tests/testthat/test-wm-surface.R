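test_that("extraction from a digital ball gives a tight genus-zero mesh", {
  ball <- digital_ball(10)
  mesh <- extract_wm_mesh(ball)
  expect_equal(euler_characteristic(mesh), 2L)
  expect_true(is_closed_manifold(mesh))
  vox_vol <- sum(ball$data) * 1
  expect_lt(abs(mesh_volume(mesh) - vox_vol) / vox_vol, 0.05)
  ctr <- (dim(ball$data) - 1) / 2
  expect_lt(mean(abs(radial_distance(mesh, ctr) - 10)), 0.5)
})

test_that("handles and cavities are corrected to spherical topology", {
  torus <- digital_torus()
  mesh <- extract_wm_mesh(torus)
  expect_equal(euler_characteristic(mesh), 2L)
  # ball with an interior cavity
  holed <- digital_ball(9, dim = rep(26L, 3))
  cav <- digital_ball(3, dim = rep(26L, 3))
  holed$data[cav$data == 1L] <- 0L
  mesh2 <- extract_wm_mesh(holed)
  expect_equal(euler_characteristic(mesh2), 2L)
  # volume encloses the cavity (it is filled, not meshed)
  expect_gt(mesh_volume(mesh2), sum(holed$data))
})

test_that("only the largest connected component is meshed", {
  dm <- rep(40L, 3)
  m <- digital_ball(8, dim = dm, center = c(12, 20, 20))$data +
    digital_ball(4, dim = dm, center = c(30, 20, 20))$data
  mesh <- extract_wm_mesh(voxel_grid(m, diag(4)))
  # all vertices near the larger ball
  d_large <- sqrt(rowSums(sweep(mesh$vertices, 2, c(12, 20, 20))^2))
  expect_lt(max(d_large), 12)
})

test_that("edge-collapse coarsening preserves topology and volume", {
  mesh <- extract_wm_mesh(digital_ball(10))
  v0 <- mesh_volume(mesh)
  cm <- coarsen_mesh(mesh, 642)
  expect_lte(nrow(cm$vertices), 642)
  expect_equal(euler_characteristic(cm), 2L)
  expect_true(is_closed_manifold(cm))
  expect_lt(abs(mesh_volume(cm) - v0) / v0, 0.1)
  expect_identical(coarsen_mesh(cm, nrow(cm$vertices)), cm)
})

test_that("inflation maps genus-zero meshes to the sphere without flips", {
  # an already-spherical mesh converges immediately
  ico <- icosphere(3)
  sm0 <- inflate_to_sphere(ico)
  expect_lte(sm0$iterations, 2L)
  expect_equal(sm0$flipped, 0L)
  expect_lt(max(abs(sqrt(rowSums(sm0$sphere$vertices^2)) - 1)), 1e-6)
  # a real folded mesh
  ph <- slab_phantom_invisible()
  wm <- voxel_grid(array(as.integer(ph$labels$data == 3L),
                         dim(ph$labels$data)), ph$labels$affine)
  mesh <- coarsen_mesh(extract_wm_mesh(wm), 3000)
  sm <- inflate_to_sphere(mesh)
  expect_equal(sm$flipped, 0L)
  expect_lt(max(abs(sqrt(rowSums(sm$sphere$vertices^2)) - 1)), 1e-6)
  expect_error(inflate_to_sphere(triangle_mesh(ico$vertices,
                                               ico$triangles[-1, ])),
               "genus-zero")
})

test_that("icosahedral resampling has the exact triangle counts", {
  ico0 <- icosphere(0)
  expect_equal(nrow(ico0$triangles), 20L)
  expect_equal(nrow(ico0$vertices), 12L)
  lvl <- 3
  ico <- icosphere(lvl)
  expect_equal(nrow(ico$triangles), 20L * 4^lvl)
  expect_equal(nrow(ico$vertices), 10L * 4^lvl + 2L)
  expect_equal(euler_characteristic(ico), 2L)
})

test_that("resampling a perfect sphere mesh reproduces its radius everywhere", {
  base <- icosphere(3)
  mesh <- triangle_mesh(base$vertices * 12, base$triangles)
  sm <- inflate_to_sphere(mesh)
  rs <- icosahedron_resample(mesh, sm, 4)
  expect_equal(nrow(rs$triangles), 20L * 4^4)
  rr <- sqrt(rowSums(rs$vertices^2))
  expect_lt(max(abs(rr - 12)) / 12, 0.01)
})

test_that("resampled meshes share connectivity across phantoms", {
  m1 <- coarsen_mesh(extract_wm_mesh(digital_ball(8, dim = rep(26L, 3))), 800)
  m2 <- coarsen_mesh(extract_wm_mesh(digital_torus()), 800)
  r1 <- icosahedron_resample(m1, inflate_to_sphere(m1), 3)
  r2 <- icosahedron_resample(m2, inflate_to_sphere(m2), 3)
  expect_identical(r1$triangles, r2$triangles)
})

test_that("self-proximity enforcement separates near-contact sheets", {
  # convex mesh: unchanged
  ico <- icosphere(2)
  big <- triangle_mesh(ico$vertices * 10, ico$triangles)
  out <- enforce_self_proximity(big, 0.25)
  expect_lt(max(abs(out$vertices - big$vertices)), 1e-9)
  # two spheres 0.1 mm apart in one mesh
  s1 <- icosphere(2)
  v1 <- s1$vertices * 5
  v2 <- s1$vertices * 5
  v2[, 1] <- v2[, 1] + 10.1
  both <- triangle_mesh(rbind(v1, v2),
                        rbind(s1$triangles,
                              s1$triangles + nrow(v1)))
  pr0 <- neosurf:::vertex_proximity_cpp(both$vertices, both$triangles, 3L, 1)
  expect_lt(min(pr0$distance), 0.25)
  fixed <- enforce_self_proximity(both, 0.25)
  pr1 <- neosurf:::vertex_proximity_cpp(fixed$vertices, fixed$triangles,
                                        3L, 1)
  expect_gte(min(pr1$distance), 0.25 - 1e-6)
  expect_equal(count_self_intersections(fixed), 0L)
})
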