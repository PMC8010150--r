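test_that("topological numbers match the flood-fill oracle on random configs", {
  cfgs <- random_configs(2000, seed = 42)
  impl <- neosurf:::simple_point_config(cfgs)
  for (i in seq_len(nrow(cfgs))) {
    expect_identical(impl[i], unname(oracle_simple_point(cfgs[i, ])),
                     label = paste("config", i))
  }
  # also compare the full (Cstar, Cbar) pairs on a subset
  for (i in seq_len(200)) {
    tn_impl <- neosurf:::topo_numbers_config(cfgs[i, ])
    tn_or <- oracle_topo_numbers(cfgs[i, ])
    expect_equal(unname(tn_impl), unname(tn_or), label = paste("config", i))
  }
})

test_that("topological numbers match the oracle on all sparse configurations", {
  # every configuration with at most 2 object neighbours, plus a sampled set
  # with 3 (exhaustive small-object coverage of the classification)
  idx <- setdiff(1:27, 14)
  cfg0 <- matrix(FALSE, 1, 27); cfg0[14] <- TRUE
  cfgs <- cfg0
  for (i in idx) {
    c1 <- cfg0; c1[1, i] <- TRUE
    cfgs <- rbind(cfgs, c1)
  }
  pairs <- utils::combn(idx, 2)
  for (k in seq_len(ncol(pairs))) {
    c2 <- cfg0; c2[1, pairs[, k]] <- TRUE
    cfgs <- rbind(cfgs, c2)
  }
  set.seed(9)
  triples <- replicate(400, sample(idx, 3))
  for (k in seq_len(ncol(triples))) {
    c3 <- cfg0; c3[1, triples[, k]] <- TRUE
    cfgs <- rbind(cfgs, c3)
  }
  impl <- neosurf:::simple_point_config(cfgs)
  orac <- apply(cfgs, 1, oracle_simple_point)
  expect_identical(unname(impl), unname(orac))
})

test_that("voxel classification recovers the nine canonical categories", {
  # isolated: empty 26-neighbourhood
  obj <- array(0L, c(5, 5, 5)); obj[3, 3, 3] <- 1L
  expect_equal(as.vector(classify_topology(cbind(2, 2, 2), obj)), "isolated")
  # interior of a solid block
  blk <- array(1L, c(5, 5, 5))
  expect_equal(as.vector(classify_topology(cbind(2, 2, 2), blk)), "interior")
  # center of a one-voxel-thick plate
  plate <- digital_sheet(dim = rep(7L, 3), x0 = 4L, yr = 2:6, zr = 2:6)
  expect_equal(as.vector(classify_topology(cbind(3, 3, 3), plate)), "surface")
  # interior point of a digital line
  line <- array(0L, c(7, 7, 7)); line[2:6, 4, 4] <- 1L
  expect_equal(as.vector(classify_topology(cbind(3, 3, 3), line)), "curve")
  # line endpoint is a border voxel
  expect_equal(as.vector(classify_topology(cbind(1, 3, 3), line)), "border")
  # classification agrees with the oracle-mapped classes on random configs
  cfgs <- random_configs(300, seed = 7)
  for (i in seq_len(300)) {
    arr <- array(as.integer(cfgs[i, ]), c(3, 3, 3))
    code <- classify_topology(cbind(1, 1, 1), arr)
    tn <- oracle_topo_numbers(cfgs[i, ])
    expected <- if (tn[2] == 0) "interior"
    else if (tn[1] == 0) "isolated"
    else if (tn[2] == 1) c("border", "curve", "curves")[min(tn[1], 3)]
    else if (tn[2] == 2) { if (tn[1] == 1) "surface" else "surface-curve" }
    else { if (tn[1] == 1) "surfaces" else "surfaces-curve" }
    expect_equal(as.vector(code), expected, label = paste("config", i))
  }
})

test_that("cubical-complex Euler characteristic is exact on canonical solids", {
  ball <- digital_ball(6)$data
  expect_equal(euler_voxel_complex(ball), 1L)        # solid ball
  torus <- digital_torus()$data
  expect_equal(euler_voxel_complex(torus), 0L)       # solid torus
  hollow <- digital_ball(9, dim = rep(24L, 3))$data -
    digital_ball(4, dim = rep(24L, 3))$data
  expect_equal(euler_voxel_complex(hollow), 2L)      # spherical shell
  expect_equal(count_components(ball), 1L)
  two <- ball
  two[1:2, 1:2, 1:2] <- 1L
  expect_equal(count_components(two), 2L)
})

test_that("well-composed repair removes critical pinches topology-safely", {
  # two diagonal voxels in a 2x2 square: the canonical pinch
  m <- array(0L, c(6, 6, 6))
  m[2:3, 2:3, 2:4] <- 1L
  m[4, 4, 2:4] <- 1L  # diagonal contact with the block along an edge
  chi0 <- euler_voxel_complex(m)
  comp0 <- count_components(m)
  wc <- array(neosurf:::well_compose_cpp(as.integer(m), dim(m)), dim(m))
  expect_true(all(wc[m == 1L] == 1L))  # only additions
  expect_equal(count_components(wc), comp0)
  expect_equal(euler_voxel_complex(wc), chi0)
  bm <- neosurf:::boundary_mesh_cpp(as.integer(wc), dim(m))
  mesh <- triangle_mesh(bm$vertices, bm$triangles)
  expect_true(is_closed_manifold(mesh))
})
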