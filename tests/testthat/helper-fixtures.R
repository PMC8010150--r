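# shared fixtures, built in code and memoized per test run

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# digital ball mask of radius r (voxels) in a cube grid
digital_ball <- function(r, dim = NULL, center = NULL, spacing = 1) {
  if (is.null(dim)) dim <- rep(ceiling(2 * r + 9), 3)
  if (is.null(center)) center <- (dim - 1) * spacing / 2
  co <- neosurf:::grid_coords(dim, spacing)
  m <- array(as.integer((co$X - center[1])^2 + (co$Y - center[2])^2 +
                          (co$Z - center[3])^2 <= r^2), dim)
  voxel_grid(m, diag(c(rep(spacing, 3), 1)))
}

# solid torus mask: tube radius a around a circle of radius R in the xy-plane
digital_torus <- function(R = 8, a = 3, dim = rep(30L, 3)) {
  co <- neosurf:::grid_coords(dim, 1)
  c0 <- (dim - 1) / 2
  q <- (sqrt((co$X - c0[1])^2 + (co$Y - c0[2])^2) - R)^2 + (co$Z - c0[3])^2
  voxel_grid(array(as.integer(q <= a^2), dim), diag(4))
}

# one-voxel-thick rectangular sheet in the x = x0 plane
digital_sheet <- function(dim = rep(16L, 3), x0 = 8L,
                          yr = 4:12, zr = 4:12) {
  m <- array(0L, dim)
  m[x0, yr, zr] <- 1L
  m
}

# standard small phantoms used across files
shell_phantom_small <- function() fixture("shell_small", function()
  make_shell_phantom(phantom_spec("shell", r1 = 20, r2 = 22, spacing = 1,
                                  noise_sd = 0)))

slab_phantom_invisible <- function() fixture("slab_invisible", function()
  make_folded_phantom(phantom_spec("folded_slab", r1 = 20, r2 = 22,
                                   sulcal_gap = 0.4, fold_amplitude = 10,
                                   fold_wavelength = 16, dim = 64,
                                   noise_sd = 0)))

# analytic meshes on the shell phantom's true surfaces
shell_truth_meshes <- function(level = 3) {
  ph <- shell_phantom_small()
  sp <- ph$truth$spec
  ctr <- sp$dim * sp$spacing / 2
  ico <- icosphere(level)
  list(wm = triangle_mesh(sweep(ico$vertices * sp$r1, 2, ctr, "+"),
                          ico$triangles),
       pial = triangle_mesh(sweep(ico$vertices * sp$r2, 2, ctr, "+"),
                            ico$triangles),
       center = ctr, r1 = sp$r1, r2 = sp$r2)
}

radial_distance <- function(mesh, center) {
  sqrt(rowSums(sweep(mesh$vertices, 2, center)^2))
}
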