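# Brute-force digital-topology oracle on 3x3x3 configurations.
# Independent of the package's C++ implementation: plain flood fills over
# precomputed adjacency lists.

.topo_coords <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
center <- which(rowSums(abs(.topo_coords)) == 0)
n18 <- which(rowSums(abs(.topo_coords)) >= 1 & rowSums(abs(.topo_coords)) <= 2)
face_nb <- which(rowSums(abs(.topo_coords)) == 1)
.adj26 <- lapply(1:27, function(i)
  which(vapply(1:27, function(j)
    j != i && max(abs(.topo_coords[i, ] - .topo_coords[j, ])) == 1,
    logical(1))))
.adj6_n18 <- lapply(1:27, function(i)
  intersect(which(vapply(1:27, function(j)
    j != i && sum(abs(.topo_coords[i, ] - .topo_coords[j, ])) == 1,
    logical(1))), n18))

flood_count <- function(members, adj, must_touch = NULL) {
  # members: logical(27); count connected components (optionally only those
  # containing a must_touch cell)
  seen <- logical(27)
  is_touch <- logical(27)
  if (!is.null(must_touch)) is_touch[must_touch] <- TRUE
  count <- 0
  for (s in which(members)) {
    if (seen[s]) next
    stack <- s
    seen[s] <- TRUE
    touch <- FALSE
    while (length(stack) > 0) {
      c0 <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (is_touch[c0]) touch <- TRUE
      for (nb in adj[[c0]]) {
        if (members[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
    if (is.null(must_touch) || touch) count <- count + 1
  }
  count
}

oracle_topo_numbers <- function(cfg27) {
  # cfg27: logical length 27 (3x3x3 array, column-major); center ignored
  obj <- cfg27
  obj[center] <- FALSE
  cstar <- flood_count(obj, .adj26)
  bg18 <- logical(27)
  bg18[n18] <- !cfg27[n18]
  cbar <- flood_count(bg18, .adj6_n18, must_touch = face_nb)
  c(cstar = cstar, cbar = cbar)
}

oracle_simple_point <- function(cfg27) {
  tn <- oracle_topo_numbers(cfg27)
  tn[1] == 1 && tn[2] == 1
}

random_configs <- function(n, seed, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- stats::runif(n, 0.15, 0.85)
  m <- matrix(FALSE, n, 27)
  for (i in seq_len(n)) m[i, ] <- stats::runif(27) < p[i]
  m[, 14] <- TRUE  # center occupied: configurations of an object voxel
  m
}
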