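single_atom_ligand <- function() {
  read_ligand(paste(
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C",
    "ENDROOT", sep = "\n"))
}

# hand-built lattice holding an arbitrary field (only the slots the
# interpolator reads)
field_cache <- function(f, origin = c(-2, -2, -2), spacing = 0.5,
                        dims = c(9L, 9L, 9L)) {
  gx <- origin[1] + (seq_len(dims[1]) - 1) * spacing
  gy <- origin[2] + (seq_len(dims[2]) - 1) * spacing
  gz <- origin[3] + (seq_len(dims[3]) - 1) * spacing
  arr <- array(0, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) arr[i, j, k] <- f(gx[i], gy[j], gz[k])
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 types = "C", values = list(C = arr),
                 stack = as.numeric(arr),
                 offsets = c(C = 0), cutoff = 8),
            class = "grid_cache")
}

test_that("pair potential is zero beyond the cutoff and continuous at it", {
  expect_equal(pair_potential("C", "C", 8.0001), 0)
  expect_equal(pair_potential("OA", "N", 9), 0)
  # continuity: approach the cutoff from below
  below <- pair_potential("C", "C", 8 - 1e-7)
  expect_lt(abs(below - 0), 1e-6)
  for (pair in list(c("C", "OA"), c("N", "OA"), c("A", "Cl"))) {
    below <- pair_potential(pair[1], pair[2], 8 - 1e-7)
    expect_lt(abs(below), 1e-6)
  }
  expect_error(pair_potential("C", "Xx", 3), "unknown AutoDock atom type")
  expect_error(pair_potential("C", "C", -1), "non-negative")
})

test_that("C-C contact value equals the hand-summed weighted terms", {
  # surface distance 0 at center distance 3.8 (two 1.9 A radii); terms
  # summed independently from the published constants, including the
  # cutoff shift at d_cut = 8 - 3.8 = 4.2
  raw <- function(d) {
    -0.035579 * exp(-(d / 0.5)^2) +
      -0.005156 * exp(-((d - 3) / 2)^2) +
      0.840245 * (if (d < 0) d^2 else 0) +
      -0.035069 * min(1, max(0, (1.5 - d) / 1)) # both carbons hydrophobic
  }
  expect_equal(pair_potential("C", "C", 3.8), raw(0) - raw(4.2),
               tolerance = 1e-12)
  # and a clashing distance with repulsion active
  expect_equal(pair_potential("C", "C", 3.3), raw(-0.5) - raw(4.2),
               tolerance = 1e-12)
  # donor-acceptor pair picks up the h-bond term at d = -0.35
  rawhb <- function(d) {
    -0.035579 * exp(-(d / 0.5)^2) +
      -0.005156 * exp(-((d - 3) / 2)^2) +
      0.840245 * (if (d < 0) d^2 else 0) +
      -0.587439 * min(1, max(0, -d / 0.7))
  }
  r <- 1.8 + 1.7 - 0.35
  expect_equal(pair_potential("N", "OA", r), rawhb(-0.35) - rawhb(8 - 3.5),
               tolerance = 1e-12)
})

test_that("grid cache stores receptor sums at the lattice nodes", {
  box <- docking_box(c(0, 0, 0), c(6, 6, 6))
  # receptor far outside interaction range -> all-zero lattice
  far <- read_receptor(paste(
    "HETATM    1  C1  POC A   1     100.000 100.000 100.000  1.00  0.00     0.000 C",
    sep = "\n"))
  empty <- build_grid_cache(far, box, "C")
  expect_true(all(empty$values$C == 0))

  # single receptor atom: the stored node value equals the direct pair
  # potential at the node's distance
  one <- read_receptor(
    "HETATM    1  O1  POC A   1       0.500   0.250   0.000  1.00  0.00     0.000 OA")
  cache <- build_grid_cache(one, box, c("C", "N"))
  node <- cache$origin + c(5, 7, 9) * cache$spacing
  r <- sqrt(sum((node - c(0.5, 0.25, 0))^2))
  expect_equal(interp_energy(cache, "C", node), pair_potential("C", "OA", r),
               tolerance = 1e-9)
  expect_equal(interp_energy(cache, "N", node), pair_potential("N", "OA", r),
               tolerance = 1e-9)

  # halving the spacing leaves values at coincident nodes identical
  coarse <- build_grid_cache(one, box, "C", spacing = 0.75)
  fine <- build_grid_cache(one, box, "C", spacing = 0.375)
  for (a in c(1, 3, 5)) {
    pt <- coarse$origin + c(a, a + 1, a) * 0.75
    expect_equal(interp_energy(coarse, "C", pt),
                 interp_energy(fine, "C", pt), tolerance = 1e-9)
  }

  expect_error(build_grid_cache(one, docking_box(c(0, 0, 0), c(500, 500, 500)),
                                "C", max_nodes = 1e6), "memory guard")
  expect_error(interp_energy(cache, "Zz", c(0, 0, 0)), "not tabulated")
})

test_that("trilinear interpolation is exact on nodes, trilinear fields and constants", {
  lin <- field_cache(function(x, y, z) 2 * x + 3 * y + 4 * z)
  # node identity
  for (idx in list(c(0, 0, 0), c(3, 5, 2), c(8, 8, 8))) {
    pt <- lin$origin + idx * lin$spacing
    expect_equal(interp_energy(lin, "C", pt),
                 2 * pt[1] + 3 * pt[2] + 4 * pt[3], tolerance = 1e-10)
  }
  # interior points: a trilinear function is reproduced exactly
  set.seed(5)
  pts <- matrix(runif(60, -1.9, 1.9), 20, 3)
  expect_lt(max(abs(interp_energy(lin, "C", pts) -
                    (2 * pts[, 1] + 3 * pts[, 2] + 4 * pts[, 3]))), 1e-10)
  # a constant field interpolates to the constant at cell centers
  const <- field_cache(function(x, y, z) 7.25)
  expect_equal(interp_energy(const, "C", c(0.25, 0.25, 0.25)), 7.25,
               tolerance = 1e-12)
  # outside the hull: clamped value plus the quadratic distance penalty
  edge <- lin$origin + (lin$dims - 1) * lin$spacing
  out_pt <- edge + c(1, 0, 0)
  expect_equal(interp_energy(lin, "C", out_pt),
               2 * edge[1] + 3 * edge[2] + 4 * edge[3] + 1^2,
               tolerance = 1e-9)
})

test_that("score decomposes exactly and matches the grid-free oracle", {
  cx <- get_fixture()
  flat <- cx$flat; cache <- cx$cache
  ctx <- receptor_context(flat, cx$receptor)
  set.seed(31)
  for (k in 1:20) {
    # poses around the pocket, where all atoms stay on the lattice and out
    # of the unresolvable repulsive core: there the grid approximates the
    # direct sum within the trilinear error at 0.375 A spacing
    cf <- cx$planted_pose
    cf$position <- cf$position + stats::runif(3, -1, 1)
    cf$quaternion <- cf$quaternion + stats::rnorm(4, 0, 0.1)
    cf$quaternion <- cf$quaternion / sqrt(sum(cf$quaternion^2))
    cf$torsions <- cf$torsions + stats::runif(flat$nrot, -0.4, 0.4)
    sp <- score_pose(flat, cf, cache)
    expect_identical(sp$e, sp$einter + sp$eintra)
    sd <- score_direct(flat, cf, ctx)
    # eintra is grid-independent, identical on both paths
    expect_identical(sp$eintra, sd$eintra)
    expect_lt(abs(sp$einter - sd$einter), 0.5)
  }
  # arbitrary random poses still decompose exactly; atoms pushed off the
  # lattice hull are charged the quadratic distance penalty on the grid
  # path only
  far <- cx$planted_pose
  far$position <- far$position + cx$box$size / 2 + 2
  expect_gt(score_pose(flat, far, cache)$einter,
            score_direct(flat, far, ctx)$einter)
})

test_that("a rigid single-atom ligand has no intramolecular energy", {
  lig <- single_atom_ligand()
  flat <- flatten_tree(lig)
  expect_length(flat$pairs$i, 0)
  box <- docking_box(c(0, 0, 0), c(7.5, 7.5, 7.5))
  one <- read_receptor(
    "HETATM    1  C1  POC A   1       0.000   0.000   0.000  1.00  0.00     0.000 C")
  cache <- build_grid_cache(one, box, "C")
  cf <- conformation(c(1.9, 0.3, 0))
  sp <- score_pose(flat, cf, cache)
  expect_equal(sp$eintra, 0)
  expect_identical(sp$e, sp$einter)

  # mirror-symmetric receptor: mirrored poses score equal
  cf2 <- conformation(c(-1.9, 0.3, 0))
  expect_lt(abs(score_pose(flat, cf2, cache)$e - sp$e), 1e-6)
})

test_that("the analytic gradient matches central finite differences", {
  cx <- get_fixture()
  flat <- cx$flat; cache <- cx$cache
  ctx <- receptor_context(flat, cx$receptor)
  set.seed(77)
  h <- 1e-5
  worst <- 0
  for (k in 1:25) {
    repeat {   # redraw states where the FD stencil is not differentiable
      cf <- random_conformation(cx$box, flat$nrot)
      if (fd_probe_ok(flat, cache, ctx, cf)) break
    }
    x <- c(cf$position, cf$quaternion, cf$torsions)
    fn <- function(v)
      score_pose(flat, conformation(v[1:3], v[4:7], v[8:9]), cache)$e
    g <- score_gradient(flat, cf, cache)
    gfd <- vapply(seq_along(x), function(j) {
      e1 <- x; e1[j] <- e1[j] + h
      e2 <- x; e2[j] <- e2[j] - h
      (fn(e1) - fn(e2)) / (2 * h)
    }, numeric(1))
    worst <- max(worst, max(abs(g - gfd) / pmax(abs(gfd), 1e-2)))
  }
  expect_lt(worst, 1e-4)
})

test_that("a uniform field exerts no positional force", {
  lig <- single_atom_ligand()
  flat <- flatten_tree(lig)
  const <- field_cache(function(x, y, z) 3)
  g <- score_gradient(flat, conformation(c(0.3, -0.2, 0.4)), const)
  expect_equal(g[1:3], c(0, 0, 0), tolerance = 1e-12)
})

test_that("scoring is bitwise-stable under re-parsing the same ligand", {
  cx <- get_fixture()
  flat2 <- flatten_tree(read_ligand(cx$ligand_text))
  cf <- conformation(cx$box$center + 0.5, c(0.8, 0.1, -0.5, 0.3),
                     c(0.7, -1.1))
  expect_identical(score_pose(cx$flat, cf, cx$cache)$e,
                   score_pose(flat2, cf, cx$cache)$e)
})
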