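test_that("flattening reproduces the worked children-map example", {
  # topology: root with two child branches, the first branch having its own
  # two children -> node 1 children {2, 5}, node 2 children {3, 4}
  flat <- flatten_tree(read_ligand(example_tree_text()))
  expect_equal(which(flat$children_map[1, ]), c(2L, 5L))
  expect_equal(which(flat$children_map[2, ]), c(3L, 4L))
  expect_false(any(flat$children_map[3, ]))
  # topological order: parent index < child index for every edge
  edges <- which(flat$children_map, arr.ind = TRUE)
  expect_true(all(edges[, 1] < edges[, 2]))
  # each non-root node has exactly one parent
  expect_equal(unname(colSums(flat$children_map)),
               c(0, rep(1, nrow(flat$children_map) - 1)))
})

test_that("flattening degenerate and linear-chain topologies", {
  rigid <- flatten_tree(read_ligand(paste(
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C",
    "ATOM      2  C2  LIG A   1       1.500   0.000   0.000  1.00  0.00     0.000 C",
    "ENDROOT", sep = "\n")))
  expect_length(rigid$nodes, 1)
  expect_false(any(rigid$children_map))

  chain <- flatten_tree(read_ligand(paste(
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C",
    "ATOM      2  C2  LIG A   1       1.500   0.000   0.000  1.00  0.00     0.000 C",
    "ENDROOT",
    "BRANCH 2 3",
    "ATOM      3  C3  LIG A   1       3.000   0.000   0.000  1.00  0.00     0.000 C",
    "BRANCH 3 4",
    "ATOM      4  C4  LIG A   1       4.500   0.000   0.000  1.00  0.00     0.000 C",
    "ENDBRANCH 3 4",
    "ENDBRANCH 2 3", sep = "\n")))
  # true entries exactly {(1,2), (2,3)}
  edges <- which(chain$children_map, arr.ind = TRUE)
  expect_equal(edges[order(edges[, 1]), , drop = FALSE],
               cbind(row = c(1L, 2L), col = c(2L, 3L)), ignore_attr = TRUE)
})

test_that("identity and pure-translation conformations reproduce reference coordinates", {
  flat <- flatten_tree(read_ligand(example_tree_text()))
  ident <- conformation(flat$root_centroid, c(1, 0, 0, 0), rep(0, flat$nrot))
  expect_equal(apply_conformation(flat, ident), flat$xyz, tolerance = 1e-12)

  shifted <- conformation(flat$root_centroid + c(1, 2, 3), c(1, 0, 0, 0),
                          rep(0, flat$nrot))
  expect_equal(apply_conformation(flat, shifted),
               flat$xyz + rep(c(1, 2, 3), each = flat$natom),
               tolerance = 1e-12)
})

test_that("a half-turn torsion rotates exactly the branch atoms as hand-computed", {
  flat <- flatten_tree(read_ligand(example_tree_text()))
  tor <- rep(0, flat$nrot)
  tor[4] <- pi    # terminal branch: atom 7, axis atom3 (0,1.5,0) -> atom7 (0,3,0)
  cf <- conformation(flat$root_centroid, c(1, 0, 0, 0), tor)
  out <- apply_conformation(flat, cf)
  # axis is +y through (0, 1.5, 0): a pi rotation maps (x, y, z) to
  # (-x, y, -z); atom 7 sits on the axis, so nothing moves there and all
  # other atoms are untouched
  expect_equal(out, flat$xyz, tolerance = 1e-9)

  tor2 <- rep(0, flat$nrot)
  tor2[1] <- pi   # axis atom2 (1.5,0,0) -> atom4 (3,0,0): +x through y=z=0
  cf2 <- conformation(flat$root_centroid, c(1, 0, 0, 0), tor2)
  out2 <- apply_conformation(flat, cf2)
  moved <- flat$nodes[[2]]$subtree    # atoms 4, 5, 6
  hand <- flat$xyz
  hand[moved, 2] <- -hand[moved, 2]
  hand[moved, 3] <- -hand[moved, 3]
  expect_equal(out2, hand, tolerance = 1e-9)
})

test_that("flattened iterative kinematics equals the recursive-tree oracle", {
  for (case in 1:50) {
    n_nodes <- 1 + (case %% 8)
    tree <- read_ligand(random_ligand_text(n_nodes, seed = 1000 + case))
    flat <- flatten_tree(tree)
    set.seed(2000 + case)
    cf <- conformation(stats::rnorm(3, sd = 3), stats::rnorm(4),
                       stats::runif(flat$nrot, -pi, pi))
    expect_lt(max(abs(apply_conformation(flat, cf) - oracle_apply(tree, cf))),
              1e-12)
  }
})

test_that("random conformations are uniform in the box with unit quaternions", {
  box <- docking_box(c(5, -3, 10), c(8, 10, 12))
  set.seed(99)
  draws <- replicate(10000, {
    cf <- random_conformation(box, 3)
    c(cf$position, abs(sum(cf$quaternion^2) - 1), cf$torsions)
  })
  pos <- t(draws[1:3, ])
  # mean within 3 sigma of the box center per axis (uniform: sd = L/sqrt(12))
  for (ax in 1:3) {
    se <- box$size[ax] / sqrt(12) / sqrt(10000)
    expect_lt(abs(mean(pos[, ax]) - box$center[ax]), 3 * se)
    expect_true(all(pos[, ax] >= box$center[ax] - box$size[ax] / 2))
    expect_true(all(pos[, ax] <= box$center[ax] + box$size[ax] / 2))
  }
  expect_lt(max(draws[4, ]), 1e-9)
  expect_true(all(abs(draws[5:7, ]) <= pi))

  set.seed(123); a <- random_conformation(box, 2)
  set.seed(123); b <- random_conformation(box, 2)
  expect_identical(a, b)
  expect_length(random_conformation(box, 0)$torsions, 0)
})

test_that("mutation changes exactly one POT block, uniformly", {
  box <- docking_box(c(0, 0, 0), c(10, 10, 10))
  mp <- mutation_params(2)
  cf <- conformation(c(1, 1, 1), c(1, 0, 0, 0), c(0.5, -0.5))
  set.seed(42)
  counts <- c(pos = 0, ori = 0, tor = 0)
  for (k in 1:3000) {
    mut <- mutate_conformation(cf, mp, box)
    changed <- c(pos = !identical(mut$position, cf$position),
                 ori = !identical(mut$quaternion, cf$quaternion),
                 tor = !identical(mut$torsions, cf$torsions))
    expect_equal(sum(changed), 1)
    counts <- counts + changed
    expect_lt(abs(sum(mut$quaternion^2) - 1), 1e-9)
    expect_true(all(abs(mut$position) <= 5))
  }
  # block selection uniform within 3 binomial sigma
  se <- sqrt(1 / 3 * 2 / 3 * 3000)
  expect_true(all(abs(counts - 1000) < 3 * se))

  # rigid ligand: torsion block never picked
  rigid <- conformation(c(0, 0, 0), c(1, 0, 0, 0))
  set.seed(1)
  for (k in 1:200)
    expect_length(mutate_conformation(rigid, mp, box)$torsions, 0)
})

test_that("quaternion norm survives long mutation chains", {
  box <- docking_box(c(0, 0, 0), c(10, 10, 10))
  mp <- mutation_params()
  cf <- conformation(c(0, 0, 0), c(0.5, 0.5, 0.5, 0.5), c(0, 0, 0))
  set.seed(7)
  for (k in 1:500) cf <- mutate_conformation(cf, mp, box)
  expect_lt(abs(sqrt(sum(cf$quaternion^2)) - 1), 1e-9)
})

test_that("rmsd matches hand arithmetic and behaves like a metric", {
  a <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, a + rep(c(2, 0, 0), each = 2)), 2)
  b <- a; b[2, ] <- b[2, ] + c(0, 2, 0)   # displacements 0 and 2
  expect_equal(rmsd(a, b), sqrt(2), tolerance = 1e-12)
  expect_error(rmsd(a, matrix(0, 3, 3)), "equal atom counts")

  set.seed(11)
  for (k in 1:25) {
    x <- matrix(rnorm(15), 5, 3); y <- matrix(rnorm(15), 5, 3)
    z <- matrix(rnorm(15), 5, 3)
    expect_equal(rmsd(x, y), rmsd(y, x))
    expect_lte(rmsd(x, z), rmsd(x, y) + rmsd(y, z) + 1e-12)
    expect_gt(rmsd(x, y), 0)
  }
})
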