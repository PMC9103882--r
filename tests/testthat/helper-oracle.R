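# Independent reference implementations used as oracles.  These deliberately
# share no code with the package: recursion over the parsed tree, Rodrigues
# rotation matrices and the quaternion sandwich product.

# recursive-tree forward kinematics (reference for the flattened iterative
# version)
oracle_apply <- function(tree, conf) {
  atoms <- tree$atoms
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(pos) <- as.character(atoms$serial)

  rot3 <- function(u, th) {
    u <- u / sqrt(sum(u^2))
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  collect_serials <- function(node)
    c(node$atoms$serial, unlist(lapply(node$children, collect_serials)))

  counter <- 0L
  walk <- function(node) {
    counter <<- counter + 1L
    th <- conf$torsions[counter]
    sub <- as.character(collect_serials(node))
    a <- as.character(node$parent_serial)
    b <- as.character(node$child_serial)
    R <- rot3(pos[b, ] - pos[a, ], th)
    origin <- pos[a, ]
    pos[sub, ] <<- t(R %*% (t(pos[sub, , drop = FALSE]) - origin) + origin)
    for (ch in node$children) walk(ch)
  }
  for (b in tree$branches) walk(b)

  q <- conf$quaternion / sqrt(sum(conf$quaternion^2))
  qmul <- function(p, r)
    c(p[1] * r[1] - sum(p[2:4] * r[2:4]),
      p[1] * r[2:4] + r[1] * p[2:4] +
        c(p[3] * r[4] - p[4] * r[3],
          p[4] * r[2] - p[2] * r[4],
          p[2] * r[3] - p[3] * r[2]))
  rotq <- function(v) qmul(qmul(q, c(0, v)), c(q[1], -q[2:4]))[2:4]

  c0 <- colMeans(pos[as.character(tree$root_atoms$serial), , drop = FALSE])
  out <- t(apply(pos, 1, function(v) rotq(v - c0) + conf$position))
  dimnames(out) <- NULL
  out
}

# random torsion-tree ligand as PDBQT text: random topology (<= n_nodes
# nodes), random coordinates, all carbons
random_ligand_text <- function(n_nodes, seed) {
  set.seed(seed)
  parents <- if (n_nodes > 1)
    c(NA, vapply(2:n_nodes, function(i) sample.int(i - 1L, 1), integer(1)))
  else NA
  sizes <- sample(1:3, n_nodes, replace = TRUE)
  sizes[1] <- max(2L, sizes[1])
  node_serials <- vector("list", n_nodes)
  serial <- 0L

  atom_lines <- function(node_id) {
    k <- sizes[node_id]
    first <- serial + 1L
    node_serials[[node_id]] <<- first:(serial + k)
    lines <- vapply(1:k, function(m) {
      serial <<- serial + 1L
      xyz <- round(runif(3, -4, 4), 3)
      sprintf("ATOM  %5d  C%-2d LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00     0.000 C",
              serial, serial %% 100, xyz[1], xyz[2], xyz[3])
    }, character(1))
    lines
  }

  emit <- function(node_id) {
    lines <- atom_lines(node_id)
    kids <- which(parents == node_id)
    for (k in kids) {
      pa <- sample(node_serials[[node_id]], 1)
      body <- emit(k)
      ch <- node_serials[[k]][1]
      lines <- c(lines, sprintf("BRANCH %d %d", pa, ch), body,
                 sprintf("ENDBRANCH %d %d", pa, ch))
    }
    lines
  }
  root_lines <- atom_lines(1L)
  out <- c("ROOT", root_lines, "ENDROOT")
  for (k in which(parents == 1L)) {
    pa <- sample(node_serials[[1L]], 1)
    body <- emit(k)
    ch <- node_serials[[k]][1]
    out <- c(out, sprintf("BRANCH %d %d", pa, ch), body,
             sprintf("ENDBRANCH %d %d", pa, ch))
  }
  paste(c(out, sprintf("TORSDOF %d", n_nodes - 1L)), collapse = "\n")
}

# memoised fixtures (grid builds are the slow part)
.fixture_env <- new.env(parent = emptyenv())
get_fixture <- function(natom = 12, nrot = 2, seed = 1, grid = TRUE) {
  key <- paste(natom, nrot, seed, grid, sep = "_")
  if (!exists(key, envir = .fixture_env)) {
    cx <- make_planted_complex(natom, nrot, seed = seed)
    if (grid)
      cx$cache <- build_grid_cache(cx$receptor, cx$box, unique(cx$flat$types))
    assign(key, cx, envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a small hand-written ligand mirroring the worked node-list example:
# root (3 atoms) with two child branches, the first branch having its own
# child -> 5 nodes, node 1 has children {2, 5}
example_tree_text <- function() {
  paste(
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C",
    "ATOM      2  C2  LIG A   1       1.500   0.000   0.000  1.00  0.00     0.000 C",
    "ATOM      3  C3  LIG A   1       0.000   1.500   0.000  1.00  0.00     0.000 C",
    "ENDROOT",
    "BRANCH 2 4",
    "ATOM      4  C4  LIG A   1       3.000   0.000   0.000  1.00  0.00     0.000 C",
    "BRANCH 4 5",
    "ATOM      5  C5  LIG A   1       4.500   0.000   0.000  1.00  0.00     0.000 C",
    "ENDBRANCH 4 5",
    "BRANCH 4 6",
    "ATOM      6  C6  LIG A   1       3.000   1.500   0.000  1.00  0.00     0.000 C",
    "ENDBRANCH 4 6",
    "ENDBRANCH 2 4",
    "BRANCH 3 7",
    "ATOM      7  C7  LIG A   1       0.000   3.000   0.000  1.00  0.00     0.000 C",
    "ENDBRANCH 3 7",
    "TORSDOF 4",
    sep = "\n")
}

# finite differences are only a valid gradient oracle where the objective
# is differentiable: reject probe states whose FD stencil could straddle a
# trilinear cell face, a piecewise-linear term kink, or the cutoff
fd_probe_ok <- function(flat, cache, ctx, cf, margin_cells = 2e-3,
                        margin_d = 0.01) {
  X <- apply_conformation(flat, cf)
  u <- sweep(X, 2, cache$origin) / cache$spacing
  fr <- u - floor(u)
  if (min(pmin(fr, 1 - fr)) < margin_cells) return(FALSE)
  hv <- ctx$lidx
  r <- sqrt(outer(X[hv, 1], ctx$rxyz[, 1], "-")^2 +
            outer(X[hv, 2], ctx$rxyz[, 2], "-")^2 +
            outer(X[hv, 3], ctx$rxyz[, 3], "-")^2)
  d <- as.numeric(r - ctx$radsum)
  kinks <- c(-0.7, 0, 0.5, 1.5)
  if (min(abs(outer(d, kinks, "-"))) < margin_d) return(FALSE)
  if (min(abs(as.numeric(r) - ctx$terms$cutoff)) < margin_d) return(FALSE)
  pp <- flat$pairs
  if (length(pp$i) > 0) {
    ri <- sqrt(rowSums((X[pp$i, , drop = FALSE] -
                        X[pp$j, , drop = FALSE])^2))
    di <- ri - pp$radsum
    if (min(abs(outer(di, kinks, "-"))) < margin_d) return(FALSE)
    if (min(abs(ri - flat_cutoff(cache))) < margin_d) return(FALSE)
  }
  TRUE
}
flat_cutoff <- function(cache) if (is.null(cache$cutoff)) 8 else cache$cutoff
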