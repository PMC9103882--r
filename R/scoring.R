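#' @title Empirical docking score and its gradient
#' @name scoring
#' @description The potential energy of a pose is e = einter + eintra: the
#'   receptor-ligand interaction energy, evaluated by trilinear
#'   interpolation of a precomputed per-atom-type grid cache, plus the
#'   intramolecular energy over eligible ligand atom pairs.  The functional
#'   form is the AutoDock-Vina empirical potential (gauss1, gauss2,
#'   repulsion, hydrophobic and hydrogen-bond terms on surface distance,
#'   8 Angstrom cutoff), truncated and shifted to zero at the cutoff so the
#'   potential is continuous there.  The gradient of the score over the
#'   (7+Nrot)-dimensional POT vector is assembled analytically from
#'   per-atom Cartesian forces through the kinematic chain.
NULL

#' Scoring term weights and constants
#'
#' The published AutoDock Vina weights, exposed as a configurable table.
#' `entropy_w` is the conformational-entropy weight of the 1/(1 + w*Nrot)
#' post-scaling applied only to final reported scores (it is
#' pose-independent and cannot affect search ordering).
#'
#' @return A list with `weights` (gauss1, gauss2, repulsion, hydrophobic,
#'   hbond), `cutoff` (Angstrom, on center-center distance) and `entropy_w`.
#' @export
scoring_terms <- function() {
  list(weights = c(gauss1 = -0.035579, gauss2 = -0.005156,
                   repulsion = 0.840245, hydrophobic = -0.035069,
                   hbond = -0.587439),
       cutoff = 8.0,
       entropy_w = 0.05846)
}

#' AutoDock atom-type parameters
#'
#' Van der Waals radii and interaction classes for the AutoDock atom-type
#' tokens.  PDBQT carries no connectivity, so hydrophobic / donor /
#' acceptor flags are assigned from the type token alone: acceptors are the
#' OA/NA/SA types, donors the plain N and O types, hydrophobic the apolar
#' carbons and halogens.  Hydrogens (H, HD) are excluded from scoring.
#'
#' @return Data frame with columns type, radius, hydrophobic, donor,
#'   acceptor, heavy.
#' @export
atom_type_table <- function() {
  data.frame(
    type   = c("C", "A", "N", "NA", "O", "OA", "S", "SA", "P",
               "F", "Cl", "Br", "I", "H", "HD"),
    radius = c(1.9, 1.9, 1.8, 1.8, 1.7, 1.7, 2.0, 2.0, 2.1,
               1.5, 1.8, 2.0, 2.2, 0.0, 0.0),
    hydrophobic = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    donor    = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    acceptor = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                 FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    heavy = c(rep(TRUE, 13), FALSE, FALSE),
    stringsAsFactors = FALSE)
}

type_row <- function(type, table = atom_type_table()) {
  k <- match(type, table$type)
  if (any(is.na(k)))
    stop("unknown AutoDock atom type: ",
         paste(unique(type[is.na(k)]), collapse = ", "), call. = FALSE)
  table[k, , drop = FALSE]
}

clamp01 <- function(v) {
  v[v < 0] <- 0
  v[v > 1] <- 1
  v
}

# raw weighted term sum at surface distance d (vectorized; hydro/hb are
# per-element logical/0-1 flags)
vina_raw <- function(d, hydro, hb, w) {
  g1 <- exp(-4 * d * d)
  g2 <- exp(-((d - 3)^2) / 4)
  rep_ <- d * d * (d < 0)
  phob <- clamp01(1.5 - d)
  hbv <- clamp01(-d / 0.7)
  w[[1]] * g1 + w[[2]] * g2 + w[[3]] * rep_ + w[[4]] * hydro * phob + w[[5]] * hb * hbv
}

# d(vina_raw)/dd
vina_raw_deriv <- function(d, hydro, hb, w) {
  g1 <- exp(-4 * d * d)
  g2 <- exp(-((d - 3)^2) / 4)
  dg1 <- -8 * d * g1
  dg2 <- -0.5 * (d - 3) * g2
  drep <- 2 * d * (d < 0)
  dphob <- -as.numeric(d > 0.5 & d < 1.5)
  dhb <- -as.numeric(d > -0.7 & d < 0) / 0.7
  w[[1]] * dg1 + w[[2]] * dg2 + w[[3]] * drep + w[[4]] * hydro * dphob +
    w[[5]] * hb * dhb
}

hb_possible <- function(pa, pb) (pa$donor & pb$acceptor) | (pa$acceptor & pb$donor)

#' Pairwise interaction potential between two atom types
#'
#' Weighted sum of the adopted steric / hydrophobic / hydrogen-bond terms,
#' evaluated on the surface distance (center distance minus the two van der
#' Waals radii), truncated and shifted to zero at the cutoff so the value is
#' continuous there.
#'
#' @param type_i,type_j AutoDock atom-type tokens.
#' @param r center-center distance(s), Angstrom (vectorized).
#' @param terms term table from [scoring_terms()].
#' @return Interaction energy (kcal/mol), 0 beyond the cutoff.
#' @export
pair_potential <- function(type_i, type_j, r, terms = scoring_terms()) {
  if (any(r < 0)) stop("distance must be non-negative", call. = FALSE)
  pa <- type_row(type_i); pb <- type_row(type_j)
  radsum <- pa$radius + pb$radius
  hydro <- pa$hydrophobic && pb$hydrophobic
  hb <- hb_possible(pa, pb)
  w <- terms$weights
  shift <- vina_raw(terms$cutoff - radsum, hydro, hb, w)
  out <- vina_raw(r - radsum, hydro, hb, w) - shift
  out[r > terms$cutoff] <- 0
  out
}

# ---- intramolecular pair list ----------------------------------------------

# PDBQT has no bond records: bonds are inferred from the reference geometry
# (heavy-to-any distance < 1.9 A counts as bonded).  Eligible pairs are
# heavy atoms in different rigid bodies separated by >= 4 bonds
# (1-2/1-3/1-4 interactions excluded).
intra_pairs <- function(flat, terms = scoring_terms()) {
  n <- flat$natom
  params <- type_row(flat$types)
  xyz <- flat$xyz
  dmat <- as.matrix(stats::dist(xyz))
  bonded <- dmat > 1e-6 & dmat < 1.9
  # graph distances via BFS from each atom (molecules are small)
  gdist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist_s <- rep(Inf, n); dist_s[s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- which(colSums(bonded[frontier, , drop = FALSE]) > 0 &
                   !is.finite(dist_s))
      dist_s[nxt] <- depth
      frontier <- nxt
    }
    gdist[s, ] <- dist_s
  }
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  keep <- i < j & params$heavy[i] & params$heavy[j] &
    gdist[cbind(i, j)] >= 4 &
    flat$node_of_atom[i] != flat$node_of_atom[j]
  i <- i[keep]; j <- j[keep]
  hydro <- params$hydrophobic[i] & params$hydrophobic[j]
  hb <- (params$donor[i] & params$acceptor[j]) |
        (params$acceptor[i] & params$donor[j])
  radsum <- params$radius[i] + params$radius[j]
  w <- terms$weights
  # signed pair-to-atom incidence matrix for gradient accumulation
  inc <- matrix(0, n, length(i))
  if (length(i) > 0) {
    inc[cbind(i, seq_along(i))] <- 1
    inc[cbind(j, seq_along(j))] <- -1
  }
  list(i = i, j = j, radsum = radsum, hydro = hydro, hb = hb,
       shift = vina_raw(terms$cutoff - radsum, hydro, hb, w),
       i_mat = cbind(i, j), inc = inc,
       heavy_idx = which(params$heavy),
       heavy_types = flat$types[params$heavy],
       heavy_by_type = split(which(params$heavy), flat$types[params$heavy]))
}

eintra_of <- function(flat, X, terms = scoring_terms(), deriv = FALSE) {
  pp <- flat$pairs
  if (length(pp$i) == 0L) {
    if (deriv) return(list(e = 0, g = matrix(0, flat$natom, 3)))
    return(0)
  }
  dvec <- X[pp$i, , drop = FALSE] - X[pp$j, , drop = FALSE]
  r <- sqrt(rowSums(dvec * dvec))
  d <- r - pp$radsum
  w <- terms$weights
  inside <- r <= terms$cutoff
  val <- (vina_raw(d, pp$hydro, pp$hb, w) - pp$shift) * inside
  e <- sum(val)
  if (!deriv) return(e)
  dv <- vina_raw_deriv(d, pp$hydro, pp$hb, w) * inside
  # d e / d x_i = dv * (x_i - x_j)/r ; opposite sign on atom j
  contrib <- dvec * (dv / pmax(r, 1e-12))
  list(e = e, g = pp$inc %*% contrib)
}

# ---- grid cache -------------------------------------------------------------

#' Precompute the receptor interaction grid over the docking box
#'
#' For every ligand atom type and lattice node, stores the sum of
#' [pair_potential()] over all receptor heavy atoms within the cutoff.  The
#' lattice spans the docking box plus one cell of margin on each side.
#'
#' @param receptor a `"receptor"`.
#' @param box a [docking_box()].
#' @param ligand_types character vector of ligand atom types to tabulate
#'   (hydrogens are skipped).
#' @param spacing lattice spacing, Angstrom (default 0.375, the
#'   AutoDock-family convention).
#' @param terms term table from [scoring_terms()].
#' @param max_nodes memory guard: error if the lattice would exceed this
#'   many nodes per atom type.
#' @return Object of class `"grid_cache"`: list with `origin`, `spacing`,
#'   `dims`, `types`, `values` (named list of 3-D arrays, kcal/mol).
#' @export
build_grid_cache <- function(receptor, box, ligand_types, spacing = 0.375,
                             terms = scoring_terms(), max_nodes = 2e7) {
  stopifnot(spacing > 0)
  table <- atom_type_table()
  ligand_types <- unique(ligand_types)
  ligand_types <- ligand_types[type_row(ligand_types, table)$heavy]
  lo <- box_lo(box) - spacing
  span <- box$size + 2 * spacing
  dims <- pmax(2L, as.integer(ceiling(span / spacing)) + 1L)
  if (prod(dims) > max_nodes)
    stop("grid of ", prod(dims), " nodes exceeds the memory guard (",
         format(max_nodes, scientific = FALSE), " nodes); enlarge spacing ",
         "or shrink the box", call. = FALSE)
  gx <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  gy <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  gz <- lo[3] + (seq_len(dims[3]) - 1) * spacing

  rp <- type_row(receptor$atoms$type, table)
  ratoms <- receptor$atoms[rp$heavy, , drop = FALSE]
  rparams <- rp[rp$heavy, , drop = FALSE]
  w <- terms$weights
  cutoff <- terms$cutoff

  values <- list()
  for (tt in ligand_types) {
    pl <- type_row(tt, table)
    arr <- array(0, dims)
    for (ai in seq_len(nrow(ratoms))) {
      ax <- ratoms$x[ai]; ay <- ratoms$y[ai]; az <- ratoms$z[ai]
      ix <- which(abs(gx - ax) <= cutoff)
      iy <- which(abs(gy - ay) <= cutoff)
      iz <- which(abs(gz - az) <= cutoff)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (gx[ix] - ax)^2; dy2 <- (gy[iy] - ay)^2; dz2 <- (gz[iz] - az)^2
      r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
      r <- sqrt(r2)
      radsum <- pl$radius + rparams$radius[ai]
      hydro <- pl$hydrophobic && rparams$hydrophobic[ai]
      hb <- (pl$donor && rparams$acceptor[ai]) ||
            (pl$acceptor && rparams$donor[ai])
      shift <- vina_raw(cutoff - radsum, hydro, hb, w)
      val <- vina_raw(r - radsum, hydro, hb, w) - shift
      val[r > cutoff] <- 0
      arr[ix, iy, iz] <- arr[ix, iy, iz] + val
    }
    values[[tt]] <- arr
  }
  # stacked copy: all type lattices in one vector for single-gather lookups
  nn <- prod(dims)
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 types = ligand_types, values = values, cutoff = cutoff,
                 stack = unlist(values, use.names = FALSE),
                 offsets = stats::setNames((seq_along(values) - 1L) * nn,
                                           names(values))),
            class = "grid_cache")
}

#' @export
print.grid_cache <- function(x, ...) {
  cat(sprintf("grid cache: %d x %d x %d nodes, spacing %.3f A, types: %s\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              paste(x$types, collapse = ", ")))
  invisible(x)
}

# fast trilinear interpolation at many points.  `arr` is a lattice vector
# (a single type's array, or the cache's stacked multi-type copy addressed
# through per-point `offs`).  Points outside the lattice hull are clamped
# to it and charged a quadratic distance penalty of 1 kcal/mol/A^2
# (differentiable, keeps the optimizer in the box).
interp_many <- function(cache, arr, pts, deriv = FALSE, offs = 0L) {
  dims <- cache$dims
  sp <- cache$spacing
  org <- cache$origin
  ux <- (pts[, 1] - org[1]) / sp
  uy <- (pts[, 2] - org[2]) / sp
  uz <- (pts[, 3] - org[3]) / sp
  mx <- dims[1] - 1L; my <- dims[2] - 1L; mz <- dims[3] - 1L
  cx <- ux; cx[cx < 0] <- 0; cx[cx > mx] <- mx
  cy <- uy; cy[cy < 0] <- 0; cy[cy > my] <- my
  cz <- uz; cz[cz < 0] <- 0; cz[cz > mz] <- mz
  exx <- (ux - cx) * sp; exy <- (uy - cy) * sp; exz <- (uz - cz) * sp
  e_pen <- exx * exx + exy * exy + exz * exz
  i0x <- floor(cx); i0x[i0x > mx - 1L] <- mx - 1L
  i0y <- floor(cy); i0y[i0y > my - 1L] <- my - 1L
  i0z <- floor(cz); i0z[i0z > mz - 1L] <- mz - 1L
  fx <- cx - i0x; fy <- cy - i0y; fz <- cz - i0z
  s2 <- dims[1]; s3 <- dims[1] * dims[2]
  id <- i0x + i0y * s2 + i0z * s3 + offs + 1
  v000 <- arr[id];            v100 <- arr[id + 1]
  v010 <- arr[id + s2];       v110 <- arr[id + 1 + s2]
  v001 <- arr[id + s3];       v101 <- arr[id + 1 + s3]
  v011 <- arr[id + s2 + s3];  v111 <- arr[id + 1 + s2 + s3]
  c00 <- v000 + (v100 - v000) * fx
  c10 <- v010 + (v110 - v010) * fx
  c01 <- v001 + (v101 - v001) * fx
  c11 <- v011 + (v111 - v011) * fx
  c0 <- c00 + (c10 - c00) * fy
  c1 <- c01 + (c11 - c01) * fy
  e <- c0 + (c1 - c0) * fz + e_pen
  if (!deriv) return(e)
  # clamped axes: the lattice term is flat there, only the penalty acts
  dex <- (((v100 - v000) * (1 - fy) + (v110 - v010) * fy) * (1 - fz) +
          ((v101 - v001) * (1 - fy) + (v111 - v011) * fy) * fz) / sp *
         (ux >= 0 & ux <= mx) + 2 * exx
  dey <- ((c10 - c00) * (1 - fz) + (c11 - c01) * fz) / sp *
         (uy >= 0 & uy <= my) + 2 * exy
  dez <- (c1 - c0) / sp * (uz >= 0 & uz <= mz) + 2 * exz
  list(e = e, de = cbind(dex, dey, dez))
}

# per-heavy-atom stacked-lattice offsets for a (flat, cache) pair
stack_offsets <- function(cache, flat) {
  offs <- cache$offsets[flat$pairs$heavy_types]
  if (anyNA(offs))
    stop("atom type '",
         paste(unique(flat$pairs$heavy_types[is.na(offs)]), collapse = ", "),
         "' missing from grid cache", call. = FALSE)
  unname(offs)
}

#' Trilinear interpolation of the grid cache
#'
#' Standard 8-corner trilinear interpolation of one atom type's lattice.
#' Points outside the lattice hull are clamped to the hull and charged a
#' quadratic distance penalty (1 kcal/mol per square Angstrom).
#'
#' @param cache a `"grid_cache"`.
#' @param type AutoDock atom-type token present in the cache.
#' @param point numeric length-3 position, or an n x 3 matrix.
#' @return Interpolated energy (kcal/mol), one value per point.
#' @export
interp_energy <- function(cache, type, point) {
  arr <- cache$values[[type]]
  if (is.null(arr))
    stop("atom type '", type, "' is not tabulated in this grid cache",
         call. = FALSE)
  pts <- if (is.matrix(point)) point else matrix(point, 1, 3)
  interp_many(cache, arr, pts)
}

# ---- scoring ----------------------------------------------------------------

#' Score a conformation against the grid cache
#'
#' Realizes the Cartesian coordinates, sums the interpolated receptor
#' interaction over all heavy ligand atoms (einter) and the pairwise
#' intramolecular potential over eligible pairs (eintra).
#'
#' @param flat a `"flat_ligand"`.
#' @param conf a [conformation()].
#' @param cache a `"grid_cache"`.
#' @param terms term table from [scoring_terms()].
#' @return Object of class `"scored_pose"`: list with `conformation`,
#'   `coords`, `e`, `einter`, `eintra` (kcal/mol, e = einter + eintra).
#' @export
score_pose <- function(flat, conf, cache, terms = scoring_terms()) {
  X <- apply_conformation(flat, conf)
  hv <- flat$pairs$heavy_idx
  einter <- sum(interp_many(cache, cache$stack, X[hv, , drop = FALSE],
                            offs = stack_offsets(cache, flat)))
  eintra <- eintra_of(flat, X, terms)
  structure(list(conformation = conf, coords = X,
                 e = einter + eintra, einter = einter, eintra = eintra),
            class = "scored_pose")
}

#' @export
print.scored_pose <- function(x, ...) {
  cat(sprintf("scored pose: e = %.3f (inter %.3f + intra %.3f) kcal/mol\n",
              x$e, x$einter, x$eintra))
  invisible(x)
}

# assemble POT gradient from per-atom Cartesian gradients
assemble_pot_gradient <- function(flat, conf, frames, g_atoms) {
  X <- frames$coords; t_xyz <- frames$torsioned
  q <- conf$quaternion
  qn <- quat_normalize(q)
  nrmq <- sqrt(sum(q * q))
  gpos <- colSums(g_atoms)
  rel <- sweep(t_xyz, 2, flat$root_centroid)
  dR <- quat_matrix_grad(qn)
  ghat <- vapply(dR, function(M) sum((rel %*% t(M)) * g_atoms), numeric(1))
  gq <- (ghat - qn * sum(qn * ghat)) / nrmq
  gtor <- numeric(flat$nrot)
  if (flat$nrot > 0) {
    R <- quat_matrix(qn)
    for (k in 2:length(flat$nodes)) {
      node <- flat$nodes[[k]]
      a <- node$axis[1]; b <- node$axis[2]
      u_t <- t_xyz[b, ] - t_xyz[a, ]
      u_t <- u_t / sqrt(sum(u_t * u_t))
      U <- as.numeric(R %*% u_t)
      relb <- sweep(X[node$subtree, , drop = FALSE], 2, X[b, ])
      gsub <- g_atoms[node$subtree, , drop = FALSE]
      cr <- cbind(relb[, 2] * gsub[, 3] - relb[, 3] * gsub[, 2],
                  relb[, 3] * gsub[, 1] - relb[, 1] * gsub[, 3],
                  relb[, 1] * gsub[, 2] - relb[, 2] * gsub[, 1])
      gtor[k - 1L] <- sum(U * colSums(cr))
    }
  }
  c(gpos, gq, gtor)
}

#' Analytic gradient of the score over the POT vector
#'
#' Partial derivatives of e with respect to the 7+Nrot POT components
#' (3 position, 4 quaternion, Nrot torsions), assembled from per-atom
#' Cartesian force contributions through the kinematic chain.  The
#' quaternion block is chain-ruled through the internal normalization, so
#' it matches central finite differences of [score_pose()] directly.
#'
#' @inheritParams score_pose
#' @return Numeric vector of length 7 + Nrot (kcal/mol per component unit).
#' @export
score_gradient <- function(flat, conf, cache, terms = scoring_terms()) {
  score_and_gradient(flat, conf, cache, terms)$g
}

# energy and POT gradient in one pass (shared kinematics/lattice gathers)
score_and_gradient <- function(flat, conf, cache, terms = scoring_terms()) {
  frames <- apply_conformation(flat, conf, frames = TRUE)
  X <- frames$coords
  hv <- flat$pairs$heavy_idx
  res <- interp_many(cache, cache$stack, X[hv, , drop = FALSE],
                     deriv = TRUE, offs = stack_offsets(cache, flat))
  g_atoms <- matrix(0, flat$natom, 3)
  g_atoms[hv, ] <- res$de
  res_intra <- eintra_of(flat, X, terms, deriv = TRUE)
  g_atoms <- g_atoms + res_intra$g
  list(e = sum(res$e) + res_intra$e,
       g = assemble_pot_gradient(flat, conf, frames, g_atoms))
}

# ---- grid-free (direct) scoring --------------------------------------------

#' Precompute ligand-receptor pair parameters for grid-free scoring
#'
#' @param flat a `"flat_ligand"`.
#' @param receptor a `"receptor"`.
#' @param terms term table.
#' @return Context object used by [score_direct()] and refinement.
#' @export
receptor_context <- function(flat, receptor, terms = scoring_terms()) {
  table <- atom_type_table()
  rp <- type_row(receptor$atoms$type, table)
  keep <- rp$heavy
  rxyz <- as.matrix(receptor$atoms[keep, c("x", "y", "z")])
  rpar <- rp[keep, , drop = FALSE]
  lp <- type_row(flat$types, table)
  lidx <- which(lp$heavy)
  lpar <- lp[lidx, , drop = FALSE]
  nl <- length(lidx); nr <- nrow(rxyz)
  radsum <- outer(lpar$radius, rpar$radius, `+`)
  hydro <- outer(lpar$hydrophobic, rpar$hydrophobic, `&`)
  hb <- outer(lpar$donor, rpar$acceptor, `&`) |
        outer(lpar$acceptor, rpar$donor, `&`)
  w <- terms$weights
  shift <- matrix(vina_raw(terms$cutoff - radsum, hydro, hb, w), nl, nr)
  list(rxyz = rxyz, lidx = lidx, radsum = radsum, hydro = hydro, hb = hb,
       shift = shift, terms = terms)
}

direct_inter <- function(ctx, X, deriv = FALSE) {
  L <- X[ctx$lidx, , drop = FALSE]
  nl <- nrow(L); nr <- nrow(ctx$rxyz)
  dx <- outer(L[, 1], ctx$rxyz[, 1], `-`)
  dy <- outer(L[, 2], ctx$rxyz[, 2], `-`)
  dz <- outer(L[, 3], ctx$rxyz[, 3], `-`)
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  d <- r - ctx$radsum
  w <- ctx$terms$weights
  inside <- r <= ctx$terms$cutoff
  val <- (vina_raw(d, ctx$hydro, ctx$hb, w) - ctx$shift) * inside
  e <- sum(val)
  if (!deriv) return(e)
  dv <- vina_raw_deriv(d, ctx$hydro, ctx$hb, w) * inside / pmax(r, 1e-12)
  g <- matrix(0, nrow(X), 3)
  g[ctx$lidx, 1] <- rowSums(dv * dx)
  g[ctx$lidx, 2] <- rowSums(dv * dy)
  g[ctx$lidx, 3] <- rowSums(dv * dz)
  list(e = e, g = g)
}

#' Score a conformation with direct (grid-free) receptor sums
#'
#' Same potential as [score_pose()] but einter is evaluated by summing
#' [pair_potential()] directly over receptor atoms, bypassing the grid and
#' its interpolation error.  Used for host-side refinement of top poses and
#' as an independent oracle for the grid pathway.
#'
#' @param flat a `"flat_ligand"`.
#' @param conf a [conformation()].
#' @param ctx context from [receptor_context()].
#' @return A `"scored_pose"`.
#' @export
score_direct <- function(flat, conf, ctx) {
  X <- apply_conformation(flat, conf)
  einter <- direct_inter(ctx, X)
  eintra <- eintra_of(flat, X, ctx$terms)
  structure(list(conformation = conf, coords = X,
                 e = einter + eintra, einter = einter, eintra = eintra),
            class = "scored_pose")
}

# analytic gradient (and energy) of the grid-free score
score_and_gradient_direct <- function(flat, conf, ctx) {
  frames <- apply_conformation(flat, conf, frames = TRUE)
  res_inter <- direct_inter(ctx, frames$coords, deriv = TRUE)
  res_intra <- eintra_of(flat, frames$coords, ctx$terms, deriv = TRUE)
  list(e = res_inter$e + res_intra$e,
       g = assemble_pot_gradient(flat, conf, frames,
                                 res_inter$g + res_intra$g))
}

gradient_direct <- function(flat, conf, ctx) {
  score_and_gradient_direct(flat, conf, ctx)$g
}

#' Export a grid-cache lattice as plain text (debugging aid)
#'
#' One value per line after a header with origin, spacing and dims.
#'
#' @param cache a `"grid_cache"`.
#' @param type atom type to export.
#' @param path output file path.
#' @export
export_grid_map <- function(cache, type, path) {
  arr <- cache$values[[type]]
  if (is.null(arr)) stop("type not in cache", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ORIGIN %.6f %.6f %.6f", cache$origin[1],
                       cache$origin[2], cache$origin[3]),
               sprintf("SPACING %.6f", cache$spacing),
               sprintf("DIMS %d %d %d", cache$dims[1], cache$dims[2],
                       cache$dims[3]),
               sprintf("TYPE %s", type),
               sprintf("%.8g", as.numeric(arr))), con)
  invisible(path)
}
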