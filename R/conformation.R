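#' @title Conformation state and ligand kinematics
#' @name conformation_model
#' @description A docking pose is parameterized by its POT state: Cartesian
#'   position (x, y, z), rigid-body orientation as a unit quaternion
#'   (a, b, c, d) and one torsion angle per rotatable bond.  The ligand's
#'   recursive torsion tree is flattened into a node list plus a boolean
#'   children map so the forward kinematics can be evaluated iteratively
#'   (no recursion) in depth-first node order.
NULL

# ---- quaternion helpers -----------------------------------------------------

quat_normalize <- function(q) {
  nrm <- sqrt(sum(q * q))
  if (nrm < 1e-12) stop("degenerate quaternion (norm ~ 0)", call. = FALSE)
  q / nrm
}

# scalar-first unit quaternion -> 3x3 rotation matrix
quat_matrix <- function(q) {
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a*a + b*b - cc*cc - d*d, 2*(b*cc - a*d),          2*(b*d + a*cc),
           2*(b*cc + a*d),          a*a - b*b + cc*cc - d*d, 2*(cc*d - a*b),
           2*(b*d - a*cc),          2*(cc*d + a*b),          a*a - b*b - cc*cc + d*d),
         nrow = 3, byrow = TRUE)
}

# partial derivatives of quat_matrix wrt each (unit) quaternion component
quat_matrix_grad <- function(q) {
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  list(
    2 * matrix(c( a, -d,  cc,  d,  a, -b, -cc,  b,  a), 3, byrow = TRUE),
    2 * matrix(c( b,  cc,  d,  cc, -b, -a,  d,  a, -b), 3, byrow = TRUE),
    2 * matrix(c(-cc,  b,  a,  b,  cc,  d, -a,  d, -cc), 3, byrow = TRUE),
    2 * matrix(c(-d, -a,  b,  a, -d,  cc,  b,  cc,  d), 3, byrow = TRUE))
}

quat_multiply <- function(p, q) {
  c(p[1]*q[1] - p[2]*q[2] - p[3]*q[3] - p[4]*q[4],
    p[1]*q[2] + p[2]*q[1] + p[3]*q[4] - p[4]*q[3],
    p[1]*q[3] - p[2]*q[4] + p[3]*q[1] + p[4]*q[2],
    p[1]*q[4] + p[2]*q[3] - p[3]*q[2] + p[4]*q[1])
}

axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis * axis))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# Rodrigues rotation of rows of `pts` about the line through `origin` with
# unit direction `u` by angle `theta` (right-hand rule)
rotate_about_axis <- function(pts, origin, u, theta) {
  r1 <- pts[, 1] - origin[1]
  r2 <- pts[, 2] - origin[2]
  r3 <- pts[, 3] - origin[3]
  ct <- cos(theta); st <- sin(theta)
  dotu <- (r1 * u[1] + r2 * u[2] + r3 * u[3]) * (1 - ct)
  cbind(r1 * ct + (u[2] * r3 - u[3] * r2) * st + dotu * u[1] + origin[1],
        r2 * ct + (u[3] * r1 - u[1] * r3) * st + dotu * u[2] + origin[2],
        r3 * ct + (u[1] * r2 - u[2] * r1) * st + dotu * u[3] + origin[3])
}

# ---- conformation -----------------------------------------------------------

#' Construct a conformation (POT state)
#'
#' @param position numeric length-3, Angstrom.
#' @param quaternion numeric length-4 (scalar-first); normalized to unit
#'   length on construction.
#' @param torsions numeric vector of rotatable-bond angles, radians in
#'   (-pi, pi].
#' @return Object of class `"conformation"`.
#' @export
conformation <- function(position, quaternion = c(1, 0, 0, 0),
                         torsions = numeric(0)) {
  position <- as.numeric(position)
  stopifnot(length(position) == 3L, length(quaternion) == 4L)
  if (!all(is.finite(position)) || !all(is.finite(quaternion)) ||
      !all(is.finite(torsions)))
    stop("conformation components must be finite", call. = FALSE)
  structure(list(position = position,
                 quaternion = quat_normalize(as.numeric(quaternion)),
                 torsions = as.numeric(torsions)),
            class = "conformation")
}

conf_to_vector <- function(conf)
  c(conf$position, conf$quaternion, conf$torsions)

vector_to_conf <- function(x, nrot) {
  stopifnot(length(x) == 7L + nrot)
  conformation(x[1:3], x[4:7], if (nrot > 0) x[8:(7 + nrot)] else numeric(0))
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation: pos (%.2f, %.2f, %.2f), |q| = %.6f, %d torsions\n",
              x$position[1], x$position[2], x$position[3],
              sqrt(sum(x$quaternion^2)), length(x$torsions)))
  invisible(x)
}

# ---- tree flattening --------------------------------------------------------

#' Flatten a ligand torsion tree into a node list + children map
#'
#' Nodes are listed in depth-first traversal order (node 1 is the root); the
#' children map is a boolean matrix whose entry (i, j) is `TRUE` iff node j
#' is a child of node i, so parent index < child index for every edge.
#' Iterating the node list in order and consulting the map reproduces the
#' recursive depth-first traversal of the tree without recursion.
#'
#' @param tree a `"ligand_tree"` from [read_ligand()].
#' @return Object of class `"flat_ligand"`: list with `nodes` (each node has
#'   `members` = atom indices, `axis` = c(parent-atom, child-atom) indices
#'   or `NULL` for the root, `parent`, `subtree` = member + descendant atom
#'   indices), `children_map` (logical matrix), `atoms` (data frame),
#'   `xyz` (reference coordinates, Natom x 3), `types`, `natom`, `nrot`,
#'   `root_centroid` and `pairs` (eligible intramolecular atom pairs).
#' @export
flatten_tree <- function(tree) {
  stopifnot(inherits(tree, "ligand_tree"))
  atoms <- tree$atoms
  idx_of_serial <- stats::setNames(seq_len(nrow(atoms)), atoms$serial)

  nodes <- list()
  edges <- list()
  add_node <- function(df, axis_serials, parent_id) {
    id <- length(nodes) + 1L
    members <- unname(idx_of_serial[as.character(df$serial)])
    axis <- if (is.null(axis_serials)) NULL
            else unname(idx_of_serial[as.character(axis_serials)])
    nodes[[id]] <<- list(members = members, axis = axis,
                         parent = parent_id, subtree = members)
    if (!is.null(parent_id)) edges[[length(edges) + 1L]] <<- c(parent_id, id)
    id
  }
  walk <- function(node, parent_id) {
    id <- add_node(node$atoms, c(node$parent_serial, node$child_serial),
                   parent_id)
    for (ch in node$children) walk(ch, id)
    id
  }
  root_id <- add_node(tree$root_atoms, NULL, NULL)
  for (b in tree$branches) walk(b, root_id)

  nn <- length(nodes)
  children_map <- matrix(FALSE, nn, nn)
  for (e in edges) children_map[e[1], e[2]] <- TRUE

  # accumulate subtree atom sets bottom-up (reverse depth-first order)
  for (k in rev(seq_len(nn))) {
    kids <- which(children_map[k, ])
    for (j in kids)
      nodes[[k]]$subtree <- c(nodes[[k]]$subtree, nodes[[j]]$subtree)
  }

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  flat <- structure(list(nodes = nodes, children_map = children_map,
                         atoms = atoms, xyz = xyz, types = atoms$type,
                         natom = nrow(atoms), nrot = nn - 1L,
                         root_centroid = colMeans(xyz[nodes[[1]]$members, ,
                                                      drop = FALSE])),
                    class = "flat_ligand")
  flat$node_of_atom <- integer(flat$natom)
  for (k in seq_len(nn)) flat$node_of_atom[nodes[[k]]$members] <- k
  flat$pairs <- intra_pairs(flat)
  flat
}

#' @export
print.flat_ligand <- function(x, ...) {
  cat("flattened ligand:", x$natom, "atoms,", length(x$nodes),
      "nodes,", x$nrot, "rotatable bonds,", nrow(x$pairs$i_mat),
      "intramolecular pairs\n")
  invisible(x)
}

# ---- forward kinematics -----------------------------------------------------

#' Realize Cartesian coordinates from a POT conformation
#'
#' Torsions are applied in node-list order (parents before children): each
#' non-root node's member atoms and all its descendants rotate by the node's
#' torsion about the normalized parent-atom -> child-atom axis (right-hand
#' rule).  The whole molecule is then rotated by the quaternion about the
#' centroid of the root-node reference atoms and translated so that this
#' centroid lands on `conf$position`.  The quaternion is normalized
#' internally, so the realized geometry is invariant to its norm.
#'
#' @param flat a `"flat_ligand"` from [flatten_tree()].
#' @param conf a [conformation()] whose torsion count equals `flat$nrot`.
#' @param frames if `TRUE`, also return the torsion-only intermediate
#'   coordinates (used by the analytic gradient).
#' @return Natom x 3 coordinate matrix (Angstrom), or a list
#'   `(coords, torsioned)` when `frames = TRUE`.
#' @export
apply_conformation <- function(flat, conf, frames = FALSE) {
  if (length(conf$torsions) != flat$nrot)
    stop("torsion count (", length(conf$torsions), ") does not match ligand (",
         flat$nrot, ")", call. = FALSE)
  t_xyz <- flat$xyz
  if (flat$nrot > 0) {
    for (k in 2:length(flat$nodes)) {
      node <- flat$nodes[[k]]
      psi <- conf$torsions[k - 1L]
      a <- node$axis[1]; b <- node$axis[2]
      u <- t_xyz[b, ] - t_xyz[a, ]
      u <- u / sqrt(sum(u * u))
      t_xyz[node$subtree, ] <- rotate_about_axis(
        t_xyz[node$subtree, , drop = FALSE], t_xyz[a, ], u, psi)
    }
  }
  q <- quat_normalize(conf$quaternion)
  R <- quat_matrix(q)
  c0 <- flat$root_centroid; pos <- conf$position
  r1 <- t_xyz[, 1] - c0[1]; r2 <- t_xyz[, 2] - c0[2]; r3 <- t_xyz[, 3] - c0[3]
  coords <- cbind(r1 * R[1, 1] + r2 * R[1, 2] + r3 * R[1, 3] + pos[1],
                  r1 * R[2, 1] + r2 * R[2, 2] + r3 * R[2, 3] + pos[2],
                  r1 * R[3, 1] + r2 * R[3, 2] + r3 * R[3, 3] + pos[3])
  if (frames) list(coords = coords, torsioned = t_xyz) else coords
}

# ---- random conformations and mutation --------------------------------------

#' Draw a uniformly random conformation inside a docking box
#'
#' Position uniform in the box, orientation uniform on the unit-quaternion
#' sphere, torsions uniform in (-pi, pi].  Uses R's global RNG stream.
#'
#' @param box a [docking_box()].
#' @param nrot number of rotatable bonds.
#' @return A [conformation()].
#' @export
random_conformation <- function(box, nrot) {
  lo <- box_lo(box); hi <- box_hi(box)
  pos <- stats::runif(3, lo, hi)
  repeat {
    q <- stats::rnorm(4)
    if (sum(q * q) > 1e-12) break
  }
  conformation(pos, q, if (nrot > 0) stats::runif(nrot, -pi, pi)
                       else numeric(0))
}

#' Mutation parameters
#'
#' @param position_amplitude maximum per-axis positional displacement
#'   (Angstrom, default 2).
#' @return Object of class `"mutation_params"`.
#' @export
mutation_params <- function(position_amplitude = 2) {
  stopifnot(position_amplitude > 0)
  structure(list(position_amplitude = position_amplitude),
            class = "mutation_params")
}

#' Randomly mutate one POT block of a conformation
#'
#' Exactly one of position / orientation / torsion is altered, picked
#' uniformly (torsion is never picked for a rigid ligand): position moves by
#' a uniform displacement within +/- amplitude per axis (clamped to the
#' box), orientation is perturbed by a rotation about a uniformly random
#' axis by an angle uniform in (-pi, pi], or one torsion is resampled
#' uniformly over its full range.
#'
#' @param conf a [conformation()].
#' @param params a [mutation_params()].
#' @param box the [docking_box()] used for positional clamping.
#' @return The mutated [conformation()] (quaternion re-normalized).
#' @export
mutate_conformation <- function(conf, params, box) {
  nrot <- length(conf$torsions)
  nblocks <- if (nrot > 0) 3L else 2L
  block <- sample.int(nblocks, 1L)
  pos <- conf$position; q <- conf$quaternion; tor <- conf$torsions
  if (block == 1L) {
    amp <- params$position_amplitude
    pos <- pos + stats::runif(3, -amp, amp)
    pos <- pmin(pmax(pos, box_lo(box)), box_hi(box))
  } else if (block == 2L) {
    repeat {
      ax <- stats::rnorm(3)
      if (sum(ax * ax) > 1e-12) break
    }
    ang <- stats::runif(1, -pi, pi)
    q <- quat_multiply(axis_angle_quat(ax, ang), q)
  } else {
    j <- sample.int(nrot, 1L)
    tor[j] <- stats::runif(1, -pi, pi)
  }
  conformation(pos, q, tor)
}

# ---- RMSD -------------------------------------------------------------------

#' Root-mean-square deviation between two coordinate sets
#'
#' Plain per-atom RMSD in the given atom ordering: no re-superposition and
#' no symmetry correction.  A docking pose is conventionally called
#' acceptable when its RMSD to the reference structure is below 2 Angstrom.
#'
#' @param a,b Natom x 3 coordinate matrices with identical atom ordering.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L)
    stop("coordinate sets must both be Natom x 3 with equal atom counts",
         call. = FALSE)
  sqrt(mean(rowSums((a - b)^2)))
}
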