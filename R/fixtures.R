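#' @title Deterministic synthetic docking fixtures
#' @name fixtures
#' @description Generates toy receptor/ligand pairs in PDBQT with a known
#'   (planted) minimum-energy pose, so every stage of the docking pipeline
#'   is testable without external structures.  The ligand is a
#'   chain-topology molecule laid out on a compact helix; the receptor is a
#'   synthetic pocket: one contact-distance partner atom per ligand atom
#'   (types chosen so the adopted pair terms are attractive at contact,
#'   with hydrogen-bond anchors at the chain ends to pin the orientation)
#'   plus an outer shell of atoms in the mid-range attractive well that
#'   widens the energy funnel toward the planted pose.  Nothing here
#'   reproduces any real structure.
NULL

fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a synthetic receptor/ligand complex with a planted pose
#'
#' Deterministic in `seed`.  The planted pose is the ligand's file geometry
#' (identity orientation, zero torsions, position at the root-atom
#' centroid); the receptor pocket is built around exactly those
#' coordinates, and the docking box is centered on the pocket.
#'
#' @param natom number of ligand atoms (>= nrot + 2).
#' @param nrot number of rotatable bonds (BRANCH records).
#' @param seed integer seed.
#' @param check_samples if > 0, verify at generation time that the planted
#'   pose scores at or below `check_samples` uniformly random conformations
#'   (error otherwise).
#' @return Object of class `"planted_complex"`: list with `receptor_text`,
#'   `ligand_text`, `box`, `planted_pose`, `planted_coords`, parsed
#'   `receptor`, `ligand`, `flat`, `cache` spacing-ready via
#'   [build_grid_cache()], `planted_e` (grid-free planted score) and the
#'   generation sizes.
#' @export
make_planted_complex <- function(natom, nrot, seed = 1L,
                                 check_samples = 0L) {
  if (natom < nrot + 2)
    stop("infeasible sizes: natom must be at least nrot + 2", call. = FALSE)
  set.seed(as.integer(seed))

  # compact helical chain, ~1.5 A consecutive spacing
  rr <- 2.3; dtheta <- 0.62; dz <- 0.40
  i <- seq_len(natom) - 1
  xyz <- cbind(rr * cos(i * dtheta), rr * sin(i * dtheta), i * dz)
  xyz <- xyz + matrix(stats::runif(3 * natom, -0.03, 0.03), natom, 3)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  # polar anchors at the chain ends (and mid-chain for longer ligands)
  # break the orientational symmetry of the pocket
  types <- rep("C", natom)
  if (natom >= 3) {
    types[1] <- "OA"
    types[natom] <- "N"
  }
  if (natom >= 8) types[floor(natom / 2)] <- "OA"

  # chain partition: root block then nrot chained branch blocks
  bsz <- if (nrot > 0) max(1L, min(3L, (natom - 2L) %/% nrot)) else 0L
  n0 <- natom - nrot * bsz
  starts <- if (nrot > 0) n0 + (seq_len(nrot) - 1L) * bsz + 1L else integer(0)

  lig_lines <- c("ROOT",
                 vapply(seq_len(n0), function(a)
                   format_atom_line("ATOM", a, paste0(types[a], a),
                                    xyz[a, 1], xyz[a, 2], xyz[a, 3],
                                    0, types[a]), character(1)),
                 "ENDROOT")
  for (k in seq_len(nrot)) {
    s <- starts[k]
    members <- s:(s + bsz - 1L)
    lig_lines <- c(lig_lines, sprintf("BRANCH %3d %3d", s - 1L, s),
                   vapply(members, function(a)
                     format_atom_line("ATOM", a, paste0(types[a], a),
                                      xyz[a, 1], xyz[a, 2], xyz[a, 3],
                                      0, types[a]), character(1)))
  }
  for (k in rev(seq_len(nrot)))
    lig_lines <- c(lig_lines,
                   sprintf("ENDBRANCH %3d %3d", starts[k] - 1L, starts[k]))
  lig_lines <- c(lig_lines, sprintf("TORSDOF %d", nrot))
  ligand_text <- paste0(paste(lig_lines, collapse = "\n"), "\n")

  ligand <- read_ligand(ligand_text)
  flat <- flatten_tree(ligand)
  planted_coords <- flat$xyz          # file geometry, format-quantized
  centroid <- colMeans(planted_coords)
  table <- atom_type_table()
  lig_par <- type_row(flat$types, table)

  # one contact partner per ligand atom, radially outward
  partner_type <- ifelse(flat$types == "OA", "N",
                         ifelse(flat$types == "N", "OA", "C"))
  par_par <- type_row(partner_type, table)
  dsurf <- ifelse(partner_type == "C", 0, -0.35)  # h-bond anchors overlap
  rec_xyz <- matrix(0, 0, 3)
  rec_type <- character(0)
  for (a in seq_len(natom)) {
    dir <- planted_coords[a, ] - centroid
    nd <- sqrt(sum(dir * dir))
    dir <- if (nd < 0.1) c(0, 0, 1) else dir / nd
    dist <- lig_par$radius[a] + par_par$radius[a] + dsurf[a]
    rec_xyz <- rbind(rec_xyz, planted_coords[a, ] + dir * dist)
    rec_type <- c(rec_type, partner_type[a])
  }
  # outer shell in the mid-range attractive well (widens the funnel)
  lig_radius <- max(sqrt(rowSums(sweep(planted_coords, 2, centroid)^2)))
  shell <- fibonacci_sphere(48) * (lig_radius + 1.9 + 1.9 + 3.0)
  rec_xyz <- rbind(rec_xyz, sweep(shell, 2, centroid, `+`))
  rec_type <- c(rec_type, rep("C", 48))

  rec_lines <- vapply(seq_len(nrow(rec_xyz)), function(a)
    format_atom_line("HETATM", a, paste0(rec_type[a], a),
                     rec_xyz[a, 1], rec_xyz[a, 2], rec_xyz[a, 3],
                     0, rec_type[a]), character(1))
  receptor_text <- paste0(paste(rec_lines, collapse = "\n"), "\n")
  receptor <- read_receptor(receptor_text)

  extent <- apply(planted_coords, 2, function(v) diff(range(v)))
  box <- docking_box(centroid, pmax(8, extent + 4))

  planted_pose <- conformation(flat$root_centroid, c(1, 0, 0, 0),
                               rep(0, nrot))
  ctx <- receptor_context(flat, receptor)
  planted_e <- score_direct(flat, planted_pose, ctx)$e

  if (check_samples > 0) {
    es <- vapply(seq_len(check_samples), function(s)
      score_direct(flat, random_conformation(box, nrot), ctx)$e, numeric(1))
    if (planted_e > min(es))
      stop("planted pose is not the sampled minimum (planted ",
           signif(planted_e, 6), " > best random ", signif(min(es), 6), ")",
           call. = FALSE)
  }

  structure(list(receptor_text = receptor_text, ligand_text = ligand_text,
                 box = box, planted_pose = planted_pose,
                 planted_coords = planted_coords,
                 receptor = receptor, ligand = ligand, flat = flat,
                 planted_e = planted_e, natom = natom, nrot = nrot,
                 seed = as.integer(seed)),
            class = "planted_complex")
}

#' @export
print.planted_complex <- function(x, ...) {
  cat(sprintf(
    "synthetic planted complex: %d ligand atoms, %d rotatable bonds, %d receptor atoms\n",
    x$natom, x$nrot, nrow(x$receptor$atoms)))
  cat(sprintf("  planted grid-free score: %.3f kcal/mol\n", x$planted_e))
  invisible(x)
}

#' Write fixture PDBQT and config files to a directory
#'
#' @param cx a `"planted_complex"`.
#' @param dir output directory (created if needed).
#' @return Named paths of the written receptor, ligand and config files.
#' @export
write_fixture_files <- function(cx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- file.path(dir, "receptor.pdbqt")
  lig <- file.path(dir, "ligand.pdbqt")
  cfg <- file.path(dir, "config.txt")
  writeLines(sub("\n$", "", cx$receptor_text), rec)
  writeLines(sub("\n$", "", cx$ligand_text), lig)
  writeLines(c(
    sprintf("receptor = %s", rec),
    sprintf("ligand = %s", lig),
    sprintf("center_x = %.3f", cx$box$center[1]),
    sprintf("center_y = %.3f", cx$box$center[2]),
    sprintf("center_z = %.3f", cx$box$center[3]),
    sprintf("size_x = %.3f", cx$box$size[1]),
    sprintf("size_y = %.3f", cx$box$size[2]),
    sprintf("size_z = %.3f", cx$box$size[3])), cfg)
  c(receptor = rec, ligand = lig, config = cfg)
}

#' Generate two synthetic compound rankings with controlled overlap
#'
#' Builds two rankings of `n` synthetic compound ids whose top-i Jaccard
#' index approximates `overlap` at i = n/10 (exactly identical rankings
#' when `overlap` is 1).
#'
#' @param n universe size.
#' @param overlap target top-decile Jaccard index in `[0, 1]`.
#' @param seed integer seed.
#' @return List with ranked id vectors `a` and `b`.
#' @export
make_ranked_universe <- function(n, overlap, seed = 1L) {
  stopifnot(n >= 10, overlap >= 0, overlap <= 1)
  set.seed(as.integer(seed))
  ids <- sprintf("CPD%05d", seq_len(n))
  a <- sample(ids)
  if (overlap == 1) return(list(a = a, b = a))
  i0 <- max(1L, floor(n / 10))
  m <- round(2 * i0 * overlap / (1 + overlap))
  top_a <- a[seq_len(i0)]
  rest_a <- a[(i0 + 1):n]
  b_top <- c(sample(top_a, m), sample(rest_a, i0 - m))
  b_top <- sample(b_top)
  b_rest <- sample(setdiff(ids, b_top))
  list(a = a, b = c(b_top, b_rest))
}
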