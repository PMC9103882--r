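#' @title PDBQT and config file input/output
#' @name pdbqt_io
#' @description Reader/writer for the AutoDock PDBQT dialect (rigid receptors,
#'   torsion-tree ligands, multi-pose MODEL output) and the Vina-style
#'   `key = value` config file.
#'
#' Atom records follow the AutoDock fixed-column layout: coordinates are read
#' from columns 31-54, the partial charge from columns 67-76 and the AutoDock
#' atom type from the final whitespace-separated token of the line.
NULL

# ---- atom records -----------------------------------------------------------

parse_atom_line <- function(line, lineno) {
  field <- function(a, b) trimws(substr(line, a, b))
  serial <- suppressWarnings(as.integer(field(7, 11)))
  x <- suppressWarnings(as.numeric(field(31, 38)))
  y <- suppressWarnings(as.numeric(field(39, 46)))
  z <- suppressWarnings(as.numeric(field(47, 54)))
  q <- suppressWarnings(as.numeric(field(67, 76)))
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  type <- toks[length(toks)]
  if (is.na(serial) || is.na(x) || is.na(y) || is.na(z))
    stop("malformed PDBQT atom record at line ", lineno, ": '", line, "'",
         call. = FALSE)
  if (!nzchar(type))
    stop("missing atom type in PDBQT record at line ", lineno, call. = FALSE)
  list(serial = serial, name = field(13, 16), x = x, y = y, z = z,
       charge = if (is.na(q)) 0 else q, type = type)
}

is_atom_line <- function(lines) grepl("^(ATOM|HETATM)", lines)

atoms_df <- function(recs) {
  if (length(recs) == 0L)
    return(data.frame(serial = integer(), name = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      charge = numeric(), type = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    serial = vapply(recs, `[[`, integer(1), "serial"),
    name   = vapply(recs, `[[`, character(1), "name"),
    x = vapply(recs, `[[`, numeric(1), "x"),
    y = vapply(recs, `[[`, numeric(1), "y"),
    z = vapply(recs, `[[`, numeric(1), "z"),
    charge = vapply(recs, `[[`, numeric(1), "charge"),
    type   = vapply(recs, `[[`, character(1), "type"),
    stringsAsFactors = FALSE)
}

as_text_lines <- function(text) {
  if (length(text) == 1L && (grepl("\n", text) || file.exists(text))) {
    if (file.exists(text)) return(readLines(text, warn = FALSE))
    return(strsplit(text, "\n", fixed = TRUE)[[1]])
  }
  text
}

#' Read a rigid receptor from PDBQT text
#'
#' Every ATOM/HETATM record becomes one atom, in file order; all other
#' records are ignored.  The receptor is treated as rigid throughout docking.
#'
#' @param text PDBQT content: a file path, a single string, or a character
#'   vector of lines.
#' @return An object of class `"receptor"`: a list with element `atoms`, a
#'   data frame with columns serial, name, x, y, z, charge, type.
#' @export
read_receptor <- function(text) {
  lines <- as_text_lines(text)
  sel <- which(is_atom_line(lines))
  if (length(sel) == 0L)
    stop("no ATOM/HETATM records found: empty receptor input", call. = FALSE)
  atoms <- atoms_df(lapply(sel, function(i) parse_atom_line(lines[i], i)))
  if (anyDuplicated(atoms$serial))
    warning("duplicate atom serial numbers in receptor")
  structure(list(atoms = atoms), class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  cat("PDBQT receptor:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$type)), "atom types\n")
  invisible(x)
}

# ---- ligand torsion tree ----------------------------------------------------

#' Read a torsion-tree ligand from PDBQT text
#'
#' Parses the ROOT/ENDROOT and (nested) BRANCH/ENDBRANCH records into a
#' recursive tree.  The number of rotatable bonds `nrot` is always derived
#' from the BRANCH count; a conflicting TORSDOF record produces a warning.
#' When the text holds several MODEL blocks only the first is read.
#'
#' @inheritParams read_receptor
#' @return An object of class `"ligand_tree"`: list with `root_atoms`
#'   (data frame), `branches` (recursive list of nodes, each with
#'   `parent_serial`, `child_serial`, `atoms`, `children`), `torsdof`,
#'   `nrot`, `natom` and `atoms` (all atoms in file = depth-first order).
#' @export
read_ligand <- function(text) {
  lines <- as_text_lines(text)
  m <- grep("^MODEL", lines)
  if (length(m) > 0L) {
    e <- grep("^ENDMDL", lines)
    if (length(e) == 0L) stop("MODEL record without ENDMDL", call. = FALSE)
    if (length(m) > 1L)
      message("multi-model ligand input: reading first MODEL only")
    lines <- lines[(m[1] + 1L):(e[1] - 1L)]
  }

  seen <- integer(0)  # serials defined so far
  i <- 1L
  n <- length(lines)
  nbranch <- 0L
  torsdof <- NA_integer_

  read_atoms_until <- function(stop_re) {
    recs <- list()
    while (i <= n && !grepl(stop_re, lines[i])) {
      if (is_atom_line(lines[i])) {
        rec <- parse_atom_line(lines[i], i)
        recs[[length(recs) + 1L]] <- rec
        seen <<- c(seen, rec$serial)
      } else if (grepl("^(BRANCH|ENDBRANCH|ROOT|ENDROOT)", lines[i])) {
        break
      }
      i <<- i + 1L
    }
    recs
  }

  parse_branch <- function() {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(hdr) < 3L)
      stop("malformed BRANCH record at line ", i, call. = FALSE)
    pa <- as.integer(hdr[2]); ch <- as.integer(hdr[3])
    if (!(pa %in% seen))
      stop("BRANCH axis atom ", pa, " not yet defined at line ", i,
           call. = FALSE)
    nbranch <<- nbranch + 1L
    i <<- i + 1L
    recs <- list(); children <- list()
    repeat {
      if (i > n) stop("unbalanced BRANCH/ENDBRANCH: unexpected end of input",
                      call. = FALSE)
      ln <- lines[i]
      if (is_atom_line(ln)) {
        rec <- parse_atom_line(ln, i)
        recs[[length(recs) + 1L]] <- rec
        seen <<- c(seen, rec$serial)
        i <<- i + 1L
      } else if (grepl("^BRANCH", ln)) {
        children[[length(children) + 1L]] <- parse_branch()
      } else if (grepl("^ENDBRANCH", ln)) {
        i <<- i + 1L
        break
      } else {
        i <<- i + 1L
      }
    }
    if (!(ch %in% vapply(recs, `[[`, integer(1), "serial")))
      stop("BRANCH child axis atom ", ch, " is not an atom of its own node",
           call. = FALSE)
    list(parent_serial = pa, child_serial = ch,
         atoms = atoms_df(recs), children = children)
  }

  root_atoms <- NULL
  branches <- list()
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^ROOT", ln)) {
      i <- i + 1L
      recs <- list()
      while (i <= n && !grepl("^ENDROOT", lines[i])) {
        if (is_atom_line(lines[i])) {
          rec <- parse_atom_line(lines[i], i)
          recs[[length(recs) + 1L]] <- rec
          seen <- c(seen, rec$serial)
        }
        i <- i + 1L
      }
      if (i > n) stop("ROOT without ENDROOT", call. = FALSE)
      i <- i + 1L
      root_atoms <- atoms_df(recs)
    } else if (grepl("^BRANCH", ln)) {
      if (is.null(root_atoms))
        stop("BRANCH record before ROOT block", call. = FALSE)
      branches[[length(branches) + 1L]] <- parse_branch()
    } else if (grepl("^ENDBRANCH", ln)) {
      stop("unbalanced BRANCH/ENDBRANCH: stray ENDBRANCH at line ", i,
           call. = FALSE)
    } else if (grepl("^TORSDOF", ln)) {
      torsdof <- as.integer(strsplit(trimws(ln), "\\s+")[[1]][2])
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }

  if (is.null(root_atoms)) {
    # rigid ligand written without ROOT markers: treat all atoms as root
    sel <- which(is_atom_line(lines))
    if (length(sel) == 0L)
      stop("no atoms found: empty ligand input", call. = FALSE)
    root_atoms <- atoms_df(lapply(sel, function(j) parse_atom_line(lines[j], j)))
  }
  if (nrow(root_atoms) == 0L)
    stop("ligand ROOT block contains no atoms", call. = FALSE)

  all_atoms <- collect_tree_atoms(root_atoms, branches)
  if (anyDuplicated(all_atoms$serial))
    stop("duplicate atom serial numbers in ligand", call. = FALSE)
  if (!is.na(torsdof) && torsdof != nbranch)
    warning("TORSDOF (", torsdof, ") disagrees with BRANCH count (", nbranch,
            "); using BRANCH count")
  structure(list(root_atoms = root_atoms, branches = branches,
                 torsdof = torsdof, nrot = nbranch,
                 natom = nrow(all_atoms), atoms = all_atoms),
            class = "ligand_tree")
}

collect_tree_atoms <- function(root_atoms, branches) {
  out <- list(root_atoms)
  walk <- function(node) {
    out[[length(out) + 1L]] <<- node$atoms
    for (ch in node$children) walk(ch)
  }
  for (b in branches) walk(b)
  do.call(rbind, out)
}

#' @export
print.ligand_tree <- function(x, ...) {
  cat("PDBQT ligand: ", x$natom, " atoms, ", x$nrot,
      " rotatable bonds (BRANCH records)\n", sep = "")
  invisible(x)
}

# ---- docking box ------------------------------------------------------------

#' Construct a docking box
#'
#' @param center numeric length-3, box center in Angstrom.
#' @param size numeric length-3, box edge lengths in Angstrom (all > 0).
#' @return Object of class `"docking_box"` with elements `center` and `size`.
#' @export
docking_box <- function(center, size) {
  center <- as.numeric(center); size <- as.numeric(size)
  stopifnot(length(center) == 3L, length(size) == 3L)
  if (!all(is.finite(center)) || !all(is.finite(size)))
    stop("docking box center/size must be finite", call. = FALSE)
  if (any(size <= 0))
    stop("docking box sizes must be positive", call. = FALSE)
  structure(list(center = center, size = size), class = "docking_box")
}

box_lo <- function(box) box$center - box$size / 2
box_hi <- function(box) box$center + box$size / 2

# ---- config file ------------------------------------------------------------

#' Parse a Vina-style config file
#'
#' Recognized keys: `receptor`, `ligand`, `center_x/y/z`, `size_x/y/z`,
#' `out`, `thread`, `search_depth`, `seed`.  Keys are case-sensitive, the
#' separator is `=` with optional whitespace, and when a key repeats the
#' last value wins (with a warning).  Unknown keys are rejected.  All six
#' box keys are required.
#'
#' @inheritParams read_receptor
#' @return A list with `box` (a [docking_box()]) plus any of `receptor`,
#'   `ligand`, `out` (character) and `thread`, `search_depth`, `seed`
#'   (integer, `NULL` when absent; resolved later by defaults or the
#'   search-depth heuristic).
#' @export
parse_config <- function(text) {
  lines <- as_text_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  known <- c("receptor", "ligand", "center_x", "center_y", "center_z",
             "size_x", "size_y", "size_z", "out", "thread", "search_depth",
             "seed")
  vals <- list()
  for (k in seq_along(lines)) {
    ln <- lines[k]
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) != 3L)
      stop("config line ", k, " is not 'key = value': '", ln, "'",
           call. = FALSE)
    key <- m[2]; val <- m[3]
    if (!(key %in% known))
      stop("unknown config key '", key, "'", call. = FALSE)
    if (!is.null(vals[[key]]))
      warning("duplicate config key '", key, "': last value wins")
    vals[[key]] <- val
  }
  boxkeys <- c("center_x", "center_y", "center_z", "size_x", "size_y", "size_z")
  missing <- setdiff(boxkeys, names(vals))
  if (length(missing) > 0L)
    stop("config is missing required box keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(vals[[k]]))
    if (is.na(v)) stop("config key '", k, "' is not numeric", call. = FALSE)
    v
  }
  box <- docking_box(c(num("center_x"), num("center_y"), num("center_z")),
                     c(num("size_x"), num("size_y"), num("size_z")))
  int_or_null <- function(k)
    if (is.null(vals[[k]])) NULL else as.integer(num(k))
  list(box = box,
       receptor = vals$receptor, ligand = vals$ligand, out = vals$out,
       thread = int_or_null("thread"),
       search_depth = int_or_null("search_depth"),
       seed = int_or_null("seed"))
}

# ---- pose output ------------------------------------------------------------

format_atom_line <- function(record, serial, name, x, y, z, charge, type) {
  sprintf("%-6s%5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          record, serial, name, "LIG", "A", 1L, x, y, z, 1.00, 0.00,
          charge, type)
}

ligand_structure_lines <- function(ligand, coords) {
  idx <- 0L
  atom_lines <- function(df) {
    vapply(seq_len(nrow(df)), function(r) {
      idx <<- idx + 1L
      format_atom_line("ATOM", df$serial[r], df$name[r],
                       coords[idx, 1], coords[idx, 2], coords[idx, 3],
                       df$charge[r], df$type[r])
    }, character(1))
  }
  out <- c("ROOT", atom_lines(ligand$root_atoms), "ENDROOT")
  walk <- function(node) {
    res <- c(sprintf("BRANCH %3d %3d", node$parent_serial, node$child_serial),
             atom_lines(node$atoms))
    for (ch in node$children) res <- c(res, walk(ch))
    c(res, sprintf("ENDBRANCH %3d %3d", node$parent_serial, node$child_serial))
  }
  for (b in ligand$branches) out <- c(out, walk(b))
  c(out, sprintf("TORSDOF %d", ligand$nrot))
}

#' Write docked poses as multi-MODEL PDBQT text
#'
#' One MODEL/ENDMDL block per pose, each preceded by a
#' `REMARK DOCKING SCORE <value>` line (kcal/mol, 3 decimals) and carrying
#' the pose's realized Cartesian coordinates in the ligand's BRANCH
#' structure.  Poses must be sorted by ascending energy.
#'
#' @param ligand a `"ligand_tree"` from [read_ligand()].
#' @param poses list of scored poses (each with elements `coords` and `e`,
#'   optionally `score` which then takes precedence in the REMARK line).
#' @return A single string of PDBQT text (empty, with a warning, for zero
#'   poses).
#' @export
write_poses <- function(ligand, poses) {
  if (length(poses) == 0L) {
    warning("no poses to write: producing empty output")
    return("")
  }
  sc <- vapply(poses, function(p) if (!is.null(p$score)) p$score else p$e,
               numeric(1))
  if (is.unsorted(sc + 1e-9 * seq_along(sc) * 0))  # exact order check
    if (any(diff(sc) < -1e-9))
      stop("poses must be sorted by ascending energy", call. = FALSE)
  out <- character(0)
  for (k in seq_along(poses)) {
    p <- poses[[k]]
    if (nrow(p$coords) != ligand$natom)
      stop("pose ", k, " has ", nrow(p$coords), " atoms but ligand has ",
           ligand$natom, call. = FALSE)
    out <- c(out,
             sprintf("MODEL %d", k),
             sprintf("REMARK DOCKING SCORE %8.3f", sc[k]),
             ligand_structure_lines(ligand, p$coords),
             "ENDMDL")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
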