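#' @title Host-side post-processing of docking threads
#' @name results_refine
#' @description Aggregates the best pose of every docking thread, sorts by
#'   docking score, removes near-duplicate poses by an RMSD radius, refines
#'   the top poses with grid-free BFGS (direct receptor pair sums, no
#'   interpolation error), and provides the rank-comparison utilities used
#'   in virtual-screening workflows (top-i Jaccard index, runtime
#'   acceleration ratios).
NULL

#' Cluster and sort thread results into a pose table
#'
#' All best poses are sorted by ascending energy (ties broken by thread
#' index); a pose is kept iff its RMSD to every already-kept pose is at
#' least `dedup_rmsd`.
#'
#' @param results a `"thread_results"` list (or list of `"thread_result"`).
#' @param dedup_rmsd de-duplication radius in Angstrom (default 1.0).
#' @return Object of class `"pose_table"`: list with `poses` (list of
#'   `"scored_pose"`, non-decreasing energies) and `dedup_rmsd`.
#' @export
cluster_and_sort <- function(results, dedup_rmsd = 1.0) {
  if (length(results) == 0L)
    stop("no thread results to cluster", call. = FALSE)
  poses <- lapply(results, function(r) r$best_pose)
  tidx <- vapply(results, function(r) r$thread_index, numeric(1))
  es <- vapply(poses, function(p) p$e, numeric(1))
  ord <- order(es, tidx)
  kept <- list()
  for (k in ord) {
    ok <- TRUE
    for (p in kept) {
      if (rmsd(poses[[k]]$coords, p$coords) < dedup_rmsd) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept[[length(kept) + 1L]] <- poses[[k]]
  }
  structure(list(poses = kept, dedup_rmsd = dedup_rmsd),
            class = "pose_table")
}

#' @export
print.pose_table <- function(x, ...) {
  es <- vapply(x$poses, function(p) p$e, numeric(1))
  cat(sprintf("pose table: %d poses, e in [%.3f, %.3f] kcal/mol\n",
              length(es), min(es), max(es)))
  invisible(x)
}

#' Refine the top poses with grid-free BFGS
#'
#' For the best `min(k, size)` poses the energy is re-minimized using
#' direct (grid-free) intermolecular sums with a doubled iteration cap,
#' removing the grid interpolation error; all pose energies are restated on
#' the grid-free scale, refined poses replace the originals only when the
#' energy does not increase, and the table is re-sorted.
#'
#' @param table a `"pose_table"`.
#' @param flat a `"flat_ligand"`.
#' @param receptor a `"receptor"` (or a precomputed [receptor_context()]).
#' @param k number of poses to refine (default 20).
#' @param max_iters BFGS budget for refinement (default 60 = doubled
#'   search-stage cap).
#' @return The refined, re-sorted `"pose_table"` with a `refined` flag per
#'   pose; energies are grid-free and never increase through refinement.
#' @export
refine_top <- function(table, flat, receptor, k = 20L, max_iters = 60L) {
  stopifnot(k >= 1)
  ctx <- if (inherits(receptor, "receptor"))
    receptor_context(flat, receptor) else receptor
  poses <- table$poses
  ntop <- min(k, length(poses))
  for (m in seq_along(poses)) {
    p0 <- score_direct(flat, poses[[m]]$conformation, ctx)
    if (m <= ntop) {
      res <- bfgs_minimize(flat, NULL, poses[[m]]$conformation,
                           max_iters = max_iters, ctx = ctx)
      if (res$e <= p0$e) {
        p0 <- res$pose
        p0$refined <- TRUE
      }
    }
    poses[[m]] <- p0
  }
  es <- vapply(poses, function(p) p$e, numeric(1))
  structure(list(poses = poses[order(es)], dedup_rmsd = table$dedup_rmsd),
            class = "pose_table")
}

#' Top-i Jaccard index between two compound rankings
#'
#' J_i = |top_i(A) n top_i(B)| / |top_i(A) u top_i(B)| over the top-i
#' compound identifiers of two ranked lists of the same universe.
#'
#' @param scores_a,scores_b ranked (best-first) compound id vectors.
#' @param i depth of the comparison (>= 1).
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_top_i <- function(scores_a, scores_b, i) {
  if (i < 1) stop("i must be at least 1", call. = FALSE)
  if (i > length(scores_a) || i > length(scores_b))
    stop("i exceeds the ranked-universe size", call. = FALSE)
  ta <- scores_a[seq_len(i)]
  tb <- scores_b[seq_len(i)]
  length(intersect(ta, tb)) / length(union(ta, tb))
}

#' Runtime acceleration ratio
#'
#' `t_ref / t_new`: the fold speed-up of a new runtime against a reference
#' runtime (used both for total and for search-stage-only timings).
#'
#' @param t_ref reference runtime, seconds (> 0).
#' @param t_new new runtime, seconds (> 0).
#' @return The acceleration ratio.
#' @export
acceleration <- function(t_ref, t_new) {
  if (any(c(t_ref, t_new) <= 0))
    stop("runtimes must be positive", call. = FALSE)
  t_ref / t_new
}

#' Write a ranked-score table as tab-separated text
#'
#' @param ids compound identifiers.
#' @param scores docking scores (kcal/mol), same length as `ids`.
#' @param path output file path.
#' @export
export_ranked_scores <- function(ids, scores, path) {
  stopifnot(length(ids) == length(scores))
  ord <- order(scores)
  utils::write.table(
    data.frame(compound = ids[ord], score = sprintf("%.3f", scores[ord])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
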