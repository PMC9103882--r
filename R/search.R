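#' @title Massively parallel reduced-depth Monte-Carlo docking search
#' @name montecarlo_search
#' @description Many independent docking threads, each a reduced-depth
#'   Monte-Carlo iterated local search: mutate one POT block, optimize with
#'   BFGS, accept via the Metropolis criterion (constant 1.2 kcal/mol), and
#'   re-optimize on acceptance.  Each thread starts from its own uniformly
#'   random conformation -- its representative of one subspace of the full
#'   conformational search space -- and owns a private RNG substream keyed
#'   by (master seed, thread index), so the result set is bitwise identical
#'   regardless of execution order or degree of actual parallelism.
NULL

#' Search hyperparameters
#'
#' @param thread number of independent docking threads (default 8000, the
#'   converged setting for medium/large complexes).
#' @param search_depth Monte-Carlo iterations per thread; `NULL` means
#'   "resolve later" via [heuristic_search_depth()] from the ligand sizes.
#' @param metropolis_constant denominator of the acceptance probability
#'   (kcal/mol, default 1.2).
#' @param k_out number of output poses kept after clustering (default 20).
#' @param master_seed integer master seed; every thread derives its own
#'   substream from (master_seed, thread_index).
#' @param mutation a [mutation_params()].
#' @return Object of class `"search_params"`.
#' @export
search_params <- function(thread = 8000L, search_depth = NULL,
                          metropolis_constant = 1.2, k_out = 20L,
                          master_seed = 0L, mutation = mutation_params()) {
  stopifnot(thread >= 1, metropolis_constant > 0, k_out >= 1)
  if (!is.null(search_depth)) stopifnot(search_depth >= 1)
  structure(list(thread = as.integer(thread),
                 search_depth = if (is.null(search_depth)) NULL
                                else as.integer(search_depth),
                 metropolis_constant = metropolis_constant,
                 k_out = as.integer(k_out),
                 master_seed = as.integer(master_seed),
                 mutation = mutation),
            class = "search_params")
}

#' Metropolis acceptance probability
#'
#' P = 1 when the optimized energy improves on the current one
#' (e0 > eopt); otherwise P = exp((e0 - eopt) / constant), so
#' energy-increasing moves are accepted with exponentially decaying
#' probability.
#'
#' @param e0 energy of the current (pre-mutation) conformation, kcal/mol.
#' @param eopt energy of the candidate after optimization, kcal/mol.
#' @param constant Metropolis constant (kcal/mol, default 1.2).
#' @return Acceptance probability in (0, 1].
#' @export
metropolis_probability <- function(e0, eopt, constant = 1.2) {
  stopifnot(is.finite(e0) || e0 == Inf, is.finite(eopt))
  if (e0 > eopt) 1 else exp((e0 - eopt) / constant)
}

#' Heuristic per-thread search depth
#'
#' Empirical formula fitted so that the per-thread iteration count scales
#' with ligand complexity: `max(1, floor(0.24 Natom + 0.29 Nrot - 3.41))`.
#'
#' @param natom number of ligand atoms.
#' @param nrot number of rotatable bonds.
#' @return Integer search depth (at least 1).
#' @export
heuristic_search_depth <- function(natom, nrot) {
  stopifnot(natom >= 1, nrot >= 0)
  as.integer(pmax(1, floor(0.24 * natom + 0.29 * nrot - 3.41)))
}

#' Split a total iteration budget over threads
#'
#' Nearest integer to total/threads (half rounded up), at least 1: used to
#' trade thread count against per-thread depth at a fixed total number of
#' search iterations.
#'
#' @param total_steps total search iterations.
#' @param n_threads number of threads.
#' @return Integer per-thread depth.
#' @export
split_depth <- function(total_steps, n_threads) {
  stopifnot(n_threads >= 1, total_steps >= n_threads)
  as.integer(max(1, floor(total_steps / n_threads + 0.5)))
}

# private, order-independent RNG substream per (master_seed, thread_index)
thread_seed <- function(master_seed, thread_index) {
  s <- ((as.numeric(master_seed) %% 65521) * 32749 +
          as.numeric(thread_index) * 7919 + 13) %% 2147483647
  as.integer(s)
}

#' Run one docking thread
#'
#' One reduced-depth Monte-Carlo iterated local search (`search_depth`
#' iterations): mutate the current conformation in one random POT block,
#' BFGS-optimize and score the candidate, accept on the first iteration or
#' by the Metropolis criterion, and on acceptance BFGS-optimize once more
#' (the second optimization replaces the current conformation only when it
#' does not increase the energy).  Tracks the best pose the thread ever
#' scored.
#'
#' @param flat a `"flat_ligand"`.
#' @param cache a `"grid_cache"`.
#' @param box the [docking_box()].
#' @param params a [search_params()] with `search_depth` resolved.
#' @param thread_index 1-based thread index (selects the RNG substream).
#' @return Object of class `"thread_result"`: list with `thread_index`,
#'   `best_pose`, `n_accepted`.
#' @export
run_docking_thread <- function(flat, cache, box, params, thread_index) {
  if (is.null(params$search_depth))
    stop("search_depth must be resolved before running threads",
         call. = FALSE)
  thread_index <- as.integer(thread_index)
  set.seed(thread_seed(params$master_seed, thread_index))
  cur <- random_conformation(box, flat$nrot)
  e_cur <- Inf
  best <- NULL
  n_acc <- 0L
  for (step in seq_len(params$search_depth)) {
    cand_conf <- mutate_conformation(cur, params$mutation, box)
    opt <- bfgs_minimize(flat, cache, cand_conf)
    if (is.null(best) || opt$e < best$e) best <- opt$pose
    accept <- step == 1L ||
      stats::runif(1) < metropolis_probability(e_cur, opt$e,
                                               params$metropolis_constant)
    if (accept) {
      n_acc <- n_acc + 1L
      cur <- opt$conformation
      e_cur <- opt$e
      opt2 <- bfgs_minimize(flat, cache, cur)
      if (opt2$e <= e_cur) {
        cur <- opt2$conformation
        e_cur <- opt2$e
      }
      if (opt2$e < best$e) best <- opt2$pose
    }
  }
  structure(list(thread_index = thread_index, best_pose = best,
                 n_accepted = n_acc),
            class = "thread_result")
}

#' Run the full multi-thread docking search
#'
#' Launches `params$thread` independent docking threads.  Every thread is
#' seeded from its own (master_seed, thread_index) substream, so the result
#' set does not depend on execution order.
#'
#' @inheritParams run_docking_thread
#' @param thread_order optional permutation of 1:thread in which to execute
#'   the threads (results are identical for any order).
#' @return List of `"thread_result"` objects (class `"thread_results"`),
#'   ordered by thread index.
#' @export
run_search <- function(flat, cache, box, params, thread_order = NULL) {
  idx <- seq_len(params$thread)
  if (is.null(thread_order)) thread_order <- idx
  stopifnot(setequal(thread_order, idx))
  out <- vector("list", params$thread)
  for (ti in thread_order)
    out[[ti]] <- run_docking_thread(flat, cache, box, params, ti)
  structure(out, class = "thread_results")
}

#' @export
print.thread_results <- function(x, ...) {
  es <- vapply(x, function(r) r$best_pose$e, numeric(1))
  cat(sprintf("docking search: %d threads, best e = %.3f kcal/mol\n",
              length(x), min(es)))
  invisible(x)
}
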