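#' @title BFGS quasi-Newton minimization over the POT vector
#' @name bfgs_optimizer
#' @description Minimizes the scoring function over the (7+Nrot)-dimensional
#'   POT vector with the classic inverse-Hessian BFGS rank-two update,
#'   starting from the identity matrix.  The exact line minimization is
#'   replaced by Armijo backtracking (c = 1e-4, halving, at most 10 trials),
#'   which preserves the descent contract; the quaternion block is
#'   re-normalized after each accepted step (energy-neutral, since the
#'   score is invariant to quaternion norm).
NULL

#' Inverse-Hessian BFGS update
#'
#' The standard rank-two inverse-BFGS update.  The update divides by
#' (s'y)^2, so it is applied only when the curvature s'y exceeds
#' 1e-12 * |s| * |y|; otherwise the matrix is returned unchanged with
#' attribute `skipped = TRUE`.
#'
#' @param Binv current approximate inverse Hessian (symmetric).
#' @param s_k step vector (x_{k+1} - x_k).
#' @param y_k gradient difference (g_{k+1} - g_k).
#' @return Updated symmetric inverse Hessian satisfying the secant
#'   condition `Binv %*% y_k == s_k` (when applied).
#' @export
bfgs_update <- function(Binv, s_k, y_k) {
  sy <- sum(s_k * y_k)
  guard <- 1e-12 * sqrt(sum(s_k^2)) * sqrt(sum(y_k^2))
  if (!is.finite(sy) || sy <= guard) {
    out <- Binv
    attr(out, "skipped") <- TRUE
    return(out)
  }
  By <- as.numeric(Binv %*% y_k)
  yBy <- sum(y_k * By)
  out <- Binv + ((sy + yBy) / sy^2) * tcrossprod(s_k) -
    (tcrossprod(By, s_k) + tcrossprod(s_k, By)) / sy
  out <- (out + t(out)) / 2   # enforce exact symmetry
  attr(out, "skipped") <- FALSE
  out
}

# Armijo backtracking: first alpha in {1, 1/2, ..., 2^-9} with sufficient
# decrease f(x + a p) <= f0 + 1e-4 * a * g'p; 0 when all trials fail.
armijo_ls <- function(fn, x, p, f0, g0) {
  gp <- sum(g0 * p)
  alpha <- 1
  for (trial in 1:10) {
    if (fn(x + alpha * p) <= f0 + 1e-4 * alpha * gp) return(alpha)
    alpha <- alpha / 2
  }
  0
}

# Generic dense-BFGS driver over a plain numeric vector.
# project(): applied to the iterate after each accepted step (used to
# re-normalize the quaternion block); must not change fn(x).
# ls: optional line-search override fn(fn, x, p, f0, g0) -> alpha.
# fgr: optional combined objective+gradient (saves one evaluation per
# iterate when both share expensive intermediates).
bfgs_core <- function(x0, fn, gr, max_iters = 30, gtol = 1e-6,
                      project = NULL, ls = armijo_ls, fgr = NULL) {
  if (is.null(fgr)) fgr <- function(x) list(e = fn(x), g = gr(x))
  x <- x0
  st <- fgr(x)
  f0 <- st$e
  g <- st$g
  n <- length(x)
  Binv <- diag(n)
  iters <- 0L
  converged <- FALSE
  while (iters < max_iters) {
    if (sqrt(sum(g * g)) < gtol) {
      converged <- TRUE
      break
    }
    p <- -as.numeric(Binv %*% g)
    if (sum(g * p) >= 0) {        # not a descent direction: steepest reset
      p <- -g
      Binv <- diag(n)
    }
    alpha <- ls(fn, x, p, f0, g)
    if (alpha <= 0) break
    x1 <- x + alpha * p
    if (!is.null(project)) x1 <- project(x1)
    st <- fgr(x1)
    Binv <- bfgs_update(Binv, x1 - x, st$g - g)
    x <- x1; f0 <- st$e; g <- st$g
    iters <- iters + 1L
  }
  list(x = x, f = f0, g = g, iters = iters, converged = converged)
}

#' Backtracking line search along a descent direction
#'
#' Returns the first step size alpha in {1, 1/2, 1/4, ...} (at most 10
#' trials) satisfying the sufficient-decrease condition
#' `SF(C + alpha p) <= SF(C) + 1e-4 * alpha * grad'p`; 0 signals failure.
#' A non-descent direction is reset to the negative gradient first.
#'
#' @param flat a `"flat_ligand"`.
#' @param cache a `"grid_cache"`.
#' @param conf the current [conformation()].
#' @param p_k search direction over the POT vector (length 7 + Nrot).
#' @param grad gradient at `conf` (length 7 + Nrot).
#' @return The accepted step size (0 when all trials fail).
#' @export
line_search <- function(flat, cache, conf, p_k, grad) {
  x <- conf_to_vector(conf)
  fn <- function(v) score_pose(flat, vector_to_conf(v, flat$nrot), cache)$e
  if (sum(grad * p_k) >= 0) p_k <- -grad
  armijo_ls(fn, x, p_k, fn(x), grad)
}

normalize_q_block <- function(x) {
  x[4:7] <- quat_normalize(x[4:7])
  x
}

#' Minimize the docking score from a starting conformation
#'
#' Iterates `s_k = alpha_k p_k` with `p_k = -Binv %*% grad`, re-normalizing
#' the quaternion block after each accepted step.  Terminates at
#' `max_iters`, gradient norm below `gtol`, or a failed line search.  The
#' returned energy is never above the starting energy.
#'
#' @param flat a `"flat_ligand"`.
#' @param cache a `"grid_cache"` (grid pathway), or `NULL` when `ctx` is
#'   given.
#' @param c0 starting [conformation()].
#' @param max_iters BFGS iteration budget per call (default 30).
#' @param gtol gradient-norm termination threshold.
#' @param ctx optional [receptor_context()]: when supplied the grid-free
#'   (direct receptor sum) objective is minimized instead of the
#'   interpolated one, as used for host-side pose refinement.
#' @return List with `conformation`, `e` (final energy), `pose` (a
#'   `"scored_pose"`), `iters` and `converged`.
#' @export
bfgs_minimize <- function(flat, cache, c0, max_iters = 30, gtol = 1e-6,
                          ctx = NULL) {
  nrot <- flat$nrot
  if (is.null(ctx)) {
    fn <- function(v) score_pose(flat, vector_to_conf(v, nrot), cache)$e
    gr <- function(v) score_gradient(flat, vector_to_conf(v, nrot), cache)
    fgr <- function(v) score_and_gradient(flat, vector_to_conf(v, nrot),
                                          cache)
  } else {
    fn <- function(v) score_direct(flat, vector_to_conf(v, nrot), ctx)$e
    gr <- function(v) gradient_direct(flat, vector_to_conf(v, nrot), ctx)
    fgr <- function(v) score_and_gradient_direct(flat,
                                                 vector_to_conf(v, nrot), ctx)
  }
  res <- bfgs_core(conf_to_vector(c0), fn, gr, max_iters = max_iters,
                   gtol = gtol, project = normalize_q_block, fgr = fgr)
  conf <- vector_to_conf(normalize_q_block(res$x), nrot)
  pose <- if (is.null(ctx)) score_pose(flat, conf, cache)
          else score_direct(flat, conf, ctx)
  list(conformation = conf, e = pose$e, pose = pose,
       iters = res$iters, converged = res$converged)
}
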