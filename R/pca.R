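## Two-level principal-component engine.
##
## Level 1: per capture region, the first principal component (local PC)
## across samples of the centered normalized depth matrix, by power
## iteration. The iteration applies R then t(R) to a length-N vector, so it
## streams one column of the depth matrix at a time and never forms the
## M x M or N x N covariance matrix.
##
## Level 2: the first K right singular vectors of the stacked local PCs
## (regions x samples), by dense SVD -- slower but more accurate for the
## lower-order components. These global PCs capture cohort-wide technical
## structure (batch, GC) and are projected out of each local PC.

#' Center the columns of a matrix
#'
#' @param m numeric matrix.
#' @return `m` minus its per-column means.
#' @export
center_columns <- function(m) {
  sweep(m, 2L, colMeans(m), "-")
}

#' First principal component by power iteration
#'
#' Computes the dominant right singular direction of a column-centered
#' matrix: starting from a random vector with entries uniform on (0, 1),
#' repeat `t <- R v`, `v <- t(R) t / ||t(R) t||` until successive `v`
#' differ by less than `tol` in Euclidean norm. Because `R t(R) R v` is an
#' application of a positive semi-definite operator, the iterate's
#' orientation is stable and convergence is monotone in direction.
#'
#' @param m column-centered M x N numeric matrix (use [center_columns()]).
#' @param tol convergence tolerance on the change of the normalized vector.
#' @param max_iter iteration cap; non-convergence is reported, not an error.
#' @param seed optional integer seed for the random start (the caller's RNG
#'   state is untouched).
#' @return list with `vector` (length N, unit norm), `n_iterations`,
#'   `converged`.
#' @export
first_pc_power_iteration <- function(m, tol = 1e-8, max_iter = 1000L,
                                     seed = NULL) {
  if (all(m == 0)) stop("degenerate region: centered depth matrix is all zero")
  n <- ncol(m)
  v <- if (is.null(seed)) runif(n) else withr::with_seed(seed, runif(n))
  v <- v / sqrt(sum(v^2))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    t_vec <- m %*% v
    v_new <- crossprod(m, t_vec)
    nv <- sqrt(sum(v_new^2))
    if (nv == 0) {
      ## start vector orthogonal to the row space; reseed deterministically
      v <- withr::with_seed(if (is.null(seed)) it else seed + it, runif(n))
      v <- v / sqrt(sum(v^2))
      next
    }
    v_new <- v_new / nv
    delta <- sqrt(sum((v_new - v)^2))
    v <- as.numeric(v_new)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(vector = v, n_iterations = it, converged = converged)
}

#' Local PC of a normalized region depth matrix
#'
#' Centers the matrix, runs the power iteration, and canonicalizes the sign
#' so the component has non-negative inner product with the per-sample mean
#' of the uncentered matrix. The component is then positively oriented with
#' relative copy number, which keeps downstream genotype cluster order
#' stable.
#'
#' @param values M x N normalized depth matrix (uncentered).
#' @inheritParams first_pc_power_iteration
#' @return list with `vector`, `n_iterations`, `converged`.
#' @export
region_local_pc <- function(values, tol = 1e-8, max_iter = 1000L,
                            seed = NULL) {
  centered <- center_columns(values)
  pc <- first_pc_power_iteration(centered, tol = tol, max_iter = max_iter,
                                 seed = seed)
  if (sum(pc$vector * colMeans(values)) < 0) pc$vector <- -pc$vector
  pc
}

#' Global principal components of the stacked local PCs
#'
#' Column-centers the regions x samples stack and returns its first K right
#' singular vectors by dense SVD.
#'
#' @param stack R x N matrix of local PC vectors, one row per region.
#' @param K number of components (default 50).
#' @param center center columns before the SVD (default TRUE).
#' @param scale_rows standardize every row (center and rescale to unit
#'   norm across samples) before the SVD (default FALSE). Local PCs are
#'   unit vectors dominated by a shared mean-depth component; without
#'   standardization a single region with an extreme depth-variance
#'   direction -- a genuine common CNV -- can surface as its own global
#'   component, and the correction then removes real signal. Row
#'   standardization weights every region equally, confining the global
#'   PCs to structure shared across many regions, and makes every
#'   component exactly orthogonal to the constant vector, so projecting
#'   them out of depth profiles never disturbs the cohort-wide mean
#'   level. The scan pipeline enables it.
#' @return list with `components` (N x K orthonormal matrix, columns ordered
#'   by decreasing singular value), `singular_values` (length K,
#'   non-increasing) and `K`.
#' @export
compute_global_pcs <- function(stack, K = 50L, center = TRUE,
                               scale_rows = FALSE) {
  r <- nrow(stack)
  n <- ncol(stack)
  if (K > min(r, n)) {
    stop("K = ", K, " exceeds min(regions, samples) = ", min(r, n))
  }
  if (center) stack <- center_columns(stack)
  if (scale_rows) {
    stack <- stack - rowMeans(stack)
    norms <- sqrt(rowSums(stack^2))
    keep <- norms > 1e-12
    stack <- stack[keep, , drop = FALSE] / norms[keep]
  }
  sv <- svd(stack, nu = 0L, nv = K)
  comps <- sv$v[, seq_len(K), drop = FALSE]
  colnames(comps) <- paste0("GPC_", seq_len(K))
  list(components = comps, singular_values = sv$d[seq_len(K)], K = as.integer(K))
}

#' Project the first H global PCs out of a vector
#'
#' Returns `v - sum_h (<v, g_h> / <g_h, g_h>) g_h` over `h = 1..H`. The
#' Rayleigh-quotient form keeps the operator exact even if components are
#' not unit norm.
#'
#' @param v length-N numeric vector.
#' @param gpcs a global PC set from [compute_global_pcs()].
#' @param H number of leading components to remove, `0 <= H <= K`.
#' @return the adjusted length-N vector.
#' @export
project_out <- function(v, gpcs, H) {
  if (H < 0 || H > gpcs$K) stop("H must be in [0, K = ", gpcs$K, "]")
  if (H == 0) return(v)
  g <- gpcs$components[, seq_len(H), drop = FALSE]
  coef <- as.numeric(crossprod(g, v)) / colSums(g^2)
  as.numeric(v - g %*% coef)
}

#' Project the first H global PCs out of every row of a matrix
#'
#' Matrix form of [project_out()] applied to each row (a length-N vector
#' across samples); used for whole-scan adjustment and for window matrices.
#'
#' @param m R x N matrix (rows adjusted independently).
#' @inheritParams project_out
#' @return matrix of the same shape.
#' @export
project_out_rows <- function(m, gpcs, H) {
  if (H < 0 || H > gpcs$K) stop("H must be in [0, K = ", gpcs$K, "]")
  if (H == 0) return(m)
  g <- gpcs$components[, seq_len(H), drop = FALSE]
  gn <- sweep(g, 2L, colSums(g^2), "/")
  m - (m %*% gn) %*% t(g)
}
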