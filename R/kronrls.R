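# Kronecker-product-kernel regularized least squares.
#
# The pairwise kernel over (row, column) pairs is K = Kc (x) Kd with
# K[(i,j),(u,v)] = Kc[i,u] * Kd[j,v]. The closed form
#   vec(Yhat^T) = K (K + sigma I)^{-1} vec(Y^T)
# is solved two ways: explicitly (solve_naive, the test oracle, guarded to
# tiny instances) and via the per-side eigendecompositions with an
# elementwise spectral filter lambda / (lambda + sigma) (solve_eigen, the
# production path, never materializing the Nc*Nd system).

.naive_guard <- 4096L

#' Closed-form Kron-RLS solve on the explicit Kronecker system (oracle)
#'
#' Forms `K = Kc %x% Kd` explicitly and solves
#' `vec(Yhat^T) = K (K + sigma I)^{-1} vec(Y^T)` with column-stacking `vec`
#' (so `vec(Y^T)` enumerates `Y` row by row, matching the Kronecker pair
#' ordering). Exists as an independent oracle for [solve_eigen()]; guarded
#' to `Nc * Nd <= 4096`.
#'
#' @param Kc,Kd symmetric kernel matrices over rows and columns of `Y`.
#' @param Y association matrix (binary or augmented).
#' @param sigma ridge regularization, `> 0`.
#' @return prediction matrix aligned with `Y`.
#' @export
solve_naive <- function(Kc, Kd, Y, sigma) {
  stopifnot(sigma > 0)
  nc <- nrow(Y); nd <- ncol(Y)
  if (nc * nd > .naive_guard) {
    stop("instance too large for the explicit Kronecker solve; use solve_eigen()")
  }
  stopifnot(nrow(Kc) == nc, ncol(Kc) == nc, nrow(Kd) == nd, ncol(Kd) == nd)
  K <- unclass(Kc) %x% unclass(Kd)
  yv <- as.vector(t(unclass(Y)))  # vec(Y^T): row-major enumeration of Y
  yh <- K %*% solve(K + sigma * diag(nc * nd), yv)
  out <- t(matrix(yh, nrow = nd, ncol = nc))
  dimnames(out) <- dimnames(Y)
  out
}

#' Eigendecompose the two side kernels
#'
#' Kernels are symmetrized as `(K + t(K)) / 2` to absorb floating-point
#' asymmetry, then decomposed with `eigen(symmetric = TRUE)`. Reconstruction
#' `V diag(lambda) V^T` holds to 1e-8 in max-abs.
#'
#' @param Kc,Kd square kernel matrices.
#' @return list of class `"eigen_factorization"` with `eigvec_c`, `eigval_c`,
#'   `eigvec_d`, `eigval_d` and the dimnames of the inputs.
#' @export
eigendecompose <- function(Kc, Kd) {
  decomp <- function(K) {
    if (nrow(K) != ncol(K)) stop("kernel matrix must be square")
    K <- unclass(K)
    eigen((K + t(K)) / 2, symmetric = TRUE)
  }
  ec <- decomp(Kc)
  ed <- decomp(Kd)
  structure(list(eigvec_c = ec$vectors, eigval_c = ec$values,
                 eigvec_d = ed$vectors, eigval_d = ed$values,
                 row_ids = rownames(Kc), col_ids = rownames(Kd)),
            class = "eigen_factorization")
}

#' Kron-RLS solve through the spectral filter (production path)
#'
#' With `Kc = Vc Lc Vc^T` and `Kd = Vd Ld Vd^T`, the Kronecker system
#' diagonalizes: each coefficient of `Vd^T Y^T Vc` is scaled by
#' `f_ij = (lc_i * ld_j) / (lc_i * ld_j + sigma)` and the prediction is
#' `Yhat = Vc Z^T Vd^T`. Cost is two small eigendecompositions plus dense
#' products; the `Nc*Nd x Nc*Nd` system is never formed. Integrated disease
#' kernels may be indefinite; the only requirement is that no eigenvalue
#' product equals `-sigma`.
#'
#' @param ef an [eigendecompose()] factorization.
#' @param Y association matrix (binary or augmented).
#' @param sigma ridge regularization, `> 0`.
#' @return prediction matrix aligned with `Y`.
#' @export
solve_eigen <- function(ef, Y, sigma) {
  stopifnot(inherits(ef, "eigen_factorization"), sigma > 0)
  nc <- length(ef$eigval_c); nd <- length(ef$eigval_d)
  stopifnot(nrow(Y) == nc, ncol(Y) == nd)
  lam <- outer(ef$eigval_d, ef$eigval_c)        # nd x nc, lam[j, i] = ld_j * lc_i
  denom <- lam + sigma
  if (any(abs(denom) < 1e-12)) {
    bad <- which(abs(denom) < 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("near-singular spectral filter at eigenpair (c=%d, d=%d)",
                 bad[2], bad[1]))
  }
  M <- crossprod(ef$eigvec_d, t(unclass(Y))) %*% ef$eigvec_c  # Vd^T Y^T Vc
  Z <- (lam / denom) * M
  out <- ef$eigvec_c %*% t(Z) %*% t(ef$eigvec_d)
  dimnames(out) <- dimnames(Y)
  out
}

#' Full DWNN-RLS prediction pipeline
#'
#' Computes the GIP kernels from the binary training matrix, integrates the
#' disease-side kernel with the semantic similarity (when provided and mode
#' is `"mean_gip_semantic"`), fills cold-start rows/columns by the
#' decreasing-weight neighbour average, and solves the Kronecker RLS system
#' through the spectral filter. Deterministic given its inputs.
#'
#' @param Y binary association matrix with dimnames.
#' @param config a [run_config()].
#' @param sem optional precomputed semantic `kernel_matrix` over the columns
#'   of `Y` (see [disease_semantic_matrix()]); ignored in `gip_only` mode.
#' @return prediction matrix aligned with `Y`.
#' @examples
#' sim <- generate_associations(synthetic_spec(n_circ = 20, n_disease = 12, seed = 7))
#' scores <- dwnn_rls(sim$Y, run_config())
#' @export
dwnn_rls <- function(Y, config = run_config(), sem = NULL) {
  Sc <- gip_kernel(Y, "rows")
  Gd <- gip_kernel(Y, "cols")
  Sd <- integrate_disease_similarity(Gd, sem, mode = config$disease_sim_mode)
  A <- augment_matrix(Y, Sc, Sd, epsilon = config$epsilon)
  ef <- eigendecompose(Sc, Sd)
  solve_eigen(ef, A, config$sigma)
}
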