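# Baseline predictors sharing the (train matrix in, score matrix out)
# interface: RLS-avg, RLS-Kron, NetLapRLS, KATZ, NBI, WP. All are
# deterministic given their inputs.

#' RLS with per-side kernels, averaged
#'
#' Solves one regularized least squares smoother per side and averages:
#' `Yhat = (Sc (Sc + sigma I)^-1 Y + (Sd (Sd + sigma I)^-1 Y^T)^T) / 2`.
#'
#' @param Y association matrix.
#' @param Sc,Sd row- and column-side kernels.
#' @param sigma ridge regularization.
#' @return prediction matrix.
#' @export
rls_avg <- function(Y, Sc, Sd, sigma = 0.2) {
  stopifnot(sigma > 0)
  Sc <- unclass(Sc); Sd <- unclass(Sd); Y <- as_plain_matrix(Y)
  hc <- Sc %*% solve(Sc + sigma * diag(nrow(Sc)), Y)
  hd <- Sd %*% solve(Sd + sigma * diag(nrow(Sd)), t(Y))
  out <- (hc + t(hd)) / 2
  dimnames(out) <- dimnames(Y)
  out
}

#' Kron-RLS on the raw training matrix
#'
#' Identical to the DWNN-RLS solver with the cold-start stage disabled:
#' GIP kernels from `Y` (column side optionally integrated with semantic
#' similarity), then the spectral-filter solve on unaugmented `Y`.
#'
#' @inheritParams rls_avg
#' @export
rls_kron <- function(Y, Sc, Sd, sigma = 0.2) {
  ef <- eigendecompose(Sc, Sd)
  solve_eigen(ef, Y, sigma)
}

# Heterogeneous adjacency [[Sc or 0, Y], [Y^T, Sd or 0]], rows/cols ordered
# circRNAs then diseases.
hetero_adjacency <- function(Y, Sc = NULL, Sd = NULL, augmented = TRUE) {
  Y <- as_plain_matrix(Y)
  nc <- nrow(Y); nd <- ncol(Y)
  A11 <- if (augmented && !is.null(Sc)) unclass(Sc) else matrix(0, nc, nc)
  A22 <- if (augmented && !is.null(Sd)) unclass(Sd) else matrix(0, nd, nd)
  rbind(cbind(A11, Y), cbind(t(Y), A22))
}

#' KATZ walk-count scores on the heterogeneous network
#'
#' Sums damped walk counts `sum_{l=1..max_length} beta^l A^l` on the
#' heterogeneous adjacency (similarity matrices on the diagonal blocks by
#' default) and returns the row-by-column block. With `max_length = NULL`
#' the closed form `(I - beta A)^-1 - I` is used, which requires
#' `beta * spectral_radius(A) < 1`.
#'
#' @inheritParams rls_avg
#' @param beta damping factor per walk step.
#' @param max_length walk-length truncation; `NULL` for the closed form.
#' @param augmented include `Sc`/`Sd` as diagonal blocks of the adjacency.
#' @export
katz <- function(Y, Sc, Sd, beta = 0.01, max_length = 4L, augmented = TRUE) {
  A <- hetero_adjacency(Y, Sc, Sd, augmented)
  nc <- nrow(Y); nd <- ncol(Y)
  if (is.null(max_length)) {
    rho <- max(abs(eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values))
    if (beta * rho >= 1) {
      stop("beta * spectral_radius >= 1: the unbounded KATZ series diverges")
    }
    S <- solve(diag(nrow(A)) - beta * A) - diag(nrow(A))
  } else {
    S <- matrix(0, nrow(A), ncol(A))
    P <- diag(nrow(A))
    for (l in seq_len(max_length)) {
      P <- P %*% A
      S <- S + beta^l * P
    }
  }
  out <- S[seq_len(nc), nc + seq_len(nd), drop = FALSE]
  dimnames(out) <- dimnames(Y)
  out
}

#' Network-based inference (two-phase resource allocation)
#'
#' Resources on diseases spread to their circRNAs and back:
#' `Yhat = Y W` with `W[j, v] = sum_i Y[i, j] Y[i, v] / (deg(d_j) deg(c_i))`,
#' degrees taken from `Y`. Zero-degree nodes contribute nothing, so
#' degenerate rows/columns simply score 0. Uses bipartite topology only.
#'
#' @param Y association matrix.
#' @export
nbi <- function(Y) {
  Y <- as_plain_matrix(Y)
  dc <- rowSums(Y)
  dd <- colSums(Y)
  inv_dc <- ifelse(dc > 0, 1 / dc, 0)
  inv_dd <- ifelse(dd > 0, 1 / dd, 0)
  W <- (inv_dd * t(Y)) %*% (inv_dc * Y)  # W[j, v]
  out <- Y %*% W
  dimnames(out) <- dimnames(Y)
  out
}

#' Weighted-profile recommendation
#'
#' Each half scores a pair by the similarity-weighted mean of the other
#' entities' labels, excluding self-weights:
#' `Yhat[i, j] = (sum_{u != i} Sc[i,u] Y[u,j] / sum_{u != i} Sc[i,u]
#'             +  sum_{v != j} Sd[j,v] Y[i,v] / sum_{v != j} Sd[j,v]) / 2`.
#' A half with zero similarity mass contributes 0.
#'
#' @inheritParams rls_avg
#' @export
wp <- function(Y, Sc, Sd) {
  Sc <- unclass(Sc); Sd <- unclass(Sd); Y <- as_plain_matrix(Y)
  num_c <- Sc %*% Y - diag(Sc) * Y
  den_c <- rowSums(Sc) - diag(Sc)
  half_c <- ifelse(den_c > 0, 1 / den_c, 0) * num_c
  num_d <- Y %*% t(Sd) - Y * rep(diag(Sd), each = nrow(Y))
  den_d <- rowSums(Sd) - diag(Sd)
  half_d <- num_d * rep(ifelse(den_d > 0, 1 / den_d, 0), each = nrow(Y))
  out <- (half_c + half_d) / 2
  dimnames(out) <- dimnames(Y)
  out
}

# Symmetric normalized Laplacian D^{-1/2} (D - W) D^{-1/2}; zero-degree
# nodes get zero rows/columns.
normalized_laplacian <- function(W) {
  d <- rowSums(W)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  diag(ifelse(d > 0, 1, 0)) - s * t(s * W)
}

#' Graph-Laplacian regularized least squares (NetLapRLS)
#'
#' Each side builds a hybrid affinity from the supplied similarity and the
#' network topology kernel (`Y Y^T` or `Y^T Y`), weighted by `gamma`, then
#' solves `F = W (W + beta L W)^-1 Y` with `L` the symmetric normalized
#' Laplacian of `W`; the two sides are averaged. With `beta = 0` the solve
#' collapses to plain ridge-free smoothing (`F = Y` for invertible `W`).
#' Rank-deficient systems (duplicate interaction profiles) are solved in the
#' least-squares sense via an SVD pseudo-inverse. Defaults follow the
#' method's original formulation.
#'
#' @inheritParams rls_avg
#' @param gamma_d2,gamma_t2 topology-kernel weights for the disease and
#'   circRNA sides.
#' @param beta_d,beta_t Laplacian regularization weights.
#' @export
netlaprls <- function(Y, Sc, Sd, gamma_d2 = 0.01, gamma_t2 = 0.01,
                      beta_d = 0.3, beta_t = 0.3) {
  Sc <- unclass(Sc); Sd <- unclass(Sd); Y <- as_plain_matrix(Y)
  Wc <- (Sc + gamma_t2 * tcrossprod(Y)) / (1 + gamma_t2)
  Wd <- (Sd + gamma_d2 * crossprod(Y)) / (1 + gamma_d2)
  # Duplicate interaction profiles make GIP-derived W exactly singular, so
  # (W + beta L W) = (I + beta L) W can be rank-deficient; solve in the
  # least-squares sense through an SVD pseudo-inverse.
  pinv_solve <- function(M, B) {
    s <- svd(M)
    tol <- max(dim(M)) * .Machine$double.eps * max(s$d)
    inv_d <- ifelse(s$d > tol, 1 / s$d, 0)
    s$v %*% (inv_d * crossprod(s$u, B))
  }
  solve_side <- function(W, B, beta) {
    L <- normalized_laplacian(W)
    W %*% pinv_solve(W + beta * L %*% W, B)
  }
  Fc <- solve_side(Wc, Y, beta_t)
  Fd <- solve_side(Wd, t(Y), beta_d)
  out <- (Fc + t(Fd)) / 2
  dimnames(out) <- dimnames(Y)
  out
}

# ---- predictor factories -------------------------------------------------
# Each returns a closure (Y_train) -> score matrix for the CV harness.
# Kernels are recomputed from the training matrix inside every fold; the
# semantic matrix does not depend on Y and may be precomputed once.

#' Predictor factories for the cross-validation harness
#'
#' Each factory captures its hyperparameters (and, where relevant, a
#' precomputed semantic similarity matrix) and returns a function
#' `(Y_train) -> score matrix` suitable for [evaluate()]. GIP kernels are
#' recomputed from the training matrix inside each fold, so no test
#' information leaks through the similarities.
#'
#' @param config a [run_config()].
#' @param sem optional semantic `kernel_matrix` over the columns.
#' @param sigma,beta,max_length,augmented method hyperparameters.
#' @return a predictor closure.
#' @name predictors
NULL

train_kernels <- function(Y, sem = NULL, mode = "gip_only") {
  Sc <- gip_kernel(Y, "rows")
  Gd <- gip_kernel(Y, "cols")
  Sd <- integrate_disease_similarity(Gd, sem, mode = mode)
  list(Sc = Sc, Sd = Sd)
}

#' @rdname predictors
#' @export
predictor_dwnn_rls <- function(config = run_config(), sem = NULL) {
  force(config); force(sem)
  function(Y) dwnn_rls(Y, config, sem = sem)
}

#' @rdname predictors
#' @export
predictor_rls_kron <- function(config = run_config(), sem = NULL) {
  function(Y) {
    k <- train_kernels(Y, sem, config$disease_sim_mode)
    rls_kron(Y, k$Sc, k$Sd, config$sigma)
  }
}

#' @rdname predictors
#' @export
predictor_rls_avg <- function(config = run_config(), sem = NULL) {
  function(Y) {
    k <- train_kernels(Y, sem, config$disease_sim_mode)
    rls_avg(Y, k$Sc, k$Sd, config$sigma)
  }
}

#' @rdname predictors
#' @export
predictor_katz <- function(config = run_config(), sem = NULL, beta = 0.01,
                           max_length = 4L, augmented = TRUE) {
  function(Y) {
    k <- train_kernels(Y, sem, config$disease_sim_mode)
    katz(Y, k$Sc, k$Sd, beta = beta, max_length = max_length,
         augmented = augmented)
  }
}

#' @rdname predictors
#' @export
predictor_nbi <- function() {
  function(Y) nbi(Y)
}

#' @rdname predictors
#' @export
predictor_wp <- function(config = run_config(), sem = NULL) {
  function(Y) {
    k <- train_kernels(Y, sem, config$disease_sim_mode)
    wp(Y, k$Sc, k$Sd)
  }
}

#' @rdname predictors
#' @export
predictor_netlaprls <- function(config = run_config(), sem = NULL,
                                gamma_d2 = 0.01, gamma_t2 = 0.01,
                                beta_d = 0.3, beta_t = 0.3) {
  function(Y) {
    k <- train_kernels(Y, sem, config$disease_sim_mode)
    netlaprls(Y, k$Sc, k$Sd, gamma_d2, gamma_t2, beta_d, beta_t)
  }
}

#' Look up a predictor factory by method name
#'
#' @param method one of `"dwnn-rls"`, `"rls-avg"`, `"rls-kron"`,
#'   `"netlaprls"`, `"katz"`, `"nbi"`, `"wp"`.
#' @param config a [run_config()].
#' @param sem optional semantic kernel matrix.
#' @return a predictor closure.
#' @export
get_predictor <- function(method, config = run_config(), sem = NULL) {
  switch(method,
    "dwnn-rls" = predictor_dwnn_rls(config, sem),
    "rls-avg" = predictor_rls_avg(config, sem),
    "rls-kron" = predictor_rls_kron(config, sem),
    "netlaprls" = predictor_netlaprls(config, sem),
    "katz" = predictor_katz(config, sem),
    "nbi" = predictor_nbi(),
    "wp" = predictor_wp(config, sem),
    stop("unknown method: ", method)
  )
}
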