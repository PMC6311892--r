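# Similarity kernels: Gaussian interaction profile (GIP) kernels on both
# sides of the bipartite network, DAG-based semantic similarity on the
# column (disease) side, and their integration.

kernel_matrix <- function(values, ids, kind) {
  dimnames(values) <- list(ids, ids)
  structure(values, kind = kind, class = c("kernel_matrix", "matrix", "array"))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %d x %d, kind = %s\n", nrow(x), ncol(x),
              attr(x, "kind")))
  invisible(x)
}

#' GIP kernel bandwidth
#'
#' The bandwidth gamma of the Gaussian interaction profile kernel is the
#' reciprocal of the mean squared profile norm: for axis `"rows"`,
#' `gamma = 1 / (mean_i ||Y[i, ]||^2)`. For a binary matrix the squared norm
#' of a profile is its number of associations, so gamma is the reciprocal of
#' the average number of associations per entity.
#'
#' @param Y binary association matrix.
#' @param axis `"rows"` (circRNA side) or `"cols"` (disease side).
#' @return positive scalar bandwidth.
#' @examples
#' Y <- assoc_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)),
#'                   row_ids = paste0("c", 1:3), col_ids = paste0("d", 1:2))
#' gip_bandwidth(Y, "rows")  # 1 / ((1 + 1 + 2) / 3) = 0.75
#' @export
gip_bandwidth <- function(Y, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (!is_binary01(Y)) stop("GIP bandwidth is defined on the binary matrix")
  P <- if (axis == "rows") unclass(Y) else t(unclass(Y))
  ss <- rowSums(P^2)
  if (all(ss == 0)) stop("no associations; bandwidth undefined")
  1 / mean(ss)
}

#' Gaussian interaction profile kernel
#'
#' `K[i, j] = exp(-gamma * ||p_i - p_j||^2)` where `p_i` is the i-th binary
#' association profile (row or column of `Y`) and gamma is
#' [gip_bandwidth()]. The kernel is symmetric with unit diagonal and entries
#' in `(0, 1]`, and is positive semidefinite. It is always computed from the
#' binary training matrix, never from augmented scores.
#'
#' @inheritParams gip_bandwidth
#' @return a `kernel_matrix` over the row or column identifiers.
#' @export
gip_kernel <- function(Y, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  gamma <- gip_bandwidth(Y, axis)
  P <- if (axis == "rows") unclass(Y) else t(unclass(Y))
  G <- tcrossprod(P)
  sq <- diag(G)
  d2 <- outer(sq, sq, "+") - 2 * G
  d2[d2 < 0] <- 0  # floating point guard
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  ids <- if (axis == "rows") rownames(Y) else colnames(Y)
  kernel_matrix(K, ids, kind = if (axis == "rows") "gip_circ" else "gip_disease")
}

#' Semantic value profile of a DAG term
#'
#' Each ancestor `t` of a term contributes `delta^w`, where `w` is the
#' smallest number of child-to-parent edges on any directed path from the
#' term to `t` (breadth-first layer), and the term itself contributes 1.
#' `sem_total` is the sum of all contributions.
#'
#' @param dag a [disease_dag()].
#' @param term a node of the DAG.
#' @param delta layer contribution factor in (0, 1).
#' @return list with `term`, `sv` (named vector of semantic values) and
#'   `sem_total`.
#' @export
semantic_profile <- function(dag, term, delta = 0.5) {
  stopifnot(delta > 0, delta < 1)
  if (!term %in% dag$nodes) stop("unknown DAG term: ", term)
  d <- igraph::distances(dag$graph, v = term, mode = "out")[1, ]
  d <- d[is.finite(d)]
  sv <- delta^d
  names(sv) <- names(d)
  list(term = term, sv = sv, sem_total = sum(sv))
}

#' Semantic similarity of two DAG terms
#'
#' Shared-ancestor similarity: the semantic values that the two terms assign
#' to their common ancestors (each term included among its own ancestors) are
#' summed and normalized by the total semantic values, giving a symmetric
#' score in `[0, 1]` with self-similarity 1.
#'
#' @inheritParams semantic_profile
#' @param a_term,b_term DAG nodes.
#' @return scalar similarity.
#' @export
semantic_similarity <- function(dag, a_term, b_term, delta = 0.5) {
  pa <- semantic_profile(dag, a_term, delta)
  pb <- semantic_profile(dag, b_term, delta)
  semsim_from_profiles(pa, pb)
}

semsim_from_profiles <- function(pa, pb) {
  common <- intersect(names(pa$sv), names(pb$sv))
  if (!length(common)) return(0)
  sum(pa$sv[common] + pb$sv[common]) / (pa$sem_total + pb$sem_total)
}

#' Pairwise semantic similarity matrix over disease columns
#'
#' Diseases mapped to several DAG terms score each pair as the maximum over
#' all term pairs (the usual convention for multi-position MeSH
#' descriptors). Entries involving an unmapped disease are `NA` (missing);
#' the diagonal is 1 for mapped diseases.
#'
#' @param dag a [disease_dag()].
#' @param col_ids disease identifiers in column order.
#' @param mapping named list disease id -> terms; defaults to `dag$mapping`.
#' @param delta layer contribution factor.
#' @return a `kernel_matrix` of kind `"semantic"`, possibly containing `NA`.
#' @export
disease_semantic_matrix <- function(dag, col_ids, mapping = dag$mapping,
                                    delta = 0.5) {
  n <- length(col_ids)
  S <- matrix(NA_real_, n, n)
  if (!is.null(mapping)) {
    terms_per <- lapply(col_ids, function(d) mapping[[d]])
    used <- unique(unlist(terms_per, use.names = FALSE))
    profiles <- lapply(used, semantic_profile, dag = dag, delta = delta)
    names(profiles) <- used
    mapped <- which(lengths(terms_per) > 0)
    for (ii in seq_along(mapped)) {
      i <- mapped[ii]
      for (j in mapped[seq_len(ii)]) {
        best <- 0
        for (ta in terms_per[[i]]) {
          for (tb in terms_per[[j]]) {
            best <- max(best, semsim_from_profiles(profiles[[ta]], profiles[[tb]]))
          }
        }
        S[i, j] <- S[j, i] <- best
      }
    }
    diag(S)[mapped] <- 1
  }
  kernel_matrix(S, col_ids, kind = "semantic")
}

#' Integrate GIP and semantic disease similarity
#'
#' In `"mean_gip_semantic"` mode the final disease similarity is the
#' elementwise mean of the GIP kernel and the semantic similarity wherever
#' the semantic value is defined; pairs with no semantic information fall
#' back to the GIP value (GIP is the base signal -- the method also runs in a
#' pure GIP ablation mode). `"gip_only"` returns the GIP kernel unchanged.
#'
#' @param gip GIP `kernel_matrix` over diseases.
#' @param sem semantic `kernel_matrix` (may contain `NA`), or `NULL`.
#' @param mode `"mean_gip_semantic"` or `"gip_only"`.
#' @return integrated `kernel_matrix` of kind `"integrated"`.
#' @export
integrate_disease_similarity <- function(gip, sem = NULL,
                                         mode = c("mean_gip_semantic", "gip_only")) {
  mode <- match.arg(mode)
  if (mode == "gip_only" || is.null(sem)) {
    return(kernel_matrix(unclass(gip), colnames(gip), kind = "integrated"))
  }
  if (!identical(colnames(gip), colnames(sem))) {
    stop("GIP and semantic matrices have mismatched identifiers")
  }
  G <- unclass(gip)
  S <- unclass(sem)
  out <- ifelse(is.na(S), G, (G + S) / 2)
  kernel_matrix(out, colnames(gip), kind = "integrated")
}
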