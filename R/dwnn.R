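# Decreasing-weight k-nearest-neighbour (DWNN) cold-start initialization.
# Entities with an all-zero profile in the training matrix ("new" circRNAs
# or diseases) carry no interaction signal, so their rows/columns are filled
# with a similarity-weighted average of their neighbours' labels before the
# RLS solve.

#' Select the neighbourhood size for the decreasing-weight average
#'
#' Given similarities to all other entities ranked from high to low, the
#' neighbourhood is the longest prefix for which
#' `(1 - sim[l]) / l <= epsilon^l` holds at every 1-based rank `l`; if the
#' condition already fails at `l = 1` no neighbour is selected. With
#' `epsilon = 1` the bound is 1 at every rank, so all neighbours are used.
#'
#' @param ranked_sims numeric vector of similarities in `[0, 1]`, sorted
#'   non-increasing.
#' @param epsilon control parameter in `(0, 1]`.
#' @return integer neighbourhood size `k >= 0`.
#' @export
select_k <- function(ranked_sims, epsilon) {
  stopifnot(epsilon > 0, epsilon <= 1)
  if (length(ranked_sims) == 0) return(0L)
  if (is.unsorted(-ranked_sims)) stop("similarities must be sorted non-increasing")
  l <- seq_along(ranked_sims)
  ok <- (1 - ranked_sims) / l <= epsilon^l
  if (!ok[1]) return(0L)
  first_bad <- which(!ok)
  if (!length(first_bad)) length(ranked_sims) else first_bad[1] - 1L
}

#' Decreasing-weight neighbour score
#'
#' Similarity-weighted average of the binary labels of the `k` most similar
#' neighbours: `sum(sim_l * label_l) / sum(sim_l)` over `l <= k`. When
#' `k = 0` or the similarity mass is zero the score is undefined and 0 is
#' returned with a warning.
#'
#' @param neighbor_sims similarities, sorted non-increasing.
#' @param neighbor_labels aligned 0/1 labels.
#' @param k neighbourhood size, `0 <= k <= length(neighbor_sims)`.
#' @return scalar score in `[0, 1]`.
#' @export
dwnn_score <- function(neighbor_sims, neighbor_labels, k) {
  stopifnot(length(neighbor_sims) == length(neighbor_labels),
            k >= 0, k <= length(neighbor_sims))
  if (k == 0) {
    warning("DWNN score undefined (k = 0); returning 0")
    return(0)
  }
  w <- neighbor_sims[seq_len(k)]
  mass <- sum(w)
  if (mass <= 0) {
    warning("DWNN score undefined (zero similarity mass); returning 0")
    return(0)
  }
  sum(w * neighbor_labels[seq_len(k)]) / mass
}

# Ranked neighbour list of entity `i` within kernel K: self excluded,
# similarity descending, ties broken by original id order (order() with
# radix is stable).
neighbor_ranking <- function(K, i) {
  sims <- unclass(K)[i, -i]
  idx <- seq_len(nrow(K))[-i]
  ord <- order(-sims, method = "radix")
  list(index = idx[ord], sims = unname(sims[ord]))
}

#' Fill cold-start rows and columns with DWNN initial scores
#'
#' Rows of `Y` whose profile is all zero are replaced entrywise by the
#' decreasing-weight average of the other rows' labels, weighted by row-side
#' similarity; all-zero columns analogously with column-side similarity.
#' Entries lying in both a new row and a new column receive the mean of the
#' two estimates. All other entries -- known 1s and structural 0s -- are
#' returned bit-identical. Neighbours that are themselves all-zero stay in
#' the ranking (their labels are 0, so they only dilute the average).
#'
#' @param Y binary association matrix.
#' @param Sc row-side (circRNA) similarity kernel aligned with `rownames(Y)`.
#' @param Sd column-side (disease) similarity kernel aligned with
#'   `colnames(Y)`.
#' @param epsilon neighbourhood control, see [select_k()].
#' @return numeric matrix with entries in `[0, 1]`; binary iff no entity was
#'   new.
#' @export
augment_matrix <- function(Y, Sc, Sd, epsilon = 1.0) {
  if (!is_binary01(Y)) stop("augment_matrix expects a binary matrix")
  if (!identical(rownames(Y), rownames(Sc)) ||
      !identical(colnames(Y), rownames(Sd))) {
    stop("kernel identifiers are not aligned with the association matrix")
  }
  Y <- as_plain_matrix(Y)
  new_rows <- which(rowSums(Y) == 0)
  new_cols <- which(colSums(Y) == 0)
  if (length(new_rows) == nrow(Y) || length(new_cols) == ncol(Y)) {
    stop("association matrix has no training signal at all")
  }
  A <- Y
  row_est <- matrix(0, length(new_rows), ncol(Y))
  for (m in seq_along(new_rows)) {
    i <- new_rows[m]
    nb <- neighbor_ranking(Sc, i)
    k <- select_k(nb$sims, epsilon)
    if (k > 0) {
      w <- nb$sims[seq_len(k)]
      if (sum(w) > 0) {
        row_est[m, ] <- as.vector(w %*% Y[nb$index[seq_len(k)], , drop = FALSE]) / sum(w)
      }
    }
  }
  col_est <- matrix(0, nrow(Y), length(new_cols))
  for (m in seq_along(new_cols)) {
    j <- new_cols[m]
    nb <- neighbor_ranking(Sd, j)
    k <- select_k(nb$sims, epsilon)
    if (k > 0) {
      w <- nb$sims[seq_len(k)]
      if (sum(w) > 0) {
        col_est[, m] <- as.vector(Y[, nb$index[seq_len(k)], drop = FALSE] %*% w) / sum(w)
      }
    }
  }
  if (length(new_rows)) A[new_rows, ] <- row_est
  if (length(new_cols)) A[, new_cols] <- col_est
  if (length(new_rows) && length(new_cols)) {
    for (m in seq_along(new_rows)) {
      for (l in seq_along(new_cols)) {
        A[new_rows[m], new_cols[l]] <-
          (row_est[m, new_cols[l]] + col_est[new_rows[m], l]) / 2
      }
    }
  }
  A
}
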