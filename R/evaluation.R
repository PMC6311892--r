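# Cross-validation over known positive pairs and rank-based AUC.
#
# Protocol: known positives are partitioned into folds; each fold is masked
# to 0 in the training matrix, the predictor is applied to the training
# matrix only, and the held-out positives are ranked against every pair that
# is 0 in the full matrix (no negative sampling -- deterministic and
# standard for GIP/Kron-RLS benchmarks). One pooled ROC per repeat.

#' Build cross-validation plans over the known positives
#'
#' For k-fold schemes the positives are shuffled with a seeded generator and
#' dealt round-robin into folds, so fold sizes differ by at most one; repeat
#' `r` (0-based) uses `seed + r`. LOOCV is deterministic: a single plan with
#' one positive per fold, in column-major position order.
#'
#' @param Y binary association matrix.
#' @param scheme `"5CV"`, `"10CV"` or `"LOOCV"`.
#' @param n_repeats number of repeats (forced to 1 for LOOCV).
#' @param seed integer base seed.
#' @return list of plans; each plan is a list with `scheme`, `repeat_index`,
#'   `seed` and `folds`, a list of integer matrices of `(row, col)` positions.
#' @export
make_cv_plan <- function(Y, scheme = c("10CV", "5CV", "LOOCV"),
                         n_repeats = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  pos <- which(unclass(Y) == 1, arr.ind = TRUE)
  dimnames(pos) <- NULL
  n <- nrow(pos)
  if (scheme == "LOOCV") {
    folds <- lapply(seq_len(n), function(m) pos[m, , drop = FALSE])
    return(list(list(scheme = scheme, repeat_index = 0L, seed = as.integer(seed),
                     folds = folds)))
  }
  k <- if (scheme == "5CV") 5L else 10L
  if (n < k) stop("fewer positives than folds")
  lapply(seq_len(n_repeats) - 1L, function(r) {
    rs <- as.integer(seed) + r
    perm <- local({ set.seed(rs); sample.int(n) })
    fold_of <- rep(seq_len(k), length.out = n)
    folds <- lapply(seq_len(k), function(f) {
      pos[perm[fold_of == f], , drop = FALSE]
    })
    list(scheme = scheme, repeat_index = r, seed = rs, folds = folds)
  })
}

#' Score one cross-validation fold
#'
#' Masks the fold's positives to 0 in the training matrix, applies the
#' predictor to the training matrix only, and returns scores for the
#' evaluation pairs: the held-out positives (label 1) together with every
#' pair that is 0 in the full `Y` (label 0). Training positives of other
#' folds are excluded from the ranking. Masking can leave a row or column
#' all-zero; such cold-start entities are deliberately passed through to the
#' predictor (this is the scenario the DWNN stage addresses).
#'
#' @param Y full binary association matrix.
#' @param plan one plan from [make_cv_plan()].
#' @param fold_index which fold to hold out.
#' @param predictor function `(Y_train) -> score matrix`.
#' @return data frame with columns `score`, `label`.
#' @export
run_fold <- function(Y, plan, fold_index, predictor) {
  test <- plan$folds[[fold_index]]
  Ytrain <- as_plain_matrix(Y)
  Ytrain[test] <- 0
  P <- tryCatch(predictor(Ytrain), error = function(e) {
    stop(sprintf("predictor failed on fold %d (repeat %d): %s",
                 fold_index, plan$repeat_index, conditionMessage(e)))
  })
  neg <- which(unclass(Y) == 0)
  data.frame(
    score = c(unclass(P)[test], unclass(P)[neg]),
    label = c(rep(1L, nrow(test)), rep(0L, length(neg)))
  )
}

#' Rank-based AUC
#'
#' Mann-Whitney statistic with mid-rank handling of ties: the probability
#' that a random positive outscores a random negative, counting ties as 1/2.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(scores)  # average ranks on ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC of a predictor
#'
#' Runs the requested scheme, pooling every fold's test scores within a
#' repeat into one ROC (per-fold AUC is undefined under LOOCV, where a fold
#' holds a single positive), and aggregates mean and standard deviation of
#' the per-repeat AUCs.
#'
#' @param Y binary association matrix.
#' @param predictor function `(Y_train) -> score matrix`; see
#'   [predictor_dwnn_rls()] and friends.
#' @param scheme `"5CV"`, `"10CV"` or `"LOOCV"`.
#' @param n_repeats repeats (LOOCV is a single deterministic run).
#' @param seed base seed.
#' @param predictor_name label stored in the result.
#' @param plans optional precomputed [make_cv_plan()] output, shared e.g.
#'   across a parameter sweep so fold noise cancels.
#' @return list of class `"eval_result"`: `scheme`, `predictor`,
#'   `auc_per_repeat`, `auc_mean`, `auc_sd`, `seed`.
#' @export
evaluate <- function(Y, predictor, scheme = c("10CV", "5CV", "LOOCV"),
                     n_repeats = 10L, seed = 1L, predictor_name = "predictor",
                     plans = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(plans)) plans <- make_cv_plan(Y, scheme, n_repeats, seed)
  aucs <- vapply(plans, function(plan) {
    per_fold <- lapply(seq_along(plan$folds), function(f) {
      run_fold(Y, plan, f, predictor)
    })
    pooled <- do.call(rbind, per_fold)
    auc_score(pooled$score, pooled$label)
  }, numeric(1))
  structure(list(scheme = scheme, predictor = predictor_name,
                 auc_per_repeat = aucs, auc_mean = mean(aucs),
                 auc_sd = if (length(aucs) > 1) stats::sd(aucs) else 0,
                 seed = as.integer(seed)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s, %s: AUC %.4f +/- %.4f over %d repeat(s)\n",
              x$predictor, x$scheme, x$auc_mean, x$auc_sd,
              length(x$auc_per_repeat)))
  invisible(x)
}
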