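# Shared fixtures and independent oracles, built in code.

# 3 x 2 toy with hand-computable GIP values: gamma_rows = 0.75, gamma_cols = 0.5.
toy_Y <- function() {
  assoc_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)),
               row_ids = c("c1", "c2", "c3"), col_ids = c("d1", "d2"))
}

rand_binary <- function(nr, nc, p = 0.4) {
  Y <- matrix(rbinom(nr * nc, 1, p), nr, nc,
              dimnames = list(sprintf("r%d", seq_len(nr)),
                              sprintf("s%d", seq_len(nc))))
  if (all(Y == 0)) Y[sample(nr, 1), sample(nc, 1)] <- 1
  Y
}

# Random symmetric kernel-like matrix; "indefinite" mimics the mean of a PSD
# GIP kernel and a bounded semantic matrix, which can leave the PSD cone.
rand_kernel <- function(n, indefinite = FALSE) {
  Y <- rand_binary(n, n + 1)
  K <- unclass(gip_kernel(assoc_matrix(Y), "rows"))
  if (indefinite) {
    S <- matrix(runif(n * n), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    K <- (K + S) / 2
  }
  dimnames(K) <- NULL
  K
}

# Exhaustive concordant-pair AUC (independent of rank()-based production path).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Small DAG fixtures as child -> parent edge matrices.
dag_chain <- function() disease_dag(rbind(c("B", "A")))
dag_siblings <- function() disease_dag(rbind(c("A", "R"), c("B", "R")))
dag_diamond <- function() {
  disease_dag(rbind(c("X", "P"), c("X", "Q"), c("P", "R"), c("Q", "R")))
}
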