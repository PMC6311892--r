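test_that("GIP bandwidth matches hand evaluation and degenerate rules", {
  Y <- toy_Y()
  expect_equal(gip_bandwidth(Y, "rows"), 0.75)   # 1 / ((1 + 1 + 2) / 3)
  expect_equal(gip_bandwidth(Y, "cols"), 0.5)    # 1 / ((2 + 2) / 2)
  ones <- assoc_matrix(matrix(1, 4, 6, dimnames = list(paste0("c", 1:4),
                                                       paste0("d", 1:6))))
  expect_equal(gip_bandwidth(ones, "rows"), 1 / 6)
  Z <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(gip_bandwidth(Z, "rows"), "bandwidth undefined")
})

test_that("GIP kernel reproduces hand-derived toy values", {
  Y <- toy_Y()
  Kc <- gip_kernel(Y, "rows")
  expect_equal(Kc["c1", "c2"], exp(-0.75 * 2), tolerance = 1e-12)
  Kd <- gip_kernel(Y, "cols")
  expect_equal(Kd["d1", "d2"], exp(-0.5 * 2), tolerance = 1e-12)
  # identical profiles are maximally similar
  Y2 <- assoc_matrix(rbind(c(1, 0), c(1, 0), c(0, 1)),
                     row_ids = paste0("c", 1:3), col_ids = c("d1", "d2"))
  expect_equal(unname(gip_kernel(Y2, "rows")["c1", "c2"]), 1)
})

test_that("GIP kernels are symmetric, unit-diagonal, bounded, and PSD", {
  set.seed(52)
  for (rep in 1:15) {
    Y <- assoc_matrix(rand_binary(sample(3:9, 1), sample(3:9, 1)))
    for (axis in c("rows", "cols")) {
      K <- unclass(gip_kernel(Y, axis))
      expect_identical(K, t(K))
      expect_equal(unname(diag(K)), rep(1, nrow(K)))
      expect_true(all(K > 0 & K <= 1))
      expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-8)
    }
  }
})

test_that("GIP kernel commutes with simultaneous row/id permutation", {
  set.seed(53)
  Y <- rand_binary(6, 5)
  K <- unclass(gip_kernel(assoc_matrix(Y), "rows"))
  p <- sample(6)
  Kp <- unclass(gip_kernel(assoc_matrix(Y[p, ]), "rows"))
  expect_equal(Kp, K[p, p], ignore_attr = TRUE)
})

test_that("semantic profiles follow the layered decay on chains and diamonds", {
  p <- semantic_profile(dag_chain(), "B", delta = 0.5)
  expect_equal(p$sv, c(B = 1, A = 0.5))
  expect_equal(p$sem_total, 1.5)

  root <- semantic_profile(dag_chain(), "A", delta = 0.5)
  expect_equal(root$sv, c(A = 1))
  expect_equal(root$sem_total, 1)

  # diamond X -> {P, Q} -> R: R is reached at layer 2 on both paths
  d <- semantic_profile(dag_diamond(), "X", delta = 0.5)
  expect_equal(d$sv[["R"]], 0.25)
  expect_equal(d$sem_total, 2.25)

  # multiple paths of different length: the smallest layer wins (BFS oracle)
  dag <- disease_dag(rbind(c("X", "M"), c("M", "R"), c("X", "R")))
  expect_equal(semantic_profile(dag, "X", 0.5)$sv[["R"]], 0.5)

  expect_error(semantic_profile(dag_chain(), "nope"), "unknown")
})

test_that("semantic similarity matches hand-derived values and is symmetric", {
  expect_equal(semantic_similarity(dag_siblings(), "A", "A", 0.5), 1)
  expect_equal(semantic_similarity(dag_siblings(), "A", "B", 0.5), 1 / 3)
  expect_equal(semantic_similarity(dag_chain(), "A", "B", 0.5), 0.6)
  # symmetry over random term pairs of a generated DAG
  dg <- generate_dag(synthetic_spec(n_disease = 10, seed = 5))
  set.seed(54)
  for (rep in 1:10) {
    ab <- sample(dg$dag$nodes, 2)
    expect_equal(semantic_similarity(dg$dag, ab[1], ab[2], 0.5),
                 semantic_similarity(dg$dag, ab[2], ab[1], 0.5))
  }
})

test_that("Sem(A) is monotone non-decreasing in delta", {
  dg <- generate_dag(synthetic_spec(n_disease = 10, seed = 6))
  deltas <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  for (term in sample(dg$dag$nodes, 5)) {
    sems <- sapply(deltas, function(d) semantic_profile(dg$dag, term, d)$sem_total)
    expect_true(all(diff(sems) >= 0))
  }
})

test_that("pairwise semantic matrix handles unmapped and multi-position diseases", {
  dag <- dag_diamond()
  ids <- c("dA", "dB", "dC")
  # all unmapped -> all missing
  S <- disease_semantic_matrix(dag, ids, mapping = NULL)
  expect_true(all(is.na(S)))
  # multi-position disease: max over term pairs, against an exhaustive oracle
  mapping <- list(dA = c("X", "P"), dB = c("Q"), dC = c("R"))
  S <- disease_semantic_matrix(dag, ids, mapping = mapping, delta = 0.5)
  oracle <- function(ta, tb) {
    max(outer(ta, tb, Vectorize(function(a, b)
      semantic_similarity(dag, a, b, 0.5))))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_equal(S[i, j], oracle(mapping[[ids[i]]], mapping[[ids[j]]]),
                 ignore_attr = TRUE)
  }
  expect_equal(unname(diag(S)), rep(1, 3))
})

test_that("disease similarity integration averages where defined, falls back to GIP", {
  ids <- c("d1", "d2")
  G <- matrix(c(1, 0.4, 0.4, 1), 2, 2, dimnames = list(ids, ids))
  S <- matrix(c(1, 0.6, 0.6, 1), 2, 2, dimnames = list(ids, ids))
  out <- integrate_disease_similarity(G, S, "mean_gip_semantic")
  expect_equal(out["d1", "d2"], 0.5)
  S[1, 2] <- S[2, 1] <- NA
  out <- integrate_disease_similarity(G, S, "mean_gip_semantic")
  expect_equal(out["d1", "d2"], 0.4)
  expect_equal(unclass(integrate_disease_similarity(G, S, "gip_only")), G,
               ignore_attr = TRUE)
  # elementwise brute force on full random matrices
  set.seed(55)
  n <- 6
  ids <- paste0("d", 1:n)
  G <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
  S <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
  S[sample(n * n, 10)] <- NA
  out <- unclass(integrate_disease_similarity(G, S))
  for (i in 1:n) for (j in 1:n) {
    expect_equal(out[i, j],
                 if (is.na(S[i, j])) G[i, j] else (G[i, j] + S[i, j]) / 2)
  }
  dimnames(S) <- list(rev(ids), rev(ids))
  expect_error(integrate_disease_similarity(G, S), "mismatch")
})
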