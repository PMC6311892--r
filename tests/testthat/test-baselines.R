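set.seed(91)
toy_kernels <- function(Y) {
  aY <- assoc_matrix(Y)
  list(Sc = unclass(gip_kernel(aY, "rows")), Sd = unclass(gip_kernel(aY, "cols")))
}

test_that("RLS-avg averages the two one-sided ridge smoothers", {
  Y <- rand_binary(3, 2, p = 0.6)
  ids <- dimnames(Y)
  expect_equal(rls_avg(Y, diag(3), diag(2), 0.2), unclass(Y) / 1.2,
               ignore_attr = TRUE)
  expect_equal(max(abs(rls_avg(matrix(0, 3, 2), diag(3), diag(2), 0.2))), 0)
  k <- toy_kernels(Y)
  # explicit two-solve oracle
  hc <- k$Sc %*% solve(k$Sc + 0.2 * diag(3)) %*% Y
  hd <- k$Sd %*% solve(k$Sd + 0.2 * diag(2)) %*% t(Y)
  expect_lt(max(abs(rls_avg(Y, k$Sc, k$Sd, 0.2) - (hc + t(hd)) / 2)), 1e-10)
})

test_that("RLS-Kron is the pipeline without cold-start augmentation", {
  Y <- rand_binary(5, 4, p = 0.5)
  k <- toy_kernels(Y)
  expect_lt(max(abs(rls_kron(Y, k$Sc, k$Sd, 0.2) -
                    solve_naive(k$Sc, k$Sd, Y, 0.2))), 1e-8)
  # differs from DWNN-RLS exactly when a cold-start entity exists
  Y2 <- Y; Y2[3, ] <- 0
  if (all(Y2 == 0) || any(colSums(Y2) == 0)) Y2[1, ] <- 1
  aY2 <- assoc_matrix(Y2)
  cfg <- run_config(disease_sim_mode = "gip_only")
  k2 <- toy_kernels(Y2)
  kron <- rls_kron(Y2, k2$Sc, k2$Sd, 0.2)
  full <- dwnn_rls(aY2, cfg)
  expect_gt(max(abs(kron[3, ] - full[3, ])), 1e-6)
})

test_that("KATZ expands damped walk counts on the heterogeneous network", {
  Y <- rand_binary(4, 3, p = 0.5)
  k <- toy_kernels(Y)
  b <- 0.05
  expect_equal(katz(Y, k$Sc, k$Sd, beta = b, max_length = 1),
               b * unclass(Y), ignore_attr = TRUE)
  # block power expansion by hand at length 2
  expected <- b * Y + b^2 * (k$Sc %*% Y + Y %*% k$Sd)
  expect_equal(katz(Y, k$Sc, k$Sd, beta = b, max_length = 2), expected,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(max(abs(katz(Y, k$Sc, k$Sd, beta = 0, max_length = 3))), 0)
  # truncated sums approach the closed form monotonically (nonnegative A)
  closed <- katz(Y, k$Sc, k$Sd, beta = b, max_length = NULL)
  errs <- sapply(1:6, function(l)
    max(abs(katz(Y, k$Sc, k$Sd, beta = b, max_length = l) - closed)))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[6], errs[1])
  expect_error(katz(Y, k$Sc, k$Sd, beta = 10, max_length = NULL), "diverges")
})

test_that("NBI conserves and routes resource through the bipartite graph", {
  Y1 <- matrix(1, 1, 2, dimnames = list("c1", c("d1", "d2")))
  expect_equal(nbi(Y1), Y1, ignore_attr = TRUE)
  I3 <- diag(3); dimnames(I3) <- list(paste0("c", 1:3), paste0("d", 1:3))
  expect_equal(nbi(I3), I3, ignore_attr = TRUE)
  expect_equal(max(abs(nbi(matrix(0, 2, 2)))), 0)
  # explicit two-step oracle on a random instance
  Y <- rand_binary(5, 4, p = 0.5)
  dc <- rowSums(Y); dd <- colSums(Y)
  W <- matrix(0, 4, 4)
  for (j in 1:4) for (v in 1:4) for (i in 1:5) {
    if (dd[j] > 0 && dc[i] > 0) W[j, v] <- W[j, v] + Y[i, j] * Y[i, v] / (dd[j] * dc[i])
  }
  expect_lt(max(abs(nbi(Y) - Y %*% W)), 1e-12)
  # the transfer operator conserves resource along its application axis:
  # sum_v W[j, v] = 1 whenever disease j has positive degree
  expect_true(all(rowSums(W) <= 1 + 1e-12))
  expect_equal(unname(rowSums(W)[dd > 0]), rep(1, sum(dd > 0)))
})

test_that("weighted-profile scores are bounded means excluding self-weights", {
  Y <- rand_binary(4, 3, p = 0.5)
  k <- toy_kernels(Y)
  out <- wp(Y, k$Sc, k$Sd)
  expect_true(all(out >= 0 & out <= 1 + 1e-12))
  expect_equal(max(abs(wp(matrix(0, 4, 3), k$Sc, k$Sd))), 0)
  # direct evaluation oracle
  for (i in 1:4) for (j in 1:3) {
    hc <- sum(k$Sc[i, -i] * Y[-i, j]) / sum(k$Sc[i, -i])
    hd <- sum(k$Sd[j, -j] * Y[i, -j]) / sum(k$Sd[j, -j])
    expect_equal(out[i, j], (hc + hd) / 2, ignore_attr = TRUE)
  }
  # two identical rows, one holding the association: row half contributes 1
  Y2 <- rbind(c(1, 0), c(0, 0), c(0, 1))
  dimnames(Y2) <- list(paste0("c", 1:3), paste0("d", 1:2))
  Sc <- diag(3); Sc[1, 2] <- Sc[2, 1] <- 1
  dimnames(Sc) <- list(rownames(Y2), rownames(Y2))
  Sd <- diag(2); dimnames(Sd) <- list(colnames(Y2), colnames(Y2))
  expect_equal(unname(wp(Y2, Sc, Sd)[2, 1]), (1 + 0) / 2)
})

test_that("NetLapRLS solves the Laplacian-regularized system on each side", {
  # all row and column profiles distinct and nonzero, so the GIP-derived
  # affinities are strictly positive definite and the plain-solve oracle works
  Y <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(0, 1, 1, 0),
             c(0, 0, 1, 1), c(1, 0, 1, 1))
  dimnames(Y) <- list(paste0("c", 1:5), paste0("d", 1:4))
  k <- toy_kernels(Y)
  expect_equal(max(abs(netlaprls(matrix(0, 5, 4), k$Sc, k$Sd))), 0)
  # direct linear-solve oracle on an invertible instance
  gm <- 0.01; bt <- 0.3
  Wc <- (k$Sc + gm * tcrossprod(Y)) / (1 + gm)
  Wd <- (k$Sd + gm * crossprod(Y)) / (1 + gm)
  lap <- function(W) {
    d <- rowSums(W); s <- 1 / sqrt(d)
    diag(nrow(W)) - s * t(s * W)
  }
  Fc <- Wc %*% solve(Wc + bt * lap(Wc) %*% Wc, Y)
  Fd <- Wd %*% solve(Wd + bt * lap(Wd) %*% Wd, t(Y))
  expect_lt(max(abs(netlaprls(Y, k$Sc, k$Sd) - (Fc + t(Fd)) / 2)), 1e-8)
  # beta = 0 removes the Laplacian penalty entirely
  expect_equal(netlaprls(Y, k$Sc, k$Sd, beta_d = 0, beta_t = 0),
               unclass(Y), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("all baselines are deterministic and honor the predictor interface", {
  Y <- rand_binary(6, 5, p = 0.4)
  cfg <- run_config(disease_sim_mode = "gip_only")
  for (m in c("dwnn-rls", "rls-avg", "rls-kron", "netlaprls", "katz", "nbi", "wp")) {
    pred <- get_predictor(m, cfg)
    p1 <- pred(Y); p2 <- pred(Y)
    expect_identical(p1, p2)
    expect_equal(dim(p1), dim(Y))
    expect_identical(dimnames(p1), dimnames(Y))
    expect_true(all(is.finite(p1)))
  }
  expect_error(get_predictor("dbsi"), "unknown method")
})
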