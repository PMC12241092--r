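toy_dataset <- function(n, p, seed = 1, f = identity) {
  set.seed(seed)
  nodes <- node_metadata(paste0("V", seq_len(p)),
                         rep("d1", p))
  item_dataset(f(matrix(rnorm(n * p), n, p)), nodes)
}

test_that("correlation_matrix is exact on its diagonal and contracts", {
  ds <- toy_dataset(100, 4, seed = 2)
  ds$values[, 2] <- 2 * ds$values[, 1] + 3  # perfectly correlated pair
  S <- correlation_matrix(ds)
  expect_equal(S$S[1, 2], 1)
  expect_equal(unname(diag(S$S)), rep(1, 4))
  expect_equal(S$n, 100)

  ds$values[, 3] <- 7
  expect_error(correlation_matrix(ds), "constant column.*V3")

  # rank correlations are invariant under monotone transforms
  ds2 <- toy_dataset(200, 3, seed = 3)
  r1 <- correlation_matrix(ds2, method = "spearman")$S
  ds2$values <- exp(ds2$values)
  r2 <- correlation_matrix(ds2, method = "spearman")$S
  expect_equal(r1, r2, tolerance = 1e-12)

  # independent columns at large n: sampling bound 3 / sqrt(n)
  ds3 <- toy_dataset(50000, 5, seed = 4)
  S3 <- correlation_matrix(ds3)$S
  expect_lt(max(abs(S3[upper.tri(S3)])), 0.03)
})

test_that("glasso fixed points and two-variable closed forms", {
  expect_equal(glasso(diag(3), 0.2)$theta, diag(3))
  expect_equal(glasso(diag(3), 0)$theta, diag(3))

  S <- matrix(c(1, .5, .5, 1), 2)
  f0 <- glasso(S, 0)
  expect_equal(f0$theta, solve(S), tolerance = 1e-12)
  expect_equal(f0$theta[1, 2], -2 / 3)

  # penalty exceeding |r| soft-thresholds the edge away
  expect_equal(glasso(S, 0.6)$theta[1, 2], 0)
  # closed form below the threshold: implied covariance moves by lambda
  f <- glasso(S, 0.2)
  expect_equal(f$sigma[1, 2], 0.3, tolerance = 1e-6)
})

test_that("glasso satisfies the KKT stationarity contract", {
  set.seed(5)
  for (rep in 1:5) {
    X <- matrix(rnorm(80 * 6), 80, 6)
    S <- cor(X)
    for (lam in c(0.05, 0.2, 0.5)) {
      fit <- glasso(S, lam)
      resid <- fit$sigma - S
      diag(resid) <- 0
      expect_lt(max(abs(resid)), lam + 1e-5)
      expect_equal(unname(diag(fit$sigma)), unname(diag(S)))
      act <- which(fit$theta != 0 & upper.tri(fit$theta))
      if (length(act) > 0) {
        expect_lt(max(abs(resid[act] - lam * sign(fit$theta[act]))), 1e-5)
      }
      # positive definite solution
      expect_gt(min(eigen(fit$theta, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
    }
  }
})

test_that("precision_to_partial standardizes and validates", {
  expect_equal(precision_to_partial(diag(4)), matrix(0, 4, 4))
  theta <- matrix(c(4 / 3, -2 / 3, -2 / 3, 4 / 3), 2)
  expect_equal(precision_to_partial(theta)[1, 2], 0.5)
  set.seed(6)
  A <- crossprod(matrix(rnorm(25), 5))
  W <- precision_to_partial(A + diag(5))
  expect_equal(W, t(W))
  expect_equal(unname(diag(W)), rep(0, 5))
  expect_error(precision_to_partial(matrix(c(-1, 0, 0, 1), 2)),
               "non-positive diagonal")
})

test_that("ebic matches its closed formula and limits", {
  set.seed(7)
  X <- matrix(rnorm(200 * 4), 200, 4)
  S <- cor(X)
  fit <- glasso(S, 0.1)
  E <- sum(fit$theta[upper.tri(fit$theta)] != 0)
  ll <- (200 / 2) * (determinant(fit$theta)$modulus[1] -
                       sum(S * fit$theta))
  expect_equal(ebic(fit, S, 200, gamma = 0),
               -2 * ll + E * log(200))
  expect_equal(ebic(fit, S, 200, gamma = 0.5),
               -2 * ll + E * log(200) + 4 * E * 0.5 * log(4))
  # empty model: no edge penalty at all
  th0 <- diag(1 / diag(cov(X)))
  ll0 <- (200 / 2) * (determinant(th0)$modulus[1] - sum(S * th0))
  expect_equal(ebic(th0, S, 200, gamma = 0.5), -2 * ll0)
  # nested models differ by the analytic penalty increment
  fit2 <- glasso(S, 0.02)
  E2 <- sum(fit2$theta[upper.tri(fit2$theta)] != 0)
  ll2 <- (200 / 2) * (determinant(fit2$theta)$modulus[1] -
                        sum(S * fit2$theta))
  expect_equal(ebic(fit2, S, 200, 0.5) - ebic(fit, S, 200, 0.5),
               -2 * (ll2 - ll) + (E2 - E) * (log(200) + 4 * 0.5 * log(4)))
  expect_error(ebic(matrix(c(1, 1, 1, 1), 2), S[1:2, 1:2], 10),
               "positive definite")
})

test_that("sparsity tracks the penalty, and larger gamma never adds edges", {
  # Glasso active sets are not strictly nested along the path (small local
  # reversals are a real property of the estimator, reproduced by an
  # independent solver), so the check is on the overall trend: empty at
  # lambda >= max |r|, dense at the bottom, strongly monotone rank trend.
  ds <- sample_dataset(default_spec(), seed = 31)
  S <- correlation_matrix(ds)
  lams <- exp(seq(log(max(abs(S$S[upper.tri(S$S)]))), log(0.01),
                  length.out = 12))
  edges <- vapply(lams, function(l) {
    th <- glasso(S, l)$theta
    sum(th[upper.tri(th)] != 0)
  }, numeric(1))
  expect_equal(edges[1], 0)  # penalty at lambda_max kills every edge
  expect_gt(edges[12], edges[2])
  expect_lt(cor(log(lams), edges, method = "spearman"), -0.8)

  m_lo <- estimate_network(ds, gamma = 0)
  m_hi <- estimate_network(ds, gamma = 1)
  expect_lte(m_hi$n_edges, m_lo$n_edges)
})

test_that("lambda = 0 matches direct-inversion partial correlations", {
  set.seed(8)
  for (p in c(3, 5, 6)) {
    X <- matrix(rnorm(500 * p), 500, p)
    S <- cor(X)
    W_glasso <- precision_to_partial(glasso(S, 0))
    W_direct <- precision_to_partial(solve(S))
    expect_lt(max(abs(W_glasso - W_direct)), 1e-6)
  }
})

test_that("independent columns select the empty network", {
  ds <- toy_dataset(2000, 8, seed = 9)
  m <- estimate_network(ds)
  expect_equal(m$n_edges, 0)
  expect_equal(m$possible_pairs, 28)
})

test_that("estimation is equivariant under column permutation", {
  spec <- null_shift_spec(400L, 400L, seed = 17L)
  ds <- sample_dataset(spec, discretize = FALSE, seed = 17)
  m <- estimate_network(ds)
  set.seed(18)
  perm <- sample(18)
  ds_p <- ds
  ds_p$values <- ds$values[, perm]
  ds_p$nodes <- ds$nodes[perm, ]
  m_p <- estimate_network(ds_p)
  expect_lt(max(abs(m_p$W - m$W[perm, perm])), 1e-5)
  expect_equal(m_p$lambda, m$lambda)
})

test_that("an 18-node model reports 153 possible pairs", {
  ds <- sample_dataset(default_spec(), seed = 1)
  m <- estimate_network(ds)
  expect_identical(m$possible_pairs, 153)
  expect_lte(m$n_edges, 153)
})

test_that("write_network exports edges and counts, and round-trips", {
  ds <- sample_dataset(default_spec(), seed = 4)
  m <- estimate_network(ds)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_network(m, path)
  edges <- read.delim(path)
  expect_equal(nrow(edges), m$n_edges)
  summ <- jsonlite::read_json(out$summary)
  expect_equal(summ$possible_pairs, 153)
  expect_equal(summ$nonzero_edges, m$n_edges)
  expect_equal(summ$positive_edges, m$n_positive)
  back <- read_network(path, m$nodes)
  expect_equal(back$W, m$W, tolerance = 1e-9)

  # hand-built model: 3 positive and 2 negative edges, then an empty one
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.3
  W[1, 3] <- W[3, 1] <- 0.2
  W[1, 4] <- W[4, 1] <- 0.1
  W[2, 3] <- W[3, 2] <- -0.15
  W[3, 4] <- W[4, 3] <- -0.05
  nodes <- node_metadata(paste0("V", 1:4), rep("d", 4))
  m2 <- symptomnet:::as_network_model(W, nodes)
  out2 <- write_network(m2, path)
  summ2 <- jsonlite::read_json(out2$summary)
  expect_equal(summ2$positive_edges, 3)
  expect_equal(summ2$nonzero_edges, 5)

  m0 <- symptomnet:::as_network_model(matrix(0, 4, 4), nodes)
  out0 <- write_network(m0, path)
  expect_equal(nrow(read.delim(path)), 0)
  expect_equal(jsonlite::read_json(out0$summary)$nonzero_edges, 0)
})
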