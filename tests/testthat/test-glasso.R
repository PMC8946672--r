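cor2 <- function(S, n = 200) structure(list(S = S, n = n), class = "cor_input")

test_that("independence and full-shrinkage limits are exact", {
  S <- diag(4)
  for (lam in c(0, 0.1, 0.5)) {
    expect_equal(glasso_fit(S, lam), diag(4), tolerance = 1e-8)
  }
  set.seed(21)
  x <- matrix(rnorm(300 * 4), 300, 4)
  S2 <- cor(x %*% matrix(rnorm(16), 4, 4))
  lam_max <- max(abs(S2[upper.tri(S2)]))
  Th <- glasso_fit(S2, lam_max + 1e-6)
  expect_equal(Th[upper.tri(Th)], rep(0, 6))
})

test_that("unpenalized fit inverts the correlation matrix", {
  set.seed(22)
  x <- matrix(rnorm(2000 * 4), 2000, 4) %*% chol(toeplitz(0.5^(0:3)))
  S <- cor(x)
  Theta <- glasso_fit(S, 0)
  expect_equal(Theta, solve(S), tolerance = 1e-6, ignore_attr = TRUE)
  W <- precision_to_partial(Theta)
  P_classic <- -stats::cov2cor(solve(S))
  diag(P_classic) <- 0
  expect_equal(W, P_classic, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the solver matches an independent proximal-gradient oracle on small problems", {
  S3 <- matrix(c(1, 0.5, 0.3,
                 0.5, 1, 0.2,
                 0.3, 0.2, 1), 3, 3)
  for (lam in c(0.05, 0.1, 0.25)) {
    expect_equal(glasso_fit(S3, lam), ista_glasso(S3, lam),
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
  S2 <- matrix(c(1, -0.6, -0.6, 1), 2, 2)
  expect_equal(glasso_fit(S2, 0.15), ista_glasso(S2, 0.15),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("KKT optimality conditions hold at the returned precision matrix", {
  set.seed(23)
  x <- planted_items(6, list(list(1, 2, 0.4), list(3, 4, 0.3)), n = 300,
                     seed = 23)
  S <- sample_correlation(npn_transform(x))
  for (lam in c(0.02, 0.08, 0.2)) {
    Theta <- glasso_fit(S, lam)
    Sigma <- solve(Theta)
    R <- Sigma - S$S
    tol <- 1e-5
    for (i in 1:5) {
      for (j in seq(i + 1, 6)) {
        if (abs(Theta[i, j]) > 1e-10) {
          expect_equal(R[i, j], lam * sign(Theta[i, j]), tolerance = 1e-4)
        } else {
          expect_lte(abs(R[i, j]), lam + tol)
        }
      }
    }
  }
})

test_that("precision_to_partial matches the inverse-covariance route and checks inputs", {
  expect_equal(precision_to_partial(diag(3)), matrix(0, 3, 3))
  Th <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_equal(precision_to_partial(Th)[1, 2], 0.5)
  set.seed(24)
  A <- matrix(rnorm(16), 4, 4)
  Theta <- crossprod(A) + diag(4)
  Sigma <- solve(Theta)
  Theta_back <- solve(Sigma)  # independent route via the covariance
  d <- 1 / sqrt(diag(Theta_back))
  expected <- -Theta_back * outer(d, d)
  diag(expected) <- 0
  expect_equal(precision_to_partial(Theta), expected, tolerance = 1e-10)
  bad <- diag(3); bad[2, 2] <- -1
  expect_error(precision_to_partial(bad), "non-positive diagonal")
})

test_that("ebic_score reproduces the closed-form penalty arithmetic", {
  set.seed(25)
  p <- 12
  Theta <- diag(p)
  Theta[1, 2] <- Theta[2, 1] <- -0.3
  Theta[3, 4] <- Theta[4, 3] <- -0.2
  Theta[5, 6] <- Theta[6, 5] <- 0.25
  S <- cor2(stats::cov2cor(solve(Theta)), n = 100)
  L <- (100 / 2) * (determinant(Theta)$modulus[1] - sum(S$S * Theta))
  expect_equal(ebic_score(Theta, S, gamma = 0.5),
               -2 * L + 3 * log(100) + 4 * 3 * 0.5 * log(12))
  # gamma = 0 reduces to BIC; no edges removes the penalty entirely
  expect_equal(ebic_score(Theta, S, gamma = 0), -2 * L + 3 * log(100))
  Dg <- diag(p)
  L0 <- (100 / 2) * (0 - sum(S$S * Dg))
  expect_equal(ebic_score(Dg, S, gamma = 0.5), -2 * L0)
})

test_that("EBIC selection finds an empty network for independent data", {
  fit <- ebic_glasso(cor2(diag(5), n = 500))
  expect_equal(fit$edge_count, 0)
  expect_equal(fit$W, matrix(0, 5, 5), ignore_attr = TRUE)
})

test_that("EBIC selection recovers a planted chain graph at large n", {
  Theta <- diag(12)
  for (i in 1:11) Theta[i, i + 1] <- Theta[i + 1, i] <- -0.35
  set.seed(26)
  x <- MASS::mvrnorm(5000, rep(0, 12), stats::cov2cor(solve(Theta)))
  colnames(x) <- paste0("Q", 1:12)
  fit <- fit_network(x)
  support <- abs(fit$W) > 1e-10
  truth <- matrix(FALSE, 12, 12)
  for (i in 1:11) truth[i, i + 1] <- truth[i + 1, i] <- TRUE
  # every chain edge is found ...
  expect_true(all(support[truth]))
  # ... spurious edges are rare (the l1 penalty biases towards a few
  # weak false positives even at large n) and clearly weaker than the
  # genuine ones
  ut <- upper.tri(truth)
  expect_gte(mean(!support[!truth & ut]), 0.9)
  spurious <- abs(fit$W[!truth & ut])
  expect_lt(max(spurious), min(abs(fit$W[truth & ut])))
})

test_that("edge count is monotone non-increasing in lambda along the path", {
  set.seed(27)
  x <- planted_items(8, list(list(1, 2, 0.4), list(2, 3, 0.3),
                             list(5, 6, 0.2)), n = 400, seed = 27)
  fit <- fit_network(x)
  path <- fit$path[fit$path$converged, ]
  expect_true(all(diff(path$edge_count) >= 0))  # path is decreasing in lambda
  expect_equal(fit$ebic, min(path$ebic))
})

test_that("network invariants hold: symmetry, zero diagonal, bounded weights, sign link", {
  x <- planted_items(6, list(list(1, 2, 0.45), list(3, 4, -0.3)), n = 600,
                     seed = 28)
  fit <- fit_network(x)
  expect_identical(fit$W, t(fit$W))
  expect_equal(unname(diag(fit$W)), rep(0, 6))
  expect_true(all(abs(fit$W) <= 1))
  expect_true(min(eigen(fit$Theta, symmetric = TRUE)$values) > 0)
  off <- upper.tri(fit$W)
  expect_identical(fit$W[off] == 0, fit$Theta[off] == 0)
  expect_equal(fit$W[off], (-fit$Theta / sqrt(tcrossprod(diag(fit$Theta))))[off])
  expect_equal(fit$edge_count, sum(fit$W[off] != 0))
})
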