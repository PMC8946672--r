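#' Graphical lasso at a fixed penalty
#'
#' Penalized maximum-likelihood estimate of the precision matrix:
#' maximizes `log det(Theta) - tr(S Theta) - lambda * sum_{i != j}
#' |theta_ij|` over symmetric positive-definite matrices, by block
#' coordinate descent on the covariance. The diagonal is unpenalized.
#'
#' @param S Either a `cor_input` from [sample_correlation()] or a bare
#'   symmetric correlation/covariance matrix.
#' @param lambda Non-negative penalty.
#' @param tol Convergence tolerance on the maximum absolute change of
#'   the working covariance per sweep.
#' @param maxit Sweep cap; non-convergence is an error reporting the
#'   KKT residual.
#' @return Symmetric positive-definite precision matrix `Theta`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-6, maxit = 10000L) {
  S <- cor_input_matrix(S)
  if (lambda < 0) abort("glasso_fit: lambda must be >= 0")
  fit <- .glasso_fit_cpp(S, lambda, tol, as.integer(maxit))
  Theta <- fit$Theta
  dimnames(Theta) <- dimnames(S)
  Theta
}

cor_input_matrix <- function(S) {
  if (inherits(S, "cor_input")) S <- S$S
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8) {
    abort("S must be a symmetric square matrix")
  }
  if (anyNA(S)) abort("S contains NA entries")
  (S + t(S)) / 2
}

#' Precision matrix to partial-correlation edge weights
#'
#' `w_ij = -theta_ij / sqrt(theta_ii * theta_jj)`, diagonal set to
#' zero. These signed weights are the edges of the displayed network:
#' the association between two items adjusted for all other items.
#'
#' @param Theta Symmetric precision matrix with positive diagonal.
#' @return Symmetric edge-weight matrix with zero diagonal.
#' @export
precision_to_partial <- function(Theta) {
  Theta <- as.matrix(Theta)
  if (any(diag(Theta) <= 0)) {
    abort("precision_to_partial: non-positive diagonal entry")
  }
  d <- 1 / sqrt(diag(Theta))
  W <- -Theta * tcrossprod(d)
  diag(W) <- 0
  (W + t(W)) / 2
}

# Nonzero upper-triangle count with the solver noise tolerance.
edge_count <- function(Theta, zero_tol = 1e-10) {
  sum(abs(Theta[upper.tri(Theta)]) > zero_tol)
}

#' Extended Bayesian Information Criterion of a fitted precision matrix
#'
#' `EBIC = -2 L + E log(n) + 4 E gamma log(p)` with Gaussian
#' log-likelihood `L = (n / 2) (log det Theta - tr(S Theta))` and `E`
#' the number of nonzero upper-triangle entries of `Theta`. `gamma = 0`
#' recovers the ordinary BIC; larger `gamma` prefers sparser models.
#'
#' @param Theta Precision matrix (positive definite).
#' @param S A `cor_input` (matrix plus the sample size `n`).
#' @param gamma EBIC hyperparameter, >= 0.
#' @param zero_tol Entries below this count as structural zeros.
#' @return The EBIC value (smaller is better).
#' @export
ebic_score <- function(Theta, S, gamma = 0.5, zero_tol = 1e-10) {
  if (!inherits(S, "cor_input")) {
    abort("ebic_score: S must be a cor_input (needs the sample size)")
  }
  n <- S$n
  p <- ncol(S$S)
  ld <- determinant(Theta, logarithm = TRUE)
  if (ld$sign <= 0) abort("ebic_score: Theta is not positive definite")
  L <- (n / 2) * (as.numeric(ld$modulus) - sum(S$S * Theta))
  E <- edge_count(Theta, zero_tol)
  -2 * L + E * log(n) + 4 * E * gamma * log(p)
}

#' EBIC-tuned graphical lasso network
#'
#' Fits the graphical lasso along a decreasing log-spaced penalty path
#' from `lambda_max = max_{i != j} |S_ij|` down to
#' `lambda_max * lambda_min_ratio`, scores every fit by [ebic_score()],
#' and returns the minimizer (ties broken towards the sparser, larger
#' penalty). The full path is retained for audit.
#'
#' @param S A `cor_input` from [sample_correlation()].
#' @param gamma EBIC hyperparameter; 0.5 is the conventional default
#'   for questionnaire networks.
#' @param n_lambda Number of penalties on the path.
#' @param lambda_min_ratio Smallest penalty as a fraction of
#'   `lambda_max`.
#' @param tol,maxit Solver controls, see [glasso_fit()].
#' @return An `rsi_network` object: edge-weight matrix `W` (partial
#'   correlations), precision matrix `Theta`, selected `lambda`,
#'   `gamma`, achieved `ebic`, `edge_count`, node labels, sample size
#'   `n`, and a `path` tibble (lambda, ebic, edge_count, converged).
#' @export
ebic_glasso <- function(S, gamma = 0.5, n_lambda = 100L,
                        lambda_min_ratio = 0.01, tol = 1e-6,
                        maxit = 10000L) {
  if (!inherits(S, "cor_input")) {
    abort("ebic_glasso: S must be a cor_input (needs the sample size)")
  }
  if (n_lambda < 2) abort("ebic_glasso: n_lambda must be >= 2")
  Sm <- cor_input_matrix(S)
  p <- ncol(Sm)
  nodes <- colnames(Sm) %||% rsi_items(p)
  lambda_max <- max(abs(Sm[upper.tri(Sm)]), 0)
  if (lambda_max == 0) {
    lambdas <- rep(0, n_lambda)  # independence: any penalty gives I
  } else {
    lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                       length.out = n_lambda))
  }
  fits <- .glasso_path_cpp(Sm, lambdas, tol, as.integer(maxit))
  ok <- fits$converged
  if (!any(ok)) abort("ebic_glasso: no penalty on the path converged")
  if (!all(ok)) {
    warn(sprintf("ebic_glasso: %d of %d path fits did not converge and were skipped",
                 sum(!ok), length(ok)))
  }
  path <- tibble::tibble(
    lambda = lambdas,
    converged = ok,
    edge_count = NA_integer_,
    ebic = NA_real_
  )
  for (i in which(ok)) {
    Theta_i <- fits$Theta[[i]]
    path$edge_count[i] <- edge_count(Theta_i)
    path$ebic[i] <- ebic_score(Theta_i, S, gamma = gamma)
  }
  best <- which(path$ebic == min(path$ebic, na.rm = TRUE))[1]  # largest lambda on ties
  Theta <- fits$Theta[[best]]
  dimnames(Theta) <- list(nodes, nodes)
  W <- precision_to_partial(Theta)
  structure(
    list(
      W = W, Theta = Theta, lambda = lambdas[best], gamma = gamma,
      ebic = path$ebic[best], edge_count = path$edge_count[best],
      nodes = nodes, n = S$n, path = path
    ),
    class = "rsi_network"
  )
}

#' Full network-estimation pipeline on raw item scores
#'
#' Convenience wrapper: nonparanormal transform, Pearson correlation,
#' EBIC-tuned graphical lasso.
#'
#' @param data An `rsi_cohort`, data frame with item columns, or a
#'   numeric matrix of item scores.
#' @param items Item columns used when `data` is a data frame.
#' @param ... Passed to [ebic_glasso()].
#' @return An `rsi_network`; see [ebic_glasso()].
#' @export
fit_network <- function(data, items = NULL, ...) {
  x <- if (is.matrix(data)) {
    data
  } else {
    cohort_matrix(data, items = items %||% intersect(rsi_items(100), names(data)))
  }
  ebic_glasso(sample_correlation(npn_transform(x)), ...)
}

#' @export
print.rsi_network <- function(x, ...) {
  cat(sprintf(
    "<rsi_network> %d nodes, %d edges | lambda = %.4g (EBIC gamma = %g), n = %d\n",
    length(x$nodes), x$edge_count, x$lambda, x$gamma, x$n
  ))
  invisible(x)
}

#' Tidy the edges of a fitted network
#'
#' @param x An `rsi_network`.
#' @param keep_zero Keep edges with zero weight (all node pairs).
#' @param ... Unused.
#' @return Tibble with one row per upper-triangle node pair: `from`,
#'   `to`, `weight`.
#' @export
tidy.rsi_network <- function(x, keep_zero = FALSE, ...) {
  edges <- edge_tibble(x$W, x$nodes)
  if (!keep_zero) edges <- dplyr::filter(edges, .data$weight != 0)
  edges
}

edge_tibble <- function(W, nodes) {
  idx <- which(upper.tri(W), arr.ind = TRUE)
  tibble::tibble(
    from = nodes[idx[, 1]],
    to = nodes[idx[, 2]],
    weight = W[idx]
  )
}

#' One-row model summary of a fitted network
#'
#' @param x An `rsi_network`.
#' @param ... Unused.
#' @return Tibble with `n`, `p`, `lambda`, `gamma`, `ebic`,
#'   `edge_count`, `density`.
#' @export
glance.rsi_network <- function(x, ...) {
  p <- length(x$nodes)
  tibble::tibble(
    n = x$n, p = p, lambda = x$lambda, gamma = x$gamma, ebic = x$ebic,
    edge_count = x$edge_count, density = x$edge_count / choose(p, 2)
  )
}
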