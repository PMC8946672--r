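# Item-level marginal means/SDs on the 0-100 scale for the two
# return-to-sport strata of the reference cohort (12-month follow-up
# after ACL reconstruction); these are the generator's default
# marginals.
rsi_marginals <- function() {
  tibble::tibble(
    item = rsi_items(),
    mean_returned = c(89.30, 74.44, 70.10, 83.94, 79.84, 60.63,
                      64.54, 83.46, 65.30, 81.81, 85.91, 80.07),
    sd_returned = c(14.80, 24.53, 29.69, 20.29, 24.24, 34.87,
                    30.84, 20.06, 30.09, 24.69, 18.85, 22.08),
    mean_not_returned = c(71.74, 59.82, 47.92, 63.77, 54.86, 39.87,
                          42.57, 65.42, 43.55, 56.58, 63.25, 55.06),
    sd_not_returned = c(26.36, 25.49, 28.53, 26.73, 29.66, 30.68,
                        28.11, 24.86, 27.77, 33.31, 27.63, 27.81)
  )
}

partial_matrix <- function(p, edges, nodes = rsi_items(p)) {
  P <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (e in edges) {
    P[e[[1]], e[[2]]] <- P[e[[2]], e[[1]]] <- e[[3]]
  }
  P
}

# Precision implied by a partial-correlation matrix with unit
# diagonal: Theta = I - P off-diagonal (since w_ij = -theta_ij when
# theta_ii = 1).
implied_precision <- function(P) {
  Theta <- -P
  diag(Theta) <- 1
  Theta
}

# Uniform off-diagonal shrinkage until the implied precision is
# comfortably positive definite; returns the (possibly unshrunken)
# matrix and the factor applied.
repair_pd <- function(P, min_eig = 1e-3) {
  shrink <- 1
  while (min(eigen(implied_precision(P * shrink), symmetric = TRUE,
                   only.values = TRUE)$values) < min_eig) {
    shrink <- shrink * 0.95
    if (shrink < 0.01) abort("repair_pd: cannot make the precision positive definite")
  }
  list(P = P * shrink, shrink = shrink)
}

#' Specify a two-group synthetic cohort
#'
#' Defines the ground truth the generator draws from: per-group sparse
#' partial-correlation matrices (the planted network), per-item
#' marginal means and SDs on the 0-100 scale, and group sizes. The
#' implied precision matrices must be positive definite; if not, the
#' off-diagonals are uniformly shrunken and the factor recorded.
#'
#' @param p Number of items.
#' @param n_returned,n_not_returned Group sizes (each at least
#'   `p + 5`).
#' @param partials_returned,partials_not_returned `p x p` symmetric
#'   partial-correlation matrices with zero diagonal.
#' @param marginals Tibble with columns `item`, `mean_returned`,
#'   `sd_returned`, `mean_not_returned`, `sd_not_returned`.
#' @param seed Seed for [simulate_cohort()].
#' @return A `sim_spec` list, including `shrink_returned` /
#'   `shrink_not_returned` repair factors (1 when no repair needed).
#' @export
sim_spec <- function(p, n_returned, n_not_returned, partials_returned,
                     partials_not_returned, marginals, seed = 1L) {
  stopifnot(nrow(marginals) == p)
  check_partials <- function(P, label) {
    if (!isTRUE(all.equal(P, t(P))) || any(diag(P) != 0)) {
      abort(paste0("sim_spec: ", label, " must be symmetric with zero diagonal"))
    }
  }
  check_partials(partials_returned, "partials_returned")
  check_partials(partials_not_returned, "partials_not_returned")
  if (min(n_returned, n_not_returned) < p + 5) {
    abort("sim_spec: each group needs at least p + 5 participants")
  }
  rep_a <- repair_pd(partials_returned)
  rep_b <- repair_pd(partials_not_returned)
  structure(
    list(
      p = p, items = marginals$item,
      n_returned = n_returned, n_not_returned = n_not_returned,
      partials_returned = rep_a$P, partials_not_returned = rep_b$P,
      shrink_returned = rep_a$shrink, shrink_not_returned = rep_b$shrink,
      marginals = marginals, seed = seed
    ),
    class = "sim_spec"
  )
}

#' Default synthetic-cohort specification
#'
#' The study conditions of the reference ACL-RSI cohort: 12 items,
#' group sizes 115 (returned) and 326 (not returned), marginal
#' means/SDs per item and group from the reference cohort's
#' descriptive table, and a sparse planted network whose two strongest
#' edges are Q7-Q9 (0.48) and Q4-Q8 (0.37) in both groups, plus ten
#' weaker common edges. Three edges differ between the groups (Q2-Q7,
#' Q5-Q8, Q3-Q12, all stronger in the returned group), giving the
#' permutation comparison a plantable alternative hypothesis.
#'
#' @param seed Seed recorded in the spec.
#' @return A `sim_spec`; see [sim_spec()].
#' @export
default_sim_spec <- function(seed = 1L) {
  common <- list(
    list("Q7", "Q9", 0.48), list("Q4", "Q8", 0.37),
    list("Q1", "Q11", 0.18), list("Q1", "Q4", 0.12),
    list("Q2", "Q10", 0.15), list("Q5", "Q11", 0.15),
    list("Q6", "Q7", 0.12), list("Q9", "Q10", 0.12),
    list("Q3", "Q6", 0.10), list("Q10", "Q12", 0.10),
    list("Q8", "Q11", 0.12), list("Q6", "Q12", 0.10)
  )
  returned_only <- list(
    list("Q2", "Q7", 0.25), list("Q5", "Q8", 0.25), list("Q3", "Q12", 0.30)
  )
  not_returned_only <- list(
    list("Q2", "Q7", 0.05), list("Q5", "Q8", 0.05), list("Q3", "Q12", 0.10)
  )
  sim_spec(
    p = 12L, n_returned = 115L, n_not_returned = 326L,
    partials_returned = partial_matrix(12L, c(common, returned_only)),
    partials_not_returned = partial_matrix(12L, c(common, not_returned_only)),
    marginals = rsi_marginals(), seed = seed
  )
}

#' Generate a synthetic two-group cohort
#'
#' Draws a latent multivariate normal with the correlation structure
#' implied by each group's planted precision matrix, maps each column
#' onto the 0-100 scale with the group/item mean and SD, clips to
#' \[0, 100\] (reproducing the ceiling effects typical of such
#' scales) and rounds to integers. Deterministic given `spec$seed`.
#'
#' @param spec A `sim_spec`.
#' @return An `rsi_cohort` tibble containing both groups, with the
#'   `returned` label; filter on `returned` to get the group tables.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  draw_group <- function(P, n, means, sds) {
    R <- stats::cov2cor(solve(implied_precision(P)))
    Z <- MASS::mvrnorm(n, mu = rep(0, spec$p), Sigma = R)
    X <- sweep(sweep(Z, 2, sds, `*`), 2, means, `+`)
    X <- round(pmin(pmax(X, 0), 100))
    colnames(X) <- spec$items
    X
  }
  m <- spec$marginals
  a <- draw_group(spec$partials_returned, spec$n_returned,
                  m$mean_returned, m$sd_returned)
  b <- draw_group(spec$partials_not_returned, spec$n_not_returned,
                  m$mean_not_returned, m$sd_not_returned)
  out <- tibble::as_tibble(as.data.frame(rbind(a, b)))
  out$returned <- rep(c(TRUE, FALSE), c(spec$n_returned, spec$n_not_returned))
  as_cohort(out, items = spec$items)
}
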