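nct_statistics <- function(net_a, net_b) {
  ut <- upper.tri(net_a$W)
  list(
    edge = abs(net_a$W[ut] - net_b$W[ut]),
    strength = abs(node_strength(net_a$W) - node_strength(net_b$W)),
    global_strength = abs(sum(abs(net_a$W[ut])) - sum(abs(net_b$W[ut]))),
    structure = max(abs(net_a$W[ut] - net_b$W[ut]))
  )
}

#' Permutation network comparison test (NCT)
#'
#' Two-tailed permutation test of between-group differences in edge
#' weights and node Strength. Each group's network is estimated with
#' the full pipeline (its own transform, correlation, and EBIC-selected
#' penalty); the pooled participants are then repeatedly reassigned at
#' random to pseudo-groups of the original sizes, both networks
#' re-estimated, and the absolute differences recomputed, giving a
#' null distribution for every statistic. P-values use the
#' `(1 + count) / (1 + M)` estimator, so they are never exactly zero.
#' Global-strength and maximum-edge-difference omnibus statistics are
#' reported as extras. No multiple-comparison adjustment is applied;
#' results are exploratory.
#'
#' @param data_a,data_b Cohort tables (or data frames of item scores)
#'   for the two groups; identical item sets.
#' @param n_permutations Permutation draws (1000 by default).
#' @param seed Master seed; fully reproducible.
#' @param items Item columns when the inputs are data frames.
#' @param ... Passed to [ebic_glasso()].
#' @return An `nct_result` with tibbles `edges` (`from`, `to`,
#'   `weight_a`, `weight_b`, `diff`, `p`), `nodes` (`node`,
#'   `strength_a`, `strength_b`, `diff`, `p`) and `global`; plus
#'   `n_permutations`, `seed`, `alpha`, `adjusted = FALSE`.
#' @export
nct <- function(data_a, data_b, n_permutations = 1000L, seed = 1L,
                items = NULL, ...) {
  data_a <- as.data.frame(data_a)
  data_b <- as.data.frame(data_b)
  items <- items %||% intersect(rsi_items(100), names(data_a))
  if (length(items) == 0) items <- colnames(data_a)
  if (!all(items %in% names(data_b))) {
    abort("nct: the two groups must share the same item columns")
  }
  p <- length(items)
  n_a <- nrow(data_a)
  n_b <- nrow(data_b)
  if (min(n_a, n_b) < max(p + 2, 4)) {
    abort("nct: each group needs more participants than items (p + 2 at least)")
  }
  if (min(n_a, n_b) < p + 5) {
    warn("nct: a group has fewer than p + 5 participants; estimates are fragile")
  }
  pooled <- rbind(data_a[items], data_b[items])
  # canonical row order makes the permutation draws, and hence the
  # p-values, invariant to swapping the group labels
  pooled <- pooled[do.call(order, as.list(pooled)), , drop = FALSE]
  net_a <- fit_network(data_a, items = items, ...)
  net_b <- fit_network(data_b, items = items, ...)
  obs <- nct_statistics(net_a, net_b)

  seeds <- replicate_seeds(seed, 2L * n_permutations)
  count_edge <- numeric(length(obs$edge))
  count_strength <- numeric(p)
  count_global <- 0
  count_structure <- 0
  k <- 0L
  attempt <- 0L
  while (k < n_permutations) {
    attempt <- attempt + 1L
    if (attempt > 2L * n_permutations) {
      abort("nct: failed permutation replicates exceeded the redraw cap")
    }
    set.seed(seeds[attempt])
    idx_a <- sample.int(n_a + n_b, n_a, replace = FALSE)
    perm_a <- refit_or_null(idx_a, pooled, items, ...)
    perm_b <- refit_or_null(setdiff(seq_len(n_a + n_b), idx_a), pooled,
                            items, ...)
    if (is.null(perm_a) || is.null(perm_b)) next
    k <- k + 1L
    st <- nct_statistics(perm_a, perm_b)
    count_edge <- count_edge + (st$edge >= obs$edge)
    count_strength <- count_strength + (st$strength >= obs$strength)
    count_global <- count_global + (st$global_strength >= obs$global_strength)
    count_structure <- count_structure + (st$structure >= obs$structure)
  }
  pval <- function(count) (1 + count) / (1 + n_permutations)
  ut <- which(upper.tri(net_a$W), arr.ind = TRUE)
  structure(
    list(
      edges = tibble::tibble(
        from = net_a$nodes[ut[, 1]], to = net_a$nodes[ut[, 2]],
        weight_a = net_a$W[ut], weight_b = net_b$W[ut],
        diff = obs$edge, p = pval(count_edge)
      ),
      nodes = tibble::tibble(
        node = net_a$nodes,
        strength_a = unname(node_strength(net_a$W)),
        strength_b = unname(node_strength(net_b$W)),
        diff = unname(obs$strength), p = pval(unname(count_strength))
      ),
      global = tibble::tibble(
        statistic = c("global_strength", "structure_max_edge"),
        observed = c(obs$global_strength, obs$structure),
        p = c(pval(count_global), pval(count_structure))
      ),
      network_a = net_a, network_b = net_b,
      n_permutations = n_permutations, seed = seed,
      alpha = 0.05, adjusted = FALSE
    ),
    class = "nct_result"
  )
}

#' @export
print.nct_result <- function(x, ...) {
  sig <- report_significant(x)
  cat(sprintf("<nct_result> %d permutations, seed %d; %d statistic(s) with p < %.2f (unadjusted)\n",
              x$n_permutations, x$seed, nrow(sig), x$alpha))
  invisible(x)
}

#' Tidy per-statistic NCT results
#'
#' @param x An `nct_result`.
#' @param ... Unused.
#' @return Tibble with one row per tested statistic: `type`
#'   (`"edge"` or `"strength"`), `statistic` (edge or node name),
#'   `diff` (observed absolute difference) and `p`.
#' @export
tidy.nct_result <- function(x, ...) {
  dplyr::bind_rows(
    x$edges |>
      dplyr::transmute(
        type = "edge",
        statistic = paste0(.data$from, "-", .data$to),
        diff = .data$diff, p = .data$p
      ),
    x$nodes |>
      dplyr::transmute(
        type = "strength", statistic = .data$node,
        diff = .data$diff, p = .data$p
      )
  )
}

#' Statistics with unadjusted p below the reporting threshold
#'
#' @param result An `nct_result`.
#' @param alpha Reporting threshold (0.05). P-values are not adjusted
#'   for multiple comparisons; treat the list as exploratory evidence,
#'   not confirmatory findings.
#' @return Tibble of significant statistics (possibly empty), columns
#'   as in [tidy.nct_result()] plus `adjusted = FALSE`.
#' @export
report_significant <- function(result, alpha = result$alpha) {
  tidy(result) |>
    dplyr::filter(.data$p < alpha) |>
    dplyr::mutate(adjusted = FALSE)
}
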