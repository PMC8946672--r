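# Draw per-replicate seeds up front from the master seed so results do
# not depend on execution order or on how many replicates get redrawn.
replicate_seeds <- function(seed, n) {
  withr_seed <- function() {
    set.seed(seed)
    sample.int(2147483646L, n)
  }
  withr_seed()
}

refit_or_null <- function(rows, data, items, ...) {
  tryCatch(
    suppressWarnings(fit_network(data[rows, , drop = FALSE], items = items, ...)),
    error = function(e) NULL
  )
}

#' Bootstrap confidence intervals for edge weights
#'
#' Nonparametric bootstrap of the whole estimation pipeline: each
#' replicate resamples `n` participants with replacement, reruns the
#' nonparanormal transform, correlation, and EBIC-tuned graphical
#' lasso (the penalty is re-selected every time), and records every
#' edge weight. Percentile 2.5/97.5 intervals are reported. Replicates
#' whose estimation fails are redrawn, with a cap of `2 * B` attempts.
#'
#' @param data Cohort table (or data frame / matrix of item scores).
#' @param B Bootstrap iterations; 1000 for reporting-quality intervals.
#' @param seed Master seed; the result is fully reproducible from it.
#' @param items Item columns when `data` is a data frame.
#' @param ... Passed to [ebic_glasso()].
#' @return An `edge_bootstrap` object; `tidy()` gives a tibble with
#'   one row per edge: `from`, `to`, `estimate` (full-sample weight),
#'   `boot_mean`, `ci_low`, `ci_high`.
#' @export
bootstrap_edges <- function(data, B = 1000L, seed = 1L, items = NULL, ...) {
  if (B < 100) warn("bootstrap_edges: B < 100 gives unreliable intervals")
  data <- as.data.frame(data)
  items <- items %||% intersect(rsi_items(100), names(data))
  if (length(items) == 0) items <- colnames(data)
  fit <- fit_network(data, items = items, ...)
  n <- nrow(data)
  edges <- edge_tibble(fit$W, fit$nodes)
  seeds <- replicate_seeds(seed, 2L * B)
  draws <- matrix(NA_real_, nrow = B, ncol = nrow(edges))
  b <- 0L
  attempt <- 0L
  while (b < B) {
    attempt <- attempt + 1L
    if (attempt > 2L * B) {
      abort(sprintf("bootstrap_edges: %d failed replicates exceeded the redraw cap", attempt - b))
    }
    set.seed(seeds[attempt])
    rows <- sample.int(n, n, replace = TRUE)
    refit <- refit_or_null(rows, data, items, ...)
    if (is.null(refit)) next
    b <- b + 1L
    draws[b, ] <- refit$W[upper.tri(refit$W)]
  }
  edges <- edges |>
    dplyr::mutate(
      estimate = .data$weight,
      boot_mean = colMeans(draws),
      ci_low = apply(draws, 2, quantile, probs = 0.025),
      ci_high = apply(draws, 2, quantile, probs = 0.975)
    ) |>
    dplyr::select(-"weight")
  structure(
    list(edges = edges, draws = draws, B = B, seed = seed, network = fit),
    class = "edge_bootstrap"
  )
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat(sprintf("<edge_bootstrap> %d edges, B = %d, seed = %d\n",
              nrow(x$edges), x$B, x$seed))
  invisible(x)
}

#' @rdname bootstrap_edges
#' @param x An `edge_bootstrap`.
#' @export
tidy.edge_bootstrap <- function(x, ...) x$edges

#' Case-dropping subset bootstrap for centrality stability
#'
#' For each drop proportion, repeatedly subsamples the retained
#' fraction of participants without replacement, re-estimates the
#' network (penalty re-selected), recomputes node Strength, and stores
#' the Pearson correlation between the replicate's Strength vector and
#' the full-sample one. Feed the result to [cs_coefficient()].
#'
#' @inheritParams bootstrap_edges
#' @param proportions Grid of drop proportions (0.05 to 0.75 by 0.05
#'   by default).
#' @param B_per_proportion Replicates per proportion.
#' @return A `case_drop` object; `tidy()` gives a tibble with
#'   `proportion`, `replicate`, `correlation`.
#' @export
case_drop_bootstrap <- function(data, proportions = seq(0.05, 0.75, by = 0.05),
                                B_per_proportion = 1000L, seed = 1L,
                                items = NULL, ...) {
  data <- as.data.frame(data)
  items <- items %||% intersect(rsi_items(100), names(data))
  if (length(items) == 0) items <- colnames(data)
  n <- nrow(data)
  p <- length(items)
  if (any(proportions <= 0 | proportions >= 1)) {
    abort("case_drop_bootstrap: proportions must lie strictly in (0, 1)")
  }
  keep_n <- floor((1 - proportions) * n)
  if (any(keep_n < p + 5)) {
    abort("case_drop_bootstrap: retained sample below p + 5 for some proportion")
  }
  fit <- fit_network(data, items = items, ...)
  s0 <- node_strength(fit$W)
  rows_out <- list()
  for (k in seq_along(proportions)) {
    pi_k <- proportions[k]
    seeds <- replicate_seeds(stage_seed(seed, paste0("drop", k)),
                             2L * B_per_proportion)
    cors <- numeric(B_per_proportion)
    b <- 0L
    attempt <- 0L
    while (b < B_per_proportion) {
      attempt <- attempt + 1L
      if (attempt > 2L * B_per_proportion) {
        abort("case_drop_bootstrap: failed replicates exceeded the redraw cap")
      }
      set.seed(seeds[attempt])
      rows <- sample.int(n, keep_n[k], replace = FALSE)
      refit <- refit_or_null(rows, data, items, ...)
      if (is.null(refit)) next
      b <- b + 1L
      s_b <- node_strength(refit$W)
      cors[b] <- if (sd(s_b) == 0 || sd(s0) == 0) NA_real_ else cor(s_b, s0)
    }
    rows_out[[k]] <- tibble::tibble(
      proportion = pi_k,
      replicate = seq_len(B_per_proportion),
      correlation = cors
    )
  }
  structure(
    list(
      correlations = dplyr::bind_rows(rows_out),
      proportions = proportions,
      B_per_proportion = B_per_proportion,
      correlation_threshold = 0.7,
      probability_level = 0.95,
      seed = seed, network = fit
    ),
    class = "case_drop"
  )
}

#' @export
print.case_drop <- function(x, ...) {
  cat(sprintf("<case_drop> proportions %.2f..%.2f, B = %d per proportion, CS = %.2f\n",
              min(x$proportions), max(x$proportions), x$B_per_proportion,
              cs_coefficient(x)))
  invisible(x)
}

#' @rdname case_drop_bootstrap
#' @param x A `case_drop`.
#' @export
tidy.case_drop <- function(x, ...) x$correlations

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion such that, at it and at every smaller
#' proportion on the grid, at least `probability_level` (default 95%)
#' of replicate centralities correlate at least
#' `correlation_threshold` (default 0.7) with the full-sample
#' centralities; 0 if no proportion qualifies. Values below 0.25 flag
#' an unstable centrality ordering; above 0.5 is considered good.
#'
#' @param result A `case_drop` object.
#' @param correlation_threshold Correlation the replicates must reach.
#' @param probability_level Required fraction of qualifying replicates.
#' @return The CS-coefficient (a member of the drop grid, or 0).
#' @export
cs_coefficient <- function(result,
                           correlation_threshold = result$correlation_threshold,
                           probability_level = result$probability_level) {
  qual <- result$correlations |>
    dplyr::group_by(.data$proportion) |>
    dplyr::summarise(
      ok = mean(!is.na(.data$correlation) &
                  .data$correlation >= correlation_threshold) >=
        probability_level,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$proportion)
  qualifies <- cumprod(as.numeric(qual$ok)) == 1
  if (!any(qualifies)) return(0)
  max(qual$proportion[qualifies])
}
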