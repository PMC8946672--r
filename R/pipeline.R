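#' Configuration for a full network analysis run
#'
#' One object holding every tunable of the pipeline. Each stochastic
#' stage derives its own seed deterministically from `seed` and the
#' stage name, so switching a stage off never shifts another stage's
#' draws.
#'
#' @param input A cohort: path to a delimited file, an `rsi_cohort`,
#'   a plain data frame with item columns and a `returned` column, or
#'   a `sim_spec` to simulate from.
#' @param gamma,n_lambda,lambda_min_ratio Network estimation controls,
#'   see [ebic_glasso()].
#' @param B Edge-bootstrap iterations.
#' @param drop_proportions,B_per_proportion Case-dropping bootstrap
#'   controls, see [case_drop_bootstrap()].
#' @param n_permutations Permutations for the group comparison.
#' @param alpha Reporting threshold for [report_significant()].
#' @param seed Master seed.
#' @param stages Character subset of `"summarize"`, `"fit"`,
#'   `"bootstrap"`, `"stability"`, `"compare"`.
#' @param output_dir Optional directory; when set, every stage writes
#'   its CSV/JSON artifacts there.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, gamma = 0.5, n_lambda = 100L,
                       lambda_min_ratio = 0.01, B = 1000L,
                       drop_proportions = seq(0.05, 0.75, by = 0.05),
                       B_per_proportion = 1000L, n_permutations = 1000L,
                       alpha = 0.05, seed = 1L,
                       stages = c("summarize", "fit", "bootstrap",
                                  "stability", "compare"),
                       output_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(
      input = input, gamma = gamma, n_lambda = n_lambda,
      lambda_min_ratio = lambda_min_ratio, B = B,
      drop_proportions = drop_proportions,
      B_per_proportion = B_per_proportion,
      n_permutations = n_permutations, alpha = alpha, seed = seed,
      stages = stages, output_dir = output_dir
    ),
    class = "run_config"
  )
}

resolve_cohort <- function(input) {
  if (inherits(input, "rsi_cohort")) return(input)
  if (inherits(input, "sim_spec")) return(simulate_cohort(input))
  if (is.character(input) && length(input) == 1) return(read_cohort(input))
  if (is.data.frame(input)) return(as_cohort(input,
    items = intersect(rsi_items(100), names(input))))
  abort("run_full_analysis: cannot resolve the input to a cohort")
}

#' Run the full network analysis
#'
#' Orchestrates the whole study analysis: descriptive summaries, three
#' networks (whole cohort, returned, not returned) with centralities,
#' edge-weight bootstrap intervals and case-dropping CS-coefficients
#' per network, and the permutation comparison of the two subgroups.
#' A machine-readable summary names the maximum-|weight| edge and the
#' top-Strength node of each network.
#'
#' @param config A [run_config()].
#' @return An `rsi_analysis` list with elements `cohort`, `summary`,
#'   `networks`, `centrality`, `edge_bootstrap`, `stability` (with
#'   `cs` per network), `comparison`, `highlights`, and the `config`.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- resolve_cohort(config$input)
  groups <- list(
    whole = cohort,
    returned = dplyr::filter(cohort, .data$returned),
    not_returned = dplyr::filter(cohort, !.data$returned)
  )
  stopifnot(nrow(groups$whole) == nrow(groups$returned) + nrow(groups$not_returned))
  net_args <- list(gamma = config$gamma, n_lambda = config$n_lambda,
                   lambda_min_ratio = config$lambda_min_ratio)
  out <- list(cohort = cohort, config = config)
  on <- function(stage) stage %in% config$stages

  if (on("summarize")) out$summary <- item_summary(cohort)
  if (on("fit")) {
    out$networks <- purrr::map(groups, function(g) {
      do.call(fit_network, c(list(data = g), net_args))
    })
    out$centrality <- purrr::imap_dfr(out$networks, function(net, id) {
      centrality_table(net, network_id = id)
    })
    out$highlights <- purrr::imap_dfr(out$networks, function(net, id) {
      edges <- tidy(net, keep_zero = TRUE)
      top_edge <- edges[which.max(abs(edges$weight)), ]
      s <- node_strength(net$W)
      tibble::tibble(
        network_id = id,
        max_edge = paste0(top_edge$from, "-", top_edge$to),
        max_edge_weight = top_edge$weight,
        top_strength_node = names(s)[which.max(s)],
        top_strength = max(s)
      )
    })
  }
  if (on("bootstrap")) {
    out$edge_bootstrap <- purrr::imap(groups, function(g, id) {
      do.call(bootstrap_edges, c(
        list(data = g, B = config$B,
             seed = stage_seed(config$seed, paste0("bootstrap_", id))),
        net_args
      ))
    })
  }
  if (on("stability")) {
    out$stability <- purrr::imap(groups, function(g, id) {
      do.call(case_drop_bootstrap, c(
        list(data = g, proportions = config$drop_proportions,
             B_per_proportion = config$B_per_proportion,
             seed = stage_seed(config$seed, paste0("stability_", id))),
        net_args
      ))
    })
    out$cs <- purrr::map_dbl(out$stability, cs_coefficient)
  }
  if (on("compare")) {
    out$comparison <- do.call(nct, c(
      list(data_a = groups$returned, data_b = groups$not_returned,
           n_permutations = config$n_permutations,
           seed = stage_seed(config$seed, "compare")),
      net_args
    ))
    out$significant <- report_significant(out$comparison, alpha = config$alpha)
  }
  res <- structure(out, class = "rsi_analysis")
  if (!is.null(config$output_dir)) write_analysis(res, config$output_dir)
  res
}

#' @export
print.rsi_analysis <- function(x, ...) {
  cat(sprintf("<rsi_analysis> n = %d (returned %d / not returned %d); stages: %s\n",
              nrow(x$cohort), sum(x$cohort$returned), sum(!x$cohort$returned),
              paste(x$config$stages, collapse = ", ")))
  if (!is.null(x$highlights)) print(x$highlights)
  invisible(x)
}

write_analysis <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_csv(x, file.path(dir, name))
  if (!is.null(res$summary)) w(res$summary, "item_summary.csv")
  if (!is.null(res$networks)) {
    purrr::iwalk(res$networks, function(net, id) {
      w(tidy(net, keep_zero = TRUE), paste0("edges_", id, ".csv"))
      w(tibble::as_tibble(as.data.frame(net$W), rownames = "node"),
        paste0("weights_", id, ".csv"))
      jsonlite::write_json(
        glance(net), file.path(dir, paste0("model_", id, ".json")),
        auto_unbox = TRUE, digits = NA
      )
    })
    w(res$centrality, "centrality.csv")
    w(res$highlights, "highlights.csv")
  }
  if (!is.null(res$edge_bootstrap)) {
    purrr::iwalk(res$edge_bootstrap, function(bt, id) {
      w(tidy(bt), paste0("edge_bootstrap_", id, ".csv"))
    })
  }
  if (!is.null(res$stability)) {
    purrr::iwalk(res$stability, function(cd, id) {
      w(tidy(cd), paste0("case_drop_", id, ".csv"))
    })
    jsonlite::write_json(as.list(res$cs), file.path(dir, "cs_coefficients.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$comparison)) {
    w(res$comparison$edges, "nct_edges.csv")
    w(res$comparison$nodes, "nct_nodes.csv")
    jsonlite::write_json(
      list(n_permutations = res$comparison$n_permutations,
           seed = res$comparison$seed, alpha = res$comparison$alpha,
           adjusted = res$comparison$adjusted),
      file.path(dir, "nct_meta.json"), auto_unbox = TRUE
    )
  }
  invisible(res)
}
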