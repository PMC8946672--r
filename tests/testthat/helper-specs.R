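# Small synthetic-cohort specifications for fast tests.

flat_marginals <- function(p, mean = 60, sd = 20) {
  tibble::tibble(
    item = paste0("Q", seq_len(p)),
    mean_returned = rep(mean, p), sd_returned = rep(sd, p),
    mean_not_returned = rep(mean, p), sd_not_returned = rep(sd, p)
  )
}

# Both groups share one planted partial-correlation structure given as
# list(list(i, j, value), ...) with integer indices.
small_sim_spec <- function(p, edges = list(), n_a = 40, n_b = 60,
                           seed = 1, mean = 60, sd = 20) {
  idx_edges <- lapply(edges, function(e) {
    list(paste0("Q", e[[1]]), paste0("Q", e[[2]]), e[[3]])
  })
  P <- rsinet:::partial_matrix(p, idx_edges, nodes = paste0("Q", seq_len(p)))
  sim_spec(
    p = p, n_returned = n_a, n_not_returned = n_b,
    partials_returned = P, partials_not_returned = P,
    marginals = flat_marginals(p, mean, sd), seed = seed
  )
}

# A single-group item matrix drawn from a planted structure.
planted_items <- function(p, edges, n, seed) {
  spec <- small_sim_spec(p, edges, n_a = n, n_b = p + 5, seed = seed)
  cohort <- simulate_cohort(spec)
  cohort_matrix(cohort[cohort$returned, ], paste0("Q", seq_len(p)))
}
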