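# Independent oracles used to cross-check the package implementation.
# They deliberately use different algorithms from the package code.

# Proximal-gradient (ISTA) solver for the penalized likelihood
#   max log det(Theta) - tr(S Theta) - lambda * sum_{i!=j} |theta_ij|
# Slow but algorithmically unrelated to block coordinate descent.
ista_glasso <- function(S, lambda, iters = 200000, step = 0.05) {
  p <- nrow(S)
  Theta <- diag(p)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  for (i in seq_len(iters)) {
    grad <- solve(Theta) - S
    Z <- Theta + step * grad
    off <- soft(Z, step * lambda)
    diag(off) <- diag(Z)
    off <- (off + t(off)) / 2
    ev <- eigen(off, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8) {
      step <- step / 2
      next
    }
    if (max(abs(off - Theta)) < 1e-10) {
      Theta <- off
      break
    }
    Theta <- off
  }
  Theta
}

# All-pairs shortest path lengths by plain Dijkstra on the
# 1/|weight| length graph.
dijkstra_lengths <- function(W) {
  p <- nrow(W)
  L <- 1 / abs(W)
  L[W == 0] <- Inf
  diag(L) <- 0
  D <- matrix(Inf, p, p)
  for (s in seq_len(p)) {
    dist <- rep(Inf, p)
    dist[s] <- 0
    visited <- rep(FALSE, p)
    for (step in seq_len(p)) {
      cand <- which(!visited & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      visited[u] <- TRUE
      for (v in which(is.finite(L[u, ]) & !visited)) {
        if (dist[u] + L[u, v] < dist[v]) dist[v] <- dist[u] + L[u, v]
      }
    }
    D[s, ] <- dist
  }
  D
}

# Enumerate every simple path between s and t, keep the shortest ones,
# and split betweenness credit equally among ties. Exponential, only
# for tiny graphs.
enumerate_geodesics <- function(W, s, t) {
  p <- nrow(W)
  L <- 1 / abs(W)
  L[W == 0] <- Inf
  paths <- list()
  walk <- function(path, len) {
    u <- path[length(path)]
    if (u == t) {
      paths[[length(paths) + 1]] <<- list(path = path, len = len)
      return()
    }
    for (v in seq_len(p)) {
      if (!is.finite(L[u, v]) || v %in% path) next
      walk(c(path, v), len + L[u, v])
    }
  }
  walk(s, 0)
  if (length(paths) == 0) return(list())
  lens <- vapply(paths, `[[`, 0, "len")
  paths[abs(lens - min(lens)) < 1e-9]
}

brute_betweenness <- function(W) {
  p <- nrow(W)
  b <- rep(0, p)
  for (s in seq_len(p - 1)) {
    for (t in seq(s + 1, p)) {
      geo <- enumerate_geodesics(W, s, t)
      if (length(geo) == 0) next
      for (g in geo) {
        inner <- setdiff(g$path, c(s, t))
        b[inner] <- b[inner] + 1 / length(geo)
      }
    }
  }
  b
}

brute_closeness <- function(W) {
  D <- dijkstra_lengths(W)
  tot <- rowSums(D)
  ifelse(is.finite(tot) & tot > 0, 1 / tot, 0)
}

# Random sparse symmetric weight matrix whose absolute values give a
# connected-ish small graph; used for centrality cross-checks.
random_weight_matrix <- function(p, density = 0.5, seed = 1) {
  set.seed(seed)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (runif(1) < density) {
        W[i, j] <- W[j, i] <- round(runif(1, 0.1, 0.9), 2) *
          sample(c(-1, 1), 1)
      }
    }
  }
  W
}
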