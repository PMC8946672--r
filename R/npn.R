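#' Nonparanormal (truncated-ECDF) transform
#'
#' Rank-Gaussianizes each column so the joint distribution is
#' approximately multivariate normal while rank dependence is
#' preserved. Column j is mapped through the normal quantile of its
#' shrunken empirical CDF: average ranks are scaled by `n / (n + 1)`,
#' clipped to `[delta_n, 1 - delta_n]` with the truncation constant
#' `delta_n = 1 / (4 n^{1/4} sqrt(pi log n))`, passed through
#' `qnorm()`, and finally standardized to unit sample variance. Ties
#' receive equal transformed values; the map is monotone within each
#' column.
#'
#' @param x Numeric matrix or data frame (`n x p`) of item scores;
#'   no missing values.
#' @return Numeric matrix of the same shape, each column with mean 0
#'   and variance 1; attributes `truncation` (the constant used) and
#'   `source_ranks` (per-column average ranks, kept for audit).
#' @export
#' @examples
#' z <- npn_transform(cbind(a = rexp(50), b = runif(50)))
#' round(colMeans(z), 10)
npn_transform <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) abort("npn_transform: missing values are not allowed")
  n <- nrow(x)
  if (n < 4) abort("npn_transform: need at least 4 rows")
  if (n < 10) {
    warn("npn_transform: fewer than 10 rows; Gaussianization is crude")
  }
  constant <- vapply(seq_len(ncol(x)), function(j) sd(x[, j]) == 0, TRUE)
  if (any(constant)) {
    abort(paste0("npn_transform: constant column(s): ",
                 paste(colnames(x)[constant] %||% which(constant),
                       collapse = ", ")))
  }
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  ranks <- apply(x, 2, rank, ties.method = "average")
  z <- apply(ranks, 2, function(r) {
    qnorm(pmin(pmax(r / (n + 1), delta), 1 - delta))
  })
  z <- scale(z, center = TRUE, scale = TRUE)
  out <- z[, , drop = FALSE]
  attributes(out)$`scaled:center` <- NULL
  attributes(out)$`scaled:scale` <- NULL
  dimnames(out) <- dimnames(x)
  attr(out, "truncation") <- delta
  attr(out, "source_ranks") <- ranks
  out
}

#' Sample correlation of Gaussianized items
#'
#' Pearson correlation of the transformed columns, with exact symmetry
#' enforced. Carries the sample size along because EBIC needs it.
#'
#' @param z Matrix from [npn_transform()] (or any numeric matrix).
#' @return A `cor_input` object: list with `S` (p x p correlation) and
#'   `n` (rows used).
#' @export
sample_correlation <- function(z) {
  z <- as.matrix(z)
  n <- nrow(z)
  p <- ncol(z)
  sds <- apply(z, 2, sd)
  if (any(sds == 0)) {
    abort("sample_correlation: zero-variance column")
  }
  if (n <= p) {
    warn(sprintf("sample_correlation: n (%d) <= p (%d); correlation is rank-deficient", n, p))
  }
  S <- cor(z)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  structure(list(S = S, n = n), class = "cor_input")
}
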