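test_that("edge bootstrap is reproducible and brackets its means", {
  x <- planted_items(4, list(list(1, 2, 0.5)), n = 120, seed = 51)
  b1 <- suppressWarnings(bootstrap_edges(x, B = 25, seed = 99))
  b2 <- suppressWarnings(bootstrap_edges(x, B = 25, seed = 99))
  expect_identical(tidy(b1), tidy(b2))
  expect_identical(b1$draws, b2$draws)
  e <- tidy(b1)
  expect_true(all(e$ci_low <= e$boot_mean & e$boot_mean <= e$ci_high))
  expect_equal(b1$B, 25)
  b3 <- suppressWarnings(bootstrap_edges(x, B = 25, seed = 100))
  expect_false(identical(b1$draws, b3$draws))
})

test_that("a planted strong edge's bootstrap CI excludes zero", {
  x <- planted_items(4, list(list(1, 2, 0.6)), n = 1000, seed = 52)
  bt <- bootstrap_edges(x, B = 200, seed = 1)
  e <- tidy(bt)
  e12 <- e[e$from == "Q1" & e$to == "Q2", ]
  expect_gt(e12$ci_low, 0)
  expect_gt(e12$estimate, 0.4)
})

make_case_drop <- function(correlations_by_pi) {
  # hand-built object for definitional checks on cs_coefficient
  tb <- purrr::imap_dfr(correlations_by_pi, function(cors, pi_chr) {
    tibble::tibble(proportion = as.numeric(pi_chr),
                   replicate = seq_along(cors), correlation = cors)
  })
  structure(
    list(correlations = tb,
         proportions = as.numeric(names(correlations_by_pi)),
         B_per_proportion = max(tb$replicate),
         correlation_threshold = 0.7, probability_level = 0.95),
    class = "case_drop"
  )
}

test_that("cs_coefficient handles the definitional extremes", {
  grid <- seq(0.05, 0.75, by = 0.05)
  perfect <- setNames(replicate(length(grid), rep(1, 40), simplify = FALSE),
                      grid)
  expect_equal(cs_coefficient(make_case_drop(perfect)), 0.75)
  hopeless <- setNames(replicate(length(grid), rep(0.2, 40), simplify = FALSE),
                       grid)
  expect_equal(cs_coefficient(make_case_drop(hopeless)), 0)
})

test_that("cs_coefficient requires monotone qualification over smaller proportions", {
  cd <- make_case_drop(list(
    "0.1" = rep(1, 20),
    "0.2" = c(rep(1, 10), rep(0, 10)),  # fails here
    "0.3" = rep(1, 20)                  # cannot rescue the larger grid point
  ))
  expect_equal(cs_coefficient(cd), 0.1)
  # the 95% rule is applied per proportion
  cd2 <- make_case_drop(list("0.1" = c(rep(1, 19), 0)))
  expect_equal(cs_coefficient(cd2), 0.1)
  cd3 <- make_case_drop(list("0.1" = c(rep(1, 18), 0, 0)))
  expect_equal(cs_coefficient(cd3), 0)
})

test_that("case-dropping bootstrap stores valid, reproducible correlations", {
  x <- planted_items(4, list(list(1, 2, 0.6), list(3, 4, 0.4)), n = 200,
                     seed = 53)
  cd <- case_drop_bootstrap(x, proportions = c(0.1, 0.3),
                            B_per_proportion = 20, seed = 7)
  cd2 <- case_drop_bootstrap(x, proportions = c(0.1, 0.3),
                             B_per_proportion = 20, seed = 7)
  expect_identical(tidy(cd), tidy(cd2))
  cors <- tidy(cd)$correlation
  expect_true(all(is.na(cors) | (cors >= -1 & cors <= 1)))
  expect_equal(nrow(tidy(cd)), 40)
  # a dominant planted structure keeps subsample Strength aligned
  strong <- tidy(cd)[tidy(cd)$proportion == 0.1, ]$correlation
  expect_gt(mean(strong, na.rm = TRUE), 0.6)
})

test_that("drop proportions violating the retained-size floor are rejected", {
  x <- planted_items(4, list(), n = 20, seed = 54)
  expect_error(case_drop_bootstrap(x, proportions = c(0.9),
                                   B_per_proportion = 5),
               "proportion|p \\+ 5")
  expect_error(case_drop_bootstrap(x, proportions = c(0, 0.5),
                                   B_per_proportion = 5),
               "strictly")
})

test_that("pure-noise data gives widely dispersed stability correlations", {
  set.seed(55)
  x <- matrix(sample(0:100, 100 * 4, TRUE), 100, 4,
              dimnames = list(NULL, paste0("Q", 1:4)))
  cd <- case_drop_bootstrap(x, proportions = 0.3, B_per_proportion = 40,
                            seed = 8)
  cors <- tidy(cd)$correlation
  # noise networks are mostly empty; correlations are NA or scattered
  expect_true(sd(cors[!is.na(cors)]) > 0.3 || mean(is.na(cors)) > 0.5)
})
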