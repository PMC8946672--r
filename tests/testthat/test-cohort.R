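make_raw <- function(n = 6, p = 12, seed = 1) {
  set.seed(seed)
  d <- as.data.frame(matrix(sample(0:100, n * p, replace = TRUE), n, p))
  names(d) <- paste0("Q", seq_len(p))
  d$returned <- rep(c(TRUE, FALSE), length.out = n)
  d
}

test_that("classify_return maps the four self-report categories and rejects unknowns", {
  expect_true(classify_return("Yes, at the same or higher level compared to before injury"))
  expect_false(classify_return("Yes, training only"))
  expect_false(classify_return("Yes, at a lower level compared to before injury"))
  expect_false(classify_return("No"))
  expect_equal(
    classify_return(c("No", "Yes, at the same or higher level compared to before injury")),
    c(FALSE, TRUE)
  )
  expect_error(classify_return("maybe"), "Unrecognized")
})

test_that("as_cohort ingests a complete table and canonicalizes item order", {
  d <- make_raw(n = 3)
  shuffled <- d[, c(sample(paste0("Q", 1:12)), "returned")]
  cohort <- as_cohort(shuffled)
  expect_s3_class(cohort, "rsi_cohort")
  expect_equal(nrow(cohort), 3)
  expect_equal(names(cohort), c("participant_id", paste0("Q", 1:12), "returned"))
  expect_equal(cohort$Q5, d$Q5)
  expect_identical(attr(cohort, "n_excluded"), 0L)
})

test_that("rows with missing items are excluded and counted, never imputed", {
  d <- make_raw(n = 5)
  d$Q5[2] <- NA
  expect_message(cohort <- as_cohort(d), class = "rsinet_excluded_rows")
  expect_equal(nrow(cohort), 4)
  expect_identical(attr(cohort, "n_excluded"), 1L)
  expect_false(anyNA(cohort_matrix(cohort)))
})

test_that("scores outside [0, 100] and missing columns are errors", {
  d <- make_raw(n = 4)
  d$Q3[3] <- 101
  expect_error(as_cohort(d), "outside \\[0, 100\\].*3")
  d2 <- make_raw(n = 4)
  d2$Q7 <- NULL
  expect_error(as_cohort(d2), "Q7")
})

test_that("read_cohort round-trips a CSV and derives the label from raw status text", {
  d <- make_raw(n = 8)
  d$status <- ifelse(d$returned,
    "Yes, at the same or higher level compared to before injury",
    "Yes, training only")
  d$returned <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  cohort <- read_cohort(path, status = "status")
  expect_equal(nrow(cohort), 8)
  expect_equal(cohort$returned, rep(c(TRUE, FALSE), 4))
  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("item_summary matches hand-computed statistics", {
  d <- tibble::tibble(
    Q1 = c(60, 80, 50, 50), Q2 = c(10, 30, 20, 20),
    returned = c(TRUE, TRUE, FALSE, FALSE)
  )
  s <- item_summary(as_cohort(d, items = c("Q1", "Q2")))
  ret_q1 <- s[s$item == "Q1" & s$stratum == "returned", ]
  expect_equal(ret_q1$mean, 70)
  expect_equal(ret_q1$sd, sqrt(sum((c(60, 80) - 70)^2) / 1))
  expect_equal(s[s$item == "Q1" & s$stratum == "not_returned", ]$sd, 0)
  expect_equal(s[s$item == "Q2" & s$stratum == "whole", ]$n, 4)
})

test_that("item_summary is row-order invariant and strata average to the whole", {
  d <- make_raw(n = 20, seed = 42)
  cohort <- as_cohort(d)
  s1 <- item_summary(cohort)
  s2 <- item_summary(as_cohort(d[sample(20), ]))
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$sd, s2$sd)
  wide <- tidyr::pivot_wider(s1, names_from = "stratum",
                             values_from = c("n", "mean", "sd"))
  expect_equal(
    wide$mean_whole,
    (wide$n_returned * wide$mean_returned +
       wide$n_not_returned * wide$mean_not_returned) / wide$n_whole
  )
  expect_equal(wide$n_whole, wide$n_returned + wide$n_not_returned)
})

test_that("item_summary refuses an empty stratum, naming it", {
  d <- make_raw(n = 4)
  d$returned <- TRUE
  expect_error(item_summary(as_cohort(d)), "not_returned")
})
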