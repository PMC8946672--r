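#' Classify a return-to-sport self-report
#'
#' Maps the four-category 12-month self-report onto the binary
#' return-to-sport label used to define the subgroups. Only a report of
#' playing at the same or a higher level than before the injury counts
#' as a return; training-only and lower-level play do not.
#'
#' @param status_text Character vector of self-report categories.
#' @return Logical vector, `TRUE` for returned to pre-injury level.
#' @export
#' @examples
#' classify_return(c("Yes, training only", "No"))
classify_return <- function(status_text) {
  returned <- "Yes, at the same or higher level compared to before injury"
  not_returned <- c(
    "No",
    "Yes, training only",
    "Yes, at a lower level compared to before injury"
  )
  status_text <- trimws(as.character(status_text))
  known <- status_text %in% c(returned, not_returned) | is.na(status_text)
  if (!all(known)) {
    abort(paste0(
      "Unrecognized return-to-sport category: ",
      paste(unique(status_text[!known]), collapse = ", ")
    ))
  }
  status_text == returned
}

new_cohort <- function(data, n_excluded = 0L) {
  structure(data,
    class = c("rsi_cohort", class(tibble::tibble())),
    n_excluded = n_excluded
  )
}

#' Assemble and validate a cohort table
#'
#' Builds the participant-by-item table all later stages consume:
#' one row per participant, item columns `Q1..Qp` each scored 0-100,
#' and a logical `returned` label. Rows with any missing item score are
#' excluded (complete-case) and counted in the `n_excluded` attribute;
#' scores outside \[0, 100\] are an error, never silently clipped.
#'
#' @param data A data frame holding the item columns and the label.
#' @param items Names of the item columns, in canonical order. Columns
#'   are reordered to this order regardless of their order in `data`.
#' @param returned Name of a logical return-to-sport column, or `NULL`
#'   if `status` is given instead.
#' @param status Name of a raw self-report column to be run through
#'   [classify_return()]; used when `returned` is `NULL`.
#' @param id Optional name of a participant identifier column.
#' @return An `rsi_cohort` tibble with columns `participant_id`, the
#'   items, and `returned`; attribute `n_excluded` counts dropped rows.
#' @export
as_cohort <- function(data, items = rsi_items(), returned = "returned",
                      status = NULL, id = NULL) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(items, if (is.null(status)) returned else status),
                          names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  lab <- if (is.null(status)) {
    as.logical(data[[returned]])
  } else {
    classify_return(data[[status]])
  }
  ids <- if (!is.null(id) && id %in% names(data)) {
    as.character(data[[id]])
  } else {
    as.character(seq_len(nrow(data)))
  }
  scores <- data[items]
  scores[] <- lapply(scores, as.numeric)
  bad <- which(
    apply(scores, 1, function(x) any(!is.na(x) & (x < 0 | x > 100)))
  )
  if (length(bad) > 0) {
    abort(paste0("Item score outside [0, 100] in row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  complete <- stats::complete.cases(scores) & !is.na(lab)
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    inform_excluded(n_excluded)
  }
  out <- tibble::tibble(participant_id = ids[complete])
  out[items] <- scores[complete, , drop = FALSE]
  out$returned <- lab[complete]
  new_cohort(out, n_excluded = n_excluded)
}

inform_excluded <- function(n) {
  rlang::inform(
    sprintf("Excluded %d row(s) with missing item scores or label (complete-case).", n),
    class = "rsinet_excluded_rows"
  )
}

#' Read a cohort from a delimited text file
#'
#' Expects a header with the item columns (default `Q1..Q12`) plus
#' either a precomputed logical `returned` column or a raw self-report
#' `status` column.
#'
#' @inheritParams as_cohort
#' @param path Path to the delimited file.
#' @param delim Field delimiter, default comma.
#' @return An `rsi_cohort` tibble; see [as_cohort()].
#' @export
read_cohort <- function(path, items = rsi_items(), returned = "returned",
                        status = NULL, id = NULL, delim = ",") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_cohort(raw, items = items, returned = returned, status = status, id = id)
}

#' Extract the item-score matrix from a cohort
#'
#' @param cohort An `rsi_cohort` (or any data frame with the item
#'   columns).
#' @param items Item column names.
#' @return Numeric `n x p` matrix with items as columns.
#' @export
cohort_matrix <- function(cohort, items = intersect(rsi_items(100), names(cohort))) {
  as.matrix(as.data.frame(cohort)[items])
}

#' Per-item descriptive statistics by return-to-sport stratum
#'
#' Item means and sample standard deviations on the original 0-100
#' scale, for the whole cohort and for the returned / not-returned
#' subgroups.
#'
#' @param cohort An `rsi_cohort` tibble.
#' @return A tibble with columns `item`, `stratum` (one of `whole`,
#'   `returned`, `not_returned`), `n`, `mean`, `sd`.
#' @export
item_summary <- function(cohort) {
  items <- intersect(rsi_items(100), names(cohort))
  strata <- list(
    whole = rep(TRUE, nrow(cohort)),
    returned = cohort$returned,
    not_returned = !cohort$returned
  )
  counts <- vapply(strata, sum, 0L)
  if (any(counts == 0L)) {
    abort(paste0("Empty stratum: ",
                 paste(names(strata)[counts == 0L], collapse = ", ")))
  }
  if (any(counts < 2L)) {
    abort(paste0("Stratum with fewer than 2 participants (SD undefined): ",
                 paste(names(strata)[counts < 2L], collapse = ", ")))
  }
  purrr::map_dfr(names(strata), function(s) {
    rows <- as.data.frame(cohort)[strata[[s]], items, drop = FALSE]
    tibble::tibble(
      item = items,
      stratum = s,
      n = nrow(rows),
      mean = unname(vapply(rows, mean, 0)),
      sd = unname(vapply(rows, sd, 0))
    )
  }) |>
    dplyr::mutate(
      item = factor(.data$item, levels = items),
      stratum = factor(.data$stratum, levels = names(strata))
    ) |>
    dplyr::arrange(.data$item, .data$stratum) |>
    dplyr::mutate(item = as.character(.data$item),
                  stratum = as.character(.data$stratum))
}
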