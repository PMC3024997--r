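# Descriptive surfaces: test-combination ascertainment, outcome-rate
# cross-tabulations with binomial standard errors, and cohort accounting.

#' Outcome rate with binomial standard error
#'
#' Computes the percentage rate `100 * cases / total` and its binomial
#' standard error `100 * sqrt(p (1 - p) / total)` on the percentage scale.
#' With `total = 0` the rate and SE are undefined (`NA`), not zero.
#'
#' @param cases,total Non-negative integer vectors (recycled); `cases <= total`.
#' @return A tibble with columns `cases`, `total`, `pct`, `se_pct`.
#' @examples
#' rate_and_se(113, 17083)
#' @export
rate_and_se <- function(cases, total) {
  n <- max(length(cases), length(total))
  cases <- rep_len(cases, n)
  total <- rep_len(total, n)
  if (any(cases < 0 | total < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(cases > total)) stop("cases cannot exceed total", call. = FALSE)
  p <- ifelse(total > 0, cases / total, NA_real_)
  tibble::tibble(
    cases = as.integer(cases),
    total = as.integer(total),
    pct = 100 * p,
    se_pct = 100 * sqrt(p * (1 - p) / total)
  )
}

ph_combination_label <- function(has_scalp, has_arterial, has_venous) {
  parts <- cbind(scalp = has_scalp, arterial = has_arterial, venous = has_venous)
  apply(parts, 1, function(row) paste(colnames(parts)[row], collapse = "+"))
}

#' Ascertainment of exposure by test combination
#'
#' Tabulates, for every non-empty combination of performed pH tests observed
#' in the data, the number of subjects tested, the number positive under the
#' all-tests-positive and the at-least-one-test-positive rules, and the
#' corresponding integer-rounded percentages.  A totals row (`any of the
#' three`) aggregates all tested subjects.
#'
#' @param table A cohort tibble carrying pH columns.
#' @return A tibble with columns `test_combination`, `n_subjects`,
#'   `n_all_positive`, `pct_all`, `n_any_positive`, `pct_any`.
#' @export
ascertainment_table <- function(table) {
  for (col in PH_COLUMNS) {
    if (!col %in% names(table)) {
      stop("ascertainment_table requires pH columns", call. = FALSE)
    }
  }
  tested <- !is.na(table$scalp_ph) | !is.na(table$arterial_ph) | !is.na(table$venous_ph)
  df <- table[tested, , drop = FALSE]
  if (nrow(df) == 0) {
    return(tibble::tibble(test_combination = character(), n_subjects = integer(),
                          n_all_positive = integer(), pct_all = numeric(),
                          n_any_positive = integer(), pct_any = numeric()))
  }
  df$all_pos <- classify_hypoxia(df$scalp_ph, df$arterial_ph, df$venous_ph,
                                 rule = "all_positive") == "positive"
  df$any_pos <- classify_hypoxia(df$scalp_ph, df$arterial_ph, df$venous_ph,
                                 rule = "any_positive") == "positive"
  df$test_combination <- ph_combination_label(!is.na(df$scalp_ph),
                                              !is.na(df$arterial_ph),
                                              !is.na(df$venous_ph))
  per_combo <- df |>
    dplyr::group_by(.data$test_combination) |>
    dplyr::summarise(n_subjects = dplyr::n(),
                     n_all_positive = sum(.data$all_pos),
                     n_any_positive = sum(.data$any_pos),
                     .groups = "drop")
  total <- dplyr::summarise(df, test_combination = "any of the three",
                            n_subjects = dplyr::n(),
                            n_all_positive = sum(.data$all_pos),
                            n_any_positive = sum(.data$any_pos))
  dplyr::bind_rows(per_combo, total) |>
    dplyr::mutate(
      pct_all = round_half_up(100 * .data$n_all_positive / .data$n_subjects),
      pct_any = round_half_up(100 * .data$n_any_positive / .data$n_subjects)
    ) |>
    dplyr::select("test_combination", "n_subjects", "n_all_positive", "pct_all",
                  "n_any_positive", "pct_any")
}

#' Outcome-by-exposure cross-tabulation with rates and SEs
#'
#' Counts outcome cases and totals in every (gender stratum) x (exposure
#' status) cell, including `both` gender and `total` exposure margins, and
#' attaches the percentage rate and its binomial SE via [rate_and_se()].
#'
#' @param table A cohort tibble with a resolved `hypoxia` column.
#' @param by_gender Include male/female strata in addition to `both`.
#' @return A tibble with columns `gender`, `exposure`, `cases`, `total`,
#'   `pct`, `se_pct`.
#' @export
asd_by_exposure_crosstab <- function(table, by_gender = TRUE) {
  strata <- list(both = rep(TRUE, nrow(table)))
  if (by_gender) {
    strata$male <- !is.na(table$gender) & table$gender == "male"
    strata$female <- !is.na(table$gender) & table$gender == "female"
  }
  cols <- c(EXPOSURE_LEVELS, "total")
  grid <- purrr::map_dfr(names(strata), function(g) {
    sub <- table[strata[[g]], , drop = FALSE]
    purrr::map_dfr(cols, function(ex) {
      inc <- if (ex == "total") rep(TRUE, nrow(sub)) else sub$hypoxia == ex
      cell <- rate_and_se(sum(sub$asd[inc]), sum(inc))
      dplyr::bind_cols(tibble::tibble(gender = g, exposure = ex), cell)
    })
  })
  grid
}

#' Sequential exclusion accounting
#'
#' Applies a cascade of exclusions to an initial count and reports the number
#' remaining after each step.
#'
#' @param initial Starting count.
#' @param exclusions Named or unnamed integer vector of sequential exclusions.
#' @return A tibble with columns `step`, `excluded`, `remaining`; the last
#'   `remaining` entry is the analysis count.
#' @examples
#' cohort_accounting(273343, c(unlinked = 25970, lost = 28421, no_gender = 62))
#' @export
cohort_accounting <- function(initial, exclusions) {
  if (any(exclusions < 0)) stop("exclusions must be non-negative", call. = FALSE)
  remaining <- initial - cumsum(exclusions)
  if (any(remaining < 0)) stop("exclusions exceed the cohort", call. = FALSE)
  labels <- names(exclusions) %||% paste0("step", seq_along(exclusions))
  labels[labels == ""] <- paste0("step", which(labels == ""))
  tibble::tibble(
    step = c("initial", labels),
    excluded = c(0L, as.integer(exclusions)),
    remaining = as.integer(c(initial, remaining))
  )
}
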