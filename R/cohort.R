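# Cohort data model: CSV I/O, covariate schema, design encoding, and the
# blood-pH exposure classifier.

# pH cut-offs below which each test is read as positive for perinatal hypoxia.
PH_THRESHOLDS <- c(scalp_ph = 7.25, arterial_ph = 7.20, venous_ph = 7.28)

PH_COLUMNS <- names(PH_THRESHOLDS)

EXPOSURE_LEVELS <- c("positive", "negative", "unknown")

#' Classify perinatal hypoxia from blood-pH measurements
#'
#' Applies the standard pH cut-offs (fetal scalp pH < 7.25, umbilical arterial
#' pH < 7.20, umbilical venous pH < 7.28; strictly below) to up to three
#' measurements per child.  A test is positive iff its value is strictly below
#' its threshold; boundary values are negative.
#'
#' @param scalp_ph,arterial_ph,venous_ph Numeric vectors of pH values; `NA`
#'   means the test was not performed.  Vectors are recycled to a common
#'   length.
#' @param rule `"any_positive"` (the case definition: positive if at least one
#'   performed test is positive) or `"all_positive"` (positive only if every
#'   performed test is positive).  A child with no performed test is
#'   `"unknown"` under either rule.
#' @return A factor with levels `positive`, `negative`, `unknown`.
#' @examples
#' classify_hypoxia(arterial_ph = c(7.19, 7.20, NA))
#' @export
classify_hypoxia <- function(scalp_ph = NA_real_, arterial_ph = NA_real_,
                             venous_ph = NA_real_,
                             rule = c("any_positive", "all_positive")) {
  rule <- match.arg(rule)
  n <- max(length(scalp_ph), length(arterial_ph), length(venous_ph))
  panel <- cbind(
    scalp_ph = rep_len(as.numeric(scalp_ph), n),
    arterial_ph = rep_len(as.numeric(arterial_ph), n),
    venous_ph = rep_len(as.numeric(venous_ph), n)
  )
  validate_ph(panel)
  pos <- sweep(panel, 2, PH_THRESHOLDS, `<`)  # NA where test absent
  n_present <- rowSums(!is.na(panel))
  n_pos <- rowSums(pos, na.rm = TRUE)
  out <- rep("unknown", n)
  tested <- n_present > 0
  out[tested] <- if (rule == "any_positive") {
    ifelse(n_pos[tested] >= 1, "positive", "negative")
  } else {
    ifelse(n_pos[tested] == n_present[tested], "positive", "negative")
  }
  factor(out, levels = EXPOSURE_LEVELS)
}

validate_ph <- function(panel) {
  for (col in colnames(panel)) {
    bad <- which(!is.na(panel[, col]) &
                   (panel[, col] <= 0 | panel[, col] >= 14))
    if (length(bad)) {
      stop(sprintf("invalid pH in '%s' at record(s) %s: values must lie in (0, 14)",
                   col, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(panel)
}

#' Define a covariate schema
#'
#' A schema maps each categorical covariate to its ordered category labels.
#' The first listed category of each covariate is its reference category in
#' design encoding.
#'
#' @param ... Named character vectors, one per covariate.
#' @return A named list of character vectors, classed `cohort_schema`.
#' @examples
#' cohort_schema(maternal_age = c("<=25", "25-30", "30-35", ">35"),
#'               smoking = c("0", "1"))
#' @export
cohort_schema <- function(...) {
  schema <- list(...)
  if (length(schema) && (is.null(names(schema)) || any(names(schema) == ""))) {
    stop("every covariate in a schema must be named", call. = FALSE)
  }
  for (nm in names(schema)) {
    cats <- as.character(schema[[nm]])
    if (length(cats) < 2 || anyDuplicated(cats)) {
      stop(sprintf("covariate '%s' needs >= 2 distinct categories", nm),
           call. = FALSE)
    }
    schema[[nm]] <- cats
  }
  structure(schema, class = "cohort_schema")
}

#' Read a covariate schema from a YAML or JSON file
#'
#' The file must contain a top-level `covariates` mapping from covariate name
#' to its ordered category list (first category = reference).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_schema`.
#' @export
read_schema <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$covariates)) {
    stop("schema file must contain a top-level 'covariates' mapping", call. = FALSE)
  }
  do.call(cohort_schema, lapply(raw$covariates, as.character))
}

#' Retrieve the schema attached to a cohort table
#' @param table A cohort tibble produced by [read_cohort()] or
#'   [simulate_cohort()].
#' @return The `cohort_schema` attribute.
#' @export
get_schema <- function(table) {
  schema <- attr(table, "schema")
  if (is.null(schema)) stop("table carries no covariate schema", call. = FALSE)
  schema
}

#' Read a cohort table from CSV
#'
#' One row per child.  Required columns: `id`, `gender` (male/female), `asd`
#' (0/1).  Exposure is supplied either as a `hypoxia` column
#' (positive/negative/unknown; empty cells are unknown) or as raw pH columns
#' `scalp_ph`, `arterial_ph`, `venous_ph`, from which it is derived with
#' [classify_hypoxia()].  Covariate columns named in `schema` are validated
#' against their category lists.  Optional columns: `fullterm` (0/1),
#' `truth_x`, `missing_indicator` (simulation bookkeeping).
#'
#' @param path CSV file path.
#' @param schema A `cohort_schema`; covariate columns not listed are ignored.
#' @param missing_codes Character vector of cell values to treat as absent, in
#'   addition to the empty cell.
#' @param rule Classification rule passed to [classify_hypoxia()] when exposure
#'   must be derived from pH columns.
#' @return A tibble with the schema attached as attribute `"schema"`.
#' @export
read_cohort <- function(path, schema = cohort_schema(), missing_codes = "",
                        rule = "any_positive") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  raw[] <- lapply(raw, function(col) {
    col[col %in% c(missing_codes, "")] <- NA_character_
    col
  })
  for (req in c("id", "gender", "asd")) {
    if (!req %in% names(raw)) {
      stop(sprintf("required column '%s' missing from %s", req, path), call. = FALSE)
    }
  }
  if (anyDuplicated(raw$id)) {
    dup <- unique(raw$id[duplicated(raw$id)])
    stop(sprintf("duplicate id(s): %s", paste(utils::head(dup, 5), collapse = ", ")),
         call. = FALSE)
  }
  out <- tibble::tibble(id = raw$id)
  out$gender <- parse_category(raw$gender, c("male", "female"), "gender")
  out$asd <- parse_binary(raw$asd, "asd")

  has_ph <- any(PH_COLUMNS %in% names(raw))
  if (has_ph) {
    for (col in PH_COLUMNS) {
      out[[col]] <- if (col %in% names(raw)) parse_ph(raw[[col]], col) else NA_real_
    }
  }
  if ("hypoxia" %in% names(raw)) {
    hyp <- raw$hypoxia
    hyp[is.na(hyp)] <- "unknown"
    out$hypoxia <- parse_category(hyp, EXPOSURE_LEVELS, "hypoxia")
  } else if (has_ph) {
    out$hypoxia <- classify_hypoxia(out$scalp_ph, out$arterial_ph, out$venous_ph,
                                    rule = rule)
  } else {
    stop("cohort needs either a 'hypoxia' column or pH columns", call. = FALSE)
  }
  if ("fullterm" %in% names(raw)) out$fullterm <- parse_binary(raw$fullterm, "fullterm")
  for (nm in names(schema)) {
    if (!nm %in% names(raw)) {
      stop(sprintf("schema covariate '%s' missing from %s", nm, path), call. = FALSE)
    }
    out[[nm]] <- parse_category(raw[[nm]], schema[[nm]], nm)
  }
  for (nm in c("truth_x", "missing_indicator")) {
    if (nm %in% names(raw)) out[[nm]] <- parse_binary(raw[[nm]], nm)
  }
  message(sprintf("read_cohort: %d records from %s", nrow(out), path))
  attr(out, "schema") <- schema
  out
}

parse_category <- function(x, levels, field) {
  bad <- which(!is.na(x) & !x %in% levels)
  if (length(bad)) {
    stop(sprintf("column '%s': unknown label(s) %s at row(s) %s",
                 field,
                 paste(unique(utils::head(x[bad], 5)), collapse = ", "),
                 paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  factor(x, levels = levels)
}

parse_binary <- function(x, field) {
  bad <- which(!is.na(x) & !x %in% c("0", "1"))
  if (length(bad)) {
    stop(sprintf("column '%s' must be 0/1; offending row(s): %s",
                 field, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  as.integer(x)
}

parse_ph <- function(x, field) {
  num <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(num))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable value(s) %s at row(s) %s",
                 field,
                 paste(unique(utils::head(x[bad], 5)), collapse = ", "),
                 paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  validate_ph(matrix(num, ncol = 1, dimnames = list(NULL, field)))
  num
}

#' Write a cohort table to CSV
#'
#' Columns are emitted in contract order: identifiers and observables first
#' (`id`, `gender`, `asd`, `hypoxia`, pH columns, `fullterm`, covariates in
#' schema order), simulation truth columns (`truth_x`, `missing_indicator`)
#' last.  Absent values are written as `missing` (default: empty cell).
#'
#' @param table A cohort tibble.
#' @param path Output path.
#' @param missing Token used for absent values.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, missing = "") {
  schema <- attr(table, "schema") %||% cohort_schema()
  order <- c("id", "gender", "asd", "hypoxia", PH_COLUMNS, "fullterm",
             names(schema), "truth_x", "missing_indicator")
  cols <- c(intersect(order, names(table)), setdiff(names(table), order))
  readr::write_csv(table[cols], path, na = missing, progress = FALSE)
  invisible(path)
}

#' Subset a cohort by gender or to full-term births
#'
#' `fullterm_only = TRUE` keeps records with `fullterm == 1`; records with an
#' absent full-term flag are dropped and their count reported (they are never
#' excluded from all-ages analyses).
#'
#' @param table A cohort tibble.
#' @param gender Optional `"male"` or `"female"`.
#' @param fullterm_only Keep only full-term births.
#' @return The filtered cohort tibble (schema preserved).
#' @export
subset_cohort <- function(table, gender = NULL, fullterm_only = FALSE) {
  schema <- attr(table, "schema")
  if (!is.null(gender)) {
    gender <- match.arg(gender, c("male", "female"))
    table <- dplyr::filter(table, .data$gender == .env$gender)
  }
  if (fullterm_only) {
    if (!"fullterm" %in% names(table)) {
      stop("fullterm_only requires a 'fullterm' column", call. = FALSE)
    }
    n_absent <- sum(is.na(table$fullterm))
    if (n_absent > 0) {
      message(sprintf("subset_cohort: dropping %d record(s) with absent fullterm flag",
                      n_absent))
    }
    table <- dplyr::filter(table, !is.na(.data$fullterm) & .data$fullterm == 1)
    if (nrow(table) == 0) {
      warning("fullterm_only produced an empty table", call. = FALSE)
    }
  }
  attr(table, "schema") <- schema
  table
}

#' Encode categorical covariates as a reference-cell design matrix
#'
#' Each k-category covariate contributes k - 1 indicator columns named
#' `"<covariate>=<category>"`; the reference is the first category listed in
#' the schema.  The intercept column comes first.  Records with an absent
#' value for any requested term are excluded and counted.
#'
#' @param table A cohort tibble.
#' @param terms Character vector of covariate names (must appear in `schema`).
#' @param schema A `cohort_schema`; defaults to the table's attached schema.
#' @return A list with `design` (numeric matrix, intercept first), `rows`
#'   (indices of retained records) and `n_dropped`.
#' @export
encode_design <- function(table, terms, schema = get_schema(table)) {
  missing_terms <- setdiff(terms, names(schema))
  if (length(missing_terms)) {
    stop(sprintf("term(s) not in schema: %s", paste(missing_terms, collapse = ", ")),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(table))
  for (nm in terms) keep <- keep & !is.na(table[[nm]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("encode_design: excluded %d record(s) with absent covariate values",
                    n_dropped))
  }
  rows <- which(keep)
  blocks <- lapply(terms, function(nm) {
    cats <- schema[[nm]]
    x <- as.character(table[[nm]][rows])
    block <- vapply(cats[-1], function(lvl) as.numeric(x == lvl),
                    numeric(length(rows)))
    block <- matrix(block, nrow = length(rows),
                    dimnames = list(NULL, paste0(nm, "=", cats[-1])))
    block
  })
  design <- do.call(cbind, c(list(`(Intercept)` = matrix(1, length(rows), 1,
                                                         dimnames = list(NULL, "(Intercept)"))),
                             blocks))
  list(design = design, rows = rows, n_dropped = n_dropped)
}
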