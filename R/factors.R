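#' Define a categorical clinical factor
#'
#' A factor is a named categorical variable measured repeatedly on each
#' subject, with two or three levels. Three-level factors are typically
#' diagnosis variables with levels none / subthreshold / full-threshold;
#' everything else is binary. Each factor belongs to a clinical domain group
#' and declares which of its levels count as "true" when the factor is
#' collapsed to binary for effect estimation (for diagnoses, both the sub-
#' and full-threshold levels are truthy).
#'
#' @param name factor identifier (a syntactic-friendly string).
#' @param levels character vector of 2 or 3 unique category labels, in order.
#' @param domain_group one of `"function"`, `"suicidality"`, `"substance"`,
#'   `"physical"`, `"syndrome"`, `"demographic"`.
#' @param truthy_levels non-empty strict subset of `levels` mapped to `TRUE`
#'   by [collapse_to_binary()].
#' @return An object of class `factor_spec`.
#' @export
factor_spec <- function(name, levels, domain_group = "syndrome",
                        truthy_levels = levels[length(levels)]) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (anyDuplicated(levels)) {
    stop("factor '", name, "': levels must be unique", call. = FALSE)
  }
  if (!length(levels) %in% c(2L, 3L)) {
    stop("factor '", name, "': need 2 or 3 levels, got ", length(levels),
         call. = FALSE)
  }
  groups <- c("function", "suicidality", "substance", "physical",
              "syndrome", "demographic")
  domain_group <- match.arg(domain_group, groups)
  truthy_levels <- as.character(truthy_levels)
  if (!all(truthy_levels %in% levels)) {
    stop("factor '", name, "': truthy_levels must be a subset of levels",
         call. = FALSE)
  }
  if (length(truthy_levels) == 0L || length(truthy_levels) >= length(levels)) {
    stop("factor '", name,
         "': truthy_levels must be a non-empty strict subset of levels",
         call. = FALSE)
  }
  structure(
    list(name = name, levels = levels, domain_group = domain_group,
         truthy_levels = truthy_levels),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s [%s]: {%s}; truthy: {%s}\n",
              x$name, x$domain_group,
              paste(x$levels, collapse = ", "),
              paste(x$truthy_levels, collapse = ", ")))
  invisible(x)
}

#' Shorthand for a binary false/true factor
#'
#' @inheritParams factor_spec
#' @return A `factor_spec` with levels `c("false", "true")`, truthy `"true"`.
#' @export
binary_factor <- function(name, domain_group = "syndrome") {
  factor_spec(name, c("false", "true"), domain_group, "true")
}

#' Shorthand for a three-level diagnosis factor
#'
#' Levels are none / subthreshold / full-threshold; when collapsed to binary,
#' sub- and full-threshold are assigned `TRUE` and none `FALSE`.
#'
#' @inheritParams factor_spec
#' @return A three-level `factor_spec`.
#' @export
diagnosis_factor <- function(name, domain_group = "syndrome") {
  factor_spec(name, c("none", "subthreshold", "full-threshold"),
              domain_group, c("subthreshold", "full-threshold"))
}

spec_names <- function(specs) vapply(specs, `[[`, character(1), "name")

as_spec_list <- function(specs) {
  if (inherits(specs, "factor_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "factor_spec")))
  names(specs) <- spec_names(specs)
  if (anyDuplicated(names(specs))) stop("duplicate factor names", call. = FALSE)
  specs
}

#' Assemble a long-format cohort table
#'
#' One row per subject x timepoint; missing values are `NA`. Timepoint
#' indices are non-negative integers with t = 0 the first presentation; gaps
#' (missed visits) are allowed and simply absent from the table. Calendar
#' dates play no role: consecutive indices are treated as homogeneous steps.
#'
#' @param data data.frame with columns `subject_id`, `timepoint`, and one
#'   column per factor (character, values among the factor's levels or `NA`).
#' @param specs list of [factor_spec()] objects covering the factor columns.
#' @return An object of class `cohort_table` (a validated data.frame).
#' @export
cohort_table <- function(data, specs) {
  specs <- as_spec_list(specs)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("subject_id", "timepoint", names(specs))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- data[, need, drop = FALSE]
  data$subject_id <- as.character(data$subject_id)
  tp <- data$timepoint
  if (!is.numeric(tp) || any(!is.finite(tp)) || any(tp < 0) ||
      any(tp != floor(tp))) {
    stop("timepoint must be a non-negative integer", call. = FALSE)
  }
  data$timepoint <- as.integer(tp)
  key <- paste(data$subject_id, data$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (subject, timepoint) record: ",
         gsub("\r", " @ t=", dup), call. = FALSE)
  }
  for (f in names(specs)) {
    v <- as.character(data[[f]])
    bad <- !is.na(v) & !(v %in% specs[[f]]$levels)
    if (any(bad)) {
      stop("factor '", f, "': value '", v[bad][1L],
           "' is not one of its levels", call. = FALSE)
    }
    data[[f]] <- v
  }
  data <- data[order(data$subject_id, data$timepoint), , drop = FALSE]
  rownames(data) <- NULL
  structure(data, specs = specs, class = c("cohort_table", "data.frame"))
}

#' Validate a cohort table and summarise its completeness
#'
#' Structural violations (unknown level labels, duplicated subject-timepoint
#' records) are raised when the table is constructed; this reports counts a
#' data owner checks before network learning.
#'
#' @param table a [cohort_table()].
#' @param specs factor specs (defaults to those stored on the table).
#' @return list with `n_subjects`, `n_records`, `missing_by_factor`
#'   (named integer vector), `n_complete_records`.
#' @export
validate_cohort <- function(table, specs = attr(table, "specs")) {
  stopifnot(inherits(table, "cohort_table"))
  specs <- as_spec_list(specs)
  fac <- names(specs)
  miss <- vapply(fac, function(f) sum(is.na(table[[f]])), integer(1))
  complete <- if (nrow(table)) {
    sum(stats::complete.cases(as.data.frame(table)[, fac, drop = FALSE]))
  } else 0L
  list(
    n_subjects = length(unique(table$subject_id)),
    n_records = nrow(table),
    missing_by_factor = miss,
    n_complete_records = complete
  )
}

complete_rows <- function(df, fac) {
  if (!nrow(df)) return(logical(0))
  stats::complete.cases(as.data.frame(df)[, fac, drop = FALSE])
}

#' Complete-case dataset for the initial network
#'
#' Keeps exactly the subjects whose first-presentation (t = 0) record has a
#' valid entry for every factor of interest; later timepoints are ignored.
#'
#' @param table a [cohort_table()].
#' @param specs factor specs (defaults to those stored on the table).
#' @return data.frame of class `initial_dataset`, one row per eligible
#'   subject, columns = factors, no missing cells; rows ordered by subject.
#' @export
build_initial_dataset <- function(table, specs = attr(table, "specs")) {
  stopifnot(inherits(table, "cohort_table"))
  specs <- as_spec_list(specs)
  fac <- names(specs)
  t0 <- as.data.frame(table)[table$timepoint == 0L, , drop = FALSE]
  keep <- complete_rows(t0, fac)
  out <- t0[keep, c("subject_id", fac), drop = FALSE]
  if (!nrow(out)) {
    stop("no subject has a complete t = 0 record; reduce the factor subset",
         call. = FALSE)
  }
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, specs = specs, class = c("initial_dataset", "data.frame"))
}

#' Stacked complete consecutive-pair dataset for the transition network
#'
#' One row per (subject, t) such that the records at t and t + 1 are both
#' complete across all factors. A subject contributes as many rows as they
#' have complete consecutive pairs, which may be zero; pairs separated by a
#' missed visit (t and t + 2) are never used. Columns are named `factor@t`
#' and `factor@t1`.
#'
#' @param table a [cohort_table()].
#' @param specs factor specs (defaults to those stored on the table).
#' @return data.frame of class `transition_dataset` with 2 x n_factor value
#'   columns plus `subject_id` and `t`; rows sorted by (subject, t).
#' @export
build_transition_dataset <- function(table, specs = attr(table, "specs")) {
  stopifnot(inherits(table, "cohort_table"))
  specs <- as_spec_list(specs)
  fac <- names(specs)
  df <- as.data.frame(table)
  ok <- complete_rows(df, fac)
  df <- df[ok, , drop = FALSE]
  # complete records are sorted by (subject, t): a consecutive pair is two
  # adjacent rows of the same subject with timepoints differing by one
  if (nrow(df) >= 2L) {
    i <- seq_len(nrow(df) - 1L)
    pair <- df$subject_id[i] == df$subject_id[i + 1L] &
      df$timepoint[i + 1L] - df$timepoint[i] == 1L
  } else {
    pair <- logical(0)
  }
  from <- which(pair)
  if (!length(from)) {
    stop("no subject has complete records at two consecutive timepoints",
         call. = FALSE)
  }
  out <- data.frame(
    subject_id = df$subject_id[from],
    t = df$timepoint[from],
    stringsAsFactors = FALSE
  )
  for (f in fac) out[[paste0(f, "@t")]] <- df[[f]][from]
  for (f in fac) out[[paste0(f, "@t1")]] <- df[[f]][from + 1L]
  names(out) <- c("subject_id", "t",
                  paste0(fac, "@t"), paste0(fac, "@t1"))
  rownames(out) <- NULL
  structure(out, specs = specs, class = c("transition_dataset", "data.frame"))
}

#' Collapse a categorical value to binary
#'
#' Diagnosis factors carry three levels; for relative-risk estimation the
#' sub- and full-threshold levels are assigned `TRUE` and none `FALSE`
#' (each spec's `truthy_levels` records the assignment). Vectorised.
#'
#' @param value character vector of observed values (`NA` passes through).
#' @param spec the factor's [factor_spec()].
#' @return logical vector.
#' @export
collapse_to_binary <- function(value, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  value <- as.character(value)
  bad <- !is.na(value) & !(value %in% spec$levels)
  if (any(bad)) {
    stop("factor '", spec$name, "': value '", value[bad][1L],
         "' is not one of its levels", call. = FALSE)
  }
  ifelse(is.na(value), NA, value %in% spec$truthy_levels)
}

#' Read a cohort CSV
#'
#' Expected header: `subject_id,timepoint,<factor1>,...`. Empty cells are
#' missing. Continuous source columns declared in a spec file's `binarize`
#' block (e.g. a SOFAS score thresholded at > 70, or age at > 18 years) are
#' thresholded into the factor's binary levels before validation.
#'
#' @param path CSV file path.
#' @param specs list of [factor_spec()]; may carry `binarize` attributes from
#'   [read_factor_specs()].
#' @return A [cohort_table()].
#' @export
read_cohort_csv <- function(path, specs) {
  specs <- as_spec_list(specs)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        na.strings = "")
  if (!all(c("subject_id", "timepoint") %in% names(df))) {
    stop("cohort CSV must have subject_id and timepoint columns",
         call. = FALSE)
  }
  df$timepoint <- as.numeric(df$timepoint)
  for (f in names(specs)) {
    bz <- attr(specs[[f]], "binarize")
    if (!is.null(bz)) {
      src <- as.numeric(df[[bz$source_column]])
      hi <- if (identical(bz$direction, "gt")) src > bz$threshold
            else src >= bz$threshold
      lv <- specs[[f]]$levels
      df[[f]] <- ifelse(is.na(src), NA_character_, ifelse(hi, lv[2L], lv[1L]))
    }
  }
  cohort_table(df, specs)
}

#' Read factor specifications from YAML
#'
#' Per factor: `levels`, `truthy_levels`, `domain_group`, and optionally
#' `binarize: {source_column, threshold, direction}` describing how a
#' continuous source column is thresholded into the two levels (direction
#' `"gt"` maps values strictly above the threshold to the second level).
#'
#' @param path YAML file path.
#' @return named list of [factor_spec()] objects.
#' @export
read_factor_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(names(raw), function(f) {
    x <- raw[[f]]
    sp <- factor_spec(f, x$levels,
                      domain_group = x$domain_group %||% "syndrome",
                      truthy_levels = x$truthy_levels %||%
                        x$levels[length(x$levels)])
    if (!is.null(x$binarize)) {
      bz <- x$binarize
      bz$direction <- bz$direction %||% "gt"
      attr(sp, "binarize") <- bz
    }
    sp
  })
  as_spec_list(specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# integer-coded matrix view of a complete dataset: column j holds values
# 1..r_j following the spec's level order; attribute "nlev" carries r
encode_dataset <- function(dataset, specs, columns = NULL) {
  specs <- as_spec_list(specs)
  df <- as.data.frame(dataset)
  if (is.null(columns)) columns <- intersect(names(df), names(specs))
  m <- matrix(0L, nrow(df), length(columns),
              dimnames = list(NULL, columns))
  nlev <- integer(length(columns))
  for (j in seq_along(columns)) {
    col <- columns[j]
    f <- sub("@t1?$", "", col)
    sp <- specs[[f]]
    if (is.null(sp)) stop("no factor spec for column '", col, "'",
                          call. = FALSE)
    v <- match(df[[col]], sp$levels)
    if (anyNA(v)) stop("missing or unknown value in column '", col, "'",
                       call. = FALSE)
    m[, j] <- v
    nlev[j] <- length(sp$levels)
  }
  attr(m, "nlev") <- stats::setNames(nlev, columns)
  m
}
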