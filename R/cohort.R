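#' Covariate scheme for the blood-pressure cohort
#'
#' Defines the ten categorical risk factors used throughout the package, their
#' category labels, and the designated reference category of each (always the
#' first level). Three factors vary at the woman level (age group, obesity,
#' education); the remaining seven describe the household.
#'
#' @return An object of class `"covariate_scheme"`: a list with elements
#'   `factors` (named list of character level vectors, reference first),
#'   `reference` (named character vector), `woman_level` and `household_level`
#'   (character vectors of factor names).
#' @examples
#' sch <- covariate_scheme()
#' names(sch$factors)
#' sch$reference[["age_group"]]
#' @export
covariate_scheme <- function() {
  f <- list(
    age_group             = c("15–24", "25–34", "35–44", "45–49"),
    obesity               = c("Not obese", "Obese"),
    cooking_fuel          = c("Advanced", "Transition", "Primitive"),
    education             = c("Secondary/higher", "No education", "Primary"),
    wealth                = c("Richer/richest", "Poorer/poorest", "Middle"),
    water_source          = c("Improved", "Unimproved"),
    toilet_type           = c("Improved", "Unimproved"),
    household_size        = c(">3 members", "1–3 members"),
    wall_type             = c("Durable materials", "Non-durable materials"),
    vegetable_consumption = c("Ate vegetable at least once",
                              "Didn’t eat vegetable")
  )
  woman <- c("age_group", "obesity", "education")
  structure(
    list(factors = f,
         reference = vapply(f, `[`, character(1), 1L),
         woman_level = woman,
         household_level = setdiff(names(f), woman)),
    class = "covariate_scheme"
  )
}

#' @export
print.covariate_scheme <- function(x, ...) {
  cat("Covariate scheme:", length(x$factors), "factors\n")
  for (nm in names(x$factors)) {
    lv <- x$factors[[nm]]
    cat(sprintf("  %-22s %s (ref: %s)\n", nm,
                paste(lv, collapse = " | "), x$reference[[nm]]))
  }
  invisible(x)
}

#' Classify hypertension from blood-pressure readings
#'
#' A woman is flagged hypertensive on SBP when systolic pressure is at least
#' 140 mmHg, on DBP when diastolic pressure is at least 90 mmHg, and on the
#' combined measure when either holds. Thresholds are inclusive.
#'
#' @param sbp,dbp Numeric vectors of systolic and diastolic blood pressure in
#'   mmHg; must be finite and positive.
#' @return A data frame with integer 0/1 columns `sbp_flag`, `dbp_flag`,
#'   `combined_flag`.
#' @examples
#' classify_hypertension(c(140, 139.9, 120), c(80, 89.9, 90))
#' @export
classify_hypertension <- function(sbp, dbp) {
  if (length(sbp) != length(dbp)) stop("'sbp' and 'dbp' must have equal length")
  if (!all(is.finite(sbp)) || !all(is.finite(dbp)) ||
      any(sbp <= 0) || any(dbp <= 0)) {
    stop("blood pressures must be finite and positive")
  }
  s <- as.integer(sbp >= 140)
  d <- as.integer(dbp >= 90)
  data.frame(sbp_flag = s, dbp_flag = d,
             combined_flag = as.integer(s | d))
}

#' Descriptive frequency table
#'
#' Tabulates the four hypertension measures (SBP, DBP, combined, ever-told)
#' and every covariate of the scheme as counts and percentages of the cohort.
#' Percentages are rounded half-away-from-zero to one decimal.
#'
#' @param data A woman-level data frame with columns `sbp`, `dbp`, `ever_told`
#'   and the scheme's factor columns.
#' @param scheme A [covariate_scheme()].
#' @return A data frame with columns `variable`, `level`, `count`, `percent`.
#' @export
descriptive_table <- function(data, scheme = covariate_scheme()) {
  if (nrow(data) == 0L) stop("no records to tabulate")
  need <- c("sbp", "dbp", "ever_told", names(scheme$factors))
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  n <- nrow(data)
  flags <- classify_hypertension(data$sbp, data$dbp)
  rows <- list()
  add <- function(variable, level, count) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, count = count,
      percent = round_half_away(100 * count / n, 1))
  }
  binary <- list(
    hypertensive_sbp      = flags$sbp_flag,
    hypertensive_dbp      = flags$dbp_flag,
    hypertensive_combined = flags$combined_flag,
    ever_told             = as.integer(data$ever_told)
  )
  for (nm in names(binary)) {
    add(nm, "No",  sum(binary[[nm]] == 0L))
    add(nm, "Yes", sum(binary[[nm]] == 1L))
  }
  for (f in names(scheme$factors)) {
    for (lvl in scheme$factors[[f]]) {
      add(f, lvl, sum(as.character(data[[f]]) == lvl))
    }
  }
  do.call(rbind, rows)
}

#' Validate a woman-level table
#'
#' Checks that every categorical value is one of its factor's declared levels,
#' flags boxplot-rule outliers in `sbp` and `dbp` (values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, quartiles by linear interpolation between
#' order statistics), and reports duplicated woman ids and incomplete records.
#' Outliers are flagged, never dropped.
#'
#' @inheritParams descriptive_table
#' @return An object of class `"bp_validation"`: a list with elements
#'   `n_records`, `category_violations` (data frame: row, factor, value),
#'   `outliers` (per outcome: indices, values, fences), `duplicate_ids`,
#'   `n_incomplete`.
#' @export
validate_records <- function(data, scheme = covariate_scheme()) {
  viol <- list()
  for (f in intersect(names(scheme$factors), names(data))) {
    vals <- as.character(data[[f]])
    bad <- which(!is.na(vals) & !(vals %in% scheme$factors[[f]]))
    if (length(bad)) {
      viol[[f]] <- data.frame(row = bad, factor = f, value = vals[bad])
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(row = integer(), factor = character(), value = character())
  rownames(viol) <- NULL

  box_flag <- function(x) {
    ok <- is.finite(x)
    q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    fen <- c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
    idx <- which(ok & (x < fen[1] | x > fen[2]))
    list(indices = idx, values = x[idx], fences = fen)
  }
  outliers <- list(sbp = box_flag(data$sbp), dbp = box_flag(data$dbp))

  dup <- if ("woman_id" %in% names(data)) {
    unique(data$woman_id[duplicated(data$woman_id)])
  } else character(0)

  need <- c("sbp", "dbp", intersect(names(scheme$factors), names(data)))
  inc <- sum(!stats::complete.cases(data[, need, drop = FALSE]))

  structure(list(n_records = nrow(data), category_violations = viol,
                 outliers = outliers, duplicate_ids = dup,
                 n_incomplete = inc),
            class = "bp_validation")
}

#' @export
print.bp_validation <- function(x, ...) {
  cat("Validation of", x$n_records, "records\n")
  cat("  category violations:", nrow(x$category_violations), "\n")
  cat("  sbp outliers flagged:", length(x$outliers$sbp$indices),
      sprintf("(fences %.1f–%.1f)\n", x$outliers$sbp$fences[1],
              x$outliers$sbp$fences[2]))
  cat("  dbp outliers flagged:", length(x$outliers$dbp$indices),
      sprintf("(fences %.1f–%.1f)\n", x$outliers$dbp$fences[1],
              x$outliers$dbp$fences[2]))
  cat("  duplicate woman ids:", length(x$duplicate_ids), "\n")
  cat("  incomplete records:", x$n_incomplete, "\n")
  invisible(x)
}

#' Build the fixed-effects design matrix
#'
#' One intercept column plus one 0/1 indicator per non-reference category,
#' ordered as in the scheme. Column names are `"factor=level"`. With the full
#' default scheme the design has 16 columns.
#'
#' @inheritParams descriptive_table
#' @return A numeric matrix with an `"assign"` attribute mapping columns to
#'   factor names (`"(Intercept)"` for the first column).
#' @export
build_design <- function(data, scheme = covariate_scheme()) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  assign <- "(Intercept)"
  for (f in names(scheme$factors)) {
    lv <- scheme$factors[[f]]
    vals <- as.character(data[[f]])
    bad <- setdiff(unique(vals), lv)
    if (length(bad)) {
      stop(sprintf("unknown level(s) for '%s': %s", f,
                   paste(bad, collapse = ", ")))
    }
    for (lvl in lv[-1]) {
      cols[[paste0(f, "=", lvl)]] <- as.numeric(vals == lvl)
      assign <- c(assign, f)
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "assign") <- assign
  X
}

# complete-case filter used by the fit wrappers; reports how many rows dropped
drop_incomplete <- function(data, scheme = covariate_scheme(), quiet = FALSE) {
  need <- c("sbp", "dbp", intersect(names(scheme$factors), names(data)))
  keep <- stats::complete.cases(data[, need, drop = FALSE])
  if (!all(keep) && !quiet) {
    message(sum(!keep), " incomplete record(s) excluded (complete-case analysis)")
  }
  data[keep, , drop = FALSE]
}
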