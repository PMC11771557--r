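# Cohort container, CSV I/O and the exclusion / complete-case machinery.

.FACTOR_LEVELS <- list(
  sex = c("girl", "boy"),
  maternal_ethnicity = c("sweden", "other"),
  breastfeeding_4m = c("exclusive_bf", "partial_bf", "exclusive_formula"),
  outdoor_env = c("city", "smaller_community", "rural"))

.BOOL_FIELDS <- c("maternal_university", "any_bf_9m", "early_solid_intro",
                  "family_fa_history", "fa_dx_9m", "fa_dx_18m",
                  "eczema_by_18m", "gi_only_symptoms")

#' Cohort column schema
#'
#' The documented CSV layout: one row per infant, columns `id`, the
#' covariates and outcomes, then `ffq_<food>` (frequency codes 1-6) for the
#' 14 scored foods and `intro_<food>` (timing codes 1-4) for the 15 foods
#' carrying an introduction item. Comma-separated, UTF-8, header required,
#' empty cell = missing. Booleans are written 1/0.
#'
#' @return A list with `columns` (name -> type/levels) and the food
#'   vocabulary; serialisable to YAML with [write_cohort_schema()].
#' @export
cohort_schema <- function() {
  cols <- c(
    list(id = list(type = "id")),
    lapply(.FACTOR_LEVELS, function(lv) list(type = "factor", levels = lv)),
    stats::setNames(rep(list(list(type = "bool")), length(.BOOL_FIELDS)),
                    .BOOL_FIELDS),
    list(maternal_age = list(type = "numeric", min = 0)),
    stats::setNames(rep(list(list(type = "code", min = 1, max = 6)),
                        length(FFQ_FOODS)), paste0("ffq_", FFQ_FOODS)),
    stats::setNames(rep(list(list(type = "code", min = 1, max = 4)),
                        length(INTRO_FOODS)), paste0("intro_", INTRO_FOODS)))
  list(version = "1.0", columns = cols,
       foods = list(ffq = FFQ_FOODS, intro = INTRO_FOODS,
                    allergenic = ALLERGEN_FOODS))
}

#' @rdname cohort_schema
#' @param path File path for the YAML rendering of the schema.
#' @export
write_cohort_schema <- function(path) {
  yaml::write_yaml(cohort_schema(), path)
  invisible(path)
}

#' Construct a cohort object
#'
#' Wraps a per-infant data frame together with a provenance label and the
#' cumulative exclusion log. Invariants enforced: ids unique;
#' gastrointestinal-only symptom flags require a food-allergy diagnosis at
#' 18 months (violations are set to missing with a warning).
#'
#' @param data Data frame in the [cohort_schema()] layout (typed columns).
#' @param provenance Free-text label describing the origin of the records.
#' @param exclusion_log Data frame with columns `rule`, `n_removed`,
#'   `n_after`; usually left to accumulate via the filter functions.
#' @return An object of class `dd_cohort`.
#' @export
new_cohort <- function(data, provenance = "unspecified", exclusion_log = NULL) {
  stopifnot(is.data.frame(data), "id" %in% names(data))
  if (anyDuplicated(data$id)) {
    dup <- unique(data$id[duplicated(data$id)])
    stop("duplicated infant id(s): ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (all(c("gi_only_symptoms", "fa_dx_18m") %in% names(data))) {
    bad <- !is.na(data$gi_only_symptoms) & data$gi_only_symptoms &
      !is.na(data$fa_dx_18m) & !data$fa_dx_18m
    if (any(bad)) {
      warning(sum(bad), " record(s) flag gastrointestinal-only symptoms ",
              "without an 18-month FA diagnosis; flag set to missing",
              call. = FALSE)
      data$gi_only_symptoms[bad] <- NA
    }
  }
  if ("maternal_age" %in% names(data)) {
    bad <- !is.na(data$maternal_age) & data$maternal_age <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive maternal age(s) set to missing",
              call. = FALSE)
      data$maternal_age[bad] <- NA_real_
    }
  }
  if (is.null(exclusion_log)) {
    exclusion_log <- data.frame(rule = character(), n_removed = integer(),
                                n_after = integer())
  }
  rownames(data) <- NULL
  structure(list(data = data, provenance = provenance,
                 exclusion_log = exclusion_log),
            class = "dd_cohort")
}

#' Number of records in a cohort
#' @param cohort A `dd_cohort`.
#' @export
n_records <- function(cohort) nrow(cohort$data)

#' @export
as.data.frame.dd_cohort <- function(x, ...) x$data

#' @export
print.dd_cohort <- function(x, ...) {
  cat("<dd_cohort> ", n_records(x), " infants  (", x$provenance, ")\n", sep = "")
  if (nrow(x$exclusion_log)) {
    cat("exclusion log:\n")
    print(x$exclusion_log, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.dd_cohort <- function(object, ...) {
  d <- object$data
  pr <- function(v) if (is.null(v)) NA_real_ else mean(v, na.rm = TRUE)
  out <- list(
    n = n_records(object),
    provenance = object$provenance,
    fa_9m = pr(d$fa_dx_9m), fa_18m = pr(d$fa_dx_18m),
    family_history = pr(d$family_fa_history), eczema = pr(d$eczema_by_18m),
    weighted_dd = tryCatch(mean(weighted_dd_score(d), na.rm = TRUE),
                           error = function(e) NA_real_),
    exclusion_log = object$exclusion_log)
  class(out) <- "summary.dd_cohort"
  out
}

#' @export
print.summary.dd_cohort <- function(x, ...) {
  cat("Cohort of", x$n, "infants --", x$provenance, "\n")
  cat(sprintf("  FA at 9m: %.1f%%   FA at 18m: %.1f%%\n",
              100 * x$fa_9m, 100 * x$fa_18m))
  cat(sprintf("  family FA history: %.1f%%   eczema by 18m: %.1f%%\n",
              100 * x$family_history, 100 * x$eczema))
  cat(sprintf("  weighted DD score (9m), mean: %.2f\n", x$weighted_dd))
  if (nrow(x$exclusion_log)) {
    cat("  exclusion log:\n")
    print(x$exclusion_log, row.names = FALSE)
  }
  invisible(x)
}

.parse_column <- function(x, spec, col) {
  x[x == ""] <- NA_character_
  n_bad <- 0L
  out <- switch(spec$type,
    id = x,
    factor = {
      bad <- !is.na(x) & !x %in% spec$levels
      n_bad <- sum(bad); x[bad] <- NA_character_
      x
    },
    bool = {
      v <- rep(NA, length(x))
      v[x %in% c("1", "TRUE", "true")] <- TRUE
      v[x %in% c("0", "FALSE", "false")] <- FALSE
      n_bad <- sum(!is.na(x) & is.na(v))
      v
    },
    numeric = {
      v <- suppressWarnings(as.numeric(x))
      n_bad <- sum(!is.na(x) & is.na(v))
      v
    },
    code = {
      v <- suppressWarnings(as.integer(x))
      bad <- !is.na(x) & (is.na(v) | v < spec$min | v > spec$max)
      n_bad <- sum(bad); v[bad] <- NA_integer_
      v
    })
  attr(out, "n_bad") <- n_bad
  out
}

#' Read a cohort CSV
#'
#' Parses and validates a cohort file against the column schema. Unparseable
#' category codes (e.g. a frequency of "7") become missing values and are
#' counted in a single warning; a missing `id` column or duplicated ids are
#' hard errors.
#'
#' @param path CSV file path.
#' @param schema Column schema, see [cohort_schema()].
#' @param provenance Label stored on the cohort; defaults to the file name.
#' @return A `dd_cohort`.
#' @export
read_cohort <- function(path, schema = cohort_schema(), provenance = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (!"id" %in% names(raw)) {
    stop("mandatory 'id' column missing in ", path, call. = FALSE)
  }
  missing_cols <- setdiff(names(schema$columns), names(raw))
  if (length(missing_cols)) {
    stop("columns missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parsed <- list()
  n_bad_total <- 0L
  for (col in names(schema$columns)) {
    v <- .parse_column(raw[[col]], schema$columns[[col]], col)
    n_bad_total <- n_bad_total + attr(v, "n_bad")
    attr(v, "n_bad") <- NULL
    parsed[[col]] <- v
  }
  if (anyNA(parsed$id) || any(parsed$id == "")) {
    stop("empty infant id(s) in ", path, call. = FALSE)
  }
  if (n_bad_total > 0L) {
    warning(n_bad_total, " unparseable cell(s) set to missing while reading ",
            path, call. = FALSE)
  }
  df <- as.data.frame(parsed, optional = TRUE, stringsAsFactors = FALSE)
  if (is.null(provenance)) provenance <- basename(path)
  new_cohort(df, provenance = provenance)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: booleans as 1/0, missing values as empty
#' cells, category codes as their integer encodings.
#'
#' @param cohort A `dd_cohort`.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "dd_cohort"))
  d <- cohort$data
  out <- lapply(d, function(v) {
    if (is.logical(v)) v <- as.integer(v)
    v <- as.character(v)
    v[is.na(v)] <- ""
    v
  })
  utils::write.csv(as.data.frame(out, optional = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

.append_log <- function(cohort, rule, n_removed) {
  cohort$exclusion_log <- rbind(
    cohort$exclusion_log,
    data.frame(rule = rule, n_removed = as.integer(n_removed),
               n_after = n_records(cohort)))
  cohort
}

#' Complete-case filter
#'
#' Keeps only records with no missing value among `required_fields` and
#' appends the removal count to the exclusion log. All model fits are run on
#' complete cases of their own variable set; no imputation anywhere.
#'
#' @param cohort A `dd_cohort`.
#' @param required_fields Character vector of column names.
#' @param rule Log label; defaults to a compact rendering of the field set.
#' @return The filtered `dd_cohort` (empty result allowed, with a warning).
#' @export
complete_case_filter <- function(cohort, required_fields,
                                 rule = NULL) {
  stopifnot(inherits(cohort, "dd_cohort"))
  unknown <- setdiff(required_fields, names(cohort$data))
  if (length(unknown)) {
    stop("unknown field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(cohort$data[required_fields])
  if (is.null(rule)) {
    rule <- paste0("complete_case[", length(required_fields), " fields]")
  }
  out <- cohort
  out$data <- cohort$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out <- .append_log(out, rule, sum(!keep))
  if (n_records(out) == 0L) {
    warning("complete-case filter removed every record", call. = FALSE)
  }
  out
}

#' Exclude infants with an early (9-month) food-allergy diagnosis
#'
#' Sensitivity filter against reverse causality: removes every record with a
#' food-allergy diagnosis at 9 months. Records where that field is missing
#' cannot be certified and are removed too, under a separate log entry.
#'
#' @param cohort A `dd_cohort`.
#' @return Filtered `dd_cohort`; idempotent.
#' @export
exclude_early_fa <- function(cohort) {
  stopifnot(inherits(cohort, "dd_cohort"))
  fa9 <- cohort$data$fa_dx_9m
  out <- cohort
  out$data <- cohort$data[!is.na(fa9) & !fa9, , drop = FALSE]
  rownames(out$data) <- NULL
  out <- .append_log(out, "early_fa", sum(fa9, na.rm = TRUE))
  if (anyNA(fa9)) out <- .append_log(out, "early_fa_missing", sum(is.na(fa9)))
  out
}

#' Exclude food-allergy cases reporting only gastrointestinal symptoms
#'
#' Guards against diagnostic misclassification: removes 18-month FA cases
#' whose only reported symptoms were gastrointestinal. Records with a
#' missing flag are retained (the flag is only defined for FA cases).
#'
#' @param cohort A `dd_cohort`.
#' @return Filtered `dd_cohort`; idempotent.
#' @export
exclude_gi_only <- function(cohort) {
  stopifnot(inherits(cohort, "dd_cohort"))
  gi <- cohort$data$gi_only_symptoms
  drop <- !is.na(gi) & gi
  out <- cohort
  out$data <- cohort$data[!drop, , drop = FALSE]
  rownames(out$data) <- NULL
  .append_log(out, "gi_only", sum(drop))
}

#' Stratify a cohort by a field
#'
#' Splits into one sub-cohort per observed value plus, when present, a
#' `"missing"` stratum, so the strata always partition the cohort. Intended
#' stratifiers are family FA history and eczema by 18 months.
#'
#' @param cohort A `dd_cohort`.
#' @param by Column name.
#' @return Named list of `dd_cohort` objects.
#' @export
stratify <- function(cohort, by) {
  stopifnot(inherits(cohort, "dd_cohort"))
  if (!by %in% names(cohort$data)) {
    stop("unknown stratification field: ", by, call. = FALSE)
  }
  v <- cohort$data[[by]]
  key <- ifelse(is.na(v), "missing", as.character(v))
  out <- lapply(split(seq_along(key), key), function(idx) {
    s <- cohort
    s$data <- cohort$data[idx, , drop = FALSE]
    rownames(s$data) <- NULL
    .append_log(s, paste0("stratum:", by, "=", key[idx[1L]]),
                n_records(cohort) - length(idx))
  })
  out
}

.field_summary <- function(v) {
  if (is.numeric(v)) {
    sprintf("mean %.2f (sd %.2f)", mean(v, na.rm = TRUE),
            stats::sd(v, na.rm = TRUE))
  } else {
    tb <- table(v, useNA = "no")
    paste(sprintf("%s %.1f%%", names(tb), 100 * prop.table(tb)),
          collapse = ", ")
  }
}

#' Compare two cohorts field by field
#'
#' Chi-square tests (Pearson, uncorrected) for categorical fields and Welch
#' t-tests for continuous ones, excluding missing values pairwise; used to
#' compare included vs excluded participants and similar group contrasts.
#' Fields constant in both groups are reported with an undefined statistic.
#'
#' @param cohort_a,cohort_b `dd_cohort` objects.
#' @param fields Character vector of column names present in both.
#' @return Data frame (class `dd_group_comparison`): one row per field with
#'   the statistic, p-value, per-group summaries and, for continuous or
#'   binary fields, the group estimates and their difference.
#' @export
compare_groups <- function(cohort_a, cohort_b, fields) {
  da <- cohort_a$data; db <- cohort_b$data
  missing_f <- setdiff(fields, intersect(names(da), names(db)))
  if (length(missing_f)) {
    stop("field(s) absent from a cohort: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(fields, function(f) {
    a <- da[[f]]; b <- db[[f]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    row <- data.frame(field = f, type = NA_character_,
                      statistic = NA_real_, p = NA_real_,
                      est_a = NA_real_, est_b = NA_real_, diff = NA_real_,
                      summary_a = .field_summary(a), summary_b = .field_summary(b),
                      note = "")
    if (is.numeric(a)) {
      row$type <- "continuous"
      row$est_a <- mean(a); row$est_b <- mean(b)
      row$diff <- row$est_a - row$est_b
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        row$note <- "constant in both groups"
      } else {
        tt <- stats::t.test(a, b)
        row$statistic <- unname(tt$statistic); row$p <- tt$p.value
      }
    } else {
      row$type <- "categorical"
      if (is.logical(a)) {
        row$est_a <- mean(a); row$est_b <- mean(b)
        row$diff <- row$est_a - row$est_b
      }
      lev <- sort(unique(c(as.character(a), as.character(b))))
      if (length(lev) < 2L) {
        row$note <- "constant in both groups"
      } else {
        tab <- rbind(table(factor(as.character(a), levels = lev)),
                     table(factor(as.character(b), levels = lev)))
        ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        row$statistic <- unname(ch$statistic); row$p <- ch$p.value
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dd_group_comparison", "data.frame")
  out
}
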