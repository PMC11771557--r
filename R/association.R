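# Association models: closed-form 2x2 odds ratios and the logistic fitting
# machinery behind the published association tables.

#' DAG-derived covariate adjustment sets
#'
#' Model 1 is the minimal sufficient adjustment set from the literature-based
#' DAG: maternal ethnicity, maternal university education (socioeconomic
#' proxy), breastfeeding status at 4 months, and early (< 4 months)
#' introduction of solids. Model 2 adds the evidence-based extension: family
#' FA history, outdoor living environment, and maternal age at delivery.
#'
#' @param adjust `"unadjusted"`, `"model1"` or `"model2"`.
#' @return Character vector of covariate column names (empty if unadjusted).
#' @export
adjustment_set <- function(adjust = c("unadjusted", "model1", "model2")) {
  adjust <- match.arg(adjust)
  m1 <- c("maternal_ethnicity", "maternal_university", "breastfeeding_4m",
          "early_solid_intro")
  switch(adjust,
    unadjusted = character(),
    model1 = m1,
    model2 = c(m1, "family_fa_history", "outdoor_env", "maternal_age"))
}

#' Item columns required by a score
#'
#' A record enters a score-specific analysis only if every item that score
#' consumes is non-missing (per-score complete case).
#'
#' @inheritParams dd_score
#' @return Character vector of cohort column names.
#' @export
score_item_columns <- function(measure = c("weighted", "introduced", "allergenic"),
                               age = 9) {
  measure <- match.arg(measure)
  switch(measure,
    weighted = paste0("ffq_", FFQ_FOODS),
    introduced = paste0("intro_", INTRO_SCORE_FOODS),
    allergenic = paste0("intro_", ALLERGEN_FOODS))
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' For a table with `a` exposed cases, `b` exposed non-cases, `c` reference
#' cases and `d` reference non-cases: OR = ad/bc, the 95% CI is
#' exp(log OR +/- z_0.975 * SE) with SE = sqrt(1/a + 1/b + 1/c + 1/d)
#' (the Woolf log-odds method), and the two-sided p-value is the normal tail
#' of log(OR)/SE. This reproduces published unadjusted category estimates at
#' printed precision. Any zero cell yields an undefined OR with an explicit
#' flag; no silent continuity correction is applied.
#'
#' @param a,b,c,d Non-negative integer cell counts, or `a` may be a 2x2
#'   matrix `rbind(c(a, b), c(c, d))`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `dd_or2x2`: `or`, `ci_low`, `ci_high`, `p`, `se`,
#'   the cells, and `zero_cell`.
#' @examples
#' odds_ratio_2x2(9, 321, 28, 466)  # OR 0.47 (0.22-1.00), p = .051
#' @export
odds_ratio_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                           conf_level = 0.95) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0))
  out <- list(a = a, b = b, c = c, d = d, conf_level = conf_level,
              zero_cell = any(cells == 0))
  if (out$zero_cell) {
    out[c("or", "ci_low", "ci_high", "p", "se")] <- NA_real_
  } else {
    lor <- log((a * d) / (b * c))
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    out$or <- exp(lor)
    out$ci_low <- exp(lor - z * se)
    out$ci_high <- exp(lor + z * se)
    out$se <- se
    out$p <- 2 * stats::pnorm(-abs(lor / se))
  }
  structure(out, class = "dd_or2x2")
}

#' @export
print.dd_or2x2 <- function(x, ...) {
  if (x$zero_cell) {
    cat("2x2 odds ratio: undefined (zero cell)\n")
  } else {
    cat(sprintf("2x2 odds ratio: %s, p = %s\n",
                format_or(x$or, x$ci_low, x$ci_high), format_p(x$p)))
  }
  cat(sprintf("  cells: a=%d b=%d c=%d d=%d\n", x$a, x$b, x$c, x$d))
  invisible(x)
}

# fit quietly: numerical glm warnings (separation, fitted 0/1) are recorded
# as flags on the result instead of escaping to the caller
.quiet_glm <- function(formula, data) {
  warnings <- character()
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data,
               model = FALSE, y = FALSE),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  attr(fit, "fit_warnings") <- unique(warnings)
  fit
}

.prep_model_frame <- function(data, covars) {
  for (v in intersect(covars, names(.FACTOR_LEVELS))) {
    data[[v]] <- factor(data[[v]], levels = .FACTOR_LEVELS[[v]])
  }
  data
}

#' Fit a diet-diversity / food-allergy association model
#'
#' The central fitting function: estimates the association between one
#' diversity exposure and a food-allergy outcome by maximum-likelihood
#' logistic regression on the complete cases of the model's variable set
#' (score items, outcome, covariates). Categorical exposures enter as
#' indicators against the lowest-diversity group; covariate reference levels
#' are Sweden-born, exclusive breastfeeding and city environment. Odds
#' ratios are exponentiated coefficients with Wald 95% intervals and normal
#' two-sided p-values, matching the closed-form 2x2 method in the
#' unadjusted categorical case.
#'
#' Degenerate fits are flagged rather than estimated: non-convergence or
#' separation voids the estimates, an exposure level with zero cases (or
#' zero non-cases) has its row flagged, and a constant exposure is
#' non-estimable.
#'
#' @param cohort A `dd_cohort`.
#' @param measure Exposure score: `"weighted"`, `"introduced"`,
#'   `"allergenic"`.
#' @param age Exposure age in months (6 or 9; weighted only at 9).
#' @param form `"categorical"` (published four groups) or `"continuous"`
#'   (per-point odds ratio).
#' @param adjust `"unadjusted"`, `"model1"` or `"model2"`, see
#'   [adjustment_set()].
#' @param outcome Outcome column, `"fa_dx_18m"` (default) or `"fa_dx_9m"`.
#' @param keep_fit Keep the underlying `glm` object (default `FALSE`; the
#'   coefficient vector and standard errors are always kept).
#' @return Object of class `dd_assoc` with a per-level result `table`
#'   (`level`, `n`, `cases`, `or`, `ci_low`, `ci_high`, `p`, `reference`,
#'   `flagged`), the model description, `n_used`, `converged` and `flags`.
#' @examples
#' set.seed(1)
#' coh <- generate_cohort(generator_params(n = 600, seed = 7))$cohort
#' fit <- dd_assoc(coh, "weighted", 9, "categorical", "unadjusted")
#' fit
#' @export
dd_assoc <- function(cohort,
                     measure = c("weighted", "introduced", "allergenic"),
                     age = 9,
                     form = c("categorical", "continuous"),
                     adjust = c("unadjusted", "model1", "model2"),
                     outcome = "fa_dx_18m",
                     keep_fit = FALSE) {
  stopifnot(inherits(cohort, "dd_cohort"))
  measure <- match.arg(measure)
  form <- match.arg(form)
  adjust <- match.arg(adjust)
  age <- as.integer(age)
  if (!outcome %in% names(cohort$data)) {
    stop("unknown outcome column: ", outcome, call. = FALSE)
  }
  covars <- adjustment_set(adjust)
  required <- c(score_item_columns(measure, age), outcome, covars)
  cc <- complete_case_filter(cohort, required,
                             rule = paste0("complete_case:", measure, age,
                                           "/", adjust))
  d <- cc$data
  score <- dd_score(cc, measure, age)
  y <- d[[outcome]]
  spec <- list(measure = measure, age = age, form = form, adjust = adjust,
               outcome = outcome)
  n_used <- nrow(d)
  res <- structure(list(table = NULL, spec = spec, n_used = n_used,
                        cases = sum(y), converged = FALSE, flags = character(),
                        coefficients = NULL, se = NULL, fit = NULL,
                        exclusion_log = cc$exclusion_log),
                   class = "dd_assoc")

  if (form == "categorical") {
    cat_def <- dd_categorization(measure, age)
    exposure <- categorize_score(score, cat_def)
    lev <- levels(exposure)
    tab_n <- as.integer(table(exposure))
    tab_cases <- as.integer(tapply(y, exposure, sum, default = 0L))
    out <- data.frame(level = lev, n = tab_n, cases = tab_cases,
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_,
                      reference = c(TRUE, rep(FALSE, length(lev) - 1L)),
                      flagged = FALSE)
    out$or[1L] <- 1
    degenerate <- tab_n == 0L | tab_cases == 0L | tab_cases == tab_n
    if (any(degenerate)) {
      out$flagged[degenerate] <- TRUE
      res$flags <- c(res$flags, paste0("degenerate_level:", lev[degenerate]))
    }
    if (n_used == 0L || degenerate[1L] || all(degenerate[-1L])) {
      res$table <- out
      return(res)
    }
    # degenerate levels carry no information about their own OR; drop their
    # records so the remaining contrasts stay estimable
    keep_rows <- !exposure %in% lev[degenerate]
    df_fit <- .prep_model_frame(
      cbind(data.frame(.y = y[keep_rows],
                       .exposure = droplevels(exposure[keep_rows])),
            d[keep_rows, covars, drop = FALSE]), covars)
    fml <- stats::as.formula(paste(
      ".y ~ .exposure", if (length(covars)) "+", paste(covars, collapse = " + ")))
    fit <- .quiet_glm(fml, df_fit)
    res$flags <- c(res$flags, attr(fit, "fit_warnings"))
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    res$converged <- isTRUE(fit$converged) && !any(is.na(est))
    sep <- res$converged && any(abs(est) > 15 | se > 1e3, na.rm = TRUE)
    if (sep) {
      res$flags <- c(res$flags, "separation")
      res$converged <- FALSE
    }
    if (res$converged) {
      z <- stats::qnorm(0.975)
      for (k in seq_along(lev)[-1L]) {
        if (out$flagged[k]) next
        nm <- paste0(".exposure", lev[k])
        out$or[k] <- exp(est[nm])
        out$ci_low[k] <- exp(est[nm] - z * se[nm])
        out$ci_high[k] <- exp(est[nm] + z * se[nm])
        out$p[k] <- 2 * stats::pnorm(-abs(est[nm] / se[nm]))
      }
    } else {
      out$or[-1L] <- NA_real_
      res$flags <- unique(c(res$flags, "not_converged"))
    }
    res$coefficients <- est
    res$se <- se
    if (keep_fit) res$fit <- fit
    res$table <- out
    return(res)
  }

  # continuous exposure: per-unit odds ratio
  out <- data.frame(level = "per 1-point increase", n = n_used,
                    cases = sum(y), or = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_, reference = FALSE,
                    flagged = FALSE)
  if (n_used == 0L || stats::var(score) == 0 || sum(y) == 0L ||
      sum(y) == n_used) {
    out$flagged <- TRUE
    res$flags <- c(res$flags,
                   if (n_used > 0L && stats::var(score) == 0)
                     "constant_exposure" else "degenerate_outcome")
    res$table <- out
    return(res)
  }
  df_fit <- .prep_model_frame(
    cbind(data.frame(.y = y, .exposure = as.numeric(score)), d[covars]),
    covars)
  fml <- stats::as.formula(paste(
    ".y ~ .exposure", if (length(covars)) "+", paste(covars, collapse = " + ")))
  fit <- .quiet_glm(fml, df_fit)
  res$flags <- c(res$flags, attr(fit, "fit_warnings"))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  res$converged <- isTRUE(fit$converged) && !any(is.na(est))
  if (res$converged && any(abs(est) > 15 | se > 1e3, na.rm = TRUE)) {
    res$flags <- c(res$flags, "separation")
    res$converged <- FALSE
  }
  if (res$converged) {
    z <- stats::qnorm(0.975)
    out$or <- exp(est[".exposure"])
    out$ci_low <- exp(est[".exposure"] - z * se[".exposure"])
    out$ci_high <- exp(est[".exposure"] + z * se[".exposure"])
    out$p <- 2 * stats::pnorm(-abs(est[".exposure"] / se[".exposure"]))
  } else {
    res$flags <- unique(c(res$flags, "not_converged"))
  }
  res$coefficients <- est
  res$se <- se
  if (keep_fit) res$fit <- fit
  res$table <- out
  res
}

#' @export
print.dd_assoc <- function(x, digits = 2, ...) {
  s <- x$spec
  cat(sprintf("Diet diversity association: %s score at %d months (%s, %s)\n",
              s$measure, s$age, s$form, s$adjust))
  cat(sprintf("  outcome %s;  n = %d, cases = %d%s\n", s$outcome, x$n_used,
              x$cases, if (x$converged || is.null(x$coefficients)) ""
              else "  [NOT CONVERGED]"))
  tab <- x$table
  tab$`OR (95% CI)` <- ifelse(
    tab$reference, "Ref 1.0",
    ifelse(is.na(tab$or), "--", format_or(tab$or, tab$ci_low, tab$ci_high)))
  tab$p <- ifelse(is.na(tab$p), "", format_p(tab$p))
  print(tab[c("level", "n", "cases", "OR (95% CI)", "p")], row.names = FALSE)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.dd_assoc <- function(object, ...) object

#' @export
coef.dd_assoc <- function(object, ...) object$coefficients

#' @export
confint.dd_assoc <- function(object, parm, level = 0.95, ...) {
  est <- object$coefficients
  se <- object$se
  if (is.null(est)) return(NULL)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - z * se, est + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
as.data.frame.dd_assoc <- function(x, ...) {
  cbind(data.frame(measure = x$spec$measure, age = x$spec$age,
                   form = x$spec$form, adjust = x$spec$adjust,
                   outcome = x$spec$outcome, n_used = x$n_used),
        x$table)
}

.TABLE_BLOCKS <- list(
  list(measure = "weighted", age = 9L),
  list(measure = "introduced", age = 6L),
  list(measure = "introduced", age = 9L),
  list(measure = "allergenic", age = 6L),
  list(measure = "allergenic", age = 9L))

#' Run the full association table
#'
#' Fits all five exposure blocks (weighted score at 9 months; introduced
#' foods at 6 and 9 months; allergenic foods at 6 and 9 months), each in
#' continuous and categorical form, under the unadjusted, model-1 and
#' model-2 adjustment sets: 30 fits, each on its own per-block complete-case
#' sample.
#'
#' @param cohort A `dd_cohort`.
#' @param outcome Outcome column (default `"fa_dx_18m"`).
#' @return A `dd_assoc_set`: named list of [dd_assoc()] results, names
#'   `<measure><age>.<form>.<adjust>`.
#' @export
run_table3 <- function(cohort, outcome = "fa_dx_18m") {
  fits <- list()
  for (blk in .TABLE_BLOCKS) {
    for (form in c("continuous", "categorical")) {
      for (adjust in c("unadjusted", "model1", "model2")) {
        key <- paste0(blk$measure, blk$age, ".", form, ".", adjust)
        fits[[key]] <- dd_assoc(cohort, blk$measure, blk$age, form, adjust,
                                outcome = outcome)
      }
    }
  }
  structure(fits, class = "dd_assoc_set", outcome = outcome)
}

#' @export
print.dd_assoc_set <- function(x, adjust = "model2", ...) {
  cat("Association table (", length(x), " fits; showing ", adjust, ")\n",
      sep = "")
  for (key in grep(paste0("\\.", adjust, "$"), names(x), value = TRUE)) {
    print(x[[key]])
    cat("\n")
  }
  invisible(x)
}

#' @export
as.data.frame.dd_assoc_set <- function(x, ...) {
  out <- do.call(rbind, lapply(unname(x), as.data.frame))
  rownames(out) <- NULL
  out
}

#' Sensitivity re-analysis after an exclusion filter
#'
#' Re-runs the full association table on the cohort filtered by one of the
#' sensitivity rules: excluding infants already diagnosed at 9 months
#' (reverse causality) or excluding FA cases with only gastrointestinal
#' symptoms (diagnostic misclassification).
#'
#' @param cohort A `dd_cohort`.
#' @param variant `"exclude_early_fa"` or `"exclude_gi_only"`.
#' @param outcome Outcome column.
#' @return A `dd_assoc_set` with attributes `variant` and `n_excluded`.
#' @export
run_sensitivity <- function(cohort,
                            variant = c("exclude_early_fa", "exclude_gi_only"),
                            outcome = "fa_dx_18m") {
  variant <- match.arg(variant)
  filtered <- switch(variant,
    exclude_early_fa = exclude_early_fa(cohort),
    exclude_gi_only = exclude_gi_only(cohort))
  out <- run_table3(filtered, outcome = outcome)
  attr(out, "variant") <- variant
  attr(out, "n_excluded") <- n_records(cohort) - n_records(filtered)
  out
}

#' Stratified association models
#'
#' Fits the fully adjusted (model 2) associations separately within strata
#' of family FA history or eczema by 18 months, for the two 9-month
#' exposures shown in the published forest plots (weighted score and number
#' of introduced foods), in continuous and categorical form. Records with a
#' missing stratifier are excluded from the fits and their count reported.
#'
#' @param cohort A `dd_cohort`.
#' @param by `"family_fa_history"` or `"eczema_by_18m"`.
#' @param outcome Outcome column.
#' @return A `dd_assoc_strata`: per-stratum named lists of [dd_assoc()]
#'   fits, with attributes `by` and `n_missing_stratifier`.
#' @export
run_stratified <- function(cohort, by = c("family_fa_history", "eczema_by_18m"),
                           outcome = "fa_dx_18m") {
  by <- match.arg(by)
  strata <- stratify(cohort, by)
  n_missing <- if ("missing" %in% names(strata))
    n_records(strata[["missing"]]) else 0L
  strata <- strata[setdiff(names(strata), "missing")]
  out <- lapply(strata, function(s) {
    fits <- list()
    for (blk in list(list(measure = "weighted", age = 9L),
                     list(measure = "introduced", age = 9L))) {
      for (form in c("continuous", "categorical")) {
        key <- paste0(blk$measure, blk$age, ".", form, ".model2")
        fits[[key]] <- dd_assoc(s, blk$measure, blk$age, form, "model2",
                                outcome = outcome)
      }
    }
    structure(fits, class = "dd_assoc_set", outcome = outcome)
  })
  structure(out, class = "dd_assoc_strata", by = by,
            n_missing_stratifier = n_missing)
}

#' @export
print.dd_assoc_strata <- function(x, ...) {
  cat("Stratified association models by", attr(x, "by"), "\n")
  cat("  records with missing stratifier:", attr(x, "n_missing_stratifier"),
      "\n\n")
  for (nm in names(x)) {
    cat("== stratum:", attr(x, "by"), "=", nm, "==\n")
    print(x[[nm]])
  }
  invisible(x)
}
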