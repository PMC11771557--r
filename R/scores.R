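# Scoring operations: weighted diet diversity, introduced foods,
# introduced allergenic foods, and the published categorisations.

# Normalise ffq/intro input to an integer code matrix with one column per
# requested food. Accepts a dd_cohort, a data.frame with prefixed columns
# (ffq_<food> / intro_<food>), a data.frame with bare food columns, or a
# single named vector (one record).
.code_matrix <- function(x, foods, prefix) {
  if (inherits(x, "dd_cohort")) x <- x$data
  if (is.null(dim(x))) {
    x <- as.data.frame(as.list(x), optional = TRUE)
  }
  want <- paste0(prefix, foods)
  cols <- ifelse(want %in% names(x), want,
                 ifelse(foods %in% names(x), foods, NA_character_))
  if (anyNA(cols)) {
    stop("missing required ", prefix, "items for foods: ",
         paste(foods[is.na(cols)], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(as.data.frame(lapply(x[cols], as.integer)))
  colnames(m) <- foods
  m
}

#' Frequency-weighted diet-diversity score
#'
#' Sums per-food points assigned to the consumption-frequency category of
#' each of the 14 scored foods: 0 for never, 1 for 1-3 times/month, 2 for
#' weekly consumption (1-6 times/week), and for daily consumption
#' (1-6 times/day) 1 point for the eleven staple/animal foods but 3 points
#' for the three plant foods. Total range 0-31. The score is missing if any
#' of the 14 items is missing (no imputation).
#'
#' @param ffq A `dd_cohort`, a data frame with `ffq_<food>` columns, or a
#'   named vector of frequency codes (1-6) for one infant.
#' @param scheme A weighted `dd_scheme` (see [dd_scheme()]).
#' @return Integer vector of scores (NA where any item is missing).
#' @examples
#' rec <- stats::setNames(rep(3L, 14), FFQ_FOODS)  # all foods weekly
#' weighted_dd_score(rec)  # 28
#' @export
weighted_dd_score <- function(ffq, scheme = dd_scheme("weighted")) {
  stopifnot(inherits(scheme, "dd_scheme"), scheme$name == "weighted")
  codes <- .code_matrix(ffq, scheme$foods, "ffq_")
  bad <- !is.na(codes) & (codes < 1L | codes > 6L)
  if (any(bad)) {
    stop("frequency codes outside 1-6; run read_cohort() validation first",
         call. = FALSE)
  }
  pts <- matrix(NA_real_, nrow(codes), ncol(codes))
  for (j in seq_along(scheme$foods)) {
    pts[, j] <- scheme$points[j, ][codes[, j]]
  }
  as.integer(rowSums(pts))
}

.intro_indicator <- function(codes, age) {
  # introduced by 6 months: first introduction at 0-3 or 4-6 months;
  # by 9 months: any category other than "not introduced by around 9 months"
  if (age == 6L) {
    ind <- codes == 2L | codes == 3L
  } else {
    ind <- codes != 1L
  }
  ind[is.na(codes)] <- NA
  ind
}

#' Introduced-foods diversity score
#'
#' Counts how many of the 14 food groups have been introduced (yes/no) by
#' the given age. Introduction by 6 months means a timing category of
#' 0-3 or 4-6 months; by 9 months, any category except "not introduced".
#' Missing if any of the 14 timings is missing.
#'
#' @param intro A `dd_cohort`, a data frame with `intro_<food>` columns, or
#'   a named vector of timing codes (1-4) for one infant.
#' @param age_months 6 or 9.
#' @param scheme An introduced-foods `dd_scheme`.
#' @return Integer vector of scores in 0-14.
#' @export
introduced_foods_score <- function(intro, age_months = 9,
                                   scheme = dd_scheme("introduced")) {
  stopifnot(inherits(scheme, "dd_scheme"), scheme$name != "weighted")
  age <- as.integer(age_months)
  if (!age %in% scheme$ages) {
    stop("score '", scheme$name, "' is not defined at ", age, " months",
         call. = FALSE)
  }
  codes <- .code_matrix(intro, scheme$foods, "intro_")
  bad <- !is.na(codes) & (codes < 1L | codes > 4L)
  if (any(bad)) {
    stop("timing codes outside 1-4; run read_cohort() validation first",
         call. = FALSE)
  }
  as.integer(rowSums(.intro_indicator(codes, age)))
}

#' Introduced allergenic-foods diversity score
#'
#' Counts how many of the 6 allergenic foods (milk -- mapped to the dairy
#' item --, wheat, egg, fish, soy, nuts and peanuts) have been introduced by
#' the given age, with the same introduction predicates as
#' [introduced_foods_score()]. Range 0-6.
#'
#' @inheritParams introduced_foods_score
#' @export
allergenic_foods_score <- function(intro, age_months = 9,
                                   scheme = dd_scheme("allergenic")) {
  introduced_foods_score(intro, age_months, scheme)
}

#' Compute a diversity score for every record of a cohort
#'
#' Vectorised dispatcher over the three measurements.
#'
#' @param cohort A `dd_cohort` (or compatible data frame).
#' @param measure `"weighted"`, `"introduced"` or `"allergenic"`.
#' @param age 6 or 9 months (the weighted score only exists at 9).
#' @param rice Rice mapping for the weighted scheme, see [dd_scheme()].
#' @return Integer vector, NA where the score's items are incomplete.
#' @export
dd_score <- function(cohort, measure = c("weighted", "introduced", "allergenic"),
                     age = 9, rice = c("staple", "plant")) {
  measure <- match.arg(measure)
  switch(measure,
    weighted = {
      if (as.integer(age) != 9L) {
        stop("the weighted score is only defined at 9 months", call. = FALSE)
      }
      weighted_dd_score(cohort, dd_scheme("weighted", rice = rice))
    },
    introduced = introduced_foods_score(cohort, age),
    allergenic = allergenic_foods_score(cohort, age))
}

#' Assign scores to published exposure categories
#'
#' Maps score values into the four-group categorisation (inclusive bounds,
#' reference = first group). Missing scores give missing labels; values
#' outside the scheme range are an invariant breach and raise an error.
#'
#' @param score Integer vector of score values.
#' @param cat A `dd_categorization`, or the measure name (with `age`) used
#'   to look one up.
#' @param age Age in months, used when `cat` is a measure name.
#' @return Factor with the category labels as levels, in order.
#' @examples
#' categorize_score(c(17, 18, NA), "weighted", age = 9)
#' @export
categorize_score <- function(score, cat, age = 9) {
  if (is.character(cat)) cat <- dd_categorization(cat, age)
  stopifnot(inherits(cat, "dd_categorization"))
  rng <- range(cat$lower, cat$upper)
  out_of_range <- !is.na(score) & (score < rng[1] | score > rng[2])
  if (any(out_of_range)) {
    stop("score value(s) outside [", rng[1], ",", rng[2],
         "]: upstream invariant breach", call. = FALSE)
  }
  idx <- rep(NA_integer_, length(score))
  for (k in seq_len(nrow(cat))) {
    hit <- !is.na(score) & score >= cat$lower[k] & score <= cat$upper[k]
    idx[hit] <- k
  }
  factor(cat$label[idx], levels = cat$label)
}

#' Exact distribution of the weighted score under a generation profile
#'
#' Convolves the per-food point distributions implied by per-food frequency
#' category probabilities, assuming independent foods. Used as the exact
#' calibration oracle for the synthetic-cohort generator.
#'
#' @param profile Named list, food -> probability vector over the six
#'   frequency categories.
#' @param scheme A weighted `dd_scheme`.
#' @return Numeric vector `p` of length `max_points + 1`; `p[k+1]` is the
#'   probability of score `k`.
#' @export
weighted_score_pmf <- function(profile, scheme = dd_scheme("weighted")) {
  stopifnot(inherits(scheme, "dd_scheme"), scheme$name == "weighted")
  pmf <- 1
  for (f in scheme$foods) {
    pr <- profile[[f]]
    stopifnot(length(pr) == 6L, abs(sum(pr) - 1) < 1e-8)
    pts <- scheme$points[f, ]
    food_pmf <- numeric(max(pts) + 1L)
    for (k in seq_len(6L)) {
      food_pmf[pts[k] + 1L] <- food_pmf[pts[k] + 1L] + pr[k]
    }
    new <- numeric(length(pmf) + length(food_pmf) - 1L)
    for (v in seq_along(food_pmf)) {
      if (food_pmf[v] > 0) {
        new[seq_along(pmf) + v - 1L] <-
          new[seq_along(pmf) + v - 1L] + pmf * food_pmf[v]
      }
    }
    pmf <- new
  }
  length(pmf) <- scheme$max_points + 1L
  pmf[is.na(pmf)] <- 0
  pmf
}

# mean and sd implied by a pmf over 0..K
.pmf_stats <- function(pmf) {
  k <- seq_along(pmf) - 1
  m <- sum(k * pmf)
  c(mean = m, sd = sqrt(sum((k - m)^2 * pmf)))
}
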