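# Food vocabulary and category scales underlying all diet-diversity scores.

#' Consumption-frequency categories
#'
#' The food frequency questionnaire records present consumption of each food
#' on a six-level ordered scale, encoded 1-6 on disk:
#' (1) never, (2) 1-3 times/month, (3) 1-3 times/week, (4) 4-6 times/week,
#' (5) 1-3 times/day, (6) 4-6 times/day. A missing answer is an empty cell,
#' never conflated with "never".
#'
#' @format Character vector of the six level names in increasing order.
#' @export
FREQ_LEVELS <- c("never", "monthly_1_3", "weekly_1_3", "weekly_4_6",
                 "daily_1_3", "daily_4_6")

#' Introduction-timing categories
#'
#' Timing of first introduction of each food, encoded 1-4 on disk:
#' (1) not introduced at around 9 months, (2) introduced at 0-3 months,
#' (3) introduced at 4-6 months, (4) introduced at 7 months or later.
#'
#' @format Character vector of the four level names.
#' @export
TIMING_LEVELS <- c("not_by_9m", "intro_0_3m", "intro_4_6m", "intro_7m_plus")

#' Food vocabulary
#'
#' Registered food identifiers used by the scoring schemes. `FFQ_FOODS` are
#' the 14 foods whose consumption frequency feeds the weighted score;
#' `INTRO_SCORE_FOODS` the 14 food groups of the introduced-foods score;
#' `ALLERGEN_FOODS` the 6 allergenic foods (milk maps to the dairy item:
#' any cow's-milk product excluding formula); `INTRO_FOODS` the union of
#' foods carrying an introduction-timing item.
#'
#' @format Character vectors of food identifiers.
#' @name food_vocabulary
NULL

#' @rdname food_vocabulary
#' @export
FFQ_FOODS <- c("potatoes", "rice", "pasta", "bread", "porridge", "egg",
               "fish", "meat", "dairy", "nuts_peanuts", "fruit_berries",
               "veg_meat_subst", "pulses", "vegetables")

# plant foods rewarded for daily consumption (0-3p); all other scored foods
# cap at 2 points, daily consumption dropping back to 1
.CLASS_B_FOODS <- c("fruit_berries", "veg_meat_subst", "vegetables")

#' @rdname food_vocabulary
#' @export
INTRO_SCORE_FOODS <- c("potatoes", "rice", "pasta", "vegetables", "meat",
                       "fish", "soy", "pulses", "fruit_berries", "egg",
                       "dairy", "porridge", "bread", "nuts_peanuts")

#' @rdname food_vocabulary
#' @export
ALLERGEN_FOODS <- c("dairy", "wheat", "egg", "fish", "soy", "nuts_peanuts")

#' @rdname food_vocabulary
#' @export
INTRO_FOODS <- union(INTRO_SCORE_FOODS, ALLERGEN_FOODS)

# per-category points for the weighted score; index = frequency code 1..6
.POINTS_STAPLE <- c(0, 1, 2, 2, 1, 1)  # never, monthly, weekly x2, daily x2
.POINTS_PLANT  <- c(0, 1, 2, 2, 3, 3)

#' Diet-diversity score schemes
#'
#' Constructs one of the three diversity measurements:
#' \describe{
#'   \item{weighted}{Frequency-weighted score over 14 foods at 9 months,
#'     total range 0-31. Eleven foods score 0/1/2/1 points for
#'     never / monthly / weekly / daily consumption; the three plant foods
#'     (fruit and berries, vegetarian meat substitutes, vegetables) score
#'     0/1/2/3, rewarding daily consumption.}
#'   \item{introduced}{Count of 14 food groups introduced (yes/no) by 6 or
#'     9 months, range 0-14.}
#'   \item{allergenic}{Count of 6 allergenic foods (milk, wheat, egg, fish,
#'     soy, nuts and peanuts) introduced by 6 or 9 months, range 0-6.}
#' }
#'
#' The published table is ambiguous about rice: it lists the 0-2p cap but
#' carries the plant-food footnote marker. Only the eleven-staples reading
#' reproduces the printed total range of 31 points, so rice defaults to the
#' staple mapping; `rice = "plant"` exposes the alternative reading.
#'
#' @param name One of `"weighted"`, `"introduced"`, `"allergenic"`.
#' @param rice For the weighted scheme, `"staple"` (default, 0-2p) or
#'   `"plant"` (0-3p).
#' @return An object of class `dd_scheme`: name, foods, ages at which the
#'   score is defined, `max_points`, and for the weighted scheme a
#'   food-by-frequency `points` matrix.
#' @examples
#' dd_scheme("weighted")$max_points  # 31
#' @export
dd_scheme <- function(name = c("weighted", "introduced", "allergenic"),
                      rice = c("staple", "plant")) {
  name <- match.arg(name)
  rice <- match.arg(rice)
  sch <- switch(name,
    weighted = {
      plant <- .CLASS_B_FOODS
      if (rice == "plant") plant <- c(plant, "rice")
      pts <- t(vapply(FFQ_FOODS, function(f) {
        if (f %in% plant) .POINTS_PLANT else .POINTS_STAPLE
      }, numeric(6L)))
      colnames(pts) <- FREQ_LEVELS
      list(name = "weighted", foods = FFQ_FOODS, ages = 9L,
           points = pts, max_points = sum(apply(pts, 1L, max)))
    },
    introduced = list(name = "introduced", foods = INTRO_SCORE_FOODS,
                      ages = c(6L, 9L), max_points = length(INTRO_SCORE_FOODS)),
    allergenic = list(name = "allergenic", foods = ALLERGEN_FOODS,
                      ages = c(6L, 9L), max_points = length(ALLERGEN_FOODS)))
  structure(sch, class = "dd_scheme")
}

#' @export
print.dd_scheme <- function(x, ...) {
  cat("Diet-diversity scheme:", x$name, "\n")
  cat("  foods (", length(x$foods), "): ", paste(x$foods, collapse = ", "),
      "\n", sep = "")
  cat("  ages:", paste(x$ages, collapse = ", "), "months;  range: 0-",
      x$max_points, "p\n", sep = "")
  invisible(x)
}

#' Exposure categorisations
#'
#' The published four-group categorisations of each score (reference = first,
#' lowest-diversity group), with inclusive bounds tiling the full range:
#' weighted at 9 months 0-17/18-20/21-23/24-31 points; introduced foods at
#' 6 months 0-7/8-9/10-11/12-14 and at 9 months 0-10/11/12/13-14; allergenic
#' foods at 6 months 0-2/3/4/5-6 and at 9 months 0-3/4/5/6.
#'
#' @param measure `"weighted"`, `"introduced"` or `"allergenic"`.
#' @param age 6 or 9 (months); the weighted score exists only at 9.
#' @return A `dd_categorization`: data frame with `lower`, `upper`, `label`.
#' @examples
#' dd_categorization("weighted", 9)
#' @export
dd_categorization <- function(measure = c("weighted", "introduced", "allergenic"),
                              age = 9) {
  measure <- match.arg(measure)
  age <- as.integer(age)
  key <- paste0(measure, age)
  tab <- switch(key,
    weighted9 = data.frame(
      lower = c(0L, 18L, 21L, 24L), upper = c(17L, 20L, 23L, 31L),
      label = c("0-17p", "18-20p", "21-23p", "24-31p")),
    introduced6 = data.frame(
      lower = c(0L, 8L, 10L, 12L), upper = c(7L, 9L, 11L, 14L),
      label = c("0-7 foods", "8-9 foods", "10-11 foods", "12-14 foods")),
    introduced9 = data.frame(
      lower = c(0L, 11L, 12L, 13L), upper = c(10L, 11L, 12L, 14L),
      label = c("0-10 foods", "11 foods", "12 foods", "13-14 foods")),
    allergenic6 = data.frame(
      lower = c(0L, 3L, 4L, 5L), upper = c(2L, 3L, 4L, 6L),
      label = c("0-2 allergenic foods", "3 allergenic foods",
                "4 allergenic foods", "5-6 allergenic foods")),
    allergenic9 = data.frame(
      lower = c(0L, 4L, 5L, 6L), upper = c(3L, 4L, 5L, 6L),
      label = c("0-3 allergenic foods", "4 allergenic foods",
                "5 allergenic foods", "6 allergenic foods")),
    stop("no categorisation defined for measure '", measure,
         "' at age ", age, " months", call. = FALSE))
  structure(tab, class = c("dd_categorization", "data.frame"),
            measure = measure, age = age)
}

#' Serialise or read a score scheme as YAML
#'
#' @param scheme A `dd_scheme`.
#' @param path File path.
#' @return `read_scheme` returns a `dd_scheme`; `write_scheme` its path,
#'   invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "dd_scheme"))
  obj <- unclass(scheme)
  if (!is.null(obj$points)) {
    obj$points <- lapply(seq_along(obj$foods), function(i) {
      as.list(stats::setNames(as.numeric(obj$points[i, ]), FREQ_LEVELS))
    })
    names(obj$points) <- obj$foods
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- yaml::yaml.load_file(path)
  if (!is.null(obj$points)) {
    pts <- t(vapply(obj$foods, function(f) {
      unlist(obj$points[[f]])[FREQ_LEVELS]
    }, numeric(6L)))
    colnames(pts) <- FREQ_LEVELS
    obj$points <- pts
  }
  obj$ages <- as.integer(obj$ages)
  obj$max_points <- as.integer(obj$max_points)
  structure(obj, class = "dd_scheme")
}
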