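# Calibrated synthetic-cohort generator: emulates the published covariate
# distributions, score means/SDs and per-field missingness, with a planted
# logistic outcome model, so the whole pipeline validates without data.

.dd_cache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, envir = .dd_cache)) {
    assign(key, force(expr), envir = .dd_cache)
  }
  get(key, envir = .dd_cache)
}

# fixed splits of point-probability mass onto concrete frequency categories;
# they do not affect the score, only the realism of the raw categories
.SPLIT_A_ONE  <- c(monthly_1_3 = 0.35, daily_1_3 = 0.50, daily_4_6 = 0.15)
.SPLIT_WEEKLY <- c(weekly_1_3 = 0.60, weekly_4_6 = 0.40)
.SPLIT_B_DAILY <- c(daily_1_3 = 0.80, daily_4_6 = 0.20)

.freq_probs_staple <- function(p0, p1, p2) {
  c(never = p0,
    monthly_1_3 = p1 * .SPLIT_A_ONE[["monthly_1_3"]],
    weekly_1_3 = p2 * .SPLIT_WEEKLY[["weekly_1_3"]],
    weekly_4_6 = p2 * .SPLIT_WEEKLY[["weekly_4_6"]],
    daily_1_3 = p1 * .SPLIT_A_ONE[["daily_1_3"]],
    daily_4_6 = p1 * .SPLIT_A_ONE[["daily_4_6"]])
}

.freq_probs_plant <- function(p0, p1, p2, p3) {
  c(never = p0, monthly_1_3 = p1,
    weekly_1_3 = p2 * .SPLIT_WEEKLY[["weekly_1_3"]],
    weekly_4_6 = p2 * .SPLIT_WEEKLY[["weekly_4_6"]],
    daily_1_3 = p3 * .SPLIT_B_DAILY[["daily_1_3"]],
    daily_4_6 = p3 * .SPLIT_B_DAILY[["daily_4_6"]])
}

#' Calibrate per-food frequency probabilities to a weighted-score target
#'
#' Deterministically finds per-food frequency-category probabilities whose
#' implied weighted-score mean equals `target_mean` exactly and implied SD
#' equals `target_sd` exactly (both have closed forms under independent
#' foods: the score mean is the sum of per-food expected points and the
#' variance the sum of per-food point variances). Within the feasible set
#' the search prefers the least bimodal per-food distributions. Matching the
#' published SD of 3.91 forces strongly bimodal items: a sum of 14 bounded
#' independent items cannot otherwise be that dispersed.
#'
#' @param target_mean Target score mean, in `[0, 31]`.
#' @param target_sd Target score SD (points).
#' @param scheme Weighted `dd_scheme`.
#' @return Named list food -> probability vector over the six frequency
#'   categories, with attributes `implied_mean` and `implied_sd`.
#' @examples
#' prof <- calibrate_ffq_profile(19.77, 3.91)
#' attr(prof, "implied_mean")
#' @export
calibrate_ffq_profile <- function(target_mean, target_sd,
                                  scheme = dd_scheme("weighted")) {
  if (target_mean < 0 || target_mean > scheme$max_points) {
    stop("target mean ", target_mean, " outside [0, ", scheme$max_points, "]",
         call. = FALSE)
  }
  plant <- scheme$foods[scheme$points[, "daily_1_3"] == 3]
  staple <- setdiff(scheme$foods, plant)
  n_a <- length(staple); n_b <- length(plant)

  build <- function(a, b) {
    prof <- c(
      stats::setNames(rep(list(.freq_probs_staple(a[1], a[2], a[3])), n_a),
                      staple),
      stats::setNames(rep(list(.freq_probs_plant(b[1], b[2], b[3], b[4])), n_b),
                      plant))
    prof <- prof[scheme$foods]
    st <- .pmf_stats(weighted_score_pmf(prof, scheme))
    attr(prof, "implied_mean") <- st[["mean"]]
    attr(prof, "implied_sd") <- st[["sd"]]
    prof
  }

  # degenerate boundary targets have forced profiles
  if (target_sd == 0 && target_mean == 0) {
    return(build(c(1, 0, 0), c(1, 0, 0, 0)))
  }
  if (target_sd == 0 && target_mean == scheme$max_points) {
    return(build(c(0, 0, 1), c(0, 0, 0, 1)))
  }

  mu <- target_mean
  s2 <- target_sd^2
  # staple foods score on {0,1,2}; given (Ea, Va) the point distribution is
  # unique. Plant foods score on {0,1,2,3}; with equal mass on 1 and 2
  # points, (Eb, Vb) also determines it. The class means/variances must
  # combine to (mu, s2); search the (Ea, Va) plane.
  ea <- seq(0, 2, by = 0.004)
  va <- seq(0, 1, by = 0.002)
  G <- expand.grid(Ea = ea, Va = va)
  G$Eb <- (mu - n_a * G$Ea) / n_b
  G$Vb <- (s2 - n_a * G$Va) / n_b
  a2 <- (G$Va + G$Ea^2 - G$Ea) / 2
  a1 <- G$Ea - 2 * a2
  a0 <- 1 - a1 - a2
  m <- (3 * G$Eb - G$Vb - G$Eb^2) / 2
  b3 <- (G$Eb - 1.5 * m) / 3
  b0 <- 1 - m - b3
  eps <- 1e-9
  ok <- a0 >= -eps & a0 <= 1 + eps & a1 >= -eps & a1 <= 1 + eps &
    a2 >= -eps & a2 <= 1 + eps & m >= -eps & m / 2 <= 1 + eps &
    b3 >= -eps & b3 <= 1 + eps & b0 >= -eps & b0 <= 1 + eps &
    G$Eb >= 0 & G$Eb <= 3 & G$Vb >= 0
  if (!any(ok)) {
    sd_env <- .ffq_sd_envelope(mu, n_a, n_b)
    stop(sprintf(paste0("no frequency profile attains mean %.2f with SD %.2f ",
                        "under independent foods; feasible SD range at this ",
                        "mean is [%.2f, %.2f]"),
                 mu, target_sd, sd_env[1], sd_env[2]), call. = FALSE)
  }
  # prefer the least extreme feasible solution (most mass off the 0/max poles)
  score_pref <- ifelse(ok, a1 + m, -Inf)
  best <- which.max(score_pref)
  a <- pmin(pmax(c(a0[best], a1[best], a2[best]), 0), 1)
  # plant-food point probabilities (0,1,2,3 points) with b1 = b2 = m/2
  b <- pmin(pmax(c(b0[best], m[best] / 2, m[best] / 2, b3[best]), 0), 1)
  a <- a / sum(a)
  b <- b / sum(b)
  prof <- build(a, b)
  st <- c(attr(prof, "implied_mean"), attr(prof, "implied_sd"))
  if (abs(st[1] - target_mean) > 0.1 || abs(st[2] - target_sd) > 0.3) {
    stop(sprintf("calibration failed: implied mean/SD %.3f/%.3f vs target %.2f/%.2f",
                 st[1], st[2], target_mean, target_sd), call. = FALSE)
  }
  prof
}

# feasible SD envelope of the weighted score at a given mean (diagnostic)
.ffq_sd_envelope <- function(mu, n_a, n_b) {
  ea <- seq(0, 2, by = 0.01)
  eb <- (mu - n_a * ea) / n_b
  keep <- eb >= 0 & eb <= 3
  ea <- ea[keep]; eb <- eb[keep]
  if (!length(ea)) return(c(NA_real_, NA_real_))
  va_max <- ea * (2 - ea)              # bimodal 0/2
  vb_max <- eb * (3 - eb)              # bimodal 0/3, capped by structure
  vmax <- max(n_a * va_max + n_b * pmin(vb_max, 2.25))
  c(0, sqrt(vmax))
}

# base introduction propensities before deterministic shifting; rows are
# (introduced by 6m, introduced by 9m)
.BASE_TIMING <- rbind(
  potatoes = c(0.92, 0.99), rice = c(0.55, 0.90), pasta = c(0.60, 0.92),
  vegetables = c(0.93, 0.99), meat = c(0.75, 0.96), fish = c(0.50, 0.86),
  soy = c(0.30, 0.55), pulses = c(0.50, 0.86), fruit_berries = c(0.93, 0.99),
  egg = c(0.45, 0.80), dairy = c(0.55, 0.90), porridge = c(0.95, 0.995),
  bread = c(0.55, 0.92), nuts_peanuts = c(0.25, 0.62), wheat = c(0.50, 0.90))

# share of by-6m introductions that happened at 0-3 months (no score
# distinguishes the two, so this only shapes the raw categories)
.EARLY_SHARE <- c(potatoes = 0.12, rice = 0.05, pasta = 0.05,
                  vegetables = 0.15, meat = 0.05, fish = 0.04, soy = 0.03,
                  pulses = 0.04, fruit_berries = 0.15, egg = 0.04,
                  dairy = 0.06, porridge = 0.15, bread = 0.05,
                  nuts_peanuts = 0.02, wheat = 0.05)

#' Calibrate introduction-timing probabilities to published score means
#'
#' Shifts base per-food introduction propensities on the logit scale, one
#' scalar shift per food group (allergenic / other) and age, so the implied
#' introduction-score means match the published values exactly: the implied
#' mean of each count score is the sum of the per-food introduction
#' probabilities, a closed form. The split of by-6-month introductions into
#' 0-3 vs 4-6 months uses fixed food-specific shares (no score depends on
#' it).
#'
#' @param targets Named numeric vector of score-mean targets:
#'   `introduced6`, `introduced9`, `allergenic6`, `allergenic9`.
#' @return Named list food -> probability vector over the four timing
#'   categories (not introduced, 0-3m, 4-6m, 7m+), with attribute
#'   `implied_means`.
#' @export
calibrate_timing_profile <- function(targets = c(introduced6 = 8.99,
                                                 introduced9 = 11.53,
                                                 allergenic6 = 2.94,
                                                 allergenic9 = 4.13)) {
  base <- .BASE_TIMING
  foods <- rownames(base)
  allerg <- intersect(foods, ALLERGEN_FOODS)
  nonallerg <- setdiff(intersect(foods, INTRO_SCORE_FOODS), ALLERGEN_FOODS)
  shift <- function(p, d) stats::plogis(stats::qlogis(p) + d)
  solve_shift <- function(p_base, target) {
    stats::uniroot(function(d) sum(shift(p_base, d)) - target,
                   c(-12, 12), tol = 1e-12)$root
  }
  pi6 <- base[, 1]
  d_a6 <- solve_shift(pi6[allerg], targets[["allergenic6"]])
  pi6[allerg] <- shift(pi6[allerg], d_a6)
  target_n6 <- targets[["introduced6"]] -
    sum(pi6[intersect(allerg, INTRO_SCORE_FOODS)])
  d_n6 <- solve_shift(pi6[nonallerg], target_n6)
  pi6[nonallerg] <- shift(pi6[nonallerg], d_n6)

  # conditional probability of introduction between 6 and 9 months among
  # the not-yet-introduced, shifted the same way to hit the 9-month targets
  cond <- pmin(pmax((base[, 2] - base[, 1]) / (1 - base[, 1]), 1e-6), 1 - 1e-6)
  pi9_of <- function(d, f) pi6[f] + (1 - pi6[f]) * shift(cond[f], d)
  d_a9 <- stats::uniroot(function(d) sum(pi9_of(d, allerg)) -
                           targets[["allergenic9"]], c(-12, 12),
                         tol = 1e-12)$root
  pi9 <- pi6
  pi9[allerg] <- pi9_of(d_a9, allerg)
  target_n9 <- targets[["introduced9"]] -
    sum(pi9[intersect(allerg, INTRO_SCORE_FOODS)])
  d_n9 <- stats::uniroot(function(d) sum(pi9_of(d, nonallerg)) - target_n9,
                         c(-12, 12), tol = 1e-12)$root
  pi9[nonallerg] <- pi9_of(d_n9, nonallerg)

  prof <- lapply(foods, function(f) {
    p2 <- .EARLY_SHARE[[f]] * pi6[[f]]
    c(not_by_9m = 1 - pi9[[f]], intro_0_3m = p2,
      intro_4_6m = pi6[[f]] - p2, intro_7m_plus = pi9[[f]] - pi6[[f]])
  })
  names(prof) <- foods
  implied <- c(
    introduced6 = sum(pi6[INTRO_SCORE_FOODS]),
    introduced9 = sum(pi9[INTRO_SCORE_FOODS]),
    allergenic6 = sum(pi6[ALLERGEN_FOODS]),
    allergenic9 = sum(pi9[ALLERGEN_FOODS]))
  attr(prof, "implied_means") <- implied
  prof
}

# implied SD of an introduction count score under the latent-factor copula:
# food f is introduced by the given age iff u_f < qnorm(pi_f), where
# u_f = -rho z + sqrt(1-rho^2) eps_f. Pairwise joint probabilities via a
# one-dimensional quantile-grid integral over z.
.intro_score_sd <- function(timing_profile, foods, age, rho, K = 129L) {
  p <- vapply(timing_profile[foods], function(pr) {
    if (age == 6L) pr[["intro_0_3m"]] + pr[["intro_4_6m"]]
    else 1 - pr[["not_by_9m"]]
  }, numeric(1L))
  v_ind <- sum(p * (1 - p))
  if (rho <= 0) return(sqrt(v_ind))
  s <- sqrt(1 - rho^2)
  z <- stats::qnorm((seq_len(K) - 0.5) / K)
  t <- stats::qnorm(pmin(pmax(p, 1e-12), 1 - 1e-12))
  H <- vapply(seq_along(z), function(k) stats::pnorm((t + rho * z[k]) / s),
              numeric(length(p)))
  M <- (H %*% t(H)) / K
  cov_sum <- sum(M - outer(p, p)) - sum(diag(M) - p^2)
  sqrt(v_ind + cov_sum)
}

#' Calibrate the latent diet-propensity loading
#'
#' Independent per-food timing draws cannot reach the published SDs of the
#' introduction scores (a sum of 14 Bernoulli items with mean 8.99 has SD at
#' most 1.87, versus a published 2.81), so timing items share one latent
#' normal factor through a Gaussian copula, leaving every per-food marginal
#' -- and hence every score mean -- unchanged. The loading is chosen
#' deterministically by least squares against the four published score SDs.
#'
#' @param timing_profile Output of [calibrate_timing_profile()].
#' @param sd_targets Named numeric vector of SD targets for
#'   `introduced6`, `introduced9`, `allergenic6`, `allergenic9`.
#' @return The loading `rho` in `[0, 0.95]`, with attribute `implied_sds`.
#' @export
calibrate_latent_rho <- function(timing_profile,
                                 sd_targets = c(introduced6 = 2.81,
                                                introduced9 = 1.51,
                                                allergenic6 = 1.44,
                                                allergenic9 = 1.06)) {
  blocks <- list(
    introduced6 = list(INTRO_SCORE_FOODS, 6L),
    introduced9 = list(INTRO_SCORE_FOODS, 9L),
    allergenic6 = list(ALLERGEN_FOODS, 6L),
    allergenic9 = list(ALLERGEN_FOODS, 9L))
  obj <- function(rho) {
    sum(vapply(names(blocks), function(b) {
      (.intro_score_sd(timing_profile, blocks[[b]][[1]], blocks[[b]][[2]],
                       rho) - sd_targets[[b]])^2
    }, numeric(1L)))
  }
  rho <- stats::optimize(obj, c(0, 0.95), tol = 1e-6)$minimum
  implied <- vapply(names(blocks), function(b) {
    .intro_score_sd(timing_profile, blocks[[b]][[1]], blocks[[b]][[2]], rho)
  }, numeric(1L))
  attr(rho, "implied_sds") <- implied
  rho
}

.DEFAULT_COVARIATES <- list(
  girl = 0.497,
  ethnicity_other = 158 / 2017,
  university = 1420 / 2017,
  feeding = c(exclusive_bf = 1339, partial_bf = 324,
              exclusive_formula = 342) / 2005,
  any_bf_9m = 809 / 1995,
  early_solid = 264 / 2056,
  family_history = 564 / 2034,
  outdoor = c(city = 1261, smaller_community = 392, rural = 407) / 2060,
  maternal_age_mean = 31.3, maternal_age_sd = 4.3,
  eczema = 596 / 1992)

# The pregnancy-questionnaire covariates go missing together: that is the
# only structure consistent with the published complete-case flow
# 2060 -> 1960 (model 1) -> 1957 (model 2) alongside the per-field
# missingness counts.
.DEFAULT_MISSINGNESS <- list(
  preg_block = 43 / 2060,        # ethnicity + university jointly
  family_in_block = 23 / 43,     # family history inside the block
  family_extra = 3 / 2017,       # family history elsewhere
  feeding = 55 / 2060,
  any_bf_9m = 65 / 2060,
  early_solid = 4 / 2060,
  eczema = 68 / 2060,
  intro_block = 4 / 2060,        # all timing items jointly
  fa_dx_9m = 1 / 2060,
  ffq = 0)

.zero_missingness <- function() {
  m <- .DEFAULT_MISSINGNESS
  m[] <- 0
  m
}

#' Generator parameters
#'
#' Bundles every knob of the synthetic cohort: size, seed, covariate
#' distributions (defaults follow the published cohort characteristics),
#' frequency and timing profiles calibrated to the published score means and
#' SDs, per-field missingness rates calibrated to the published missingness
#' and complete-case flow, and the planted logistic outcome model. The
#' outcome defaults put a per-point log-odds slope of `log(0.96)` on the
#' weighted score and the published predictor odds ratios on family FA
#' history (2.51) and feeding mode (1.77 partial, 1.89 formula), with the
#' intercept calibrated by closed-form expectation to a marginal 18-month FA
#' prevalence of 4.9%.
#'
#' @param n Cohort size (default 2060).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @param dd_slope Per-point log-odds slope of the weighted score.
#' @param target_prevalence Marginal 18-month FA prevalence the intercept is
#'   calibrated to (ignored when `intercept` is given).
#' @param intercept Optional fixed intercept on the log-odds scale.
#' @param or_family_history,or_partial_bf,or_exclusive_formula Planted
#'   predictor odds ratios.
#' @param early_fraction Fraction of 18-month FA cases already diagnosed at
#'   9 months (73/100 published).
#' @param gi_only_fraction Fraction of 18-month FA cases reporting only
#'   gastrointestinal symptoms (33/100 published).
#' @param ffq_targets,intro_targets,intro_sd_targets Calibration targets for
#'   the score distributions.
#' @param ffq_profile,timing_profile Optional pre-built profiles overriding
#'   calibration.
#' @param latent_rho Latent diet-propensity loading for timing items
#'   (default: calibrated, see [calibrate_latent_rho()]).
#' @param ffq_rho Latent loading for the frequency items (default 0, which
#'   keeps the weighted-score SD at its calibrated value; positive values
#'   correlate the weighted and introduction scores).
#' @param covariate_dist,missingness Partial override lists merged into the
#'   defaults; `missingness = 0` switches all masking off.
#' @param modifier_field,modifier_slopes Optional effect modification: a
#'   logical cohort field and a named vector `c(true = , false = )` of
#'   stratum-specific weighted-score slopes replacing `dd_slope`.
#' @param or_modifier Main-effect odds ratio of the modifier field on the
#'   outcome (default 1; effect-modification scenarios typically raise it,
#'   eczema being a strong predictor of food allergy).
#' @return Object of class `dd_genparams`.
#' @export
generator_params <- function(n = 2060, seed = 1L,
                             dd_slope = log(0.96),
                             target_prevalence = 0.049,
                             intercept = NULL,
                             or_family_history = 2.51,
                             or_partial_bf = 1.77,
                             or_exclusive_formula = 1.89,
                             early_fraction = 73 / 100,
                             gi_only_fraction = 33 / 100,
                             ffq_targets = c(mean = 19.77, sd = 3.91),
                             intro_targets = c(introduced6 = 8.99,
                                               introduced9 = 11.53,
                                               allergenic6 = 2.94,
                                               allergenic9 = 4.13),
                             intro_sd_targets = c(introduced6 = 2.81,
                                                  introduced9 = 1.51,
                                                  allergenic6 = 1.44,
                                                  allergenic9 = 1.06),
                             ffq_profile = NULL, timing_profile = NULL,
                             latent_rho = NULL, ffq_rho = 0,
                             covariate_dist = NULL, missingness = NULL,
                             modifier_field = NULL, modifier_slopes = NULL,
                             or_modifier = 1) {
  stopifnot(n > 0, early_fraction >= 0, early_fraction <= 1,
            gi_only_fraction >= 0, gi_only_fraction <= 1,
            ffq_rho >= 0, ffq_rho < 1)
  if (is.null(ffq_profile)) {
    key <- paste0("ffq:", ffq_targets[["mean"]], ":", ffq_targets[["sd"]])
    ffq_profile <- .cached(key, calibrate_ffq_profile(ffq_targets[["mean"]],
                                                      ffq_targets[["sd"]]))
  }
  if (is.null(timing_profile)) {
    key <- paste0("timing:", paste(intro_targets, collapse = ","))
    timing_profile <- .cached(key, calibrate_timing_profile(intro_targets))
  }
  if (is.null(latent_rho)) {
    key <- paste0("rho:", paste(intro_targets, collapse = ","), "|",
                  paste(intro_sd_targets, collapse = ","))
    latent_rho <- .cached(key, calibrate_latent_rho(timing_profile,
                                                    intro_sd_targets))
  }
  cov <- utils::modifyList(.DEFAULT_COVARIATES, covariate_dist %||% list())
  miss <- if (identical(missingness, 0) || identical(missingness, "none")) {
    .zero_missingness()
  } else {
    utils::modifyList(.DEFAULT_MISSINGNESS, missingness %||% list())
  }
  for (fld in c("feeding", "outdoor")) {
    if (abs(sum(cov[[fld]]) - 1) > 1e-6) {
      stop("covariate probabilities for '", fld, "' must sum to 1",
           call. = FALSE)
    }
  }
  if (!is.null(modifier_field) &&
      (is.null(modifier_slopes) ||
       !all(c("true", "false") %in% names(modifier_slopes)))) {
    stop("modifier_slopes must be a named vector c(true = , false = )",
         call. = FALSE)
  }
  params <- structure(list(
    n = as.integer(n), seed = as.integer(seed),
    dd_slope = dd_slope, target_prevalence = target_prevalence,
    intercept = intercept,
    or_family_history = or_family_history, or_partial_bf = or_partial_bf,
    or_exclusive_formula = or_exclusive_formula,
    early_fraction = early_fraction, gi_only_fraction = gi_only_fraction,
    ffq_profile = ffq_profile, timing_profile = timing_profile,
    latent_rho = as.numeric(latent_rho), ffq_rho = ffq_rho,
    covariate_dist = cov, missingness = miss,
    modifier_field = modifier_field, modifier_slopes = modifier_slopes,
    or_modifier = or_modifier,
    # the score enters the generative linear predictor centred at its
    # implied mean, so the intercept anchors prevalence at the typical diet
    # and slopes do not shift the marginal level
    dd_center = as.numeric(attr(ffq_profile, "implied_mean") %||% 0)),
    class = "dd_genparams")
  if (is.null(params$intercept)) {
    params$intercept <- .calibrate_intercept(params)
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dd_genparams <- function(x, ...) {
  cat("Synthetic cohort generator parameters\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  weighted score: implied mean %.2f, SD %.2f (latent rho %.3f, ffq rho %.2f)\n",
              attr(x$ffq_profile, "implied_mean"),
              attr(x$ffq_profile, "implied_sd"), x$latent_rho, x$ffq_rho))
  cat(sprintf("  outcome: intercept %.3f, DD slope %.4f, target prevalence %.1f%%\n",
              x$intercept, x$dd_slope, 100 * x$target_prevalence))
  invisible(x)
}

# pmf of the weighted score under the profile; mixture over the latent
# factor when the frequency items load on it
.dd_pmf_for_params <- function(params, K = 41L) {
  if (params$ffq_rho <= 0) {
    return(weighted_score_pmf(params$ffq_profile))
  }
  rho <- params$ffq_rho
  s <- sqrt(1 - rho^2)
  zg <- stats::qnorm((seq_len(K) - 0.5) / K)
  pmf <- 0
  for (z in zg) {
    prof_z <- lapply(params$ffq_profile, function(pr) {
      cum <- stats::qnorm(pmin(pmax(cumsum(pr), 1e-12), 1 - 1e-12))
      cz <- stats::pnorm((cum - rho * z) / s)
      diff(c(0, cz[1:5], 1))
    })
    names(prof_z) <- names(params$ffq_profile)
    pmf <- pmf + weighted_score_pmf(prof_z) / K
  }
  pmf
}

# marginal outcome prevalence has a closed form: expectation of the inverse
# logit over the joint distribution of score, family history, feeding mode
# (and the optional modifier field), which are independent by construction
.expected_prevalence <- function(b0, params, pmf) {
  cov <- params$covariate_dist
  dd <- seq_along(pmf) - 1
  feed_lor <- c(0, log(params$or_partial_bf), log(params$or_exclusive_formula))
  feed_p <- as.numeric(cov$feeding)
  fam_p <- cov$family_history
  mods <- if (is.null(params$modifier_field)) {
    list(list(p = 1, slope = params$dd_slope, main = 0))
  } else {
    mp <- if (identical(params$modifier_field, "eczema_by_18m"))
      cov$eczema else cov$family_history
    list(list(p = mp, slope = params$modifier_slopes[["true"]],
              main = log(params$or_modifier)),
         list(p = 1 - mp, slope = params$modifier_slopes[["false"]],
              main = 0))
  }
  total <- 0
  for (mod in mods) {
    for (fam in 0:1) {
      for (fd in 1:3) {
        eta <- b0 + mod$main + mod$slope * (dd - params$dd_center) +
          log(params$or_family_history) * fam + feed_lor[fd]
        w <- mod$p * (if (fam == 1) fam_p else 1 - fam_p) * feed_p[fd]
        total <- total + w * sum(pmf * stats::plogis(eta))
      }
    }
  }
  total
}

.calibrate_intercept <- function(params) {
  pmf <- .dd_pmf_for_params(params)
  stats::uniroot(function(b0) {
    .expected_prevalence(b0, params, pmf) - params$target_prevalence
  }, c(-20, 5), tol = 1e-10)$root
}

# draw categorical codes through the Gaussian copula: thresholds on the
# cumulative marginal, latent score rho * z + noise
.copula_codes <- function(z, probs, rho, code_order) {
  n <- length(z)
  cum <- cumsum(probs)[-length(probs)]
  thr <- stats::qnorm(pmin(pmax(cum, 0), 1))
  u <- if (rho > 0) rho * z + sqrt(1 - rho^2) * stats::rnorm(n) else
    stats::rnorm(n)
  code_order[findInterval(u, thr) + 1L]
}

#' Generate a synthetic cohort
#'
#' Draws a fully populated cohort from the calibrated generative model:
#' covariates from the published marginals, timing items through the latent
#' diet-propensity copula, frequency items independently (by default), the
#' 18-month FA outcome from the planted logistic model applied to each
#' infant's own generated weighted score -- the exposure-outcome path runs
#' through the real scoring code --, the 9-month diagnosis as a sub-event of
#' the 18-month outcome, gastrointestinal-only flags among cases, and
#' missingness applied last as pure masking (regenerating with all rates
#' zero and the same seed reproduces the complete data).
#'
#' @param params A `dd_genparams` object.
#' @param seed Seed overriding `params$seed`.
#' @return List with `cohort` (a `dd_cohort`) and `report` (realized
#'   marginals, score means/SDs, outcome prevalence, seed).
#' @export
generate_cohort <- function(params, seed = NULL) {
  stopifnot(inherits(params, "dd_genparams"))
  seed <- seed %||% params$seed
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  n <- params$n
  cov <- params$covariate_dist

  sex <- ifelse(stats::runif(n) < cov$girl, "girl", "boy")
  ethnicity <- ifelse(stats::runif(n) < cov$ethnicity_other, "other", "sweden")
  university <- stats::runif(n) < cov$university
  feeding <- names(cov$feeding)[
    findInterval(stats::runif(n), cumsum(cov$feeding)[-3]) + 1L]
  any_bf <- stats::runif(n) < cov$any_bf_9m
  early_solid <- stats::runif(n) < cov$early_solid
  family <- stats::runif(n) < cov$family_history
  outdoor <- names(cov$outdoor)[
    findInterval(stats::runif(n), cumsum(cov$outdoor)[-3]) + 1L]
  age <- stats::rnorm(n, cov$maternal_age_mean, cov$maternal_age_sd)
  age <- pmax(age, 16)  # maternal age is positive by design
  eczema <- stats::runif(n) < cov$eczema

  z <- stats::rnorm(n)  # latent diet propensity

  intro <- matrix(NA_integer_, n, length(INTRO_FOODS),
                  dimnames = list(NULL, paste0("intro_", INTRO_FOODS)))
  # categories ordered earliest-first on the latent scale so that high
  # propensity means earlier introduction; codes map back to the disk scale
  for (f in INTRO_FOODS) {
    pr <- params$timing_profile[[f]]
    intro[, paste0("intro_", f)] <- .copula_codes(
      -z, pr[c("intro_0_3m", "intro_4_6m", "intro_7m_plus", "not_by_9m")],
      params$latent_rho, c(2L, 3L, 4L, 1L))
  }

  ffq <- matrix(NA_integer_, n, length(FFQ_FOODS),
                dimnames = list(NULL, paste0("ffq_", FFQ_FOODS)))
  for (f in FFQ_FOODS) {
    ffq[, paste0("ffq_", f)] <- .copula_codes(
      z, params$ffq_profile[[f]], params$ffq_rho, 1:6)
  }

  dd <- weighted_dd_score(as.data.frame(ffq))

  mod_main <- 0
  slope <- if (is.null(params$modifier_field)) {
    rep(params$dd_slope, n)
  } else {
    mod <- switch(params$modifier_field,
                  eczema_by_18m = eczema,
                  family_fa_history = family,
                  stop("unsupported modifier field: ", params$modifier_field,
                       call. = FALSE))
    mod_main <- log(params$or_modifier) * mod
    ifelse(mod, params$modifier_slopes[["true"]],
           params$modifier_slopes[["false"]])
  }
  eta <- params$intercept + mod_main + slope * (dd - params$dd_center) +
    log(params$or_family_history) * family +
    log(params$or_partial_bf) * (feeding == "partial_bf") +
    log(params$or_exclusive_formula) * (feeding == "exclusive_formula")
  fa18 <- stats::runif(n) < stats::plogis(eta)
  fa9 <- fa18 & stats::runif(n) < params$early_fraction
  gi_only <- fa18 & stats::runif(n) < params$gi_only_fraction

  d <- data.frame(
    id = sprintf("S%06d", seq_len(n)),
    sex = sex, maternal_ethnicity = ethnicity,
    maternal_university = university, breastfeeding_4m = feeding,
    any_bf_9m = any_bf, early_solid_intro = early_solid,
    family_fa_history = family, outdoor_env = outdoor, maternal_age = age,
    fa_dx_9m = fa9, fa_dx_18m = fa18, eczema_by_18m = eczema,
    gi_only_symptoms = gi_only, stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(ffq), as.data.frame(intro))

  # missingness: drawn after all data so it is pure masking
  miss <- params$missingness
  mask <- function(p) stats::runif(n) < p
  preg <- mask(miss$preg_block)
  d$maternal_ethnicity[preg] <- NA
  d$maternal_university[preg] <- NA
  fam_na <- (preg & mask(miss$family_in_block)) |
    (!preg & mask(miss$family_extra))
  d$family_fa_history[fam_na] <- NA
  d$breastfeeding_4m[mask(miss$feeding)] <- NA
  d$any_bf_9m[mask(miss$any_bf_9m)] <- NA
  d$early_solid_intro[mask(miss$early_solid)] <- NA
  d$eczema_by_18m[mask(miss$eczema)] <- NA
  intro_na <- mask(miss$intro_block)
  d[intro_na, paste0("intro_", INTRO_FOODS)] <- NA
  d$fa_dx_9m[mask(miss$fa_dx_9m)] <- NA
  if (miss$ffq > 0) {
    ffq_na <- mask(miss$ffq)
    d[ffq_na, paste0("ffq_", FFQ_FOODS)] <- NA
  }

  cohort <- new_cohort(d, provenance = sprintf("synthetic(seed=%d,n=%d)",
                                               seed, n))
  report <- structure(list(
    seed = seed, n = n,
    prevalence_fa18 = mean(fa18), prevalence_fa9 = mean(fa9),
    weighted_dd = c(mean = mean(dd), sd = stats::sd(dd)),
    introduced6 = .score_report(cohort, "introduced", 6L),
    introduced9 = .score_report(cohort, "introduced", 9L),
    allergenic6 = .score_report(cohort, "allergenic", 6L),
    allergenic9 = .score_report(cohort, "allergenic", 9L),
    covariates = c(girl = mean(sex == "girl"),
                   family_history = mean(family),
                   eczema = mean(eczema),
                   early_solid = mean(early_solid)),
    gi_only = mean(gi_only)), class = "dd_genreport")
  list(cohort = cohort, report = report)
}

.score_report <- function(cohort, measure, age) {
  s <- dd_score(cohort, measure, age)
  c(mean = mean(s, na.rm = TRUE), sd = stats::sd(s, na.rm = TRUE))
}

#' @export
print.dd_genreport <- function(x, ...) {
  cat(sprintf("Generation report (seed %d, n = %d)\n", x$seed, x$n))
  cat(sprintf("  FA prevalence: %.2f%% at 18m, %.2f%% at 9m\n",
              100 * x$prevalence_fa18, 100 * x$prevalence_fa9))
  cat(sprintf("  weighted DD: mean %.2f (sd %.2f)\n",
              x$weighted_dd[["mean"]], x$weighted_dd[["sd"]]))
  cat(sprintf("  introduced foods 6m/9m: %.2f / %.2f;  allergenic 6m/9m: %.2f / %.2f\n",
              x$introduced6[["mean"]], x$introduced9[["mean"]],
              x$allergenic6[["mean"]], x$allergenic9[["mean"]]))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Validation harness for the adjusted models: repeatedly generates a cohort
#' under known truth, scores it, fits the fully adjusted continuous
#' weighted-score model, and summarises bias, empirical spread and Wald
#' 95% CI coverage of the planted per-point log-odds slope. Non-estimable
#' replicates (non-convergence, constant exposure) are counted and excluded.
#'
#' @param truth A `dd_genparams` with the planted slope.
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param adjust Adjustment set to fit (default `"model2"`).
#' @return Object of class `dd_recovery`: per-replicate estimates and a
#'   summary (bias, mean estimate, empirical SE, mean model SE, coverage,
#'   non-estimable count).
#' @export
parameter_recovery_experiment <- function(truth, n_reps, seed = 1L,
                                          adjust = "model2") {
  stopifnot(inherits(truth, "dd_genparams"), n_reps >= 1)
  true_beta <- truth$dd_slope
  est <- se <- rep(NA_real_, n_reps)
  ok <- rep(FALSE, n_reps)
  for (r in seq_len(n_reps)) {
    coh <- generate_cohort(truth, seed = seed + r)$cohort
    fit <- dd_assoc(coh, "weighted", 9, "continuous", adjust)
    if (fit$converged && !any(fit$table$flagged)) {
      est[r] <- unname(fit$coefficients[".exposure"])
      se[r] <- unname(fit$se[".exposure"])
      ok[r] <- TRUE
    }
  }
  z <- stats::qnorm(0.975)
  cover <- (est - z * se <= true_beta) & (true_beta <= est + z * se)
  structure(list(
    true_slope = true_beta,
    estimates = data.frame(rep = seq_len(n_reps), estimate = est, se = se,
                           estimable = ok, covered = cover),
    n_estimable = sum(ok),
    n_nonestimable = sum(!ok),
    mean_estimate = mean(est[ok]),
    bias = mean(est[ok]) - true_beta,
    empirical_se = stats::sd(est[ok]),
    mean_model_se = mean(se[ok]),
    coverage = mean(cover[ok])), class = "dd_recovery")
}

#' @export
print.dd_recovery <- function(x, ...) {
  cat("Parameter recovery for the weighted-score slope\n")
  cat(sprintf("  truth %.4f | mean estimate %.4f (bias %+.4f)\n",
              x$true_slope, x$mean_estimate, x$bias))
  cat(sprintf("  empirical SE %.4f | mean model SE %.4f | 95%% CI coverage %.1f%%\n",
              x$empirical_se, x$mean_model_se, 100 * x$coverage))
  cat(sprintf("  replicates: %d estimable, %d non-estimable\n",
              x$n_estimable, x$n_nonestimable))
  invisible(x)
}
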