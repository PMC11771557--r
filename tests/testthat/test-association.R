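# 2x2 odds ratios, the logistic fitting function, and the table drivers.

test_that("Woolf odds ratios reproduce published category estimates", {
  # highest weighted-score group vs reference
  o <- odds_ratio_2x2(9, 321, 28, 466)
  expect_identical(round(o$or, 2), 0.47)
  expect_identical(round(o$ci_low, 2), 0.22)
  expect_identical(round(o$ci_high, 2), 1.00)
  expect_identical(round(o$p, 3), 0.051)
  # 13-14 introduced foods vs 0-10
  o <- odds_ratio_2x2(23, 559, 32, 433)
  expect_identical(round(c(o$or, o$ci_low, o$ci_high), 2), c(0.56, 0.32, 0.97))
  expect_identical(round(o$p, 3), 0.037)
  # equal odds give OR exactly 1
  expect_equal(odds_ratio_2x2(5, 95, 10, 190)$or, 1, tolerance = 1e-15)
  # matrix interface agrees with the cell interface
  expect_equal(odds_ratio_2x2(rbind(c(9, 321), c(28, 466)))$or,
               odds_ratio_2x2(9, 321, 28, 466)$or)
  # zero cells are flagged, not continuity-corrected
  z <- odds_ratio_2x2(0, 100, 10, 90)
  expect_true(z$zero_cell)
  expect_true(is.na(z$or) && is.na(z$p))
})

test_that("unadjusted categorical logistic ORs equal the closed-form 2x2 ORs", {
  coh <- generate_cohort(test_params(), seed = 31)$cohort
  for (blk in list(c("weighted", 9), c("introduced", 9), c("allergenic", 6))) {
    fit <- dd_assoc(coh, blk[1], as.integer(blk[2]), "categorical",
                    "unadjusted")
    tab <- fit$table
    for (k in which(!tab$reference & !tab$flagged)) {
      o <- odds_ratio_2x2(tab$cases[k], tab$n[k] - tab$cases[k],
                          tab$cases[1], tab$n[1] - tab$cases[1])
      expect_equal(tab$or[k], o$or, tolerance = 1e-6)
      expect_equal(tab$ci_low[k], o$ci_low, tolerance = 1e-4)
      expect_equal(tab$p[k], o$p, tolerance = 1e-4)
    }
  }
})

test_that("the continuous model recovers a planted slope at large n", {
  p <- generator_params(n = 50000, seed = 1, dd_slope = -0.05)
  coh <- generate_cohort(p, seed = 32)$cohort
  fit <- dd_assoc(coh, "weighted", 9, "continuous", "model2")
  expect_true(fit$converged)
  expect_lt(abs(unname(fit$coefficients[".exposure"]) + 0.05), 0.03)
})

test_that("the exposure OR is collapsible over outcome-independent covariates", {
  # covariates carry no outcome effect here, so adjusting for them must
  # leave the per-point OR essentially unchanged at low prevalence
  p <- generator_params(n = 200000, seed = 1, dd_slope = -0.05,
                        or_family_history = 1, or_partial_bf = 1,
                        or_exclusive_formula = 1)
  coh <- generate_cohort(p, seed = 33)$cohort
  un <- dd_assoc(coh, "weighted", 9, "continuous", "unadjusted")
  ad <- dd_assoc(coh, "weighted", 9, "continuous", "model2")
  expect_lt(abs(ad$table$or / un$table$or - 1), 0.02)
})

test_that("run_table3 produces the full 5-block x 2-form x 3-model layout", {
  coh <- generate_cohort(test_params(), seed = 34)$cohort
  tab <- run_table3(coh)
  expect_length(tab, 30L)
  expect_setequal(
    unique(sub("\\..*", "", names(tab))),
    c("weighted9", "introduced6", "introduced9", "allergenic6", "allergenic9"))
  # per-block complete-case n: intro blocks lose the intro-missing records
  expect_lte(tab$introduced9.continuous.unadjusted$n_used,
             tab$weighted9.continuous.unadjusted$n_used)
  # within a block, model 2 cannot use more records than model 1
  expect_lte(tab$weighted9.continuous.model2$n_used,
             tab$weighted9.continuous.model1$n_used)
  # the unadjusted categorical columns are the 2x2 estimates on the same data
  t3 <- tab$allergenic9.categorical.unadjusted$table
  o <- odds_ratio_2x2(t3$cases[4], t3$n[4] - t3$cases[4],
                      t3$cases[1], t3$n[1] - t3$cases[1])
  expect_equal(t3$or[4], o$or, tolerance = 1e-6)
  # flat export carries one row per fitted level
  df <- as.data.frame(tab)
  expect_identical(nrow(df), sum(vapply(tab, function(f) nrow(f$table), 1L)))
})

test_that("sensitivity variants re-run the table on the filtered cohort", {
  coh <- generate_cohort(test_params(), seed = 35)$cohort
  sens <- run_sensitivity(coh, "exclude_early_fa")
  expect_length(sens, 30L)
  n_early <- sum(coh$data$fa_dx_9m, na.rm = TRUE) +
    sum(is.na(coh$data$fa_dx_9m))
  expect_identical(attr(sens, "n_excluded"), n_early)
  # n never grows after exclusion, and drops by at least the excluded cases
  expect_lte(sens$weighted9.continuous.unadjusted$n_used,
             n_records(coh) - sum(coh$data$fa_dx_9m, na.rm = TRUE))
  # oracle equality holds on the filtered subset too
  t3 <- sens$weighted9.categorical.unadjusted$table
  o <- odds_ratio_2x2(t3$cases[2], t3$n[2] - t3$cases[2],
                      t3$cases[1], t3$n[1] - t3$cases[1])
  expect_equal(t3$or[2], o$or, tolerance = 1e-6)

  gi <- run_sensitivity(coh, "exclude_gi_only")
  expect_identical(attr(gi, "n_excluded"),
                   sum(coh$data$gi_only_symptoms, na.rm = TRUE))
})

test_that("stratified fits partition the cohort and flag empty-case strata", {
  coh <- generate_cohort(test_params(), seed = 36)$cohort
  strat <- run_stratified(coh, "family_fa_history")
  expect_setequal(names(strat), c("TRUE", "FALSE"))
  pooled <- sum(vapply(strat, function(s)
    s$weighted9.continuous.model2$n_used, 1L))
  # the two strata use disjoint subsets of the complete cases
  full <- dd_assoc(coh, "weighted", 9, "continuous", "model2")
  expect_identical(pooled, full$n_used)
  expect_identical(attr(strat, "n_missing_stratifier"),
                   sum(is.na(coh$data$family_fa_history)))

  # a stratum without cases is flagged, not estimated
  d <- coh$data
  d$gi_only_symptoms[d$eczema_by_18m %in% TRUE] <- FALSE
  d$fa_dx_18m[d$eczema_by_18m %in% TRUE] <- FALSE
  d$fa_dx_9m[d$eczema_by_18m %in% TRUE] <- FALSE
  degen <- new_cohort(d, "no cases among eczema")
  s2 <- run_stratified(degen, "eczema_by_18m")
  fit <- s2$`TRUE`$weighted9.continuous.model2
  expect_true(any(fit$table$flagged))
  expect_false(fit$converged)
})

test_that("a protective effect planted only in the eczema stratum is recovered there", {
  # eczema is itself a strong FA predictor (or_modifier), which is what
  # gives the stratum enough cases to see its planted slope
  p <- generator_params(n = 2060, seed = 1,
                        modifier_field = "eczema_by_18m",
                        modifier_slopes = c(true = -0.12, false = 0),
                        or_modifier = 3)
  n_reps <- 200
  ecz_neg <- other_covers <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    coh <- generate_cohort(p, seed = 40000 + r)$cohort
    strata <- stratify(coh, "eczema_by_18m")
    f_e <- dd_assoc(strata$`TRUE`, "weighted", 9, "continuous", "model2")
    f_o <- dd_assoc(strata$`FALSE`, "weighted", 9, "continuous", "model2")
    ecz_neg[r] <- f_e$converged && f_e$table$or < 1
    other_covers[r] <- f_o$converged &&
      f_o$table$ci_low <= 1 && 1 <= f_o$table$ci_high
  }
  expect_gte(mean(ecz_neg), 0.90)
  expect_gte(mean(other_covers), 0.90)
})
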