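# Cohort I/O, exclusion filters, stratification and group comparison.

test_that("cohort CSV round-trips with bit-exact category codes", {
  gen <- generate_cohort(test_params(), seed = 21)
  coh <- gen$cohort
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  code_cols <- c(paste0("ffq_", FFQ_FOODS), paste0("intro_", INTRO_FOODS))
  expect_identical(back$data[code_cols], coh$data[code_cols])
  expect_identical(back$data$id, coh$data$id)
  expect_identical(back$data$breastfeeding_4m, coh$data$breastfeeding_4m)
  expect_identical(back$data$fa_dx_18m, coh$data$fa_dx_18m)
  expect_equal(back$data$maternal_age, coh$data$maternal_age, tolerance = 1e-12)
})

test_that("invalid cells degrade to missing; id problems are hard errors", {
  coh <- make_hand_cohort(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  txt <- readLines(path)
  header <- strsplit(txt[1], ",")[[1]]
  # frequency code outside 1-6 in row 2 -> record kept, item missing
  row <- strsplit(txt[2], ",")[[1]]
  row[which(header == "ffq_potatoes")] <- "7"
  writeLines(c(txt[1], paste(row, collapse = ","), txt[3:4]), path)
  expect_warning(back <- read_cohort(path), "unparseable")
  expect_identical(n_records(back), 3L)
  expect_true(is.na(back$data$ffq_potatoes[1]))
  expect_true(is.na(weighted_dd_score(back)[1]))
  # duplicated id names the offender
  write_cohort(coh, path)
  txt <- readLines(path)
  txt[3] <- sub("^A02", "A01", txt[3])
  writeLines(txt, path)
  expect_error(read_cohort(path), "A01")
  # a file without the id column is rejected outright
  txt <- readLines(path)
  drop <- which(header == "id")
  strip <- function(line) paste(strsplit(line, ",")[[1]][-drop], collapse = ",")
  writeLines(vapply(txt, strip, character(1)), path)
  expect_error(read_cohort(path), "'id' column")
})

test_that("complete-case filter matches direct enumeration and logs removals", {
  coh <- make_hand_cohort(4)
  fields <- c("maternal_age", "family_fa_history")
  same <- complete_case_filter(coh, fields)
  expect_identical(n_records(same), 4L)
  expect_identical(same$exclusion_log$n_removed, 0L)

  gen <- generate_cohort(test_params(), seed = 22)$cohort
  fields <- c(score_item_columns("weighted"), "fa_dx_18m",
              adjustment_set("model2"))
  filtered <- complete_case_filter(gen, fields)
  # brute-force oracle: count records carrying any missing required field
  n_bad <- sum(apply(is.na(gen$data[fields]), 1L, any))
  expect_identical(n_records(filtered), n_records(gen) - n_bad)
  expect_identical(utils::tail(filtered$exclusion_log$n_removed, 1), n_bad)
  expect_false(anyNA(filtered$data[fields]))

  expect_error(complete_case_filter(coh, "no_such_field"), "unknown field")
  empty <- make_hand_cohort(2, maternal_age = NA_real_)
  expect_warning(res <- complete_case_filter(empty, "maternal_age"),
                 "every record")
  expect_identical(n_records(res), 0L)
})

test_that("early-FA and GI-only exclusions count, log, and are idempotent", {
  coh <- make_hand_cohort(10)
  coh$data$fa_dx_9m[1:3] <- TRUE
  coh$data$fa_dx_18m[1:5] <- TRUE
  coh$data$gi_only_symptoms[4:5] <- TRUE
  coh <- new_cohort(coh$data, "fixture")

  e1 <- exclude_early_fa(coh)
  expect_identical(n_records(e1), 7L)
  expect_identical(e1$exclusion_log$rule[1], "early_fa")
  expect_identical(e1$exclusion_log$n_removed[1], 3L)
  expect_false(any(e1$data$fa_dx_9m))
  expect_identical(exclude_early_fa(e1)$data, e1$data)  # idempotent

  g1 <- exclude_gi_only(coh)
  expect_identical(n_records(g1), 8L)
  expect_identical(sum(g1$data$fa_dx_18m), 3L)  # FA cases reduced by 2
  expect_identical(exclude_gi_only(g1)$data, g1$data)

  # no-op on cohorts without affected records
  clean <- make_hand_cohort(4)
  expect_identical(n_records(exclude_early_fa(clean)), 4L)
  expect_identical(n_records(exclude_gi_only(clean)), 4L)
})

test_that("exclusion log reconciles the full pipeline flow", {
  gen <- generate_cohort(test_params(), seed = 23)$cohort
  n0 <- n_records(gen)
  out <- exclude_early_fa(gen)
  out <- exclude_gi_only(out)
  out <- complete_case_filter(out, c(score_item_columns("weighted"),
                                     "fa_dx_18m", adjustment_set("model2")))
  expect_identical(n_records(out), n0 - sum(out$exclusion_log$n_removed))
  # running n_after entries are internally consistent too
  expect_identical(utils::tail(out$exclusion_log$n_after, 1), n_records(out))
})

test_that("stratification partitions the cohort with an explicit missing stratum", {
  coh <- make_hand_cohort(11)
  coh$data$family_fa_history <- c(rep(TRUE, 6), rep(FALSE, 4), NA)
  coh <- new_cohort(coh$data, "fixture")
  strata <- stratify(coh, "family_fa_history")
  sizes <- vapply(strata, n_records, integer(1))
  expect_identical(sort(unname(sizes), decreasing = TRUE), c(6L, 4L, 1L))
  expect_identical(sum(sizes), n_records(coh))
  expect_setequal(names(strata), c("TRUE", "FALSE", "missing"))
  # single-valued stratifier gives a single stratum
  uni <- make_hand_cohort(5)
  expect_identical(names(stratify(uni, "family_fa_history")), "FALSE")
  expect_error(stratify(coh, "shoe_size"), "unknown")
  # partition property on a generated cohort
  gen <- generate_cohort(test_params(), seed = 24)$cohort
  sz <- vapply(stratify(gen, "eczema_by_18m"), n_records, integer(1))
  expect_identical(sum(sz), n_records(gen))
})

test_that("group comparison reproduces a hand-computed Pearson chi-square", {
  a <- make_hand_cohort(100, fa_dx_18m = c(rep(TRUE, 50), rep(FALSE, 50)))
  b <- make_hand_cohort(100, fa_dx_18m = c(rep(TRUE, 80), rep(FALSE, 20)))
  cmp <- compare_groups(a, b, "fa_dx_18m")
  # closed-form Pearson statistic for the 2x2 table 50/50 vs 80/20
  o <- matrix(c(50, 50, 80, 20), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  x2 <- sum((o - e)^2 / e)
  expect_equal(cmp$statistic, x2, tolerance = 1e-12)
  expect_equal(cmp$p, stats::pchisq(x2, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(cmp$diff, 0.5 - 0.8, tolerance = 1e-12)

  # a cohort compared with itself shows zero differences everywhere
  self <- compare_groups(a, a, c("fa_dx_18m", "maternal_age", "sex"))
  expect_true(all(self$diff[!is.na(self$diff)] == 0))
  # constant fields are reported as undefined, not errors
  const <- compare_groups(make_hand_cohort(5), make_hand_cohort(5),
                          c("sex", "maternal_age"))
  expect_true(all(const$note == "constant in both groups"))
  expect_true(all(is.na(const$statistic)))
})

test_that("a two-point difference in maternal age is detected almost surely", {
  pa <- generator_params(n = 500, seed = 1)
  pb <- generator_params(n = 500, seed = 1,
                         covariate_dist = list(maternal_age_mean = 33.3))
  hits <- vapply(seq_len(200), function(r) {
    a <- generate_cohort(pa, seed = 3000 + r)$cohort
    b <- generate_cohort(pb, seed = 7000 + r)$cohort
    compare_groups(a, b, "maternal_age")$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
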