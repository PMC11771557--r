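# Scoring engine: point maps, introduction predicates, categorisations.

test_that("weighted score reproduces the defining boundary profiles", {
  all_at <- function(code) stats::setNames(rep(code, 14L), FFQ_FOODS)
  expect_identical(weighted_dd_score(all_at(1L)), 0L)      # never eaten
  expect_identical(weighted_dd_score(all_at(2L)), 14L)     # all monthly
  expect_identical(weighted_dd_score(all_at(3L)), 28L)     # all weekly
  expect_identical(weighted_dd_score(all_at(4L)), 28L)     # 4-6/week = weekly
  # all daily: 11 staples drop back to 1 point, 3 plant foods reach 3
  expect_identical(weighted_dd_score(all_at(5L)), 20L)
  expect_identical(weighted_dd_score(all_at(6L)), 20L)
  # printed maximum: staples weekly, plant foods daily
  top <- all_at(3L)
  top[c("fruit_berries", "veg_meat_subst", "vegetables")] <- 5L
  expect_identical(weighted_dd_score(top), 31L)
})

test_that("31 points are attained only by weekly staples with daily plant foods", {
  plant <- c("fruit_berries", "veg_meat_subst", "vegetables")
  top <- stats::setNames(rep(3L, 14L), FFQ_FOODS)
  top[plant] <- 5L
  for (f in FFQ_FOODS) {
    for (code in 1:6) {
      rec <- top
      rec[f] <- code
      s <- weighted_dd_score(rec)
      at_max <- if (f %in% plant) code %in% 5:6 else code %in% 3:4
      if (at_max) expect_identical(s, 31L) else expect_lt(s, 31L)
    }
  }
})

test_that("a three-food mini-scheme matches exhaustive brute-force scoring", {
  mini <- structure(list(
    name = "weighted", foods = c("rice", "egg", "vegetables"), ages = 9L,
    points = rbind(rice = c(0, 1, 2, 2, 1, 1), egg = c(0, 1, 2, 2, 1, 1),
                   vegetables = c(0, 1, 2, 2, 3, 3)),
    max_points = 7L), class = "dd_scheme")
  colnames(mini$points) <- FREQ_LEVELS
  grid <- expand.grid(rice = 1:6, egg = 1:6, vegetables = 1:6)
  got <- weighted_dd_score(grid, scheme = mini)
  # independent oracle: literal reading of the two footnote point maps
  staple_pts <- function(code) {
    if (code == 1) 0 else if (code == 2) 1 else if (code %in% 3:4) 2 else 1
  }
  plant_pts <- function(code) {
    if (code == 1) 0 else if (code == 2) 1 else if (code %in% 3:4) 2 else 3
  }
  want <- mapply(function(r, e, v) staple_pts(r) + staple_pts(e) + plant_pts(v),
                 grid$rice, grid$egg, grid$vegetables)
  expect_identical(got, as.integer(want))
})

test_that("rice can be switched to the plant-food mapping", {
  rec <- stats::setNames(rep(5L, 14L), FFQ_FOODS)  # all daily
  expect_identical(weighted_dd_score(rec, dd_scheme("weighted")), 20L)
  # daily rice is worth 3 instead of 1 under the alternative reading
  expect_identical(weighted_dd_score(rec, dd_scheme("weighted", rice = "plant")),
                   22L)
  expect_identical(dd_scheme("weighted", rice = "plant")$max_points, 32)
})

test_that("introduction scores follow the timing predicates", {
  all_at <- function(code) stats::setNames(rep(code, length(INTRO_FOODS)),
                                           paste0("intro_", INTRO_FOODS))
  expect_identical(introduced_foods_score(all_at(3L), 6), 14L)
  expect_identical(introduced_foods_score(all_at(3L), 9), 14L)
  expect_identical(introduced_foods_score(all_at(4L), 6), 0L)
  expect_identical(introduced_foods_score(all_at(4L), 9), 14L)
  expect_identical(allergenic_foods_score(all_at(2L), 6), 6L)
  expect_identical(allergenic_foods_score(all_at(2L), 9), 6L)
  # egg + fish at 4-6m, wheat at 7m+, other allergens never introduced
  rec <- all_at(1L)
  rec[c("intro_egg", "intro_fish")] <- 3L
  rec["intro_wheat"] <- 4L
  expect_identical(allergenic_foods_score(rec, 6), 2L)
  expect_identical(allergenic_foods_score(rec, 9), 3L)
})

test_that("scores stay in range, propagate missingness, and are monotone", {
  ffq <- random_ffq(60, seed = 11)
  s <- weighted_dd_score(ffq)
  expect_true(all(s >= 0 & s <= 31))
  intro <- random_intro(60, seed = 12)
  s6 <- introduced_foods_score(intro, 6); s9 <- introduced_foods_score(intro, 9)
  a6 <- allergenic_foods_score(intro, 6); a9 <- allergenic_foods_score(intro, 9)
  expect_true(all(s6 >= 0 & s6 <= 14) && all(a6 >= 0 & a6 <= 6))
  # introduction by 6 months implies introduction by 9 months
  expect_true(all(s9 >= s6) && all(a9 >= a6))
  # one missing item voids the score for exactly the affected records
  ffq$ffq_egg[1:5] <- NA
  expect_identical(which(is.na(weighted_dd_score(ffq))), 1:5)
  intro$intro_wheat[3] <- NA
  expect_true(is.na(allergenic_foods_score(intro, 9)[3]))
  expect_false(anyNA(introduced_foods_score(intro, 9)))  # wheat not counted
  # monotone in the frequency scale: never -> monthly -> weekly never
  # decreases; weekly -> daily moves by exactly -1 (staple) or +1 (plant)
  base <- random_ffq(40, seed = 13)
  for (f in paste0("ffq_", c("rice", "meat", "vegetables", "fruit_berries"))) {
    fix <- function(code) { d <- base; d[[f]] <- code; weighted_dd_score(d) }
    s1 <- fix(1L); s2 <- fix(2L); s3 <- fix(3L); s5 <- fix(5L)
    expect_true(all(s1 <= s2) && all(s2 <= s3))
    delta <- if (sub("ffq_", "", f) %in% c("vegetables", "fruit_berries"))
      1L else -1L
    expect_true(all(s5 - s3 == delta))
  }
})

test_that("categorisation uses the printed inclusive boundaries", {
  expect_identical(as.character(categorize_score(c(0, 17, 18, 20, 21, 23, 24, 31),
                                                 "weighted", 9)),
                   c("0-17p", "0-17p", "18-20p", "18-20p", "21-23p", "21-23p",
                     "24-31p", "24-31p"))
  expect_identical(as.character(categorize_score(c(10, 11, 12, 13, 14),
                                                 "introduced", 9)),
                   c("0-10 foods", "11 foods", "12 foods", "13-14 foods",
                     "13-14 foods"))
  expect_identical(as.character(categorize_score(c(2, 3, 4, 5), "allergenic", 6)),
                   c("0-2 allergenic foods", "3 allergenic foods",
                     "4 allergenic foods", "5-6 allergenic foods"))
  expect_identical(as.character(categorize_score(c(3, 4, 6), "allergenic", 9)),
                   c("0-3 allergenic foods", "4 allergenic foods",
                     "6 allergenic foods"))
  expect_true(is.na(categorize_score(NA_integer_, "weighted", 9)))
  expect_error(categorize_score(32L, "weighted", 9), "outside")
  expect_error(dd_categorization("weighted", 6), "no categorisation")
})

test_that("score schemes round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  sch <- dd_scheme("weighted")
  write_scheme(sch, path)
  back <- read_scheme(path)
  expect_identical(back$foods, sch$foods)
  expect_equal(back$points, sch$points)
  expect_identical(back$max_points, 31L)
  rec <- stats::setNames(rep(3L, 14L), FFQ_FOODS)
  expect_identical(weighted_dd_score(rec, back), 28L)
})
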