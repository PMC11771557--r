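# Shared fixture builders; everything is generated in code.

# default generator parameters, built once per test run
test_params <- local({
  cache <- NULL
  function(...) {
    args <- list(...)
    if (length(args) == 0L) {
      if (is.null(cache)) cache <<- generator_params(n = 2060, seed = 1)
      return(cache)
    }
    do.call(generator_params, args)
  }
})

# one fully observed hand-made record as a 1-row data frame
make_record <- function(id = "A1", ffq_code = 3L, intro_code = 3L, ...) {
  base <- list(
    id = id, sex = "girl", maternal_ethnicity = "sweden",
    maternal_university = TRUE, breastfeeding_4m = "exclusive_bf",
    any_bf_9m = TRUE, early_solid_intro = FALSE, family_fa_history = FALSE,
    outdoor_env = "city", maternal_age = 31.0, fa_dx_9m = FALSE,
    fa_dx_18m = FALSE, eczema_by_18m = FALSE, gi_only_symptoms = FALSE)
  ffq <- stats::setNames(as.list(rep(as.integer(ffq_code), length(FFQ_FOODS))),
                         paste0("ffq_", FFQ_FOODS))
  intro <- stats::setNames(as.list(rep(as.integer(intro_code),
                                       length(INTRO_FOODS))),
                           paste0("intro_", INTRO_FOODS))
  rec <- utils::modifyList(c(base, ffq, intro), list(...))
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_hand_cohort <- function(n = 5, ...) {
  rows <- lapply(seq_len(n), function(i) make_record(id = sprintf("A%02d", i)))
  d <- do.call(rbind, rows)
  mods <- list(...)
  for (nm in names(mods)) d[[nm]] <- mods[[nm]]
  new_cohort(d, provenance = "hand-made fixture")
}

# random valid ffq code matrix (as data frame) for property tests
random_ffq <- function(n, seed) {
  set.seed(seed)
  m <- matrix(sample(1:6, n * length(FFQ_FOODS), replace = TRUE), nrow = n)
  colnames(m) <- paste0("ffq_", FFQ_FOODS)
  as.data.frame(m)
}

random_intro <- function(n, seed) {
  set.seed(seed)
  m <- matrix(sample(1:4, n * length(INTRO_FOODS), replace = TRUE), nrow = n)
  colnames(m) <- paste0("intro_", INTRO_FOODS)
  as.data.frame(m)
}
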