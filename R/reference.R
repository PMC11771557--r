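# Published reference table shipped with the package.

#' Published unadjusted category counts and estimates
#'
#' The per-category sample sizes, case counts and published unadjusted odds
#' ratios (95% CI, p) of the NorthPop diet-diversity / food-allergy
#' association table, for all five exposure blocks at 18 months. Non-cases
#' are `n - cases`; the first row of each block is the reference category.
#' The `note` column marks cells whose printed digits are not reproducible
#' from their own printed counts under the Woolf method (single-digit print
#' artifacts) and the one category whose odds ratio was not printed.
#'
#' @return Data frame with columns `block`, `age`, `level`, `n`, `cases`,
#'   `reference`, `pub_or`, `pub_ci_low`, `pub_ci_high`, `pub_p`, `note`.
#' @examples
#' ref <- published_unadjusted_table()
#' subset(ref, block == "weighted")
#' @export
published_unadjusted_table <- function() {
  path <- system.file("extdata", "northpop_table3_unadjusted.tsv",
                      package = "dietdiv", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  df$reference <- df$reference == 1
  df$note[is.na(df$note)] <- ""
  df
}

#' Recompute the unadjusted table from the published counts
#'
#' Forms each category's 2x2 table against its block reference from the
#' published counts and recomputes OR, 95% CI and p with
#' [odds_ratio_2x2()].
#'
#' @return The reference data frame with computed `or`, `ci_low`, `ci_high`,
#'   `p` columns appended.
#' @export
recompute_unadjusted_table <- function() {
  ref <- published_unadjusted_table()
  ref$or <- ref$ci_low <- ref$ci_high <- ref$p <- NA_real_
  for (blk in unique(paste(ref$block, ref$age))) {
    idx <- which(paste(ref$block, ref$age) == blk)
    r <- idx[ref$reference[idx]]
    for (i in setdiff(idx, r)) {
      o <- odds_ratio_2x2(ref$cases[i], ref$n[i] - ref$cases[i],
                          ref$cases[r], ref$n[r] - ref$cases[r])
      ref$or[i] <- o$or; ref$ci_low[i] <- o$ci_low
      ref$ci_high[i] <- o$ci_high; ref$p[i] <- o$p
    }
    ref$or[r] <- 1
  }
  ref
}
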