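# Rendering and export: published-table styling, TSV/JSON emission,
# forest-plot data and base-graphics forest plots.

#' Format p-values and odds ratios in table style
#'
#' P-values render with three decimals and no leading zero (".051"), values
#' below 0.001 as "<.001". Odds ratios and confidence bounds render with two
#' decimals: "0.47 (0.22-1.00)". Underlying values are never rounded in the
#' result objects, only at rendering.
#'
#' @param p,or,ci_low,ci_high Numeric vectors.
#' @return Character vector.
#' @export
format_p <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
                ifelse(p < 0.001, "<.001",
                       sub("^0", "", sprintf("%.3f", p))))
  out
}

#' @rdname format_p
#' @export
format_or <- function(or, ci_low = NULL, ci_high = NULL) {
  if (is.null(ci_low)) return(sprintf("%.2f", or))
  sprintf("%.2f (%.2f-%.2f)", or, ci_low, ci_high)
}

#' Export association results
#'
#' `write_association_tsv` writes one row per exposure level per model;
#' `write_association_json` nests results by fit (block, form, adjustment).
#'
#' @param x A `dd_assoc` or `dd_assoc_set`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_association_tsv <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_association_tsv
#' @export
write_association_json <- function(x, path) {
  if (inherits(x, "dd_assoc")) x <- list(fit = x)
  payload <- lapply(x, function(fit) {
    list(spec = fit$spec, n_used = fit$n_used, cases = fit$cases,
         converged = fit$converged, flags = fit$flags,
         levels = fit$table)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Forest-plot data
#'
#' Flattens association results into the columns a forest plot needs:
#' label, odds ratio and 95% bounds, with reference rows at OR 1.
#'
#' @param x A `dd_assoc`, `dd_assoc_set` or `dd_assoc_strata`.
#' @return Data frame with `label`, `or`, `ci_low`, `ci_high`, `reference`.
#' @export
forest_data <- function(x) {
  if (inherits(x, "dd_assoc_strata")) {
    out <- do.call(rbind, lapply(names(x), function(nm) {
      fd <- forest_data(x[[nm]])
      fd$label <- paste0(attr(x, "by"), "=", nm, ": ", fd$label)
      fd
    }))
    rownames(out) <- NULL
    return(out)
  }
  df <- as.data.frame(x)
  out <- data.frame(
    label = paste0(df$measure, df$age, " ", df$adjust, ": ", df$level),
    or = df$or, ci_low = df$ci_low, ci_high = df$ci_high,
    reference = df$reference)
  rownames(out) <- NULL
  out
}

.forest_plot <- function(fd, main) {
  fd <- fd[!is.na(fd$or), , drop = FALSE]
  if (!nrow(fd)) {
    warning("nothing to plot: no estimated odds ratios", call. = FALSE)
    return(invisible(NULL))
  }
  k <- nrow(fd)
  xlim <- range(c(fd$or, fd$ci_low, fd$ci_high, 1), na.rm = TRUE)
  op <- graphics::par(mar = c(4, 16, 3, 2))
  on.exit(graphics::par(op))
  graphics::plot(fd$or, rev(seq_len(k)), log = "x", xlim = xlim,
                 ylim = c(0.5, k + 0.5), pch = 15, xlab = "Odds ratio (log scale)",
                 ylab = "", yaxt = "n", main = main)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  ok <- !is.na(fd$ci_low)
  graphics::segments(fd$ci_low[ok], rev(seq_len(k))[ok],
                     fd$ci_high[ok], rev(seq_len(k))[ok])
  graphics::axis(2, at = rev(seq_len(k)), labels = fd$label, las = 1,
                 cex.axis = 0.7)
  invisible(fd)
}

#' @export
plot.dd_assoc <- function(x, ...) {
  .forest_plot(forest_data(x),
               main = sprintf("%s score at %dm (%s)", x$spec$measure,
                              x$spec$age, x$spec$adjust))
}

#' @export
plot.dd_assoc_set <- function(x, adjust = "model2", form = "categorical", ...) {
  keys <- grep(paste0("\\.", form, "\\.", adjust, "$"), names(x), value = TRUE)
  fd <- do.call(rbind, lapply(x[keys], forest_data))
  .forest_plot(fd, main = paste("Diet diversity and food allergy --", adjust))
}

#' @export
plot.dd_assoc_strata <- function(x, ...) {
  .forest_plot(forest_data(x),
               main = paste("Stratified models by", attr(x, "by")))
}

#' @export
print.dd_group_comparison <- function(x, ...) {
  y <- as.data.frame(x)
  y$statistic <- round(y$statistic, 3)
  y$p <- format_p(y$p)
  y$est_a <- round(y$est_a, 3); y$est_b <- round(y$est_b, 3)
  y$diff <- round(y$diff, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
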