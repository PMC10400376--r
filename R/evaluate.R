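# Evaluation: Pearson/Spearman correlations, seeded paired bootstrap of
# prediction sets, and the expression-"wall" stratified diagnostic.

#' Pearson and Spearman correlation between predictions and truth
#'
#' @param pred,truth Equal-length numeric vectors (length >= 3).
#' @return `list(pearson, spearman, n)`; a constant input yields `NA`
#'   correlations with the reason in `$note`.
#' @export
correlations <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  if (length(pred) < 3)
    return(list(pearson = NA_real_, spearman = NA_real_, n = length(pred),
                note = "fewer than 3 observations"))
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_, n = length(pred),
                note = "constant input, correlation undefined"))
  list(pearson = cor(pred, truth),
       spearman = cor(pred, truth, method = "spearman"),
       n = length(pred))
}

#' Seeded (paired) bootstrap of correlation estimates
#'
#' Resamples indices with replacement and recomputes Pearson and Spearman
#' per resample. When a second prediction set is supplied, the same
#' resample indices are used for both sets (paired bootstrap) and the
#' per-resample difference (A - B) is summarized as well. Degenerate
#' (constant) resamples are skipped and counted.
#'
#' @param pred_a Predictions of model A.
#' @param truth Ground-truth values.
#' @param pred_b Optional predictions of model B (paired comparison).
#' @param resamples Number of bootstrap resamples (default 10000).
#' @param seed Bootstrap seed; identical seeds reproduce the report
#'   exactly.
#' @return An `evaluation_report` list: `n`, point estimates, 2.5/50/97.5
#'   percentiles of each correlation (and of the A - B differences when
#'   `pred_b` is given), `resamples`, and `skipped` degenerate resamples.
#' @export
bootstrap_correlations <- function(pred_a, truth, pred_b = NULL,
                                   resamples = 10000L, seed = 1L) {
  n <- length(truth)
  stopifnot(length(pred_a) == n, resamples >= 1,
            is.null(pred_b) || length(pred_b) == n)
  pa <- matrix(NA_real_, resamples, 2)
  pb <- if (!is.null(pred_b)) matrix(NA_real_, resamples, 2) else NULL
  skipped <- 0L
  with_seed(sub_seed(seed, "bootstrap"), {
    for (r in seq_len(resamples)) {
      idx <- sample.int(n, n, replace = TRUE)
      tt <- truth[idx]
      if (stats::sd(tt) == 0 || stats::sd(pred_a[idx]) == 0 ||
          (!is.null(pred_b) && stats::sd(pred_b[idx]) == 0)) {
        skipped <- skipped + 1L
        next
      }
      pa[r, ] <- c(cor(pred_a[idx], tt),
                   cor(pred_a[idx], tt, method = "spearman"))
      if (!is.null(pred_b))
        pb[r, ] <- c(cor(pred_b[idx], tt),
                     cor(pred_b[idx], tt, method = "spearman"))
    }
  })
  qs <- c(0.025, 0.5, 0.975)
  summarize <- function(v) quantile(v, qs, na.rm = TRUE, names = TRUE)
  point <- correlations(pred_a, truth)
  rep <- list(n = n, resamples = as.integer(resamples), skipped = skipped,
              pearson = point$pearson, spearman = point$spearman,
              pearson_ci = summarize(pa[, 1]),
              spearman_ci = summarize(pa[, 2]))
  if (!is.null(pred_b)) {
    point_b <- correlations(pred_b, truth)
    rep$pearson_b <- point_b$pearson
    rep$spearman_b <- point_b$spearman
    rep$pearson_diff_ci <- summarize(pa[, 1] - pb[, 1])
    rep$spearman_diff_ci <- summarize(pa[, 2] - pb[, 2])
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, %d resamples (%d degenerate)\n",
              x$n, x$resamples, x$skipped))
  cat(sprintf("  Pearson  %.4f  [%.4f, %.4f]\n", x$pearson,
              x$pearson_ci[1], x$pearson_ci[3]))
  cat(sprintf("  Spearman %.4f  [%.4f, %.4f]\n", x$spearman,
              x$spearman_ci[1], x$spearman_ci[3]))
  if (!is.null(x$pearson_diff_ci))
    cat(sprintf("  Pearson diff (A-B) median %.4f [%.4f, %.4f]\n",
                x$pearson_diff_ci[2], x$pearson_diff_ci[1],
                x$pearson_diff_ci[3]))
  invisible(x)
}

#' Stratified diagnostic around the low-expression prediction "wall"
#'
#' Splits observations at a truth threshold and reports per-stratum
#' counts and correlations; purely diagnostic for the known loss of
#' resolution at low expression.
#'
#' @param pred,truth Numeric vectors.
#' @param threshold Expression threshold separating the strata.
#' @return Data frame with rows `below`/`above`: `n`, `pearson`,
#'   `spearman`, `note`.
#' @export
expression_wall_report <- function(pred, truth, threshold) {
  stopifnot(length(pred) == length(truth))
  strat <- function(i, label) {
    if (!sum(i))
      return(data.frame(stratum = label, n = 0L, pearson = NA_real_,
                        spearman = NA_real_, note = "empty stratum"))
    cc <- correlations(pred[i], truth[i])
    data.frame(stratum = label, n = sum(i), pearson = cc$pearson,
               spearman = cc$spearman, note = cc$note %||% "")
  }
  rbind(strat(truth < threshold, "below"),
        strat(truth >= threshold, "above"))
}
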