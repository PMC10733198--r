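# Prediction-performance metrics: percentage average fold error (%AFE,
# bias), percentage absolute average fold error (%AAFE, accuracy),
# two-/five-fold classification per drug, and visual-predictive-check
# percentile bands.

.check_pairs <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 1)
  bad <- which(!(is.finite(predicted) & is.finite(observed) &
                   predicted > 0 & observed > 0))
  if (length(bad))
    stop("non-positive or non-finite prediction pairs at indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  invisible(TRUE)
}

#' Percentage average fold error (bias)
#'
#' `100 * 10^(mean(log10(pred/obs)))`: 100% means unbiased; symmetric
#' over- and under-prediction cancel on the log scale.
#'
#' @param predicted,observed positive numeric vectors (paired).
#' @return percent.
#' @export
afe_percent <- function(predicted, observed) {
  .check_pairs(predicted, observed)
  100 * 10^(mean(log10(predicted / observed)))
}

#' Percentage absolute average fold error (accuracy)
#'
#' `100 * 10^(mean(|log10(pred/obs)|))`; always >= 100%.
#'
#' @inheritParams afe_percent
#' @return percent.
#' @export
aafe_percent <- function(predicted, observed) {
  .check_pairs(predicted, observed)
  100 * 10^(mean(abs(log10(predicted / observed))))
}

#' Classify per-drug prediction error into fold-error bands
#'
#' A drug falls "within-k" when its drug-level geometric absolute fold
#' error `10^(mean |log10(pred/obs)|)` is at most `k`; the smallest
#' qualifying threshold is reported.  The alternative rule
#' `"all_points"` requires every individual pair within k-fold.
#'
#' @param data data frame with columns `drug`, `predicted`, `observed`.
#' @param thresholds increasing fold thresholds (default `c(2, 5)`).
#' @param rule `"geometric"` (default) or `"all_points"`.
#' @return data frame with `drug`, `fold` (the drug-level statistic) and
#'   `class` (e.g. `"within-2"`, `"within-5"`, `"beyond-5"`).
#' @export
fold_error_classification <- function(data, thresholds = c(2, 5),
                                      rule = c("geometric", "all_points")) {
  rule <- match.arg(rule)
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 1))
  out <- lapply(split(data, data$drug), function(d) {
    .check_pairs(d$predicted, d$observed)
    fold <- if (rule == "geometric")
      10^(mean(abs(log10(d$predicted / d$observed))))
    else
      max(pmax(d$predicted / d$observed, d$observed / d$predicted))
    k <- thresholds[fold <= thresholds]
    cls <- if (length(k)) paste0("within-", k[1])
           else paste0("beyond-", thresholds[length(thresholds)])
    data.frame(drug = d$drug[1], fold = fold, class = cls)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Visual-predictive-check percentile bands
#'
#' Pointwise empirical percentiles across simulation replicates on a
#' common time grid.
#'
#' @param replicates numeric matrix, replicates in rows, one column per
#'   grid time; or a data frame with `replicate`, `time_min`,
#'   `conc_ng_ml` (must form a complete grid).
#' @param times optional time vector for matrix input.
#' @param percentiles probabilities (default 2.5/50/97.5).
#' @return data frame with `time_min` and one `p<percentile>` column per
#'   requested percentile.
#' @export
vpc_bands <- function(replicates, times = NULL,
                      percentiles = c(2.5, 50, 97.5)) {
  if (is.data.frame(replicates)) {
    tab <- table(replicates$replicate, replicates$time_min)
    if (any(tab != 1))
      stop("ragged replicate grid: every replicate needs every time point")
    times <- sort(unique(replicates$time_min))
    replicates <- do.call(rbind, lapply(
      split(replicates, replicates$replicate),
      function(d) d$conc_ng_ml[order(d$time_min)]))
  }
  if (nrow(replicates) < 20)
    stop("need at least 20 replicates for percentile bands")
  if (is.null(times)) times <- seq_len(ncol(replicates))
  q <- apply(replicates, 2, stats::quantile, probs = percentiles / 100,
             names = FALSE)
  out <- data.frame(time_min = times, t(q))
  names(out) <- c("time_min", paste0("p", percentiles))
  out
}
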