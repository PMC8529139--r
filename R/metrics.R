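#' Continuity correction for a 2x2 table
#'
#' Zero cells make the empirical logits and ratio measures undefined. The
#' standard remedy in DTA meta-analysis adds a small constant (0.5 by
#' default) to all four cells of a table containing a zero.
#'
#' @param study one-row [study_set] or anything with `tp`, `fn`, `fp`,
#'   `tn` fields.
#' @param cc non-negative correction constant.
#' @param policy `"zero_cells_only"` corrects all four cells only when the
#'   table has a zero cell; `"all_cells"` always corrects; `"never"`
#'   returns the counts unchanged.
#' @return named numeric vector `c(tp, fn, fp, tn)`.
#' @examples
#' continuity_correct(data.frame(tp = 30, fn = 0, fp = 0, tn = 10))
#' @export
continuity_correct <- function(study, cc = 0.5,
                               policy = c("zero_cells_only", "all_cells", "never")) {
  policy <- match.arg(policy)
  stopifnot(cc >= 0)
  k <- c(tp = as.numeric(study$tp[1L]), fn = as.numeric(study$fn[1L]),
         fp = as.numeric(study$fp[1L]), tn = as.numeric(study$tn[1L]))
  add <- switch(policy,
    never = 0,
    all_cells = cc,
    zero_cells_only = if (any(k == 0)) cc else 0
  )
  k + add
}

## vectorized internal form: matrix of corrected counts, one row per trial
.corrected_counts <- function(studies, cc = 0.5, policy = "zero_cells_only") {
  k <- cbind(tp = as.numeric(studies$tp), fn = as.numeric(studies$fn),
             fp = as.numeric(studies$fp), tn = as.numeric(studies$tn))
  add <- switch(policy,
    never = rep(0, nrow(k)),
    all_cells = rep(cc, nrow(k)),
    zero_cells_only = ifelse(rowSums(k == 0) > 0, cc, 0)
  )
  k + add
}

#' Per-study accuracy statistics
#'
#' Computes sensitivity, specificity, predictive values, likelihood
#' ratios, the diagnostic odds ratio and the logit-scale quantities (with
#' their large-sample variances `1/tp* + 1/fn*` and `1/fp* + 1/tn*`) for
#' one trial, after the continuity-correction policy.
#'
#' @inheritParams continuity_correct
#' @return one-row data frame (an `AccuracyEstimates` record).
#' @examples
#' study_metrics(data.frame(study_id = "toy", tp = 21, fn = 5, fp = 1, tn = 22))
#' @export
study_metrics <- function(study, cc = 0.5,
                          policy = c("zero_cells_only", "all_cells", "never")) {
  policy <- match.arg(policy)
  k <- continuity_correct(study, cc, policy)
  if (any(k == 0)) {
    stop("zero cell in study '", study$study_id[1L],
         "' with no continuity correction applied", call. = FALSE)
  }
  tp <- k["tp"]; fn <- k["fn"]; fp <- k["fp"]; tn <- k["tn"]
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  plr <- sens / (1 - spec)
  nlr <- (1 - sens) / spec
  data.frame(
    study_id = as.character(study$study_id[1L]),
    sens = unname(sens), spec = unname(spec),
    ppv = unname(tp / (tp + fp)), npv = unname(tn / (tn + fn)),
    plr = unname(plr), nlr = unname(nlr), dor = unname(plr / nlr),
    logit_sens = unname(log(tp / fn)),
    logit_fpr = unname(log(fp / tn)),
    var_logit_sens = unname(1 / tp + 1 / fn),
    var_logit_fpr = unname(1 / fp + 1 / tn),
    corrected = unname(any(k != c(study$tp[1L], study$fn[1L],
                                  study$fp[1L], study$tn[1L]))),
    stringsAsFactors = FALSE
  )
}

#' Per-study accuracy table with exact confidence intervals
#'
#' One [study_metrics()] row per trial, in input order, augmented with
#' 95% Clopper-Pearson intervals for sensitivity and specificity computed
#' from the *uncorrected* counts (the usual forest-plot data table).
#'
#' @param studies a [study_set].
#' @inheritParams continuity_correct
#' @param level confidence level for the exact intervals.
#' @return data frame with one row per trial.
#' @export
metrics_table <- function(studies, cc = 0.5,
                          policy = c("zero_cells_only", "all_cells", "never"),
                          level = 0.95) {
  policy <- match.arg(policy)
  if (!is.data.frame(studies) || nrow(studies) == 0L) {
    stop("metrics_table needs a non-empty study set", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(studies)),
                 function(i) study_metrics(studies[i, , drop = FALSE], cc, policy))
  out <- do.call(rbind, rows)
  se_ci <- clopper_pearson(studies$tp, studies$tp + studies$fn, level)
  sp_ci <- clopper_pearson(studies$tn, studies$tn + studies$fp, level)
  out$sens_lo <- se_ci$lo; out$sens_hi <- se_ci$hi
  out$spec_lo <- sp_ci$lo; out$spec_hi <- sp_ci$hi
  rownames(out) <- NULL
  out
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x successes, `n` trials (vectorized).
#' @param n number of trials.
#' @param level confidence level.
#' @return data frame with columns `lo`, `hi`.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  data.frame(lo = lo, hi = hi)
}
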