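#' Cochran's Q statistic
#'
#' Fixed-effect inverse-variance heterogeneity test:
#' \eqn{Q = \sum w_i (y_i - \bar y)^2} with \eqn{w_i = 1/v_i} and
#' \eqn{\bar y} the weighted mean; p-value from \eqn{\chi^2_{n-1}}.
#'
#' @param y per-study effect estimates (e.g. corrected logits).
#' @param v their within-study variances (all > 0).
#' @return list with `Q`, `df`, `p`.
#' @export
cochran_q <- function(y, v) {
  if (length(y) < 2L) stop("insufficient data: need at least 2 studies", call. = FALSE)
  stopifnot(length(v) == length(y), all(v > 0))
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  df <- length(y) - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

#' Inconsistency index I-squared
#'
#' \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100}: the percentage of total
#' variability attributable to between-study heterogeneity. Returns 0
#' when Q = 0.
#'
#' @param Q Cochran's Q (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return percentage in `[0, 100]`.
#' @export
i_squared <- function(Q, df) {
  stopifnot(Q >= 0, df >= 1)
  if (Q == 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' Heterogeneity of sensitivity and specificity
#'
#' Cochran Q and I-squared computed separately for the corrected logit
#' sensitivities and logit specificities (the two univariate axes).
#'
#' @param studies a [study_set].
#' @inheritParams continuity_correct
#' @return list with `q_sens`, `q_spec`, `df`, `p_sens`, `p_spec`,
#'   `i2_sens`, `i2_spec`.
#' @export
heterogeneity <- function(studies, cc = 0.5,
                          policy = c("zero_cells_only", "all_cells", "never")) {
  policy <- match.arg(policy)
  k <- .corrected_counts(studies, cc, policy)
  if (any(k == 0)) stop("zero cell with no continuity correction", call. = FALSE)
  qs <- cochran_q(log(k[, "tp"] / k[, "fn"]), 1 / k[, "tp"] + 1 / k[, "fn"])
  qp <- cochran_q(log(k[, "tn"] / k[, "fp"]), 1 / k[, "fp"] + 1 / k[, "tn"])
  list(q_sens = qs$Q, q_spec = qp$Q, df = qs$df,
       p_sens = qs$p, p_spec = qp$p,
       i2_sens = i_squared(qs$Q, qs$df), i2_spec = i_squared(qp$Q, qp$df))
}

#' Spearman screen for a threshold effect
#'
#' Rank correlation (average ranks for ties) between the per-study logit
#' sensitivity and logit(1 - specificity). A strong positive correlation
#' (rho > 0.6 with p < 0.05 by convention) indicates that between-study
#' heterogeneity is driven by differing positivity thresholds. The
#' two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 df by default; an exact
#' permutation p-value (via the [stats::cor.test()] machinery) is
#' available for small n.
#'
#' @param studies a [study_set] with at least 3 trials.
#' @inheritParams continuity_correct
#' @param exact use the exact permutation distribution (no ties, n <= 10).
#' @return list with `rho`, `p`, `n`, `threshold_effect`.
#' @export
threshold_spearman <- function(studies, cc = 0.5,
                               policy = c("zero_cells_only", "all_cells", "never"),
                               exact = FALSE) {
  policy <- match.arg(policy)
  n <- nrow(studies)
  if (is.null(n) || n < 3L) stop("insufficient data: need at least 3 studies", call. = FALSE)
  k <- .corrected_counts(studies, cc, policy)
  if (any(k == 0)) stop("zero cell with no continuity correction", call. = FALSE)
  la <- log(k[, "tp"] / k[, "fn"])
  lx <- log(k[, "fp"] / k[, "tn"])
  if (length(unique(la)) < 2L || length(unique(lx)) < 2L) {
    stop("undefined correlation: a rank vector has zero variance", call. = FALSE)
  }
  rho <- cor(rank(la), rank(lx))     # average ranks for ties
  if (exact && n <= 10L) {
    p <- cor.test(la, lx, method = "spearman", exact = TRUE)$p.value
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n,
       threshold_effect = (rho > 0.6 && p < 0.05))
}

#' Deeks' funnel-plot asymmetry test
#'
#' The standard small-study-effect test for DTA meta-analysis: weighted
#' least squares of \eqn{\ln DOR_i} on \eqn{1/\sqrt{ESS_i}} with weights
#' \eqn{ESS_i}, where the effective sample size is
#' \eqn{ESS_i = 4 n_{i1} n_{i2} / (n_{i1} + n_{i2})} from the
#' *uncorrected* arm sizes (diseased \eqn{n_{i1} = tp+fn}, non-diseased
#' \eqn{n_{i2} = fp+tn}); the DOR uses corrected counts. A slope
#' significantly different from zero (two-sided t on n-2 df) indicates
#' funnel asymmetry, i.e. possible publication bias.
#'
#' @param studies a [study_set] with at least 3 trials.
#' @inheritParams continuity_correct
#' @param alpha significance threshold stored alongside the result
#'   (conventional 0.10 for this low-powered test).
#' @return list with `slope`, `slope_se`, `intercept`, `t_stat`, `p`,
#'   `n`, `significant`, and the funnel coordinates `data`
#'   (`inv_sqrt_ess`, `dor`).
#' @export
deeks_test <- function(studies, cc = 0.5,
                       policy = c("zero_cells_only", "all_cells", "never"),
                       alpha = 0.10) {
  policy <- match.arg(policy)
  n <- nrow(studies)
  if (is.null(n) || n < 3L) stop("insufficient data: need at least 3 studies", call. = FALSE)
  k <- .corrected_counts(studies, cc, policy)
  if (any(k == 0)) stop("zero cell with no continuity correction", call. = FALSE)
  n1 <- as.numeric(studies$tp + studies$fn)
  n2 <- as.numeric(studies$fp + studies$tn)
  ess <- 4 * n1 * n2 / (n1 + n2)
  if (length(unique(ess)) < 2L) {
    stop("degenerate regressor: all effective sample sizes equal", call. = FALSE)
  }
  ldor <- log(k[, "tp"] * k[, "tn"] / (k[, "fn"] * k[, "fp"]))
  x <- 1 / sqrt(ess)
  fit <- lm(ldor ~ x, weights = ess)
  ct <- summary(fit)$coefficients
  list(slope = ct["x", "Estimate"], slope_se = ct["x", "Std. Error"],
       intercept = ct["(Intercept)", "Estimate"],
       t_stat = ct["x", "t value"], p = ct["x", "Pr(>|t|)"], n = n,
       significant = ct["x", "Pr(>|t|)"] < alpha,
       data = data.frame(study_id = studies$study_id,
                         inv_sqrt_ess = x, dor = exp(ldor)))
}
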