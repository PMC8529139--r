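#' Leave-one-out sensitivity analysis
#'
#' Refits the bivariate model n times, omitting one trial at a time, and
#' reports each refit's pooled sensitivity/specificity and their change
#' relative to the full fit. The pooled result is called *stable* when
#' every leave-one-out estimate stays inside the full fit's confidence
#' intervals.
#'
#' @param studies a [study_set] with at least 5 trials.
#' @param quad_nodes passed to [fit_bivariate()].
#' @param level confidence level for the stability verdict.
#' @return data frame with one row per omitted trial (`omitted_id`,
#'   `sens`, `spec`, `delta_sens`, `delta_spec`, `converged`), with the
#'   full-fit summary in `attr(, "full")` and the verdict in
#'   `attr(, "stable")`. Refit failures are recorded per row, not fatal.
#' @export
leave_one_out <- function(studies, quad_nodes = 25, level = 0.95) {
  n <- nrow(studies)
  if (is.null(n) || n < 5L) stop("leave-one-out needs at least 5 trials", call. = FALSE)
  full_fit <- fit_bivariate(studies, quad_nodes = quad_nodes)
  full <- pooled_summary(full_fit, level)
  rows <- lapply(seq_len(n), function(i) {
    res <- tryCatch({
      f <- fit_bivariate(studies[-i, , drop = FALSE], quad_nodes = quad_nodes)
      s <- pooled_summary(f, level)
      data.frame(omitted_id = studies$study_id[i],
                 sens = s$estimate[s$measure == "sens"],
                 spec = s$estimate[s$measure == "spec"],
                 converged = f$converged, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(omitted_id = studies$study_id[i], sens = NA_real_,
                 spec = NA_real_, converged = FALSE, stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  fs <- full$estimate[full$measure == "sens"]
  fp <- full$estimate[full$measure == "spec"]
  out$delta_sens <- out$sens - fs
  out$delta_spec <- out$spec - fp
  ok <- out$converged & !is.na(out$sens)
  stable <- all(ok) &&
    all(out$sens >= full$lo[full$measure == "sens"] &
        out$sens <= full$hi[full$measure == "sens"]) &&
    all(out$spec >= full$lo[full$measure == "spec"] &
        out$spec <= full$hi[full$measure == "spec"])
  attr(out, "full") <- full
  attr(out, "stable") <- stable
  out
}

#' Refit the pipeline after excluding trials
#'
#' @param studies a [study_set].
#' @param exclude_ids study ids to drop (must all exist; at least 4
#'   trials must remain).
#' @param quad_nodes passed to [fit_bivariate()].
#' @return list with `fit`, `summary` (a [pooled_summary()]) and `sroc`
#'   (an [sroc()] result).
#' @export
refit_excluding <- function(studies, exclude_ids = character(), quad_nodes = 25) {
  unknown <- setdiff(exclude_ids, studies$study_id)
  if (length(unknown) > 0L) {
    stop("unknown study id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- !(studies$study_id %in% exclude_ids)
  if (sum(keep) < 4L) {
    stop("insufficient studies: fewer than 4 trials remain after exclusion",
         call. = FALSE)
  }
  fit <- fit_bivariate(studies[keep, , drop = FALSE], quad_nodes = quad_nodes)
  list(fit = fit, summary = pooled_summary(fit), sroc = sroc(fit))
}

#' Model-based outlier detection
#'
#' Flags trials whose corrected logit pair \eqn{(logit\ se_i, logit\ sp_i)}
#' is improbably far from the pooled mean under the fitted model:
#' \deqn{d_i = z_i' (\hat\Sigma + W_i)^{-1} z_i, \qquad
#'       z_i = (logit\ pair)_i - \hat\mu,}
#' with \eqn{W_i} the diagonal within-study variance matrix evaluated at
#' the model-predicted probabilities (expected binomial information,
#' \eqn{1/(n_{i1}\hat p_1 \hat q_1)} and \eqn{1/(n_{i2}\hat p_2 \hat q_2)}).
#' Using the expected rather than the observed-count variance keeps
#' degenerate tables (100% cells) from masking themselves through their
#' own inflated empirical variances. A trial is flagged when
#' \eqn{d_i > \chi^2_2(level)}.
#'
#' @param studies the [study_set] the fit was computed on.
#' @param fit a converged [fit_bivariate()] object.
#' @param level flagging quantile (default 0.95).
#' @return list with `flagged_ids`, `statistic` (named per-study values),
#'   `threshold`.
#' @export
detect_outliers <- function(studies, fit, level = 0.95) {
  stopifnot(inherits(fit, "bivariate_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  p1 <- plogis(fit$mu[[1]]); p2 <- plogis(fit$mu[[2]])
  n1 <- as.numeric(studies$tp + studies$fn)
  n2 <- as.numeric(studies$fp + studies$tn)
  within <- cbind(1 / (n1 * p1 * (1 - p1)), 1 / (n2 * p2 * (1 - p2)))
  d <- .study_quadform(studies, fit$mu, fit$sigma, within)
  names(d) <- studies$study_id
  thr <- qchisq(level, df = 2)
  list(flagged_ids = studies$study_id[is.finite(d) & d > thr | !is.finite(d)],
       statistic = d, threshold = thr)
}

#' Stratified subgroup analysis
#'
#' Refits the pooled model independently within each level of a grouping
#' column. Levels with at least 4 trials get the full bivariate fit and
#' an SROC AUC; levels with 2-3 trials are pooled with the between-study
#' correlation fixed at 0 (univariate-style pooling) and report no AUC;
#' single-trial levels report that trial's own estimates (exact CIs for
#' proportions, log-Wald for ratios), also without an AUC. Per-axis
#' I-squared values accompany every level with >= 2 trials.
#'
#' @param studies a [study_set].
#' @param grouping name of a column of `studies`.
#' @param quad_nodes passed to [fit_bivariate()].
#' @param min_trials_auc minimum trials for a full bivariate fit + AUC.
#' @return data frame with one row per level: `label`, `n_trials`,
#'   point estimates and 95% CIs for sens/spec/plr/nlr/dor, `auc`
#'   (NA below the threshold), `i2_sens`, `i2_spec`.
#' @export
subgroup_analysis <- function(studies, grouping, quad_nodes = 25,
                              min_trials_auc = 4L) {
  if (!grouping %in% names(studies)) {
    stop("unknown grouping column: ", grouping, call. = FALSE)
  }
  g <- as.character(studies[[grouping]])
  rows <- lapply(unique(g), function(lev) {
    sub <- studies[g == lev, , drop = FALSE]
    n <- nrow(sub)
    het <- if (n >= 2L) heterogeneity(sub) else list(i2_sens = NA_real_, i2_spec = NA_real_)
    if (n >= min_trials_auc) {
      fit <- fit_bivariate(sub, quad_nodes = quad_nodes)
      ps <- pooled_summary(fit)
      auc <- sroc_auc(fit)
    } else if (n >= 2L) {
      fit <- fit_bivariate(sub, quad_nodes = quad_nodes, constrain = "rho_zero")
      ps <- pooled_summary(fit)
      auc <- NA_real_
    } else {
      ps <- .single_trial_summary(sub)
      auc <- NA_real_
    }
    wide <- setNames(
      as.vector(t(as.matrix(ps[, c("estimate", "lo", "hi")]))),
      as.vector(t(outer(ps$measure, c("", "_lo", "_hi"), paste0))))
    cbind(data.frame(label = lev, n_trials = n, stringsAsFactors = FALSE),
          as.data.frame(as.list(wide)),
          data.frame(auc = auc, i2_sens = het$i2_sens, i2_spec = het$i2_spec))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## descriptive summary for a 1-trial stratum (mirrors the pooled_summary
## layout; exact binomial CIs for the proportions)
.single_trial_summary <- function(study) {
  m <- study_metrics(study)
  se_ci <- clopper_pearson(study$tp, study$tp + study$fn)
  sp_ci <- clopper_pearson(study$tn, study$tn + study$fp)
  k <- continuity_correct(study)
  z <- qnorm(0.975)
  n1 <- k["tp"] + k["fn"]; n2 <- k["fp"] + k["tn"]
  ratio <- function(val, se) {
    c(val, exp(log(val) - z * se), exp(log(val) + z * se))
  }
  out <- rbind(
    sens = c(m$sens, se_ci$lo, se_ci$hi),
    spec = c(m$spec, sp_ci$lo, sp_ci$hi),
    plr = ratio(m$plr, sqrt(1 / k["tp"] - 1 / n1 + 1 / k["fp"] - 1 / n2)),
    nlr = ratio(m$nlr, sqrt(1 / k["fn"] - 1 / n1 + 1 / k["tn"] - 1 / n2)),
    dor = ratio(m$dor, sqrt(sum(1 / k)))
  )
  out <- as.data.frame(out)
  names(out) <- c("estimate", "lo", "hi")
  out$measure <- rownames(out)
  out[, c("measure", "estimate", "lo", "hi")]
}
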