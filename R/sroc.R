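#' Map a bivariate fit to hierarchical SROC parameters
#'
#' The bivariate binomial-normal model and the hierarchical SROC
#' (Rutter-Gatsonis) model are algebraically equivalent; this returns the
#' HSROC parameters implied by a bivariate fit. Writing the fit in
#' (logit sensitivity, logit FPR) coordinates — mean \eqn{(\mu_1, m_2)}
#' with \eqn{m_2 = -\mu_2}, variances \eqn{\sigma_1^2, s_2^2} and
#' covariance \eqn{s_{12} = -\sigma_{12}} — the mapping is
#' \deqn{\beta = \tfrac12 \ln(s_2^2/\sigma_1^2), \quad
#'       \Lambda = (s_2/\sigma_1)^{1/2}\mu_1 - (\sigma_1/s_2)^{1/2} m_2,}
#' \deqn{\sigma_\theta^2 = (\sigma_1 s_2 + s_{12})/2, \quad
#'       \sigma_\alpha^2 = 2(\sigma_1 s_2 - s_{12}).}
#' \eqn{\Lambda} is the accuracy parameter, \eqn{\beta} the asymmetry
#' parameter; \eqn{\sigma_\alpha^2} is truncated at 0 (with a warning)
#' when rounding pushes it negative.
#'
#' @param fit a converged [fit_bivariate()] object.
#' @return named list: `lambda`, `beta`, `theta_mean`, `theta_var`,
#'   `alpha_var`.
#' @seealso [hsroc_to_bivariate()] for the inverse map.
#' @export
hsroc_params <- function(fit) {
  stopifnot(inherits(fit, "bivariate_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  s1sq <- fit$sigma[1, 1]
  s2sq <- fit$sigma[2, 2]
  if (s1sq <= 0 || s2sq <= 0) {
    stop("degenerate geometry: zero between-study variance on an axis; ",
         "the SROC curve is not identified", call. = FALSE)
  }
  mu1 <- fit$mu[[1]]
  m2 <- -fit$mu[[2]]
  s12 <- -fit$sigma[1, 2]          # covariance on the (sens, fpr) scale
  s1 <- sqrt(s1sq); s2 <- sqrt(s2sq)
  beta <- 0.5 * log(s2sq / s1sq)
  lambda <- sqrt(s2 / s1) * mu1 - sqrt(s1 / s2) * m2
  theta_mean <- (mu1 * exp(beta / 2) + m2 * exp(-beta / 2)) / 2
  alpha_var <- 2 * (s1 * s2 - s12)
  if (alpha_var < 0) {
    warning("alpha_var truncated at 0 (|covariance| exceeded its bound numerically)")
    alpha_var <- 0
  }
  list(lambda = lambda, beta = beta, theta_mean = theta_mean,
       theta_var = (s1 * s2 + s12) / 2, alpha_var = alpha_var)
}

#' Recover bivariate moments from HSROC parameters
#'
#' Inverse of [hsroc_params()]: returns the mean and covariance of
#' (logit sensitivity, logit specificity) implied by the HSROC accuracy
#' \eqn{\Lambda}, asymmetry \eqn{\beta}, threshold mean \eqn{\Theta} and
#' variances.
#'
#' @param lambda,beta,theta_mean,theta_var,alpha_var HSROC parameters.
#' @return list with `mu` (length 2) and `sigma` (2x2).
#' @export
hsroc_to_bivariate <- function(lambda, beta, theta_mean, theta_var, alpha_var) {
  mu1 <- (theta_mean + lambda / 2) * exp(-beta / 2)
  m2 <- (theta_mean - lambda / 2) * exp(beta / 2)
  s1sq <- (theta_var + alpha_var / 4) * exp(-beta)
  s2sq <- (theta_var + alpha_var / 4) * exp(beta)
  s12 <- theta_var - alpha_var / 4   # on the (sens, fpr) scale
  list(mu = c(mu1, -m2),
       sigma = matrix(c(s1sq, -s12, -s12, s2sq), 2, 2))
}

#' Summary ROC curve coordinates
#'
#' The HSROC curve traced by varying the threshold at the pooled accuracy:
#' for \eqn{x = logit(fpr)},
#' \eqn{sens(x) = expit(\Lambda e^{-\beta/2} + x e^{-\beta})}. With
#' `mode = "regression"` the curve is instead the regression line of
#' logit sensitivity on logit FPR implied by the fitted moments
#' (slope \eqn{s_{12}/s_2^2}), a sensitivity-analysis alternative.
#'
#' @param fit a converged [fit_bivariate()] object.
#' @param n_points number of curve points.
#' @param fpr_range FPR interval covered by the curve.
#' @param mode `"hsroc"` (default) or `"regression"`.
#' @return data frame with columns `fpr`, `sens`, increasing in `fpr`.
#' @export
sroc_curve <- function(fit, n_points = 500, fpr_range = c(0, 1),
                       mode = c("hsroc", "regression")) {
  mode <- match.arg(mode)
  stopifnot(n_points >= 2, length(fpr_range) == 2, fpr_range[1] < fpr_range[2])
  fpr <- seq(fpr_range[1], fpr_range[2], length.out = n_points)
  x <- qlogis(fpr)
  if (mode == "hsroc") {
    hp <- hsroc_params(fit)
    lsens <- hp$lambda * exp(-hp$beta / 2) + x * exp(-hp$beta)
  } else {
    s2sq <- fit$sigma[2, 2]
    if (s2sq <= 0) stop("degenerate geometry: zero FPR-axis variance", call. = FALSE)
    slope <- -fit$sigma[1, 2] / s2sq
    lsens <- fit$mu[[1]] + slope * (x + fit$mu[[2]])
  }
  sens <- plogis(lsens)
  ## limits at the boundary of ROC space
  sens[fpr == 0] <- 0
  sens[fpr == 1] <- 1
  data.frame(fpr = fpr, sens = sens)
}

#' Area under the summary ROC curve
#'
#' Trapezoidal integral of sensitivity over FPR. By default the full
#' (0, 1) range on 2001 points, unnormalized; a restricted range (e.g.
#' the observed FPR band) can be requested, optionally normalized by the
#' range width.
#'
#' @inheritParams sroc_curve
#' @param normalize divide by the range width (only meaningful for a
#'   restricted range).
#' @return scalar in `[0, 1]` (unnormalized full range).
#' @export
sroc_auc <- function(fit, n_points = 2001, fpr_range = c(0, 1),
                     normalize = FALSE, mode = c("hsroc", "regression")) {
  if (fpr_range[1] >= fpr_range[2]) stop("empty FPR range", call. = FALSE)
  cur <- sroc_curve(fit, n_points, fpr_range, mode = match.arg(mode))
  auc <- sum(diff(cur$fpr) * (head(cur$sens, -1) + tail(cur$sens, -1)) / 2)
  if (normalize) auc <- auc / diff(fpr_range)
  auc
}

#' Full SROC result bundle
#'
#' Convenience wrapper collecting the HSROC parameters, curve
#' coordinates, AUC and the pooled summary point.
#'
#' @inheritParams sroc_auc
#' @param curve_points points on the exported curve.
#' @return object of class `sroc_result`.
#' @export
sroc <- function(fit, curve_points = 500, n_points = 2001,
                 fpr_range = c(0, 1), mode = c("hsroc", "regression")) {
  mode <- match.arg(mode)
  hp <- if (mode == "hsroc") hsroc_params(fit) else NULL
  structure(list(
    lambda = hp$lambda, beta = hp$beta,
    theta_var = hp$theta_var, alpha_var = hp$alpha_var,
    curve = sroc_curve(fit, curve_points, fpr_range, mode),
    auc = sroc_auc(fit, n_points, fpr_range, mode = mode),
    fpr_range = fpr_range, mode = mode,
    summary_point = c(fpr = unname(1 - plogis(fit$mu[[2]])),
                      sens = unname(plogis(fit$mu[[1]])))
  ), class = "sroc_result")
}

#' @export
print.sroc_result <- function(x, ...) {
  cat("Summary ROC (", x$mode, ")\n", sep = "")
  if (!is.null(x$lambda)) {
    cat(sprintf("  accuracy Lambda = %.3f, asymmetry beta = %.3f\n",
                x$lambda, x$beta))
  }
  cat(sprintf("  AUC = %.4f over FPR (%g, %g)\n",
              x$auc, x$fpr_range[1], x$fpr_range[2]))
  cat(sprintf("  summary point: FPR %.3f, sensitivity %.3f\n",
              x$summary_point["fpr"], x$summary_point["sens"]))
  invisible(x)
}
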