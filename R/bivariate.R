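#' Bivariate binomial-normal log-likelihood
#'
#' Marginal log-likelihood of the bivariate random-effects model: study
#' \eqn{i}'s true logit sensitivity and logit specificity \eqn{(a_i,b_i)}
#' are bivariate normal with mean `mu` and covariance `sigma`, and
#' \eqn{tp_i \sim Bin(tp_i+fn_i, expit(a_i))},
#' \eqn{tn_i \sim Bin(fp_i+tn_i, expit(b_i))}. Each study's double
#' integral is evaluated by tensor-product Gauss-Hermite quadrature after
#' adaptive standardization: nodes are centred at the study's posterior
#' mode and scaled by the inverse curvature there, so the rule stays
#' accurate even when a large study's binomial likelihood is much
#' narrower than the between-study distribution. Rank-deficient `sigma`
#' (including `sigma = 0`) is handled by integrating only along the
#' non-degenerate directions.
#'
#' @param mu length-2 numeric, mean (logit sensitivity, logit specificity).
#' @param sigma 2x2 positive-semidefinite between-study covariance.
#' @param studies a [study_set].
#' @param quad_nodes Gauss-Hermite nodes per dimension (>= 3).
#' @return the log-likelihood (scalar).
#' @export
binom_bivariate_loglik <- function(mu, sigma, studies, quad_nodes = 25) {
  stopifnot(length(mu) == 2, quad_nodes >= 3)
  sigma <- .check_psd(sigma)
  dat <- .biv_data(studies)
  B <- .sigma_factor(sigma)
  .biv_loglik(mu, B, dat, .gh_rule(quad_nodes))
}

.check_psd <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == c(2L, 2L)) || abs(sigma[1, 2] - sigma[2, 1]) > 1e-8) {
    stop("sigma must be a symmetric 2x2 matrix", call. = FALSE)
  }
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("sigma is not positive semi-definite", call. = FALSE)
  }
  (sigma + t(sigma)) / 2
}

.biv_data <- function(studies) {
  if (!is.data.frame(studies) || nrow(studies) == 0L) {
    stop("need a non-empty study set", call. = FALSE)
  }
  list(tp = as.numeric(studies$tp), n1 = as.numeric(studies$tp + studies$fn),
       tn = as.numeric(studies$tn), n2 = as.numeric(studies$fp + studies$tn),
       lc = sum(lchoose(studies$tp + studies$fn, studies$tp) +
                lchoose(studies$fp + studies$tn, studies$tn)))
}

## factor B (2 x r) with sigma = B B', dropping near-null directions
.sigma_factor <- function(sigma, tol = 1e-10) {
  e <- eigen(sigma, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 1)
  if (!any(keep)) return(matrix(0, 2, 0))
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                           nrow = sum(keep))
}

.gh_rule <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x, w = gh$w, n = n)
}

## log binomial kernel (no choose term) and its derivatives wrt the logit
.binll <- function(eta, y, n) y * eta - n * log1p(exp(eta))

## Marginal log-likelihood given mu and factor B (2 x r).
## Per study: adaptive GH in the r-dimensional standardized space
## z ~ N(0, I_r), eta = mu + B z.
.biv_loglik <- function(mu, B, dat, gh) {
  r <- ncol(B)
  const <- dat$lc
  if (r == 0L) {  # degenerate: integral collapses to the plug-in value
    return(const + sum(.binll(mu[1], dat$tp, dat$n1) +
                       .binll(mu[2], dat$tn, dat$n2)))
  }
  if (r == 1L) {
    grid <- matrix(gh$x, ncol = 1)
    W <- gh$w
  } else {
    grid <- cbind(rep(gh$x, each = gh$n), rep(gh$x, times = gh$n))
    W <- rep(gh$w, each = gh$n) * rep(gh$w, times = gh$n)
  }
  E <- rowSums(grid^2)
  ll <- 0
  for (i in seq_along(dat$tp)) {
    h <- .study_mode(mu, B, dat$tp[i], dat$n1[i], dat$tn[i], dat$n2[i])
    ## nodes z = zhat + sqrt(2) * C' x, C upper-triangular, C'C = (-H)^-1
    Z <- sweep(sqrt(2) * grid %*% h$C, 2, h$zhat, `+`)
    eta1 <- mu[1] + as.vector(Z %*% B[1, ])
    eta2 <- mu[2] + as.vector(Z %*% B[2, ])
    g <- .binll(eta1, dat$tp[i], dat$n1[i]) +
      .binll(eta2, dat$tn[i], dat$n2[i]) -
      0.5 * rowSums(Z^2) - 0.5 * r * log(2 * pi)
    m <- max(g + E)
    ll <- ll + m + 0.5 * r * log(2) + h$logdetC +
      log(sum(W * exp(g + E - m)))
  }
  ll + const
}

## posterior mode and curvature of z | study, via damped Newton
## (the objective is strictly concave).
.study_mode <- function(mu, B, tp, n1, tn, n2, tol = 1e-10, maxit = 100L) {
  r <- ncol(B)
  z <- rep(0, r)
  for (it in seq_len(maxit)) {
    eta <- mu + as.vector(B %*% z)
    p <- plogis(eta)
    gr <- as.vector(crossprod(B, c(tp - n1 * p[1], tn - n2 * p[2]))) - z
    Hn <- crossprod(B * sqrt(c(n1 * p[1] * (1 - p[1]),
                               n2 * p[2] * (1 - p[2])))) + diag(r)
    step <- solve(Hn, gr)
    if (sqrt(sum(step^2)) > 5) step <- step * 5 / sqrt(sum(step^2))
    z <- z + step
    if (max(abs(step)) < tol) break
  }
  eta <- mu + as.vector(B %*% z)
  p <- plogis(eta)
  Hn <- crossprod(B * sqrt(c(n1 * p[1] * (1 - p[1]),
                             n2 * p[2] * (1 - p[2])))) + diag(r)
  U <- chol(Hn)                      # Hn = U'U  =>  (-H)^-1 = U^-1 U^-T
  C <- backsolve(U, diag(r))         # C upper triangular with C C' = Hn^-1
  list(zhat = z, C = t(C), logdetC = sum(log(diag(C))))
}

## ---- parameter transforms -------------------------------------------------
## theta = (mu1, mu2, log sd1, log sd2, atanh rho); sds clamped to
## [e^-6, e^4] and |rho| to 0.9999 so the optimizer cannot leave the
## numerically safe region (the likelihood is flat past the clamps).
.theta_to_B <- function(theta) {
  s1 <- exp(min(max(theta[3], -6), 4))
  s2 <- exp(min(max(theta[4], -6), 4))
  rho <- tanh(theta[5])
  rho <- sign(rho) * min(abs(rho), 0.9999)
  matrix(c(s1, s2 * rho, 0, s2 * sqrt(1 - rho^2)), 2, 2)
}

.theta_to_sigma <- function(theta) {
  B <- .theta_to_B(theta)
  B %*% t(B)
}

## moment-based starting values from continuity-corrected logits
.moment_start <- function(studies, cc = 0.5) {
  k <- .corrected_counts(studies, cc, "zero_cells_only")
  la <- log(k[, "tp"] / k[, "fn"])
  lb <- log(k[, "tn"] / k[, "fp"])
  s1 <- max(sd(la), 0.1); s2 <- max(sd(lb), 0.1)
  r0 <- suppressWarnings(cor(la, lb))
  if (!is.finite(r0)) r0 <- 0
  c(mean(la), mean(lb), log(s1), log(s2), atanh(min(max(r0, -0.95), 0.95)))
}

## deterministic jitter directions for optimizer restarts
.JITTER <- rbind(
  c( 0.00,  0.00,  0.0,  0.0,  0.0),
  c( 0.30, -0.30,  0.5,  0.5,  0.0),
  c(-0.30,  0.30, -0.5, -0.5,  0.5),
  c( 0.50,  0.50,  0.0,  0.0, -1.0),
  c(-0.50, -0.50,  0.7, -0.7,  1.0),
  c( 0.00,  0.00, -1.0,  1.0, -0.5)
)

#' Fit the bivariate random-effects model by maximum likelihood
#'
#' Maximizes [binom_bivariate_loglik()] over \eqn{(\mu, \Sigma)} with a
#' quasi-Newton (BFGS) search in the unconstrained coordinates
#' (mean pair, log standard deviations, atanh correlation), starting from
#' moment estimates of the continuity-corrected logits and retrying from
#' up to five deterministically jittered starts if the first search does
#' not converge. The covariance of \eqn{\hat\mu} comes from the inverse
#' numerical Hessian at the optimum (pseudo-inverse when a variance or
#' correlation sits on its boundary and the Hessian is singular there).
#' The fit is deterministic: no random numbers are consumed.
#'
#' `method = "normal_approx"` instead fits the marginal bivariate normal
#' to the corrected logit pairs with fixed within-study variances
#' (`1/tp* + 1/fn*`, `1/fp* + 1/tn*`) — a fallback for degenerate inputs;
#' the exact binomial likelihood needs no continuity correction and is
#' the default.
#'
#' @param studies a [study_set] with at least 4 trials for the full
#'   model (2-3 trials are allowed only with `constrain = "rho_zero"` or
#'   `"sigma_zero"`).
#' @param method `"glmm_quadrature"` (exact binomial likelihood) or
#'   `"normal_approx"`.
#' @param quad_nodes Gauss-Hermite nodes per dimension.
#' @param constrain `"none"` for the full 5-parameter model;
#'   `"rho_zero"` fixes the between-study correlation at 0 (univariate
#'   pooling per axis); `"sigma_zero"` fixes \eqn{\Sigma = 0} (common
#'   effect).
#' @param cc continuity-correction constant used for starting values and
#'   the normal approximation only.
#' @return an object of class `bivariate_fit`: list with `mu`, `sigma`,
#'   `cov_mu`, `loglik`, `converged`, `n_trials`, `method`, `quad_nodes`.
#' @export
fit_bivariate <- function(studies,
                          method = c("glmm_quadrature", "normal_approx"),
                          quad_nodes = 25,
                          constrain = c("none", "rho_zero", "sigma_zero"),
                          cc = 0.5) {
  method <- match.arg(method)
  constrain <- match.arg(constrain)
  n <- nrow(studies)
  if (is.null(n) || n < 2L) stop("insufficient studies: need at least 2 trials", call. = FALSE)
  if (n < 4L && constrain == "none") {
    stop("insufficient studies: the full bivariate model needs >= 4 trials; ",
         "use constrain = \"rho_zero\" (or \"sigma_zero\") for 2-3 trials",
         call. = FALSE)
  }
  dat <- .biv_data(studies)
  gh <- .gh_rule(quad_nodes)
  free <- switch(constrain, none = 1:5, rho_zero = 1:4, sigma_zero = 1:2)
  fill <- function(th) {
    full <- c(0, 0, -6, -6, 0)
    full[free] <- th
    if (constrain == "sigma_zero") full[3:4] <- -Inf
    full
  }
  objective <- if (method == "glmm_quadrature") {
    function(th) {
      full <- fill(th)
      B <- if (constrain == "sigma_zero") matrix(0, 2, 0) else .theta_to_B(full)
      .biv_loglik(full[1:2], B, dat, gh)
    }
  } else {
    k <- .corrected_counts(studies, cc, "zero_cells_only")
    y1 <- log(k[, "tp"] / k[, "fn"]); y2 <- log(k[, "tn"] / k[, "fp"])
    v1 <- 1 / k[, "tp"] + 1 / k[, "fn"]; v2 <- 1 / k[, "fp"] + 1 / k[, "tn"]
    function(th) {
      full <- fill(th)
      S <- if (constrain == "sigma_zero") matrix(0, 2, 2) else .theta_to_sigma(full)
      .normal_marglik(full[1:2], S, y1, y2, v1, v2)
    }
  }
  start_full <- .moment_start(studies, cc)
  best <- NULL
  for (j in seq_len(nrow(.JITTER))) {
    st <- (start_full + .JITTER[j, ])[free]
    opt <- tryCatch(
      optim(st, objective, method = "BFGS",
            control = list(fnscale = -1, maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value > best$value + 1e-9) best <- opt
    if (!is.null(best) && best$convergence == 0 && j >= 1L) break
  }
  if (is.null(best)) stop("bivariate fit failed from all starting values", call. = FALSE)
  converged <- best$convergence == 0
  if (!converged) {
    warning("bivariate fit did not converge; returning best point found")
  }
  full <- fill(best$par)
  sigma <- if (constrain == "sigma_zero") matrix(0, 2, 2) else .theta_to_sigma(full)
  H <- tryCatch(
    optimHess(best$par, objective, control = list(fnscale = -1)),
    error = function(e) NULL)
  V <- .vcov_from_hessian(H)
  structure(list(
    mu = setNames(full[1:2], c("logit_sens", "logit_spec")),
    sigma = sigma, cov_mu = V[1:2, 1:2, drop = FALSE],
    loglik = best$value, converged = converged, n_trials = n,
    method = method, quad_nodes = quad_nodes, constrain = constrain,
    par = best$par, vcov_par = V, studies = studies
  ), class = "bivariate_fit")
}

## invert -Hessian robustly; flat (boundary) directions get a
## pseudo-inverse so mu's block stays usable.
.vcov_from_hessian <- function(H) {
  if (is.null(H)) return(matrix(NA_real_, 5, 5))
  V <- tryCatch(solve(-H), error = function(e) NULL)
  ok <- !is.null(V) && all(is.finite(diag(V)[1:2])) && all(diag(V)[1:2] > 0)
  if (!ok) V <- MASS::ginv(-H)
  V
}

## marginal normal log-likelihood for the approximation method
.normal_marglik <- function(mu, S, y1, y2, v1, v2) {
  ll <- 0
  for (i in seq_along(y1)) {
    V <- S + diag(c(v1[i], v2[i]))
    d <- det(V)
    z <- c(y1[i] - mu[1], y2[i] - mu[2])
    q <- (z[1]^2 * V[2, 2] - 2 * z[1] * z[2] * V[1, 2] + z[2]^2 * V[1, 1]) / d
    ll <- ll - log(2 * pi) - 0.5 * log(d) - 0.5 * q
  }
  ll
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat("Bivariate binomial-normal fit (", x$method, ")\n", sep = "")
  cat(sprintf("  %d trials, log-likelihood %.4f, converged: %s\n",
              x$n_trials, x$loglik, x$converged))
  cat(sprintf("  pooled sensitivity %.4f, specificity %.4f\n",
              plogis(x$mu[1]), plogis(x$mu[2])))
  s <- sqrt(diag(x$sigma))
  rho <- if (all(s > 0)) x$sigma[1, 2] / prod(s) else NA_real_
  cat(sprintf("  between-study SD (logit): %.3f / %.3f, correlation %.3f\n",
              s[1], s[2], rho))
  invisible(x)
}

#' Pooled summary measures with confidence intervals
#'
#' Back-transforms the fitted means to the pooled sensitivity and
#' specificity (Wald intervals on the logit scale), and derives the
#' positive/negative likelihood ratios and diagnostic odds ratio at the
#' pooled point, with delta-method intervals on the log scale using the
#' covariance of \eqn{\hat\mu}. Note \eqn{\ln DOR = \mu_1 + \mu_2}
#' exactly, so the DOR interval is Wald on that sum.
#'
#' @param fit a converged [fit_bivariate()] object.
#' @param level confidence level.
#' @return object of class `pooled_summary`: data frame with rows
#'   `sens`, `spec`, `plr`, `nlr`, `dor` and columns `estimate`, `lo`, `hi`.
#' @export
pooled_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "bivariate_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  mu <- fit$mu; V <- fit$cov_mu
  se_mu <- sqrt(pmax(diag(V), 0))
  sens <- unname(plogis(mu[1])); spec <- unname(plogis(mu[2]))
  ## delta-method gradients of the log ratio measures wrt mu
  grad <- list(
    plr = c(1 - sens, spec),
    nlr = c(-sens, -(1 - spec)),
    dor = c(1, 1)
  )
  vals <- c(plr = sens / (1 - spec), nlr = (1 - sens) / spec)
  vals["dor"] <- vals["plr"] / vals["nlr"]
  ratio_row <- function(nm) {
    se <- sqrt(max(drop(t(grad[[nm]]) %*% V %*% grad[[nm]]), 0))
    c(vals[[nm]], exp(log(vals[[nm]]) - z * se), exp(log(vals[[nm]]) + z * se))
  }
  out <- rbind(
    sens = c(sens, plogis(mu[1] - z * se_mu[1]), plogis(mu[1] + z * se_mu[1])),
    spec = c(spec, plogis(mu[2] - z * se_mu[2]), plogis(mu[2] + z * se_mu[2])),
    plr = ratio_row("plr"), nlr = ratio_row("nlr"), dor = ratio_row("dor")
  )
  out <- as.data.frame(out)
  names(out) <- c("estimate", "lo", "hi")
  out$measure <- rownames(out)
  out <- out[, c("measure", "estimate", "lo", "hi")]
  structure(out, class = c("pooled_summary", "data.frame"), level = level)
}

#' @export
print.pooled_summary <- function(x, digits = 4, ...) {
  cat("Pooled summary (", 100 * attr(x, "level"), "% CI)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Confidence or prediction region in ROC space
#'
#' The ellipse \eqn{(z-\mu)' M^{-1} (z-\mu) = \chi^2_2(level)} in
#' (logit sensitivity, logit specificity) space, with \eqn{M} the
#' covariance of \eqn{\hat\mu} for the confidence region and
#' \eqn{\Sigma + cov(\hat\mu)} for the prediction region (where a future
#' study's true accuracy pair is expected to lie), back-transformed to
#' (false-positive rate, sensitivity) coordinates.
#'
#' @param fit a converged [fit_bivariate()] object.
#' @param level coverage probability in (0, 1).
#' @param kind `"confidence"` or `"prediction"`.
#' @param n_points number of points on the closed curve.
#' @return data frame with columns `fpr`, `sens` (first point repeated
#'   last, so the curve is closed).
#' @export
predict_region <- function(fit, level = 0.95,
                           kind = c("confidence", "prediction"),
                           n_points = 200) {
  stopifnot(inherits(fit, "bivariate_fit"), level > 0, level < 1)
  kind <- match.arg(kind)
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  M <- fit$cov_mu
  if (kind == "prediction") M <- M + fit$sigma
  if (!all(is.finite(M)) || det(M) <= 0) {
    stop("degenerate region: covariance matrix is singular", call. = FALSE)
  }
  r <- sqrt(qchisq(level, df = 2))
  ang <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(cos(ang), sin(ang))
  pts <- fit$mu + r * t(chol(M)) %*% circ
  data.frame(fpr = plogis(-pts[2, ]), sens = plogis(pts[1, ]))
}

#' Mahalanobis-type distance of each study from the pooled summary
#'
#' Internal helper shared by [detect_outliers()] and region-containment
#' checks: quadratic form of the corrected logit pair around `mu` under
#' covariance `M` plus an optional per-study within-study variance.
#' @noRd
.study_quadform <- function(studies, mu, M, within = NULL) {
  k <- .corrected_counts(studies, 0.5, "zero_cells_only")
  la <- log(k[, "tp"] / k[, "fn"])
  lb <- log(k[, "tn"] / k[, "fp"])
  vapply(seq_len(nrow(k)), function(i) {
    Vi <- M
    if (!is.null(within)) Vi <- Vi + diag(within[i, ])
    z <- c(la[i] - mu[1], lb[i] - mu[2])
    d <- det(Vi)
    if (!is.finite(d) || d <= 0) return(Inf)
    (z[1]^2 * Vi[2, 2] - 2 * z[1] * z[2] * Vi[1, 2] + z[2]^2 * Vi[1, 1]) / d
  }, numeric(1))
}
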