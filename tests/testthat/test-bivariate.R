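test_that("degenerate sigma collapses the likelihood to the plug-in value", {
  s <- make_set(tp = c(8, 5), fn = c(2, 3), fp = c(2, 4), tn = c(8, 6))
  mu <- c(qlogis(0.8), qlogis(0.7))
  ll <- binom_bivariate_loglik(mu, matrix(0, 2, 2), s)
  direct <- sum(dbinom(s$tp, s$tp + s$fn, plogis(mu[1]), log = TRUE)) +
    sum(dbinom(s$tn, s$fp + s$tn, plogis(mu[2]), log = TRUE))
  expect_equal(ll, direct, tolerance = 1e-10)

  one <- make_set(tp = 8, fn = 2, fp = 2, tn = 8)
  mu <- rep(qlogis(0.8), 2)
  expect_equal(binom_bivariate_loglik(mu, matrix(0, 2, 2), one),
               2 * dbinom(8, 10, 0.8, log = TRUE), tolerance = 1e-10)
})

test_that("quadrature matches brute-force dense-grid integration", {
  s <- make_set(tp = c(8, 5), fn = c(2, 3), fp = c(2, 4), tn = c(8, 6))
  set.seed(7)
  for (k in 1:5) {
    mu <- runif(2, -1, 1)
    sd1 <- runif(1, 0.3, 1); sd2 <- runif(1, 0.3, 1)
    rho <- runif(1, -0.8, 0.8)
    sigma <- matrix(c(sd1^2, rho * sd1 * sd2, rho * sd1 * sd2, sd2^2), 2, 2)
    expect_equal(binom_bivariate_loglik(mu, sigma, s),
                 brute_loglik(mu, sigma, s), tolerance = 1e-5)
  }
})

test_that("quadrature is stable under node refinement", {
  f <- fixture_fit()
  mu <- f$fit$mu
  sigma <- f$fit$sigma
  l25 <- binom_bivariate_loglik(mu, sigma, f$studies, quad_nodes = 25)
  l51 <- binom_bivariate_loglik(mu, sigma, f$studies, quad_nodes = 51)
  expect_equal(l25, l51, tolerance = 1e-6)
  # and at a second, non-optimal parameter point
  sigma2 <- diag(c(0.5, 1.2))
  expect_equal(binom_bivariate_loglik(c(1, 1), sigma2, f$studies, 25),
               binom_bivariate_loglik(c(1, 1), sigma2, f$studies, 51),
               tolerance = 1e-6)
})

test_that("non-PSD sigma is rejected", {
  s <- make_set(tp = 8, fn = 2, fp = 2, tn = 8)
  expect_error(binom_bivariate_loglik(c(0, 0), matrix(c(1, 2, 2, 1), 2), s),
               "positive semi-definite")
})

test_that("common-effect fit on identical trials recovers the aggregate ML", {
  s <- make_set(tp = c(8, 8), fn = c(2, 2), fp = c(2, 2), tn = c(8, 8))
  fit <- fit_bivariate(s, constrain = "sigma_zero")
  expect_true(fit$converged)
  expect_equal(unname(plogis(fit$mu)), c(0.8, 0.8), tolerance = 1e-5)
})

test_that("trial count preconditions are enforced", {
  s <- make_set(tp = c(8, 7, 9), fn = c(2, 3, 1), fp = c(2, 2, 3), tn = c(8, 8, 7))
  expect_error(fit_bivariate(s), "insufficient studies")
  expect_error(fit_bivariate(s[1, ], constrain = "rho_zero"), "insufficient studies")
  # 3 trials are allowed with the correlation fixed at zero
  expect_s3_class(fit_bivariate(s, constrain = "rho_zero"), "bivariate_fit")
})

test_that("estimates are invariant to trial order and parameterization", {
  set.seed(11)
  s <- simulate_studies(sim_config(n_studies = 8, seed = 301))
  f1 <- fit_bivariate(s)
  f2 <- fit_bivariate(s[sample(nrow(s)), ])
  expect_equal(f1$mu, f2$mu, tolerance = 1e-5)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-4)

  # independent Cholesky parameterization reaches the same optimum
  dat_ll <- function(p) {
    L <- matrix(c(exp(p[3]), p[4], 0, exp(p[5])), 2, 2)
    binom_bivariate_loglik(p[1:2], L %*% t(L), s)
  }
  st <- c(f1$mu, log(sqrt(f1$sigma[1, 1])) + 0.2,
          f1$sigma[2, 1] / sqrt(f1$sigma[1, 1]) - 0.1,
          log(sqrt(max(f1$sigma[2, 2] - f1$sigma[2, 1]^2 / f1$sigma[1, 1], 0.05))))
  alt <- optim(st, dat_ll, method = "BFGS",
               control = list(fnscale = -1, maxit = 500, reltol = 1e-10))
  expect_equal(unname(alt$par[1:2]), unname(f1$mu), tolerance = 1e-3)
  expect_equal(alt$value, f1$loglik, tolerance = 1e-6)
})

test_that("fixture fit agrees with an independent GLMM implementation", {
  skip_if_not_installed("lme4")
  f <- fixture_fit()
  s <- f$studies
  long <- data.frame(
    study = rep(s$study_id, 2),
    se = rep(c(1, 0), each = nrow(s)),
    sp = rep(c(0, 1), each = nrow(s)),
    pos = c(s$tp, s$tn),
    n = c(s$tp + s$fn, s$fp + s$tn))
  g <- suppressWarnings(lme4::glmer(
    cbind(pos, n - pos) ~ 0 + se + sp + (0 + se + sp | study),
    family = binomial, data = long))
  # Laplace vs adaptive quadrature: small approximation gap expected
  expect_equal(unname(f$fit$mu), unname(lme4::fixef(g)), tolerance = 0.01)
})

test_that("pooled_summary satisfies its algebraic identities", {
  f <- fixture_fit()
  ps <- pooled_summary(f$fit)
  est <- setNames(ps$estimate, ps$measure)
  expect_equal(est[["plr"]], est[["sens"]] / (1 - est[["spec"]]), tolerance = 1e-12)
  expect_equal(est[["nlr"]], (1 - est[["sens"]]) / est[["spec"]], tolerance = 1e-12)
  expect_equal(est[["dor"]], est[["plr"]] / est[["nlr"]], tolerance = 1e-12)
  expect_true(all(ps$lo <= ps$estimate & ps$estimate <= ps$hi))

  # mu = 0 maps to the chance-level summary
  f0 <- f$fit
  f0$mu[] <- 0
  ps0 <- pooled_summary(f0)
  expect_equal(ps0$estimate, c(0.5, 0.5, 1, 1, 1), tolerance = 1e-12)
})

test_that("prediction region nests the confidence region and the data", {
  f <- fixture_fit()
  conf <- predict_region(f$fit, kind = "confidence")
  pred <- predict_region(f$fit, kind = "prediction")
  # same angular grid: prediction point is farther from the centre in logit space
  centre <- f$fit$mu
  d2 <- function(df) (qlogis(df$sens) - centre[1])^2 + (qlogis(1 - df$fpr) - centre[2])^2
  expect_true(all(d2(pred) >= d2(conf) - 1e-10))

  # 50% region strictly inside the 95% one
  p50 <- predict_region(f$fit, level = 0.5, kind = "prediction")
  expect_true(all(d2(p50) < d2(pred)))

  # calibration: the 95% prediction region is for a new study's *true*
  # accuracy pair; latent pairs drawn from the fitted distribution land
  # inside at close to the nominal rate (observed pairs carry additional
  # within-study noise and need not reach it)
  set.seed(9)
  M <- f$fit$sigma + f$fit$cov_mu
  draws <- t(centre + t(chol(M)) %*% matrix(rnorm(2 * 2000), 2))
  Minv <- solve(M)
  qf <- rowSums((draws - rep(centre, each = 2000)) %*% Minv *
                  (draws - rep(centre, each = 2000)))
  expect_equal(mean(qf <= qchisq(0.95, 2)), 0.95, tolerance = 0.02)
  # and a majority of the observed fixture pairs still fall inside
  k <- t(vapply(seq_len(nrow(f$studies)), function(i)
    continuity_correct(f$studies[i, ]), numeric(4)))
  la <- log(k[, 1] / k[, 2]); lb <- log(k[, 4] / k[, 3])
  qf_obs <- vapply(seq_along(la), function(i) {
    z <- c(la[i] - centre[1], lb[i] - centre[2])
    drop(t(z) %*% Minv %*% z)
  }, numeric(1))
  expect_gt(mean(qf_obs <= qchisq(0.95, 2)), 0.5)
})

test_that("sigma = 0 makes confidence and prediction regions coincide", {
  s <- make_set(tp = c(40, 42, 41, 39), fn = c(10, 9, 11, 12),
                fp = c(9, 11, 10, 10), tn = c(41, 39, 40, 42))
  fit <- fit_bivariate(s, constrain = "sigma_zero")
  conf <- predict_region(fit, kind = "confidence")
  pred <- predict_region(fit, kind = "prediction")
  expect_equal(conf, pred, tolerance = 1e-12)
})

test_that("a large on-pooled-value trial barely moves the estimate", {
  f <- fixture_fit()
  mu <- f$fit$mu
  n1 <- 2000; n2 <- 2000
  extra <- data.frame(
    study_id = "atpool", article_id = "atpool", tp = round(n1 * plogis(mu[1])),
    fn = n1 - round(n1 * plogis(mu[1])), fp = n2 - round(n2 * plogis(mu[2])),
    tn = round(n2 * plogis(mu[2])), stringsAsFactors = FALSE)
  s2 <- study_set(rbind(as.data.frame(f$studies)[names(extra)], extra))
  f2 <- fit_bivariate(s2)
  se <- sqrt(diag(f$fit$cov_mu))
  expect_lt(abs(f2$mu[1] - mu[1]), se[1])
  expect_lt(abs(f2$mu[2] - mu[2]), se[2])
})
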