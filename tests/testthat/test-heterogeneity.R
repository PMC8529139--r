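test_that("Cochran Q matches hand computation", {
  # ybar = 1, Q = 1 + 1 + 4 = 6 on 2 df
  q <- cochran_q(c(0, 0, 3), c(1, 1, 1))
  expect_equal(q$Q, 6)
  expect_equal(q$df, 2L)
  expect_equal(q$p, pchisq(6, 2, lower.tail = FALSE))

  ident <- cochran_q(c(1.3, 1.3), c(0.2, 0.2))
  expect_equal(ident$Q, 0)
  expect_equal(ident$p, 1)
  expect_error(cochran_q(1, 1), "insufficient data")
})

test_that("I-squared follows its definition and stays in [0, 100]", {
  expect_equal(i_squared(0, 5), 0)
  expect_equal(i_squared(4, 2), 50)
  expect_equal(i_squared(1, 2), 0)     # Q < df truncates to 0
  set.seed(3)
  for (k in 1:20) {
    v <- i_squared(runif(1, 0, 50), sample(1:20, 1))
    expect_gte(v, 0); expect_lte(v, 100)
  }
})

test_that("fixture heterogeneity is substantial on both axes", {
  s <- load_fixture()
  het <- heterogeneity(s)
  expect_equal(het$df, 29L)
  expect_lt(het$p_sens, 0.05)
  expect_gt(het$i2_sens, 50)
  expect_gt(het$i2_spec, 50)
  # cross-check Q against metafor's fixed-effect Q
  skip_if_not_installed("metafor")
  k <- t(vapply(seq_len(nrow(s)), function(i) continuity_correct(s[i, ]),
                numeric(4)))
  r <- metafor::rma(yi = log(k[, 1] / k[, 2]), vi = 1 / k[, 1] + 1 / k[, 2],
                    method = "FE")
  expect_equal(het$q_sens, r$QE, tolerance = 1e-8)
})

test_that("Spearman screen is exact on monotone toys and handles ties", {
  mono <- make_set(tp = c(2, 6, 18), fn = c(6, 6, 6), fp = c(2, 6, 18),
                   tn = c(6, 6, 6))
  r <- threshold_spearman(mono)
  expect_equal(r$rho, 1)
  expect_equal(r$p, 0)
  anti <- make_set(tp = c(2, 6, 18), fn = c(6, 6, 6), fp = c(18, 6, 2),
                   tn = c(6, 6, 6))
  expect_equal(threshold_spearman(anti)$rho, -1)

  # tie case against a brute-force average-rank computation
  s <- make_set(tp = c(4, 8, 8, 2, 9), fn = c(6, 2, 2, 8, 1),
                fp = c(3, 5, 2, 7, 4), tn = c(7, 5, 8, 3, 6))
  la <- log(s$tp / s$fn); lx <- log(s$fp / s$tn)
  avg_rank <- function(x) {  # independent average-rank implementation
    vapply(x, function(xi) sum(x < xi) + (1 + sum(x == xi)) / 2, numeric(1))
  }
  rho_oracle <- cor(avg_rank(la), avg_rank(lx))
  expect_equal(threshold_spearman(s)$rho, rho_oracle, tolerance = 1e-12)

  expect_error(threshold_spearman(s[1:2, ]), "insufficient data")
  flat <- make_set(tp = c(4, 4, 4), fn = c(6, 6, 6), fp = c(3, 5, 7),
                   tn = c(7, 5, 3))
  expect_error(threshold_spearman(flat), "undefined correlation")
})

test_that("Spearman is invariant under monotone transforms (rank-based)", {
  s <- make_set(tp = c(4, 8, 12, 2, 9, 30), fn = c(6, 2, 4, 8, 1, 5),
                fp = c(3, 5, 2, 7, 4, 9), tn = c(7, 5, 8, 3, 6, 21))
  base <- threshold_spearman(s)$rho
  # doubling every cell of the diseased arm transforms logit sens monotonely
  s2 <- make_set(tp = 2L * s$tp, fn = 2L * s$fn, fp = s$fp, tn = s$tn)
  expect_equal(threshold_spearman(s2)$rho, base, tolerance = 1e-12)
})

test_that("Deeks regression matches a hand weighted-least-squares oracle", {
  # three studies with lnDOR (2, 2.5, 3) and ESS (100, 50, 25):
  # explicit weighted normal equations, computed independently here
  y <- c(2, 2.5, 3); ess <- c(100, 50, 25); x <- 1 / sqrt(ess)
  xb <- sum(ess * x) / sum(ess); yb <- sum(ess * y) / sum(ess)
  slope_oracle <- sum(ess * (x - xb) * (y - yb)) / sum(ess * (x - xb)^2)
  expect_equal(slope_oracle, 10.303, tolerance = 1e-3)

  # counts engineered so corrected lnDOR and arm sizes reproduce y, ess:
  # equal arms n1 = n2 = ess gives ESS = ess exactly
  mk <- function(ldor, n) {
    # symmetric table with or = exp(ldor): tp = tn, fn = fp
    or <- exp(ldor / 2)
    tp <- round(n * or / (1 + or)); fn <- n - tp
    c(tp, fn, fn, tp)
  }
  k <- t(mapply(mk, y, ess))
  s <- make_set(tp = k[, 1], fn = k[, 2], fp = k[, 3], tn = k[, 4])
  d <- deeks_test(s)
  ldor <- log(s$tp * s$tn / (s$fn * s$fp))
  n1 <- s$tp + s$fn; n2 <- s$fp + s$tn
  ess_a <- 4 * n1 * n2 / (n1 + n2)   # the set's actual effective sizes
  xa <- 1 / sqrt(ess_a)
  slope_o2 <- {
    xb <- sum(ess_a * xa) / sum(ess_a); yb2 <- sum(ess_a * ldor) / sum(ess_a)
    sum(ess_a * (xa - xb) * (ldor - yb2)) / sum(ess_a * (xa - xb)^2)
  }
  expect_equal(d$slope, slope_o2, tolerance = 1e-10)
  expect_equal(d$n, 3L)
})

test_that("Deeks slope follows the ESS rescaling law", {
  s <- make_set(tp = c(20, 40, 15, 60), fn = c(5, 12, 8, 10),
                fp = c(6, 14, 5, 18), tn = c(19, 38, 18, 52))
  base <- deeks_test(s)$slope
  s4 <- make_set(tp = 4L * s$tp, fn = 4L * s$fn, fp = 4L * s$fp, tn = 4L * s$tn)
  # all cells x4: lnDOR unchanged, ESS x4, regressor 1/sqrt(ESS) halves
  # while the weights quadruple => the WLS slope scales by sqrt(4)
  expect_equal(deeks_test(s4)$slope, base * sqrt(4), tolerance = 1e-10)
})

test_that("Deeks test holds its size when lnDOR is unrelated to study size", {
  n_reps <- 500
  reject <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_studies = 50, mu = c(1.2, 1.2),
                      sigma = matrix(0, 2, 2),
                      arm_size_law = list(kind = "uniform_range", min = 150, max = 500),
                      seed = 5000 + r)
    s <- simulate_studies(cfg)
    reject[r] <- deeks_test(s)$p < 0.10
  }
  rate <- mean(reject)
  band <- 0.10 + c(-1, 1) * 1.96 * sqrt(0.1 * 0.9 / n_reps)
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("degenerate Deeks inputs are rejected", {
  s <- make_set(tp = c(8, 8, 8), fn = c(2, 2, 2), fp = c(2, 2, 2),
                tn = c(8, 8, 8))
  expect_error(deeks_test(s), "degenerate regressor")
  expect_error(deeks_test(s[1:2, ]), "insufficient data")
})
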