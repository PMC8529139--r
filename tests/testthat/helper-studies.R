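# builders and independent oracles shared across tests

make_set <- function(tp, fn, fp, tn, id = NULL, ...) {
  n <- length(tp)
  study_set(data.frame(
    study_id = if (is.null(id)) sprintf("s%02d", seq_len(n)) else id,
    tp = tp, fn = fn, fp = fp, tn = tn, ...,
    stringsAsFactors = FALSE
  ), provenance = "test")
}

# fit the fixture once per test run; several files reuse it
fixture_fit <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$fit)) {
      cache$studies <- load_fixture("liu2021_mir21")
      cache$fit <- fit_bivariate(cache$studies)
    }
    list(studies = cache$studies, fit = cache$fit)
  }
})

# independent oracle: brute-force 2-D integration of the bivariate
# binomial-normal likelihood on a dense grid (trapezoid is spectrally
# accurate for this smooth, decaying integrand)
brute_loglik <- function(mu, sigma, studies, half_width = 10, h = 0.01) {
  a <- seq(mu[1] - half_width, mu[1] + half_width, by = h)
  b <- seq(mu[2] - half_width, mu[2] + half_width, by = h)
  Sinv <- solve(sigma)
  da <- a - mu[1]
  db <- b - mu[2]
  # log bivariate normal density over the grid (outer expansion)
  ldet <- determinant(sigma)$modulus[1]
  qf <- outer(da^2 * Sinv[1, 1], db^2 * Sinv[2, 2], `+`) +
    2 * Sinv[1, 2] * outer(da, db)
  lphi <- -log(2 * pi) - 0.5 * ldet - 0.5 * qf
  ll <- 0
  for (i in seq_len(nrow(studies))) {
    f1 <- dbinom(studies$tp[i], studies$tp[i] + studies$fn[i], plogis(a), log = TRUE)
    f2 <- dbinom(studies$tn[i], studies$fp[i] + studies$tn[i], plogis(b), log = TRUE)
    lg <- outer(f1, f2, `+`) + lphi
    m <- max(lg)
    ll <- ll + m + log(sum(exp(lg - m)) * h * h)
  }
  ll
}
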