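---
title: "Pooling diagnostic accuracy with the bivariate binomial-normal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling diagnostic accuracy with the bivariate binomial-normal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtapool)
```

## The model and its assumptions

Each diagnostic accuracy study contributes a 2×2 table: `tp` of `tp + fn`
diseased subjects test positive, `tn` of `fp + tn` non-diseased subjects
test negative. `dtapool` pools such tables under the bivariate
binomial–normal random-effects model. Study $i$'s true accuracy pair on
the logit scale, $(a_i, b_i) = (\mathrm{logit}\,Se_i,
\mathrm{logit}\,Sp_i)$, is a draw from $N_2(\mu, \Sigma)$, and the
counts are conditionally binomial:

$$tp_i \sim \mathrm{Bin}(tp_i + fn_i,\ \mathrm{expit}\,a_i), \qquad
  tn_i \sim \mathrm{Bin}(fp_i + tn_i,\ \mathrm{expit}\,b_i).$$

The assumptions this encodes: trials are independent units (articles
contributing several patient strata enter as separate trials); true
accuracies vary between studies rather than being one common pair (the
packaged study set has $I^2 > 50\%$ on both axes, so a common-effect
model is untenable); the between-study law is bivariate normal on the
logit scale; and within-study sampling is exactly binomial, which is
what makes continuity corrections unnecessary in the likelihood itself.
The between-study correlation absorbs the sensitivity–specificity
trade-off induced by studies choosing different positivity thresholds.

Pooled summaries follow from the fit: $Se = \mathrm{expit}\,\mu_1$,
$Sp = \mathrm{expit}\,\mu_2$, $PLR = Se/(1-Sp)$, $NLR = (1-Se)/Sp$, and
$DOR = \exp(\mu_1 + \mu_2)$ exactly. Proportions get Wald intervals on
the logit scale; ratios get delta-method intervals on the log scale with
$z = 1.96$ at 95%, using the covariance of $\hat\mu$ from the inverse
numerical Hessian (the full parameter Hessian is inverted and the
$\mu$ block taken, with a pseudo-inverse when a boundary flattens it).

## Numerical choices

**Adaptive quadrature.** Each study's marginal likelihood is a double
integral with no closed form. We use tensor-product Gauss–Hermite
quadrature, 25 nodes per dimension by default, after *adaptive*
standardization: the integrand's mode is found by a damped Newton search
(the log-integrand is strictly concave) and nodes are centred there and
scaled by the local inverse curvature. Centring at the between-study
mean instead fails a basic refinement check on realistic data — with a
326-subject trial in the set, the binomial likelihood is narrower than
the node spacing and the 25- vs 51-node values differ in the first
decimal; with adaptive centring they agree to ~1e-13. The test suite
checks both node-refinement stability and agreement with brute-force
dense-grid integration on small examples. Rank-deficient $\Sigma$
(including $\Sigma = 0$, where the integral collapses to the plug-in
binomial likelihood) is handled by integrating only along non-degenerate
eigendirections.

**Optimization.** Maximum likelihood over the unconstrained coordinates
$(\mu_1, \mu_2, \log\sigma_1, \log\sigma_2, \mathrm{atanh}\,\rho)$ by
BFGS (relative tolerance 1e-8), started from moment estimates of the
continuity-corrected logits, with up to five deterministically jittered
restarts. The fit consumes no random numbers. Standard deviations are
clamped to $[e^{-6}, e^4]$ and $|\rho| \le 0.9999$; small subgroups do
drive $\hat\rho$ to this boundary, where the likelihood is flat and the
clamp simply stops the search. Fewer than four trials cannot identify
the five parameters, so the full fit refuses them; 2–3 trials are pooled
with $\rho$ fixed at 0, and a single trial is reported descriptively.

**Continuity correction.** The default policy adds 0.5 to all four
cells of any table containing a zero, and only to such tables. This
feeds every *descriptive* layer — per-study metrics, Q/I², the Spearman
screen, Deeks' regression, starting values — but never the binomial
likelihood, which is defined for zero cells as it stands. Six of the 30
packaged trials contain a zero cell.

**SROC and AUC.** The bivariate fit maps algebraically to the
hierarchical SROC model's accuracy $\Lambda$ and asymmetry $\beta$; the
curve is $sens(x) = \mathrm{expit}(\Lambda e^{-\beta/2} + x e^{-\beta})$
for $x = \mathrm{logit}\,fpr$. The mapping and its exact inverse are both
implemented and round-trip to 1e-10. The AUC integrates the curve by
trapezoid on 2001 uniform FPR points over the full $(0,1)$ range;
restricting to the observed FPR band is available but off by default,
since the full range reproduces the reference results and makes AUCs
comparable across subgroups. No AUC confidence interval is reported: a
delta-method interval would misstate the uncertainty of an extrapolated
curve, and a bootstrap is left as future work. A regression-mode curve
(logit sens on logit fpr) is available as a sensitivity analysis.

## Heterogeneity, threshold effect and small-study effects

Q and $I^2 = \max(0, (Q - df)/Q) \cdot 100$ are computed separately per
axis from the corrected logits; both axes are reported because a single
unlabelled figure is ambiguous. The threshold-effect screen is the
Spearman correlation between logit sensitivity and logit(1−specificity)
(average ranks for ties; $t$-approximate $p$, exact permutation optional
for $n \le 10$), flagged when $\rho > 0.6$ with $p < 0.05$. Deeks' test
regresses $\ln DOR$ on $1/\sqrt{ESS}$ with weights $ESS = 4 n_1 n_2 /
(n_1 + n_2)$ from uncorrected arm sizes — the canonical formulation for
DTA data, where Egger-type tests on $\ln DOR$ variance are invalid. Its
conventional significance threshold is 0.10. One algebraic property
worth noting: rescaling all effective sample sizes by $c$ rescales the
WLS slope by $\sqrt{c}$ (the regressor shrinks by $\sqrt c$ while the
weights grow by $c$).

On the packaged set the Deeks slope is large and decisively positive
($p \approx 3\cdot10^{-4}$ under every defensible variant we examined:
zero-cell or all-cell correction, weighted or unweighted, excluding
zero-cell trials). The small trials with perfect cells report enormous
DORs, which *is* a small-study effect; a reader should treat the set's
pooled DOR with corresponding caution.

## Outliers, robustness, subgroups

The outlier statistic is the quadratic form
$d_i = z_i^\top(\hat\Sigma + W_i)^{-1} z_i$ of the corrected logit pair
around $\hat\mu$, flagged above $\chi^2_2(0.95)$. $W_i$ is the
*expected-information* within-study variance, $1/(n_{i1}\hat p_1 \hat
q_1)$ and $1/(n_{i2}\hat p_2 \hat q_2)$ at the model-predicted
probabilities, not the observed-count variance $1/tp^* + 1/fn^*$: a
table with a 100% cell inflates its own empirical variance so much that
it can mask itself, which defeats the statistic's purpose. With expected
information the two perfect-accuracy trials in the packaged set are the
most extreme flags; with observed-count variances they would not be
flagged at all. The same reasoning applies to the 95% prediction region,
which is a statement about a *new study's true accuracy pair*
($M = \Sigma + \mathrm{cov}\,\hat\mu$): observed study points scatter
wider than the region because they add within-study noise, so
containment of observed points below the nominal level is expected, not
a defect.

Leave-one-out refits the model $n$ times and calls the result stable
when every refit's pooled pair stays inside the full fit's intervals.
Subgroups are handled by independent stratified refits (no
meta-regression): full bivariate fit with AUC at $\ge 4$ trials,
$\rho$-fixed pooling without AUC at 2–3, descriptive single-trial rows
at 1 — reporting a pooled CI or an SROC from one or two trials would be
false precision.

## The simulator and what passing tests mean

`simulate_studies()` generates sets from exactly the assumed hierarchy:
logit pairs from $N_2(\mu, \Sigma)$, study totals uniform on 20–300
with diseased fraction uniform on 0.3–0.7 by default (echoing the
packaged set's 18–326 range), binomial counts within. A root seed
spawns per-study and per-replicate substreams deterministically, so any
single draw is reproducible in isolation. `parameter_recovery()` wraps
simulate-then-fit; at the packaged-set-like regime (30 trials of 50–300
subjects, 100 replicates) the mean bias of $\hat\mu$ is below 0.1 with
Wald coverage between 0.90 and 0.99 — coverage is assessed on the
internal estimation scale, where the Wald approximation is honest.

What the simulator does *not* emulate: threshold drift that correlates
accuracy with reported cut-offs, publication-bias selection (so it
cannot power-check Deeks' test against a biased-world alternative),
covariate structure between subgroups, or imperfect gold standards.
Passing recovery tests therefore validates the estimator under the
model's own assumptions — it does not certify those assumptions for any
real data set.

## Known limitations

- Subgroup estimates from small strata (a handful of trials, boundary
  $\hat\rho$) are fragile; different software finds slightly different
  optima, and published small-stratum tables are often not reproducible
  by maximum likelihood at all.
- No meta-regression, no Bayesian fitting, no AUC interval.
- The packaged study set carries the documented column-labelling
  correction and one defensible (not unique) completion of its
  subgroup memberships; both are spelled out in the fixture README.
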