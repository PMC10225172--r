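---
title: "Modeling excess prostate cancer mortality under active surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling excess prostate cancer mortality under active surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrisk)
```

## The question and the model

Men with favorable intermediate-risk (FIR) prostate cancer — fewer than half
of biopsy cores positive plus exactly one intermediate-risk feature (grade
group 2, PSA 10–20 ng/mL, or clinical stage cT2b–c) — face a management
choice between immediate radical prostatectomy (RP) and active surveillance
(AS). No randomized trial isolates FIR disease, so `asrisk` implements a
counterfactual modeling approach:

1. Estimate the baseline cumulative risk of the outcome after surgery,
   $x(t) = 1 - S_{\mathrm{RP}}(t)$, at landmark horizons $t \in \{5, 10, 15\}$
   years, with the Kaplan–Meier product-limit estimator.
2. Assume surveillance multiplies that cumulative risk by a factor
   $k \in \{1.25, 1.5, 1.75, 2\}$:
   $x_{\mathrm{AS}}(t) = k \, x(t)$.
3. Report the absolute excess risk $(k - 1)\,x$ and the number needed to
   harm $\mathrm{NNH} = 1 / \big((k-1)\,x\big)$, the number of men who must
   choose surveillance for one additional outcome by the horizon.

The multiplier acts on the **risk scale**, not the hazard scale. This is
not an aesthetic choice: under risk scaling, doubling ($k = 2$) makes the
excess risk exactly equal to the baseline $x$, which is what the published
grid shows (excess 2.17% at 15 years from $x = 2.17\%$). A
proportional-hazards model $S^k$ would instead give
$1 - S^2 \approx 4.29\%$ total, excess $\approx 2.12\%$ — close, but
distinguishably different. `scale_survival_curve()` offers the
hazard-ratio form behind an explicit `model = "hazard-ratio"` flag for
sensitivity analysis only; every grid and table in the package uses risk
scaling. Only $k \ge 1$ is accepted: the model describes potential harm,
not benefit, and a reciprocal "number needed to treat" reading of $k < 1$
would be a different analysis.

```{r grid}
grid <- evaluate_grid(fir_baseline_risks()$pcsm, c(1.25, 1.5, 1.75, 2))
grid
```

## Two strictly separated modes

`run_analysis()` works in one of two modes, kept apart so exact arithmetic
never silently depends on simulation:

* **printed-baselines** — the landmark risks $x$ are supplied (defaults in
  `fir_baseline_risks()`), the grids are pure decimal arithmetic, and no
  random state is touched. This is the mode that reproduces the published
  tables digit for digit.
* **full-pipeline** — a synthetic cohort is generated, Kaplan–Meier curves
  are fitted per endpoint, landmark risks are read off the fitted step
  functions, and the grids follow. Results then carry Monte-Carlo and
  sampling noise, as any reanalysis of real data would.

The baseline inputs deserve one caveat. The published landmark survival
table rounds to one decimal (5-year PCSM-free survival 99.9%), while the
excess-risk grid prints its own baseline column to two decimals
($x = 0.14\%$, implying survival 99.86%). The two cannot both be exact.
The grid's $x$ values are treated as authoritative for all scenario
arithmetic, because every downstream printed number (twelve excess cells,
the NNH grid, the worked 1.98% doubling example) is consistent with them.
For the secondary endpoints the same reasoning applies at 15 years: the
published text gives 2$\times$ excesses of 3.35% (CRPC) and 3.47%
(metastasis), pinning those baselines more precisely than the rounded
survival table (96.6% and 96.5%, i.e. 3.4% and 3.5%); `asrisk` adopts the
text-pinned values as defaults and reports computed results rather than
forcing agreement with both sources at once.

## Rounding

Reported percentages round half-up at two decimals and NNH rounds half-up
to the nearest integer, applied to a decimal reading of the value
(`round_half_up()` pre-rounds at nine decimals so binary-float artifacts
like $0.75 \times 0.14$ being stored just above $0.105$ cannot flip a
digit). One published NNH cell resists every consistent rule: the 10-year,
1.75$\times$ cell prints 134 while $1 / (0.75 \times 0.0099) = 134.68$
rounds to 135, and the same source's prose elsewhere also says "every 134
men". The package reports the computed 135 and documents the discrepancy;
no rounding rule that yields the neighboring cells (1429, 404, 101) can
also produce 134.

## The Kaplan–Meier implementation

`km_fit()` implements the product-limit estimator from first principles:
$S(t) = \prod_{t_i \le t} (1 - d_i / n_i)$ over distinct event times, with
Greenwood variance $S(t)^2 \sum_{t_i \le t} d_i / \big(n_i (n_i - d_i)\big)$
and pointwise confidence intervals on the complementary log-log scale,
which keeps bounds inside $[0, 1]$ without truncation. At tied times,
events are processed before censorings, so a subject censored at $t_i$
still counts in the risk set at $t_i$. The test suite checks the
implementation two independent ways: against a deliberately naive
brute-force oracle (explicit counting and running products) on hundreds of
small cohorts with ties and censoring, to $10^{-12}$; and against
`survival::survfit(conf.type = "log-log")`, including variances and
interval bounds.

Landmark evaluation is right-continuous (`survival_at()`); a horizon past
the largest observed time returns the last estimate carrying an
`extrapolated` attribute rather than an error. With accrual ending the
same year follow-up closes, 15-year landmarks necessarily extrapolate for
much of any real cohort, and an error there would make the headline
horizon unreachable. When the estimator collapses to zero the Greenwood
sum is formally infinite; the variance is reported as 0 there (the
estimate is degenerate, not uncertain), a convention the oracle shares.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` stands in for the surgical registry data, which were
never deposited. Its defaults (`fir_cohort_spec()`) encode the published
cohort conditions:

* **n = 920** subjects.
* **Endpoint hazards**: piecewise-constant on intervals $[0,5)$, $[5,10)$,
  $[10,15)$, $[15,\infty)$, calibrated by
  `calibrate_piecewise_hazard()` so the survival function passes exactly
  through the published 5/10/15-year landmarks
  ($\lambda_j = \log(S_{j-1}/S_j)/(t_j - t_{j-1})$); the last rate extends
  indefinitely. Event times are drawn by inverse transform along the
  piecewise-linear cumulative hazard.
* **Endpoint independence**: prostate cancer-specific mortality (PCSM),
  castration-resistant disease (CRPC) and metastasis are drawn
  independently per subject. The published summaries are marginal per
  endpoint and every downstream computation consumes only marginals, so
  no joint structure is identifiable or needed. Real endpoints are of
  course ordered and correlated (metastasis precedes CRPC precedes PCSM);
  joint or competing-risk analyses must not be run on these fixtures.
* **Censoring**: surgery years from a triangular distribution on
  1988–2017 with mode 2011, administrative cutoff at 2017, plus optional
  exponential dropout at 0.01/year — a small allowance for loss to
  follow-up in a registry with otherwise complete vital-status capture.
  The source never describes its censoring distribution, so this is a
  plausible reconstruction, not a fit; one consequence is that the
  triangular's median surgery year ($\approx 2006$) sits earlier than the
  published median (2011), which a triangular with that support and mode
  cannot reproduce. Follow-up is therefore somewhat longer in the
  synthetic cohort than the published quartiles imply. Landmark recovery
  tests disable censoring entirely, so none of the validated quantities
  depend on this choice.
* **Demographics** (age, race, PSA, grade group, stage) are cosmetic —
  estimation never reads them — but are generated to resemble the
  published cohort profile: age normal and PSA log-normal with
  quantile-matched parameters, and one intermediate-risk qualifying
  feature per subject drawn with probabilities proportional to the
  published marginals (77% grade group 2, 15% PSA 10–20, 7% cT2b–c, which
  partition the cohort up to rounding). This construction guarantees the
  FIR membership invariant by design. The induced PSA distribution is a
  two-piece truncated log-normal, so its upper tail is shaped by the
  feature mix rather than the registry's empirical tail.

One integer seed drives everything; per-endpoint sub-streams are derived
from it deterministically, so adding an endpoint does not perturb the
others and repeated runs are bit-identical.

Passing tests on these cohorts demonstrate that the pipeline recovers the
generative landmarks (e.g. 97.8% at 15 years within binomial error at
$n = 200{,}000$) and that the estimator is correct; they cannot certify
behavior under real-world features the generator omits — correlated
endpoints, covariate-dependent hazards, non-administrative informative
censoring, or calendar-time trends in surgical practice.

## Problem sizes and numerical choices

The validation suite uses cohorts of up to 30 subjects for
oracle-equivalence checks (500 replicates), 50,000 draws for
distributional checks on the sampler, and a single 200,000-subject
uncensored cohort for landmark recovery, where the binomial standard error
at the 15-year landmark is about 0.033%, small enough to resolve the
printed one-decimal value. Scenario arithmetic carries a $10^{-12}$
tolerance on the $k x \le 1$ domain check to absorb float representation
at the boundary; `scaled_risk()` is computed as $x + (k-1)x$ so the
additivity identity with `excess_risk()` holds to the last bit.

## Limitations

* The hypothetical surveillance cohort is exactly that: a multiplicative
  assumption, not data. The multiplier range 1.25–2 brackets the
  best available randomized evidence for mixed-risk cohorts; outside that
  range the arithmetic still holds but the epidemiological grounding does
  not.
* Confidence intervals for the published curves are not reproducible
  without the original data; the synthetic cohort reproduces landmark
  point estimates and censoring *structure*, not the registry's exact
  information content, so interval widths are indicative only.
* No competing-risk adjustment: the landmark "risk" is one minus
  Kaplan–Meier survival, which treats other-cause death as censoring. At
  the mortality levels involved (under 4% at 15 years) the practical
  impact on the grids is small, but the all-cause mortality context that
  dominates this population's prognosis is deliberately out of scope.
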