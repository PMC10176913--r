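---
title: "Flexible polynomial trajectories for sparse clinical outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible polynomial trajectories for sparse clinical outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexpoly)
```

## Motivation and model

Continuous clinical outcomes such as FEV₁ % predicted or BMI are measured at
irregular clinic visits, typically months apart, while remote-monitoring
exposures arrive daily. `flexpoly` estimates a smooth personal trajectory for
the outcome and evaluates it on a daily grid, for two purposes: aligning the
outcome with dense exposures at a chosen resolution, and reading change off a
fitted trend instead of two noisy raw measurements.

The trajectory model is deliberately simple: for each subject, ordinary
least-squares polynomials of order 1 through 4 in (min–max scaled) time, with
the order chosen by the Gaussian AIC,

$$\mathrm{AIC} = n\log 2\pi + n\log(\mathrm{RSS}/n) + n + 2(p+2),$$

the full-likelihood convention in which the error variance counts as a
parameter (this matches `stats::AIC()` on the corresponding `lm` fit; since
all candidate orders share the same data, any convention that counts
parameters consistently ranks them identically). Ties are broken toward the
lower order. Subjects are fitted independently — there is no pooling across
individuals, no mixed-effects structure, and no spline/LOESS alternative; the
method trades some flexibility for per-person interpretability and for
robustness at the very small sample sizes routine care produces.

Assumptions worth stating explicitly: measurement errors are treated as
independent and homoscedastic Gaussian around a smooth polynomial trend; a
4th-order polynomial is assumed sufficient to describe several years of
within-person change; and the daily grid is an *interpolation* device — the
package never extrapolates beyond a subject's first and last measurement.

## Eligibility and the sparsity rules

Two exclusion rules and two conditional guard rules govern modelling, all
surfaced in `rule_config()`:

| parameter | default | meaning |
|---|---|---|
| `min_measurements` | 2 | a trend needs at least two points |
| `max_intra_subject_gap_days` | 365 | any gap over 1 year excludes the whole subject |
| `forced_linear_below_n` | 8 | subjects with n < 8 get a 1st-order model only |
| `segmentation_below_n` | 15 | subjects with n < 15 are segmented at long gaps |
| `segmentation_gap_days` | 183 | gaps of ≥ 6 months split a sparse series |
| `max_order` | 4 | overfitting guard |

"1 year" and "6 months" are fixed at 365 and 183 days: the pipeline works in
integer day offsets (day 1 = first measurement), and calendar-aware variants
would make the rules non-deterministic across ingest dates. A gap over one
year excludes the subject entirely rather than splitting the series — with so
little information about the intervening period, within-year fluctuation
cannot be estimated. The segmentation comparison uses ≥ 183 to split, so that
*within* every modelled segment all consecutive gaps are strictly under 6
months; segmentation is applied once, exhaustively, at split time. The
forced-linear and segmentation thresholds are judged against the subject's
*total* measurement count (the criteria are per person), while each segment's
maximum order is additionally capped at its own length − 1. Singleton
segments are retained, flagged non-modellable, and their observations are
reported as uncovered rather than dropped. `rule_mode = "UNRESTRICTED"`
disables both guard rules, which is how the consequences of sparse fitting
(implausible interpolated values between distant measurements) can be
demonstrated.

## Numerical choices

- **Basis.** Fits use raw powers of min–max scaled time
  $u=(t-t_1)/(t_n-t_1)\in[0,1]$, not orthogonal polynomials, so coefficients
  are portable across implementations; conditioning at order 4 on $[0,1]$ is
  adequate, and an affine shift of all days leaves the selected order, RSS,
  AIC and predictions unchanged (tested to 1e−8).
- **Zero-RSS floor.** A perfect fit has RSS = 0 and an infinite log-likelihood.
  The AIC then substitutes the floor
  $\max(10^{-12}\, n\, \widehat{\mathrm{Var}}(y),\; 10^{-20}\, n \max(\overline{y^2}, 1),\; 10^{-300})$.
  The first term scales with the data; the second absorbs floating-point noise
  when the outcome is constant (variance 0), where ranking machine-noise RSS
  values would otherwise select an arbitrary high order. Under the floor, all
  exactly fitting orders share one RSS and the +2-per-order penalty decides —
  so a noiseless quadratic selects order 2 and a constant series selects the
  linear model with zero slope.
- **Confidence bands** are pointwise intervals for the *mean* trajectory,
  $\hat y(t) \pm t_{n-p-1,\,0.975}\,\hat\sigma\sqrt{x_0^\top(X^\top X)^{-1}x_0}$,
  not prediction intervals for new observations; they are undefined (NA, not
  an error) when the fit interpolates ($n=p+1$).
- **Degenerate inputs.** All days identical is a hard error at scaling; a
  constant outcome fits with zero slope coefficients; rank deficiency (only
  possible with duplicated days, which the container already rejects) errors.

## Implausibility and alignment

Between-measurement daily values can be clinically implausible when sparse
series are overfitted. A daily prediction is flagged when it is negative or
when its absolute deviation from the subject's observed mean exceeds 30% of
that mean. The 30% rule is interpreted as a *relative deviation band* around
the observed mean — the literal alternative ("value greater than 30% of the
mean") would flag essentially every prediction for any healthy-range outcome.
Similarly, the residual "investigation threshold" defaults to 20 outcome
units (percentage points, for a %-predicted outcome), interpreted as an
absolute observed−predicted discrepancy. Both interpretations are recorded
here because the originating descriptions are ambiguous; both are parameters.

Alignment bins exposures and daily predictions into common intervals: exact
days, or consecutive 7-day (week) / 30-day (month) blocks anchored at the
subject's first predicted day. Calendar months were rejected for determinism.
Within-bin summaries are means over the days available on each side, and bins
lacking either side are dropped. No uncertainty is propagated into aligned
summaries, and the package deliberately stops short of modelling
exposure–outcome associations.

## Evaluation tools

- `residual_summary()` compares observations with the selected fit at
  measurement days (cohort and per-subject mean/sd/range of |obs − pred|,
  plus exceedance counts).
- `pairwise_change()` compares |Δpredicted| with |Δobserved| over all pairs
  of measurement days within 183 days inside the same modelled segment.
  Because the fitted trajectory smooths i.i.d. noise, model-based change is
  systematically smaller than raw paired change — the noise-mitigation
  property the daily grid exists for. Pairs are restricted to measurement
  days (the comparison is against *measured* pairs) and never straddle
  segment boundaries.
- `stability_resample()` redraws ⌈0.8·n⌉ measurements without replacement
  (day order preserved) 100 times, re-runs segmentation + candidate orders +
  AIC selection on each subsample, and reports the fraction of iterations
  whose selected order matches the full-data fit. Two choices here were
  genuinely open: (1) the conditional rules are re-evaluated on the
  *subsample's* n, so a subject near a threshold can cross it under
  resampling — this measures the stability of the whole procedure, not just
  of the AIC comparison; (2) the whole-subject eligibility gap rule is not
  re-applied, since deleting interior points can widen a gap past a year and
  would void iterations; a subsample with no modellable segment records NA
  and counts as inconsistent. Multi-segment fits report the order of the
  longest modellable segment. Per-subject RNG streams derive from
  (seed, subject index), so reports are reproducible bit-for-bit.

## The synthetic-cohort generator

`cohort_spec()` defaults emulate the structure of routine paediatric CF
lung-function records: measurement counts uniform on 2–150 per subject,
inter-visit gaps gamma(shape 2) with mean 53 days rounded and clamped to
[1, 365] (clamped, not resampled, so eligibility under default rules is
guaranteed; essentially all gaps then fall within 6 months), outcomes centred
near 70 on a %-predicted-like scale, and i.i.d. Gaussian noise with sd 5
units — the order of short-term within-person FEV₁ variability.

Ground-truth trajectories are polynomials of a drawn order k. Coefficients
are drawn in the shifted-Legendre basis on [0, 1] with per-component weights
from ±[0.5, 1], then rescaled so the trajectory's range over the subject's
span equals `signal_range` (default 20 units) and recentred on the baseline.
The Legendre construction matters: raw-power draws leave the order-k
component nearly collinear with lower orders, so "true order k" would often
be indistinguishable from k−1 and order-recovery experiments would measure an
artefact of the draw rather than the selector. Truth coefficients are stored
on the scaled-time basis together with the (offset, range) map — converting
to raw-day powers at spans of 10³ and order 4 would lose precision for no
gain — and `true_values()` evaluates them exactly.

What the generator does *not* emulate: pulmonary-exacerbation drops and
treatment responses (truth is smooth), visit scheduling that depends on
health status (gaps are independent of the outcome), heteroscedastic or
autocorrelated measurement error, and cohort-level age trends. Passing tests
on synthetic cohorts therefore demonstrate correctness of the machinery and
behaviour under the stated noise model — not clinical validity on real
records, which must be assessed against held-out measurements as the
evaluation tools support.

## Test problem sizes and known limitations

The test-suite experiments use: 500 random series (n between 2 and 40) for
oracle agreement of the selector; 200 subjects per true order (n = 30,
~1000-day span, signal range 20, noise sd 2) for order recovery and
daily-grid RMSE; cohorts of 20–100 subjects for the noiseless-recovery,
noise-mitigation and stability experiments, with 100 subsampling iterations.
These sizes give stable Monte-Carlo estimates while keeping a full run fast.

One property deserves honesty: for a *true linear* trajectory, plain AIC
retains the linear model in only about two-thirds to 70% of replicates at
n = 30, because each of the three superfluous higher orders is selected when
its pure-noise RSS improvement exceeds the +2 penalty — a probability that no
signal strength or generator setting changes. This is a known characteristic
of AIC (it is not consistent for order selection); the method accepts it
because mild overfitting barely moves the daily grid (recovered-trajectory
RMSE stays well inside the noise sd), and because the subsampling stability
report makes the resulting selection uncertainty visible per subject. Users
wanting sparser selection could lower `max_order`.

Other limitations: polynomials are global (within segment) and can behave
poorly near segment ends relative to local smoothers; daily interpolation
assumes the outcome evolves smoothly between visits, which a mid-interval
exacerbation violates; and the implausibility flag is a screen, not a
correction — flagged days are reported, never altered.
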