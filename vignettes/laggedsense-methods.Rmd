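---
title: "Methods: lagged sensing-symptom correlation and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lagged sensing-symptom correlation and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model the package implements, the
generative model behind its synthetic cohorts, and the numerical and design
conventions a user should know before trusting either.

## The study design

Participants are followed for 16 weeks. Symptom questionnaires are
completed at baseline and then every three weeks: depression (PHQ-8,
0–24) at weeks 1, 4, 7, 10, 13 and 16 after baseline; generalized anxiety
(GAD-7, 0–21) and social anxiety (SPIN, 0–68) at weeks 4–16. Baseline is
collected item-level (8 + 7 + 17 = 32 items) and feeds two things only:
the k-means symptom clustering, and the within-person mean used to fill
single missing assessments. Change pairs are formed from consecutive
*post-baseline* check-ins, so the PHQ-8 yields five pairs per participant
and the GAD-7/SPIN four.

Each check-in at week $w$ (study day $7w$) carries two 14-day sensor
windows: the *preceding* window (days $7w-14 \dots 7w-1$) and the
*proceeding* window (days $7w \dots 7w+13$). For a pair of check-ins
$(w_1, w_2)$, the forward direction correlates
$\Delta S_n = S_n(w_2) - S_n(w_1)$ over preceding windows with
$\Delta S_x = S_x(w_2) - S_x(w_1)$; every sensor day involved strictly
precedes both symptom measurements' interpretation point, and a property
test enumerates all schedules to confirm every preceding-window day falls
before the pair's second check-in. The reverse direction uses the
proceeding windows, $\Delta S_n'$, so sensing strictly follows the symptom
reports. With 21 days between check-ins and 14-day windows, the proceeding
window of one check-in and the preceding window of the *next* share 7
days; the consequences are discussed under the generator below.

## Repeated-measures correlation

The association estimate is the common within-participant slope model:
$y_{ij} = \alpha_i + \beta x_{ij} + \varepsilon_{ij}$, an ANCOVA with one
intercept per participant. The coefficient reported is

$$ r_{rm} = \operatorname{sign}(\hat\beta)\sqrt{\frac{SS_x}{SS_x + SS_{res}}} $$

which reduces to the pooled correlation of within-participant-centered
values. Inference uses $df = N - n - 1$ ($N$ observations, $n$
participants) with a two-sided $t$ test; the table also reports
$n(\bar k - 1) = N - n$, a convention some study reports use for the same
quantity, so both are available for comparison — the package never uses
the latter for p values. Participants contributing fewer than two complete
pairs are excluded. The unit tests verify the implementation against an
independent `lm()` design-matrix construction to $10^{-10}$, and verify
invariance to per-participant location shifts.

Multiple testing is corrected with the Benjamini–Hochberg step-up
procedure. The family is the 14 feature groups within each measure ×
analysis frame (full sample or one symptom cluster) × direction; this
matches how such result tables are presented (one block per measure and
subgroup, both directions side by side) and is deliberately conservative
about cross-measure pooling. Missing tests (e.g. a cluster with too few
eligible participants) do not count toward the family size. Ties among
adjusted values are expected: they are the running minimum of the step-up
procedure.

The design sample-size calculation uses the Fisher-z normal approximation
$n = \lfloor ((z_{1-\alpha/2} + z_{power})/\operatorname{atanh}\rho)^2
\rfloor$; truncation (not rounding) is the convention that reproduces the
canonical 255 at $\rho = 0.2$, $\alpha = .05$, power $.90$ (the raw value
is 255.66). A flag adds the classical $+3$ small-sample correction with
ceiling instead. A Monte-Carlo check in the acceptance suite confirms
empirical power $\approx 0.90$ at the returned $n$.

## Sensor features

**GPS.** Fix-to-fix speeds use the haversine distance on a 6371-km sphere;
a fix is stationary at ≤ 1 km/h (default, configurable), and the first fix
inherits the second's state. Sampling gaps over 30 min break segments: no
distance is imputed across a gap. Stationary fixes are clustered by
k-means with k grown from 1 until every member is within 500 m (default)
of its centroid; dwell credits 5 min per fix. The seven features are
`location_variance` $= \log(\mathrm{var(lat)} + \mathrm{var(lon)} +
\varepsilon)$, the cluster count, entropy $-\sum p_i \ln p_i$ over dwell
fractions, normalized entropy $H/\ln k$ (defined 0 at $k = 1$, where the
ratio is 0/0 but there is genuinely no variability), circadian movement,
total transition distance and distance-weighted mean transition velocity.
$\varepsilon = 10^{-10}$ guards the logs because single-location traces
are legitimate input. Circadian movement is $\log(E_{lat} + E_{lon} +
\varepsilon)$ where $E$ is Lomb least-squares periodogram energy summed
over a 25-point period grid spanning 23.5–24.5 h. The band edges are a
design choice, not an external constant; they are configurable. The Lomb
implementation is the classic tau-shifted form, and for centered data its
energy equals half the regression sum of squares of the least-squares
sinusoid fit at that frequency — the identity the tests exploit as an
independent oracle.

**Semantic locations.** Participants label visited places during
assessment weeks; labels propagate to location clusters by nearest labeled
centroid within 200 m (default), ties broken by smallest distance then
lexicographic category, else `other`. Daily dwell minutes credit 5 min per
stationary fix, but only for episodes of ≥ 3 consecutive fixes in the same
cluster — a conservative enforcement of the "visited for more than 10
minutes" rule (two fixes span only 5 minutes of measured time).

**Communication and apps.** Daily sums of call/SMS counts, call seconds
and message characters; app foreground samples credit 5 min to their
mapped category (`active`, `information`, `social`; unmapped apps fall to
`other`, excluded from the feature groups). The map ships as editable
YAML. Days are local midnight-to-midnight using a per-participant UTC
offset; the day-boundary convention is a package decision since such
protocols rarely state one.

**Aggregation.** Base features are standardized (mean 0, variance 1,
$n-1$ denominator — stated so that $[1,2,3] \to [-1,0,1]$ exactly) across
*all* participant-windows jointly, then averaged with unit weights into
groups: Locations = {cluster count, location variance}; Time = {entropy,
normalized entropy, circadian movement}; Transitions = {distance,
velocity}; Calls and Text Messages = their three daily sums; the six
semantic and three app groups are their single standardized durations. A
group with some members missing is the mean of the present ones; all
missing means missing. Communication/app/semantic window values are means
of daily values over covered days (robust to missing days; summing would
confound missingness with level); GPS features are computed once over the
whole window because cluster counts and circadian rhythm are window-level
constructs. Windows with fewer than 7 of 14 covered days (half-window,
configurable) are treated as missing.

## Symptom clustering

k-means on the raw 32 baseline items (items share comparable 0–3/0–4
ranges; a config switch enables standardization), best of 50 restarts, k
scanned over 1–8. The elbow heuristic is operationalized as the largest
second difference of the inertia curve, a codeable stand-in for the visual
rule. Cluster indices are relabeled by ascending mean PHQ-8 so the
solution is reproducible up to content; at $k = 4$ the canonical profile
names are attached by rule (lowest PHQ-8 → minimal symptom; highest →
multiple comorbidities; the middle two split on relative SPIN vs GAD-7
elevation). Downstream analysis is keyed by cluster content, never by the
arbitrary k-means label.

## The synthetic cohort

The generator is the package's evidence that the inference chain works;
its defaults are fixed choices, not tuning knobs.

Each participant belongs to one of four symptom-profile groups (weights
88:71:69:54) with baseline totals drawn per group (e.g. the multiple-
comorbidities group is elevated on all three measures) and items
distributed uniformly over capped unit-score slots so items sum to totals
exactly. Symptom totals follow
$S_j = S_0 + e_j + \lambda \sum_{l<j} z_l$, where $e_j$ is a stationary
AR(1) process across check-ins (coefficient 0.6, marginal SD 2.5 points —
plausible short-term fluctuation for these scales) and $z_l$ is the
cohort-standardized change in the latent behavioral state averaged over
the preceding 14-day window. Because
$\Delta S = \lambda z + \Delta e$, setting
$\lambda = \operatorname{sd}(\Delta e)\,\rho/\sqrt{1-\rho^2}$ makes the
lagged change correlation equal the configured `coupling_rho` exactly in
expectation; integer rounding and scale clamping attenuate it mildly.
Totals are rounded and clamped to each scale's range.

The daily behavioral state $B_t$ is a stationary AR(1) with coefficient
0.9 (unit variance). The strong persistence reflects the week-scale
stability of mobility routines, and it matters structurally: with the
7-day overlap between one check-in's proceeding window and the next
check-in's preceding window, a forward-only coupling mechanically leaks
into the reverse-direction statistic with magnitude proportional to the
correlation between preceding- and proceeding-window *changes*. That
correlation is $-0.25$ for white daily noise but crosses zero near a daily
AR coefficient of 0.9, so with the default dynamics a forward coupling
produces a genuinely null reverse direction — which is what makes the
directional-specificity property testable at all. Users lowering
`ar_daily` substantially should expect a small spurious reverse
association of the opposite sign to the forward coupling; that is a
property of the window layout, not a bug.

Two resolutions are provided. `generate_cohort()` emits raw event
streams: GPS days of 288 five-minute fixes built from per-participant
anchor locations (home plus `n_anchors - 1` labeled places 0.5–3 km away),
where the probability of visiting each anchor increases with $B_t$, travel
is interpolated over 2–4 fixes, away dwells last ≥ 30 min, and every fix
gets 30 m Gaussian jitter (typical consumer GPS error); Poisson
call/SMS counts and app-sampling rates with log-links in $B_t$.
`generate_window_cohort()` emits standardized feature-group window values
directly — each group driven by its own independent latent daily process,
the coupled group by the same latent state that drives symptoms, plus
$N(0, 0.2^2)$ measurement noise. The lagged coupling is *defined* at the
window level, so the Monte-Carlo calibration studies (coupling recovery,
directional specificity, null false-discovery control) run on this path;
the raw-stream path is validated separately for the properties it owns
(feature monotonicity in $B_t$, conservation identities, schema and
round-trip fidelity, distance oracles). Running hundreds of raw-stream
cohorts would add cost, not evidence, to the window-level properties.

Missingness: post-baseline assessments are removed with probability
logistic in standardized baseline PHQ-8 (slope 1 by default), recentered
so the marginal rate matches `assessment_missing_rate` — missing *not* at
random, matching the empirical pattern that more severe participants miss
more assessments. Whole sensor days are removed jointly across streams at
`sensor_missing_day_rate`.

All randomness flows through one seeded Mersenne-Twister stream per
generator call (the caller's RNG state is preserved), so identical
configurations give identical cohorts.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use: coupling recovery and
directional specificity at $n = 200$ participants, five PHQ-8 pairs,
coupling $-0.3$ on Locations (100 seeds in the tests, 50 in the script);
null false-discovery control at coupling 0 over 100–200 cohorts of
$n = 100$–200; cluster recovery at $n = 150$–200; Monte-Carlo power with
3000–5000 replicates at $n = 255$. These sizes give Monte-Carlo standard
errors comfortably inside the asserted tolerances while keeping a full
run in minutes on one core.

## Limitations

- No map matching, altitude, GPS accuracy weighting, or realistic street
  trajectories; the generator's mobility is anchor-based.
- The generator specifies none of the distributional detail real sensor
  streams have (burstiness, weekday/weekend structure, device artifacts);
  passing synthetic-recovery tests demonstrates the *inference chain* is
  correct, not that real cohorts will show any particular effect.
- Aggregation is unit-weighted by design; data-driven weighting (PCA,
  factor models) is out of scope.
- The lag design estimates temporal precedence within 2-week windows only
  and supports no causal claims beyond that ordering.
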