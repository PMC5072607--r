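---
title: "Methods: developing and validating a four-item neuropathy screen"
author: "chant package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developing and validating a four-item neuropathy screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chant)
```

## The problem

HIV-associated sensory neuropathy (HIV-SN) is a length-dependent distal
symmetrical polyneuropathy affecting roughly half of patients on
antiretroviral therapy, often with neuropathic pain. Definitive diagnosis
needs quantitative sensory testing (QST), skin biopsy for intraepidermal
nerve fibre density (IENFD), and specialist examination — none of which are
available in the busy HIV clinics, high- or low-resource, where most
patients are seen. The practical alternative is a brief screen: a handful of
bedside items, each dichotomised at a clinical cutoff, combined by a simple
rule.

This package implements, end to end, the statistical machinery for building
and validating such a screen around four bilateral items — feet pain and
feet numbness (symptoms, 0–10 ratings), timed great-toe vibration sense and
ankle reflexes (signs) — and for the second-stage triage of neuropathic pain
using the 7-item pain interview (DN4-I) plus a body map. Because the
underlying patient-level cohorts are not publicly deposited, the package
ships a calibrated synthetic-cohort generator so that every stage is
testable and reproducible.

## The synthetic cohort model

One latent class (neuropathy, prevalence $\pi$) and one latent severity
$S$ drive everything:

$$S \mid \text{control} \sim N(0, 1), \qquad S \mid \text{case} \sim N(\delta, 1).$$

Each screening item $i$ has a side-level latent
$T_{i,\mathrm{side}} = w_i S + \sigma_i \varepsilon_i + \tau \varepsilon_{\mathrm{side}}$,
where $\varepsilon_i$ is shared by the two feet (the item's measurement
context) and $\varepsilon_{\mathrm{side}}$ is side-specific. Observed values
are affine in $T$ — oriented so that pain/numbness are abnormal high,
vibration seconds abnormal low, and reflexes are graded ordinally
(0 normal, 1 hypoactive, 2 absent) by two thresholds on $T$.

**Calibration.** Given a target per-item accuracy $(se_i, sp_i)$ against
latent status, define $k_i = \Phi^{-1}(se_i) + \Phi^{-1}(sp_i)$. Placing the
decision threshold at $t_i = \sigma_{tot,i}\,\Phi^{-1}(sp_i)$ and solving
$w_i \delta = \sigma_{tot,i} k_i$ (with
$\sigma_{tot,i}^2 = w_i^2 + \sigma_i^2 + \tau^2$) makes the dichotomised
item reproduce $(se_i, sp_i)$ exactly in expectation. The solution requires
$\delta > k_i$: an item cannot be more accurate than the class separation
allows. The generator then maps $t_i$ onto the published clinical cutoff of
each item (pain $\ge 5.5$, numbness $\ge 2.55$, vibration $\le 13.2$ s,
reflex grade $\ge 1$), so those cutoffs are the generating truth that the
development machinery should rediscover.

**Why the severity shift controls internal consistency.** With the per-item
accuracies held fixed, the within-class correlation between two items'
latents is bounded by $k^2/\delta^2$ — it does not depend on the noise
scale, only on how much of the fixed discriminating signal flows through
the shared severity. Two profiles are therefore provided as study
conditions rather than dials:

* `severity_shift = 3` (default) — a well-separated deep-phenotype
  development cohort; prevalence defaults to 0.42 (28/66).
* `severity_shift = 1.7` — a clinic validation profile in which the four
  items cohere strongly; with the default accuracy targets this implies a
  Cronbach $\alpha$ near the reported 0.88. (At $\delta = 1.7$,
  the marginal inter-item latent correlation is about 0.87, and binary
  attenuation brings the 4-item $\alpha$ to $\approx 0.88$.)

Default accuracy targets are the reported per-item values: pain
(0.74, 0.81), numbness (0.778, 0.632), vibration (0.74, 0.81), reflex
(0.857, 0.684). Observed scales (units per latent SD: pain 2, numbness 1.5,
vibration 3 s) were chosen for clinical realism — e.g. a within-class
vibration SD of ≈3.5 s and control mean ≈16 s match normative timed-vibration
spreads. Reference-standard components (clinical signs, 13 QST z-scores,
lognormal IENFD), the examination score (linear in $S$, split binomially
over sides), the body-map flag and interview items are drawn per class with
probabilities stated in `?cohort_config`.

**Second rater.** Binary fields flip independently with probability 0.02;
continuous values receive Gaussian remeasurement noise with SD 0.15, chosen
so that the induced flip rate of the dichotomised side items matches the
2% binary flip rate — the agreement level implied by the reported
inter-tester rank correlations (minimum 0.933). Reflex grades take a
one-step move with the same probability.

**What the generator does not emulate.** Demographics, treatment exposure,
item non-response, floor/ceiling heaping of integer rating scales, and any
non-Gaussian shape of real measurands. Passing tests demonstrate that the
machinery is correct and well-calibrated under this generative model, not
that the published instrument performs identically on real patients.

## Reference standards

* **Composite 2-of-3 case definition**: clinical signs, $\ge 2$ of 13 QST
  parameters abnormal, IENFD $\le 7.63$ fibres/mm (boundary inclusive, as
  printed). QST abnormality uses the two-sided band $|z| > 1.96$ by default;
  the source definition says only "abnormal", so the threshold is exposed.
* **Symmetric examination proxy**: total score (right + left) $\ge 8$, with
  an asymmetry exclusion — if the smaller side carries less than 25% of a
  cutoff-reaching total, the patient is flagged and excluded (verdict `NA`,
  never "negative"). The source states the intent (exclude high unilateral
  scores) without a formula; the 25% minimum-side share is a declared
  stand-in, exposed as a parameter.

## Cutoff machinery

Operating characteristics are evaluated at thresholds placed halfway
between adjacent distinct values (plus one beyond each end), so inclusive
and strict comparison coincide and both degenerate ends (all-positive,
all-negative) are represented. Comparisons are inclusive on the abnormal
side, matching the printed "$\ge 5.5$" / "$\le 13.2$" conventions.

Four cutoff-selection criteria are computed per measurand:

1. **Sensitivity/specificity crossover** — curves treated as piecewise
   linear in the cutoff; if they touch over an interval, the midpoint is
   returned.
2. **Predictive-value crossover** — PPV and NPV curves, same interpolation,
   restricted to cutoffs where both are defined.
3. **Likelihood-ratio balance** — the literal crossing of $LR+$ and $LR-$
   has no interior solution ($LR+ = LR-$ iff $sens + spec = 1$, which an
   informative test attains only at the extremes), so the criterion is
   operationalised as $\log LR+ = -\log LR-$: the cutoff where a positive
   and a negative result carry equal evidence. This reduces to
   $sens(1-sens) = spec(1-spec)$, computed in that product form so it stays
   defined at degenerate operating points.
4. **Minimum misdiagnosis cost** — with error weights $c_{fp} = 1$,
   $c_{fn} = 2$ (a missed case costs twice a false alarm),
   $$cost(c) = \frac{c_{fp}\,FP(c) + c_{fn}\,FN(c)}{c_{fp}N_- + c_{fn}N_+} \in [0,1],$$
   zero only for perfect classification. The published cost column values
   use an unstated normalisation and are not reproducible without the raw
   data; this formula is the package's documented choice. The $c_{tp}$,
   $c_{tn}$ weights are carried for fidelity but are inert. Cost ties
   resolve to the tied cutoff closest to the sensitivity/specificity
   crossover.

The consensus cutoff is the geometric mean of the four. Small-sample wobble
can produce several crossings; these resolve deterministically to their
median. Scales containing zero use a documented offset transform
($+1$ before, $-1$ after). The AUC is the concordance probability with ties
counted one half, identical to the trapezoid over the empirical curve.

Effect sizes use $\eta_p^2 = SS_{effect}/(SS_{effect}+SS_{error})$ from the
linear-model decomposition with any covariates entered first; the default
is factor-only, since the source does not state which covariates entered
its covariance-adjusted analysis.

In `develop_chant()` the per-patient summary of each item is the mean of
the two sides: the instrument is explicitly bilateral, and the side mean is
the symmetric summary whose dichotomisation point coincides with the
per-side generating threshold.

## The combination rule and its rubric

Side values are dichotomised and tallied per item (0, 1, or 2 abnormal
sides); a tally of 2 is "bilateral". The published wording "present ('0')
or absent ('1')" conflicts with the rubric's 0/1/2 entries; the package
adopts the tally reading, which the rubric requires. The canonical
**verbal rule** is

> (bilateral feet pain OR bilateral reduced vibration) AND
> (bilateral feet numbness OR bilateral reduced ankle reflex).

Exhaustive enumeration over all $3^4 = 81$ tally quadruples shows the
verbal rule accepts 25 of them, a strict superset of the 21 rows printed in
the rubric; the four extras all have bilateral pain and bilateral absent
reflex without bilateral numbness or vibration. Whether their omission was
deliberate or typographical cannot be determined from the text, so both
rules are implemented (`verbal` is canonical; `table2_strict` reproduces
the 21 printed rows verbatim) and the disagreement is surfaced by
`rubric_discrepancy()` and in pipeline logs, never silently resolved.

The in-silico **alpha test** interprets "all possible cutoff combinations"
as every non-constant monotone Boolean function of the four bilateral
indicators — monotone because a clinical abnormality can only add evidence
for disease. Brute force over all $2^{16}$ truth tables yields 168 monotone
functions (the Dedekind count for four variables), 166 after removing the
constants. Candidates are ranked by Youden index with a deterministic
lexicographic tie-break.

## Pain triage

The interview uses the 7 interview-only items of the 10-item instrument
(the three examination items are excluded by construction), positive at the
inclusive cutoff $\ge 3/7$. Bilateral feet pain (BFP) requires both foot
regions of a fixed body-map vocabulary; finer anatomy is out of scope. The
five triage categories — neuropathic pain, pain of probably neuropathic
origin (POPNO: BFP with a sub-threshold interview), neuropathy without BFP,
screen-negative with BFP (referred for follow-up), and no neuropathy —
partition the input space; the test suite asserts this exhaustively.

## Validation statistics

Likelihood ratios follow the standard definitions with no continuity
correction ($LR+ = \infty$ at perfect specificity, matching the source's
printed $LR- = 0$). Post-test probabilities use exact odds arithmetic
rather than nomogram reading; consequently the field-test cohort's
printed LR of 5.29 and post-test 92% — read off a nomogram graphic — come
out as 5.21 and 91% under exact arithmetic from the same 2×2 table. The
package computes exactly and reports the comparison instead of asserting
the graphic's values.

Item-total correlations are **corrected** (item vs rest-score) Spearman
correlations with midranks; the uncorrected variant is available via
`corrected = FALSE` but inflates each item's value through
self-correlation. Cronbach's $\alpha$ uses unbiased variances. The content
validity ratio is Lawshe's $(n_e - N/2)/(N/2)$. Percentages are rounded to
the published precision only in the reporting layer; internal values keep
full precision.

## Numerical choices and problem sizes

Tests calibrate against independent brute-force oracles (pair-counting
AUC, hand-built midranks, explicit sums of squares) on fixtures of up to a
few hundred patients, where exact equality is asserted. Monte-Carlo
calibration checks use cohorts of $n = 5000$ (per-item accuracy within
±0.03; threshold recovery and alpha-test accuracy across seeds 1–5) and
$n = 1000$ for reliability — sizes chosen to keep binomial error well
inside the asserted bands. All randomness flows through explicit seeds; no
global random state is used (the generator saves and restores the R RNG).

## Known limitations

* The published development table's AUC, crossover and cost values cannot
  be reproduced jointly with the published per-item sensitivities and
  specificities by any near-equal-variance one-dimensional generator: for
  feet pain, calibrating to (0.74, 0.81) implies an AUC of
  $\Phi(k/\sqrt2) \approx 0.86$ and a crossover accuracy of ≈78%, versus
  the printed 0.79 and 69%. The tests therefore check the AUC against the
  value the calibration implies, not the printed one.
* Similarly, an AND-of-ORs rule cannot reach the reported 90% rule-level
  specificity under the reported per-item specificities with non-negative
  inter-item correlation; the alpha test's top-ranked (Youden) rule on
  calibrated cohorts is a slightly stricter monotone rule, with
  specificity around 0.86–0.87.
* The four criterion cutoffs estimate trade-off operating points (e.g. the
  equal-error point), not the generating threshold itself, so their
  geometric mean carries a small systematic offset whenever the target
  sensitivity and specificity differ. On the vibration scale (seconds per
  latent SD = 3) this offset is a few tenths of a second and the recovery
  check in the test suite occasionally exceeds its ±0.5 s band.
* Asymmetry exclusion (25% minimum-side share) and the QST normative band
  ($|z| > 1.96$) are declared stand-ins for verbally-stated intents.
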