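---
title: "Methods: the pediatric O-RADS rule engine and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pediatric O-RADS rule engine and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oradsped)
```

## The classification model

`classify_orads()` operationalizes the O-RADS MRI score for pediatric
adnexal lesions as a strict decision tree over structured descriptors.
The tree is evaluated in a fixed order — no mass, peritoneal disease,
intralesional fat, solid tissue, cystic morphology — and the first branch
taken decides the class; descriptors irrelevant to that branch are
deliberately ignored rather than rejected, because a radiologist's record
of, say, the locularity of a fatty lesion is extra information, not an
error. This makes the engine total and deterministic: the test suite
enumerates every boolean/enum combination that satisfies the schema
invariants (with enhancing-component diameters straddling the 8-cm
threshold) and checks exactly one class in 1–5 comes out, twice, and that
the vectorised cohort path agrees with the scalar tree everywhere.

Assumptions worth making explicit:

* **The 8-cm rule routes to class 5, inclusive.** A fat-containing lesion
  whose enhancing component reaches 80 mm is treated as high risk
  (class 5), not class 4. Pediatric fatty lesions are overwhelmingly
  mature teratomas; the one malignant teratoma pattern in the motivating
  cohort is exactly a large enhancing area within fat, and the cohort's
  tabulated counts only reproduce under this routing. The comparison is
  `>= 80` mm (`LARGE_ENHANCING_THRESHOLD`), with the boundary tested at
  79.9 / 80.0.
* **Dark-dark solid tissue is class 2.** Homogeneously T2-hypointense,
  homogeneously non-restricting solid tissue is the classic benign
  fibroma pattern. No such lesion occurs in the canonical cohort, so this
  branch rests on the parent framework, not on pediatric evidence — the
  margin summary tracks the pattern precisely so a user can see when that
  changes.
* **Endometriotic fluid in a unilocular cyst is class 2 regardless of
  wall enhancement.** Endometrioma walls commonly enhance; enhancement is
  only allowed to raise the class for hemorrhagic/proteinaceous fluid,
  where it distinguishes a bland cyst from one needing follow-up.
* **Ascites alone does not trigger the peritoneal branch.** The branch
  requires nodularity or irregular thickening; ascites is a frequent,
  nonspecific pediatric finding.
* **peritoneal disease without a mass is a validation error**, not a
  class-1 case: the tree would silently ignore it, so the validator
  refuses it instead.

`classify_simplified()` is the two-level pediatric reading: likely
malignant iff peritoneal disease, a large enhancing component within fat,
or non-fatty solid tissue. It agrees with the low/high dichotomy of the
full score (`dichotomize_orads()`: classes 1–3 low, 4–5 high) for every
valid descriptor combination except dark-dark solids, which it still
flags — a sensitivity-first choice for a pattern with no pediatric data
behind it, verified as the *only* divergence by the grid test.

## Validation statistics

**Proportion intervals.** Two methods are carried side by side because
small validation cohorts genuinely need both: the Wilson score interval
behaves well at zero events (every low-risk class in the motivating
cohort has zero malignancies), while Clopper–Pearson is the exact,
conservative choice for tiny cells like 1 of 2. `binom_ci()` selects by
name; reports can print both. Display rounding is to whole percents,
half away from zero. One caution established by exact enumeration in
the tests: Wilson's true coverage oscillates at very small n (about
0.91–0.92 at n = 10 for p between 0.05 and 0.7) before settling within
two points of nominal by n = 50; Clopper–Pearson stays at or above
nominal throughout the tested grid.

**Weighted kappa.** `weighted_kappa()` implements linearly weighted
Cohen's κ over an ordered category set, `w_ij = 1 − |i − j|/(K − 1)`,
with expected agreement from the product of observed marginals. With two
categories the weights degenerate to unweighted κ (tested against an
independent 2×2 computation). When both raters are constant on one
category the expected agreement is 1 and κ is undefined; the result
carries an explicit `undefined` flag instead of a misleading number.

**Predictor screening.** With seven events among 109 patients and
predictors that separate the outcome completely (every peritoneal-disease
lesion is malignant), ordinary maximum likelihood diverges. All screening
therefore runs Firth penalized logistic regression: the modified-score
IWLS with the hat-diagonal correction, step-halving against the penalized
log-likelihood, convergence when the largest modified-score component
falls below 1e-8 (cap 200 iterations). P-values are penalized
likelihood-ratio tests computed by constraining one coefficient to zero
and re-maximizing the *same* penalized likelihood — not by refitting a
smaller design, which changes the penalty and, for a perfectly balanced
2×2 table, fails to return p = 1. The fit is cross-checked in the tests
against a direct BFGS maximization of the penalized log-likelihood and
against plain `glm()` on a well-conditioned n = 2000 recovery problem
(known log-odds 1.5, bias under 15%).

`screen_predictors()` screens each predictor **individually** by default,
with `joint = TRUE` giving one multivariable model. The default is a
deliberate design decision. On the canonical cohort the
composition/fat/malignancy cross-table is completely determined by the
cohort margins (48 fatty lesions with 2 malignancies, 45 purely cystic
with none, 3 peritoneal all malignant), and in any joint model the fat
term — which cleanly splits the solid-component stratum — comes out
*more* significant than composition. Per-predictor screening is what
reproduces the clinically reported pattern for cohorts of this shape:
peritoneal disease and composition dominant, fat protective but weaker,
age, size, septation and fluid type uninformative. For a rare-event
cohort of this size the univariable tests are also simply the more
honest summary; a seven-covariate joint model with seven events leans
heavily on the penalty.

**Continuous summaries.** `summarize_continuous()` fixes the percentile
convention at linear interpolation between order statistics
(`quantile(type = 7)`); conventions differ enough across software that
IQR endpoints on small integer samples depend on the choice.

## The synthetic cohort

`canonical_cohort()` is a deterministic, code-built table of 109 records
that reproduces the motivating cohort's printed margins exactly: class
counts 7/68/23/2/9, malignancy 0/0/0/1/6, the class-2 fat/cystic overlap
(46 fatty, 63 cystic, 41 both), class-5 composition (3 peritoneal of
which one fatty, 1 fat-with-large-component, 5 hyperenhancing solid), the
seven malignant histologies, age median 13 (IQR 11–15) years, lesion size
median 62 (IQR 45–110) mm, and 54 right / 48 left. Ages and sizes are
fixed multisets pinned so the type-7 quantiles hit the printed values
exactly (duplicated order statistics at the interpolation points).
Free choices the margins do not determine are made once and documented:
the class-3 split is 12 multilocular / 11 unilocular non-simple with
enhancing walls; the three peritoneal records carry the borderline-tumor,
rhabdoid and one dysgerminoma histology; sizes for the eleven class-4/5
lesions are spread evenly over the size distribution, since lesion size
was reported not to discriminate malignant from benign lesions and an
accidental size–class correlation would contradict that.

Two inconsistencies in the source tables cannot be satisfied jointly with
the class totals; the fixture resolves both toward the authoritative
counts and `repro_report()` flags them instead of hiding them: the
class-5 malignant count is 6 (the 6/9 results figure; the table's "7
(75%)" is incompatible with seven total malignancies), and the simplified
split is reported over all 109 records (11/98) where the source prints
11 + 93 = 104 without explaining the five missing patients.

`generate_cohort()` is the stochastic counterpart: intended class from
the class mixture, descriptors from class-appropriate archetypes so the
engine reproduces the intended class with probability one (the round-trip
is asserted over 10,000 seeded records), malignancy from per-class
probabilities, ages from a rounded normal (mean 13, sd 2.97, truncated to
4–18), sizes from a log-normal (median 62 mm, quartile ratio 110/45),
laterality Bernoulli(54/102). What it emulates is the *statistical
shape* of a pediatric referral cohort — mixtures, rates, demographics —
not real data's feature correlations (size–age, histology-specific
morphology), reader noise, or missingness. Tests passing on generated
cohorts therefore certify the pipeline's arithmetic and contracts, not
clinical performance on new patients.

## Problem sizes and numerical choices

The default suite runs the full descriptor grid (57 valid combinations),
the 109-record canonical fixture, a 10,000-record round-trip, a
50,000-record margin check (each empirical margin within three binomial
standard errors of its generator input), a 10,000-replicate coverage
simulation over p ∈ {0.05, 0.3, 0.7} × n ∈ {10, 50}, and an n = 2000
regression-recovery problem — sizes chosen so the whole suite stays
comfortably under a minute on a laptop while keeping Monte-Carlo noise
far below every asserted tolerance. Probability vectors must sum to one
within 1e-9; diameters are millimetres, ages whole years; CSV booleans
are lowercase `true`/`false` with uppercase accepted on input but never
written.

## Limitations

The engine consumes structured descriptors; it does not read images, so
inter-reader variability enters only through the optional second-reader
column. Dynamic contrast (time–intensity curve) scoring is out of scope,
as are tubal/paraovarian lesions and incomplete-exam (class 0) handling.
The dark-dark and endometriotic branches follow the parent framework
without pediatric evidence. The canonical fixture reproduces margins, not
patients: statistics that depend on joint feature distributions beyond
those margins (notably joint-model regression coefficients) are
fixture-dependent and should be read qualitatively.
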