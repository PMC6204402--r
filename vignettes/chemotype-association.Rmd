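---
title: "Methods: vote-weighted chemotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vote-weighted chemotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemovote)
```

## The design being analysed

A licensed producer's patients vote the strains they found most and least
effective for anxiety (multi-select allowed) and rate overall effectiveness
on a 0–10 Likert scale. Each named strain is linked to laboratory panels of
its last three production lots: four cannabinoids as total potential
(acid + neutral), thirty terpenes, and a total-terpenes aggregate, all in
% w/w. The analysis asks which constituents separate the preferred from the
non-preferred chemotypes.

Two facts about such data shape everything below:

* votes are *preferences*, not measurements — a strain's vote count scales
  the influence of its lot values but adds no analytical replication;
* a lot–analyte cell can be *not tested* (a laboratory that does not assay
  four of the terpenes), which is a different datum from a measured zero.
  Measured zeros are real (many constituents are absent from a chemotype);
  not-tested cells are removed together with their weight from that
  analyte's denominator only.

## The weighted profile

For analyte $a$ and the top-$k$ strains of a category (default $k = 4$,
ties broken alphabetically after sorting by votes), every measured lot
value $x_i$ carries its strain's vote count $V_{s(i)}$:

$$\mathrm{WA}_a = \frac{\sum_i V_{s(i)} x_i}{\sum_i V_{s(i)}},\qquad
  \mathrm{SD}_a = \sqrt{\frac{\sum_i V_{s(i)} (x_i - \mathrm{WA}_a)^2}
  {\sum_i V_{s(i)}}}.$$

With integer votes these are exactly the mean and population SD of the
sample in which each lot value is replicated $V_s$ times — the
*vote-expansion oracle* that the test suite checks on a thousand random
instances. The reported standard error is $\mathrm{SD}_a/\sqrt{n_a}$ with
$n_a$ the number of contributing lot measurements (12 per group when
complete): votes are preference weights, so using the vote total as a
sample size would understate uncertainty by an order of magnitude.

## The association coefficient

$$\mathrm{cc}_a = \frac{\mathrm{WA}_{a,\mathrm{me}} -
  \mathrm{WA}_{a,\mathrm{le}}}{\mathrm{WA}_{a,\mathrm{me}} +
  \mathrm{WA}_{a,\mathrm{le}}} \in [-1, 1]$$

is antisymmetric under group swap, scale-invariant, and hits $\pm 1$
exactly when a constituent is absent from one group; it is undefined
(`NA`) when absent from both. Its standard error is propagated from the
two group SEs by the delta method. All computation is at full precision;
three decimals are used only for display.

A reproduction note: recomputing the coefficient from *rounded, printed*
group averages is numerically fragile whenever the denominator
$\mathrm{WA}_\mathrm{me} + \mathrm{WA}_\mathrm{le}$ is small. At three
printed decimals the operand rounding error alone can move the coefficient
by $0.001/(\mathrm{WA}_\mathrm{me} + \mathrm{WA}_\mathrm{le})$ — 0.05 for
a denominator of 0.02 — and a printed `0.000` may stand for any
concentration below 0.0005 % w/w, which flips a coefficient between, say,
$-0.84$ and exactly $-1$. The packaged reference table
(`reference_weighted_averages()`) therefore reproduces exactly only the
rows whose printed operands are self-consistent with their printed
coefficient; the remainder require the unrounded source data.

## The significance test

The null hypothesis is a zero difference of the two group weighted means.
The test is a summary-level Welch (unequal-variance) $t$ with a
Satterthwaite approximation, applied to the weighted summaries. Because the
weights are unequal, two corrections are required for the test to attain
its nominal size, both reducing to the classic Welch test at equal
weights:

* the population-denominator weighted SD is Bessel-corrected for
  reliability weights, dividing by $\sqrt{1 - \sum w_i^2/(\sum w_i)^2}$;
* the variance of a weighted mean is $\sigma^2 \sum w_i^2/(\sum w_i)^2$,
  i.e. $\sigma^2/n_\mathrm{eff}$ with the Kish effective sample size
  $n_\mathrm{eff} = (\sum w_i)^2/\sum w_i^2$, so the standard error uses
  $n_\mathrm{eff}$ while the Satterthwaite degrees of freedom use the
  actual measurement counts (the variance estimate is built from $n$
  observations, not $n_\mathrm{eff}$).

These choices were fixed by simulation during design: without them the
test's measured size at $\alpha = 0.05$ was 0.065–0.09 (no Bessel
correction, weight inequality ignored) or drifted conservative; with them
it is 0.049 under both normal and lognormal lot noise at the study's
sample sizes (200,000-draw checks). Degenerate inputs are defined
explicitly: both SDs zero with equal means gives $t = 0, p = 1$; with
unequal means, $p = 0$ plus a degenerate-variance flag.

Significance flags mirror the reporting convention `*` ($p < 0.05$) and
`#` ($0.05 \le p < 0.10$) and are deliberately unadjusted — the design
this package mirrors applies no multiple-testing correction across its 33
constituents — but a Benjamini–Hochberg column is emitted alongside as a
clearly-labelled extension.

One caveat the analysis inherits from its design: when the same strain
appears in both preference groups (always the case with 7 strains and two
groups of 4), the groups share lot measurements and the two-sample test's
independence assumption fails, biasing it conservative. The association
table is still produced — the original design has exactly this overlap —
but calibration claims are only meaningful for disjoint groups (below).

## The synthetic-data generator

The generator is first-class, tested code whose defaults emulate the
study conditions end to end.

**Chemotypes.** Four archetypes (kush, myrcene-dominant,
terpinolene-dominant, type II) span the observed chemotype space, with
cannabinoids at 0–19 % w/w and terpenes at 0–0.5 % w/w; the
terpinolene-dominant archetype carries the co-occurring minor terpenes
(α-phellandrene, 3-carene, α-/γ-terpinene) that act as chemotype markers.
Lot values are archetype mean × unit-mean lognormal noise —
concentrations are positive and right-skewed, and the noise-free limit
(`lot_cv = 0`) returns the means exactly. The default lot CV of 0.12 is
the empirical CV of the three published THC lot values (16.6, 19.4,
21.0 % w/w) in the worked example this generator emulates. The study
configuration simulates 7 strains × 3 lots with two lots not tested for
trans-nerolidol, eucalyptol, γ-terpinene and α-terpinene, reproducing the
two-laboratory coverage mask.

**Voting.** Respondent $r$'s latent utility for tried strain $s$ is

$$u_{rs} = \mathrm{pop}_s + \sum_a w_a \, \mu_{s,a} + \varepsilon_{rs},
  \qquad \varepsilon_{rs} \sim N(0, \sigma_r^2),$$

with $\mu_{s,a}$ the strain's *ground-truth* (archetype-mean)
concentration and $w_a$ the planted, recoverable effect weights. Linear
utility is the simplest mechanism whose ground truth the
difference-over-sum statistic should recover in sign.
$\mathrm{pop}_s$ (default 0) is a chemotype-independent popularity
offset — preference heterogeneity that has nothing to do with chemistry.
Respondents vote every tried strain within a utility margin of their best
(worst) strain as most (least) effective, reproducing multi-select
behaviour; a strain within the margin of both extremes is dropped from
both sets, and a fully tied respondent falls back to a deterministic
alphabetical tie-break. A respondent never votes the same strain in both
categories; cross-respondent disagreement (the same strain in both
*aggregate* groups) arises naturally. The Likert rating is an affine map
of the respondent's best tried utility, rounded and clamped to 0–10.
Category and rating response rates default to the study's 219/442,
189/442 and 260/442.

**What the defaults were set to.** The remaining free constants (effect
weights on THC, trans-nerolidol, terpinolene, guaiol and CBD; respondent
noise SD 3; vote margin 0.15; Likert map $3.2 + 1.0\,u$) were chosen once
so that the simulated survey lands near the published descriptives — the
kush trio plus one myrcene strain preferred, the terpinolene-dominant
strain voted least effective most often, Likert mean ≈ 8.0 / SD ≈ 1.6
with ~85% of ratings ≥ 7 — and were not revisited. What the generator
does *not* emulate: biphasic dose response, set-and-setting covariates,
longitudinal dosing, recall and selection bias, or cross-producer strain
name collisions. Passing tests therefore validate the *arithmetic and its
operating characteristics under the stated model*, not the
epidemiological reliability of any real survey.

## Calibration and recovery experiments

`run_recovery_experiment()` replays the full
tally → profile → association pipeline over replicated synthetic data and
scores the result against the planted weights. A replicate is excluded
(and its reason counted) when a vote category is empty, when fewer than
$k$ strains received votes, or when the two top-$k$ groups overlap — in
the overlap case the two-sample comparison shares data between its own
groups and neither calibration nor recovery is interpretable.

* **Null calibration** uses 8 strains sharing one archetype, all effect
  weights zero, and a spread of popularity offsets. Every systematic
  difference between the groups is then preference, not chemistry, the
  no-association null holds exactly, and the groups are almost always
  disjoint. At 500 replicates the false-positive rate at $\alpha = 0.05$
  is ~0.048 (Monte-Carlo SE ~0.002, computed from the spread of
  per-replicate false-positive fractions).
* **Signal recovery** plants a single analyte gradient across 8 strains
  with a strong positive utility weight: at low respondent noise the
  coefficient's sign is recovered on every valid replicate, and the mean
  recovered coefficient decays monotonically as respondent noise grows
  (checked at noise SDs 0.25, 2 and 6 with common base seeds).

Problem sizes used by the shipped experiments — 500 null replicates, 100
strong-signal replicates, 60 per noise level — give Monte-Carlo precision
comfortably below the effect sizes being checked while keeping a full
suite run in about a minute.

## Numerical and interface decisions

* Seeds: every generator call is deterministic given `sim_config$seed`
  (assays use `seed`, the survey `seed + 1`, replicate $i$ of an
  experiment `seed + 2i`), and the caller's RNG stream is left untouched.
* Ranking ties: votes descending, then alphabetical — the reference
  rankings contain no ties, and a deterministic rule is required for
  reproducibility. A catch-all "Others" label is tallied but excluded
  from rankings by default.
* Side-effect percentages use a configurable denominator (default:
  respondents reporting at least one side effect), because published
  tables of this kind are often ambiguous about theirs; the reference
  table's header count and printed percentages imply different
  denominators (442 vs 422), and the package does not guess beyond the
  configurable default.
* Likert summary: sample SD ($n-1$), Student-$t$ 95% CI, median of the
  central pair for even $n$, rated respondents only.
* Not-tested handling is `exclude` by default; `as_zero` is provided only
  as a sensitivity mode, since published averages with exact `0.000`
  entries show below-LOD values entering as measured zeros while the
  coverage gaps were presumably excluded.
* CSV dialects: long-format assays (`strain,lot,lab,analyte,value`;
  empty = not tested, `0` = measured zero), one-row-per-respondent
  surveys with semicolon-delimited multi-select fields; analyte names are
  canonicalized against the packaged panel with Greek-letter and
  single-letter prefix variants mapped. Report tables display three
  decimals; a full-precision companion table and a JSON manifest
  (config + MD5) make every bundle regenerable bit-identically.

## Known limitations

* The coefficient compares *weighted group means* only; bimodal
  constituents (a type-II strain's CBD, a single terpinolene-dominant
  strain) violate the implicit unimodality, and their p-values should be
  read cautiously — the same caution the original design calls for.
* With 7 strains the preference groups necessarily overlap, so the
  reported p-values for the study-emulating configuration are mildly
  conservative (shared lots correlate the group means).
* The generator's voting model is cross-sectional and noise-additive; it
  cannot produce within-respondent contradictions or dose effects.
* No multiple-testing correction is applied to the headline flags (by
  design, mirroring the reference analysis); use the `p_adjusted` column
  when error control across the panel matters.
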