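---
title: "Multi-criteria health priority setting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-criteria health priority setting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthrank)
```

## The problem

Regional health authorities must decide which health conditions deserve
priority attention when resources are finite. `healthrank` operationalizes
that decision as a weighted additive multi-criteria decision analysis
(MCDA): health conditions are scored on five criteria — scale of disease
(Scale), household financial effect (HFE), cost-effectiveness of available
interventions (CE), health equity (Equity), and multimorbidity burden
(Multimorbidity) — the criteria are weighted by elicited public preferences,
and conditions are ranked by the composite score

$$A_{score} = \frac{w_s \cdot Scale + w_h \cdot HFE + w_c \cdot CE +
  w_e \cdot Equity + w_m \cdot Multimorbidity}{100},$$

with the $w$'s integer percentage weights summing to 100. The score is
ordinal: it orders conditions but its ratios carry no meaning, and the
package's output says so.

## Preference elicitation and the preference matrix

Public preferences are collected on a 5-point ordered verbal scale
("Not at all important" = 1 ... "Extremely important" = 5), one question per
criterion. Responses form the $P \times Q$ preference matrix $A$ with
entries $a_{ij} \in \{1, \dots, 5\}$ ($P$ respondents, $Q = 5$ criteria).
Missing answers are handled by listwise deletion by default
(`missing_policy = "drop_respondent"`), with the exclusion count reported in
the decision log; an `error` policy is available for strict pipelines.

Subgroup comparisons (e.g. by ethnicity or age band) use Welch's
unequal-variance two-sample $t$-test, two-sided, and a percentage mean
difference $100(\bar{x}_{g1} - \bar{x}_{g2})/\bar{x}_{g2}$ computed on
unrounded means. The Welch form is the right default for ordinal survey
scores with unequal subgroup sizes and variances. The denominator group is
configurable since the convention is not standardized. When any criterion's
absolute difference exceeds the stratification threshold (default 5%),
separate subgroup weight vectors are computed; otherwise the pooled matrix
is used. When weights are stratified, pooled-matrix weighting remains the
default for any single "all respondents" computation — averaging the
subgroup vectors instead is possible but not the default, and the choice is
recorded in the run log.

## Two weighting methods

**Normalized-sum weights.** The matrix total $s = \sum_i \sum_j a_{ij}$
normalizes each entry; column sums of the normalized matrix give each
criterion's share of the total expressed preference mass. This method
preserves the *cardinal* information in near-equal preference profiles.

**Rank-order-centroid (ROC / SMARTER) weights.** Criteria are first ranked
by descending median preference (midpoint convention for even counts), ties
broken by descending mean, residual ties by declaration order (flagged).
The criterion at rank $i$ of $n$ receives the centroid weight

$$w_i = \frac{1}{n} \sum_{j=i}^{n} \frac{1}{j},$$

which depends only on the ordering. For $n = 5$ the raw fractions are
(0.4567, 0.2567, 0.1567, 0.0900, 0.0400). ROC is preferable when only an
ordinal ranking is trustworthy; when raw preferences are near-equal it
forces a much wider spread than respondents expressed, so the package
surfaces the fraction spread for the analyst rather than switching methods
automatically.

## Hare–Niemeyer rounding

Both methods end with integer percentages that must sum to exactly 100.
The largest-remainder (Hare–Niemeyer) procedure floors each quota
$100 f_i$ and hands the $100 - \sum \lfloor 100 f_i \rfloor$ leftover seats
to the largest fractional remainders. Two numerical choices matter:

* **Equal-remainder ties** are resolved in favour of the earlier tie-order
  position (the higher-ranked criterion, or the earlier-declared one). This
  is not cosmetic: for $n = 5$ ROC the three remainders are all exactly
  $2/3$, and only this rule yields (46, 26, 15, 9, 4) rather than, say,
  (46, 25, 16, 9, 4).
* **Float noise**: remainders are compared after rounding to 9 decimals, so
  analytically exact ties (like those thirds) are recognized as ties
  instead of being ordered by floating-point accident; quotas get a
  $10^{-9}$ guard before flooring for the same reason.

Raw fractions are carried at full precision until this single rounding
step; by default the *integer* percentages (not the raw fractions) enter
the composite score, matching the published sequencing of rounding before
combination. `rank_conditions(..., use_raw_fractions = TRUE)` provides the
sensitivity variant.

## Indicator-to-level maps

Raw indicators map to 1–5 impact levels through fixed bands whose boundary
semantics are preserved exactly as printed in their sources, including the
two dialects:

| Criterion | Indicator | Bands | Boundary dialect |
|---|---|---|---|
| Scale | share of national DALYs (%) | 1, 2, 3, 5 | closed-left (`>=` / `<`) |
| HFE | diminished annual income (NZD) | 750, 1735, 2789, 5091 | open-left (`>` / `<=`) |
| CE | ICER (NZD/QALY) | 5000, 10000, 20000, 25000 | open-left, decreasing |
| Equity, Multimorbidity | rate/hazard ratio | 1.11, 1.26, 1.51, 2.00 | open-left (`>` / `<=`) |

Equity combines two Level-II sub-criteria with ethnicity weighted twice as
heavily as gender: $(2/3)\,Ethnicity + (1/3)\,Gender$, producing fractional
thirds that are deliberately *not* re-rounded (composite scores are
reported to two decimals anyway). The multimorbidity hazard ratio may be
supplied directly or aggregated from per-comorbidity 1-year-mortality HRs
as $\exp(\sum_k \hat{w}_k \ln HR_k)$ with prevalence weights renormalized
to sum to 1 — renormalization is this package's interpretation (an
unnormalized weighted sum of log-HRs would grow without bound as
comorbidities are added); direct HR entry bypasses it. The ICER map
requires strictly positive costs; cost-saving (dominant) interventions
should be entered as a small positive value, which lands in the top band
regardless of magnitude.

User-supplied overrides win over mapped indicators, cell by cell, and are
flagged `"user"` in the provenance matrix so an audit can separate sourced
from asserted levels.

## Ranking

Conditions are ordered by descending composite score at full precision
(display rounding to two decimals is separate, so near-ties are never
manufactured by rounding). Exact ties share the score, order
alphabetically, and carry a tie flag — a documented, deterministic policy
rather than an arbitrary one.

## Free-text validation

Respondents' free-text health concerns validate the algorithmic ranking.
Processing: lowercase, strip punctuation (hyphens separate), tokenize on
whitespace, remove stopwords, Porter-stem. The Porter (1980) stemmer is
implemented in the package and reproduces the canonical behaviour
("hypertension"/"hypertensive" → "hypertens"); it is pluggable via the
`stemmer` argument. The stopword list is frozen under `inst/extdata/` so
results do not drift with external library versions.

The term–document matrix is *binary* per respondent: a word repeated by one
respondent counts once, so row sums count respondents, not mentions.
Condition-level comparison uses an editable YAML lexicon mapping each
condition to a set of search terms (stemmed at use time); many-to-one
mappings absorb the fact that the public rarely distinguishes, e.g., cancer
subtypes. Conditions never mentioned get no free-text rank and are flagged
instead of being forced into the correlation, which is a Spearman rank
correlation over matched pairs only.

## Synthetic data: what it emulates and what it does not

The generators make every stage testable without any external data:

* `generate_survey()` draws subgroup membership from declared fractions
  (default 83.3% / 16.7% two-group ethnicity mix), answers i.i.d. from
  per-subgroup per-criterion categorical distributions, and free text from
  a concern vocabulary plus filler words (fillers include stopwords on
  purpose, so the text pipeline is exercised). The default preference
  profile plants the study conditions this package targets: high Scale/HFE
  means (~4.6–4.7), lower CE (~3.6–3.8), and a subgroup Equity shift of
  4.6 vs 4.2 — about a 9.5% difference, comfortably over the 5%
  stratification threshold. `score_distribution(mean)` solves a
  two-adjacent-point distribution with a 5% uniform tail so the target mean
  is hit *exactly* in expectation.
* `generate_indicators()` samples a ground-truth level per indicator and a
  raw value strictly interior to that level's band, then emits both, so
  level-map recovery is checkable by construction (boundary values are
  tested separately and deterministically).

Determinism: each generator seeds R's Mersenne-Twister from its spec's
seed, so a fixed spec reproduces byte-identical fixtures; distinct pipeline
stages use distinct derived seeds so adding one generator call does not
perturb another's stream.

What the synthetic data does **not** emulate: respondents whose answers are
correlated across criteria, demographic structure beyond one grouping
variable at a time, realistic linguistic free text (typos, negation,
multi-word disambiguation), and indicator values clustered near band
boundaries as real burden tables are. Passing tests therefore demonstrate
algorithmic correctness and calibration recovery, not robustness to messy
field data.

## Problem sizes

Tests and the acceptance script run surveys of 300–2000 respondents, 5–25
conditions, and 500-respondent text corpora — sizes chosen to keep
Monte-Carlo error on recovered percentages near one percentage point while
the whole suite completes in seconds.

## Known limitations

* Composite scores inherit every caveat of additive MCDA: criteria are
  assumed preference-independent, and level maps discretize continuous
  indicators (a condition at 4.99% DALY share scores like one at 3.0%).
* The 5% stratification rule tests each criterion marginally; no
  multiplicity correction is applied, mirroring its use as a decision
  screen rather than an inference.
* Currency conversion of foreign ICERs is out of scope; indicator inputs
  must already be in NZD.
* The free-text comparison is only as good as the lexicon; the shipped one
  covers 25 common high-burden conditions and is meant to be edited.
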