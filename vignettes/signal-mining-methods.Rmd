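---
title: "Methods: disproportionality signal mining for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal mining for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignals)
```

## The problem and the data model

Spontaneous reporting systems such as FAERS and JADER collect voluntary
post-marketing adverse-event reports. They have no denominator (the number
of treated patients is unknown), so absolute risks are not estimable; what
is estimable is *disproportionality* — whether a drug-event pair occupies a
larger share of the database than the event's share among all other drugs'
reports.

`pvsignals` normalizes both supported file dialects into one case model:
one row per report carrying demographics, receipt/therapy/event dates (with
a precision flag), suspect and concomitant drugs with canonicalized names,
reaction preferred terms (PTs), indications and outcome codes. Counting is
always at the report level: a report mentioning a PT twice counts once for
that PT, and at system-organ-class (SOC) level a report counts once per SOC
regardless of how many of its PTs fall there. This union semantics is why
`aggregate_to_soc()` recomputes SOC tables from reports rather than summing
PT-level tables — sums would double-count multi-PT reports within a SOC.

Deduplication keeps one record per case id by a total order: highest case
version, then latest receipt date, then lexicographically largest report
id. The rule is deliberately a total order so that the result is unique and
idempotent; it is configurable through `dedup_policy()`.

Two deterministic vocabularies replace external services: a synonym →
canonical drug lexicon (folded, punctuation-insensitive lookup; unmatched
names pass through folded and flagged, never dropped) and a PT → primary
SOC dictionary. The shipped dictionary is a *synthetic stand-in* with the
structure of a real MedDRA export; a licensed export can be substituted by
path without code changes.

## Contingency tables

For each event observed in the corpus, `build_tables()` forms the 2×2 table
(a, b, c, d). Margins are **pair-based** by default: `a + b` is the number
of distinct (focal report, event) pairs, so `n = a + b + c + d` is the
corpus-wide pair total and is conserved across events — a convenient
invariant that the tests exploit. Report-based margins (`a + b` = number of
focal reports) are available via `margins = "reports"`; the two differ only
through multi-event reports and the choice is documented rather than
silently made.

"Focal" means the canonical drug appears with role primary suspect; the
role set is widenable (`roles = c("primary_suspect", "secondary_suspect")`)
because reporting practice differs on whether secondary suspects count. The
narrow default is the conservative reading.

## The four statistics

*ROR and PRR* are evaluated exactly as their textbook formulas; the ROR
interval is computed in log space. Tables with a zero cell are marked not
evaluable for ROR (and for PRR when `c = 0` or a margin is empty) rather
than imputed; the Haldane–Anscombe +0.5 correction is available as a switch
and is applied only to the zero-cell tables so that exact tables stay
exact. The χ² uses the Yates-corrected form, transcribed literally (the
term `|ad − bc| − n/2` is not clamped at zero); the uncorrected statistic
is a switch.

*The information component* uses the closed-form posterior moments of the
BCPNN under pseudo-count priors (defaults α = β = 2, α₁ = β₁ = γ₁₁ = 1,
centring IC at 0 under independence). The lower credibility bound is
IC − 2SD; the "IC025" column label common in published tables is treated as
identical to IC − 2SD, matching the definition used when the bound is
derived from the posterior variance rather than a separate quantile
computation. Because the pseudo-counts regularize every cell, IC is defined
even for zero-cell tables.

*EBGM* follows DuMouchel's gamma-Poisson shrinker: counts are modelled as
Poisson(λE) with `E = (a+b)(a+c)/n`, and λ has the two-component gamma
mixture prior. The marginal likelihood of a count is a two-component
negative-binomial mixture; `fit_mgps()` maximises its sum over pairs.
Numerical choices:

- the five parameters are optimised on an unconstrained scale (log shapes
  and rates, logit mixing weight) from the conventional start
  (0.2, 0.1, 2.0, 4.0, 1/3), Nelder-Mead first, BFGS polish;
- mixture log-densities are combined by log-sum-exp;
- zero-count pairs are excluded from the likelihood (the fit describes the
  observed signal mass; the exclusion is the documented convention here);
- pairs enter from both the focal cells (a, E) and the comparator cells
  (c, E-of-c) of every PT-level table, so the prior reflects the whole
  corpus, not one drug;
- **component collapse**: when the optimum assigns one component a total
  posterior responsibility below 10⁻³ over all pairs, the likelihood is
  flat in that component's parameters and the optimizer may leave it
  anywhere — with a vanishing weight times an arbitrary mean, prior
  summaries would be meaningless. The unidentified component is therefore
  collapsed onto the dominant one, which never decreases the likelihood
  and makes the reported prior mean well-defined.

The per-pair posterior is again a gamma mixture with component weights from
the negative-binomial marginals. EBGM is `exp(E[ln λ])` (digamma closed
form); EBGM05 solves the mixture CDF = 0.05 by `uniroot` bracketed between
the component 5th percentiles, to an absolute tolerance of 10⁻⁸ on λ. With
a two-component prior the posterior geometric mean is bounded by the
component prior geometric means and a/E — the mixture-level bound (prior
mixture GM vs a/E) can be overshot by about a percent when one component
dominates locally, which is a property of mixtures, not an artifact.

## Signal criteria and ranking

The positive-signal flag is the **conjunction** a ≥ 3, ROR CI low > 1,
PRR > 2, IC > 0, IC − 2SD > 0, EBGM05 > 2 — the literal reading of the
common criteria set; any not-evaluable statistic vetoes the flag rather
than being imputed. Each threshold is configurable in `signal_criteria()`.
Ranked surfaces (`rank_signals()`) drop counts below 3, drop events that
match the treated indications (which trivially co-report with the drug) and
a configurable disease-progression term list, sort by ROR or by count with
the other as tie-break, and truncate to top-N.

## Profiling surfaces

Demographic summaries report per-category counts and percentages per
source and pooled; percentages are count over the source's report count,
rounded *half away from zero* to 2 decimals (base R's banker's rounding
would turn 49.845 into 49.84), and the male-to-female ratio is reported to
2 decimals. Multi-valued variables (indications, outcomes) count mentions
and may exceed 100% in total, as in published report-characteristics
tables; the package always recomputes percentages from counts and never
reproduces externally printed percentages that disagree with their own
counts.

Time-to-onset uses only reports with day-precision therapy-start and event
dates and a non-negative interval; everything else is excluded and counted.
Bin edges default to {7, 30, 60, 90, 180} days so that "within 7 days" and
"within 30 days" statements can be read off the cumulative column.
Published onset summaries for this drug class are internally inconsistent
(the quoted percentages do not share a denominator with the quoted
evaluable count), which is precisely why the package reports recomputed
proportions only.

Indication strata: free-text indications classify by case-folded keyword
containment (tumor: lymphoma / leukaemia / leukemia / macroglobulinaemia /
neoplasm; non-tumor: nephritis / nephrotic / lupus / glomerulonephritis);
the lists are disjoint by construction, a text matching both kinds
classifies as tumor (the malignancy dominates the treatment context), and
unmatched text is unknown. `stratified_signals()` restricts the focal
cohort to one stratum while keeping the full non-focal corpus as
comparator (the restricted-comparator variant is a switch); focal reports
of other strata are excluded entirely, so the stratum a-cells partition
the overall a-cell per PT.

## The synthetic-report generator

`generate_reports()` emulates the statistical structure the analysis
assumes: a background population over a PT catalogue with baseline
reporting weights; a focal-drug cohort in which injected PTs' weights are
multiplied by a known relative rate and the vector renormalized (keeping
the per-report PT count distribution fixed, so the injected relative rate
is interpretable); per-report PT multiplicity Poisson(mean) floored at one,
drawn without replacement (implemented with the exponential-race
construction, which reproduces successive weighted sampling and vectorizes
across reports); duplicate case versions that are exact copies with
version + 1 and a later receipt date (making keep-latest-version the unique
correct dedup); receipt dates uniform over a configurable year range;
event onset preceding receipt by a short filing delay; therapy start =
onset − Weibull time-to-onset rounded to days; and a configurable fraction
of reports losing one of the two dates.

Defaults are chosen to resemble a mid-sized anti-CD20 cohort: 20,000
background + 2,000 focal reports, 2.5 PTs per report, 5% duplicates, 30%
missing dates, demographics and indication mixes matching published
report-level shares for such a cohort, and Weibull onset with shape 0.8,
scale 22.2 days — the median of that distribution is 14 days, matching the
published onset median; its early-onset fraction is *not* forced to match
the published within-7-days percentage, because no Weibull satisfies both
(see above). Ground truth (expected per-PT counts under the binomial
approximation `n × (mean + e^{−mean}) × p`, with the floored-Poisson
multiplicity correction, and the injected PT list) accompanies every
universe.

What the generator does **not** emulate: co-medication networks and
channeling, reporting waves and stimulated reporting, free-text narratives,
LLT-level vocabulary, country-specific reporting cultures. Passing the
recovery tests therefore shows the pipeline recovers known multiplicative
signals under clean conditions — not that real-database signals are
causal, nor that masking and confounding are handled.

## Problem sizes and determinism

The test suite exercises universes from a few hundred reports (IO round
trips, enumerated contingency examples) up to 102,000 reports across five
seeds for the recovery study (20 injected PTs at relative rate 10 over a
100-PT catalogue at baseline 0.01, 2,000 focal / 100,000 background);
MGPS fit quality uses 5,000 simulated pairs with expected counts uniform
on (0.5, 20). These sizes give the recovery and calibration checks enough
resolution (binomial standard errors of a few percent) while keeping a
full run in about a minute. Every stochastic component is seeded; the
pipeline itself is deterministic given its inputs, and reruns produce
byte-identical outputs.

## Known limitations

- Crude (unstratified) expected counts; no age/sex adjustment of E.
- No multiple-comparison control: the criteria are per-pair thresholds.
- The conjunction of six thresholds is conservative by construction;
  single-method positivity can be obtained by relaxing
  `signal_criteria()`.
- JADER's dialect stores age as a decade band and has no country field, so
  reading back a written JADER set reproduces the band midpoint, not the
  exact age (`jader_projection()` states the representable subset
  precisely).
- The drug lexicon is table-driven; misspellings outside it pass through
  as unmatched folded text rather than being fuzzily resolved.
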