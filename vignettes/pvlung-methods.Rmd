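---
title: "Methods: disproportionality and time-to-onset analysis of spontaneous reports"
author: "pvlung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and time-to-onset analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvlung)
```

## The setting

Spontaneous adverse-event reporting databases such as Japan's JADER collect
voluntary post-marketing reports of suspected adverse drug reactions. They
have no exposure denominator: every quantity is a count of *reports*, and
risk can only be assessed *relatively*, by asking whether an event is
reported disproportionately often under one drug compared with all others.
pvlung implements that workflow end to end for JADER-shaped data — three CSV
tables keyed by an anonymous case identifier: demographics (`DEMO`), drug
records with involvement codes and start/end dates (`DRUG`), and reaction
records with MedDRA-style preferred terms, onset dates and outcomes
(`REAC`).

## Constructing the data table

`read_jader()` normalizes labels (trim, collapse whitespace, case-fold; no
dictionary mapping, since MedDRA licensing is out of scope) and maps
unrecognized categorical tokens to `unknown`/missing rather than dropping
rows, so denominators are never silently reduced. `dedup_reports()` removes
duplicates; because the source databases do not publish their duplicate
key, we use the only assumption-free, reproducible rule — exact equality of
all fields within one table. Two records that differ in any field (for
example the same reaction with two onset dates) are both kept.

`merge_jader()` inner-joins DRUG and REAC on the case identifier, attaches
demographics (cases absent from DEMO become `unknown`), and collapses to
unique (case, drug, term, involvement) combinations. `filter_suspected()`
then keeps only reports where the reporter judged the drug causal. The
resulting *data table* of unique (case, suspected drug, preferred term)
triples is the counting unit for every denominator in the package; this
makes the tabulated arithmetic (per-term cases + non-cases = the drug's
report total; term counts summing to the toxicity-class total)
self-consistent.

Dates are carried as partial dates (`YYYY`, `YYYY-MM`, `YYYY-MM-DD`, or
missing). Year/month records resolve to day 1 by default — a conservative,
reproducible choice under the onset-interval convention below; the
`month_day` argument switches to mid-month resolution if desired.
Year-only records are treated as missing: a bare year is too coarse for
day-scale intervals.

## Signal detection: the reporting odds ratio

For a target drug and event term the data table partitions into the 2x2
table (a, b, c, d) — target-drug reports with/without the event, other-drug
reports with/without. The reporting odds ratio is

$$\mathrm{ROR} = \frac{a/b}{c/d} = \frac{ad}{bc},$$

with the Woolf (log-normal) 95% interval
$\exp(\ln \mathrm{ROR} \pm z_{0.975}\sqrt{1/a + 1/b + 1/c + 1/d})$ —
the universal pharmacovigilance convention, chosen here because published
analyses in this field rarely name their interval method. A term is a
*signal* when it has at least `min_cases` reports (default 5, inclusive)
and the lower interval bound strictly exceeds 1. The per-term p-value is
the classical two-sided Fisher exact test (probability-mass rule, via
`stats::fisher.test`), reported for completeness; the signal criterion is
the interval, not the p-value, and no multiple-testing correction is
applied (none is conventional in this screening setting).

Zero cells make the ROR undefined. The `correction` flag applies the
Haldane–Anscombe +0.5 to all four cells and marks the row `corrected`; it
is off by default so that corrections are explicit, and the ≥5-case screen
already makes a zero target cell impossible.

Displayed rates, RORs and interval bounds are rounded half-away-from-zero
to two decimals (percentages to one), matching tabulated pharmacovigilance
reports; CSV outputs carry full-precision columns alongside the rounded
companions, and the signal flag is always computed before rounding.

## Time to onset and the Weibull model

Time to onset for a report is measured from the start of the *most recent
continuous administration episode* beginning on or before the event onset:

* drug records for the case are resolved to calendar dates and sorted;
  a gap of more than 365 days between one record's end (its start if no end
  is recorded) and the next record's start opens a new episode, so
  re-challenge after a year or more off drug restarts the clock;
* `days = (onset − episode start) + 0.5`, the half-day convention placing
  an event on the first administration day at 0.5 days;
* samples beyond the analysis horizon of 730 days (two years) are
  rejected, as are onsets preceding every episode; rejections are counted,
  never clamped or raised.

The retained samples are uncensored by construction, and the fit is a
two-parameter Weibull maximum-likelihood fit (`fitdistrplus::fitdist`):
scale $\alpha$ in days (the 63.2% onset quantile) and dimensionless shape
$\beta$. Confidence intervals are Wald intervals on the log-parameter
scale from the observed information, back-transformed — log-scale Wald
keeps the bounds positive and is the default because reference
implementations of this analysis do not document their method;
profile-likelihood intervals are available via
`confint(fit, type = "profile")`. The position of $\beta$'s interval
relative to 1 classifies the hazard: upper bound < 1, *early failure*
(front-loaded risk); interval spanning 1, *random failure* (roughly
constant hazard); lower bound > 1, *wear-out* (risk growing with time on
drug).

Numerical edge cases: a single sample, or samples with zero spread, make
the shape estimate diverge; such fits return distribution-free summaries
only, a warning, and classification `indeterminate`. With as few as two
distinct samples the MLE exists and is reported with (very wide)
intervals — published analyses do the same, and suppressing them would
discard information the reader can weigh. Median and quartiles are always
the linear-interpolation sample quantiles (R type 7), never
model-derived.

`onset_histogram()` bins samples in left-closed 30-day bins from zero
(the final bin closed on the right so a sample exactly at the horizon is
kept); 30 days is a display default, exposed as `bin_width`.

## Outcomes

`outcome_report()` tabulates the six outcome categories (recovery,
remission, not recovered, sequelae, death, unclear) per term. The fatality
denominator is reports with a *stated* outcome: "unclear" is a stated
category and stays in the denominator, record-level missingness does not
(it is reported separately). The source material for this analysis style
never defines its denominator; this choice is documented rather than
guessed.

## The synthetic-data generator

`generate_reports()` emulates what the analysis assumes about the data:
cases shared across three tables; drugs used independently with configured
marginals; events fired by independent Bernoulli draws per (case, drug,
event) at background rate x rate ratio, with no richer within-case
correlation (the analysis assumes nothing richer); onset dates at drug
start + a Weibull draw; a six-category outcome field with missingness;
involvement codes including concomitant noise; exact-duplicate rows and
year/month-degraded dates at configured fractions; drug start dates
uniform over April 2004 – March 2021, the reporting window of the study
this package reproduces. Defaults for the onset model (alpha 120 days,
beta 1.1) and demographics (male-predominant, peaked in the 60s–70s)
mirror a typical oncology time-to-onset profile.

Two things the generator deliberately does *not* emulate: reporting-delay
dynamics and realistic drug-name vocabularies. It also shares one
structural property with the real merge: because tables join on the case
identifier alone, an event fired by one drug pairs with *every* drug the
case uses. `expected_counts()` gives the analytic expected cells including
this co-use leakage; the "true" ROR planted by a configuration is the
odds ratio of those expected cells. A consequence worth knowing: when
drug co-use or per-report event multiplicity is common, the four cells
are positively correlated and the Woolf interval becomes conservative
(its coverage rises above the nominal 95%). The coverage test therefore
runs in a sparse regime — rare drugs, rare events — where reports are
nearly independent; passing it shows the interval is calibrated for
near-multinomial data, not that real dense databases behave this way.

`published_margin_fixture()` is the deterministic companion: it rebuilds the
published bevacizumab margin exactly (20,399 target-drug reports, 1,679
lung-toxicity reports over 29 terms with the printed per-term counts, and
the printed sex/age margins), plus a comparator filler mass carrying the
same event profile. Its dates and outcomes are blank: onset times and
outcome splits are not recoverable from printed margins, and the fixture
does not invent them.

## Problem sizes and test design

The validation suite exercises: exhaustive agreement of the Fisher p-value
with direct hypergeometric enumeration for every 2x2 table up to n = 30;
Weibull parameter recovery at n = 1000 (within 5% on the scale, 7.5% on
the shape) and near-nominal shape-interval coverage over 200 replicates of
n = 150, the scale of the largest published time-to-onset sample this
package reproduces; null calibration of the screen over 500 replicates of
2,000-case databases (signal rate at most ~7%); and power against a
planted five-fold rate ratio over 100 replicates of 20,000-case databases
(detection in at least 95%). These sizes were chosen as the smallest at
which the asymptotic claims under test are expected to hold.

## Limitations

Everything a spontaneous-report analysis cannot do, this package cannot
do either: no incidence, no exposure adjustment, no causal attribution,
and reporting biases pass straight through. The duplicate rule, fatality
denominator, year/month resolution, gap threshold and interval methods
are documented choices where the field's published analyses are silent;
all are parameterized, and changing them changes results. The package
reproduces published *arithmetic* exactly from printed margins, but
full-database quantities (for example the 5-million-row data table) are
reproduced structurally, not numerically, because the raw database is not
redistributable.
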