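---
title: "Mining multi-item adverse drug event associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining multi-item adverse drug event associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ademiner)
```

## The model

A spontaneous report is treated as a transaction over typed items: a set
of drug names and a set of adverse-event terms (plus outcome codes and
optional drug role codes, which are summarized but never used to filter
items). Item multiplicity within a report carries no information here —
the support S(X) of an itemset X is defined as the number of *reports*
containing X — so drugs and events are stored as sets from ingestion
onward.

A candidate association rule has the form A → B with A a non-empty drug
set and B a non-empty event set. Its strength is measured by

* support S(A∪B): how often the full combination is reported;
* confidence S(A∪B)/S(A): an estimate of Pr(B | A);
* relative reporting ratio RR = S(A∪B)·N / (S(A)·S(B)): observed joint
  frequency over the frequency expected under independence, i.e.
  confidence normalized by the consequent's base rate S(B)/N.

Screening uses support and RR, not confidence. Confidence is biased by
the marginal frequency of B: ubiquitous events (nausea) yield high
confidence for almost any drug set, while genuinely interesting
multi-item associations are rare and therefore low-confidence. RR = 1
under independence, so an RR floor directly encodes "reported more often
together than chance predicts". No variance-shrinkage adjustment (such as
a Gamma Poisson shrinker) is applied: at the default support floor of 50
reports the adjusted and unadjusted RR essentially coincide, and below it
rules are discarded anyway.

An association is called **multi-item** when |A| + |B| ≥ 3, i.e. at least
two drugs or at least two events; these are the associations pairwise
screening cannot see, and the reason the miner exists.

## The mining algorithm

The miner is level-wise Apriori over typed itemsets with two tailorings.

**Typed emission constraint.** Unconstrained rule generation would emit
every antecedent/consequent partition of every frequent itemset, most of
which (drug → drug, event → event, events in the antecedent) do not
describe an ADE. Here each *mixed* frequent itemset emits exactly one
rule: drug part → event part. Drug-only and event-only itemsets are still
generated and retained — dropping them would break downward-closure
pruning, and they provide the S(A) and S(B) denominators of RR, whose
presence in a downward-closed table is guaranteed (a lookup miss is
reported as an internal error, never silently patched).

**Index-based support counting.** An inverted index maps every item to
the set of report positions containing it. `itemset_support()` intersects
posting lists smallest-first and can short-circuit once the running
intersection falls below a requested floor. Inside the level-wise miner
the equivalent but cheaper form is used: each candidate of size k is
generated by joining two frequent (k−1)-sets sharing a (k−2)-prefix, and
its report set is obtained by intersecting the two parents' (already
narrowed) report sets — one intersection per candidate instead of k
posting intersections, with supports identical by construction. The
brute-force oracle (`brute_force_mine()`) deliberately shares none of
this machinery: it enumerates all itemsets and counts support by
incidence-matrix full scan, and the test suite requires exact agreement
of itemsets, supports, emitted rules and RR values between the two on
randomized corpora.

**Determinism.** Items order as (kind, id) with drugs before events,
lexicographic within kind under a locale-independent radix sort;
candidate join uses the shared prefix in that order; output tables sort
by size then item order; ranked rules order by descending RR, then
descending joint support, then antecedent/consequent lexicographically.
Identical inputs and configuration therefore give byte-identical output
files.

Degenerate inputs behave predictably: an empty corpus refuses to mine; an
itemset containing an unseen item has support 0; `min_support` below 1 is
a parameter error; corpora whose frequent sets are all single-typed emit
no rules.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_support` | 50 reports | joint-support floor; high enough that chance co-reporting is unlikely and shrinkage unnecessary, low enough to keep rare combinations |
| `min_rr` | 2 | disproportionality floor; twice the independence expectation |
| `max_size` | 8 items | largest itemset mined; real multi-item findings rarely exceed 7 items |
| `multi_item_only` | TRUE | keep only |A|+|B| ≥ 3 survivors |
| `serious_codes` | DE, LT, HO, DS, CA, RI | outcome codes counted as serious; empty set disables the filter |
| `min_drugs_per_report` | 2 | polypharmacy selection, applied after name normalization; 0 disables |

The serious-outcome code set follows AERS outcome coding (death,
life-threatening, hospitalization, disability, congenital anomaly,
required intervention); "other" (OT) is not serious. Both filters are
per-report predicates on disjoint fields, so their application order does
not matter; the minimum-drug filter is applied after normalization so
that brand/generic collapse is reflected in the drug count.

## Drug-name normalization

Verbatim drug strings are reduced deterministically: uppercase, strip
slash-delimited annotations `/…/`, strip parenthesized qualifiers `(…)`
(innermost first, repeated), strip trailing dose/form tokens from a
configurable list, collapse whitespace. The fixed order makes the
procedure idempotent and testable; a string emptied by cleanup falls back
to its raw (case/space-normalized) form so mapping stays total. Cleaned
names then pass through a user-supplied two-column table to a generic
identifier; unmapped names are left as-is. No fuzzy matching is applied:
typographical variants not covered by the table simply remain distinct
items, which dilutes but never fabricates signal. The table-driven design
replaces NLP- and terminology-service-based mapping chains, whose
behavior cannot be reproduced offline; the package makes no claim of
faithfulness to any specific such chain.

## The synthetic generator

`generate_corpus()` emulates the features of serious-outcome, multi-drug
SRS samples that matter to the miner:

* heavy-tailed item marginals — drugs and events drawn from Zipf-ranked
  vocabularies (default 250 of each, exponent 1.0);
* overdispersed per-report item counts — drugs per report
  2 + NB(size 0.5, mean 1.3), events per report 1 + NB(size 0.8,
  mean 2.4), targeting means of 3.3 drugs and 3.4 events with medians of
  2 and roughly two thirds of reports multi-event;
* planted associations — each `planted_rule()` contributes case reports
  that always contain the full drug set and, with probability
  `penetrance`, the full event set, *plus* background padding items on
  both sides, so cases are not trivially separable from background;
* optional whole-report duplication, emulating unlinked follow-ups and
  multi-reporter duplicates, which measurably inflate joint support and
  RR.

The ground truth returned with the corpus restates each planted rule's
*realized* supports and RR by full scan of the emitted corpus, and the
test suite checks that against independent index-based recomputation.
`expected_rule_stats()` gives closed-form approximations (case
contribution plus background coincidence, using mean item counts) for
sizing specs; under them the reference validation spec
(`planted_validation_spec()`: 20,000 reports, five planted rules of 2–5
items, 150 cases each, penetrance 0.8) has expected joint support ≈ 120
and expected RR from ≈ 40 to ≈ 130, comfortably above the (50, 2)
thresholds.

What the generator does **not** emulate: correlated background
prescribing (confounding by co-medication), indication-driven reporting,
terminology granularity (every synthetic item is already canonical), or
temporal structure. Passing recovery tests on synthetic corpora therefore
demonstrates algorithmic correctness — the miner finds what is present at
the declared thresholds and calibrates to RR ≈ 1 under independence — not
clinical validity of mined rules on real data, which requires expert
review.

## Validation design choices

Recovery of a planted rule means its exact drug set → event set rule
appears among the screened survivors. The accompanying rank criterion
("top decile by RR") is evaluated over the *full ranked candidate-rule
list* at the support floor, not over the screened survivors: the survivor
set at the reference conditions is small (a few dozen rules) and consists
almost entirely of sub- and super-combinations of the planted families
themselves, so a decile within survivors would measure family
combinatorics rather than signal strength. Against the full candidate
list — hundreds to thousands of rules, overwhelmingly background pairs
with RR near 1 — the planted rules rank in the top few percent.

Null calibration uses the same generator with nothing planted and
averages RR over drug–event pairs at support ≥ 50. The average sits
slightly above 1 (conditioning on observed support selects upward
fluctuations for borderline pairs) but well inside [0.8, 1.2] at the
reference size.

Problem sizes used throughout the test suite — 20,000-report validation
corpora, 50 randomized oracle-comparison corpora of up to 300 reports,
brute-force enumeration capped at 4-item sets over ≤ 18-item universes —
were chosen so the whole suite runs in well under a minute of mining time
while keeping every comparison exact.

## Known limitations

* RR is a point estimate; no confidence intervals, shrinkage, or
  multiple-testing control are provided. At support ≥ 50 this is a minor
  concern, but survivors remain *hypotheses* for expert review.
* Confounding is not detected: a drug co-prescribed with a true culprit
  inherits its association (the synthetic generator does not simulate
  this structure either).
* Duplicate *reports* with distinct ids (the duplication artifact the
  generator can inject) are not deduplicated — only duplicate report ids
  are — so duplicity inflates RR exactly as it does in real systems;
  detecting it is out of scope.
* The mining loop is pure R; it is comfortable at tens of thousands of
  reports and a few hundred frequent items, and has headroom via
  `min_support` rather than via parallelism.
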