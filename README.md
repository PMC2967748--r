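# ademiner

Mining multi-item adverse drug event (ADE) associations from spontaneous
reporting system (SRS) data.

## The problem

Post-marketing drug safety surveillance rests on spontaneous reporting
systems: databases of voluntarily or mandatorily submitted reports, each
listing the drugs a patient was taking, the adverse events (AEs) observed,
and the patient outcome. The standard screening tools are *bivariate*:
each single drug–event pair is tested for disproportionate reporting on
its own. But many reports carry several drugs and several events, and
clinically important signals — drug–drug interactions, adverse effects of
combination regimens — are *multi-item*: they relate a **set** of drugs to
one or more events (e.g. `Aspirin + Warfarin → Bleeding`) and are
invisible to pairwise screening.

Brute-force enumeration of multi-item combinations is hopeless: with
10,000 drugs and 10,000 event terms, the naive space of 2-drug/3-event
candidates alone is on the order of 10^20
(`candidate_space_bound(10000, 10000, 2, 3)`). `ademiner` makes the search
tractable with a typed, constrained Apriori frequent-itemset miner and
screens the resulting rules with a disproportionality measure instead of
confidence.

## The method

A report is a transaction over typed items (drugs and events). For an
itemset X, the **support** S(X) is the number of reports containing all of
X. For a candidate rule A → B (A a drug set, B an event set):

- **confidence** `C(A→B) = S(A∪B) / S(A)`, an estimate of Pr(B | A);
- **relative reporting ratio** `RR = S(A∪B) · N / (S(A) · S(B))`, the
  observed joint reporting frequency over the frequency expected if A and
  B were reported independently. RR = 1 means independence; RR > 1 a
  positive association.

The miner is plain Apriori with two domain tailorings:

1. **Typed rule constraint.** Only the drugs-in-antecedent /
   events-in-consequent form describes an ADE, so each *mixed* frequent
   itemset emits exactly one rule (its drug part → its event part) rather
   than all 2^k − 2 partitions. Drug-only and event-only itemsets are
   still mined — downward-closure pruning needs them, and they are the
   S(A) and S(B) denominators of RR.
2. **Inverted-index support counting.** Posting lists (item → report set)
   replace repeated database scans; each candidate's report set is the
   intersection of its parents' report sets.

Screened rules must clear a joint-support floor (default 50 reports) and
an RR floor (default 2); confidence is reported but deliberately not used
for screening, because frequent events inflate it and rare-but-real
multi-item associations deflate it. A **multi-item** association is a rule
with at least 3 items overall (at least 2 drugs or 2 events).

The package also provides deterministic drug-name cleanup with a
table-driven brand→generic mapping (collapsing verbatim variants like
`AVANDIA /SCH/ (ROSIGLITAZONE MALEATE)` onto one generic), readers for a
simple transactions format and an AERS-style `$`-delimited quarterly ASCII
dialect, corpus summary statistics, a synthetic SRS generator with planted
ground-truth associations, and a command-line pipeline.

## Worked example

A four-report toy corpus (`inst/extdata/tc4.tsv`): reports R1 and R2
carry drugs {D1, D2} and event E1, R3 carries D1 with E2, R4 carries D2
with E1.

```r
library(ademiner)
tc4 <- read_transactions(system.file("extdata/tc4.tsv", package = "ademiner"))
cfg <- mining_config(min_support = 2, min_rr = 1,
                     serious_codes = character(), min_drugs_per_report = 0)
summ <- run_pipeline(tc4, config = cfg)
print(summ)
#> reports read:            4
#> after serious filter:    4
#> after min-drugs filter:  4
#> drug names raw -> norm:  2 -> 2
#> frequent itemsets:       7 (size 1: 3, size 2: 3, size 3: 1)
#> candidate rules:         3
#> pass support+RR:         2
#>   of which multi-item:   1
#> survivors written:       1
```

Seven itemsets reach support 2 ({D1}, {D2}, {E1}, {D1,D2}, {D1,E1},
{D2,E1}, {D1,D2,E1}); the three mixed ones emit the candidate rules
`D1→E1` (RR 0.889), `D2→E1` (RR 1.333, but only 2 items) and
`{D1,D2}→E1`. The single multi-item survivor:

```r
summ$rules[, 3:8]
#>   support_joint support_ante support_cons n_reports confidence       rr
#> 1             2            2            3         4          1 1.333333
```

Both reports containing D1 and D2 together also report E1, 4/3 times more
often than expected if {D1,D2} and E1 were independent.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/ademine.R mine --input reports.tsv --output rules.tsv \
    --min-support 50 --min-rr 2
Rscript inst/cli/ademine.R describe --input reports.tsv
Rscript inst/cli/ademine.R simulate --output synthetic.tsv --planted --seed 1
```

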