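---
title: "Tiered virtual gene panels for familial pulmonary fibrosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered virtual gene panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpftiers)
```

## The procedure

`fpftiers` triages germline variants in families with familial pulmonary
fibrosis (FPF) by applying three virtual gene panels sequentially to
exome-wide, annotated variants, with two gates: the ACMG class of what has
already been found, and severe telomere shortening in an affected family
member.

**Tier 0.** A variant enters the analysis only if it is non-synonymous at
the protein level (nonsense, missense, frameshift, splice-site or in-frame
indel) and rare: population allele frequency strictly below 0.01, with a
*missing* frequency treated as "absent from the reference population" and
therefore rare. The strictness matters at both edges — a variant at exactly
AF = 0.01 is excluded, and a novel variant with no AF record must not be
dropped, since truly pathogenic FPF variants are often unobserved in
population databases. Both choices are in `filter_config()` and
`filter_variants()` is total, order-preserving and idempotent.

**Panels.** Panel A is a curated 14-gene panel of monogenic FPF genes,
split into telomere-related (TERC, TERT, TINF2, DKC1, RTEL1, PARN, NAF1,
ZCCHC8) and non-telomere (surfactant and mitotic-spindle) categories, each
entry carrying inheritance mode, evidence level and whether loss of
function is an established disease mechanism. Panels B (extended ILD,
syndromic and GWAS genes) and C (further telomere-maintenance genes) are
user-replaceable; the bundled B/C lists are illustrative defaults built
from genes commonly reported in this setting, since extended panels evolve
quickly and are expected to be supplied per laboratory. A gene may appear
in at most one panel; `read_panels()` enforces this.

**Family triage** (`triage_family()`). For each family, tier-0 variants in
Panel A genes carried het/hom by at least one affected member are
classified. Benign-side calls (B, LB, VUS-LB) are excluded from the
candidate list (they still count toward the per-case interpretation
workload reported by `tier_variant_summary()`). Any P or LP candidate stops
the family's analysis; otherwise Panel B is assessed identically; Panel C
is assessed only when, in addition, at least one affected member has severe
telomere shortening. VUS-level candidates — including VUS-LP — never halt
escalation; this is deliberate, because an intermediate call should not
suppress the search for a definitive one. A P/LP found at Panel C simply
completes the analysis (`completed_C`); the distinct stop reasons
(`plp_found_A`, `plp_found_B`, `no_severe_tl`, `completed_C`) are recorded
per family and logged.

**Carriers and yield.** Each candidate found in patients is looked up in
unaffected relatives (`detect_asymptomatic_carriers()`); a missing or
absent genotype makes a relative *untested*, never a non-carrier.
Diagnostic yield is family-level: the fraction of families with at least
one candidate in the chosen relevant-class set ({P, LP} conservatively,
optionally including VUS-LP), with a Wilson score 95% interval.

## The classification engine

`combine_acmg()` implements the published ACMG/AMP combining tables over
counts of assertions by strength class (very strong, strong, moderate,
supporting on the pathogenic side; stand-alone, strong, supporting on the
benign side). Counting by strength rather than by code means a curator can
up- or down-weight an individual criterion and the tables still apply. The
"≥" semantics are used throughout: a rule fires if the available counts
contain the pattern. When both a pathogenic-side and a benign-side rule
fire, the evidence is conflicting and the class is VUS; with no rule fired
it is VUS as well. The engine is total and deterministic, and the test
suite compares it against an independent, pattern-by-pattern transcription
of the tables over all 512 subsets of a nine-criterion universe.

**VUS subclasses.** The intermediate labels VUS-LP and VUS-LB are used in
clinical practice without a standard printed definition, so the policy here
is explicit and configurable: a VUS is VUS-LP when there is at least one
moderate-or-stronger pathogenic assertion (or two supporting ones) and no
benign assertion; VUS-LB is the mirror image. Anything mixed stays plain
VUS. Note the subclassification only applies when the combining tables
returned VUS: two supporting benign criteria alone already make LB by the
tables and are never re-labelled VUS-LB.

**Automatic evidence** (`derive_auto_evidence()`):

| criterion | fires when | default |
|---|---|---|
| PVS1 | nonsense/frameshift/splice-site in a gene with an established LOF mechanism | — |
| PM2 | AF absent or < `pm2_af` | 1e-4 |
| PP3 | in-silico score ≥ `pp3_score` (CADD-phred scale) | 20 |
| TL support | telomere-category gene and the carrier shows severe TL shortening | supporting strength, code `PP4` |

The TL criterion is deliberately supporting-level only and restricted to
telomere-category genes: severe telomere shortening corroborates a
telomere-gene variant but can never, alone, move a variant out of VUS.
Evidence-strength modulation of PVS1 (e.g. last-exon truncations) is not
modelled; criteria that require external databases or cosegregation
analysis (PS1, PP1, ...) enter only through the curator file, whose
assertions override auto-derived ones with the same code. Hard class
overrides (curated final classes) bypass the engine entirely — this is how
the bundled fixture reproduces its published classifications, which were
made with family-level human evidence the engine cannot see, rather than
re-deriving them.

## Telomere-length normalisation

A measured T/S ratio is converted to a Z-score against the age-matched
control bin, `z = (T/S − mean) / sd`, with half-open bins
`[age_lo, age_hi)`; the percentile is `100·Φ(z)`, assuming the control
distribution within a bin is normal. That assumption is the simplest bridge
from the Z-score to the "below the 10th percentile" severity rule; if a
laboratory's control quantiles are skewed, an empirical reference can be
used instead by converting quantiles to the mean/sd table or by supplying
percentile categories directly. Severity is strict: percentile < 10;
exactly 10 is not severe. Unknown TL (missing T/S, age outside all bins) is
never severe and never satisfies the Panel C gate.

The categorical mode (`tl_results_from_categories()`) mirrors printed
clinical tables that report percentile bands ("<1", "<10", "10-25",
"25-50", "50-75"): the two lower-tail bands are severe, band midpoints
stand in for numeric percentiles so group means remain computable, and
"unknown"/empty is known = FALSE. Where two printed tables disagreed on one
individual's band, the per-variant table was followed; this affects no
cohort-level count.

## Statistics

* **Fisher exact, 2×2, two-sided** — hypergeometric enumeration with the
  minimum-likelihood convention: sum of the probabilities of all tables (at
  fixed margins) not exceeding the observed table's probability, within
  relative tolerance 1e-7 to absorb floating-point ties. This is the
  commonest convention (and the one used by `stats::fisher.test`, which
  serves as an independent oracle in the tests — the doubling convention
  would differ). A table with an empty margin has a single attainable
  configuration and p = 1.
* **Welch t** — unequal-variance t with Satterthwaite df, via
  `stats::t.test`; requires n ≥ 2 per group and nonzero variance in at
  least one.
* **Wilson score interval** — closed form, no continuity correction; the
  interval always brackets k/n and hits the 0/1 boundaries exactly at
  k = 0 / k = n. Chosen because it behaves sensibly at the small n typical
  of family cohorts. A known limitation is the small-n coverage
  oscillation of every score-type interval: at some (n, p) the realised
  coverage dips several points below nominal (the acceptance suite
  measures this empirically at n = 13), which is inherent to discrete
  binomial intervals rather than to this implementation.
* **TL association** (`tl_association()`) — builds the severe-vs-carrier
  2×2 over affected members only or over everyone with known TL, Fisher
  p-value, group means, and Welch comparisons both between carriers and
  non-carriers and between members of families with and without a relevant
  telomere-gene variant. Relevant means P, LP or VUS-LP. Degenerate scopes
  warn and report p = 1. No multiple-testing correction is applied.
* **Descriptive summaries** use the sample SD (n − 1); a single
  observation reports SD 0 with `sd_defined = FALSE`.

## Prioritizer concordance

`evaluate_rankings()` scores external ranked lists against a manually
prioritized truth set of (patient, variant) pairs: hits within top-k,
sensitivity = hits/|truth|, and PPV = hits over a denominator that is
configurable because published figures rarely state it — either the top-k
slots actually emitted across truth patients (default) or the distinct
variants proposed. "Combined" counts a hit when either tool ranks the pair
within k, so union sensitivity dominates each tool by construction. Ties in
rank keep input order (stable sort); 0/0 ratios are reported as 0 and
flagged degenerate. Because the PPV denominator convention is a choice,
concordance numbers are comparable within one convention only.

## The cohort simulator

`simulate_cohort()` generates what the triage assumes and nothing more:

* **Pedigrees** — founder couple, children, optional grandchildren
  (family size uniform on `members_min:members_max`, default 4–8; founder
  ages 70–90, children 40–65, grandchildren 15–39).
* **Planted variant** — in a planted family (default 5 of 13), founder 1
  is het for a novel nonsense variant in a telomere-related Panel A gene
  with an established LOF mechanism (score 25–45); each meiosis transmits
  it with probability 1/2.
* **Penetrance** — carriers above age 50 are affected with probability
  0.6, younger carriers never (late onset); ascertainment then guarantees
  at least two affected per family (oldest carriers are promoted, and in
  single-carrier families the remaining affected slot is a phenocopy, as
  happens in real ascertained cohorts). Non-planted families get their two
  oldest members affected — families enter such a study because of familial
  disease, with or without a Panel A cause.
* **Background variants** — Poisson per individual (mean 1.5), singleton
  het, random gene (panel or non-panel), missense, AF absent with
  probability 0.2 or uniform below 0.01, score uniform below 15. They pass
  tier 0 by construction, so they exercise the classification and panel
  logic rather than the filter.
* **Telomeres** — percentiles drawn per group: carriers Beta(1.2, 8),
  non-carrier offspring of carriers Beta(2, 6) (both scaled to 0–100),
  unrelated individuals Uniform(0, 100); converted to T/S through the
  written control reference (10-year bins, mean declining linearly with
  age, constant SD), so re-normalising the written T/S table recovers the
  drawn percentiles exactly. The three-group structure mirrors the
  inheritance of short telomeres by offspring of telomere-gene
  heterozygotes. Penetrance, the Beta parameters and the age ranges are
  modelling defaults — the underlying clinical distributions are not
  published — and all are config-exposed; they were fixed once and are not
  tuned.

Outputs are standard formats (PED, VCF 4.2 with GENE/CSQ/AF/SCORE INFO
keys, TSV) consumed unchanged by the package's own readers, plus a truth
table and a provenance JSON echoing the seed; a fixed seed gives
byte-identical files.

What the simulator does **not** emulate: linkage disequilibrium, genotyping
error and missingness, sequencing depth, multi-allelic sites, consanguinity
and recessive disease, phenocopy clustering, age-structured censoring.
Passing recovery tests on simulated cohorts therefore demonstrates the
correctness of the gating, classification and carrier logic under clean
genotypes — not performance on real exomes, where annotation quality and
VUS burden dominate.

Problem sizes used by the test and acceptance suites were chosen to make
sampling error negligible relative to the tolerances: 3,000 single-founder
families (≥ 10,000 meioses) for the transmission check, 250 families for
the TL group ordering, 10,000 replicates for interval coverage, and the
13-family design for end-to-end recovery.

## The bundled fixture

The fixture transcribes the published 13-family cohort: 61 individuals, 16
affected (families 5, 7 and 12 with two each), the 9 distinct Panel A
variants with their curated classes (the recurrent RTEL1 nonsense variant
appears in two families, giving 10 family-level candidate records), and 58
TL measurements as percentile categories. Individuals named in the
publication carry their printed attributes; relatives beyond those named
are synthetic fill constructed once to match the printed cohort totals
(21 severe / 36 non-severe with 8 and 5 relevant-variant carriers), and are
documented as such. Variant genomic coordinates are taken from the bundled
toy gene-coordinate table — HGVS strings, genes, consequences and classes
are the data of record, not the positions. The printed patient-level Fisher
subgroup (5/6 vs 1/6) is not reconstructible from the published tables and
is therefore not asserted anywhere; the all-individuals table (8/21 vs
5/36) is.

## Degenerate inputs and tie-breaks

* Multi-allelic VCF sites are decomposed per alt allele; per-allele INFO
  values split on commas when their length matches the allele count,
  otherwise the value is recycled.
* "chr1" and "1" are the same chromosome everywhere; BED intervals are
  0-based half-open, VCF positions 1-based, conversions centralised in the
  I/O layer.
* Unknown consequence terms map to `other` with a warning (and `other` is
  not retained by the default tier-0 filter).
* A gene with no covered target bases reports coverage 0 with a warning;
  coverage fractions are weakly decreasing in the depth threshold by
  construction.
* An empty cohort, an empty VCF and an empty candidate list all produce
  valid (empty) outputs, not errors; a family without an affected member
  is an error, since triage is undefined for it.

## Known limitations

Cosegregation (PP1/BS4) and hot-spot (PM1) evidence are not automated;
compound-het/homozygous logic for AR genes is reported but a single het in
an AD/AR gene still qualifies as a candidate, matching how such variants
are reported in practice; the ACMG engine does not modulate PVS1 strength
by transcript position; and the Wilson interval's discrete-coverage
oscillation at small n is measured, not corrected — laboratories wanting
guaranteed ≥ 95% coverage at n ≈ 13 should use an exact (Clopper–Pearson)
interval at the cost of width.
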