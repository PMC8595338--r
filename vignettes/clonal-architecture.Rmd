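---
title: "Clonal architecture of synchronous multiple primary lung adenocarcinomas"
author: "mplaclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal architecture of synchronous multiple primary lung adenocarcinomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplaclone)
```

## The problem

When a patient presents with two or three lung adenocarcinomas at once
(synchronous multiple primary lung adenocarcinoma, sMPLA), the clinical
question is whether the lesions are independent primaries or seeding from a
common clone. Targeted-panel sequencing of each lesion gives one somatic
mutation profile per lesion, and the lineage question becomes a set question:
how much of each profile is common to all lesions, how much is shared by
some, and how much is private?

`mplaclone` implements the complete analysis around that question for
small multi-lesion cohorts:

* per-patient **trunk / shared / branch** classification of mutation events
  and patient-level **concordance** calls;
* germline-rooted **maximum-parsimony phylogenies** over a patient's
  lesions, with events assigned to edges;
* strand-collapsed six-class **substitution spectra**, stratified by smoking
  history and sex;
* a gene-by-covariate **association screen** (chi-square / Fisher exact with
  an explicit selection rule) plus a t-based proportion confidence interval;
* **VAF comparisons** across clonality classes with the Wilcoxon rank-sum
  test;
* a seeded **synthetic-cohort simulator** with recorded ground truth, and a
  deterministic **study-constrained fixture** cohort used to verify every
  stage offline.

## The model and its definitions

### Event identity

A mutation event is identified by the normalized triple
`(gene, alteration, variant_class)` - e.g. `EGFR L858R nonsynonymous_SNV`.
Genomic coordinates, when present, never participate in identity; they exist
only so single-base substitutions can be classified on the pyrimidine
strand. This matches how panel reports identify events (gene plus protein
change) and makes amplification and fusion events first-class citizens of
the clonality analysis, which matters because worked cases hinge on them
(an ERBB2 amplification and an A1CF-RET fusion both occur as private
events).

### Trunk, shared, branch

For a patient with lesions $L$ and the distinct event set $E$ (the union of
lesion profiles), each event $e$ with carrier set $C(e) \subseteq L$ is

* **trunk** if $C(e) = L$ (present in every lesion, inferred
  pre-divergence),
* **shared** if $2 \le |C(e)| < |L|$ (only possible with three or more
  lesions),
* **branch** (private) if $|C(e)| = 1$.

Cohort-level proportions use the *distinct-event* denominator: a trunk event
counts once for its patient, not once per lesion. The per-lesion *call*
count is also reported, because the two denominators differ exactly by the
extra lesion-copies of trunk and shared events and published totals mix the
two conventions (see "Known discrepancies").

### Concordance

A patient is `concordant_wildtype` when no lesion carries any event,
`concordant_mutant` ("matched") when all lesion profiles are identical and
non-empty (equivalently: every event is trunk), and `discordant` otherwise.
Distinguishing the two concordant flavours reconciles the two published
rates (3/42 consistent gene status vs 1/42 matched mutations): two of the
three concordant patients are concordant because both their lesions are
wild-type.

### Parsimony trees

Each patient gets a rooted tree over `germline + lesions`. Because rooting
an unrooted binary tree at the germline leaf is a bijection onto rooted
binary trees over the lesions, the search space for $k$ taxa is the
classical $(2k-5)!!$ and is enumerated exhaustively; with at most three
lesions per patient in the motivating data (and a hard cap of 7 lesions /
8 taxa) heuristic search would be over-engineering and is deliberately out
of scope.

Each event is a binary presence character scored with unit-cost Sankoff
dynamic programming under two constraints chosen deliberately:

1. **The root state is fixed at 0** - no somatic event precedes the
   germline. Without this, parsimony happily infers "ancestrally present
   then lost" where independent gains suffice.
2. Among minimal-change labelings, **losses are minimized first** (priced at
   $1+\varepsilon$), then remaining ties resolve towards the mutant state
   top-down, which places gains as close to the root as possible. The first
   rule keeps a non-trunk event off the trunk edge whenever an all-gain
   labeling of equal cost exists; the second makes the trunk assignment
   unique and consistent with reading trunk events as early events. Under
   these rules an event sits on the root-incident edge exactly when the
   clonality module labels it trunk (a property the suite verifies across
   simulated cohorts).

Edge lengths are edge-assigned event counts, and the tree score is their
sum. A published description ties branch length to "the number of mutations
in each lesion"; that conflates lesion mutation counts with edge
assignments (the two differ whenever an internal edge carries a shared
event), and this package deliberately uses edge assignment.

Among equally parsimonious topologies, the one with the lexicographically
smallest canonical Newick string is returned and the tie count `n_mpt` is
always reported - star-like data (all-private patients) tie across every
topology, and pretending otherwise would manufacture phylogenetic signal.

### Substitution spectra

Only single-base substitutions qualify (nonsynonymous SNV and stopgain by
default - the motivating cohort's published class totals sum over both).
Raw `ref>alt` pairs are stored strand-specifically as reported; the
classifier complements purine-reference pairs so each of the 12 raw pairs
maps onto the six pyrimidine-strand classes C>A, C>G, C>T, T>A, T>C, T>G.
Counting is per distinct event per patient, consistent with the clonality
denominator. Smoking stratification is binary (pack-years 0 vs > 0); the
three-level pack-year binning exists only in the association screen. The
source text labels C>A "transitions"; this package ignores that
(internally inconsistent) transition/transversion nomenclature and works
purely with the six-class convention.

### Statistics

* **Proportion CI**: $\hat p \pm t_{1-\alpha/2,\,n-1}\, s/\sqrt n$ with
  $s = \sqrt{k(n-k)/(n(n-1))}$, i.e. the t-interval over the binary
  indicators with Bessel correction. This convention (common in commercial
  statistics software) is the only standard interval that reproduces all
  five published 95% CIs at three decimals, including a negative lower
  bound at $k=2, n=93$; bounds are therefore *not* clipped to $[0,1]$.
  Rounding is half-away-from-zero (so $-0.00853 \to -0.009$).
* **Test selection**: 2x2 tables use chi-square (Pearson, no continuity
  correction) when every expected count is at least 5, otherwise Fisher's
  exact test; larger tables use chi-square when fewer than 20% of expected
  counts are below 5 and none is below 1, otherwise Fisher (exact while the
  table count with fixed margins stays within $10^7$, else Monte Carlo with
  a fixed, logged seed and $10^5$ draws). The source does not state
  per-table choices, so computed p-values are outputs, never assertions
  against published ones.
* **Wilcoxon rank-sum**: exact enumeration when both groups have at most 12
  observations and no ties; otherwise the normal approximation with
  tie-corrected variance and no continuity correction.
* **Covariate binnings** (closed, upper-inclusive to match the published
  "a-b" labels): pack-years $\{0, (0,30), \ge 30\}$; diameter
  $\{\le 1, (1,2], (2,3], >3\}$ cm; CTR
  $\{[0,0.25], (0.25,0.5], (0.5,1]\}$; stage collapsed to
  $\{0, I, II, III\}$. Gene status is lesion-level: at least one SNV/indel
  event in the gene; amplification and fusion are excluded from gene-status
  tables. The EGFR-subtype screen compares L858R-mutant and 19del-mutant
  lesions against fully-EGFR-wild lesions, excluding other EGFR mutants, so
  its margins are 31+36 and 18+36.
* No multiple-testing correction is applied anywhere, mirroring the
  motivating analysis; with ~18 tests in the screen this inflates the
  family-wise error rate, and readers should treat individual p-values
  accordingly.

## The synthetic-data generator

`simulate_cohort()` draws, per patient: covariates, a lesion count (2 with
probability 33/42, 3 with 9/42), architecture counts (trunk events
$\sim\mathrm{Pois}(5/42)$ per patient; shared events
$\sim\mathrm{Pois}(4/9)$ per three-lesion patient; private events
$\sim\mathrm{Pois}(92/93)$ per lesion), event identities, strand-specific
substitutions, and VAFs. The defaults are the motivating study's observed
conditions, fixed once:

* **Covariates**: sex female with probability 31/42; smoking drawn
  conditionally on sex (males 3/4/4 over the pack-year strata, females
  never-smokers), because the study cohort couples the two - its 34
  never-smokers are the 31 women plus 3 men - and independent marginals
  would dilute every smoking- and sex-linked signal the generator is
  supposed to carry.
* **Drivers**: per-gene Bernoulli presence with base log-odds tuned to the
  cohort frequencies and additive log-odds shifts EGFR +1.6 for female and
  +1.6 for never-smoker, KRAS +1.2 male / +1.5 smoker, TP53 +0.6 per cm
  diameter, +0.7 per CTR bin and +0.5 per stage group.
* **Spectra**: six-class substitution probabilities conditional on smoking
  (never-smokers T>G-dominated at 0.50; smokers C>A 0.40 / C>T 0.33),
  emitted on the purine strand with probability 0.5 so downstream
  collapsing is always exercised.
* **VAF**: Beta distributions per clonality class, located near the
  published medians (trunk 0.164, shared 0.091, branch 0.086).

The generator records its ground-truth label for every event. Since
trunk/shared/branch classification is deterministic set logic, the
downstream classifier must agree with this truth *exactly*, and the test
suite demands 100% agreement, not a high percentage.

What the generator does **not** emulate: within-lesion subclonal structure
(VAFs are drawn i.i.d. given the class, with no purity or copy-number
effects), mutational hotspottedness beyond a small driver catalog,
inter-lesion contamination, or sequencing noise in the presence calls.
Passing tests therefore show the pipeline's logic is correct under the
stated generative assumptions - they do not validate variant calling or
guarantee behaviour on cohorts whose VAF distributions violate the class
ordering.

## The deterministic fixture

`generate_study_fixture()` assembles - statically, with no RNG - a
42-patient, 93-lesion cohort satisfying simultaneously: the lesion
architecture (33x2 + 9x3), the smoking strata 34/4/4, exactly three
concordant patients (P20 matched with EGFR L858R in both lesions; P19 and
P35 wild-type pairs), clonality totals 5 trunk / 4 shared / 92 branch over
101 distinct events, the named trunk patients (P2, P16, P20, P42 with
L858R; P27 with 19del) and shared patients (P5, P15, P25, P30, all L858R),
the six-class SNV totals 12/3/18/5/9/32 with their exact smoking and sex
marginals, per-class VAF medians 0.164/0.091/0.086 (deterministic
symmetric ladders around each median), and the eight individually
described patient profiles verbatim. Substitutions are stored in mixed
strand representations.

Satisfying all of that at once required choosing a joint allocation the
source never prints: which patients are male, which smoke, and which
filler events carry which substitution class. The chosen allocation makes
all eight smokers male, places the smoker-enriched C>A/C>T classes on
KRAS-driven smoker profiles, and fills the female never-smoker majority
with EGFR- and TP53-driven profiles. `validate_fixture()` checks a tiered
constraint list: all *required* constraints (the ones above) must pass;
*best-effort* constraints cover the remaining printed marginals and
gene-level tumour counts, and their failures are reported as data. Three
best-effort constraints are genuinely unsatisfiable together with the
required tier and fail by design: the ERBB2 YVMA tumour count (1 vs 2),
the BRAF tumour count (1 vs 6), and the indel subtype counts - all victims
of the distinct-indel budget forced by the published clonality totals (see
next section).

## Known discrepancies in the source numbers

* **108 vs 101.** The source reports "108 gene mutations (79 SNV + 29
  indel)" but its clonality totals imply 101 distinct events (5+4+92). The
  two reconcile exactly if 108 counts per-lesion SNV/indel *calls* while
  101 counts distinct events including one amplification and one fusion:
  with 79 distinct SNVs, 20 distinct indels, and the 9 extra lesion-copies
  contributed by trunk/shared events (all SNVs), calls = 88 + 20 = 108.
  The fixture realizes this reconciliation, and the clonality summary
  always reports both denominators. The price is 20 distinct indels, which
  is why the published indel subtype breakdown (which sums to 29) cannot
  be satisfied.
* **78 vs 79.** The prose says 78 nonsynonymous SNVs plus 1 stopgain, but
  the printed class totals sum to 79, as do both stratifications (12+67
  and 16+63). The class totals are followed; the validation report
  surfaces the stopgain count instead of resolving the contradiction.
* **Figure-level spectrum p-values.** Whether the published smoking
  (P=0.026) and sex (P=0.039) comparisons come from a 2x6 chi-square,
  Fisher, or a collapsed table is unstated; `compare_spectra()` reports
  its own test and p-value (Fisher exact on the fixture: 0.043 for
  smoking), and no published p-value is asserted anywhere.

## Numerical and degenerate-input choices

* Proportion CIs degenerate to a zero-width interval at $k \in \{0, n\}$
  and are flagged rather than patched with a different method.
* A contingency table with a zero marginal is an error for chi-square; for
  Fisher it is fully determined by its margins and returns p = 1.
* Identical values across both rank-sum groups return p = 1 with a notice.
* Characters absent from every lesion cannot reach the parsimony scorer
  (the event matrix only contains observed events) and are rejected if
  constructed by hand.
* The simulator announces - rather than silently ignoring - a positive
  shared-event rate combined with a lesion-count distribution that makes
  shared events impossible.
* MPT ties, VAF-class pairs without observations, skipped screen
  covariates: all reported explicitly in the respective outputs.

## Problem sizes used by the test suite

Chosen to keep the default suite around two minutes on one core while
still exercising every oracle: the parsimony-vs-enumeration audit runs
1,000 random instances at up to 5 taxa; the Fisher-vs-hypergeometric audit
sweeps every 2x2 table with total at most 30 exhaustively plus 500 seeded
random tables with totals 31-40; classifier-vs-truth agreement runs 20
seeded 42-patient cohorts; VAF-median ordering runs 20 seeded 200-patient
cohorts; the clonality brute-force oracle runs 1,000 random matrices.

## A worked example

```{r example}
fx <- generate_study_fixture()
summarize_clonality(fx)
build_parsimony_tree(fx, "P25")
spectrum_table(fx, stratify_by = "smoking")
proportion_ci(57, 93)
```

## Limitations

Raw VAFs are compared without purity, ploidy or copy-number correction, so
cross-lesion VAF comparisons inherit any purity differences between
lesions. The parsimony machinery is exhaustive-only (at most 7 lesions).
There is no annotation layer: the package trusts the gene/alteration
labels it is given and validates only their structure. The association
screen is tumour-level and treats a patient's lesions as independent
observations, as the motivating analysis did - a generalized estimating
equation or mixed model would be more defensible for correlated lesions
but is out of scope here.
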