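---
title: "Methods: recessive burden in non-coding elements and MPRA activity calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive burden in non-coding elements and MPRA activity calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncburden)
```

# Overview

`ncburden` tests whether rare, recessive variation in classes of non-coding
elements — human accelerated regions (HARs), neural VISTA enhancers (VEs),
and conserved neural enhancers (CNEs) — is enriched in affected individuals
relative to familial controls, and provides the MPRA count analysis used to
measure the regulatory activity of such elements. This vignette documents
the statistical model, the tunable parameters, the synthetic-data
generators that back the tests, and the numerical and design choices made
where the methodology left room.

# The burden model

## Recessive events

A *recessive event* is, per individual and element, one of:

* a homozygous-alternate genotype (autosomes; female X only in
  sex-stratified female analyses),
* a hemizygous-alternate genotype on the male X,
* a compound-heterozygous pair: two heterozygous sites in the same element
  whose transmission-phased parental origins are one paternal and one
  maternal (in trans).

Because hemizygous events arise far more readily than female X homozygotes,
combined-sex analyses use autosomal events only; male- and female-stratified
analyses additionally admit chrX events of the corresponding kind. The
aggregation unit for compound heterozygotes is the element itself; the
alternative (element plus a flanking regulatory domain) is not identified by
the data we emulate, and the carrier statistic is insensitive to event
multiplicity within the unit.

Phasing is deterministic transmission phasing: a heterozygous child variant
is assigned to the single parent that carries the alternate allele.
Double-carrier parents, apparent de novo sites, and missing parental
genotypes are *ambiguous* and conservatively yield no compound-het call.
Statistical phasing of rare variants is known to be unreliable, so no
population-LD phasing is attempted; the cost is a conservative loss of the
double-het-parent configurations.

## Variant filters

Variants enter the analysis after per-cohort genotype QC, an allele
frequency (AF) cutoff, and classification:

* **QC profiles** (per genotype, never per site): the consanguineous WGS
  profile keeps AD > 2, DP > 10, GQ > 20; the targeted-sequencing profile
  keeps DP ≥ 10 ("minimum of 10x"), GQ > 20, AD > 4; the simplex WGS
  profile keeps AD ≥ 3, DP ≥ 5, GQ ≥ 20 on PASS records. The comparators
  follow the wording of each filter exactly (strict where "greater than"
  is stated, inclusive where "minimum of" is stated).
  Reference-homozygous genotypes are exempt from the alt-depth test, which
  measures support for an allele they do not carry. Missing QC fields fail
  any threshold that tests them.
* **AF cutoff**: the smallest value in a descending grid (default 0.01,
  0.005, 0.001, 0.0005) at which more than five predicted-damaging
  variants remain in cases and in controls for each sex; if no grid point
  qualifies the largest value is used with a warning. The AF source is
  INFO/AF when present, otherwise a founder-only estimate (founders avoid
  double-counting transmitted alleles). Whether the cutoff is applied
  against a cohort-internal or external reference frequency is a user
  choice via the AF source.
* **Classification** (ensemble of conservation-based predictors):
  exonic variants are excluded; variants with GERP > 2 and (CADD > 15 or
  DANN > 0.85 or FATHMM-nc > 0.85) are *damaging at a conserved base*,
  except that in UTRs/promoters (within 1 kb of a TSS) they must also
  overlap a phastCons conserved element; variants failing **all** predictor
  thresholds are *neutral*; everything else is *other* and enters neither
  numerator. Formalising "no predicted functional effect" as the
  conjunction of negated thresholds keeps the neutral class genuinely inert
  for the correction below; variants passing some predictors but failing
  the conservation gate are deliberately left out of both classes.
  Note the promoter/phastCons requirement restricts the *damaging* class
  only: a predictor-negative promoter variant stays neutral, which is what
  makes the consanguinity-correction set (below) non-empty.

## Statistics

With a = cases carrying ≥ 1 qualifying event, b = cases without,
c/d likewise for controls:

$$OR = \frac{a/b}{c/d},\quad
SE(\ln OR) = \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d},\quad
z = \frac{\ln OR}{SE}$$

with 95% CI $\exp(\ln OR \pm 1.96\,SE)$ and two-sided normal p-values.
"Rate" throughout is the carrier proportion (individuals with ≥ 1 event /
individuals): that is the quantity the 2×2 table counts, and it reproduces
the published odds ratios from the published rates. When any cell is zero
the Haldane–Anscombe 0.5 correction is added to all four cells; an empty
margin is undefined and flagged rather than forced. Benjamini–Hochberg
adjustment is applied across the element-class × cohort × sex family of one
run, with significance at 5% FDR. The *contribution* of an element class is
100 × (case rate − control rate), floored at zero.

## Consanguinity correction

Consanguineous and endogamous cohorts have elevated homozygosity at all
sites, inflating case rates regardless of effect. The harmonization check
compares likely-neutral variant rates between cases and controls with a
two-proportion z-test at α = 0.05 (the methodology only requires that the
rates "be compared"; the z-test is this package's concrete choice). When
the case rate is elevated, the damaging case rate is reduced
proportionally to the neutral excess observed at non-conserved promoter
sites, where no selection differential is expected:

$$\text{corrected case rate} = \text{damaging case rate}\times
\frac{\text{neutral control rate}}{\text{neutral case rate}}$$

The corrected carrier count a′ = round(corrected rate × (a+b)) keeps the
2×2 table integral so the Woolf SE remains defined, and OR, CI and
contribution are recomputed from the corrected table. Under a uniform
multiplicative inflation of case rates (affecting neutral and damaging
sites alike) the corrected OR is centred on 1; this neutrality is verified
by simulation in the test suite.

# Element-set construction

* **HAR merging**: overlapping intervals are merged to their union under
  0-based half-open coordinates; abutting intervals (end = start) do not
  overlap and stay separate.
* **VE subdivision**: long enhancers are reduced to conserved cores —
  maximal runs of bases with phastCons > 0.57 (strict, matching the
  printed ">"), merging runs separated by ≤ 50 intervening bases ("50 bp
  or closer" read inclusively; the boundary is covered by a test).
* **CNE selection**: candidate conserved segments pass all of: phastCons
  Viterbi log-odds > 400; ≥ 1 bp overlap with an enhancer chromatin state
  (EnhG, Enh, EnhBiv) in neurospheres, fetal brain or adult brain (no
  minimum overlap is stated by the source methodology, so 1 bp is used);
  no exon/splice overlap; and ≤ 2% of bases carrying a population variant
  (unique variant bases over element length).

Interval arithmetic is delegated to GenomicRanges/IRanges; all internal
coordinates are 0-based half-open, with VCF and score tables (1-based)
converted at parse time, eliminating off-by-one drift between element and
variant coordinates.

# MPRA analysis

Barcode counts are error-corrected with the directional network rule
(a barcode absorbs a Hamming-distance-1 neighbour when its count is at
least twice the neighbour's minus one, applied greedily from the
highest-count barcode and followed transitively along chains; ties broken
lexicographically for determinism). Columns are normalised to barcodes per
million; barcodes absent from the plasmid pool or from any cDNA replicate
are dropped; each surviving barcode yields one log2(cDNA/plasmid) ratio per
replicate, summarised per barcode by the mean across replicates.

A sequence is tested with the Wilcoxon rank-sum test of its barcodes'
pooled ratios against a reference distribution. The reference is all other
barcodes in the library by default — the methodology we emulate does not
name its null reference — with an explicit negative-control set as an
option. A sequence is *active* when its BH-adjusted p ≤ 0.05 and its
median exceeds the reference median, and *2-fold active* when the median
sits ≥ 1 log2 unit above the reference median. Sequences with fewer than
3 barcodes (configurable) are *untestable* rather than inactive. An element
is active if at least one of its probes is. A variant *modulates* activity
when either of its matched with/without sequences is active **and** the
rank-sum comparison between the two barcode sets passes 5% BH-FDR;
direction is the sign of the median difference. Mutagenesis libraries are
classified the same way against the probe's wild-type barcodes, after
excluding records whose variants all fall in flanking sequence, optionally
restricted to single-variant barcodes.

The rank-sum test uses the normal approximation with continuity correction
(`stats::wilcox.test`, `exact = FALSE`): barcode sets are compared against
references of hundreds of values, where the approximation is accurate and
ties are handled uniformly.

# Synthetic data

## Cohort generator

`simulate_cohort()` emulates a consanguineous/multiplex/simplex family
cohort: quad families (two parents, two children) by default; element sets
of 60/40/40 HARs/VEs/CNEs of 150–600 bp with Poisson(6) sites per element;
per-site allele frequencies Beta(3, 700) (mean ≈ 0.004, essentially all
mass below 0.01 — rare but dense enough that a desk-scale element panel
yields a workable carrier rate, standing in for the genome-wide panels of
real studies); 5% of elements X-linked; predictor scores drawn consistent
with each site's planted class (40% damaging-conserved).

Founder haplotypes are drawn per-site from the AF; children are generated
by Mendelian transmission with haploid male X. Consanguinity is modelled by
identical-by-descent sharing of founder alleles: with probability 4F per
site the mother's first allele is an IBD copy of the father's first allele,
which yields offspring autozygosity F (default 0.0625, first-cousin
offspring) while preserving Mendelian consistency — simpler than explicit
multi-generation pedigrees and sufficient to inflate homozygosity at rare
alleles. Affection is assigned retrospectively by a logistic penetrance on
damaging-recessive carrier status with non-carrier baseline 1/3, so the
expected case:control carrier odds ratio equals the planted value exactly
and equals 1 at neutral sites. QC fields default to passing values
(failures can be injected with `qc_fail_rate`), so the planted truth table
is recoverable and recall can be asserted at 100%.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, locus heterogeneity in effect sizes, population
stratification, sequencing error models, and relatedness beyond the
nuclear family. Passing tests therefore demonstrate the correctness of the
calling and statistics on clean inheritance, not robustness to artefacts
of real sequencing data.

`simulate_carrier_cohort()` draws per-individual carrier status directly
from the same penetrance model, skipping genotype materialisation. Large
replicate studies (null calibration at 10,000 cohorts of 200 cases/400
controls with control carrier rate 0.128, the published consanguineous-
cohort HAR control rate; CI coverage at 1,000 cohorts; correction
neutrality at 1,000 cohorts with inflation 1.3 and neutral control rate
0.4 — neutral carriers are common because non-conserved sites dominate)
run at this level, because the burden statistic depends on genotypes only
through the 2×2 carrier table. The genotype-level generator is validated
separately for exactly the properties the carrier-level one assumes:
Mendelian consistency, autozygosity ≈ F, 100% recall of planted events,
and absence of in-cis compound-het calls.

## MPRA generator

`simulate_mpra()` draws plasmid counts NB(mean 200, size 10) and cDNA
counts NB with mean scaled by 2^effect for active sequences (default 20%
active, log2 effect 1.5, 10 barcodes per sequence, 6 replicates — the
synthesized-oligo design). Optional with/without-variant sequence pairs
carry a planted effect delta for variant-effect validation. The generator
does not emulate barcode sequencing errors (directional clustering is
validated against an enumeration oracle instead), GC or length biases, or
replicate batch effects.

# Numerical choices and degenerate inputs

* Zero 2×2 cells → Haldane–Anscombe 0.5 on all cells; empty margins →
  `NA` with an `undefined` flag.
* Zero neutral case rate → the correction is an error (inapplicable), and
  an inverted neutral excess (control > case) raises the corrected rate
  with a warning rather than silently shrinking it.
* Zero control rate in the harmonization check → ratio undefined, flagged.
* Barcode clustering ties → lexicographic order; the output is invariant
  to input ordering.
* Empty element sets, empty count tables, and cutoffs excluding all
  variants produce explicit empty/flagged results, not errors.
* All simulation randomness flows from one mandatory seed; pipeline runs
  are byte-deterministic given config + inputs, and every output file
  carries the config hash and seed.

# Problem sizes used by the test suite

Unit tests run on trio-scale fixtures and 40–100-family synthetic cohorts
(a few hundred sites × a few hundred samples). The statistical property
tests use 10,000 carrier-level null cohorts, 1,000-cohort coverage and
correction studies, 20 + 20 simulated MPRA libraries of 100 sequences, and
1,000 random barcode sets against the clustering oracle; these sizes give
the assertions their stated resolution (e.g. a 99% binomial envelope of
±0.006 around a 5% type-I rate) while keeping the full suite around two
minutes on one core.

# Known limitations

* Transmission phasing drops double-het-parent compound-het
  configurations; the caller is conservative relative to statistical
  phasing and the burden estimates inherit that conservatism.
* The consanguinity correction assumes the neutral promoter set is free of
  selection differentials and large enough that its rate ratio is stable;
  with few neutral events the corrected OR is noisy.
* The Woolf z-test relies on the normal approximation of ln(OR); at very
  small carrier counts the test is only approximately calibrated (the
  continuity correction keeps it defined but not exact).
* Element-context annotation and predictor scores are taken as given in
  the score table; the package does not recompute conservation or
  chromatin state from raw data.
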