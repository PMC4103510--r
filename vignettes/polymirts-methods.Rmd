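---
title: "Methods: site scanning, allele effects and assay statistics in polymirts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site scanning, allele effects and assay statistics in polymirts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymirts)
```

# The model

## Pairing geometry

All predictions assume **gapless antiparallel alignment** between a mature
miRNA and a 3′UTR. If the UTR base at position $s$ pairs miRNA position 7,
miRNA position $i$ faces UTR position $s + (7 - i)$: the seed core (miRNA
2–7) occupies UTR $s..s{+}5$, position 8 faces $s{-}1$, position 1 faces
$s{+}6$, and the miRNA 3′ end reaches upstream of the seed match. Bulged
or offset alignments are deliberately out of scope: the site classes below
are defined on collinear pairing, and thermodynamic duplex models
(RNAhybrid-style free energies, context scores, conservation) are not
reimplemented here.

Base pairs are classified as Watson–Crick (A:U, U:A, G:C, C:G), **G:U
wobble** (G:U, U:G), or mismatch — `pair_type()` is the single source of
truth, and every other routine (scanner, oracle tests, generators) is
derived from it.

## Site classes and precedence

For each window the seed pairing at miRNA 2–8 and the identity of the UTR
base facing miRNA position 1 ("A1") determine the class:

| class | definition |
|---|---|
| 8mer | 2–8 Watson–Crick and A1 adenosine |
| 7mer-m8 | 2–8 Watson–Crick, no A1 |
| 7mer-A1 | 2–7 Watson–Crick, A1 adenosine |
| 6mer | 2–7 Watson–Crick only |
| noncanonical-wobble | one G:U in 2–8, rest Watson–Crick |
| noncanonical-mismatch | one mismatch in 2–8, rest Watson–Crick |

Canonical labels take precedence (8mer > 7mer-m8 > 7mer-A1 > 6mer), and a
window receives exactly one label. The A1 condition is the *identity* of
the UTR base, not its pairing, following the standard seed-match
convention. One consequence worth stating: a single deviation at miRNA
position 8 with 2–7 fully paired is classified canonical (7mer-A1 or
6mer), because the defining window of those classes is 2–7; non-canonical
labels can therefore only arise from a deviation at positions 2–7. The
synthetic-data generator places its non-canonical implant deviations
accordingly.

6mer sites are emitted but flagged `low_confidence`: a 6-nt match alone is
weak evidence, yet such weak/non-seed sites must be representable because
annotated screens list them. Overlapping sites — same or different miRNAs,
different offsets — are all reported; there is no greedy suppression,
since per-(variant, miRNA) classification needs every candidate site.

The **supplementary score** counts Watson–Crick pairs between miRNA
positions 13–16 and the facing UTR bases (positions off either molecule
contribute 0, giving the `[0, 4]` range). This is the 3′ compensatory
region where a variant can sit inside a site's footprint without touching
the seed.

## Variant application and allele effects

Variants are SNVs, pure deletions, or pure insertions with 1-based
inclusive coordinates; the affected interval is
`[position, position + nchar(ref) - 1]`. `apply_allele()` hard-checks the
reference allele against the sequence (a mismatch is an error naming
position, expected and found — cheap insurance against fixture or
coordinate drift) and returns a coordinate map that is bijective outside
the affected interval, maps deleted bases to nothing, and preserves order.
Its inverse polymorphism is returned alongside, so applying an allele and
its inverse provably round-trips.

`allele_effect()` compares the sites of one miRNA whose footprints
intersect the variant on the two alleles. The rescan is windowed for
efficiency but anchored on the full sequence, so footprints truncate at
the true UTR ends and the windowed result is identical to a full rescan
restricted to the neighborhood (a property the test suite checks
directly). Calls follow set logic: `site_loss` when reference sites
disappear, `site_gain` for the reverse, `type_change` when sites persist
with a different class or seed pairing (compared as the multiset of
(class, wobble count, mismatch count)), else `unchanged`.

"In or near" a site is operationalized as footprint intersection with a
configurable `flank` (default 0). Any-overlap semantics apply, so a
deletion spanning a boundary counts. Classification is per
(variant, miRNA) pair: one variant can be a seed hit (`Y`) for one miRNA
and a footprint-only hit (`N`) for another, which matches the
one-row-per-miRNA layout of published polymiRTS tables.

## The packaged reference table

`ncstn_polymirts()` ships the published Nicastrin 3′UTR screen: 22 rows of
(polymorphism, predicted miRNA, seed flag, neocortex raw reads) across 9
loci. Two ambiguities in the source are documented rather than resolved:
whether UTR positions count from the first base after the stop codon or
from the cloned ~700-bp fragment start, and whether an `N` flag denotes a
non-seed footprint overlap or a non-canonical seed. The fixture stores the
printed values; the scanner's own classification of any given sequence is
reported separately and never forced to match. For the same reason the
scanner does not promise to regenerate the table's miRNA list from public
sequences — the table is consumed as data.

# Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| expression cutoff | 45 | raw small-RNA reads | inclusive (`>=`); the published narrowing retains the boundary miRNA sitting at exactly 45 reads, which pins the inclusive convention |
| `flank` | 0 | nt | "near" defaults to the footprint itself; widen explicitly when a looser neighborhood is wanted |
| `min_supplementary` | 0 | Watson–Crick pairs | non-canonical sites are not filtered on 3′ pairing unless asked |
| `max_deviations` | 1 | seed deviations | the minimal faithful reading of "a G:U wobble or a seed mismatch"; more than one deviation is not a recognizable site class |
| Bonferroni family | vs-control comparisons | — | post-hoc stars in reporter assays compare each miRNA to SCR, not all pairs |

miRNA identity is the exact name string: no `-5p`/`-3p`/star folding is
applied, because silent nomenclature normalization corrupts joins between
prediction, expression and assay tables. Supply an explicit mapping table
if harmonization is needed.

# Statistics

Scrambled-control (SCR) normalization divides each firefly/renilla ratio
(or band/GAPDH ratio, or Aβ concentration) by the **mean** of the SCR
group within the same experiment — mean rather than median, matching
standard dual-luciferase practice — so the control mean is exactly 1 per
normalization group and every relative quantity is invariant to rescaling
the denominator channel. Normalization is per experiment (and per
construct when constructs are present); whether pooling across
experiments would be preferable is unknowable from typical figure
legends, so the per-experiment choice is implemented and flagged here.
Aβ40 and Aβ42 are never mixed; mature and immature target bands are
quantified separately by default with a `summed` option.

The tests are computed from first principles and cross-checked in the
suite against the base R implementations to 1e-8:

* one-way ANOVA from between/within sums of squares; Bonferroni post-hoc
  t-tests vs the control use the pooled residual variance and residual
  degrees of freedom (the classical convention), multiplied by the number
  of vs-control comparisons and capped at 1;
* balanced two-way ANOVA with interaction from sums of squares; an
  unbalanced or incomplete design is an explicit error, not a silent
  refit under a different sum-of-squares type;
* Student's paired t-test on differences.

Degenerate inputs follow fixed conventions: zero effect sum of squares
gives F = 0, p = 1 (likewise t = 0, p = 1 for all-zero differences);
a zero residual with a positive effect gives an infinite statistic and
p = 0. The two-sided Fisher exact test sums hypergeometric point
probabilities not exceeding the observed one (with the customary 1e-7
relative slack against floating-point ties) — stated explicitly because
two-sided conventions differ. Carrier-frequency intervals are
Clopper–Pearson via beta quantiles.

# The synthetic-data generator

`simulation_spec()` defaults encode the study conditions the package is
tested under: a 700-nt UTR (the length of a typical cloned 3′UTR
fragment) at GC 0.5 with three implanted sites; the three validated
variant archetypes (an in-seed 2-bp deletion, an in-seed SNV, and a
compensatory-region SNV); negative-binomial expression counts (variance
$\mu + \alpha\mu^2$, one miRNA placed exactly at the 45-read boundary);
dual-luciferase wells in 3 experiments × triplicate (n = 9 per condition)
with true repression factor r = 0.5 and multiplicative lognormal noise
σ = 0.1 on the firefly/renilla ratio (intensities are positive ratios, so
noise is multiplicative by nature); and a cohort of 511 cases with 1
carrier vs 631 controls with none, as exact counts.

Ground truth is exact by **implant-and-reject** construction, not
post-hoc labelling: site windows are written into the sequence, and the
background is redrawn until the scanner finds no accidental canonical
site for any listed miRNA outside the implants. `simulate_study()`
extends the same rejection across stages: occasionally (about 0.7% of
backgrounds) a deletion junction recreates a weak site for every possible
in-seed placement, in which case the whole (UTR, variant) layout is
redrawn under a derived attempt seed rather than accepting a mislabelled
variant or weakening the verification scan. Everything is deterministic
given the spec and seed; variant-construct attenuation moves the expected
relative activity from r toward 1 by the stated fraction
($r + a(1-r)$), with full attenuation modelling a repression-abolishing
seed deletion.

What the generator does **not** emulate: real transcriptome backgrounds
(compositional structure, repeats, conserved elements), read-level
sequencing noise, linkage between variants, cell-line miRNome context, or
plate/batch effects in reporter data beyond the single lognormal term.
Passing tests therefore demonstrate correctness of the algorithms and
calibration of the statistics under the stated generative model — not
predictive accuracy of seed matching on biological sequence, which is
bounded by the seed-match model itself.

# Numerical and design choices

* Internal alphabet is RNA; DNA input is mapped T→U on read because the
  pairing logic is defined over RNA. N and ambiguity codes are rejected
  rather than wildcarded — the scanning substrate must be fully
  determined.
* User-facing coordinates are 1-based inclusive everywhere; no 0-based
  value ever reaches a file or message.
* Duplicate miRNA names in an expression table are an error, not
  last-wins: the join to records would be ambiguous.
* Report rows are totally ordered (position, miRNA, SNP id), so writing
  twice is byte-identical and write→read is lossless.
* Output ordering ties in the scanner break by miRNA name then class
  label, making every result reproducible to the byte.
* In the two-way ANOVA, interaction and residual sums of squares are
  clamped at zero against negative floating-point residue on noiseless
  inputs.

# Problem sizes in the shipped checks

The test suite validates the scanner against an exhaustive brute-force
enumeration on 1,000 random (UTR, miRNA) pairs (UTRs 120–220 nt), calls
100 constructed seed deletions (site loss in all of them), recovers
r = 0.5 within ±0.05 in ≥ 95% of 600 per-miRNA estimates across 200
seeded runs, and measures the one-way ANOVA type-I error at α = 0.05
over 10,000 null simulations (three groups of three), expecting it inside
[0.03, 0.07]. These sizes were chosen so the full suite and the
acceptance script each complete in a couple of minutes on a single CPU
while keeping the Monte-Carlo error of each check well below its decision
band.

# Known limitations

* The seed-match taxonomy is the classical one; bulged sites, offset
  6mers and 3′-compensatory-only sites are not modelled, so a variant
  could in reality act through a site class this scanner cannot emit.
* Repression magnitude is not predicted from sequence; the package
  quantifies *measured* repression and tests allele differences.
* The reference table cannot be regenerated from public sequence alone
  (see above); analyses that start from it inherit its printed
  ambiguities.
* The Fisher test and carrier frequencies treat samples as independent;
  relatedness or stratification must be handled upstream.
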