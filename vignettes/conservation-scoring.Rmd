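---
title: "Scoring human miRNA conservation from population allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring human miRNA conservation from population allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirconserve)
```

## The model

`mirconserve` measures how strongly purifying selection has acted on a
mature human miRNA, using only within-population variant data. The unit
of analysis is the collapsed mature miRNA: mature sequences identical
across multiple genomic loci are pooled under a single name, with
variants de-duplicated by (locus, genomic position, ref, alt) and the
copy number recorded.

Four component scores are computed per miRNA of length $L$
(nucleotides), all in $[0, 1]$ with 1 meaning maximal conservation:

$$\mathrm{SCS} = 1 - \frac{\sum f_s}{n_s}, \qquad
  \mathrm{NSCS} = 1 - \frac{\sum f_{ns}}{n_{ns}}, \qquad
  \mathrm{PCS} = 1 - \frac{p_v}{L}, \qquad
  \mathrm{TVS} = 1 - \frac{v_t}{L}$$

where $f_s$ ($f_{ns}$) are allele frequencies of the $n_s$ seed
($n_{ns}$ non-seed) variants, $p_v$ is the number of distinct mature
positions with at least one variant, and $v_t$ the total variant count.
The seed is positions 2–7 of the mature sequence, 5′→3′. The Overall
Conservation Score is the convex combination

$$\mathrm{OCS} = \alpha\,\mathrm{SCS} + \beta\,\mathrm{NSCS} +
  \gamma\,\mathrm{PCS} + \delta\,\mathrm{TVS},$$

with $\alpha + \beta + \gamma + \delta = 1$, all weights positive, and
$\alpha > \beta$ (seed conservation must weigh more than non-seed
conservation). The reference weights are $(0.2, 0.1, 0.6, 0.1)$.

Assumptions worth making explicit:

- *Conservation here is intra-human*: a variant-free miRNA may simply be
  poorly covered; no cross-species alignment enters the score.
- SCS/NSCS average allele frequencies over observed variants, so one
  common variant depresses them more than many rare ones; the count
  burden is carried by PCS and TVS instead.
- AF-weighted and count-based components are deliberately partially
  redundant ($v_t \ge p_v$ always); the weight optimization decides how
  much each view matters.

## Numerical and degenerate-input choices

- $n_s = 0$ (or $n_{ns} = 0$) makes the corresponding score 1: absence
  of variants is maximal conservation; the raw formula is 0/0 there.
- A miRNA with *no* passing variants at all gets OCS exactly 1 and a
  `zero_variant` flag; it is excluded from HC/LC selection, the
  optimization universe and downstream comparisons, because it carries
  no population information.
- PCS and TVS are clamped to $[0,1]$: $v_t > L$ is possible at dense
  multiallelic sites.
- InDels: the first affected miRNA-sense position is the variant's
  position; a deletion spanning $k$ mature positions contributes all $k$
  to the $p_v$ position set but 1 to $v_t$ ($p_v$ is positional
  coverage, $v_t$ an event count). A variant is a *seed* variant if any
  affected reference position falls in 2–7.
- Ti/Tv is computed on genomic DNA alleles (a mutation-process
  property), while ref:alt pair classes (A:G, C:U, G:U) use miRNA-sense
  RNA alleles; InDels are excluded from both.
- HC/LC selection takes the top/bottom $\lfloor tN \rfloor$ by OCS with
  lexicographic name tie-breaks, so results are reproducible
  bit-for-bit.

## Coordinates and hairpin geometry

All coordinates are 1-based inclusive (GFF3 convention); VCF positions
are used as-is, multiallelic sites split per alternate allele before
filtering. Mature positions run 5′→3′ on the annotated strand; on the
minus strand alleles are reverse-complemented and T→U gives the
miRNA-sense RNA.

Precursor hairpins are partitioned into 5′ lower stem, 5p arm, terminal
loop, 3p arm and 3′ lower stem. When only one arm is annotated, the
opposite arm is inferred from the canonical Drosha/Dicer geometry: an
arm of equal length placed so that the duplex carries a 2-nt 3′
overhang at both ends. Concretely, if the annotated 5p arm starts $d$
nt into the precursor, the inferred 3p arm ends $d - 2$ nt before the
precursor end (mirrored for a known 3p arm), which propagates the
3′-overhang asymmetry through a fully paired lower stem. Inferred arms
occupy their own partition rows and are excluded from loop/stem
tallies. Flanks default to 25 nt per side when no primary transcript is
annotated (the annotation dialect read here only carries hairpins and
matures); "upstream" is the transcription-sense 5′ side.

Precursor-level tallies are emitted separately from mature-level
tallies: a variant inside a mature arm yields both a mature-context row
and a precursor-context row (region `arm_5p`/`arm_3p`), so either
inclusion rule can be applied downstream.

## Weight optimization

The constrained grid at step 0.1 has exactly 34 combinations. For each
combination, the OCS ranking is compared against two independent
expression datasets: per dataset, the universe is the intersection of
scored and expressed names (fixed before any top fraction is taken);
at each threshold $t \in \{0.05, 0.1, 0.15, 0.2, 0.25\}$ the F1 of
top-conserved vs top-expressed sets is averaged over datasets. Per
threshold, each combination's mean F1 becomes a z-score across
combinations (population standard deviation; a zero-spread threshold
contributes z = 0 for all). The combination with the highest mean
absolute z across thresholds wins; ties break by higher grand-mean F1,
then lexicographically smallest weights.

Selection by $|z|$ follows the stated procedure exactly, but it can in
principle reward a consistently *under*-performing outlier. The
grand-mean tie-break only guards exact ties, so a `selection = "signed"`
switch is provided for users who prefer the average signed z.

## Compensatory miRNA–target variant pairs

Seed-match sites are typed canonically: the 6mer core is the UTR's
reverse complement of seed positions 7..2; `7mer-m8` adds a match to
position 8 at the site's 5′ end, `7mer-A1` an adenosine opposite
position 1 at the 3′ end, `8mer` both. Site search is exact string
matching on the representative (longest) reference UTR, restricted to
experimentally supported miRNA–gene interactions; one site per core
locus at the strongest type.

A pair requires *simultaneous* variants at aligned duplex positions
(miRNA positions 2–8; position 1 is never base-paired, so variants
there never pair). Only SNV–SNV duos are classified: the pair is
*compensatory* iff the two alternate alleles form a Watson–Crick pair.
G:U after substitution counts as disruptive by default — a wobble is
not complementary — with an `allow_wobble` switch. A pair is
population-specific iff both variants attain their per-population AF
maximum in the same, strictly unique, population; AF ties or all-zero
AF vectors fail the uniqueness rule. When a variant duo aligns in
several site occurrences it is reported per occurrence.

## Downstream statistics

Permutation tests use the add-one estimator
$p = (1 + \#\{\text{null} \le \text{obs}\})/(n_{\text{perm}} + 1)$ with
an explicit seed, so p-values are in $(0,1]$ and bit-reproducible. The
arm-balance null re-pairs 5p and 3p scores across precursors (random
arm pairing is the stated chance model, rather than sign-flipping
deltas). Arm/target binning uses |ΔOCS| quantile cuts (equal-count
bins); precursors with exactly equal arm OCS are excluded from win
counting. "Upstream of the representative APA site" uses strict
inequality on the site start, restricted to genes with ≥ 2 APA sites;
the representative site is the one with the highest read support. All
two-group tests (Mann–Whitney AF comparisons, multi-copy Wilcoxon,
Fisher 2×2 tests) are two-sided by default with one-sided options;
fully tied rank tests report p = 1. Fisher density tests place the
region's base-pair total minus the variant count in the complement
cell. No multiple-testing layer is applied; tests are reported singly.

## The synthetic-fixture generator

`make_fixture()` emulates the *shapes* of the real inputs — a
miRBase-dialect GFF3 (default 10 precursors / 16 matures, 20–24-nt
arms, ~30% minus-strand, one multi-copy mature pair), a gnomAD-style
variant table with joint plus nine per-population AFs, two expression
tables, a UTR FASTA with planted seed-match sites, interaction / APA /
ClinVar-style tables — with every planted truth recorded in a manifest.
Design choices:

- AFs are drawn from class-conditional scaled Beta distributions
  truncated to the class interval (rare ≤ 0.01 < SNP ≤ 0.05 < common),
  so planted classes respect the classification boundaries by
  construction.
- Highly conserved miRNAs carry exactly one rare non-seed variant
  (keeping them scoreable rather than zero-variant); least conserved
  miRNAs carry 6–10 variants including two seed SNPs and a two-position
  deletion, which separates the two groups' OCS with a wide margin.
- Mid-burden miRNAs decouple the components: the number of distinct
  variant positions (3–5, driving PCS) is drawn independently of a
  latent allele-frequency burden that jointly drives SCS, NSCS and the
  depth of multiallelic stacking behind TVS. With expression generated
  as a monotone function of PCS (plus optional noise), PCS is the only
  component aligned with expression, and the weight search recovers the
  γ-maximal combination (0.2, 0.1, 0.6, 0.1) — that is the planted
  truth the optimizer is tested against.
- Compensatory/disruptive pairs are planted by writing a seed-match
  site into a UTR and mutating aligned seed/UTR positions; disruptive
  alternates avoid both Watson–Crick and wobble pairing, and
  non-population-specific pairs force the two members' argmax
  populations apart. Background UTR sequence is scrubbed of accidental
  seed-core matches of the interacting miRNAs, so detection recovers
  exactly the planted pairs.
- One RNG stream per output file, all derived from the master seed:
  identical specs give byte-identical files, and adding a file never
  perturbs the others.

`null_fixture()` keeps the file shapes but removes all structure:
uniform variant placement, expression independent of scores, pair
classifications and population assignments as independent coin flips.
The calibration tests run ~200 such fixtures and check that permutation
and Fisher p-values are approximately uniform (Kolmogorov–Smirnov
distance < 0.1). Because exact-test p-values are discrete and
conservative at small counts, the calibration fixtures plant 380 pairs
across a balanced group split (40 two-arm precursors), making the
achievable p-value lattice much finer than the 0.1 band; this is a
resolution requirement of the check, not a tuning of the science.

What passing these tests does *not* show about real data: the generator
makes no attempt to match real gnomAD AF spectra beyond class
membership, UTRs are random sequence with planted motifs, expression is
a clean monotone link rather than tissue-structured counts, and linkage
between nearby variants is absent. Results on real inputs depend on
annotation and AF quality in ways the fixtures cannot probe.

## Problem sizes used in the tests

Unit tests run on hand-built examples and 10–24-precursor fixtures;
oracle suites use 150 random Fisher tables (total ≤ 500), 1,000 random
variant sets for the OCS formula, and 1,000 random UTRs for the site
finder; calibration uses 200 null fixtures with 199 permutations each.
These sizes were chosen so the full suite completes in a few minutes on
one CPU while keeping every check statistically meaningful.

## Known limitations

- The "discrepant AF" filter is consumed as an input flag; no numeric
  re-derivation is attempted (no threshold is defined for it here).
- Variants are mapped to overlapping loci independently; no attempt is
  made to resolve which annotation is "primary".
- Site search does not re-scan alternate alleles: variant alleles are
  applied per aligned position of reference-sequence sites, so sites
  created de novo by variants are out of scope, as are thermodynamic
  duplex models and 3′-supplementary pairing.
- Population-mode scoring treats AF > 0 as "observed in population",
  which is sensitive to AF reporting precision.
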