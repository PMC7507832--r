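---
title: "From capsid lattice to metagenome: methods behind giantvirion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From capsid lattice to metagenome: methods behind giantvirion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(giantvirion)
```

## Overview

giantvirion implements the computational chain used to characterize a
giant-virus particle and trace one of its metabolic capabilities into the
environment. Four stages share one backbone: the capsid lattice fixes the
major capsid protein (MCP) copy number; that constant converts label-free
mass-spectrometry intensities into per-virion protein copies; packaged
proteomes are then compared across viruses by reciprocal best hits (RBH);
and the same threshold-based decision logic is reused to screen assembled
metagenomic contigs for virus-encoded polysaccharide lyases. A simulator
generates every input with planted ground truth, so the whole chain is
testable without any external data.

## Capsid lattice arithmetic

A quasi-equivalent icosahedral capsid assembled from pseudo-hexameric
trimeric capsomers is indexed by lattice steps $(h, k)$ counted between
adjacent fivefold vertices. The triangulation number
$T = h^2 + hk + k^2$ gives the number of jelly-roll subunits per
asymmetric unit, hence per particle:

* $60T$ jelly rolls in total;
* $60$ of them in the 12 pentameric vertex capsomers (five single
  jelly rolls each) — a fixed constant, since every icosahedron has 12
  vertices;
* the remaining $60(T-1)$ from $10(T-1)$ trimeric capsomers of
  double-jelly-roll MCPs, i.e. $30(T-1)$ MCP copies.

The hexameric capsomers organize into symmetrons: 12 pentagonal patches
(pentasymmetrons) around the vertices and 20 triangular patches
(trisymmetrons) on the faces. The pentasymmetron size — 30 hexameric
capsomers plus the central pentamer — is conserved across icosahedral
giant viruses, so it is exposed as a constant
(`PENTASYMMETRON_HEXAMERS`), not a parameter, and the trisymmetron size
is derived: $(10(T-1) - 360)/20$. For lattices too small to accommodate
30-hexamer pentasymmetrons (or whose counts are not divisible by 20),
`capsid_architecture()` raises a symmetron-decomposition error rather
than returning a fractional patch size.

$T$ is invariant under swapping $h$ and $k$ and under the lattice's
chiral reflection; the package canonicalizes to $h \le k$ and does not
model handedness — only counts. `hk_candidates_from_T()` enumerates all
canonical solutions by brute force over $0 \le h \le k \le \lceil\sqrt
T\rceil$; since the $h = 7$ step is conserved across known icosahedral
giant viruses, recovering $k$ from an observed $T$ with `h_fixed = 7` is
the typical use. Note the "capsomers" figure reported for these viruses
counts hexameric capsomers only ($10(T-1)$), excluding the 12 pentamers.

```{r geometry}
capsid_architecture(7, 8)
```

## Anchor-based per-virion quantification

With the MCP copy number fixed structurally ($30 \times 168 = 5040$ for
$T = 169$), each protein's copies-per-particle in replicate $r$ is

$$\mathrm{copies}(i, r) = N_\mathrm{anchor}
  \frac{I(i, r)}{I(\mathrm{anchor}, r)}.$$

Design choices a user should know:

* **Per-replicate first, then average.** Copies are computed within each
  replicate and averaged over the replicates where the protein was
  detected (arithmetic mean). This matches the dispersion statistic — the
  percent CV (sample SD over mean, $n-1$ denominator) — computed on the
  same per-replicate values, and makes the procedure invariant to
  arbitrary per-replicate rescaling (instrument response, loading).
* **No imputation.** Missing intensities stay missing and are carried as
  explicit detection counts; vendor-side resampling imputation is out of
  scope. A protein detected in fewer than two replicates has an undefined
  CV, reported as `NA`.
* **Replicates without the anchor are dropped** (with a warning): a run
  in which the anchor is undetected carries no scale.
* **Host proteins** are processed identically and then flagged: detected
  in every replicate with CV below 36% → "possibly packaged"; in every
  replicate with higher CV → "putative contaminant"; otherwise
  "insufficient evidence". The 36% default reflects the empirical
  observation that consistently packaged components co-purify with low
  run-to-run dispersion.
* **Percentages** (category fractions) are rounded half away from zero to
  integer percent, the convention used in reported summaries.

The reference table of the 43 packaged AaV proteins
(`aav_packaged_proteins()`) records a per-protein run count rather than
raw intensities; `detection_table()` expands it into a detection-pattern
table for the summary functions. Counting its run-count column yields 4
proteins at exactly two runs; the prose summary accompanying the original
table says 5. The package reports what it counts, and the test suite pins
only the internally consistent aggregates (43 total, 14 in all three
runs, regions 12/18/13, transcription 14%).

## Reciprocal best hits and presence/absence clustering

`best_hits()` consumes standard 12-column tabular search output. The
e-value cutoff ($< 10^{-15}$) is a strict inequality, as are all
thresholds in the package. The best-hit rule is bitscore-maximal; because
score ties do occur with small integer-rounded bitscores, the tie-break
chain (higher bitscore → lower e-value → lexicographically smallest
subject) is fully deterministic across platforms. Multiple HSPs for one
query/subject pair are collapsed to the single best record first, the
common RBH convention. A pair is emitted only when both directions agree
(`reciprocal_pairs()`), and `packaged_rbh()` restricts to pairs packaged
by both viruses.

For clustering, raw pairs are not directly usable as virus × feature
columns, so RBH edges are first merged into connected components
(`cluster_components()`); each component is one ortholog feature a virus
either contributes to or not. This component-level interpretation is a
deliberate design choice; pair-level features would double-count
multi-virus orthologs. Virus rows of the 0/1 matrix are compared with
Bray–Curtis dissimilarity — on binary data identical to Sørensen–Dice,
$1 - 2|A\cap B|/(|A|+|B|)$ — and clustered by unweighted average linkage
(UPGMA; the linkage is parameterized, since published analyses do not
always state theirs). Two all-zero rows are defined as identical
(dissimilarity 0, with a warning) rather than undefined. Merge heights
are halved onto branches, so cophenetic distances reproduce merge
heights exactly.

## The metagenomic lyase screen

The screen encodes a fixed decision procedure per contig:

1. **Lyase call**: any translated-search hit against a biochemically
   characterized polysaccharide lyase with $e < 10^{-10}$ (strict).
2. **Viral call**: any NCVOG (giant-virus orthologous group) marker hit
   with $e < 10^{-10}$; the best passing hit (minimum e-value, ties by
   maximum bitscore, then reference id) assigns the putative family.
   Family labels are free strings from the annotation file — nothing is
   hard-coded.
3. **Excision and translation**: passing hits on the same strand with
   overlapping intervals merge into one region. External 1-based
   inclusive coordinates are converted on ingest to 0-based half-open
   forward-strand intervals; all internal arithmetic uses the latter.
   The merged region is trimmed to a multiple of 3 in the reading frame
   of its highest-bitscore hit (anchored at that hit's start on the
   forward strand, its end on the reverse), reverse-complemented when
   needed, and translated with the standard code; internal stops are
   kept as `*`. Conflicting frames among merged hits warn and defer to
   the dominant hit.
4. **Length filter**: the peptide passes when strictly longer than 0.8 ×
   the shortest reference lyase. "Near full-length" is operationalized by
   this rule alone; no additional coverage criterion is invented.

Station summaries pool all depths and size fractions per station;
contigs with multiple distinct loci are reported once at contig level
with the locus count (`n_loci`) preserved, since published totals do not
state which convention they used. Abundances are normalized as RPKM
($\mathrm{reads} \times 10^9 / (\mathrm{length_{nt}} \times
\mathrm{library})$) — the normalization formula behind published
"normalized read abundances" is unstated, so the package uses this
standard form and labels it as such. Group differences use classical
one-way ANOVA with Tukey HSD, via `stats::aov()`/`TukeyHSD()`. Read
mapping itself is external; the package consumes count tables.

## The synthetic-data generators

Each generator is a pure function of its parameters and seed
(byte-identical reruns) and returns its planted truth alongside the
data:

* `simulate_virus_proteomes()` plants one-to-one ortholog groups as
  point-mutated copies of a common random peptide (i.i.d. uniform over
  the 20 residues, lengths 100–600 aa — composition-matched sequences
  are unnecessary because downstream logic only consumes scores and
  coordinates). Defaults (6 viruses, 3 families, 4 within-family and 1
  between-family ortholog groups per pair, 60% packaged) give the
  within/between contrast the comparison stage needs at test scale.
* `simulate_hit_tables()` scores planted pairs as
  $N(\mathrm{bits/aa}\times\mathrm{length},\sigma)$, identically in both
  directions, with e-values generated directly (the pipeline uses them
  only as thresholds and tie-breakers, so deriving them from a score
  model would add nothing testable). Decoy hits with a controllable mean
  allow recall-degradation experiments.
* `simulate_intensity_table()` draws $I(p,r) = s_r \cdot
  \mathrm{copies}(p)\cdot e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma^2)$, with random per-replicate scales
  $s_r$; missingness is Bernoulli per cell and never hits the anchor. At
  $\sigma = 0$ recovery is exact; at $\sigma = 0.1$ with 3 replicates
  the mean relative error over 200 proteins stays under 15%.
* `simulate_metagenome()` embeds exact reverse-translated reference
  peptides (one fixed codon per residue, the first codon of the standard
  table) at random loci, strands, and frames; viral contigs additionally
  embed an NCVOG marker in the left flank. True loci get e-values far
  below threshold ($10^{-30}$, $10^{-25}$), decoys near but above it
  ($10^{-8}$), so the planted truth is recoverable exactly — by design.
  Defaults (3 stations × 10 lyase contigs, 20% viral, 60 decoys) match
  the screen's test conditions.

What the simulators do *not* emulate: residue composition, alignment
ambiguity, chimeric or fragmented assemblies, read-level noise, and
database incompleteness. Passing the planted-truth suites therefore
demonstrates the decision logic is implemented exactly as specified —
not that the thresholds themselves are optimal on real survey data, nor
that field-scale totals (thousands of lyase contigs, hundreds of RBH
pairs across real proteomes) are reproduced; those depend on external
assemblies and a specific search engine build and are covered instead by
the property-based suites.

## Numerical and interface choices

* All cutoffs are strict inequalities and exposed as parameters
  (`pipeline_config()`), defaulting to $10^{-15}$ (RBH), $10^{-10}$
  (screen), 0.8 (length fraction), 36% (CV), 5040 (anchor copies).
* Reverse-strand frame magnitudes require the contig length; when a hit
  table is read without lengths, the sign is kept and the magnitude set
  to 1 (excision anchors on coordinates, never on the magnitude).
* Problem sizes in tests — e.g. 50 random RBH instances of ≤ 30 proteins
  per side, 100 random presence matrices, 6-leaf UPGMA oracles, a
  90-contig metagenome — are small enough to enumerate exhaustively
  against independent oracles while exercising every code path.
* Ties in UPGMA input distances resolve by `stats::hclust` order, which
  is deterministic for a fixed input matrix.

## Known limitations

* The geometry model covers quasi-equivalent lattices with 30-hexamer
  pentasymmetrons; non-icosahedral or decorated capsids (fibers, unique
  vertices) are out of scope, as is any density-map work.
* Quantification assumes intensities proportional to molar abundance
  within a run; no peptide-level inference or FDR modelling.
* The RBH engine consumes search output; it does not run the search.
* The screen reports putative viral origin from marker co-occurrence —
  on real contigs this is evidence, not proof, of viral origin.
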