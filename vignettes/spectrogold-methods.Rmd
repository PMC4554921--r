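---
title: "SpectroGold methods: spectral-count fraction profiling and immunogold stereology"
author: "SpectroGold authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpectroGold methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpectroGold)
```

SpectroGold implements two quantitative procedures that together
characterize an isolated organelle: label-free spectral counting of
subcellular fractions with parsimony protein inference, and zonal
quantification of immunogold labelling on electron micrographs. This
vignette explains the models, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Parsimony protein inference

The input is a set of confidently assigned peptide sequences and a
protein database. `mapPeptides()` assigns each peptide to every protein
whose sequence contains it as an exact substring. Redundancy in the
database — homologous sequences, truncated or partial entries, splice
variants — makes the naive protein list over-count, so
`inferMinimalSet()` reduces it in three phases:

1. **Identity merge.** Proteins with identical matched-peptide sets are
   indistinguishable on the evidence and merge into one group; the
   lexicographically smallest accession represents the group.
2. **Subset absorption.** A protein whose peptide set is a strict subset
   of another remaining protein's set adds no explanatory power and is
   absorbed as a member of the larger group. When several supersets
   exist, the one sharing the most peptides wins, ties going to the
   lexicographically smallest representative. (For true subsets every
   superset shares the full set, so the tie-break is what decides; the
   attribution of subsumed members is not identifiable from the data and
   we state our convention rather than pretend otherwise.)
3. **Minimum cover.** The remaining groups are reduced to a minimum set
   that still explains every peptide. Greedy selection — repeatedly keep
   the group explaining the most not-yet-covered peptides, ties broken
   by total peptide count then accession — gives the initial solution;
   any retained group whose peptides are all covered by the other
   retained groups is then pruned (smallest evidence first). When at
   most 15 candidate groups survive absorption, an exhaustive
   iterative-deepening search certifies a true minimum and, among
   minima, returns the lexicographically smallest. We added the pruning
   and certification steps because plain greedy cover is demonstrably
   suboptimal on a small but real fraction of instances (a homologue
   whose peptides are jointly covered by two variants is the canonical
   case), and the scientific claim of the procedure is *minimality*.

All tie-breaks are lexicographic in accession, so the result is
invariant to database order. After selection, peptides are re-labelled
**unique** (contained in exactly one retained group's members) or
**shared**; peptides matching no database protein are *orphans*,
reported and excluded — a complete search database cannot produce them,
but toy databases can.

Isoleucine and leucine are distinct by default; `equateIL = TRUE`
conflates them, as isobaric residues are indistinguishable to most
search engines.

## Spectral counting and apportionment

Each PSM counts once. Spectra of unique peptides increment their group
directly. A shared peptide with $s$ spectra in a sample is divided among
the $k$ groups containing it proportionally to each group's unique
evidence $u_g$ **in that same sample**:

$$\mathrm{alloc}(g) = s\,\frac{u_g}{\sum_h u_h},
\qquad \mathrm{alloc}(g) = s/k \ \text{ when } \sum_h u_h = 0 .$$

Two readings of "unique evidence" are defensible: unique *spectral
counts* or distinct unique *peptide* counts. The default is spectral
counts (`method = "spectra"`), because spectra are the quantity being
divided; `method = "peptides"` provides the alternative. Apportionment
is strictly per sample, never pooled across fractions, so fraction
profiles stay independent. The allocation to the last involved group is
computed as the arithmetic remainder $s - \sum_{g<k}\mathrm{alloc}(g)$,
which conserves per-sample totals at full floating precision while
leaving every allocation equal to the proportional formula to within
rounding.

Percent of total is $100\,n_{gs}/\sum_h n_{hs}$ per sample, and the
fraction profile is the per-fraction arithmetic mean with sample
standard deviation ($n-1$ denominator, 0 when $n=1$) over biological
replicates — typically $n = 3$ or $4$. No length or NSAF normalization
and no differential-abundance testing are applied; percent of total
peptides is the abundance unit throughout.

## Profile analysis

`clusterProfiles()` clusters protein groups over their
replicate-averaged profiles with **uncentred correlation** distance

$$d(x, y) = 1 - \frac{\sum_i x_i y_i}
{\sqrt{\sum_i x_i^2}\sqrt{\sum_i y_i^2}}$$

and **average linkage** — the defaults of the Cluster 3.0 program whose
CDT/GTR output format we also write, so dendrograms open in Java
TreeView. The program's defaults were chosen for reproducibility; the
transform and distance behind any particular published heat map are
rarely stated, so both are configurable and ours are documented, not
asserted to be anyone else's. Percentages span orders of magnitude, so
by default rows are transformed $\log_{10}(x + p)$ with pseudocount $p$
equal to half the smallest non-zero percent; a zero-norm row has no
direction under uncentred correlation and receives distance 1 to
everything, with a warning. Rows are put in accession order before
clustering, making the result invariant to input order.

`classifyEnrichment()` compares a group's target-fraction mean percent
with its **maximum** reference-fraction mean: `unique_to_target` when
all references are 0, `enriched_in_target` at fold ≥ threshold,
`depleted_in_target` at fold ≤ 1/threshold, `shared_with_reference`
otherwise. The default threshold of 2 is deliberately conservative and
is an exposed parameter, never hard-coded into results. Groups that are
zero everywhere are excluded and reported. `categoryRollup()` sums
percent by functional category over a closed 22-name vocabulary
(`functionalCategories()`); unannotated groups pool under `unknown`, so
per-fraction mass is conserved exactly.

## Immunogold zonal quantification

Scenes are 2-D digitizations of micrographs: polylines in nanometres
(image convention, origin top-left, y down) labelled with a compartment
(plasma membrane, cisterna, flagellum) and a section kind (cross or
oblique), plus particle coordinates. Section kind is an input label,
not inferred — inferring obliquity from a single 2-D section is
ill-posed.

`distanceToStructure()` returns the Euclidean distance to the nearest
polyline segment, signed for closed traces (negative inside, the
intracellular side). `bandHistogram()` scores particles around the
plasma membrane in half-open bins $[k w, (k+1)w)$ of width $w = 12$ nm
— the colloidal-gold particle diameter — out to a maximum scored span of
120 nm (10 increments per side), wide enough to contain any particle
plausibly attributable to the membrane while excluding the deep
cytoplasm. `referenceBand()` then finds the smallest symmetric span, in
whole increments, containing at least a coverage fraction (default
0.95) of the scored particles. On membrane-only calibration scenes with
15 nm localization jitter — the displacement scale implied by a primary
plus gold-conjugated secondary antibody on 12 nm gold — this yields a
72 nm span (36 nm per side), which is also the package default band.

`classifyParticles()` assigns a particle lying within the band of one or
more structures to the **nearest** such structure, ties favouring the
plasma membrane (the criterion by which a particle near two structures
should be resolved is not identifiable from the data; nearest-in-band is
the least-assumption rule and the tie preference is stated). The five
scoring areas are cross/oblique plasma membrane, intracytoplasmic
(cisternae) and cross/oblique flagellum. Particles inside the cell but
in no band default to intracytoplasmic; particles outside the cell and
all bands are excluded as unassigned. `zoneDistribution()` collapses the
five areas to three reporting compartments, pools counts within each
aggregation unit — dilution by default, configurable to animal or
micrograph, since which unit underlies a reported $n = 3$ is usually
unstated — and reports mean ± s.d. of percentages across units. Control
scenes (no primary antibody) are summarized separately and never pooled.

## The synthetic-data generator

`generateProteome()` builds proteins from whole tryptic segments (every
segment ends in K or R, none starts with P), so family constructions
digest cleanly: truncations are sequence prefixes cut at cleavage
boundaries, splice-like variants delete internal blocks of whole
segments, homologues replace two internal segments. The digest
(`digestSequence()`) is fully tryptic with no missed cleavages and a
6–30 residue window by default — small enough to keep peptide maps
unambiguous, configurable where that matters. `generatePSMTables()`
draws a Poisson total per replicate at the design depth, allocates
spectra to proteins multinomially by the fraction's abundance column and
uniformly over each protein's peptides, and attaches synthetic
confidences at or above the 0.95 acceptance threshold.
`generateGoldScenes()` places particles along structures chosen by the
design's compartment proportions and displaces them by isotropic
Gaussian jitter (default σ = 10 nm, the antibody–gold offset scale).

Every draw derives from one top-level seed through `childSeed()`, a
documented string-hash stream splitter, so each fraction × replicate
table and each scene is individually reproducible and whole runs are
byte-identical.

What the generator does **not** emulate: mass spectra, retention times,
charge states or search-engine scoring (confidences are synthetic);
missed cleavages and modified peptides; correlated replicate structure
or batch effects; 3-D section geometry, membrane curvature in the third
dimension, or particle clustering. Passing recovery tests therefore
demonstrates that the *computational* pipeline is unbiased and
conservative under its own sampling assumptions — not that those
assumptions exhaust real data.

## Problem sizes and default conditions

The validation suite runs at sizes chosen for statistical power:
quantification recovery uses 30-protein proteomes with 3 redundancy
families, 5 fractions × 3 replicates at depth $10^4$ spectra over 20
seeds, asserting that ≥ 95% of group × fraction means fall within 3
multinomial standard errors of the expected value under the generative
model (the expectation accounts for shared-peptide apportionment, since
"the generating abundance of a merged group" is otherwise ill-defined).
Planted enrichment uses blocks of 10 target-enriched (planted fold 6),
10 reference-enriched and 10 flat proteins with log-normal magnitudes
(sdlog 0.4), recovered at the default fold threshold 2. Gold composition
recovery uses 500 particles × 10 micrographs per seed at the
cisternae-dominated (67/21/12) and membrane-dominated (55/40/5)
compositions, with 20% no-antibody control scenes capped at 5 background
particles.

## Known limitations

- Substring peptide mapping is exact-match only; I/L equivalence is the
  single supported ambiguity.
- Minimality is certified only for candidate pools of ≤ 15 groups after
  absorption; larger pools use greedy + pruning, which can in principle
  retain one group more than necessary.
- Apportionment assumes unique evidence is proportional to abundance
  within a sample; proteins with no unique evidence anywhere are
  quantifiable only through the equal-split fallback.
- Gold scenes are 2-D; attribution near strongly curved or closely
  apposed membranes inherits the nearest-structure convention.
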