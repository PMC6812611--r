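---
title: "Inferring circRNA sponge networks from two-group microarrays"
author: "ceRNAsponge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring circRNA sponge networks from two-group microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAsponge)
```

## The model

Competing-endogenous-RNA (ceRNA) inference rests on one mechanism: a
circular RNA carrying miRNA response elements (MREs) can sequester those
miRNAs and thereby derepress the miRNAs' mRNA targets. Observable
consequences in a two-group expression experiment are (i) differential
expression of the circRNA and of the derepressed mRNAs, (ii) shared
predicted miRNA partners between the circRNA and those mRNAs, and (iii)
positive circRNA–mRNA co-expression. The package chains these three signals
into a tripartite circRNA → miRNA → mRNA network.

The stages, in pipeline order (`runAll()`):

1. **Quantile normalization** (`quantileNormalize()`): every sample's
   intensity distribution is replaced by the rank-wise mean distribution.
2. **Detection filtering** (`detectionFilter()`): a probe survives when at
   least `minPresent` samples call it present (`P`) or marginal (`M`).
3. **Differential expression** (`differentialExpression()`): per probe, the
   linear fold change `2^|Δ|` from the log2 group-mean difference `Δ`, a
   two-sided unpaired t-test, and the strict gate
   `fold_change > 1.5 AND p < 0.05`.
4. **MRE prediction** (`rankMirnasForCirc()`): canonical seed matching on
   the circular sequence with the four TargetScan tiers
   (8mer > 7mer-m8 > 7mer-A1 > 6mer), flank AU scoring, and selection of the
   top 5 miRNAs per circRNA.
5. **Target intersection** (`predictGeneTargets()`, `intersectTargets()`):
   genes whose 3'UTR carries a site of tier ≥ 7mer-A1 for a selected miRNA,
   intersected with the differentially expressed genes.
6. **Edge filtering**: Pearson correlation between circRNA and mRNA
   profiles across shared samples (`correlationEdges()`), gate `p < 0.05`;
   optionally the shared-miRNA hypergeometric test per (circRNA, gene) pair.
7. **Network assembly and modules** (`buildNetwork()`,
   `extractFunctionalModule()`), **enrichment** (`enrich()`), and **qPCR
   concordance** (`relativeQuantity()`, `qpcrConcordance()`).

### The shared-miRNA test

For a candidate pair, with `N` miRNAs in the prediction universe, `K` of
them interacting with the gene, `n` with the circRNA, and `c` shared:

$$P \;=\; \sum_{i=c}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}$$

`cernaPvalue()` evaluates this tail in log space (`lchoose`) so that large
`N` cannot overflow, and returns exactly 1 at `c = 0`. The same tail is the
over-representation statistic in `enrich()` with
`(c, K, n, N) = (k, K_set, n_list, N_bg)`.

### Seed-site definitions

Sites are perfect Watson–Crick reverse complements of the miRNA seed — no
G:U wobble by default, since canonical-site prediction is the convention the
selection step needs. On the target read 5'→3', the nucleotide pairing miRNA
position 1 lies immediately 3' of the seed match; an adenosine there
upgrades 7mer-m8 → 8mer and 6mer → 7mer-A1. Each target window, keyed by
that position-1 anchor, is reported once at its best tier so a 6mer inside
an 8mer is never double-counted. Circular targets are covalently closed:
the scanner appends the first 7 nt (the longest seed span minus one),
reports positions modulo length, and deduplicates wrapped hits, which makes
the site multiset invariant under rotation of the circle — the property a
back-splice junction demands.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minPresent` (circ / mRNA) | 3 / 6 | P/M detection calls required per probe |
| `fcThreshold` | 1.5 | linear fold-change gate, strict `>` |
| `pThreshold` | 0.05 | raw t-test gate, strict `<` |
| `welch` | `FALSE` | pooled Student t by default; Welch optional |
| `topK` | 5 | MREs kept per circRNA |
| `minTier` | `7mer-A1` | weakest accepted UTR site |
| `flank` | 30 nt | AU-context window per side of a site |
| `corrAlpha` | 0.05 | Pearson edge gate |
| `useCernaFilter` | `FALSE` | hypergeometric pair filter (see below) |
| `enrichAlpha`, `nTopTerms` | 0.05, 10 | enrichment gate and report size |

Design choices made where the procedure was genuinely open:

- **t-test variant.** Pooled-variance Student is the default — the
  microarray-era convention for small balanced designs; Welch is a flag.
- **Fold change** is computed from the log2 group-mean difference, not the
  ratio of linear means, matching the volcano-plot `log2(FC)` convention.
  The two differ under skewed within-group noise; the log-scale definition
  composes exactly with the planted additive log2 effects.
- **BH adjustment** is reported (`adjusted_p`) but does not gate: the
  classic workflow gates on raw p.
- **The hypergeometric pair filter is off by default.** With a top-5 MRE
  policy (`n = 5`) and a desk-scale miRNA universe (`N = 60`), a pair
  sharing a single miRNA has `P ≈ 1 − C(N−K,5)/C(N,5) > 0.05` for any
  `K ≥ 1`, so enabling the filter at α = 0.05 empties any small network.
  The statistic is implemented and tested; it becomes informative when `n`
  and `N` are genome-scale.
- **Enrichment score** is `-log10(p)`; the term-ranking quantity is
  otherwise underdetermined.
- **Enrichment background** is the set of genes surviving the detection
  filter — the defensible analogue of "all genes on the array", and a
  function argument.
- **RQ direction tie**: a treated-group mean RQ of exactly 1 is classified
  `down` and flagged `ambiguous`, so concordance calls are deterministic.
- **Interface**: the package exposes the pipeline as functions
  (`runAll()` plus one function per stage) rather than a shell executable;
  an analysis session, not a command line, is the intended surface.

## Numerical choices

- **Quantile-normalization ties** follow the rank-average convention: tied
  entries within a sample receive the mean of the tied ranks' reference
  quantiles. A consequence worth knowing: the "identical sorted sample
  vectors" contract holds exactly when tie patterns agree across samples
  (tie-free data trivially agree; ties planted at a common sorted rank in
  every sample agree too). When one sample is tied at ranks the others are
  not, its sorted vector contains the averaged value twice instead of the
  two distinct reference quantiles — this is a property of the convention
  itself, and the tests exercise both regimes explicitly.
- **Zero-variance probes** in the t-test: equal means give `t = 0`
  (`p = 1`); unequal constant groups give `p = 0` (the |r| = 1 analogue in
  `pearsonEdge()` likewise gives `p = 0`).
- **Zero-variance rows** in hierarchical clustering get distance 1 to all
  others; items are pre-sorted lexicographically so leaf order is invariant
  to input permutation.
- **Ranking tie-breaks** in `rankMirnasForCirc()` form a total order
  (tier, site count, AU score, miRNA id), so top-K selection is invariant
  to library shuffling.
- **Deterministic serialization**: network nodes sort by (type, id), edges
  by (type, source, target); two writes of the same network are
  byte-identical, and GraphML round trips reproduce the object exactly.

## What the generator emulates — and what it does not

`generateSyntheticData()` plants a complete ground truth:

- two groups of 6 samples each (the defaults: 40 circRNAs, 60 miRNAs,
  800 genes) with log-normal intensities — baseline log2 ~ N(8, 1.5),
  within-probe noise N(0, 0.3);
- planted DE probes shifted by ±1.2 log2 units in the treated group
  (fraction 0.1), significant at the FC > 1.5 / p < 0.05 gate with high
  probability at n = 6+6;
- one sponge circRNA with two planted miRNAs, two exact 8mer sites each,
  one spanning the back-splice junction; each sponge miRNA gets eight
  target genes with planted 8mer UTR sites; those genes are upregulated
  and, through a shared latent factor mixed into the noise at weight 0.8
  *without inflating the marginal noise SD*, positively correlated with
  the sponge;
- detection flags assigned by intensity quantile (A below the 5% quantile,
  M up to 1.5× it), annotations with exonic as the modal circRNA type and
  a chromosome skew, three disjoint functional modules, and a Ct table
  with reference Ct ~ N(18, 0.2), σ_Ct = 0.15, n = 3 per group, including
  a planted 4-fold knockdown and two assays deliberately discordant with
  the array call.

All randomness flows from one seed through a fixed stream order, so the
same configuration reproduces the same files byte for byte.

Deliberately **not** modeled: probe-level optical artifacts, dye and batch
effects, non-canonical or wobble-paired sites, miRNA expression (the
network's miRNA layer is prediction-derived, direction `n/a`),
amplification-efficiency deviations in qPCR, and any real ontology content
(modules are user-supplied GMT sets). Passing tests therefore certify the
statistical machinery and its calibration on clean planted structure — not
performance on arrays with correlated probe noise or on proprietary MRE
scores.

## Validation design and problem sizes

The test suite checks each stage against an independent oracle: the
hypergeometric tail against exhaustive `combn()` enumeration (full grid
N ≤ 12 plus N = 20 spot checks), the seed scanner against a brute-force
position-by-position matcher (50 random pairs up to 500 nt, junction-planted
circles, all 60 rotations of a circle), quantile normalization against a
first-principles implementation, DE calibration on 20 null studies of 1000
probes (type-I within [0.03, 0.07]) and sensitivity ≥ 0.9 on 200 planted
FC-2.0 probes per study among a null background, end-to-end sponge recovery
(rank 1 by mRNA reachability) over 100 seeded studies, and 2^-ddCt anchors
exactly. These sizes keep the suite a few minutes long while leaving the
binomial noise of every calibration band an order of magnitude below the
band width.

One dimension was chosen analytically rather than by convention: the null
enrichment calibration uses a background of 500 genes, lists and sets of 50,
because the discrete hypergeometric test's attained level at α = 0.05 is
then 0.048 — close enough to nominal that the [0.03, 0.07] band measures
calibration of the implementation, not discreteness of the statistic.
Sparser margins would push the attained level below the band for any
correct implementation.

## Worked example

```{r example, eval = FALSE}
fix <- file.path(tempdir(), "study")
sim <- generateSyntheticData(simConfig(seed = 1), outDir = fix)
report <- runAll(fix)
report$network          # node composition of the inferred network
head(report$sponge_ranking)  # planted sponge should rank first
report$qpcr             # direction concordance with the array calls
```

## Known limitations

- Correlation edges require ≥ 3 shared sample ids between the circRNA and
  mRNA arrays; designs with disjoint sample sets cannot be correlation-
  filtered.
- The AU score is an unweighted flank A/U fraction; distance-weighted
  context scores (and duplex thermodynamics) are out of scope.
- Multi-factor and paired designs are not supported; the DE stage is a
  two-group unpaired comparison.
- Enrichment tests sets one at a time against a fixed background; no
  term hierarchy, no multiple-testing correction by default (a BH column
  is available downstream via `p.adjust` on the result table).
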