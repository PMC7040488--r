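---
title: "Methods: ceRNA network inference and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernetr)
```

## The problem

Competing endogenous RNA (ceRNA) regulation is the hypothesis that
transcripts sharing miRNA recognition elements (MREs) titrate a common
miRNA pool and thereby regulate each other indirectly. In a bulk
time-course experiment — here the motivating design is three developmental
stages with three biological replicates each, profiled for mRNA, lncRNA
and small RNA — a candidate ceRNA relationship is a triplet (miRNA m,
mRNA g, lncRNA l) in which both g and l carry a seed site for m and both
are negatively co-expressed with m across samples.

`cernetr` implements the full inference chain: small-RNA clean-tag
filtering, FPKM/TPM normalization, differential-expression (DE)
screening, canonical seed-match target prediction with an n-way consensus
rule, hypergeometric gene-set enrichment with a "development" gate,
negative Pearson co-expression screening, and assembly/export of the
typed miRNA–mRNA–lncRNA network. Because the real raw data cannot be
bundled, a first-class synthetic-data generator provides complete input
bundles with planted ground truth, so every stage — and the chain end to
end — is testable offline.

## Stage models and defaults

### Small-RNA QC (`clean_reads`)

Reads are `adapter5 + insert + adapter3`. Four rules are applied in a
fixed order, and a read failing several is attributed to the first:

1. more than `max_low_quality` (default 1) bases with Phred quality at or
   below `q_threshold` (default 20, **inclusive** — a Q20 base counts as
   low quality);
2. any unknown nucleotide (N);
3. missing 5' adapter prefix or 3' adapter, or an empty insert (adapters
   back to back);
4. insert shorter than `min_insert_len` (default 18 nt, adapters
   excluded).

Adapter matching is exact-substring with no mismatch tolerance: the
filtering contract is then fully deterministic and testable. "More than
one low-quality base" is read strictly: rejection starts at two such
bases. Surviving inserts are collapsed into unique tags sorted by
descending count, ties broken lexicographically.

### Normalization (`fpkm_matrix`, `tpm_matrix`, `ddct`)

FPKM uses the within-matrix column sum as library size:
`FPKM = c * 1e9 / (L * C)`. Alignment-based "total mapped reads" would
require the raw data and is out of scope; the within-matrix sum is the
reproducible surrogate. TPM for miRNAs defaults to the length-free
per-million-tags convention standard for small RNA; a length-normalized
mode is available for mRNA-style TPM. Every TPM column sums to 1e6 by
construction. `ddct` implements 2^-ddCt relative quantification anchored
to a calibrator group; the calibrator's geometric mean is 1 by identity.

### Differential expression (`de_screen`)

The screen is fold-change plus Welch t: `log2fc` from group means of the
normalized values with a pseudocount (default 1), p from a Welch
two-sample t-test on `log2(value + 1)`, Benjamini–Hochberg q across all
features of a matrix, and a feature is significant when `p < 0.05` and
`|log2fc| > 1`, both strict. Design choices worth stating:

* The fold-change gate is interpreted on the log2 scale (`|log2fc| > 1`,
  i.e. a two-fold change); a linear-scale reading would flag any nonzero
  change. The threshold is configurable.
* Welch t on log-transformed abundances is the simplest defensible test
  for a 3-vs-3 normalized design and keeps the stage dependency-free;
  count-model DE (negative-binomial GLMs) is deliberately out of scope.
* Significance is gated on p, not q, matching the screening convention
  the defaults mirror; q is reported alongside.
* When both groups are numerically constant the Welch statistic is
  undefined; the screen then returns p = 1 for equal means and p = 0
  otherwise, a deterministic rule exercised by the tests.

### Target prediction (`find_seed_sites`, `predict_targets`, `intersect_predictions`)

The predictor is a canonical seed-match engine. Scanning the transcript
5'→3' for the reverse complement of miRNA seed positions 2–7 anchors a
site; extension to position 8 and an A opposite position 1 upgrade the
class: `8mer` (seed7 match + A), `7mer-m8` (seed7, no A), `7mer-A1`
(seed6 + A, not extendable), `6mer`. Coordinates are 0-based half-open on
the transcript; each anchor yields exactly one class; overlapping anchors
are reported separately; U and T are interchangeable on input.

The published analyses this package re-implements combined three external
predictors (RNAhybrid+svm_light, miranda, TargetScan) by intersection.
Those engines' internal scoring models are proprietary or
alignment-dependent and are not re-implemented; instead the package
supplies the seed-match engine plus a generic n-way intersection over any
number of externally supplied prediction tables (`read_prediction_tsv`),
which reproduces the consensus rule exactly: a pair survives only if
every predictor reports it, support labels are unioned, and site
coordinates deduplicated.

### Enrichment and the development gate (`enrich_genesets`, `select_development_genes`)

Enrichment is the hypergeometric upper tail (inclusive) of the overlap
between DE genes and each gene set, with BH q across the collection and
significance at `q < 0.05`. The background is the set of all features
tested for DE in that class — the analysis universe, since no annotation
service is called. The rich factor is x/K. Records sort by ascending q,
ties by descending rich factor then term id; the top-20 report is a
prefix of that order. The network's mRNA side is gated to DE genes
annotated to terms whose name contains "development" (case-insensitive
substring, configurable to explicit ids), mirroring the published gate on
the GO "development" terms.

### Co-expression screening (`screen_negative_pairs`)

Candidate (miRNA, target) pairs — consensus-predicted targets among DE
features — are screened by Pearson correlation with the two-sided
t-transform p-value; pairs pass at `r < -0.7` and `p < 0.05`, both
strict. Two choices are surfaced as explicit configuration because the
published methods leave them open:

* **Sample scope.** Default: all nine samples. At n = 9 the printed
  thresholds are jointly satisfiable (r = -0.7 gives p ≈ 0.036 < 0.05),
  whereas over the six samples of one comparison they are not at the
  boundary (r = -0.7 gives p ≈ 0.121) — the package ships a consistency
  test of exactly this. A `"comparison"` scope restricts to the two
  compared groups.
* **Transform.** Correlations are computed on `log2(normalized + 1)` by
  default to stabilize scale; raw values are available.

### Network assembly (`build_cernet`)

Kept mRNA edges require the mRNA in the development gene set and the
(miRNA, mRNA) pair in the consensus targets; lncRNA edges require target
evidence (configurable) but not the development gate, which the published
procedure applies to DEGs only. "Sharing the same MRE" is operationalized
as: both partners are consensus-predicted targets of the same miRNA with
at least one seed site each — site-coordinate identity across partners is
not required, since the shared element is the miRNA's seed. The graph is
the union of kept edges, so edges without a completing partner remain
(published networks show unpaired nodes); triplets are all (m, g, l) with
both edges kept. Exports: SIF, edge/node TSV tables (round-trippable via
`import_network`) and GraphML.

## The synthetic-data generator

`generate_dataset()` emulates the motivating design: 3 stages × 3
replicates (labelled 30d/60d/90d), log-normal baselines with
negative-binomial counts, planted DE features, planted ceRNA triplets,
a planted "development" gene set, and adapter-flanked small-RNA reads
with controlled QC failures. Defaults, with rationale:

* **Counts**: NB with dispersion 0.1 around per-feature log-normal
  baselines (log2 mean 8, sd 1.5) — the standard overdispersed RNA-seq
  model at typical biological-replicate variability; no generative model
  is published, so this is the field-standard choice.
* **Planted DE**: stage offsets of ±`de_lfc` (default 3 log2 units)
  around the middle stage, so adjacent comparisons see a 2^3-fold change
  and the extreme comparison twice that. Planted-DE truth records
  expected direction per comparison.
* **Repression coupling**: each triplet's miRNA follows its stage trend
  plus a shared per-sample latent factor (sd 0.75 log2); both targets
  receive the negated signal plus stage-level dilution noise whose
  variance is solved from the target correlation `repression_r`, with a
  first-order analytic correction for attenuation by NB measurement
  noise so the *empirical* correlation targets `repression_r`. The
  dilution is drawn per stage, not per replicate: it models repression
  strength varying with developmental stage (site accessibility and
  competitor abundance change with stage), and replicate-level dilution
  would inflate within-group variance, which is not what stage-coherent
  ceRNA competition looks like. Realized correlations are stochastic by
  design; with the defaults the planted-pair mean is ≈ -0.89 and ≳95%
  of pairs fall below -0.7 across seeds.
* **Abundance structure**: background (non-planted) miRNAs get a +3 log2
  baseline boost, emulating the dominance of abundant constitutive
  miRNAs in small-RNA libraries. This keeps per-sample library
  composition stable, so per-million normalization does not imprint the
  planted trends onto every other profile — with only 30 miRNA features,
  letting 10 strongly trending miRNAs dominate the library would make
  TPM normalization itself the largest source of spurious correlation.
* **Sequences**: planted targets carry exactly one guaranteed 8mer site
  for their partner; every other transcript is rejection-sampled (1,000
  tries, exhaustion is an error, never silent leakage) to be free of any
  planted miRNA's seed match. Planted seeds are drawn mutually distinct
  and are barred from occurring inside another triplet's fixed 8mer
  site, which would otherwise make the rejection sampling unsatisfiable.
  Background transcripts may contain seeds of *non-planted* miRNAs —
  realistic, and harmless downstream because those miRNAs carry no
  planted signal.
* **Reads**: 2,000 reads of `adapter5 + insert + adapter3` (Illumina
  TruSeq small-RNA RA5/RA3 adapters), inserts 21–23 nt drawn from the
  mature miRNA pool, Phred+33 qualities in the 28–40 range. A 10%
  planted-violation fraction cycles through the five QC rules, one rule
  per bad read (two Q20 bases; an N; a missing 3' adapter; an empty
  insert; a 17 nt insert), and the truth records exactly which reads
  must survive.

What the generator does **not** emulate: genomic alignment, isoforms,
sequencing error profiles beyond the QC violations, within-animal
pairing of samples (the motivating design alternated left/right antlers,
but no pairing covariate is published, so samples are treated as
group-labelled replicates), GO graph structure, or realistic miRNA
family/seed redundancy. Passing tests therefore demonstrate the
correctness of the inference chain under a faithful but idealized null
and signal model — not performance on real libraries, where adapter
mismatches, compositional shifts and correlated biology would all blur
the gates.

## Numerical choices and degenerate inputs

* BH is the q-value procedure throughout (none is named in the published
  methods); it is validated against a brute-force step-up oracle.
* Hypergeometric p is the inclusive upper tail via `phyper`, validated
  against exhaustive enumeration for every case with N ≤ 12.
* Pearson p is the exact t-transform tail; |r| = 1 returns p = 0;
  constant profiles raise a "zero variance" error rather than NA.
* Strictness: every printed threshold is a strict inequality (`p <
  0.05`, `|log2fc| > 1`, `r < -0.7`, `q < 0.05`); boundary values fail.
* Empty libraries (all-zero columns) and missing lengths are errors
  naming the sample or feature; empty candidate sets, empty networks and
  empty gene-set matches are legal and produce empty, well-formed
  outputs.
* Determinism: every stochastic step sits behind a single integer seed;
  identical configurations give byte-identical bundles and pipeline
  outputs, and the generator restores the caller's RNG state.

## Problem sizes used by the shipped checks

The test-suite and acceptance checks run the default bundle (200 mRNA,
50 lncRNA, 30 miRNA, 10 triplets, repression -0.9, 2,000 reads), a
1,000-feature null (no planted effects) over 20 seeds for type-I
control, 1,000 random vector pairs for the correlation oracle, 1,000
random p-vectors for BH, 500 random miRNA–transcript pairs for the
seed-site oracle, and exhaustive hypergeometric enumeration to N = 12 —
sizes at which every oracle comparison is exact or tightly bounded while
the whole suite stays fast.

## Known limitations

* The seed-match engine is deliberately minimal: no hybridization
  free-energy, conservation, or 3'-supplementary pairing; consensus with
  richer external predictors is supported only through imported tables.
* DE at n = 3 per group with Welch t is conservative on overdispersed
  counts (the shipped null sits near 3–4% at nominal 5%); a count-model
  test would be sharper but heavier.
* At n = 9 samples the sampling spread of a true r = -0.9 correlation
  still leaves a tail above the -0.7 threshold, so even perfectly
  planted triplets are recovered with recall around 0.85–0.95, not 1 —
  an honest property of the published thresholds at this design size,
  visible in the recovery metrics.
* The ceRNA score is a plain pairwise screen: no partial correlation,
  conditional independence, or competition modelling.
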