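---
title: "Methods: regulon clustering, motif enrichment and promoter models in crelearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulon clustering, motif enrichment and promoter models in crelearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`crelearn` links promoter cis-regulatory elements (CREs) to stress-responsive
expression programs. This vignette documents the models and the design
decisions behind each step, the tunable parameters, what the synthetic data
generator does and does not emulate, and the known limitations.

## The analysis model

The package assumes the standard regulon picture of transcriptional stress
response: genes sharing an expression pattern across conditions are presumed
co-regulated, and their co-regulation is encoded by short binding sites in a
TSS-anchored promoter window. The pipeline therefore proceeds
expression → regulons → motifs → models:

1. **Expression input.** A gene × condition matrix of log2(treated/control)
   ratios. When several treatment levels of the same condition are present
   (e.g. four Fe-excess levels per tissue), they are merged first by the
   geometric mean of the ratios — the arithmetic mean in log2 space
   (`geometric_mean_merge`) — and differential expression is assessed on the
   merged matrix. Merging before filtering is one of two defensible orders; a single
   merged value per tissue feeding the network analysis keeps the DEG
   criterion level-independent, and it is the package default.
2. **DEG filter and no-response genes.** A gene is differentially expressed
   iff its maximum |log2 ratio| over conditions reaches log2 of the fold
   threshold: 2-fold (2^1) as the default, 2.82-fold (2^1.5) as the stricter
   threshold used for Fe-deficient roots. The `n = 100` genes with the
   smallest maximum |log2 ratio| (all below 2-fold) form the no-response
   class; ties break lexicographically on gene id so the selection is
   deterministic.
3. **Regulon clustering.** On the DEG genes, a signed weighted adjacency
   `a_ij = ((1 + r_ij)/2)^β` (Pearson r across conditions, β = 6) is
   converted to the topological overlap measure
   `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij)`, and
   `1 − TOM` is clustered by average-linkage hierarchical clustering, cut at
   k = 4 modules. β = 6 is the common signed-network default. Fixed k = 4 (rather than
   dynamic tree cutting) reflects the four-regulon structure this analysis
   targets and makes tests deterministic; a dynamic cut is deliberately not
   implemented.
4. **Semantic labels.** Each module is labeled by the responsive-class
   template (below) with the highest cosine similarity to the module
   centroid, assigned greedily so no label repeats. Labeling clusters by
   inspecting member genes is not automatable; template matching is the
   package's mechanization of that step.
5. **Motif discovery.** Within a window (default −500..+150 relative to the
   TSS; −3000..+2000 for positional profiles) every exact k-mer present in
   the regulon windows is scored by the enrichment ratio
   `E = (k_reg/L_reg)/(k_bg/L_bg)` (occurrences per bp in regulon vs
   background windows) and an upper-tail binomial p-value. The binomial is
   constructed on **per-gene presence**: k = regulon genes containing ≥ 1
   hit, n = regulon size, p = fraction of background genes containing ≥ 1
   hit. Counting motifs in a regulon is ambiguous between occurrences and
   genes; per-gene presence matches the presence/absence features used
   downstream, and an occurrence-based variant (n = scannable positions)
   is available via `per_gene = FALSE`. Candidates are ranked by
   p-value, then enrichment (descending), then lexicographic k-mer — fully
   deterministic — and cut at `top_m` (50 for upstream windows, 30 for
   −50..+150) after an uncorrected `alpha = 0.001` filter; a Bonferroni
   option over the 4^k family exists but is off by default: uncorrected
   filtering is the customary screening practice for candidate ranking.
6. **Scanning and features.** IUPAC consensi are matched on the promoter
   strand only, with overlapping occurrences counted and an N in the
   sequence matching nothing (conservative on ambiguous sequence). Plant
   CRE catalogs record single-stranded consensi, so promoter-strand
   scanning is the default (a both-strands treatment would collapse each
   motif with its reverse complement).
   PWMs are scored as `Σ_j log2(p_j(base)/q(base))` with a hit at
   ≥ `threshold_fraction` (default 0.8) of the maximum attainable score; 0.8
   is a conventional fraction. The strand-pooled promoter background
   {A: 0.52, C: 0.48, G: 0.48, T: 0.52} sums to 2 and is interpreted as
   per-strand weights, normalized to
   A = T = 0.26, C = G = 0.24. Features are binary presence (≥ 1 hit), not
   counts, matching the presence/absence language of the modeling step.
7. **Modeling.** All-relevant feature selection follows the shadow-feature
   scheme: each iteration appends a permuted copy of every feature, fits a
   gradient-boosted tree ensemble, and scores a "hit" for real features
   whose gain exceeds the best shadow; after `max_iter` iterations a
   two-sided binomial test at `alpha = 0.05` against p = 0.5 confirms or
   rejects each feature. Gradient-boosted trees are used both inside
   selection and as the final classifier (the classical pairing backs the
   selector with random forests; a single ensemble family keeps the
   pipeline deterministic). Evaluation undersamples every class to the minority size,
   then runs stratified 5-fold cross-validation, reporting the pooled
   confusion matrix (predicted rows × true columns), per-cell enrichment
   percentages (cell / predicted-row total × 100, so diagonal enrichment reads as
   class precision; 20% = chance for five balanced classes), macro balanced accuracy
   (mean over classes of (sensitivity + specificity)/2) and macro
   one-vs-rest AUC-ROC (plain binary AUC for two classes).
8. **Promoter structure.** Positional profiles report, per 50-bp window
   across −3000..+2000, the fraction of set genes and of all genes with a
   hit starting in the window, and their ratio. Coverage ratios stratify
   genes by ratio-scale fold change into bins
   {<0.2, 0.2–0.5, 0.5–0.66, 0.66–1.5, 1.5–2, 2–3, 3–5, >5} — spanning the
   customary suppression (<0.2) to strong-induction (>5) fold levels with
   an unregulated 0.66–1.5 band — and
   report the percentage of genes per bin whose −500..+150 window contains
   the motif. The YES/NO flowchart is a CART tree (Gini impurity, fixed
   `max_depth = 5`, `min_leaf = 10`, fitted via rpart with complexity
   pruning disabled) over motif presence on the undersampled balanced set;
   each node carries its five-class composition and the branch statistic
   `(p_type_in_branch × p_all_in_branch)/(p_type_overall/p_all_overall)`,
   reported raw (it exceeds 100% for concentrated branches). Gini with a
   fixed depth is chosen over the significance-based stopping of
   conditional-inference trees: the fixed rule is deterministic and
   dependency-light.

## The synthetic data generator

`generate_dataset(synth_config())` emulates the statistical structure of a
tissue-by-treatment Fe-stress microarray design: seven
conditions (Fe excess in newest leaf, old leaf, stem, discrimination centre
and root — each representing the merged Fe levels — plus Fe-deficient root
and Zn-deficient root), five gene classes in equal proportions, and one
planted promoter motif per responsive class (IDEF1-binding CATGCATG for
storage, bZIP/bHLH CTACGTGC for uptake, DCEp1 AGCTAGCT for chelator,
Myb-like CACCAACC for WRKY co-expression) at probability 0.7 per gene,
positioned Normal(−100, 150) bp around the TSS and clipped to the promoter
span. Planted instances overwrite background bases, so coordinates stay
TSS-aligned; genes sit on multi-gene contigs (50 genes, 10 kb TSS spacing)
to exercise multi-contig I/O; strands are uniform; background bases are
i.i.d. from the A = T = 0.26, C = G = 0.24 composition.

**Expression templates.** The four responsive classes are defined by
qualitative sign patterns (storage: up under Fe excess everywhere, down in
Fe-deficient root; uptake: down under Fe excess, strongest in root, up in
Fe-deficient root; chelator: up under Fe excess and Zn deficiency; WRKY
co-expression: up in stem, down in Fe-deficient root). Magnitudes and the
columns left free by those descriptions are package choices: the defaults
(|log2| up to 3) were set, before any recovery test was run, by a
correlation analysis of candidate templates so that row-centred class
profiles are near-orthogonal (max pairwise Pearson r ≈ 0.3) while every
stated sign is respected. This matters because Pearson-correlation
clustering sees only centred profiles; two classes whose centred templates
correlate strongly are not separable at any noise level. Expression noise
defaults to 0.5 log2 units per condition — a round value typical of
between-replicate scatter on merged log-ratio microarray data; effect sizes
of |log2| ≈ 2 and noise 0.5 are package choices, not source values.

**What the generator does not emulate:** realistic genome composition
(isochores, repeats, CpG structure), probe effects or dye bias, correlated
noise across conditions, multiple TSSs per gene, or motif grammar
(spacing/orientation constraints). Passing recovery tests therefore show
that the algorithms recover the structure they assume, at realistic
signal-to-noise — not that real promoters satisfy those assumptions.

## Numerical choices and degenerate inputs

- **Window convention.** Windows are half-open `[start_rel, end_rel)` with
  the TSS base at relative 0, so "−500 to +150" spans 650 bp including the
  TSS base. Inclusivity conventions vary between tools; this one is fixed here for
  bit-exact tests. Minus-strand windows cover `(tss − end, tss − start]`
  genomic and are reverse-complemented, which makes every analysis exactly
  invariant under reverse-complementing the genome and flipping strands
  (asserted in the test suite).
- **Clipping.** Windows near contig edges are clipped and flagged rather
  than dropped (edge density differs between synthetic and real data;
  analyses may filter on the flag). An empty clipped window is an empty
  string, not an error. Out-of-range planted positions are clipped to the
  span edge rather than resampled, keeping instance counts deterministic.
- **Degenerate binomial background.** A k-mer present in the regulon but
  absent from a finite background would get a plug-in p of 0 and a p-value
  of 0 regardless of evidence; the background presence estimate is floored
  at half a count for the test (the reported background fraction stays
  raw). With genome-scale backgrounds the floor is never active.
- **Merging to IUPAC.** Equal-width motifs are grouped by greedy single
  linkage at Hamming distance ≤ 1 and replaced by the per-column IUPAC
  union; a merged consensus reverts to its members if its re-computed
  enrichment falls below the members' minimum (union consensi can absorb
  background-only variants).
- **Ties.** Discovery ranking breaks ties by enrichment then k-mer;
  no-response selection by gene id; module labels by greedy best-first
  cosine assignment. All randomized steps (generation, undersampling, fold
  assignment, shadow permutations) are driven by explicit integer seeds and
  single-threaded fits, so reports are bit-identical per seed.
- **Zero-variance genes** are excluded from clustering with a warning
  (correlation is undefined); constant features are never confirmed by
  selection (their importance cannot exceed a shadow's).

## Problem sizes

The test suite runs the recovery analyses at the study-shaped default of
1500 genes (≈ 15 Mb of synthetic genome): planted-motif discovery over 20
seeds at 2000 genes with plant probability 0.6, classification and
clustering recovery over 10 seeds each at the default configuration, the
binomial and topological-overlap oracles over their full small-n grids, and
one full pipeline run. These sizes were chosen so each property is measured
at the conditions the generator defines while the whole suite stays
desk-scale.

## Known limitations

- Exact k-mer enumeration is restricted to motif widths ≤ 12 and ungapped
  motifs; SVM-weighted sequence-similarity discovery, as used by dedicated
  expression-aware motif tools, is out of scope, so candidate lists from
  such tools are comparable in spirit, not item-by-item.
- The binomial null treats genes as exchangeable; promoter composition
  heterogeneity (e.g. position-specific base trends around the TSS) is not
  modeled. Position-specific background windows are a recognized extension
  and deliberately not implemented.
- At ~65k tested k-mers, the uncorrected `alpha = 0.001` filter is a
  ranking device, not an error-rate guarantee; the Bonferroni flag provides
  family-wise control when needed.
- One TSS per gene; transcript isoforms and alternative TSSs are out of
  scope.
- The package ships no real expression data; its accuracy claims are
  calibrated on the synthetic conditions above, with known ground truth.
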