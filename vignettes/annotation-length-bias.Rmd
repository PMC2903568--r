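---
title: "Auditing and removing annotation-length bias in GO semantic similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing and removing annotation-length bias in GO semantic similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gosimnorm)
```

## The problem

Semantic similarity between two proteins is routinely computed from their
Gene Ontology (GO) annotations and then used downstream — to validate
predicted interactions, to cluster genes into functional modules, to relate
functional to sequence similarity. All of these uses implicitly assume the
score measures biology. It does not only do that: proteins differ enormously
in how *much* annotation they have, because well-studied proteins (disease
genes above all) accumulate more GO terms, and essentially every similarity
measure in common use increases with the number of annotated terms per
protein — the *annotation length* — even for biologically meaningless random
term sets. Two heavily annotated proteins therefore look "functionally
similar" partly because they are heavily annotated.

`gosimnorm` implements the full apparatus for dealing with this:

1. fourteen protein-pair similarity measures over an IS-A ontology;
2. a randomized null model that quantifies each measure's length bias;
3. a power-transformation normalization that converts raw scores into
   length-comparable standard-normal scores;
4. a clustering + hypergeometric-enrichment layer to evaluate the effect;
5. synthetic ontology/corpus generators so all of it is testable
   without downloading any release data.

## Measures

Term-pair measures use the information content `IC(c) = -log p(c)`, where
`p(c)` is the fraction of annotated gene products covered by term `c` and
its descendants (natural log; the base cancels in every ratio measure and
only rescales Resnik). With `mica` the most informative common ancestor of
terms `m`, `n`:

| measure  | definition | range |
|----------|------------|-------|
| Resnik   | `IC(mica)` | `>= 0` |
| Lin      | `2 IC(mica) / (IC(m) + IC(n))` | `[0, 1]` |
| Relevance (RS) | `Lin * (1 - p(mica))` | `[0, 1)` |
| Jiang    | `1 / (1 + IC(m) + IC(n) - 2 IC(mica))` | `(0, 1]` |

Protein-pair scores either combine the term-pair matrix of the two
proteins' direct annotations — all-pairs average (AVG) or the symmetric
best-match average (BMA) — giving eight combined measures, or compare the
ancestor-closed annotation sets directly: term overlap (TO), normalized
term overlap (NTO), Dice, Cohen's kappa over term-indicator vectors, the
IC-weighted Jaccard index (GIC), and the IC-weighted cosine (VSM).

Two conventions deserve a note because the literature is loose about them:

* **BMA**: we use the symmetric mean of the two directional best-match
  averages, `(mean_i max_j S_ij + mean_j max_i S_ij) / 2`; the pooled
  variant `(sum row maxima + sum col maxima) / (L1 + L2)` is available via
  `combine_bma(..., alternative = TRUE)`.
* **NTO/Dice denominators**: the numerator counts overlap of ancestor-closed
  sets, so the denominators default to closed-set sizes — the only reading
  under which the documented `(0, 1]` ranges are guaranteed on a single-root
  ontology. Direct annotation lengths are available via
  `overlap_score(..., denominator = "direct")`.
* **Jiang**: the similarity mapping `1 / (1 + d_JC)` of the Jiang–Conrath
  IC distance is the simple form with range `(0, 1]`; other mappings exist
  in the literature.
* **Kappa/VSM universe**: all terms of the loaded aspect.

Degenerate cases are pinned down explicitly: `0/0` in Lin is 0; a pair with
no common IC-defined ancestor (possible with multiple roots) has an empty
MICA with IC 0; kappa is clamped to `[0, 1]` and defined as 1 when both
indicator vectors are all-ones; GIC/VSM are 0 when every shared term has
zero IC. MICA ties break to the lexicographically smallest term identifier
so results are reproducible across platforms.

## The null model and the bias audit

`build_null()` draws, for each group-length combination, `n_pairs`
independent pairs of uniform random term groups from the pool of IC-defined
terms and scores them under all requested measures (the same sampled pairs
are scored by every measure). `bias_report()` then correlates the per-size
median score with the group size (Spearman). On realistic corpora this
correlation is essentially 1 for every one of the 14 measures — the bias
phenomenon itself. The per-size standard deviation moves in opposite
directions: it grows with size for TO (a raw overlap count, hypergeometric
in character) and shrinks for the normalized overlap measures.

Groups are sampled uniformly *without* excluding ancestor–descendant pairs;
nothing in the randomization scheme forbids redundant terms, and uniformity
over the pool is the simplest defensible null.

## Normalization

For each length combination `(L1, L2)` the raw null scores `SS` are
power-transformed, `TSS = SS^lambda`, with the exponent chosen by quantile
symmetry: `lambda` solves

```
(T_{1-q}^lambda + T_q^lambda) / 2 = M^lambda
```

where `M` is the null median and `T_q`, `T_{1-q}` the lower and upper
q-quantiles. The equation is solved numerically in `lambda` ∈ [0.01, 5];
because no single canonical `q` exists we solve on the grid
q = 0.05, 0.10, …, 0.45 and take the median of the per-q solutions. When a
q-level has no solution in the bracket it is skipped; if none has one (or
the cell is degenerate: zero median, constant scores) the exponent falls
back to 1 with a warning and the cell is flagged. Note one structural
property of this equation: by the AM–GM inequality a solution with
`lambda > 0` exists only when the median exceeds the geometric mean of the
two quantiles, i.e. for distributions whose right skew is *lighter* than
lognormal — heavier-skewed cells legitimately fall back.

The pure power family `s^lambda` is used rather than Box–Cox
`(s^lambda - 1)/lambda`: the logarithmic transform is treated as a separate
comparator (see `transform_comparison()`, which reports KS pass fractions
for the estimated exponent against fixed exponents 1, 1/3, 1/2, 2, −1 and
log), so the family does not need to contain the log limit.

Each cell's transformed null sample is tested for normality with a
one-sample Kolmogorov–Smirnov test at significance level 0.1. Because the
normal's parameters are estimated from the same sample the naive KS test is
anti-conservative; the Lilliefors correction is applied by default
(`ks_normality(..., lilliefors = FALSE)` reproduces the naive test). The
fraction of cells passing is the headline diagnostic of whether a measure
is normalizable at all — in practice the Resnik/Lin/RS-based combined
scores, Jiang(AVG), Dice and kappa normalize well, while TO, NTO, GIC, VSM
and Jiang(BMA) resist (their null distributions are too discrete or too
skewed).

The normalized similarity score of a protein pair with lengths `(L1, L2)`
is then the z-score within its cell:

```
NSS = (SS^lambda - M_TSS) / STD_TSS
```

with `M_TSS` and `STD_TSS` the median and standard deviation of the
transformed null cell (median, not mean, because the transformed
distribution may remain skewed). NSS = 0 means "no more similar than random
term groups of the same annotation lengths"; scores are comparable across
length combinations, and within a combination the ranking of raw scores is
preserved exactly. Length combinations outside the modeled grid clamp to
the nearest cell with a warning. Applied back to its own null, the
construction gives median 0 exactly and SD 1; applied to held-out null
samples, the per-size median NSS is flat noise of order
`sqrt(2) * 1.25 / sqrt(n_pairs)` (≈ 0.02 SD units at 10,000 pairs/cell) —
the length dependence is gone, though the *rank* correlation of those
residual medians with size is itself a noise statistic and should not be
over-read (see Limitations).

## Clustering and enrichment

The application layer mirrors standard practice: similarities are Min-Max
scaled over the analyzed protein set, converted to distances `d = 1 - MM`,
clustered by complete linkage, and each cluster is tested for enrichment of
externally labeled gene categories with the hypergeometric upper tail,
Benjamini–Hochberg-adjusted at FDR 1%. We deliberately do *not* claim the
triangle inequality for `1 - MM` — it does not hold for arbitrary
similarity matrices — but agglomerative linkage does not require it.

## What the synthetic generators emulate

`generate_dag()` builds a single-root layered DAG (default ~500 terms,
depth 6) with geometrically growing level sizes; each non-root term takes
one parent from the previous level plus, with probability 0.2, an extra
parent from a shallower level. `generate_corpus()` gives each of ~2,000
genes a geometric annotation length (mean 3, capped at 10, matching the
observation that almost all real proteins carry at most 10 BP annotations),
with a "well-studied" subpopulation (15% by default) whose lengths are
multiplied by 3 — the annotation-bias phenomenon itself. Terms are drawn
with per-level decaying weights (`depth_decay = 0.45`, i.e. a term's chance
of being used as a direct annotation roughly halves per level). That decay
is what gives the information content its strongly right-skewed, GO-like
spread; with uniform annotation sampling IC is nearly flat and ratio
measures like Lin degenerate. The value 0.45 was fixed during generator
design as the point where the synthetic audit reproduces the qualitative
structure of real-corpus audits (strong positive median trends for all 14
measures, opposite SD trends for TO versus the normalized overlaps).

`generate_labeled_categories()` plants functional categories on disjoint
level-1 subgraphs: category genes draw a `category_purity` share of their
annotations from their own subgraph and the rest anywhere. With
`confound_lengths = TRUE` successive categories receive 3-fold longer
annotations, entangling length with category. At purity 0.6 (heterogeneous,
disease-like categories) this reproduces the failure mode that motivates
normalization: under raw RS(BMA) distances the short-annotation category's
genes are mutually *dissimilar* and fail to form a cluster (co-clustering
accuracy ~0.6), while normalized distances recover both categories
(accuracy ~0.75, both enriched at FDR ≤ 1%). With purer categories
(the default 0.8) the functional signal dominates and even raw scores
cluster correctly — there is then no failure mode to correct.

What the generators do **not** emulate: real GO's scale (tens of thousands
of terms, depth > 12), its heterogeneous branch sizes and term-usage
frequencies, evidence codes, multiple aspects, and the annotation *growth*
over database releases. Conclusions from passing tests are therefore about
the correctness and qualitative behavior of the machinery, not about any
specific real corpus.

## Numerical and scale choices

* All randomized procedures accept explicit seeds and are bit-reproducible.
* The similarity engine precomputes the dense term×term MICA table
  (filled ancestor-by-ancestor in decreasing IC order, first-writer-wins,
  which also implements the lexicographic tie-break); this is intended for
  ontologies up to a few thousand terms, the scale of the generators.
* Audits in the test-suite run at the full study scale — 14 measures ×
  10 sizes × 10,000 pairs/size (~1.4 M pair scorings per null build) —
  which the vectorized batch scorer completes in seconds; the
  planted-category experiment uses 120 genes and a lower-triangle null
  grid up to length 15.
* `uniroot` tolerance 1e-9 for the exponent; KS at alpha 0.1; BH at FDR
  0.01 in the enrichment layer.

## Limitations

* The quantile-symmetry exponent is weakly identified for nearly-symmetric
  cells (the objective is almost flat in `lambda`); this is harmless for
  normalization, which only needs *a* symmetrizing transform, but the
  fitted `lambda` values themselves should not be interpreted.
* Normalization is only as good as its null table: cells are estimated
  from 10,000 pairs, so each cell's centering carries a fixed realized
  error of ~0.013 SD units. Any statistic computed *across* cells (such as
  rank-correlating held-out per-size medians with size) inherits that
  frozen noise.
* Five measures (TO, NTO, GIC, VSM, Jiang(BMA)) do not reach satisfactory
  KS pass fractions under any of the implemented transforms; their
  normalized scores still center and scale the null but should not be
  treated as standard-normal.
* IS-A edges only; PART-OF and regulates relations are out of scope, as is
  cross-aspect analysis in a single run.
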