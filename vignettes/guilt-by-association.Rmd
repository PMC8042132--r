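---
title: "Cross-evidence guilt-by-association analysis with gbanet"
author: "gbanet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-evidence guilt-by-association analysis with gbanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbanet)
```

# The model

`gbanet` predicts gene function by *guilt by association*: a gene is
linked to a concept (a disease, phenotype, chemical, drug, or GO
category) when its most co-expressed genes share literature connections
to that concept more often than chance allows. Three largely
independent evidence streams are combined over one gene universe:

1. **Co-expression.** Expression panels are quantile normalized and a
   full gene–gene Pearson correlation matrix is computed; each gene's
   query set is its $K$ most positively correlated partners (the KNN
   set, default $K = 40$).
2. **Literature.** Thesaurus terms are recognized in a corpus of
   abstracts and an undirected network is built whose edge weight
   $w(a,b)$ counts documents mentioning both terms.
3. **Strain genetics.** Gene expression across a recombinant-inbred
   strain panel is correlated with phenotypes (plain Pearson, raw
   $p < 0.05$), with pathway overrepresentation and robust expression
   profiling as companion summaries.

## Commonality scoring

For a query set of $q$ genes from an $N$-gene universe, a concept $c$
connected to $d_c$ universe genes receives

$$S_c = \#\{g \in \text{query}: w(g,c) \ge 1\}, \qquad
  E_c = \frac{q\, d_c}{N}, \qquad
  \text{Obs/Exp} = \frac{S_c}{E_c}, \qquad
  \text{Score} = S_c \cdot \frac{S_c}{E_c}.$$

$E_c$ is the exact mean of $S_c$ when query sets of size $q$ are drawn
uniformly from the universe (the hypergeometric mean); the package's
test suite pins the implementation to this null by exhaustive
enumeration of all $\binom{N}{q}$ query sets on small networks. The
Score multiplies enrichment by evidence volume: Obs/Exp alone favours
rare concepts whose support is a handful of links, while raw counts
alone favour ubiquitous concepts; their product ranks concepts that are
both strongly and broadly connected to the query. No p-value is
attached to Obs/Exp — the ranking, not a significance claim, is the
output — and edge weights beyond presence/absence are ignored at
scoring time (a `wMin` threshold is available when weak single-document
co-occurrences should not count as connections).

## Assumptions and scope

The procedure assumes that (i) functionally related genes are
co-expressed strongly enough to populate each other's KNN sets, and
(ii) the literature mentions related gene–concept pairs within single
abstracts. Both break down gracefully: a gene whose neighbors carry no
literature edges simply yields an empty profile. Correlations are
computed over all samples pooled (normalization happens once, before
the matrix); no batch handling, covariance shrinkage, QTL mapping or
kinship correction is attempted.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 40 | neighbors per gene (signed $r$ ranking); 10 at the 60-gene synthetic scale |
| `minShared` | 2 | minimum $S_c$ to report; a single link carries no enrichment information |
| `wMin` | 1 | minimum co-occurrence count for an edge to count as a connection |
| `alpha` | 0.05 | raw-p threshold of the association screen (uncorrected by design) |
| `minOverlap` | 5 | ORA overlap filter, applied **before** BH adjustment |
| `alphaAdj` | 0.05 | ORA adjusted-p threshold |
| `top` | 10 | ORA report cap (reporting only; statistics unaffected) |
| `zCutoff` | 3.5 | modified-Z "highly expressed" flag, the usual robust-outlier convention |

Decisions taken where the design was genuinely open:

- **Neighbor ranking by signed $r$**, not $|r|$: "most highly
  correlated" reads as top positive co-expression; `absolute = TRUE`
  switches.
- **The gene is excluded from its own query set** in `gammaProfile`:
  its trivial self-association would otherwise inflate every count.
- **The universe is an explicit argument** (not inferred): whether the
  background is all platform genes or all genes with literature edges
  changes $d_c$ and $N$, so both analyses must be expressible.
- **Filter-then-adjust ORA ordering**: sets failing the overlap
  minimum are removed before BH, which changes the number of tests $m$;
  this matches the behavior of the standard web ORA tools.
- **Raw p-values in the association screen**: the screen's own
  threshold is uncorrected $p < 0.05$; multiple-testing correction
  lives in the enrichment stage, and output headers say so.
- **Document-level, unit-weight co-occurrence**: no sentence-level
  weighting, no edge-count threshold at build time (thresholding is
  deferred to scoring via `wMin`).
- **Curation as a filter**: selecting, say, cardiovascular concepts
  from a full ranking is represented by `conceptTypes`/`keywords`
  output filters, not as computation.

# Numerical choices and degenerate inputs

- **Quantile-normalization ties** receive the mean of the reference
  values at the tied ranks, so tied inputs stay tied and per-sample
  rank order is preserved exactly. (This differs from rank
  interpolation for ties of order three and higher; the package's rule
  keeps the output a function of the tie group only.)
- **Zero-variance genes** get $r = 0$ against all partners and are
  reported in a flag list — the matrix stays total and KNN stays
  deterministic. The association screen, by contrast, *errors* on
  zero-variance input: a trait screen must surface degenerate traits.
- **KNN ties** break by ascending lexicographic gene id; commonality
  ties by shared relations, then term id; ORA ties by enrichment ratio,
  then set name. All orderings are platform-independent.
- **Exact linear dependence** ($1 - r^2 < 10^{-14}$) returns $p = 0$
  rather than an overflowing t.
- **Modified Z with MAD = 0** (at least half the genes identical) is an
  error by default; the mean-absolute-deviation fallback
  $0.7979\,(x - \tilde x)/\text{meanAD}$ is applied only on explicit
  request. The mean-then-standardize summarization order is the
  default reading of "mean expression level (modified Z-score)"; the
  per-sample alternative is exposed as `summarization =
  "zPerSampleMean"` for comparison.
- **Missing values**: traits use pairwise deletion with per-pair $n$
  reported; expression matrices must be complete (normalized arrays).

# The synthetic-data generators

Every stage is tested against planted truth:

- **Expression** uses a single-factor model per module:
  $x_g = \sqrt{\rho}\, f_m + \sqrt{1-\rho}\,\varepsilon_g$ with
  standard-normal factor and noise, so $E[r] = \rho$ for two module
  genes — the simplest generator with an analytically known pairwise
  correlation.
- **Corpus** documents are space-separated surface forms plus filler
  tokens: a signal document (probability `pSignal`) names a random
  subset of one module's genes together with the module's planted
  concepts; background documents draw terms uniformly. Synonyms are
  chosen uniformly, so recognition (case, token boundaries, longest
  match) is exercised without NLP complexity.
- **Traits** are linear gene effects plus Gaussian noise over a
  38-strain panel, the scale of the aorta expression panels such
  screens are run on; an effect of $\beta = 0.7$, $\sigma =
  \sqrt{1-0.49}$ on a unit-variance gene yields population $r = 0.7$.
- **Gene sets** embed each planted module in a padded set among uniform
  decoys.

The default study (`simulateStudy`) uses 60 genes, two 10-gene modules
at $\rho = 0.8$, 100 compendium samples, 150 thesaurus terms (60 genes,
2 planted + 88 background concepts), 500 documents at `pSignal = 0.2`
with 4 mentions each, and $K = 10$. The corpus defaults keep the
background gene–concept co-occurrence probability near 0.2 per pair —
sparse, as gene–concept co-mentions are in real abstract corpora —
which is what makes degree-normalized enrichment informative; a corpus
dense enough that every pair co-occurs carries no ranking signal for
presence/absence scoring.

What the generators do **not** emulate: probe-level and batch effects,
realistic abstract language (negation, abbreviation induction,
ambiguous symbols), non-Gaussian expression marginals, population
structure or kinship in the strain panel, and overlapping or
hierarchical pathway structure. Passing recovery tests therefore
demonstrates correctness of the computations and calibration of the
statistics under the stated model — not robustness to those real-data
phenomena.

# What the test suite establishes

Oracle equivalences (exact): KNN against brute-force row sorts;
network weights against the per-document pair budget
$\sum_d \binom{m_d}{2}$; commonality expectations against exhaustive
enumeration of query subsets; hypergeometric tails against enumeration;
BH against the reference step-up; Score $\equiv S_c \times$ Obs/Exp on
every emitted record.

Statistical calibration at the study's problem sizes (fixed seeds):
type-I error of the screen $0.05 \pm 0.02$ over 1000 null replicates
of 10 genes at $n = 38$; power $\ge 0.99$ for planted $r = 0.7$ at
$n = 38$ over 500 replicates; the planted concept ranks first for
$\ge 95\%$ of module genes; ORA detects the planted set in 200
replicates while flagging $\le 5\%$ of decoys. The analytic Pearson p
is compared with a $10^4$-shuffle permutation oracle at $n$ between 20
and 40, where the permutation and t-based nulls agree to Monte-Carlo
error; at $n \lesssim 15$ the two genuinely differ (the permutation
null conditions on the observed marginals), which is a property of the
tests, not of this implementation.

# Known limitations

- Term recognition is dictionary-driven: no disambiguation of symbols
  that are also English words, no stemming, no abbreviation induction.
  Ambiguous thesaurus surfaces are rejected rather than resolved.
- Score has no attached significance; rankings across corpora of very
  different sizes are not comparable without recalibration.
- Quantile normalization across small gene panels (tens of genes)
  visibly attenuates absolute correlations because values are remapped
  through coarse ranks; on platform-scale panels the effect is
  negligible.
- The pipeline's correlation stage holds the full $n_\text{genes}^2$
  matrix in memory; it targets panels up to a few tens of thousands of
  genes, not single-cell-scale feature spaces.

# Session info

```{r}
sessionInfo()
```
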