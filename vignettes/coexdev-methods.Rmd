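---
title: "Methods: developmental coexpression networks, module detection and gene-list enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developmental coexpression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coexdev` implements a developmental weighted gene coexpression analysis:
expression matrices are split by age interval, a weighted coexpression
network is fitted independently per interval, modules are detected by an
adaptive cut of the topological-overlap dendrogram, and modules are
interrogated with eigengene--trait correlations, hypergeometric gene-set
enrichment and a bootstrap empirical-null overlap test against a risk-gene
list. This vignette documents the model, its tunable parameters, the
numerical choices behind the implementation, and what the synthetic
validation data do and do not establish.

## The network model

For genes $i, j$ with expression profiles across the samples of one
interval, the network is built from the Pearson correlation $r_{ij}$.
Soft thresholding raises the correlation to a power $\beta \ge 1$:

* unsigned (the default): $a_{ij} = |r_{ij}|^\beta$;
* signed: $a_{ij} = \left(\frac{1 + r_{ij}}{2}\right)^\beta$.

Raising to a power suppresses weak, noise-driven correlations continuously
instead of imposing a hard cutoff. $\beta$ is chosen by the scale-free
topology criterion: for each candidate power (default $1..20$) the
connectivity $k_i = \sum_{j \ne i} a_{ij}$ is binned into 10 equal-width
bins, and the fit index $R^2$ is the squared correlation between
$\log_{10} p(k)$ and $\log_{10} \bar{k}$ over the non-empty bins. The
smallest power with $R^2 \ge 0.85$ is selected; if no candidate qualifies,
the best-fitting power is used and flagged. $R^2$ is reported unsigned and
the regression slope alongside it, so a (pathological) positively sloped
fit is visible in the diagnostics table rather than silently accepted.

Pairwise similarity is then the topological overlap

$$\mathrm{TOM}_{ij} = \frac{L_{ij} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
  L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$

which scores two genes as similar when they are directly connected *and*
share neighbours; it is less noisy than raw adjacency. `1 - TOM` is the
clustering dissimilarity.

Missing values are rejected rather than handled with pairwise-complete
correlations: the intended inputs are complete expression matrices, and
refusing incomplete ones keeps the numerics exact. Constant genes are an
error naming the gene, since their correlation is undefined.

## Module detection

The dissimilarity is clustered with average-linkage hierarchical
clustering and cut adaptively (`cut_tree_dynamic()`), controlled by three
parameters: `deep_split` (0--4, default 1, "medium" sensitivity),
`cut_height` (default 0.99) and `min_module_size` (default 27).

**Relative height scale.** All height thresholds are interpreted relative
to the spread of the dendrogram's merge heights, between their 5th
percentile $h_{0.05}$ and their maximum: the cut is placed at
$h^* = h_{0.05} + \texttt{cut\_height} \cdot (h_{\max} - h_{0.05})$.
This choice matters: at the soft powers the scale-free criterion selects,
all TOM dissimilarities compress into a narrow band just below 1, and an
absolute cut at 0.99 would fall below every merge and return no modules.
The relative interpretation follows the convention of the established
dynamic tree cut implementations and makes the parameter meaningful
across powers.

**Two-stage cut.** A static cut at $h^*$ yields candidate branches. Each
branch is then split recursively into its two children whenever both
children (i) have at least `min_module_size` leaves, (ii) have a tight
core — the mean of their lowest `min_module_size` − 1 merge heights must
stay below a deep-split-dependent threshold — and (iii) hang well below
the height at which they merge (a minimum "gap"). `deep_split` maps
linearly to a maximum core scatter from 0.64 (level 0) to 0.98 (level 4),
with the minimum gap $0.75 \cdot (1 - \text{max core scatter})$; both are
expressed on the same relative height scale as the cut. Clusters smaller
than `min_module_size` dissolve into the background module 0, and labels
are reassigned by decreasing size (1 = largest; ties broken by the
lexicographically smallest member identifier, so the cut is fully
deterministic). Exact label-for-label agreement with any particular
reference implementation is not a goal; recovery of planted structure is
(see below).

**Membership stage.** The branch cut labels only the tight core of each
module: genes that follow a module's profile weakly attach to the tree too
high and would be left in module 0. A second stage therefore computes each
module's eigengene from the core assignment and moves a background gene
into the module whose eigengene it correlates with best, provided
$|kME| \ge 0.5$ — the conventional threshold for moderate module
membership. Under a pure-noise background $kME \sim N(0, 1/\sqrt{n})$
across $n$ samples, so at $n = 100$ the probability that a noise gene
clears 0.5 is negligible ($\sim 3 \times 10^{-7}$), while genuinely
coexpressed genes with loadings around 0.7 sit near $kME \approx 0.57$ or
above. A distance-based (PAM-like) stage on the TOM dissimilarity was
considered and rejected: at high powers the compressed dissimilarity scale
separates weak module members from background only in the fifth decimal,
which makes any distance threshold fragile. The stage can be disabled
(`treecut_config(kme_reassign = FALSE)`); core labels are never changed by
it. Eigengene-based module *merging* is not performed.

## Module summaries and statistics

The **module eigengene** is the first principal component of the module's
member genes after per-gene standardization, computed by SVD, scaled to
unit variance and oriented to correlate positively with the module's mean
standardized profile (PCA sign is otherwise arbitrary). The share of
variance it explains is the leading eigenvalue share.

**Eigengene--trait correlations** use Pearson $r$ with the exact two-sided
p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom.
Two-level categorical traits are encoded 0/1; multi-level traits (e.g. a
four-level brain region factor) get one indicator column per level, one
row per (module, level) — a choice made here because no canonical encoding
exists for correlating a multi-level factor with a continuous summary.
Constant traits are flagged and excluded rather than propagating `NA`s.

**Cross-interval label matching** relabels each interval's modules against
the first interval's network: for every (test module, reference module)
pair the inclusive upper-tail hypergeometric overlap p-value is computed
on the shared gene universe, pairs are matched greedily in ascending p
(ties: larger overlap, then smaller reference label), each reference label
is used at most once, and matches require $p < 0.05$ — a default chosen
because no significance level is canonical for this step; it is
configurable. Unmatched modules get fresh labels after the reference's
maximum, so "module 3" refers to the same gene community in every
interval's report.

**Gene-set enrichment** of modules in marker collections uses the same
inclusive upper-tail hypergeometric p with the background equal to the
analysed genes, and Bonferroni correction over all (module, list) tests of
one interval (module 0 is not tested and not counted). Collections are
restricted to the background first; lists emptied by the restriction are
dropped with a warning.

**The bootstrap overlap test** draws $B$ (default 10,000) gene sets of the
tested module's size uniformly without replacement from the background and
records each replicate's overlap with the risk list. The empirical p-value
is $\max(r, 1)/B$ with $r$ the number of replicates reaching the observed
overlap, which gives the natural resolution floor $1/B$; the add-one
convention $(r+1)/(B+1)$ is available via `convention = "add_one"`.
Sampling is from the analysed-gene background, not the genome, because the
risk list is itself restricted to the analysed genes before testing. The
gene of interest is not removed from its own module by default (a flag
exists), and the test is skipped with a warning when that gene is absent
or in module 0. The bootstrap null is exactly hypergeometric, and the test
suite checks convergence of the empirical p to the hypergeometric tail as
well as calibration of the p-value under a null risk list.

## Preprocessing

Probe-level matrices collapse to one row per gene by the max-mean rule
(the probe with the highest mean intensity represents the gene), the
standard convention for exon arrays. Sample QC keeps RIN $\ge 8$
(inclusive). The low-expression filter keeps a gene only if its summary
intensity is $\ge 6$ (log2, inclusive) in **every** region-by-interval
group; the summary is the group mean by default — robust to single outlier
samples — with a switch to the stricter per-sample minimum
(`filter_config(per_sample = TRUE)`), since either reading of "expressed
in all areas and periods" is defensible. An empty region-interval group is
an error naming the group. Ages live on a unified axis of postnatal years
with birth fixed at 38 weeks postconception; the shipped default scheme
has four intervals: 10 WPC to birth, birth to <6 y, 6 to <40 y, and 40 y
on. Samples outside the scheme are flagged `NA`, never silently dropped.

## The synthetic-data generator

`generate_dataset()` draws from a planted factor model: module $m$ has a
latent profile $f_m \sim N(0, 1)$ i.i.d. across samples; member gene $g$
has $x_{gs} = \lambda_g f_{m(g)}(s) + \varepsilon_{gs}$ with positive
loadings $\lambda_g \sim U(0.7, 0.9)$ by default (positive, so modules are
coherent under the unsigned network) and noise sd 1; background genes are
unit-variance Gaussian noise; everything is shifted by +8 onto a plausible
log2-intensity scale, without clipping. Traits are generated as
$\rho f_m + \sqrt{1 - \rho^2} z$ so their correlation with the driving
profile converges to the configured $\rho$. Marker lists are uniform
subsets of a planted module; the risk list draws a configured fraction
from one module and the rest uniformly. An optional `low_expr_fraction`
writes a slice of background genes around intensity 5 to exercise the
expression filter. All randomness flows from one integer seed through
named sub-streams, so identical configurations are bit-identical.

The standard validation conditions are 2,000 genes and 100 samples with
five planted modules of sizes 300/250/200/150/100 (half the genes are
background). Under these conditions the selected power reaches
$R^2 \ge 0.85$, every detected module clears the minimum size 27, and the
planted partition is recovered with adjusted Rand index 0.87--0.98 across
ten seeds (background excluded). The full test suite, including these
end-to-end runs, completes in about a minute.

What the generator does **not** emulate: probe-level artifacts, batch and
region effects, correlated latent profiles, heavy-tailed expression noise,
or modules with mixed-sign loadings. Passing tests on this model therefore
establishes the correctness and calibration of the pipeline's machinery,
not the biological validity of modules found in any real dataset — real
cohorts can violate the factor-model assumptions in all of these ways.

## Degenerate inputs and edge behaviour

Constant genes, missing values, empty grouping cells, modules with fewer
than two genes, disjoint gene universes in label matching, and modules
larger than the background are all hard errors with named offenders.
A vanishing cut height yields only module 0. A two-bin connectivity
histogram fits perfectly ($R^2 = 1$, two points); fewer than two distinct
connectivity values is an error. Observed overlap 0 gives empirical
p = 1, as does a module equal to the background (a single possible draw).

## Limitations

* No block-wise network construction: matrices beyond ~20,000 genes
  require memory quadratic in gene count.
* Biweight midcorrelation, signed-hybrid adjacency and eigengene-based
  module merging are not implemented.
* The dynamic cut reproduces the behaviour, not the exact labels, of any
  particular reference tree-cut implementation.
* Enrichment is generic over GMT collections; no gene-ontology retrieval
  is performed.
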