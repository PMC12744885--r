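---
title: "Screening candidate genes for co-regulation with an anchor pair"
author: "coexscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening candidate genes for co-regulation with an anchor pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexscreen)
```

## The scientific question

An enzyme that modifies a protein inside the secretory pathway must be made
in the same cells as its substrate.  That simple constraint turns a
biochemical question — *which of many paralogous candidate genes encodes
the enzyme acting on a given substrate?* — into a transcriptomic one:
among the candidates, which one is consistently co-expressed with the
substrate genes, across tissues, cell lines, developmental stages and
single cells?  The motivating case is the Drosophila collagen IV system:
the two collagen IV subunit genes (*Col4a1* and *viking*) are co-regulated
from a shared promoter and serve as the *anchor pair*, and a panel of ~26
prolyl-4-hydroxylase-related genes are the *candidates*.  `coexscreen`
implements the full screening pipeline so that it can be run on real
expression tables and, just as importantly, on synthetic data with planted
ground truth, where its operating characteristics can be measured.

## The bulk screen

Given a genes × samples expression table (microarray intensities or RPKM),
each candidate *g* is scored by the sample Pearson correlation
$r(\mathrm{ref}, g)$ with the reference gene and ranked in decreasing
order of *r* (`rankCandidates()`).  Correlations are computed on the raw
table; since Pearson *r* is invariant to positive per-gene scaling this
equals correlating the brightness-coded rows.  Three supporting operations
mirror the usual presentation of such screens:

* `maxNormalize()` — divide each gene row by its maximum ("brightness
  coding"); all-zero rows are left unchanged; idempotent.
* `sortByPeak()` — order genes by the sample index of their maximum, for
  temporal panels.
* `coexpressionPresence()` — count, at a visibility threshold (default
  5 % of a gene's own maximum), the samples where the reference is
  expressed and, among them, those where the candidate accompanies it.
* `writeTextImage()` — export a matrix of values in [0, 1] as
  whitespace-delimited rows, the dialect ImageJ's *Text Image* import
  reads.

Degenerate inputs are errors, not silent values: a constant vector has no
defined correlation and is reported as not-available (ranked last) rather
than 0.  Ties in *r* break alphabetically by gene id so output is
deterministic.

## The single-cell arm

### Preprocessing

`qcFilter()` retains cells expressing between `minGenes` (default 200) and
`maxGenes` detected genes; `maxGenes` has no default because the sensible
ceiling is tissue- and platform-specific.  `normalizeLog1p()` computes
$\log(1 + s\,c_{ij}/C_i)$ with scale $s = 10^4$ and natural log;
`selectHVG()` ranks genes by variance standardised against a running-median
mean–variance trend (plain variance by flag) and keeps the top 2000;
`scaleGenes()` z-scores each gene with clipping at ±10 (a finite clip
keeps outlier cells from dominating the PCA); `reduceDims()` computes the
top 50 principal components, with each component's sign fixed so its
largest-magnitude loading is positive.  Every stage is deterministic.

### Metacells

Droplet-style single-nucleus counts are sparse; aggregating ~25
transcriptionally neighbouring cells ("metacells") before computing
correlations removes most sampling noise while keeping cell-type
resolution.  `buildMetacells()` works per annotated group: seed cells are
drawn without replacement (seeded RNG); each seed's `k = 25` nearest
neighbours (Euclidean in the PCA space, self included) form a candidate
metacell, accepted iff it shares at most `max_shared = 10` members with
every previously accepted metacell of that group.  Acceptance stops at
`targetPerGroup` (default `floor(group_size / (k - max_shared))`, a
feasibility bound) or after `maxAttempts` (default five times the group
size).  Groups smaller than *k* are skipped with a warning.  Aggregation
averages raw counts; because `normalizeMetacells()` re-normalises each
metacell to a common library size before the log transform, mean and sum
aggregation are equivalent.

### Co-expression networks and modules

Per group, genes passing the prevalence filter (detected in ≥ 5 % of
cells) and the HVG selection enter a signed weighted network
$a_{ij} = ((1 + r_{ij})/2)^\beta$ over metacells.  The soft power $\beta$
is the lowest power whose connectivity distribution reaches a scale-free
topology fit of 0.8 (`pickSoftPower()`): connectivities are binned on the
log10 scale and log-frequency is regressed on log-mean-connectivity, with
the R² signed negative when the slope is positive.  When no power reaches
the target — which is the norm for small gene panels and planted-block
simulations, whose connectivity distributions are bimodal rather than
scale-free — the scan falls back to the customary signed-network default
of 12.  We deliberately do not fall back to the best-fitting power: that
argmax is driven by noise in an R² estimated from ~10 bins, and
statistically identical datasets would receive wildly different powers
(we observed 3 to 26), which destabilises everything downstream.

The adjacency is transformed to topological overlap (`tomSimilarity()`),
$\omega_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$,
and modules are detected by average-linkage hierarchical clustering of
$1-\omega$ with a single static cut (`detectModules()`).  The default cut
height is 98 % of the median off-diagonal dissimilarity.  A fixed absolute
height cannot work here: the numeric scale of TOM values moves with the
soft power (the typical unrelated-pair dissimilarity is ~0.93 at power 3
and ~0.9999 at power 26), so any constant either merges the whole network
or cuts it to singletons at some power.  What is stable across powers is
that unrelated pairs concentrate tightly at the top of the dissimilarity
range while co-expressed blocks assemble far below it; requiring clusters
to form distinctly below the typical unrelated pair admits genuine modules
while chance correlations only produce clusters below the
`minModuleSize = 10` floor, which receive the reserved label
`"unassigned"`.  The dynamic hybrid tree cut used by some network
packages is intentionally out of scope; an explicit numeric `cutHeight`
can be passed instead of the default rule.  Module labels are
deterministic (ordered by size, then by lexicographically smallest
member).  `moduleEigengene()` summarises a module as the first principal
component of its standardised expression (unit norm, oriented to correlate
positively with the module mean) and reports each gene's correlation with
it (kME).

### The co-assignment statistic and its null

The headline statistic is
$S$ = the number of cell-type groups in which the candidate occupies the
same module as **both** anchors, out of $T$ groups whose partition has a
module containing both anchors (`anchorModules()`, `coocCount()`).
`permutationTest()` assesses $S$ against a size-preserving permutation
null: within each group the module labels of all non-anchor genes are
permuted uniformly, the anchors stay fixed (the anchor modules are
conditioned on, matching a fixed denominator $T$), one candidate is drawn
uniformly from the panel, and its null count is recorded; the p-value is
the proportion of `B = 10000` replicates reaching the empirical count.
Two implementation notes:

* Only the drawn candidate's permuted label enters the statistic, and the
  marginal distribution of a uniform permutation at a single position is
  uniform over the label multiset; replicates therefore draw that one
  label per group directly.  This is distributionally identical to
  materialising the full permutation and keeps 10⁵–10⁶ replicates cheap.
* The reported p-value is never 0: when no replicate reaches the
  empirical count the result is flagged as "< 1/B".

Under this null, a random non-anchor gene lands in group *g*'s anchor
module with probability $q_g = (m_g - 2)/(N_g - 2)$ ($m_g$ = anchor module
size, $N_g$ = analysed genes), so the null count is Poisson-binomial over
the $T$ groups.  `exactTail()` computes $P(S_{\mathrm{null}} \ge s)$ by
dynamic programming — an independent closed-form oracle that the Monte
Carlo route is tested against (and that assumes the candidate is analysed
in every anchor-module group; groups where a candidate failed the
prevalence filter contribute no possible match for it in the Monte Carlo
route).  A variant null in which the anchors also move is deliberately not
the default: the statistic's denominator T is defined by the observed
anchor modules, conditioning keeps that denominator fixed across
replicates, and the conditioned null admits the exact oracle.

## Synthetic data: the study conditions

The generators define the conditions under which the pipeline is
validated; their defaults are fixed and are not tuning knobs.

**Bulk** (`simulateBulk()`): 25 samples; a latent sample profile
$\ell_s \sim N(0, 1)$ on the log scale shared by the reference, the
partner and the true candidate; independent log-normal noise with sd 0.3
(0.05 for the partner, emulating the near-identical co-promoter pair);
25 decoys with independent profiles of the same magnitude; per-gene
log-normal scale factors.  With these values the true candidate's *r* to
the reference is ~0.85–0.95 while decoys scatter around 0 — the regime in which a correlation screen
can single out one candidate at all.

**Single cell** (`simulateSingleCell()`): 8 groups × 500 cells × 300
genes; 3 planted modules of 10 genes per group; per-cell module activity
$z \sim N(0, 1)$ (module effect 1.0) scaling member-gene means
multiplicatively; gene baselines log-normal (sd 0.5 on the log scale);
library sizes log-normal around 2000 counts; negative-binomial counts with
dispersion 1 (variance $\mu + \mu^2$).  The anchors always occupy module
M1; the candidate joins M1 in 5 of the 8 groups and a different module
elsewhere, so the planted co-assignment count is 5.  Sparsity arises from
low means — there is no explicit zero-inflation, which for snRNA-seq-like
data is the standard modelling choice.  The generators do **not** emulate
batch effects, doublets or ambient RNA; passing tests therefore
demonstrate correctness of the algorithms under a clean generative model,
not robustness to those artefacts.

For the 300-gene synthetic data the screens use QC bounds
`minGenes = 100, maxGenes = 300` — the conventional 200/2000–3500 bounds
presume a ~16,000-gene transcriptome, and `maxGenes` is deliberately a
required argument scaled to the data at hand.

## A worked run

```{r screen, eval = FALSE}
sim <- simulateSingleCell(seed = 1)
res <- runScScreen(sim$counts, anchors = c("Col4a1", "vkg"),
                   candidate = "PH4aEFB", minGenes = 100, maxGenes = 300,
                   B = 10000, seed = 1)
res$cooc
#> CoocResult for 'PH4aEFB': matched 5 of 8 anchor-module groups
#>   Monte Carlo p < 0.0001 (B = 10000, seed = 1015841); exact p = 5.95258e-06
```

The result mirrors the structure of a per-tissue co-occurrence table:
matched groups, total anchor-module groups, Monte Carlo and exact
p-values.  (The chunk is not evaluated during vignette building; the
output shown was produced by running the code as-is, and the same numbers
are recomputed by `scripts/acceptance.R`.)

## Numerical choices and edge cases

* Correlations of constant vectors are errors (bulk) or NA (per-group
  metacell mode); they never silently become 0.
* PCA signs, module labels, ranking ties and seed-cell order are all
  fixed or seeded, so every pipeline stage is bit-reproducible given its
  inputs and seed.
* `scaleFreeFit()` returns 0 with a warning when all connectivities are
  equal or fewer than two log-bins are occupied.
* Genes constant across a group's metacells are dropped from that group's
  network (their correlations are undefined); a candidate absent from a
  group's analysed genes cannot match there, and the permutation null
  accounts for it.
* Module-sized blocks of `"unassigned"` labels participate in the
  permutation; a null draw landing on `"unassigned"` never matches.
* Seeds are 32-bit integers; stage seeds are derived from the master seed
  arithmetically and recorded in the output manifest.

## Problem sizes used by the test suite

The packaged tests validate the Monte Carlo route against the exact
oracle on 100 random partitions (≤ 12 groups, B = 10,000), run the full
single-cell screen on the default conditions above, calibrate the null on
50 simulated datasets without planted structure, and check the bulk
ranking on 100 simulated panels.  These sizes were chosen so the whole
suite exercises every claim at meaningful statistical resolution while
remaining runnable on a laptop in minutes.

## Known limitations

* The static cut (even with the adaptive default height) recovers
  well-separated modules; nested or overlapping module structure calls
  for the dynamic tree cut, which is out of scope here.
* Module merging by eigengene similarity, module preservation statistics
  and consensus networks across tissues are not implemented.
* The exact oracle conditions on the anchor modules; for the
  unconditioned "anchors also move" variant only a Monte Carlo route
  would exist, and it is not the default for the reasons above.
* Loom/H5AD ingestion is not built in.  Convert with the usual Python
  tooling, e.g. `anndata` → Matrix-Market: write `matrix.mtx` (genes ×
  cells), `features.tsv`, `barcodes.tsv` and an `annotations.tsv` with
  columns `cell_id` and `group`, then `readSparseCounts()`.
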