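---
title: "Models and design choices in kinwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in kinwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinwave)
```

`kinwave` analyzes two-arm (vehicle vs treated), multi-time-point
single-cell RNA-seq experiments of the kind used to study drug-induced hair
follicle regeneration. This vignette explains the statistical machinery, the
parameters that matter, and the design decisions taken where more than one
reasonable convention exists. Nothing here reports an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The synthetic study design

The generator (`sim_config()`, `simulate_dataset()`) is a first-class,
tested component, not a test fixture: it is the ground truth against which
every downstream stage is validated. It emulates a design with two treatment
arms sampled at days 0 (baseline), 3 (priming), 9 (pigmentation) and 15
(full anagen), a configurable number of cell types, and four planted kinetic
gene programs.

Counts are negative binomial: for gene $g$ and cell $c$,

$$ y_{gc} \sim \mathrm{NB}\big(\mu_{gc},\ \theta\big), \qquad
   \mu_{gc} = b_g \, \ell_c \, m_{k(g)}(d_c; a, \text{arm}_c) \, s_{gc}, $$

with per-gene lognormal baselines $b_g$, per-cell lognormal library-size
factors $\ell_c$ (default log-sd 0.3), the kinetic template $m_k$ of the
gene's planted module evaluated at the cell's day, and a marker boost
$s_{gc} = 8$ for a cell type's marker genes inside that type (1 elsewhere).
The dispersion default $\theta = 2$ gives the strong overdispersion typical
of UMI data; $\theta \to \infty$ recovers Poisson behaviour, which the test
suite exploits for moment checks. Mitochondrial content is produced by
giving a flagged `mt-` gene block a Dirichlet-weighted share of each cell's
expected reads equal to $p_c/(1-p_c)$ times its non-mitochondrial total,
where $p_c$ is drawn from a Beta law matched to the configured
mean/sd — so the expected per-cell mitochondrial proportion equals $p_c$ by
construction.

The four kinetic templates are the simplest smooth curves realizing the four
canonical shapes, all anchored at $m(0) = 1$:

* module 1 (*decreasing*): exponential decay
  $m(d) = (1 + (a-1)e^{-d/\tau})/a$ with $\tau$ a third of the day range, so
  expression falls towards $1/a$;
* module 2 (*bell*): an affine-rescaled Gaussian bump
  $m(d) = 1 + (a-1)\,\frac{g(d) - g(0)}{1 - g(0)}$, with $g$ centered at 40%
  of the day range (day 6 for a 0–15 design, symmetric between the sampled
  days 3 and 9) and sd 15% of the range; the peak reaches exactly $a$;
* module 3 (*valley*): the reflected bump,
  $m(d) = 1 - (1-1/a)\,\frac{g(d) - g(0)}{1 - g(0)}$, dipping to $1/a$ and
  recovering to ≈ baseline;
* module 4 (*increasing*): a saturating rise normalized to end exactly at
  $a$ on the final day in the treated arm; in the vehicle arm the same curve
  is evaluated at $\min(d, d_2)$ (the second design day), producing the
  plateau after the priming period that distinguishes treatment-responsive
  induction from the baseline regeneration program.

Only module 4 differs between arms by default; amplitudes can be set per
module and per arm. The narrow bump sd keeps all templates strictly positive
for any amplitude, which the affine form would otherwise violate for large
$a$.

What the generator deliberately does **not** emulate: doublets, batch
effects, ambient RNA, gene-length effects, and UMI-vs-read distinctions.
Passing tests on this generator therefore demonstrate correctness of the
statistical machinery under a clean NB model, not robustness to those
artifacts on real data.

## QC, normalization and annotation

`qc_filter()` retains cells with 500–5,000 detected genes and at most 20%
mitochondrial reads. Both gene bounds and the mitochondrial cap are read
**inclusively** (a closed interval; "no more than" as $\le$), a literal
convention recorded in the QC report. Mitochondrial genes are identified by
an explicit flag, or by the mouse-style `mt-` prefix when none is given.

Downstream of QC the package uses plain library-size log-normalization,
$\ln(10^4 \cdot y_{gc} / L_c + 1)$. Variance-stabilizing transforms, anchor
integration, SNN/graph clustering and UMAP are deliberately out of scope:
cell identity is either ground-truthed (synthetic data) or user-supplied,
and `annotate_by_markers()` covers the remaining need by scoring each cell
type as the mean of z-scored marker expression, labeling by argmax with
deterministic ties broken in marker-table order. The margin (top minus
runner-up score) flags low-confidence calls. A doublet mask, if available
from external tools, can simply be applied to the metadata before analysis.

## TDEG discovery and kinetic modules

`de_test()` is a two-sided Wilcoxon rank-sum test: exact (from the rank-sum
null distribution) when both groups have ≤ 8 tie-free observations, normal
approximation with tie and continuity corrections otherwise. The fold
change uses the back-transformed-mean convention
$\ln\frac{\overline{e^{x_A} - 1} + 1}{\overline{e^{x_B} - 1} + 1}$ — the
convention under which the standard 0.25 cutoff is meaningful.

Decisions where conventions genuinely diverge:

* **Day pairs.** "Differential between time points" can mean consecutive
  pairs or all pairs; `find_time_degs()` defaults to **all unordered
  pairs** (6 for a 4-day design) and takes the union, maximizing
  sensitivity for genes whose change needs the full day-0-to-15 contrast;
  `day_pairs = "consecutive"` restricts it.
* **Multiplicity family.** BH adjustment is applied within each
  (cell type, arm, day pair) gene family; the family choice is exposed by
  construction (adjustment happens per pair inside the function).
* **Strictness.** Both thresholds are strict inequalities: a gene at
  exactly `|avg_logFC| = 0.25` is not a TDEG.
* **Arms.** Module discovery is fit per arm (matching side-by-side per-arm
  kinetic heatmaps); pooling arms before smoothing is possible by passing
  the combined stratum but is not the default.

`smooth_time_curves()` regresses each gene on a natural cubic spline basis
of the continuous day coordinate (df = 3, the smallest basis that can
express all four planted shapes with four distinct days; evaluated on a
100-point grid). Natural splines reproduce constants and straight lines
exactly, which the tests assert. Rows are standardized (mean 0, sd 1;
constant rows flagged and zeroed) before clustering so that Euclidean
distance is monotone in $1 - r$ (Pearson), i.e. modules group by shape, not
magnitude. Clustering uses `hclust` with the `ward.D2` convention
(unsquared distances) and a k = 4 tree cut; k is a parameter because the
choice of four kinetic classes is a modeling decision, not a theorem.

Raw tree-cut labels are arbitrary, so `label_module_shapes()` correlates
each module's mean curve with the four canonical templates and solves the
4×4 maximum-total-correlation bijective matching (all 24 permutations —
exact, no greedy ties), then renumbers modules 1–4 in canonical order
(decreasing, bell, valley, increasing). This makes module ids comparable
across cell types, which the shared-gene rule (`shared_tdeg_genes()`,
inclusive "in at least *k* cell types" counting) requires.

## Pseudotime and wave-DEGs

Tree-embedding algorithms (DDRTree and kin) are external published methods;
`kinwave` substitutes a transparent ordering with the same contract:
project cells onto d = 10 principal components (top 2,000 highly variable
genes by default; a curated marker panel can be supplied instead), build a
symmetric k = 15 nearest-neighbor graph with Euclidean weights, and take
shortest-path distance from the root — the root population's
centroid-nearest member, honoring the fact that the root is a population,
not a cell — rescaled to [0, 1]. Disconnected cells get pseudotime 1 and a
flag. The substitution is recorded in the result's method metadata. Branch
inference is out of scope; the ordering is single-lineage.

`spline_lrt()` tests pseudotime dependence by NB regression (log link) of
raw counts on a df = 3 natural spline basis against an intercept-only null.
The dispersion $\theta$ is estimated once under the null (maximum
likelihood with a method-of-moments fallback, clamped to $[10^{-3},
10^5]$) and held fixed in both fits: the models are then strictly nested,
the statistic is guaranteed non-negative, and the $\chi^2_3$ reference is
well calibrated (the suite checks a type-I error of 0.03–0.07 at
$\alpha = 0.05$ over 1,000 null genes). Estimating $\theta$ separately per
model can produce negative "LRT" values and was rejected. Non-convergence
triggers a flagged Gaussian F-test fallback on log1p counts.

Wave-DEG selection filters to `q < 0.05` (BH — the conventional "q-value"
here is Benjamini–Hochberg, not the Storey estimator) and expression ratio
> 10% (fraction of cells with a nonzero count), ranks by q ascending with
LRT-statistic descending as tie-break, and keeps at most 1,000 genes. The
selected genes are smoothed against pseudotime with the same spline
machinery, Ward-clustered into k = 3 waves, and renumbered by the position
of each wave's peak (early = 1, mid = 2, late = 3). Binned composition uses
20 equal half-open bins (the last closed) by default — the bin count is not
canonical and is exposed as a parameter; empty bins are reported explicitly
rather than silently zero-filled.

## Gene-set scoring and enrichment

`aucell_score()` reimplements ranking-based recovery-curve AUC: per cell,
genes are ranked by expression descending and the count of set members
recovered among the top $x$ genes is accumulated for $x = 1, \dots,
\lceil 0.05\,G \rceil$, normalized by the maximum achievable area, giving a
score in [0, 1]. The 5% `top_fraction` follows the common default for this
statistic and is configurable. Ties get **average ranks** — deterministic,
unlike randomized tie-breaking — with a seeded randomized mode available
for sensitivity analysis. Because the score is rank-based it is invariant
to any strictly increasing transform of a cell's expression vector.

`gsea_enrichment()` implements the classical weighted Kolmogorov–Smirnov
statistic: hits weighted by $|r|^p$ ($p = 1$) normalized over the set,
misses by $-1/(G - m)$, ES the running-sum extremum. The null is built from
gene-label permutations (set positions redrawn uniformly); NES divides ES by
the mean |null ES| of matching sign; the nominal p is the sign-matched tail
with +1 smoothing (hence bounded below by $1/(B+1)$); FDR follows the
sign-matched NES-ratio convention across the tested sets, and reduces to
the nominal p when a single set is tested. Curated pathway collections are
user inputs (GMT); the package ships none.

## Ligand–receptor crosstalk

Full cell–cell communication frameworks model mass-action kinetics with
multi-subunit complexes; the quantity actually contrasted between arms in
this analysis is simpler — the count of significant ligand–receptor events
per (sender, receiver) pair. `lr_score_test()` therefore scores a pair as
trimean(ligand in sender) × trimean(receptor in receiver) (Tukey trimean,
type-7 quantiles) within one arm, and calibrates it by shuffling cell-type
labels **within the arm** (preserving each arm's expression distribution),
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$. A pair is significant
iff $p < 0.05$ and the score is positive. Multi-subunit complexes are not
modeled; complex database entries must be pre-split or are skipped with a
warning. `interaction_delta()` then reports treated-minus-vehicle counts of
significant events per (sender, receiver) — antisymmetric under arm
exchange, and checked against brute-force recounting in the tests.

Each (pair, sender, receiver) test derives its own sub-seed from the master
seed, so results are independent of evaluation order and reproducible.

## Problem sizes and numerical conventions

The validation suite runs at deliberately compact scales chosen to give the
statistical checks adequate resolution while staying quick on one CPU:
simulated designs of 1,000 genes with 50 cells per (type, day, arm) for
module recovery (five seeds), 2,000 cells for moment checks, 1,000 null
genes for LRT calibration, 500 repetitions for permutation-p uniformity,
and exhaustive enumeration oracles wherever group sizes permit
(rank-sum tests with $n \le 7$, AUC universes of 12 genes). Degenerate
inputs follow fixed conventions: empty QC output is a warning, not an
error; constant genes test as null (p = 1); constant smoothed curves are
exempt from standardization and flagged; annotation ties resolve by table
order and are flagged low-confidence.

## Known limitations

* Pseudotime is single-lineage; branching topologies are collapsed onto
  one axis.
* The marker-scoring annotator assumes markers are enriched, not merely
  present; closely related types with shared markers will blur.
* The NB spline test conditions on a null-estimated dispersion; strong
  signal inflates that estimate slightly, making the test mildly
  conservative for extreme effects (power checks still pass at 4-fold
  signal).
* The crosstalk score ignores receptor stoichiometry and pathway-level
  aggregation by design; it supports event counting, not quantitative
  communication-strength inference.
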