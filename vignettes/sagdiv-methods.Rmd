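---
title: "Methods: diversity-guided selection and QC of single-cell amplified genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity-guided selection and QC of single-cell amplified genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagdiv)
library(dplyr)
```

# The problem

Microbial single-cell genomics surveys sort individual cells by flow
cytometry, amplify each cell's genome, and sequence the amplified DNA to
obtain single-cell amplified genomes (SAGs). Two practical questions
dominate such surveys:

1. **Which cells should be sequenced deeply?** Sequencing budgets allow only
   a subset of sorted cells to be taken to high coverage. Cells differ both
   in how informative they are (how much *new* phylogenetic diversity their
   genome would add to what is already sequenced) and in how much effort
   they cost (cells whose whole-genome amplification is slow tend to yield
   poor assemblies).
2. **Which assemblies can be trusted?** Single-cell sorting occasionally
   deposits two cells in one well; the resulting assembly mixes two
   genomes and must be flagged. Assemblies may also simply be too fragmentary
   to use.

`sagdiv` implements the full desk-side workflow around these questions —
assembly QC and contamination screening, amplification-kinetics cost
estimation, budgeted phylogenetic-diversity selection, per-clade
phylogenetic gain, gene-catalog novelty, and the comparative statistics on
top — together with a synthetic-data generator that provides controlled
ground truth for every stage.

# The selection model

## Faith's phylogenetic diversity

For a rooted reference tree with branch lengths and a set $S$ of leaves,
the rooted phylogenetic diversity $PD(S)$ is the total branch length of the
union of root-to-leaf paths of $S$ — the length of the "active" part of the
tree. `pd_of()` computes this directly. PD is monotone and submodular in
$S$, which the test suite asserts on random probes and which the solvers
exploit.

## The budgeted selection problem (Noah's Ark)

Each candidate cell $l$ carries a cost $c_l$ (minutes to amplification
inflection, below). Selection maximizes the sum of active branch lengths
subject to a cost budget $B$ and a cardinality cap $k$:

$$\max \sum_e \mathrm{len}(e)\, y_e \quad \text{s.t.}\quad
  y_e \le \sum_{l\ \text{under}\ e} x_l,\quad
  \sum_l c_l x_l \le B,\quad \sum_l x_l \le k,$$

with binary leaf variables $x_l$ and edge variables $y_e$ — the bipartite
leaf/branch formulation built by `build_ip()`. Three solvers share this
contract:

* `solve_bruteforce()` — exhaustive enumeration (≤ 20 candidates), the
  oracle for everything else;
* `solve_exact()` — with a finite budget, a depth-first branch-and-bound
  whose pruning bound is the tighter of (i) the sum of the top-$k'$
  remaining marginal gains (valid by submodularity) and (ii) a fractional
  knapsack bound on the remaining budget; with an infinite budget the
  problem is PD maximization under a pure cardinality constraint, which the
  greedy algorithm solves *exactly* on trees (Steel 2005; Pardi & Goldman
  2005), so that fast path is used and still reported `optimal = TRUE`;
* `solve_greedy()` — two sweeps (marginal gain per unit cost, then plain
  marginal gain), returning the better selection. With uniform costs the
  classic $(1 - 1/e)$ submodular guarantee applies.

All solvers break objective ties toward the lexicographically smallest
chosen leaf set, so outputs are reproducible. `ip_lp_bound()` solves the LP
relaxation (simplex) as an independent upper bound used in testing.

**Anchoring.** By default (`anchored = TRUE`) the non-candidate leaves of
the tree count as already selected: candidates are scored by the *marginal*
diversity they add to the reference genomes among which they were placed.
This matches the survey setting, where the reference tree is already
sequenced; the unanchored variant is a flag away. How reference leaves
enter the objective was a genuinely open design point; anchoring was chosen
because an unanchored objective would reward re-selecting diversity the
databases already contain.

## Amplification cost

Real-time whole-genome-amplification curves are fit with a 4-parameter
logistic $F(t) = F_0 + A/(1+e^{-r(t-t_{inf})})$ (`fit_amplification()`,
Levenberg–Marquardt, initial values from data quantiles, one perturbed
restart, tolerance $10^{-8}$, ≤ 500 iterations). The fitted $t_{inf}$ *is*
the inflection time — the model's steepest point by construction — and is
the cell's selection cost; the fit was preferred over a numerical
derivative of the raw curve because it is far more stable under noise.

**Failed amplification.** A cell is excluded (cost $+\infty$) when the fit
does not converge, the signal has zero variance, or the fitted curve's rise
across the observed window is below $3\times$ the residual standard
deviation of the fit. The window-rise form (rather than the raw amplitude
$A$) matters for two degeneracies: a genuine logistic spends much of its
time at both plateaus, so its *total* variation is of the same order as
$A$ and amplitude-vs-total-SD comparisons misfire; and a flat noisy signal
can be fit by a large-amplitude logistic whose inflection sits far outside
the data (saturated fit), which the window rise catches. The rule is
scale-free: costs are invariant to affine rescaling of fluorescence.

Forward-scatter calibration uses the log-linear model
$D = 10^{a\,\log_{10}(FSC) - b}$ fit by OLS on the log-log scale
(`fit_fsc_calibration()`, `predict_diameter()`).

# Assembly QC

* Contig ends are trimmed by 100 bp and only contigs strictly longer than
  2,000 bp retained (`trim_contigs()`); "longer than" is read strictly, so
  a post-trim length of exactly 2,000 bp is dropped.
* Sequences containing less than 5% of any nucleotide are removed as
  low-complexity (`filter_low_complexity()`).
* Assemblies with total length below 20,000 bp fail QC (`qc_metrics()`);
  GC% is computed over A/C/G/T only, excluding N from both numerator and
  denominator so masked assemblies are not biased.
* `five_number()` provides the Tukey five-number summaries used to
  describe the QC metric panel.

## Tetramer-PCA contamination screen

Contigs are cut into non-overlapping 5,000 bp windows (a trailing window is
kept at ≥ 1,600 bp; a contig shorter than one window contributes its single
window so short inputs are not silently invisible); each window yields a
256-entry tetranucleotide frequency vector, N-containing tetramers
excluded. Window size 5 kb follows common tetramer-binning practice and
guarantees at least 3–4 windows for the 20 kb minimum assembly; per-window
(rather than per-contig) profiles were chosen so that a contaminant
occupying part of a long contig set is still visible as a second mode.

The window vectors are projected on the first 2 principal components, the
scores are split by a deterministic 2-means (centers initialized at the two
most distant points), and the score is the ratio of between-cluster to
within-cluster sum of squares. A two-genome assembly shows two composition
modes and a large ratio; a pure assembly does not. With fewer than 3
windows the screen is declared inconclusive (flag `FALSE`, score `NaN`,
warning) rather than guessing.

**Threshold.** The flagging cutoff (default 5) was calibrated once on the
synthetic benchmark: across seeds, pure assemblies score below ~2 and
two-genome mixtures above ~12, so 5 sits mid-gap with a wide margin on both
sides. On the shipped benchmark (100 pure + 100 mixed per seed, 5 seeds)
the screen reaches sensitivity and specificity of 1.0.

# Placement, grafting, and phylogenetic gain

Placements (one best location per SAG: reference edge, position along it,
pendant length) are grafted by splitting the edge at the given position and
attaching a pendant edge (`graft_placements()`). Splits conserve base
branch length exactly, so total length grows by exactly the summed pendant
lengths; when only an edge is known the split position defaults to the
midpoint, which moves within-clade topology but no gain number.

`gain_table()` reports, per internal node of the base tree, the clade's
base branch length (edges strictly inside the subtree — the stem edge is
excluded, a documented choice since either convention is defensible), the
pendant length added inside it, the count of genomes placed below, and the
phylogenetic gain $100 \cdot \mathrm{added}/\mathrm{base}$ — the percentage
increase in the clade's diversity.

Genome-level novelty consumes an externally computed ANI table
(`ani_novelty()`): a genome is novel when no reference hit exceeds 97%
identity strictly. Computing ANI itself is out of scope — it is the job of
dedicated genome-alignment tools — and only the decision rule is
implemented.

# Gene-catalog novelty and enrichment

Nucleotide identity between genes (`seq_identity()`) aligns the shorter
sequence globally against the longer with identity counted over the shorter
sequence — the convention of greedy clustering tools — trying both strands.
Candidate pairs are prefiltered by shared 8-mers; because a *single* shared
8-mer is near-certain between unrelated genes once a catalog has a few
hundred entries, a candidate must share at least 5% of the query's distinct
8-mers on one strand. True matches above ~85% identity share 30–60% of
their 8-mers, so the prefilter costs no sensitivity while keeping the
alignment count linear.

`label_novelty()` marks a gene novel when it has no catalog match strictly
above 95% identity (a gene at exactly 95% is novel). `dereplicate_genes()`
implements greedy longest-first clustering at ≥ 95% identity on both
strands. `overlap_counts()` produces the per-catalog and joint known/novel
counts.

`enrichment_test()` asks whether novel genes concentrate in particular
functional categories. The full ontology-weighted enrichment methodology
reduces, for a flat single-level category set such as COG letters, to a
label permutation test, which is what is implemented: novelty labels are
permuted across genes (preserving the total novel count and each gene's
category multiset), and a two-sided permutation p-value with the add-one
correction is computed per category, followed by BH adjustment. Permutation
counts below 1,000 are rejected because the discrete p-value floor
$1/(n_{perm}+1)$ would otherwise dominate.

# Statistics layer

`wilcoxon_unpaired()` uses exact enumeration for combined samples of ≤ 16
without ties and the tie- and continuity-corrected normal approximation
otherwise; `wilcoxon_paired()` is the signed-rank test on per-pair
differences aligned by id (a "paired rank-sum test" is not a defined test,
so the standard paired Wilcoxon is used), exact for ≤ 15 untied nonzero
differences. Zero differences are dropped by default (the original rule,
deterministic); Pratt's treatment is available via `zero_method = "pratt"`.
At the exact/approximate boundary the two branches agree to about 0.011 in
p — the measured accuracy of the continuity-corrected normal approximation
at $n = 16\!-\!17$; sub-0.01 agreement there is not attainable for the
standard approximation.

`bh_adjust()` is the step-up FDR adjustment; `prevalence_counts()` counts
species with strictly more than 5 k-mer hashes per sample as a prevalence
proxy; `compare_conditions()` runs all pairwise condition comparisons of a
long metric table with joint BH adjustment and a display threshold of
adjusted p < 0.1.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions used by the tests and the acceptance benchmark.

* **Trees** (`sim_tree()`): random binary topology by sequential leaf
  attachment; branch lengths i.i.d. exponential (default mean 0.1
  substitutions/site) — the simplest process with strictly positive,
  variable lengths. Default 100 leaves.
* **Curves** (`sim_curves()`): 4-parameter logistic plus Gaussian noise on
  a 0–160 min grid at 2-min steps; inflection uniform in the central half
  of the window, rate 0.10–0.30/min, amplitude ~1, noise SD 0.05 (5% of
  amplitude, a realistic plate-reader noise level); a 10% failure fraction
  produces flat baseline-plus-noise curves. The instrument's export format
  is not standardized, so a generic long CSV (`cell_id, time_min,
  fluorescence`) is assumed.
* **Assemblies** (`sim_assemblies()`): each of 5 source genomes is an
  independent random 3rd-order Markov composition model (Dirichlet rows),
  guaranteeing distinct tetramer signatures without hand-tuning; 40 kb per
  cell in 4–8 contigs. A 10% doublet fraction mixes two genomes at a 50:50
  ± 10% length share — the canonical co-sort model, and close to the
  hardest detectable ratio.
* **Genes** (`sim_gene_sets()`): a catalog of random genes (300–1,200 bp);
  query genes are catalog genes mutated by point substitutions to an exact
  target identity (the substitution count is derived from the target, so
  ground-truth identity is exact by construction) plus fresh random genes
  as true novels.

What the generator does **not** emulate: read-level errors and assembly
(contigs are composition-true by construction), amplification bias along
the genome, shared ancestry between source genomes (real contaminant pairs
can be compositionally closer than independent Markov models), catalog
redundancy, and indels in gene divergence. Passing the synthetic benchmark
therefore demonstrates correctness of the algorithms under the stated
model, not field performance on real sequencing data.

# Numerical and determinism choices

* Every generator derives its RNG stream from an explicit seed and restores
  the caller's RNG state; identical configs give byte-identical outputs.
* PD equality across solvers is tested to $10^{-9}$; grafting conserves
  length to $10^{-9}$; newick round-trips preserve lengths to ≥ 10
  significant digits (12 written).
* Tie-breaks: candidate processing and result sets are ordered
  lexicographically; clustering processes length-descending then id;
  2-means initialization is deterministic.
* Degenerate inputs: empty selection is always feasible (budget 0 yields
  the empty set, PD 0); zero-variance screens score 0; all-zero paired
  differences give p = 1 with `n_effective = 0`.

# Problem sizes used in the shipped benchmark

Solver oracle equivalence uses 100 random instances on trees of 4–10
leaves with random exponential lengths, random costs, budgets, and caps;
property probes use 1,000 (tree, subset) draws; gain uses 200 random
grafts; cost recovery 100 curves at 5% noise; the contamination benchmark
100 pure + 100 mixed assemblies per seed over 5 seeds; novelty 501
construction genes at 90/96/97% identity; enrichment calibration 50 null
repeats at 1,000 permutations; and the determinism check two full 10-cell
pipeline runs. These sizes keep the whole benchmark around a minute on one
CPU while leaving each estimate's sampling error well inside the asserted
margins.

# Known limitations

* The exact solver's branch-and-bound is practical to roughly 200
  candidates with a binding budget; beyond that, use `solve_greedy()`.
* The contamination screen assumes the two genomes in a doublet have
  distinguishable composition; real close relatives may not separate, and
  the 2-means score targets *two*-source mixtures specifically.
* Identity is computed from a global alignment with affine gaps; the
  generator produces substitution-only divergence, so indel-heavy real
  gene families are outside the validated regime.
* `ani_novelty()` and classifier metric tables consume external tools'
  outputs; those tools are not reimplemented.
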