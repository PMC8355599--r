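---
title: "Building and pruning distance-based gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and pruning distance-based gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnprune)
```

## The problem

ChIP-Seq tells us *where* a transcription factor (TF) binds, not *which gene*
that binding regulates. The cheapest genome-wide heuristic assigns a TF to
every gene whose transcription start site (TSS) lies within some distance of
one of its binding sites. That heuristic is deliberately generous — a single
binding site can sit within a few kilobases of several TSSs, and many bound
sites are not functional — so the resulting network over-states each TF's
target set, often by an order of magnitude.

`grnprune` implements a two-step remedy:

1. **Reference network.** `assign_tfs()` draws a directed edge `TF → gene`
   whenever a peak of that TF lies within a distance threshold of the gene's
   TSS (typical thresholds: 1.5 kb, 2 kb, 5 kb).
2. **Expression-based pruning.** For each gene, `prune_grn()` asks which of
   its *pre-assigned* candidate TFs actually predict its expression across a
   large compendium of RNA-Seq samples, using random-forest importance
   scores, and removes every candidate whose relevance falls below 10% of
   the gene's top-scoring regulator.

The crucial design point is the restriction in step 2: the forest never sees
TFs outside the gene's distance-based candidate set. Tree-ensemble network
inference used genome-wide is noisy; used as a *pruner* of physically
plausible candidates it only has to rank a handful of TFs, which is a much
easier statistical task.

## Coordinate conventions

All internal coordinates are 0-based half-open, the BED convention. BED input
is taken verbatim; GTF/GFF (1-based inclusive) is converted on read, and the
TSS of a gene is its strand-aware 5' end: `start − 1` on `+`, `end − 1` on
`−` after conversion. One convention internally removes a whole class of
off-by-one bugs; the converters are involutions and the test-suite
round-trips them.

A peak's distance to a TSS is 0 when the TSS falls inside the peak, otherwise
the distance to the nearest covered base. "Within the threshold" is
`distance ≤ threshold`, symmetric upstream and downstream — nothing in the
construction privileges promoters over downstream binding. An alternative
midpoint-based distance is available (`mode = "midpoint"`); the interval
reading is the default because it is the most inclusive and makes threshold
nestedness exact: the 1.5 kb network is a subgraph of the 2 kb network, which
is a subgraph of the 5 kb network.

Each gene contributes exactly one TSS (gene-level annotation records). Where
a genome annotation carries one record per transcript, collapsing to
gene-level records is up to the caller; gene-level is the least-assumption
choice and matches gene-level count matrices.

## The pruning model

For a target gene with candidate set $C$, the forest predicts the gene's
standardised expression $y$ from the candidate expression profiles
$\{x_c\}_{c \in C}$. Each of `n_trees` regression trees is grown on a
bootstrap resample, choosing at each node the best variance-reducing split
among `k_split` randomly drawn candidates (default $\lceil\sqrt{|C|}\rceil$).
The importance $w_c$ of candidate $c$ is the impurity decrease (sample-
weighted variance reduction) summed over nodes splitting on $x_c$, averaged
over trees and scaled by the sample count. The retained regulator set is

$$ \{\, c \in C : w_c \ge f \cdot \max_{c'} w_{c'} \,\}, $$

with `relevance_fraction` $f = 0.1$ by default: removal requires relevance
*strictly lower* than 10% of the maximum, so a score exactly at the cutoff
survives and the top-scoring TF always survives. The threshold is *dynamic* —
proportional to each gene's own top score — because absolute importances are
not comparable across genes even after target standardisation.

Decisions worth stating explicitly:

* **Counts are used raw.** Tree splits are invariant to monotone transforms
  of each predictor, so library-size scaling of TF profiles would not change
  the trees; only the target is standardised, which makes importances
  comparable across genes. This mirrors common practice of feeding
  untransformed counts to tree-ensemble network inference.
* **Dropping rules.** A target gene absent from the expression matrix, with
  zero expression variance, or whose candidate set (after removing itself
  and TFs absent from the matrix) is empty, is dropped entirely. Pruning can
  only remove — the pruned network is always a subgraph of the reference —
  and the drop rule is what shrinks node counts, not just edge counts. A
  gene whose only candidate is itself is dropped: self-prediction is
  meaningless.
* **Determinism.** Each gene's forest is seeded by a deterministic hash of
  the global seed and the gene identifier, so results are bit-for-bit
  reproducible and independent of gene iteration order (and would remain so
  under parallel evaluation).
* **The forest engine.** The ensemble is delegated to
  `randomForest::randomForest()`, whose `IncNodePurity` importance is
  precisely the mean total variance reduction the contract requires. The
  correctness contract is the behavioural one above, not any engine default;
  `n_trees`, `k_split` and `min_samples_split` map onto the engine
  explicitly, and the test-suite pins the behaviour (ranking of informative
  vs noise regulators, determinism, degenerate inputs) rather than the
  engine's internals. `min_samples_split = 2` (grow fully) is the default;
  the engine's terminal-node parameter is derived as
  `max(1, min_samples_split − 1)`.

## Validating that pruning helped

Ground truth for real regulatory edges is scarce, so validation is indirect,
built on one biological expectation: TFs that co-regulate a gene tend to
interact, physically or functionally.

**Connectance.** For one gene with regulator set $R$, the connectance against
a TF–TF interaction network is the fraction of realised pairs,
$\rho = m / \binom{|R|}{2}$, where $m$ counts interaction edges with both
endpoints in $R$; $\rho \in [0,1]$, undefined for $|R| < 2$.
`compare_connectance()` tallies, per gene, whether $\rho$ rose, fell or
stayed equal after pruning. Two conventions matter and are deliberate:

* Regulators missing from the interaction network's node set stay in the
  denominator. Incomplete interaction coverage should depress connectance,
  not be silently ignored.
* Genes with fewer than two regulators on either side are excluded from the
  better/worse/equal fractions and reported separately (`n_undefined`);
  including them in "equal" would conflate "no change" with "no information".
  Equality is tested exactly — both values are rationals with known
  denominators — so no tolerance is involved.

**Interaction networks.** Three sources are supported: curated PPI edge
lists (`read_interaction_network()`), STRING-style scored tables filtered at
a confidence threshold per evidence channel (`filter_scored_edges()`, which
auto-detects the 0–1000 integer scale), and co-expression networks built
from the same expression data (`correlation_network()`). Correlation edges
use the positive convention `r ≥ t` by default — co-regulating TFs are
expected to be co-expressed, not anti-expressed — with `|r| ≥ t` available
as an option.

**Co-expression of co-regulated genes.** Genes sharing regulators should
co-express. For each $k = 2, \dots, k_{max}$, `coexpression_comparison()`
collects the unordered target pairs sharing *at least* $k$ regulators
(cumulative sets) in the reference and pruned networks separately, computes
Pearson correlations per pair, and compares pruned vs reference correlations
with a Welch two-sample t-test. Welch rather than pooled variance because
the two pair sets have very different sizes and variances by construction.
Raw p-values are reported; no multiplicity correction is applied across $k$,
and a stringent significance level (e.g. $p \le 5\times10^{-4}$) is the
recommended reading.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` builds a toy genome in which the reference network is
forced by construction: each gene receives peaks for `true_per_gene` real
regulators and `decoys_per_gene` decoy TFs, all within the window, with
inter-gene spacing greater than twice the threshold so no peak can reach a
neighbouring gene. `simulate_expression()` draws TF profiles from a small
set of latent factors (loading 0.7, one factor per ~8 TFs) plus independent
noise, and each target gene as the weighted sum of its true regulators plus
Gaussian noise, shifted and rounded to a counts-like non-negative range.

Defaults define the standard study conditions used throughout the tests:
25 TFs, 150 genes, 3 true regulators with weights in $[0.7, 1.3]$ and 12
decoys per gene, noise standard deviation 1 (noise comparable to one
regulator's signal), 400 samples. These sizes keep a full multi-seed run in
the minutes range on one core while leaving the ranking task non-trivial:
decoys correlate with true regulators through the latent factors, exactly
the hazard that defeats naive correlation-based pruning.

The linear-Gaussian model is the simplest one under which variance-reduction
importances provably favour true regulators, which is what makes recovery
bounds meaningful. It does **not** emulate: negative-binomial count noise or
library-size variation, nonlinear or combinatorial regulation, repression
(weights are positive), chromatin context, or TF activity differing from TF
expression. Passing recovery tests on this generator therefore demonstrates
the machinery is correct and the method behaves as designed under its own
assumptions — not that real networks will prune equally well.

On the standard conditions (seeds 1–10, 100 trees), pruning raises edge
precision above the reference baseline of 0.20 on every seed at recall 1.0,
and the per-gene connectance against the truth-derived co-regulation network
improves for more genes than it worsens in 9 of 10 seeds — the package's
acceptance suite recomputes both facts on every run.

## Numerical and degenerate-input choices

* Importance scores are nonnegative by construction; a clamped floor at 0
  guards against the engine's floating-point dust.
* `dynamic_threshold()` on an empty table is an error (the caller drops the
  gene before this point); a single candidate is trivially retained.
* Fewer than 10 samples is an error — forests on a handful of samples
  produce rankings indistinguishable from noise.
* Peaks on chromosomes absent from the annotation are skipped with a
  warning (chromosome naming mismatches should be loud, not fatal).
* Duplicate edges collapse; the networks are unweighted throughout.
* Zero-variance TFs are excluded from correlation networks with a warning;
  `cor()` would return `NA` and silently delete edges otherwise.

## Problem sizes in the test-suite

Unit tests run on miniatures (5–10 TFs, 10–40 genes, 50–200 samples, 20–100
trees). The acceptance suite uses the standard conditions above across 10
seeds, plus exhaustive enumerations where the domain is finite: every 5-TF
interaction subgraph against every regulator subset of size 2–5 for
connectance, and 20 random genome fixtures for assignment against a
brute-force all-pairs oracle. These sizes were chosen so the complete suite
runs in a few minutes on one core.

## Known limitations

* Average in/out-degree conventions differ between published network tables;
  `summarize_grn()` defines them as edges ÷ distinct targets and edges ÷
  distinct TFs with out-edges, so the arithmetic identities
  `avg_outdegree × n_tfs = n_edges` hold exactly. Counts over other
  denominators (e.g. all annotated genes) must be derived by the caller.
* Replicate ChIP-Seq experiments are not merged: each peak row is treated
  independently (duplicate edges collapse anyway).
* The pruner ranks *expressed* candidates; a true regulator absent from the
  expression matrix cannot be retained, and condition-specific regulation
  that never varies in the compendium is invisible to it.
* `ego_out()` uses induced-subgraph semantics: edges among the center's
  targets, and from targets back to the center, are retained. Star-only
  extraction can be had by filtering `grn_edges()` on the source column.
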