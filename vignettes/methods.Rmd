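---
title: "Ranking endothelial populations by EHT potential: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking endothelial populations by EHT potential: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the approach

During embryogenesis, blood stem cells arise from hemogenic endothelium by
the endothelial-to-hematopoietic transition (EHT). Whether any adult
endothelial population retains a vestige of this competence is a question
one can put to single-cell expression data: how strongly does each tissue's
endothelium express, co-express, and *use* (in the sense of downstream
target regulation) the transcription-factor machinery of the EHT?

`hemorank` operationalizes this as three measurements per tissue, anchored
on a fixed panel of eleven seed TFs (Cbfa2t3, Cbfb, Erg, Fli1, Gata1,
Gata2, Ldb1, Lmo2, Lyl1, Runx1, Tal1) with an eight-TF co-expression
subset (Cbfb, Erg, Fli1, Gata2, Lmo2, Lyl1, Runx1, Tal1):

1. **Frequency** — the fraction of endothelial cells detecting each panel
   gene (detection = raw count > 0), classed *moderate* above 25% and
   *low* at or below it.
2. **Co-expression** — per cell, how many subset TFs are detected
   simultaneously; summarized as the distribution of that count and the
   largest k such that at least half the cells co-detect k TFs.
3. **Regulatory-network evidence** — seed-TF → target edges inferred by
   distance correlation, cleaned of indirect relationships by partial
   distance correlation, signed, and summarized by (a) how many seed TFs
   positively regulate an actually-expressed target set and (b) how large
   the group of TFs with strongly overlapping target sets is.

The three scores are max-normalized across tissues, averaged with equal
weights, and the composite ranks the tissues. Everything is validated
end-to-end on synthetic cohorts with planted ground truth.

## Network inference

For one population (at least 30 cells), candidate targets are the non-seed
genes detected in at least 10% of its cells — distance statistics carry no
information on near-all-zero vectors, and the floor bounds the
multiple-testing family.

**Stage 1 (marginal edges).** For each seed TF and candidate, the sample
distance correlation (Székely–Rizzo V-statistic: double-centered pairwise
absolute-difference matrices; dCor = dCov/√(dVarₓ·dVarᵧ)) is computed on
log-normalized expression and tested by permutation: the target is permuted
`n_permutations` (999) times and p = (1 + #{permuted dCov² ≥ observed}) /
(n_perm + 1). P-values are Holm-adjusted per TF family across its
candidates; edges with adjusted p < α (0.05) are kept. With 999
permutations the smallest attainable p is 10⁻³, so a family of ~45
candidates is the practical ceiling at which a maximally significant edge
still clears the Holm threshold α/m — the synthetic cohort's gene universe
is sized with that in mind, and the rarely-detected gene block (below, ~100
genes under the 10% floor) deliberately stays out of the family.

**Stage 2 (indirect-edge pruning).** For each kept edge (a, t) and every
other seed TF b that also has a kept edge to t, the bias-corrected
(U-centered) partial distance correlation pdcor(a, t; b) is computed by
projecting b's U-centered matrix out of a's and t's. The edge is marked
pruned (with the conditioning TF recorded as a TF–TF interaction) when
conditioning removes at least `pruning_drop_fraction` (half) of the
dependence, or when the conditional permutation test (199 permutations,
compared directly to α — no family correction, hence the lower count)
loses significance. The conditional test does not permute the target
freely: that would test *full* independence and is miscalibrated whenever
the target genuinely depends on the conditioning TF. Instead the target is
shuffled within quantile strata of the conditioner (10 bins), preserving
the target–conditioner relationship under the conditional null — the
standard stratified-permutation calibration for conditional independence.
The drop-fraction comparison is made against the
*bias-corrected* unconditional dependence R\*(a, t), not the raw dCor: the
two live on different scales (raw dCor behaves like a correlation, the
U-centered R\* like its square), and mixing them would prune essentially
every true multi-regulator edge. Conditioning is restricted to co-seed
TFs: the design is seed-TF-centric, and conditioning on arbitrary genes
would change the question being asked.

**Stage 3 (signs).** Retained edges get the sign of the Spearman
correlation between TF and target over the cells where the TF is detected
("none" below |ρ| = 0.1 or under 10 expressing cells). Restricting to
expressing cells keeps the shared detection mask from dictating the sign.

Permutations are generated once per network from the configured seed, so
inference is exactly reproducible. Inside network inference the permutation
loops use Besag–Clifford sequential stopping (stop a pair after 30
exceedances): a stopped pair's p-value is by construction ≥ ~0.15, far from
any Holm threshold, so early stopping changes nothing about which edges
survive while making null pairs ~15× cheaper. `dcor_pvalue()` itself
defaults to the exact fixed-m form.

## Target-set activity

Per tissue, genes are ranked within each cell from highest to lowest
normalized expression with seeded random tie-breaking (zeros therefore land
in random order at the bottom). The recovery-curve AUC of a TF's target
set walks ranks 1..L (L = `auc_top_fraction` × n_genes) accumulating set
hits, normalized by the best possible curve. AUC measures enrichment but
not significance, so each cell additionally gets a two-group
Kruskal–Wallis test of set ranks versus background ranks — with tie-free
ranks the statistic has a closed form and a χ²(1) reference, equivalent to
a Wilcoxon rank-sum — and the per-cell p-values are Holm-corrected across
cells with the stepwise rule (sorted pᵢ vs α/(m−i+1), stop at first
failure). A cell is *assigned* to the set when its AUC reaches the
threshold **and** its adjusted p is below α.

The AUC threshold emulates picking the valley of a bimodal AUC
distribution, automated for reproducibility: a two-component Gaussian
mixture (mclust, deterministic hierarchical initialization) is fitted; if
the component means are separated by more than two pooled standard
deviations the threshold is the equal-posterior point between them,
otherwise the distribution is flagged unimodal and the 99th percentile is
used as a conservative fallback.

Two sizing facts shaped defaults here. First, the two-group Kruskal–Wallis
statistic is bounded by roughly 3×|set| whatever the number of genes, so a
target set needs ≥ ~6 members before any cell can clear a Holm correction
across a few hundred cells — the synthetic modules are sized accordingly.
Second, `auc_top_fraction` defaults to the conventional 0.05, but
`cohort_config()` raises it to 0.25 for the synthetic cohort: its compact
universe starts with a block of eight abundant housekeeping genes that
always occupy the first ranks, and a 5% window would end inside that block.

## Overlaps, signatures, ranking

Pairwise target-set overlaps are counted exactly; the asymmetric fraction
|Tᵢ∩Tⱼ|/|Tⱼ| is the secondary, display-oriented normalization. The
"high-overlap clique" is the largest TF subset in which every pair
overlaps reciprocally by at least half — found by exhaustive subset search
(≤ 2¹¹ subsets), so the reported clique is exact, and the 50% anchor is the
one quantified overlap the adult-tissue narrative provides.

Runx1⁺ signatures: endothelial cells of each tissue are split by Runx1
detection (both groups ≥ 3 cells; a tissue with no Runx1⁺ endothelium is a
reported error, mirroring the pancreas); markers are genes with
Holm-adjusted two-sided rank-sum p < α and log fold-change > 0.25 in the
positive group; the split gene itself is excluded as trivially
informative. Genes recurring in ≥ 4 tissues' marker lists form the
recurrent signature.

The composite score averages the three max-normalized components with
equal weights — the simplest aggregation consistent with "normalize to the
maximum, then rank" — and exposes the weights as an argument. The GRN
component gives half its weight to the fraction of seed TFs with a
retained positive edge whose target set is expressed by endothelial cells
(assigned fraction > 0) and half to clique size over panel size; these are
the two network outputs the ranking argument actually uses. Exact
composite ties are broken by raw frequency score then tissue name, and
flagged.

## The synthetic cohort

The generator emulates the structure the method consumes, not a full
transcriptome. Per tissue and population:

* **Seed TFs.** Detection is Bernoulli at the spec frequency (detected
  cells draw 1 + NB(μ−1, size), so the planted frequency *is* the
  detection frequency; no extra dropout is applied to panel genes).
  "Program" TFs — the pool that jointly regulates the shared targets —
  additionally share a latent per-cell activity a ~ N(0,1): their
  detection uses a Gaussian copula (marginal frequency exactly preserved,
  loading 0.75) and their expression level is scaled by exp(0.8·a −
  0.8²/2). This is the coordinated hemogenic program: cells high in the
  program co-detect and co-express the whole pool, which both reproduces
  the co-expression enrichment seen in embryonic endothelium and keeps
  each single TF marginally informative about jointly regulated targets.
  Non-program TFs stay fully independent, so their edges probe the
  program-free regime.
* **Planted targets.** log μ(target) = log(baseline) + Σ effect·sign·z(TF)
  over its regulators (z standardized within the population), capped at ±2
  log-units, then NB-sampled and thinned by Bernoulli dropout (5%).
  Per-edge effects are scaled as σ_target/√(m + m(m−1)·0.3·f) so a pool
  target's planted log-sd is ~1.2 whatever its regulator count.
* **Chains** route tf → mediator → target with no direct term; the
  separate `simulate_seed_chain()` builds the seed-TF-mediated variant
  used to validate pruning, in a low-dispersion regime chosen so the
  spurious marginal tf → target edge is reliably detected *and* reliably
  explained away by the mediator. Two caveats are intrinsic rather than
  implementation details: dropout on a mediator is measurement error on
  the conditioning variable and genuinely re-opens the path (the
  conditional-independence property is therefore checked with dropout
  off), and an over-driven, strongly nonlinear link leaves a residual
  that the linear Hilbert-space projection behind partial distance
  correlation cannot remove.
* **Housekeeping block** (8 genes, μ = 300, size 100): a stable library
  mass, as in full-length protocols where abundant core transcripts
  dominate the total. Without it, per-cell totals track the planted
  program and normalization induces compositional dependence between
  unrelated genes.
* **Rare block** (100 genes at 5% detection): the long tail of rarely
  captured transcripts. It gives rankings realistic depth for the AUC and
  rank tests while staying under the 10% candidate floor.

The default cohort: embryo_AGM (all 11 TFs at 95%, the 8 coexpression TFs
all regulating 12 shared targets), brain (6-TF pool × 10 targets at 60%
moderate frequency), heart (5 × 8 at 38%), kidney (3 × 6 at 26%), liver
(2 × 6 at 15%), pancreas (≤ 6%, Runx1 absent from endothelium, no
endothelial modules). A 6-target Runx1 module recurs in exactly brain,
heart, kidney and liver — never in a tissue where Runx1 belongs to the
program pool, keeping those edges free of program-mediated confounding —
and the pancreas leukocyte population (80 cells) alone carries a shared
Fli1/Runx1 module, planting the known white-blood-cell confound: a
Fli1–Runx1 target overlap that belongs to the tissue, not its endothelium.
Private targets, the two negative edges and the two chains are attached to
the three non-program TFs (Cbfa2t3, Gata1, Ldb1). The true tissue order is
defined by construction (mean endothelial TF frequency × (1 + planted
endothelial edge count)), monotone along the list above.

Population sizes default to 200 endothelial + 60 other cells per tissue
(plus the pancreas leukocytes): large enough that every planted edge class
is comfortably above the permutation detection limit, small enough that a
full cohort analysis runs in well under a minute.

**What passing does and does not show.** The generator produces NB counts
with dropout, a latent co-regulation program, indirect chains, and a
compact gene universe. It does not model batch effects, library-size
gradients, doublets, UMI sampling, cell-type mixtures beyond discrete
populations, or transcriptome-scale gene counts; recovering the planted
ordering here demonstrates the pipeline's statistical machinery end to
end, not performance on any real atlas.

## Numerical choices and degenerate inputs

* Constant vectors have zero distance variance: dCor is defined as 0 with
  a degenerate flag, permutation p as 1; a degenerate conditioning
  variable falls back to unconditional dependence with a warning.
* Permutation p-values use the add-one form and are therefore never zero;
  determinism comes from generating the permutation block once per seed.
* `rank(-x, ties.method = "random")` under a set seed implements the
  "shuffle tied genes" ranking contract; zeros are random at the bottom.
* The exp cap (±2 log-units) keeps planted means finite and per-cell
  totals within a realistic range; effect magnitudes that still produce
  non-finite means are an error.
* Matrix Market round trips: the normalized layer is written at full
  double precision (%.17g) because the stock writer truncates reals.
* The gene filter is strict ("more than 10 cells": detected-in-10 is
  removed); the cell filter is inclusive (≥ min_genes). Both are
  idempotent, and panel genes are exempt from the gene filter so a
  low-frequency TF can never be silently dropped before frequency
  analysis.

## Problem sizes used in validation

Unit and acceptance tests run the oracle comparisons at n ≤ 60 (100
instances), type-I calibration at n = 100 with 999 permutations × 500
replicates, planted-network recovery on a 500-cell embryo-like tissue,
chain pruning over 50 replicates at n = 300, and the end-to-end ranking
over 20 cohort seeds at the default sizes. These sizes were chosen so the
full suite exercises every claim at meaningful power while remaining quick
to run routinely.

## Known limitations

* Distance correlation is O(n²) per pair; populations beyond a few
  thousand cells would need subsampling or the fast univariate algorithms.
* The Holm-per-family design with 999 permutations bounds the usable
  candidate family at ~45 genes; genome-scale candidate sets would require
  more permutations or a different error-rate target.
* The per-cell Kruskal–Wallis reading of significance is conservative for
  small target sets (the statistic is bounded by ~3×|set|).
* Interactive threshold picking is replaced by a deterministic mixture
  rule; on genuinely multimodal or skewed AUC distributions the
  two-component assumption is a simplification.
* Edge signs are association signs, not causal directions.
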