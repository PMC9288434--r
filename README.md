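# hemorank

Ranking endothelial populations by their potential for the
endothelial-to-hematopoietic transition (EHT), from single-cell expression
data.

## The problem

During embryogenesis, hemogenic endothelial cells convert into blood stem
cells (the EHT), a competence that appears to be lost in the adult. Given
cells-by-genes expression matrices from multiple tissues with annotated
endothelial populations, `hemorank` asks: *how close is each tissue's
endothelium to the transcriptional state that permits the EHT?* It is
aimed at computational biologists studying hemogenic endothelium,
reprogramming target selection, or any setting where a fixed
transcription-factor panel should be traced from expression through
co-expression to downstream target regulation.

The pipeline anchors everything on eleven seed TFs — Cbfa2t3, Cbfb, Erg,
Fli1, Gata1, Gata2, Ldb1, Lmo2, Lyl1, Runx1, Tal1 — with an eight-TF
co-expression subset (Cbfb, Erg, Fli1, Gata2, Lmo2, Lyl1, Runx1, Tal1),
and scores each tissue on three axes:

1. **Frequency** — fraction of endothelial cells detecting each panel
   gene (moderate above 25%, low below);
2. **Co-expression** — per-cell counts of simultaneously detected subset
   TFs;
3. **Network evidence** — seed-TF → target edges inferred by distance
   correlation (dCor = dCov/√(dVarₓ·dVarᵧ), permutation-tested, Holm-
   corrected per TF family), pruned of indirect relationships via
   bias-corrected partial distance correlation against co-seed TFs,
   signed by Spearman correlation in TF-expressing cells; target-set
   activity is confirmed per cell by recovery-curve AUC plus
   Kruskal–Wallis/Holm significance, and target-set overlaps yield the
   high-overlap TF clique (exhaustively verified).

Per tissue, the three scores are normalized to their maximum across
tissues and averaged; the composite ranks the tissues. A synthetic
multi-tissue generator with planted ground truth (graded TF frequencies, a
latent co-regulation program, signed regulatory modules, indirect chains,
dropout, overdispersed counts, and a leukocyte-borne Fli1/Runx1 confound)
validates every stage end to end.

## Worked example

```r
library(hemorank)

cohort <- generate_cohort(default_cohort(), seed = 1)
result <- run_pipeline(cohort$bundle, cohort_config(rng_seed = 1))
result$scorecards[, c("tissue", "freq_score", "coexpr_score",
                      "grn_score", "composite", "rank")]
```

```
      tissue freq_score coexpr_score grn_score composite rank
1 embryo_AGM     0.9486       0.9450     0.727    1.0000    1
2      brain     0.5200       0.5262     0.455    0.5767    2
3      heart     0.3368       0.3294     0.500    0.4637    3
4     kidney     0.2282       0.2306     0.318    0.3074    4
5      liver     0.1327       0.1306     0.227    0.1969    5
6   pancreas     0.0509       0.0494     0.000    0.0353    6
```

The embryo-like tissue detects the full panel in ~95% of endothelial
cells, co-expresses it, and supports a network in which 8 of 11 TFs
positively regulate expressed target sets with a full 8-TF overlap clique
— so it tops every component and its composite is 1 after
max-normalization. The adult tissues fall away in the planted order, and
the null pancreas (no panel expression, no endothelial modules) lands
last. The recovered order matches the generator's ground truth
(`cohort$truth$true_tissue_order`) exactly.

The same run reports the two signature analyses: the recurrent
Runx1⁺-endothelium markers
(`result$signatures$recurrence$recurrent_genes` — the six planted Runx1
module genes, found independently in the four tissues carrying them) and
the white-blood-cell confound: the Fli1/Runx1 target-set overlap in the
pancreas appears in `result$overlap[["pancreas/leukocyte"]]` but not in
`result$overlap[["pancreas/endothelial"]]`, reproducing the situation
where a promising TF overlap belongs to a tissue's leukocytes rather than
its endothelium.

The step-by-step version of this analysis lives in `analysis/01..07` —
simulate, preprocess, TF-panel profiling, network inference, activity
scoring, overlaps/signatures, ranking — each a thin driver over the
package functions that writes its tables under `results/`.

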