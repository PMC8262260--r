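# MLtiplet

Multi-omic identification of doublets and multiplets in droplet-based
single-cell RNA-seq, for experiments that captured CITE-seq (antibody-derived
tags) and/or VDJ-seq (BCR/TCR contigs) alongside the transcriptome.

## The problem

A droplet that captures two cells reports one hybrid transcriptome.
Simulation-based doublet detectors need the expected doublet rate as a prior,
which is rarely known, and they struggle with homotypic doublets (two cells of
the same type). But multi-omic readouts contain droplets that give themselves
away:

* **CITE-seq**: a droplet positive for both members of a mutually exclusive
  surface-marker pair (e.g. CD19 + CD3) contains more than one cell. Per-
  antibody positivity thresholds are fitted by a one-dimensional linear
  discriminant on CLR-normalised ADT counts between reference populations
  with known high / low expression; antibodies must recall >70% of their
  positive reference to be used.
* **VDJ-seq**: after filtering to productive chains with ≥6 UMIs, a droplet
  is flagged when it carries (a) both BCR and TCR chains, (b) ≥2 IGH or ≥2
  light chains, (c) ≥2 TRB chains, (d) a BCR without clustering with B cells,
  or (e) a TCR without clustering with T cells.

These *identified* doublets form a training set. A logistic generalized
linear model then generalises the labels to every droplet from its features:

```
logit P(doublet) = b0 + b1 * mito_ribo_ratio + b2 * CLR(nUMI) + sum_k g_k * score_k
```

where `mito_ribo_ratio = m / (m + r)` (m, r = % mitochondrial and
% ribosomal-protein UMIs; elevated in apoptotic, aggregation-prone cells),
`CLR(nUMI)` is the per-sample centred log-ratio of the droplet's UMI count,
and `score_k` are per-cell-type module scores (mean marker expression minus
expression-matched controls). Training groups are trimmed to within 2 SD of
their group means before fitting. The output is a doublet probability per
droplet — no doublet-rate prior anywhere.

The package also ships a two-component Gaussian-mixture threshold on the
mito-ribo ratio for flagging apoptotic droplets, the doublet-spiking
simulation protocol, and a fully synthetic multi-omic generator (RNA + ADT +
VDJ + ground truth), so the entire method is testable offline.

## Worked example

Generate a synthetic three-type PBMC-like dataset, spike 5% doublets, and run
the full pipeline (the generator's gene panel is a few hundred genes, so the
QC gene threshold is scaled accordingly):

```r
library(MLtiplet)

cfg <- synth_config(n_cells = c("B cell" = 600, "T cell" = 1000, "Monocyte" = 400),
                    seed = 42)
sim    <- generate_synthetic(cfg)
spiked <- spike_doublets(clean_base(sim), proportion = 0.05, seed = 43)

res <- run_pipeline(list(
  expr = spiked$expr, adt = spiked$adt, contigs = spiked$contigs,
  marker_sets = sim$marker_sets,
  qc = list(min_genes = 100, min_umi = 1000, max_pct_mito = 25)), seed = 1)
#> [read] 1715 droplets
#> [qc] 1616 droplets
#> [labelled] 1616 droplets
#> [cite_flagged] 58 droplets
#> [vdj_flagged] 59 droplets
#> [features] 1616 droplets
#> [called] 92 droplets

print(res$model)
#> MLtiplet doublet classifier (logistic GLM)
#>   training: 67 positives / 1371 negatives after 2-SD trim
#>   features: mito_ribo_ratio, clr_n_umi, B cell, Monocyte, T cell
#>   cutoff: 0.5  (ridge-stabilised fit)
#>     (Intercept) mito_ribo_ratio       clr_n_umi          B cell        Monocyte
#>         -6.3157         -0.0779         13.7079          1.0266          1.2561
#>          T cell
#>          0.7932

estimate_doublet_proportion(res$calls)
#> [1] 0.0569

score_detection(res$calls, spiked$truth)$table
#>      combination     subtype n_planted n_detected sensitivity
#>  B cell+Monocyte heterotypic        14         14           1
#>    B cell+T cell heterotypic        26         26           1
#>  Monocyte+T cell heterotypic        18         18           1
#>    T cell+T cell   homotypic        20         20           1
```

The identified doublets (58 CITE-flagged and 59 VDJ-flagged, overlapping;
67 positives remain after the 2-SD trim) train the GLM;
the dominant coefficient is on CLR nUMI — doublets carry about twice the RNA
— and the estimated doublet proportion (5.7%) tracks the spiked 5% with no
prior. Every planted combination with more than five doublets, including the
homotypic T+T pairs that transcriptome-only detectors miss, is fully
recovered here, at 99.5% specificity on true singlets.

Real 10x data enter through `read_expression()` (MTX triplet directory or
dense CSV), `read_contigs()` (`filtered_contig_annotations.csv` dialect) and
an `adt_matrix()`; supply your own `labels` (barcode → cell type TSV) to skip
the built-in clusterer, and your own antibody map / exclusive-pair list in
the config to match your panel. A thin CLI wraps the same functions:
`exec/mltiplet run --config cfg.yaml`, `... simulate`, `... score`.

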