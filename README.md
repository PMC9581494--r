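# perturbnet

Case-control network perturbation scoring for disease gene
prioritization.

## What it does

Rare coding variants that drive complex disease are scattered across
many genes, so single-gene burden tests are often underpowered.
perturbnet instead asks, gene by gene, whether the *mutational
perturbation of a gene's protein-interaction neighborhood* differs
between cases and controls.

For each sample, every gene's variants are collapsed into a
perturbation score

    PS = 1 − Π_i (1 − VIS_i)^zyg_i

where `VIS` is a per-variant impact score in [0, 1] (e.g. Evolutionary
Action or PolyPhen2 output, consumed as input) and `zyg` ∈ {0, 1, 2} is
zygosity — the probability that at least one allele disrupts the gene
product. PS values weight the edges of a protein-interaction network
(default weight of edge (x, y): `|PS_x + PS_y|`), weights are averaged
over all cases and over all controls, and the two resulting cohort
graphs are embedded with heat-kernel spectral graph wavelets
(`Ψ = V e^{−sΛ} Vᵀ`) summarized by empirical characteristic functions.
Per-gene signed distances between the paired embeddings, measured on
the first principal component of the jointly stacked embeddings,

    d_g = sign(Δ_g) · sqrt(|Δ_g|),   Δ_g = PC1_case(g) − PC1_ctrl(g)

are standardized to z-scores, tested one-tailed, BH-corrected
(FDR < 0.01 by default), and filtered by a control-versus-control rerun
that removes background hits. The survivors are the candidate genes.

The package also ships a seeded synthetic-cohort simulator with an
implanted, network-local disease module, site-level QC (exact
Hardy-Weinberg test, genotyping-rate filter), gene-set enrichment
utilities (one-tailed hypergeometric with explicit universe,
permutation Z-test), and a robustness benchmark harness
(downsampling, random edge deletion/addition, label shuffling).

Intended users: statistical-genetics and systems-biology researchers
with per-sample annotated variant tables (or a VCF plus an impact map),
a case/control phenotype table, and a PPI edge list.

## Worked example

A fully synthetic study: a 400-gene scale-free network with a 25-gene
disease module whose genes carry a 3-fold variant rate and
high-impact variants in cases only (300 cases, 300 controls).

```r
library(perturbnet)

cfg <- simulation_config(seed = 1)           # the defaults above
net <- simulate_network(cfg)
coh <- simulate_cohort(net$network, net$module, cfg)
fit <- gene_embed(coh$records, coh$phenotypes, net$network, seed = 1)
print(fit)
#> Case-control network perturbation fit
#>   genes embedded:   400
#>   samples:          600
#>   PC1 variance explained:  90.8%
#>   pre-candidates (q < 0.01): 5
#>   candidates:       5
#>   top candidates:   G0004, G0006, G0007, G0003, G0005

head(summary(fit), 3)
#>    gene  distance        z            p           q precandidate candidate
#> 1 G0004 0.8176748 4.424394 4.835671e-06 0.001934268         TRUE      TRUE
#> 2 G0006 0.7808979 4.180837 1.452193e-05 0.002618101         TRUE      TRUE
#> 3 G0007 0.7659777 4.082026 2.232238e-05 0.002618101         TRUE      TRUE

unlist(evaluate_recovery(fit, net$module))
#>    precision       recall   top_recall        auroc n_candidates
#>    1.0000000    0.2000000    0.9600000    0.9998933    5.0000000
```

All five candidates are true module genes (precision 1); ranking by
|distance| places 24 of the 25 module genes in the top 25
(`top_recall` 0.96) with AUROC ≈ 1.0. The candidate list itself is
conservative (recall 0.2 at FDR < 0.01) — the ranking, not the
thresholded list, carries most of the signal. Note the sign of the
distances is a fixed convention with no biological meaning; see the
methods vignette (`vignettes/methods.Rmd`) on choosing the test tail.

Real data enter the same way: `gene_embed("variants.tsv",
"phenotypes.tsv", "string_edges.tsv", vis_column = "ea", qc = TRUE)`.
A thin CLI with `run`, `simulate`, `benchmark` and `enrich` subcommands
is installed at `inst/scripts/perturbnet.R`.

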