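---
title: "Methods: case-control network perturbation scoring"
author: "perturbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control network perturbation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbnet)
```

## The problem and the model

Rare-variant association at the single-gene level is underpowered for
complex diseases: damaging variants are scattered across many genes, and
individually none may reach significance. perturbnet takes a network
view instead. The premise is that disease-relevant genes sit in
protein-interaction neighborhoods whose *aggregate* mutational burden
differs between affected and unaffected individuals, even when no single
gene does. The pipeline quantifies that difference in four stages.

**1. Gene perturbation scores.** For one sample, all coding variants in
a gene are collapsed into a perturbation score

$$ PS = 1 - \prod_i (1 - VIS_i)^{zyg_i}, $$

where $VIS_i \in [0,1]$ is a variant impact score (an externally
computed probability-like damage score such as Evolutionary Action or
PolyPhen2 output — perturbnet consumes these, it does not compute them)
and $zyg_i \in \{0,1,2\}$ is the zygosity. Treating per-allele impacts
as independent damage probabilities, $PS$ is the probability that at
least one allele disrupts the gene product: it is 0 with no qualifying
variants, saturates at 1 as soon as any variant has $VIS = 1$, and a
homozygous variant counts exactly as two heterozygous copies. We
accumulate the product in `log1p` space so hundreds of mild variants
cannot underflow; an exact zero factor short-circuits to $PS = 1$.

**2. Cohort graphs.** $PS$ values are mapped onto an undirected
protein-interaction network (STRING/HINT-style edge lists; source
confidence scores are discarded and the template weight is 1). For one
sample, the weight of edge $(x, y)$ is $|PS_x + PS_y|$ under the default
`sum` scheme; `max` uses $\max(PS_x, PS_y)$, and `threshold` zeroes the
edge ("dead" interaction) when either endpoint exceeds $\tau = 0.7$.
The sum scheme is the default because it lets each interaction of a
multi-interface protein be perturbed independently. Per-sample weights
are then averaged arithmetically across all cases and, separately,
across all controls, giving two cohort graphs that share the identical
edge set and differ only in weights. Edges whose averaged weight is 0
are kept: they contribute nothing to the spectrum but preserve the
shared topology, which the comparability argument below relies on.

**3. Spectral graph wavelet embedding.** Each cohort graph is embedded
with heat-kernel spectral graph wavelets. With Laplacian
$L = D - A = V \Lambda V^T$, the wavelet matrix at diffusion scale $s$
is $\Psi = V e^{-s\Lambda} V^T$; column $a$ is the heat-diffusion
pattern seeded at gene $a$, and entry $\Psi_{ma}$ is the signal $a$
receives from $m$. Each gene's coefficient distribution is summarized
by its empirical characteristic function
$\phi_a(t) = \frac{1}{N}\sum_m e^{i t \Psi_{ma}}$ sampled at $d$ evenly
spaced points, concatenating real and imaginary parts across the grid
and across scales. Because two structurally equivalent nodes — and any
node compared across two graphs with identical topology — have matching
coefficient multisets, their embeddings coincide; this is what makes
case and control embeddings directly comparable, and it is asserted by
test on path, star and barbell graphs.

**4. Gene ranking.** Case and control embeddings are stacked
($2N \times F$), column-centered, and projected onto the first
principal component of the *joint* matrix (so both cohorts share one
basis). The per-gene signed distance is
$d_g = \mathrm{sign}(\Delta_g)\sqrt{|\Delta_g|}$ with
$\Delta_g = p^{case}_g - p^{ctrl}_g$; the square root compresses heavy
tails so the distances form an approximately gaussian distribution.
Distances are standardized (population SD, for determinism), tested
one-tailed against the normal, BH-corrected, and genes with
$q < \alpha$ (default 0.01) become pre-candidates. Finally the whole
pipeline is rerun on the controls alone, split at random into two
pseudo-cohorts: genes significant in that healthy-versus-healthy
comparison are background variation and are removed, leaving the
candidate genes.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `weighting`, `tau` | `"sum"`, 0.7 | edge weight scheme; dead-edge threshold |
| `J`, `eta` | 2, (0.95, 0.80) | number of wavelet scales and the kernel-coverage pair that selects them |
| `d`, `t_max` | 50, 100 | characteristic-function grid: points and range (unitless; $t$ multiplies wavelet coefficients) |
| `distance` | `"pca"` | `"pca"` projects on PC1; `"full"` uses $\sqrt{\lVert\cdot\rVert_2}$ on the raw embeddings |
| `alpha` | 0.01 | FDR threshold for pre-candidates and the control-split filter |
| `tail` | `"upper"` | tail of the one-tailed Z-test (see below) |
| `min_component` | 3 | smallest connected component analyzed |
| `hwe_threshold`, `rate_threshold` | 5e-8, 0.95 | site QC: exact HWE p in controls; genotyping-rate floor per group and combined |

Scales are selected automatically from the case graph's spectrum as
$s(\eta) = -\ln(\eta)/\sqrt{\lambda_2\lambda_N}$, $J$ values evenly
spaced on $[s(\eta_{max}), s(\eta_{min})]$ — the published heuristic of
the underlying structural-embedding algorithm. The control graph is
embedded with the *case* graph's scales so the feature spaces align.
The grid defaults ($d = 50$ on $[0, 100]$, $J = 2$) follow the
reference implementation of that algorithm and are exposed in
`embedding_config()`.

## Numerical choices and degenerate inputs

- **Eigendecomposition is exact and dense** (`eigen(symmetric = TRUE)`),
  chosen for bit-stable, oracle-checkable results at the network sizes
  the package targets (thousands of nodes; the synthetic studies use
  hundreds). No polynomial approximation is implemented.
- **Eigenvector sign ambiguity is harmless by construction**: only
  products $V_{mi}V_{ai}$ enter $\Psi$ (asserted by test).
- **Weighted disconnection.** Keeping zero-weight edges means a
  topologically connected component can decouple *as a weighted graph*
  (common in small pseudo-cohorts, where some genes are never mutated).
  Scale selection therefore uses the smallest **positive** Laplacian
  eigenvalue — identical to $\lambda_2$ whenever the weighted graph is
  connected — and fails only when the whole spectrum is zero. Wavelet
  mass conservation (every column of $\Psi$ sums to 1) holds regardless,
  because the constant vector is always in the Laplacian null space.
- **PC1 sign** is fixed by making the largest-magnitude loading
  positive. This makes signed distances deterministic and antisymmetric
  (swapping case and control labels negates every distance), but the
  orientation carries no biological meaning: on synthetic cohorts the
  implanted module lands in the positive or the negative tail with
  roughly equal frequency across seeds. Consequently the default
  `tail = "upper"` can face away from the signal in any one dataset.
  Recovery metrics in `evaluate_recovery()` use $|d_g|$ and are immune;
  for candidate calling on real data, inspect `plot(fit)` and consider
  `tail = "both"` (at the cost of a factor-2 in p-values) or rerun with
  `tail = "lower"` if the signed distribution is left-skewed.
- **Degenerate distances** (identical case and control inputs, or a
  zero-variance stacked embedding) produce all-zero projections, an
  `NA` variance-explained, a loud warning, and an empty candidate set —
  never an error.
- **Ties in ranking metrics** are mid-ranked (Mann-Whitney AUROC).
- The control-vs-control split is a single seeded random halving,
  recorded in the manifest; with fewer than 4 controls the filter is
  skipped with a warning and candidates equal pre-candidates.

## Site-level QC and the record model

Variant records are gene-level (`sample_id`, `gene`, `vis`,
`zygosity`), which is all the scoring model needs. Site-level QC —
the exact conditional Hardy-Weinberg test (computed on controls only,
sites removed at $p <$ `5e-8`) and the genotyping-rate filter
($< 0.95$ in cases, controls, or combined) — additionally requires a
site identity, so records accept an optional `variant_id`.
`vcf_to_variant_table()` fills it with `chrom:pos:ref:alt`; explicit
homozygous-reference genotypes are kept as zygosity-0 records (inert
for scoring) precisely so that genotyping rate = records/samples is
computable per site. Gene-level tables without `variant_id` cannot be
site-QC'd and `apply_qc_filters()` says so rather than guessing.
Multiallelic VCF records are refused (normalize first, e.g.
`bcftools norm -m-`); per-transcript impact duplicates collapse to the
most damaging score.

## What the synthetic generator emulates — and what it does not

`simulate_network()` + `simulate_cohort()` generate the study the
package validates itself on: a connected random graph (scale-free by
default; stochastic-block and small-world alternatives) with a
ground-truth disease module chosen as a hub plus its neighbors, so the
implanted signal is network-local (pairwise distance $\le 2$ whenever
the hub degree allows — the method's own premise). Per sample and gene,
variant counts are Poisson(0.1); impacts are Beta(1, 4) (most variants
mild); zygosity is homozygous with probability 0.05. In cases only,
module genes get a 3-fold variant rate and Beta(4, 2) impacts. These
defaults define the package's reference conditions: 400 genes, a
25-gene module, 300 cases and 300 controls. The variant rate is far
above the per-gene rate of a real exome; it compensates for the
400-gene scale-down so that per-gene burden is comparable to what a
cohort of thousands of samples accumulates on a 15k-node network.
Setting `rate_multiplier = 1, case_vis_shape = NULL` gives an
exchangeable null cohort.

The generator deliberately omits linkage disequilibrium, allele
frequencies, relatedness, ancestry structure and genotyping error.
Passing tests therefore demonstrate that the *statistical machinery*
recovers a network-local case-only burden shift under its own model;
they say nothing about confounding in real cohorts, which must be
handled upstream (the QC filters here remove only gross site-level
artifacts).

At these reference conditions the test suite checks: mean candidate
fraction $\le 2\%$ over 20 null replicates; ranking AUROC $\ge 0.9$
and top-25 recall $\ge 0.6$ over 5 strong-effect replicates;
non-increasing AUROC (within Monte-Carlo slack 0.05, 3 replicates per
point) as 0/20/40% of edges are deleted; exactly zero candidates when
case inputs are byte-identical to control inputs; and byte-identical
outputs under a fixed seed. `scripts/acceptance.R` recomputes the same
quantities from scratch. These problem sizes keep a full run at a few
seconds while leaving the spectral stage exact.

## Design choices where the design was open

- **Joint PCA, not per-cohort PCA**: projections must share a basis for
  their difference to be meaningful.
- **Population SD in the z-score**: immaterial at genome scale, fixed
  for determinism.
- **Signed square-root distance**: a norm is non-negative, so the sign
  must come from the PC1 difference; $\mathrm{sign}(\Delta)\sqrt{|\Delta|}$
  is the reading that produces the intended two-tailed, gaussian-like
  distribution.
- **`threshold` scheme falls back to the sum weight** below $\tau$,
  making it a strict modification of the default scheme.
- **Components smaller than `min_component = 3`** are excluded: a
  2-node component has a single nontrivial eigenvalue and its wavelet
  carries no neighborhood structure worth ranking.
- **Enrichment universes are always explicit.** Overlap p-values are
  meaningless without the background set, so
  `hypergeometric_overlap()` takes the universe as an argument, clips
  out-of-universe genes loudly, and reports all set sizes. A sensible
  default universe is the intersection of network genes and genes
  observed in the variant input.

## Known limitations

- Dense eigendecomposition is $O(N^3)$: fine to ~5k nodes, slow beyond;
  very large networks (15k+ nodes) need hours, as the full-scale method
  does.
- The embedding compares graphs sharing a node set and topology; it
  cannot compare cohorts genotyped against different networks.
- The one-tailed default can face away from the signal (above); the
  package reports the signed distribution so the user can see this.
- The control-vs-control filter is one random split; a conservative
  user may intersect candidate lists across several seeds or cohorts.

## A worked run

```{r run, eval = FALSE}
cfg <- simulation_config(seed = 1)
net <- simulate_network(cfg)
coh <- simulate_cohort(net$network, net$module, cfg)
fit <- gene_embed(coh$records, coh$phenotypes, net$network, seed = 1)
print(fit)
evaluate_recovery(fit, net$module)
plot(fit)
```
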