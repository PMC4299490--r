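# hemaCCC

Cell–cell communication (CCC) network analysis of the human
hematopoietic system.

The hematopoietic system is a distributed tissue: a dozen phenotypically
distinct cell types, continuously produced by hematopoietic stem cell
(HSC) differentiation, signal to each other through secreted ligands and
their receptors, and those signals feed back onto HSC fate decisions
(quiescence, self-renewal, differentiation, proliferation). hemaCCC is
for computational biologists who want to reconstruct that signaling
network from expression data and interrogate its structure: which cell
types produce which ligands, who can bind them, who outcompetes whom for
shared ligands when cell frequencies are skewed, and which signals can
physically reach the stem cell across tissue compartments.

## What it computes

Starting from a gene-by-sample expression matrix with cell-type labels
and a curated ligand–receptor interaction table:

- **Differential over-expression** — per cell type, one-sided Wilcoxon
  rank-sum tests against every other cell type, Benjamini–Hochberg
  adjusted per comparison; a gene is called when it wins at least
  `minWins` (default 6) of the pairwise contrasts at the FDR threshold.
  The threshold itself can be selected by ROC against a benchmark of
  known cell-type-associated receptors (Youden's J, ties to the smaller
  FDR).
- **The bipartite CCC network** — binary production matrix
  `A[i, j]` (cell *i* over-expresses ligand *j*) and binding matrix
  `B[j, i]` counting receptor species; an edge B → A via ligand *x*
  exists when B produces *x* and A expresses a receptor for it. Orphan
  signals route through an aggregate "Others" node; hetero-multimeric
  receptor complexes can be collapsed to all-subunits-required counting.
- **Structure** — Jaccard/Ward clustering of the production network with
  silhouette-selected module number; Dhillon bipartite spectral
  co-clustering of the binding network; a two-sample t-test contrasting
  inter-module ligand sharing between the two sides.
- **Competition** — the potential of apparent competition,
  `P[i, j] = Σ_k (w[i,k]/Σ_m w[i,m]) · (w[j,k]/Σ_l w[l,k])` with
  `w[i,k] = f_i · R[i,k]` (cell frequency × receptor count): a
  row-stochastic matrix of who dominates whose ligand portfolio under a
  given cell-frequency scenario.
- **Compartmentalization** — an OR-gate Monte-Carlo model: each
  compartment (stem cell, progenitors, niche-resident mature cells,
  peripheral mature cells) holds its over-expressed ligands and a reach
  probability (defaults 1, 0.8, 0.7, 0.1); per-ligand Bernoulli draws,
  union across compartments, enrichment `E = n(M ∧ B)/n(B)` per
  biological-process ligand set, averaged over 500 simulations.
- **Ligand effects** — linear mixed models (`log(count+1)`, experiment
  as random intercept) turn in vitro culture counts into signed one-tail
  p-values over three output populations; a 17-row decision table maps
  the arrow triple to a functional category; binomial prediction-capacity
  tests, hypergeometric enrichment Z-scores (enriched at Z > 1.15) and
  weighted cell → category → stem-cell feedback networks follow.
- **Synthetic data** — a generator that plants module-exclusive ligand
  production, configurably promiscuous binding, and category-true
  culture counts, so every stage is benchmarked against known truth.

## Worked example

```r
library(hemaCCC)

design <- syntheticDesign(seed = 7)      # 12 cell types, 4 planted modules
expr   <- generateExpression(design)
lr     <- generateLRTable(design)

calls <- callOverexpressed(expr, lr, fdr = 0.1, minWins = 6)
net   <- buildNetwork(calls, lr)
net
#> CCCNetwork: 13 cell nodes, 44 ligand nodes
#>   production edges: 124  binding edges: 423  cell-to-cell relationships: 1169

part <- clusterProduction(productionNetwork(net, producingOnly = TRUE))
part
#> ModulePartition: k = 4  mean silhouette = 0.846
#>   module 1 : HSCe MLP CMP MEP GMP
#>   module 2 : Neut Mono
#>   module 3 : EryB Others
#>   module 4 : Baso Eos Mega PreB
```

The network has 13 cell nodes (12 modeled types plus "Others") and the
silhouette criterion selects exactly the four planted production
modules: the primitive stem/progenitor block, neutrophils+monocytes,
the erythroid module (joined by "Others", which also produces a broad
orphan portfolio here), and the remaining mature cells. Binding, by
contrast, is promiscuous — the degree ranking shows almost every cell
binding almost every ligand:

```r
head(rankCellsByDegree(net, sortBy = "bound"), 4)
#>   cell n_produced_ligands n_bound_ligands
#> 1  MLP                 10              40
#> 2  MEP                 10              40
#> 3  GMP                 10              40
#> 4 HSCe                 10              39
```

Screening statistics work directly on printed numbers:

```r
unlist(predictionCapacityTest(33, 27, 0.5))
#>        point         tail     expected
#> 1.289379e-04 1.620317e-04 1.650000e+01
# 27 effective ligands of 33 tested: point probability prints as 0.0001

overlapTTest(c(9, 13, 10, 12, 12, 17), c(75, 75, 69))$p
#> [1] 5.08844e-05          # production vs binding ligand sharing, p < 0.001

classifyLigand(c(0.0036, 0.30, 0.50), alpha = 0.02)
#> [1] "self_renewal_induction"
# an increase confined to the stem-cell-enriched population
```

`runPipeline(list(outDir = "run1", seed = 1))` executes all stages on
freshly generated synthetic inputs and writes every intermediate table
plus a provenance manifest into `run1/`.

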