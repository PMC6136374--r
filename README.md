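# abacross

Crosstalk analysis between **ABA-dependent** and **ABA-independent**
drought-responsive gene networks.

Plants integrate drought signals through two routes: one mediated by the
stress hormone abscisic acid (ABA) and one independent of it. `abacross` is
for researchers who have (i) per-gene expression contrasts — log2 fold change
and p-value for drought (two time points), rewatering, and ABA treatment,
each versus control — and (ii) a genome-scale protein–protein interaction
(PPI) network with edge confidences, and who want to know whether and where
the two drought-response pathways talk to each other at the protein level.

## What it computes

1. **DEG classification.** A gene is a DEG in a contrast when its fold
   change is ≥ 2 (|log2FC| ≥ 1) and p < 0.05. Drought-responsive genes
   (DEG at day 10 *or* 12) whose expression recovers after rewatering are
   split into `ABA_DEPENDENT` (also a DEG under ABA) and `ABA_INDEPENDENT`
   (not); non-recovering genes are set aside as `NOT_RECOVERED`.
2. **Degree-preserving null model.** An ensemble of R = 1000 randomized
   networks built by double-edge swaps, preserving every node's degree.
3. **Crosstalk enrichment.** For each gene, the count of its interactions
   with the opposite set, with an empirical p-value

       p = #(null counts ≥ observed) / R

   (ties count toward the null). Genes with p < 0.05 are the *core
   interacting components*. Globally, with N the observed A–B interaction
   count and μ, SD the ensemble mean and standard deviation,

       Z = (N − μ) / SD,

   plus a Welch t comparison of DEG-pair Z-scores against size-matched
   non-DEG set pairs, and co-expression link enrichment among the top 1%
   most-correlated gene pairs.
4. **Core subnetwork export** as SIF and GraphML for Cytoscape, with set
   membership, empirical p, edge confidence and verification flags.

A synthetic-data module (configuration-model networks with planted cross-set
enrichment, contrast tables with known classes, latent-factor expression
matrices) makes the whole pipeline testable against ground truth.

## Worked example

```r
library(abacross)

# a synthetic study with five-fold planted cross-set enrichment
st <- simulate_study(n_nodes = 1000, mean_degree = 30, size_A = 40,
                     size_B = 120, enrichment_factor = 5,
                     n_core_A = 8, n_core_B = 12, n_samples = 0, seed = 42)

cls <- classify_degs(st$contrast_table)
table(cls$class)
#>   ABA_DEPENDENT ABA_INDEPENDENT   NOT_RECOVERED         NON_DEG
#>              40             120              40             800

A <- cls$gene_id[cls$class == "ABA_DEPENDENT"]
B <- cls$gene_id[cls$class == "ABA_INDEPENDENT"]
ens <- build_ensemble(st$network, R = 500, seed = 43)
global_enrichment(st$network, ens, A, B)
#> Global cross-set interaction enrichment
#>   observed: 1147  null mean: 310.98  null sd: 14.654
#>   Z-score: 57.051  (R = 500)

rec <- per_gene_enrichment(st$network, ens, A, B)
head(rec[order(rec$empirical_p),
         c("gene_id", "set", "degree", "observed_cross", "null_mean", "empirical_p")], 3)
#>    gene_id set degree observed_cross null_mean empirical_p
#> 1 SYN00007   A     51             27     7.208           0
#> 2 SYN00022   A     53             24     7.366           0
#> 3 SYN00044   A     27             14     3.880           0
```

The observed 1147 cross-set interactions are ~57 null standard deviations
above the randomized-network expectation of ~311 — the planted five-fold
enrichment plus the extra core-gene edges. `SYN00007` touches 27
ABA-independent partners where the null expects ~7, so its empirical p is
below the 1/500 resolution floor: a core interacting component. In this run
all 20 planted core genes are recovered at α = 0.05.

`run_pipeline(demo_config("out"))` runs the same analysis end-to-end and
writes class tables, enrichment tables, the core subnetwork (SIF + GraphML),
a run log and a checksum manifest into `out/`.

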