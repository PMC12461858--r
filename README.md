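# dnbtrace

Dynamic network biomarkers (DNBs) are small gene groups whose *network
context* — correlations with each other and with the rest of the
regulatory network — becomes disordered just before a critical disease
transition, often before mean-expression differences are visible. For
diseases that progress through ordered pathological stages (staged bulk
expression cohorts: normal, pre-malignant stages, tumor grades), DNBs are
candidate early-warning markers of the reversible pre-disease state.

`dnbtrace` finds DNBs from a staged expression matrix plus a prior
gene-interaction network, for computational biologists working with staged
cohort data. The pipeline:

1. **Stage-specific regulatory networks** — ANOVA screen across stages
   (BH-adjusted), candidate genes (screen ∪ known disease genes) mapped
   onto the prior network, per-stage edge pruning by Gaussian mutual
   information `MI = -½·log(1-r²)` (optionally first-order
   path-consistency conditioning, removing edges with
   `min_z CMI(i,j|z) ≤ τ`), and signed Pearson edge weights.
2. **Graph-convolutional embedding** — per stage,
   `H⁽ˡ⁺¹⁾ = σ(A H⁽ˡ⁾ W⁽ˡ⁾)` with `A = D̃^(-1/2) Ã D̃^(-1/2)` (self-looped,
   |weight|-valued), trained by Adam against a fixed seeded random target
   embedding `E` (MSE over an 8:2 node split); `E` is shared across stages
   so per-gene vectors are comparable.
3. **Anomaly scoring** — k-means clusters at stage *t* (k by the elbow of
   the within-cluster sum of squares), cluster representatives
   `v_cj = argmin‖h_i − c_j‖`, and per-gene outlier score at stage *t+1*:
   `min_j ‖h_i(t+1) − h_cj(t+1)‖`. Top `⌈q·N⌉` genes per scored stage
   (union over stages 2..T) form the anomaly set.
4. **Core extraction** — greedy minimum dominating set of the
   anomaly-induced subgraph of the union network, reconnected by shortest
   hop-count paths (interior genes become connectors): a connected DNB
   core.
5. **Evaluation** — the dynamic network index
   `DNI = exp(−CE)`, `CE = −(g/D(G₀))·log₂(D(α)/D(G₀))` (boundary |weight|
   mass `g`, module/union degree sums), whose per-stage maximum flags the
   putative pre-disease stage; and temporal classification: all `T−1`
   ordered splits (stages ≤ s vs > s) scored by a class-weighted linear
   SVM under stratified cross-validation (AUROC/AUPRC/accuracy/F1/
   precision/recall, mean ± SD).

A seeded synthetic benchmark (`generate_synthetic()`) plants one rewiring
module inside pathway-structured expression coupled to a decoy-laden prior
network, so the whole pipeline is testable offline.

## Worked example

```r
library(dnbtrace)

sim <- generate_synthetic(synthetic_config(seed = 1))   # 300 genes, 6 stages,
                                                        # 12-gene module rewired at stage 3
run <- dnb_run(sim$expr, sim$prior, benchmark_config(seed = 1),
               prior_disease = sim$truth$partner_genes)
run
#> == dnbtrace run ==
#> <dnb_result> 2 genes (2 dominators, 0 connectors), 1 edges, connected
#> DNI peak at stage 5
#> <dnb_classification> 2 features, 5 split(s): mean AUROC 0.756 +/- 0.041

recovery_score(run$anomalies$genes, sim$truth)
#> # A tibble: 1 × 6
#>   precision recall    f1 n_predicted n_true empty_prediction
#>       <dbl>  <dbl> <dbl>       <int>  <int> <lgl>
#> 1     0.615  0.667  0.64          13     12 FALSE

tidy(run$dni)
#> # A tibble: 6 × 6
#>   stage g_alpha d_alpha d_union     ce   dni
#>   <int>   <dbl>   <dbl>   <dbl>  <dbl> <dbl>
#> 1     1   17.9       28     396 0.173  0.841
#> 2     2   14.2       23     396 0.147  0.863
#> 3     3    9.42      15     396 0.112  0.894
#> 4     4    5.66      11     396 0.0739 0.929
#> 5     5    4.19       7     396 0.0616 0.940
#> 6     6    8.39      15     396 0.100  0.905
```

Reading the output: the anomaly set (13 genes) recovers the planted
12-gene module at F1 0.64; the dominating-set step then compresses the
densely interconnected module to a 2-gene core. The DNI curve rises after
the planted transition (stage 3) — the module's boundary coupling `g`
collapses from ~18 to ~4–9 — and stays high through the persistently
rewired stages, so the curve localizes the transition only up to "at or
before the peak" (see the methods vignette on why persistent rewiring
blurs the peak). Temporal classification of the 2-gene core separates the
ordered stage splits with mean AUROC 0.756.

`autoplot()` methods draw the DNI curve, per-stage outlier scores and the
per-split classification metrics; `tidy()`/`glance()` give tabular views
of every result type.

### Command line

```sh
exec/dnbtrace run-all  --config run.yaml --seed 1 --out out/
exec/dnbtrace simulate --seed 1 --out out/      # synthetic inputs only
exec/dnbtrace build-nets|embed|score|extract|evaluate --config run.yaml --out out/
```

Subcommands read and write plain-text artifacts (TSV networks and
embeddings, JSON reports) in `--out`, are idempotent, and compose to
exactly the `run-all` result.

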