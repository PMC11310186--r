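# psgnn — patient similarity graph neural networks for EHR outcome prediction

`psgnn` predicts binary clinical outcomes (ICU mortality, readmission) from
encounter-level electronic health record features by learning on a **patient
similarity graph**. It is aimed at clinical-informatics researchers who want
a fully reproducible, inspectable implementation of clique-weighted graph
learning with stochastic edge perturbation — runnable end to end on
synthetic EHR-like cohorts, with no access to credentialed clinical
databases required.

## The method

Given an encounter feature matrix $X \in \mathbb{R}^{N\times F}$ (sparse
binary diagnosis/treatment indicators plus numeric features) and labels
$y \in \{0,1\}^N$:

1. **Similarity graph.** Encounters $i, j$ are joined by an edge iff
   $k(\vec x_i,\vec x_j) = \frac{\vec x_i\cdot\vec x_j}{\lVert\vec x_i\rVert\lVert\vec x_j\rVert} > 0.85$
   (strict threshold).
2. **Clique weighting.** All maximal cliques are enumerated by
   Bron–Kerbosch with pivoting; edge $(i,j)$ gets weight $A_{ij} = c$ when
   its endpoints co-occur in a maximal $(c{+}1)$-clique (maximum over
   memberships), so cohesive patient groups dominate aggregation.
3. **Encoder.** Two mean-pooling layers
   $\mathrm{MP}(H,A)=\mathrm{ReLU}(\hat D^{-1}\hat A H\Theta)$ with
   $\hat A = A+I$, each yielding 16-dimensional embeddings, plus a
   linear–sigmoid head; trained with binary cross-entropy.
4. **Edge Flux.** Each epoch the graph is redrawn from the pristine
   adjacency: absent pairs appear with probability $p_{\mathrm{add}}$,
   existing edges vanish with probability $p_{\mathrm{delete}}$ — a
   structural regulariser for data-scarce regimes.
5. **Evaluation.** Adam (lr 0.001, batch 128, 250 epochs),
   best-validation-AUPRC checkpointing, test AUPRC as mean ± std over 5
   repeated random splits; split regimes from 70/15/15 down to 20/40/40;
   ablations without Edge Flux and without clique weighting.

A synthetic cohort generator (`generate_cohort()`) emulates the statistical
shape of large ICU cohorts — ~16 active codes per visit, 7–17% positives,
latent high-similarity patient clusters, missing values repaired by
mean/mode imputation — so every stage is testable offline. See the methods
vignette (`vignettes/psgnn-methods.Rmd`) for the full model description and
design rationale.

## Worked example

```r
library(psgnn)

spec <- cohort_spec(n_encounters = 300, n_clusters = 10, positive_rate = 0.15,
                    cluster_outcome_strength = 0.9, seed = 42)
cohort <- impute_cohort(generate_cohort(spec))
cohort
#> <encounter_matrix> 300 encounters x 204 features (200 categorical, 4 numeric)
#>   positives: 47 (15.7%); missing cells: 0

graph <- build_graph(cohort, threshold = 0.85)
cliques <- enumerate_maximal_cliques(graph)
cliques
#> <clique_set> 245 maximal cliques (sizes 1..19)

graph <- assign_clique_weights(graph, cliques)
graph
#> <patient_graph> 300 nodes, 1820 undirected edges (cosine threshold 0.85); edge weights in [1, 18]

cfg <- train_config(epochs = 100, n_repeats = 5, seed = 42)
result <- run_experiment(cohort, cfg, graph = graph)
result
#> <run_result> full, split 70/15/15, 5 repeats
#>   test AUPRC 0.7534 +/- 0.1916  (per repeat: 0.8329, 1.0000, 0.8163, 0.5620, 0.5556)
```

Reading the output: the generator produced a 300-encounter cohort whose 10
latent clusters induce 1820 supra-threshold edges; the largest maximal
clique has 19 members, so its internal edges carry weight 18. With 90% of
labels following their cluster's dominant outcome, the trained model ranks
held-out encounters well above the 0.157 no-skill AUPRC baseline
(prevalence), averaging 0.75 over five independent splits — with visible
spread across repeats, as expected for 45-node test sets at this class
imbalance.

A command-line front end with subcommands `generate`, `build-graph`,
`cliques`, `train`, and `ablation` is installed at `inst/cli/psgnn`
(`Rscript inst/cli/psgnn train --cohort cohort.csv --outdir run/ ...`).

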