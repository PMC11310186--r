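---
title: "Methods: clique-weighted patient similarity graphs for EHR outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clique-weighted patient similarity graphs for EHR outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psgnn)
```

## The problem

Electronic health records describe each hospital or ICU encounter as a sparse
bag of coded diagnoses and treatments plus a handful of numeric measurements.
Outcomes of interest — in-hospital mortality, readmission — are binary and
heavily imbalanced (typically 7–17% positives). No relational structure
between encounters is recorded, yet clinically similar patients carry
information about each other, especially when labelled data are scarce. The
approach implemented here builds that structure explicitly: a patient
similarity graph over encounters, sharpened by maximal-clique edge weighting,
on which a small graph neural network performs semi-supervised node
classification.

## The model

**Graph construction.** Encounters $i$ and $j$ are connected iff the cosine
similarity of their feature vectors strictly exceeds a threshold,

$$k(\vec x_i, \vec x_j) = \frac{\vec x_i \cdot \vec x_j}{\lVert \vec x_i\rVert\,\lVert \vec x_j\rVert} > 0.85 .$$

The cut is strict: a similarity exactly at the threshold produces no edge.
Cosine similarity is symmetric, so the graph is undirected, and we store it
symmetrically. Zero-norm feature rows are rejected rather than silently
isolated — in practice they indicate failed imputation upstream.

**Clique weighting.** All maximal cliques of the thresholded graph are
enumerated with the Bron–Kerbosch recursion, implemented with pivoting
(pivot = the candidate with the most remaining candidates as neighbours, ties
to the lowest index). Pivoting matters: similarity graphs contain
near-complete clusters on which the unpivoted recursion explodes. Each edge
$(i,j)$ then receives weight $c$ when the largest maximal clique containing
both endpoints has $c+1$ members, so $A_{ij}=c$ records "these two encounters
sit together in a $(c{+}1)$-clique". An edge can lie in several maximal
cliques; we take the **maximum** clique size by default because it rewards
the strongest community containment and keeps weights bounded by the clique
number. `sum` and `count` aggregators are available for comparison. Weighting
never changes the edge set — every edge lies in some maximal clique of size
at least 2 — and re-running it is idempotent.

**Encoder.** Two mean-pooling layers

$$\mathrm{MP}(H, A) = \mathrm{ReLU}\!\left(\hat D^{-1} \hat A\, H\, \Theta\right),
\qquad \hat A = A + I,\ \hat D_{ii} = \textstyle\sum_j \hat A_{ij},$$

each producing 16-dimensional features. Every row of $\hat D^{-1}\hat A$ is a
convex combination over the node's closed neighbourhood, so clique weights
act directly as aggregation weights: a heavier edge pulls the node's
representation toward that neighbour. Self-loops enter with weight 1 — clique
weights do not apply to them. A single linear layer plus sigmoid on the
rectified 16-dimensional embedding produces the outcome score; this minimal
head matches the node-classification framing. Scores are clamped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-7}$ before any
logarithm. Training minimises the standard binary cross-entropy

$$\mathcal L = -\frac1N \sum_i \left( y_i \log \hat y_i + (1-y_i)\log(1-\hat y_i) \right)$$

with $y$ the ground truth and $\hat y$ the score. Parameters are initialised
with seeded uniform Glorot draws (limit $\sqrt{6/(\mathrm{fan_{in}}+\mathrm{fan_{out}})}$).

**Edge Flux.** Once per training epoch, the adjacency is redrawn: each absent
unordered pair gains an edge (weight 1) with probability $p_{\mathrm{add}}$,
each present edge is deleted with probability $p_{\mathrm{delete}}$, anything
else is unchanged and keeps its clique weight. The perturbation is sampled
per unordered pair and mirrored, keeping the adjacency symmetric. Two
deliberate choices:

* Flux is always applied to the **pristine** clique-weighted graph, never to
  the previous epoch's perturbed graph. Compounding would drift the edge
  density toward the $p_{\mathrm{add}}/(p_{\mathrm{add}}+p_{\mathrm{delete}})$
  fixed point instead of hovering near the observed graph.
* Cliques are **not** re-enumerated for perturbed graphs: enumeration cost
  would dominate training, and added edges are transient noise, not evidence
  of community structure. Added edges therefore carry weight 1.

On large sparse graphs the additions are sampled by drawing a
$\mathrm{Binomial}(M-|E|, p_{\mathrm{add}})$ count and then that many uniform
absent pairs — distributionally equivalent to per-pair Bernoulli draws
without an $O(N^2)$ scan.

**Training loop.** Adam (learning rate 0.001, default moment constants, no
weight decay), 250 epochs, mini-batches of 128 *training* nodes. Batch
semantics for a full-graph model: each forward pass uses the whole graph;
a mini-batch only restricts which labelled nodes contribute to the loss and
gradients. Per epoch the validation AUPRC is computed and the best-validation
checkpoint retained. Evaluation — validation during training and the final
test measurement — always uses the pristine graph: Edge Flux is a train-time
regulariser, switched off at evaluation exactly as dropout would be.
Evaluation is transductive: test nodes participate in message passing through
their features, but their labels never touch training or model selection.

**Metric.** AUPRC in the average-precision formulation: thresholds sweep the
distinct scores descending (ties grouped), and the area is the sum of
precision-weighted recall increments. For constant scores it equals the
positive prevalence — the no-skill baseline — which makes it the right metric
for imbalanced outcomes.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.85 | cosine cut-off for an edge (strict) |
| `aggregator` | `"max"` | how an edge combines multiple clique memberships |
| `p_add` | 0.01 | per-pair probability of adding an absent edge, per epoch |
| `p_delete` | 0.05 | per-edge probability of deleting an edge, per epoch |
| `learning_rate` | 0.001 | Adam step size |
| `batch_size` | 128 | training nodes per gradient step |
| `epochs` | 250 | training epochs (= flux redraws) |
| `hidden_dim` | 16 | embedding width of both MP layers |
| `split_fractions` | 0.70/0.15/0.15 | train/val/test; `split_regimes()` lists the four standard regimes down to 20/40/40 |
| `n_repeats` | 5 | independent (split, init, flux) repetitions |

`p_add` and `p_delete` have no canonical published values; the defaults keep
the expected perturbation a small fraction of the edge set on sparse graphs
(for $|E| \ll M$, roughly $5\%$ of edges dropped and a comparable number of
noise edges added per epoch).

## Randomness discipline

A single master seed spawns named sub-streams — splits, parameter
initialisation, Edge Flux, mini-batch order — via a deterministic hash, and
every draw runs under a locally-set RNG state that is restored afterwards.
Consequences worth knowing:

* any run repeated with the same master seed is bit-for-bit identical;
* ablations differ *only* in their intended component: the no-Edge-Flux
  variant consumes exactly the same split/init/batch randomness as the full
  model, so with $p_{\mathrm{add}}=p_{\mathrm{delete}}=0$ the two are
  bit-identical;
* the flux stream is indexed by epoch, so epoch $e$'s perturbation does not
  depend on how many random numbers earlier epochs consumed.

## The synthetic cohort generator

Real ICU datasets are credentialed; the generator produces cohorts with their
statistical shape so the whole pipeline is testable. Each of `n_clusters`
latent patient groups owns `codes_per_cluster = 16` active codes drawn
without replacement from a 200-code vocabulary — matching the observed
11.5 diagnoses + 4.5 treatments per visit in large ICU cohorts, and
guaranteeing low cosine overlap between distinct clusters so the 0.85
threshold separates them. An encounter copies its cluster's code profile and
flips `n_noise_flips = 2` random bits. Numeric features are generated on a
standardised scale with modest cluster shifts (means $\sim N(0, 0.5)$, noise
sd 0.3) so that, as in real EHR feature construction, the binary code profile
dominates similarity. Labels follow the cluster's dominant label with
probability `cluster_outcome_strength`, else an independent
Bernoulli(`positive_rate`) draw; which clusters carry a positive dominant
label is chosen by an exact subset-sum optimisation over cluster sizes so the
positive mass tracks `positive_rate` as closely as cluster granularity
allows. Missing values are inserted per cell at `missing_rate` using `NA` —
an explicit not-a-value marker that cannot collide with a legitimate code —
and repaired by `impute_cohort()`: observed mean for numeric features,
observed mode for categorical ones (binary code indicators are categorical;
ties break to the smallest value).

What the generator does **not** emulate: longitudinal visit sequences (the
model deliberately ignores the time-series aspect of EHRs), realistic
marginal code frequencies, admission-duration filtering (that operates on raw
timestamps the package never sees), and patient-to-encounter multiplicity —
splits are by encounter, and with `cluster_outcome_strength = 1` every
cluster is label-pure, which is far cleaner than any real cohort. Passing
tests on these cohorts therefore demonstrate the *mechanics* (graph, cliques,
flux, optimisation, evaluation) and the pipeline's capacity to recover known
structure, not clinical-grade performance.

## Numerical and degenerate-input choices

* Similarity is computed blockwise on row-normalised features; the dense
  $N\times N$ similarity matrix is never materialised, and only
  supra-threshold pairs are stored.
* Similarity is computed on imputed, unstandardised features;
  `build_graph(standardise = TRUE)` z-scores columns first for cohorts whose
  numeric features would otherwise dominate.
* An edgeless graph is legal everywhere: every node is its own singleton
  maximal clique, weighting is a no-op, and the encoder degenerates to a
  per-node two-layer ReLU network.
* Clique output is normalised (each clique sorted, cliques ordered
  lexicographically) so enumeration order is reproducible.
* A clique set is bound to its graph by a content digest; weighting with a
  stale clique set is an error, not a silent mismatch.
* Single-class label vectors are rejected up front: AUPRC (and model
  selection on it) is undefined without both classes.
* Training aborts with a diagnostic (epoch, batch, learning rate) on a
  non-finite loss or parameter.
* Permutation equivariance of the encoder holds to working precision
  ($<10^{-12}$); exact bitwise equality is not guaranteed because sparse
  products sum in column order, which relabelling permutes.

## Problem sizes in the shipped checks

The test suite and the acceptance script run at deliberately modest sizes
chosen to exercise every code path with comfortable margins: clique
enumeration is cross-checked against exhaustive subset search on graphs of up
to 12 nodes; Edge Flux statistics use a 50-node graph and 1000–2000 draws;
learnability uses a 500-encounter separable cohort (cluster-determined
labels, 15% positives) trained for the full 250 epochs over 5 repeats, where
held-out AUPRC is expected above 0.9; the ablation and split-regime sweeps
use 300–500 encounters. These sizes are the package's own test design; the
implementation itself handles cohorts orders of magnitude larger (the graph
construction is blockwise and the adjacency sparse).

## Known limitations

* **Transductive only.** Evaluation nodes are present in the graph during
  training (their labels are not). An inductive mode — building the graph on
  training encounters only and attaching test encounters at evaluation — is
  future work.
* **Encounter-level splits.** Without a patient-to-encounter mapping, the
  guarantee that no patient spans train and test is honoured at encounter
  level only.
* **Static graph per cohort.** Cliques are enumerated once; neither feature
  drift nor flux perturbations trigger re-enumeration.
* **No baselines.** Random-forest/MLP/attention-GNN comparisons and
  hyper-parameter search are out of scope; the ablations (no Edge Flux, no
  clique weighting) are the only built-in comparisons.
* **Binary codes only.** Code features are 0/1 indicators; count-valued
  codes would need a different generator and possibly a different similarity
  kernel.
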