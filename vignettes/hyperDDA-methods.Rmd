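---
title: "Predicting drug-disease associations with hypergraph convolution and enhanced message passing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-disease associations with hypergraph convolution and enhanced message passing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperDDA)
```

## The problem

Drug repositioning asks which approved drugs might treat diseases they were
never indicated for. Framed computationally: given a sparse binary matrix
$A \in \{0,1\}^{M \times N}$ of known drug-disease associations, several
drug-drug similarity matrices $P^r_1, \dots, P^r_S$ (chemical structure,
targets, side effects, ... — each a different *view* of drug relatedness), a
disease-disease semantic similarity $S^d$, and optionally a drug-protein /
disease-protein / protein-protein association layer, score every unobserved
pair $(i, j)$ with the probability that drug $i$ is therapeutically linked to
disease $j$. The scores are used to rank candidates for a disease (or
indications for a drug), so ranking metrics — AUROC and, under heavy class
imbalance, AUPR — are the quantities of interest.

hyperDDA implements a two-layer graph neural model for this task, a
synthetic-network generator with planted structure so that every stage can be
tested end to end without external databases, and the two evaluation
protocols used in this literature (pair-level k-fold cross-validation and
cold-start disease holdout).

## The model

### Intra-domain branch: hypergraph convolution with channel attention

Each similarity view is converted to a K-nearest-neighbour **hypergraph**:
vertex $v$ spawns one hyperedge containing $v$ and its $K$ most similar other
vertices, so the incidence matrix $H$ is square and every hyperedge has
degree $K + 1$. Ties are broken by (similarity descending, index ascending),
which makes construction deterministic and permutation-equivariant. A
hypergraph captures groups of mutually similar drugs as single hyperedges,
rather than only pairwise links.

One convolution layer is
$$X^{l+1} = \sigma\!\left(D_v^{-1/2} H D_e^{-1} H^T D_v^{-1/2}\, X^l\, \theta^l\right),$$
the two-step vertex-to-hyperedge-to-vertex aggregation with symmetric degree
normalization. The operator is symmetric, has spectrum in $[-1, 1]$ and fixes
$D_v^{1/2}\mathbf{1}$ exactly — properties the test suite asserts. It is
precomputed once per view (it does not change during training). Hyperedge
weights are the identity; the model does not learn them.

The $S$ per-view outputs form an $M \times F \times S$ channel stack, fused
by **efficient channel attention**: global average pooling gives one scalar
per channel, a single shared 1D convolution (kernel length 3, zero
same-padding) mixes neighbouring channel descriptors, and a logistic squash
gives weights $\omega_s \in (0, 1)$; the fused embedding is
$\sum_s \omega_s X_s$. The weights are *not* renormalized to sum to one. With
a single view ($S = 1$) the block is bypassed entirely — a logistic weight on
the only channel would merely rescale the embedding without selecting among
views. The disease branch is a plain hypergraph convolution of $S^d$'s KNN
hypergraph.

Both branches are seeded with incidence matrices as initial features:
$X_r^0 = H^r_{1}$ (the configured view's incidence, `initialViewIndex`) and
$X_d^0 = H^d$.

### Inter-domain branch: edge-aware bipartite convolution

Known associations propagate embeddings across domains. First the edges are
mapped into the node domain: drug $i$ receives $(\sum_j A_{ij}) \cdot w^r$
with a learnable vector $w^r$ (and symmetrically for diseases) — a
degree-scaled edge embedding. The propagation layer is
$$X^{inter,l+1}_{r,i} = \sigma\Big(\sum_{j \in N_i}
  \tfrac{1}{\sqrt{|N_i||N_j|}}\, (X^l_{d,j} \odot X^{edge}_{d,j})\, W^l_{d \to r}\Big),$$
i.e. neighbour embeddings gated elementwise by the edge embedding, with the
symmetric GCN normalization and a cross-domain projection. With unit edge
features and identity projections this reduces exactly to bipartite graph
convolution (a tested identity). Nodes with no associations receive zero
here; the layer fusion compensates through the intra-domain term.

### Protein branch: attention-based heterogeneous propagation

When drug-protein, disease-protein and PPI data are present, a third
contribution flows through proteins. All stages use single-head **graph
attention**: for destination $u$ with source neighbours $N_u$,
$$\alpha_{uv} = \operatorname{softmax}_{v \in N_u}
  \rho\!\left(a^{T} [W_u x_u \,\|\, W_v x_v]\right), \qquad
  x'_u = \sigma\Big(\sum_{v} \alpha_{uv} W_v x_v\Big),$$
with leaky slope 0.2. Per layer: drugs and diseases are projected onto
proteins; the two protein images are concatenated and linearly combined back
to width $k$ (proteins linked on only one side simply contribute via that
side); one further attention pass over the PPI network smooths protein
embeddings; and the smoothed embeddings are projected back to drugs and to
diseases. Proteins have no natural input feature, so layer 1 seeds them with
their binary association profile $[A_{rp}^T \,|\, A_{dp}^T]$ — the bipartite
analogue of the incidence-matrix inputs used for drugs and diseases. A
config flag (`unsmoothedDrugProjection`) routes the *unsmoothed* combined
embedding to the drug side instead, an asymmetric variant kept for
sensitivity analysis; the default treats both sides symmetrically.

### Fusion, skip connection, scoring, loss

Per layer $l \in \{1, 2\}$ (widths `k1`, `k2`):
$X^l = X^{intra,l} + X^{inter,l} + X^{p,l}$ (protein term zero when the
branch is off). The final embedding adds a skip connection
$\hat X = X^1 W_{skip} + X^2$, where $W_{skip}$ is a learnable bias-free
$k_1 \to k_2$ projection — a literal sum is dimensionally impossible when
$k_1 \ne k_2$, and `equalWidths = TRUE` restores it when $k_1 = k_2$. Scores
are $\hat A = \operatorname{logistic}(\hat X_r \hat X_d^T)$.

Training minimizes the class-balanced cross-entropy over **all** usable
pairs (no negative sampling),
$$\mathcal{L} = -\tfrac{1}{MN}\Big(\lambda \sum_{(i,j) \in y} \log \hat A_{ij}
  + \sum_{(i,j) \in \bar y} \log (1 - \hat A_{ij})\Big), \qquad
  \lambda = |\bar y| / |y|,$$
with Adam. Probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ inside the
logarithms; reported scores are unclamped. On a $2 \times 2$ matrix with one
positive and constant scores $1/2$ the loss is exactly
$\tfrac{3}{2}\log 2$ — an analytic fixed point the tests assert.

### Differentiation

No deep-learning framework is available to (or required by) the package:
training runs on a small reverse-mode automatic-differentiation tape
(`R/autodiff.R`) covering exactly the operations the model needs (dense
products, activations, gather/segment-softmax over edge lists, the channel
pooling/convolution/fusion chain, and the loss on logits). Its correctness
is established two ways: every forward stage must match the plain-matrix
module functions (`hgcnLayer`, `attentionFuse`, `neegcnPass`,
`gatProject`, `proteinMessageRound`), which are themselves tested against
scalar-loop oracles; and the end-to-end gradient must match central finite
differences to a relative error below $10^{-4}$ on a small network.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k1`, `k2` | 256, 128 | hidden widths of the two layers |
| `lr` | 0.002 | Adam learning rate |
| `beta` | 0.4 | feature dropout on the fused embeddings (training only) |
| `gamma` | 0.1 | per-epoch edge dropout on association and protein edges |
| `K` | 15 | hyperedge neighbourhood size (clamped to $N_v - 1$) |
| `ecaKernel` | 3 | channel-attention kernel length (odd) |
| `epochs` | 1000 | fixed training length; no early stopping |
| `weightDecay` | 0 | L2 penalty on all weights |
| `seed` | 1 | controls initialization and all dropout |

Edge dropout masks edges *before* the normalization constants are computed,
per epoch; feature dropout acts on the fused embedding of each layer. Both
follow the placement conventions of the bipartite-GCN models this design
descends from. The defaults for `k1`/`k2`/`lr`/`beta` are the reference
values for database-scale networks (hundreds of drugs and diseases). Fixed
epoch counts (no early stopping) keep runs comparable and deterministic.

For the small synthetic benchmark shipped with the package (60 drugs, 80
diseases; see below) these defaults are oversized, and the package's
experiments use `k1 = 64, k2 = 32, K = 8, gamma = 0.5, weightDecay = 0.005,
epochs = 500`: widths scaled to the entity counts, a neighbourhood that is a
comparable *fraction* of the graph as 15 is at database scale, and stronger
regularization because 2-fold splits leave little training signal. These
were chosen by screening held-out performance on a single fold and then
frozen for all reported experiments.

## The synthetic generator

`generateDataset()` plants a low-rank logistic world: drug factors $U$
($M \times r$) and disease factors $V$ ($N \times r$) are standard normal,
association probabilities are
$\operatorname{logistic}(U V^T / \sqrt{r} + b)$ — the division keeps the
logit variance at 1 for every rank, so no row or column is starved of
probability mass — and $b$ is calibrated by bisection so the mean probability
hits the target density within $10^{-3}$. The observed matrix is one
Bernoulli draw per pair, redrawn wholesale (shifted seed, at most 100 times)
if any drug or disease ends up with no association. Similarity views squash
the correlation kernel of $U$'s rows through a logistic with gain 3 (off a
correlation of $\pm 1$ this spans roughly 0.05-0.95), each view adding its
own symmetric Gaussian noise (`viewNoise`, default 0.3). Protein links are
drawn with probability increasing in the entity-factor/protein-direction
score and floored at `proteinLinkProb`; PPI edges connect proteins with
similar directions, and every protein is guaranteed at least one PPI
partner.

The generator emulates the *statistical* situation the model assumes —
multiple noisy views consistent with one latent drug geometry, associations
reflecting latent proximity, protein links correlated with the same factors.
It does not emulate biological semantics (views are statistically, not
pharmacologically, differentiated), degree heavy tails of curated databases,
or similarity measures with different scales per view. Passing tests on it
therefore demonstrate correct mechanics and genuine signal recovery, not
database-scale performance.

One consequence worth stating explicitly: under the reference conditions
(M = 60, N = 80, rank 4, density 0.08, 2-fold pair splits) even the *planted
probability matrix itself* — the Bayes-optimal scorer — reaches only about
0.75 held-out AUROC, because half the positives are hidden and the
unit-variance logits keep probabilities moderately spread. Measured
recoveries must be read against that ceiling, and against the degree-product
baseline (~0.52), not against 1.

## Evaluation protocols

**Pair-level k-fold**: positives are shuffled and partitioned; per fold the
training adjacency drops the test positives, and the loss additionally
masks them out (they are neither positives nor negatives during training).
The evaluation universe is the fold's test positives plus *all*
never-positive pairs; training positives are never scored. Optional knobs
subsample training negatives to a given ratio or remove a fraction of
positives from the experiment entirely (for sensitivity studies).

**Cold-start disease holdout**: a fraction (default 20%) of disease columns
is emptied entirely; the model must rank their associations from similarity
and protein context alone. Held-out columns are excluded from the training
loss — treating unknown pairs of an unseen disease as confirmed negatives
would push their scores down by construction. Five repeats use either
independent draws (default) or a seed-driven disjoint partition of the
diseases. Splits are leakage-checked programmatically: the package asserts
on every split that no test positive is present in any training adjacency.

**Metrics**: AUROC via the rank statistic (ties averaged; equal to
exhaustive positive-negative pair comparison), AUPR by non-interpolated
step integration (the variant matters at low positive rates), and recall /
accuracy / F1 at a 0.5 threshold by default — the threshold is exposed
because logistic scores concentrate above 0.5 when embeddings are
non-negative.

## Numerical and design choices

- Similarity loading repairs asymmetry up to $10^{-6}$ by averaging,
  forces the diagonal to 1, silently clips excursions $\le 10^{-6}$, warns
  up to $0.01$, and errors beyond — gross violations indicate corrupt
  files, not rounding.
- KNN ties and ranking ties are broken by index/identifier order:
  deterministic, seed-free.
- The hyperedge contains its centre ($\delta_e = K + 1$): excluding it
  would make a vertex unable to retain its own information in one hop. The
  exclusion variant is reachable for sensitivity checks by editing the
  incidence matrix.
- The rectifier sits between the two layers; the second layer is linear so
  final embeddings (and hence logits) can be negative. A config flag can
  make the stack fully linear, which on very small data behaves like a
  structured matrix factorization.
- Glorot-uniform initialization everywhere; the attention kernel starts
  small-uniform so initial channel weights are near 0.5 (near-uniform
  fusion); degree-edge vectors start at a common positive value scaled by
  the mean association degree.
- All randomness (initialization, edge and feature dropout, splits,
  generator) flows from explicit integer seeds; identical seeds give
  byte-identical networks, training logs and reports.

## Known limitations

- Full-graph dense training: memory and time scale as $O(M^2 + N^2)$ per
  operator; suitable for the hundreds-of-entities regime this problem lives
  in, not for tens of thousands.
- Single-head attention; no learnable hyperedge weights; PPI confidence
  weights are ignored (edges are unit weight).
- The cold-start protocol can only rank diseases that retain similarity or
  protein context; a disease absent from every input cannot be placed.
- On small, heavily masked problems the model's held-out ranking tracks
  (slightly below) the strength of its one-hop neighbourhood signal, and
  the contributions of the individual enhancements (multi-view attention,
  protein branch) fall below fold-to-fold variance — at the shipped
  benchmark size a 2-fold, 3-seed ablation cannot resolve them in either
  direction. Detecting those effects needs database-scale networks and
  many-fold protocols.
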