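---
title: "Disease-gene prioritization on heterogeneous networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-gene prioritization on heterogeneous networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetGTN)
```

## The problem

Curated disease-gene associations are sparse: for any one disease only a
few hundred genes are confidently annotated, while thousands of candidates
remain untested. hetGTN ranks candidate genes for a query disease by
learning from three complementary sources at once: a disease similarity
network derived from an ontology, a gene interaction network, and the
known disease-gene links that tie the two together. Both node types carry
binary miRNA-indicator features — a gene's feature vector records which
miRNAs are reported to regulate it, a disease's which miRNAs are reported
to be involved in it — so miRNAs act as a molecular bridge between the
disease and gene vocabularies.

## Models

### Disease similarity

Terms of a disease ontology form a rooted DAG. The information content of
a term is $IC(t) = -\log(|\mathrm{desc}(t) \cup \{t\}| / N)$, zero at the
root and non-decreasing towards the leaves. Two diseases are compared by
Lin similarity,

$$\mathrm{sim}(d_1, d_2) = \frac{2\, IC(\mathrm{MICA})}{IC(d_1) + IC(d_2)},$$

where MICA is their common ancestor of maximal IC. The score is 1 for a
term against itself and 0 when the only shared ancestor is the root. An
alternative mode scores the Jaccard overlap of annotation-entity sets;
Lin over the hierarchy is the default because it needs no annotations and
directly captures "sharing a specific ancestor means similar". Pairwise
similarities are binarized at a threshold `tau` (default 0.3, chosen so
sibling leaves under a specific parent in small ontologies stay
connected — the worked 5-term example scores `r round(log(5/3)/log(5), 3)`
— while pairs that only share the root drop out); binary edges keep the
disease-disease matrix on the same footing as the other edge types.

### The heterogeneous graph

Nodes are all diseases followed by all genes, stably sorted by id. The
graph is a stack of five square adjacency matrices — disease-disease,
gene-gene, disease-gene, gene-disease, and the identity — each nonzero
only in its own quadrant. The identity type is not cosmetic: a graph
transformer with $k$ selection slots composes meta-paths of length
exactly $k$, and including the identity lets it express shorter paths.

### Feature reduction by a deep belief network

Gene and disease indicator matrices share one miRNA column universe, so
both node types can be reduced by a single model into a common code
space. The reducer is a stack of three restricted Boltzmann machines.
An RBM over binary visibles $v$ and hiddens $h$ has energy

$$E(v, h) = -a^\top v - b^\top h - v^\top W h,$$

joint distribution $p(v,h) = e^{-E(v,h)}/Z$, and — because the
interaction graph is bipartite — factorized conditionals
$P(h_j = 1 \mid v) = \sigma(b_j + \sum_i v_i W_{ij})$ (symmetrically for
visibles). Layers are trained greedily by single-step contrastive
divergence (CD-1), the canonical RBM trainer: learning rate 0.05,
minibatch 32, 100 epochs. Each next layer trains on sampled binary hidden
states of the previous one, preserving the binary-visible contract of CD;
encoding, in contrast, is a deterministic mean-field pass so identical
inputs always map to identical codes. Layer sizes default to
256, 128, 64, each clipped to its input width; with the 200-miRNA
reference data the effective stack is 200 to 128 to 64. The final
dimension is a free choice — no principled value exists at this scale —
and 64 keeps the downstream encoder small while leaving ample room for
the roughly 10-active-miRNA profiles the reference data carry.

On tiny models (up to 16 units total) the package exhaustively
enumerates the joint distribution; energies, marginals and conditionals
are all cross-checked against that enumeration in the tests.

### Graph transformer encoding

Each channel of the encoder learns, per selection slot, a softmax over
edge types; the selected matrix is the convex combination
$Q = \sum_t \alpha_t A_t$. Two slots are composed by matrix product into
a meta-path adjacency, which is row-normalized (divided by its out-degree)
so repeated products cannot inflate edge weights. Graph convolutions then
propagate the reduced features:

$$H^{(l+1)} = \mathrm{ReLU}\!\left(\tilde{D}^{-1/2} (A + I)
\tilde{D}^{-1/2} H^{(l)} W^{(l)}\right),$$

with self-loops so no node is isolated and symmetric degree
normalization, whose propagation operator has spectral norm at most 1.
Symmetric normalization is used everywhere for numerical stability, and
channel outputs are concatenated column-wise into the final embedding.
Defaults: 2 channels, 2 selection slots (meta-paths of length 2), and a
single graph-convolution layer of width 64.

One graph-convolution layer is a deliberate choice. With two stacked
ReLU convolutions the pair-similarity structure of the reduced features
is progressively averaged away before the head ever sees it, visibly
costing held-out accuracy on reference bundles; one convolution over a
learned length-2 meta-path already mixes information two hops away while
leaving the feature geometry intact. The depth remains configurable
(`gcnLayers`).

### Link-prediction head and joint training

A pair $(d, g)$ is represented as
$[z_d \,\|\, z_g \,\|\, z_d \odot z_g]$ — the two embeddings and their
elementwise product — and scored by a one-hidden-layer MLP with logistic
output. The product block matters: the planted (and, in real data,
expected) association signal is similarity between a disease's and a
gene's miRNA profiles, which a plain concatenation forces the MLP to
rediscover as a quadratic interaction; giving the head the product
explicitly makes that similarity directly learnable. Encoder and head
are trained jointly by full-batch Adam on binary cross-entropy
(learning rate 0.01, at most 200 epochs), with decoupled weight decay
available. A stratified 10% carve-out of the training pairs is monitored
every 20 epochs; training stops after 4 evaluations without AUPR
improvement and the best checkpoint is restored. The backward pass —
including the paths through the softmax selections, the meta-path
product and both degree normalizations — is analytic and verified
against finite differences in the tests.

Before encoding, the reduced feature columns are standardized
(zero mean, unit variance). Mean-field codes live in $(0,1)$ with a
large common component across nodes; removing it lets the product block
measure correlation rather than shared offset.

## Evaluation protocol

Known associations are the positives; negatives are sampled per disease,
uniformly without replacement from that disease's non-associated genes,
at a 1:1 ratio by default. Pairs are split into 5 folds stratified by
disease *and* label: each disease's positives and negatives are dealt
round-robin over the folds. The double stratification is not cosmetic.
Because negatives are balanced 1:1 within each disease, a disease whose
training pairs are positive-heavy under plain label stratification
necessarily has negative-heavy held-out pairs — its totals are fixed —
and any classifier that partially memorizes disease identity then scores
systematically away from chance even on signal-free data. Dealing per
(disease, label) cell removes the complementarity; the matched-noise
calibration in the test suite checks that every method then sits within
a few points of 0.5.
Per fold, the heterogeneous graph is rebuilt with only that fold's
training positives as cross-links — held-out links never enter the
adjacency — and the held-out scores of all folds are pooled into AUC
(Mann-Whitney with midrank tie handling) and AUPR (average precision
with deterministic, input-order tie-breaking). Per-fold values are
retained in every report alongside the seed list and a configuration
fingerprint.

## Baselines and ablations

The classical baselines cannot encode a network, so each pair is the
concatenation of raw disease and gene indicator rows: an RBF-kernel SVM,
a one-hidden-layer perceptron (64 units, the "BP-ANN" of the comparison),
Bernoulli naive Bayes with Laplace smoothing (the features are binary),
and a 200-tree random forest. None of their hyperparameters were tuned;
they are the standard defaults of their implementations.

The ablation grid crosses three reducers with two encoders. PCA reduces
to the same dimension as the deep belief network. t-SNE reduces to 2
dimensions — the method is only meaningful at 2-3 — with the package's
own exact $O(n^2)$ implementation (perplexity 30, early exaggeration,
momentum gradient descent); t-SNE has no out-of-sample transform, so the
map is fitted on all nodes jointly and every report carries a
transductive flag. The alternative encoder replaces the heterogeneous
graph transformer with two independent graph convolutions, one over the
disease similarity network and one over the gene network, concatenated
at the head: it sees the same features but never the cross-links,
isolating the value of heterogeneous encoding.

## The synthetic generator

No public accession reproduces the original data sources, so the package
generates complete input bundles with a planted, tunable signal:

* **Ontology** — a random recursive tree (each new term attaches to an
  earlier term with spare child capacity, mean branching 3) plus a
  second parent with probability 0.1, so multi-ancestor DAG code paths
  are exercised as they would be by a real disease ontology.
* **Gene network** — preferential attachment, 2 edges per new gene,
  because curated interaction networks are heavy-tailed. The exact
  generative family is a modeling choice, not something the data sources
  prescribe.
* **Associations and features** — each disease draws a latent profile of
  `max(5, nMirnas/20)` miRNAs; planted associations are uniform over
  disease-gene pairs. A gene's *signal cells* are the union of the
  profiles of its associated diseases: signal cells fire with
  probability `pSignal`, every other cell with the background
  probability `pNoise`. Signal replaces the background rather than
  stacking on it — under an additive (OR) construction profile cells
  would still fire at `1-(1-pSignal)(1-pNoise)` when
  `pSignal == pNoise`, leaving a residual signal — so the matched-noise
  setting is an exact null: every gene row is i.i.d.
  Bernoulli(`pNoise`) and every method must fall to chance.

The reference conditions are 50 diseases, 300 genes, 200 miRNAs, 400
associations, `pSignal = 0.8`, `pNoise = 0.05`, seeds 0-4. All
randomness flows from the single config seed (distinct fixed offsets per
stage), so identical configs give byte-identical bundles.

What the generator does *not* emulate: realistic identifier
nomenclature, evidence weights, the true density/degree profiles of the
curated databases (which the original sources do not publish), shared
miRNA machinery between *unrelated* diseases, or annotation biases.
Passing tests on these bundles therefore demonstrate that the
implementation recovers a planted signal of the assumed form — not that
the method attains any particular accuracy on real curated data.

## Numerical choices and degenerate inputs

* Row normalization of meta-path products clamps row sums at `1e-12`;
  all-zero rows stay zero rather than becoming NaN.
* Self-loops guarantee positive degrees in every propagator.
* Report and checkpoint serialization writes doubles as 17-significant-
  digit strings, which reproduces IEEE doubles bit-for-bit; plain JSON
  number emission does not.
* Ranking ties are broken by gene id; AUPR ties by input position —
  both make outputs reproducible byte-for-byte.
* The exhaustive RBM enumeration refuses models with more than 16 units;
  the partition function is intractable beyond toy sizes.
* Binary indicator matrices reject any value outside {0, 1} rather than
  thresholding silently.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
reference conditions above (350 nodes, 800 labeled pairs per bundle,
five seeds, 5-fold cross-validation) and exact small-model checks at
toy sizes (graphs of at most 10 nodes, RBMs of at most 16 units). The
determinism check runs a reduced configuration (12 diseases, 60 genes)
twice end to end; determinism does not depend on problem size.

## Known limitations

* Full-batch training with dense matrices is intended for desk-scale
  graphs (hundreds to a few thousand nodes), not genome-scale ones.
* The deep belief network is frozen after unsupervised pretraining; no
  end-to-end fine-tuning through the encoder.
* Negative sampling treats unlabeled pairs as negatives, the standard
  but imperfect assumption of link prediction.
* t-SNE's transductive fit mildly favors that ablation; the flag in its
  reports marks this.
* Disease-disease edges are unweighted; a weighted variant would retain
  more similarity information but change the edge-type semantics.
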