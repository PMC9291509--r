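---
title: "Deep evolutionary learning for molecular optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep evolutionary learning for molecular optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`delfrag` implements a deep evolutionary learning (DEL) loop for
multi-objective molecular optimization. Three objectives are minimized
simultaneously: the Ertl–Schuffenhauer synthetic accessibility score
(SAS, dimensionless, roughly 1–10), the Crippen octanol–water partition
coefficient (logP, log units), and a protein–ligand binding affinity
score (BAS, kcal/mol; more negative is stronger). One DEL generation
consists of (1) encoding the current population into the latent space of
a fragment-based variational autoencoder, (2) non-dominated ranking and
crowding-distance computation, (3) tournament selection, uniform
crossover and Gaussian mutation on the latent vectors, (4) decoding the
evolved latents and eliminating invalid and duplicate molecules, (5)
elitist construction of the next population from the previous members
and the new molecules, and fine-tuning of the generative model on the
highest-ranked molecules. Steps 2–5 repeat for a configured number of
generations.

# Molecular representation

## Ring-entry BRICS fragmentation

Molecules are cleaved into fragment sequences at a subset of
BRICS-breakable bonds. Scanning the SMILES left to right, a cut is made
at every breakable bond whose later-scanned atom belongs to a ring; the
star-marked fragments are emitted in scan order. The ring-entry
restriction is a deliberate coarsening: cutting every BRICS bond
shreds a drug-like molecule into many small pieces (acyl, amine and
ether linkers become two-atom fragments), whereas cutting only at
ring-system entries keeps acyclic linkers attached to the ring they
decorate and yields the 2–4 chunky fragments per molecule that make
fragment sequences usable as short "sentences" for a sequence model.

Since BRICS bonds are acyclic they are bridges, so any cut set induces a
tree over fragments. Sequences are emitted in preorder; within a
fragment, the first `*` (reading order) points to its parent and the
remaining `*`s to its children in sequence order. This convention makes
`reassemble()` exact — a stack-based right-to-left fold restores every
cleaved bond, including bond order (one BRICS rule cleaves C=C double
bonds) and tetrahedral parity at the cut atoms, and the round trip
`reassemble(brics_fragment(m))` returns the canonical SMILES of `m`.
Fragment tokens are kept in their emitted orientation rather than
canonicalized, so a two-star fragment's parent- and child-facing
attachment points are never confused; the token vocabulary is slightly
larger in exchange for an unambiguous assembly semantics.

Dummy atoms carry no BRICS environment labels (bare `*`). This keeps
the vocabulary compact; it also means reassembly does not re-validate
BRICS compatibility of a joined pair, only chemical sanity.

## Junction-tree decomposition

The graph route decomposes a molecule into clusters: smallest-set-of-
smallest-rings members, with rings sharing three or more atoms merged
(to a fixed point) into bridged-ring clusters; every non-ring bond; and
a singleton atom cluster wherever an atom belongs to three or more
clusters. Clusters sharing at least one atom are connected in a cluster
graph with edge weight equal to the shared-atom count, and the junction
tree is its maximum spanning tree (Kruskal; ties broken by the lower
node-index pair, making the construction deterministic). The resulting
tree covers every atom and every bond of the molecule, which the test
suite asserts on every decomposition.

# The generative model

## Architecture

The model is a property-regularized VAE over fragment-token sequences,
implemented in base R with hand-written backpropagation. Sequences are
padded to the training maximum plus an end token. The encoder embeds
each position, flattens, and applies `recurrent_layers` tanh layers to
produce the posterior mean and log-variance; the decoder maps a latent
vector through the mirror stack to position-wise token logits; a
two-layer perceptron predicts the three objectives from the latent
vector. For the junction-tree variant the latent vector is laid out as
`z = [z_T, z_G]` (tree and graph halves); the decoder and the property
predictor consume the concatenation — the two-part layout is an
interface for latent-space manipulation, not two separate decoders, a
simplification appropriate at the package's reduced scale.

The training loss is

```
L = reconstruction + beta * KL(q(z|x) || N(0, I)) + alpha * SE(f(z), y)
```

with single-sample Monte-Carlo estimation of the expectations (the
standard reparameterization estimator). The reconstruction term is
reported as the sum of a topology component (the cross-entropy of the
stop decision) and a label component (the cross-entropy of the fragment
choices), mirroring the tree-decoder loss decomposition; the subgraph
and stereoisomer terms of the full-scale graph decoder are identically
zero in this architecture and the `jtvae_reconstruction()` helper
accepts them for completeness.

Objectives are standardized to zero mean and unit variance over the
training set before entering the property head; the centering constants
are stored in the model and used to invert predictions.

## Guarded decoding and the validity guarantee

Decoding is greedy. In the junction-tree variant every step is guarded:
only tokens whose attachment arity can extend the current partial
assembly are eligible (the chain must stay closable within the length
budget — a fragment with `s` stars changes the number of open
attachment points by `s - 2`), the partial molecule is assembled and
sanitized after every step, and a candidate that fails sanitization is
replaced by the next-best eligible token. Because a molecule is only
ever emitted once its assembly has passed sanitization with no open
attachment points, validity of decoded output is 1.0 by construction;
the test suite asserts this over 1,000 prior samples. The
SMILES-fragment variant decodes unguarded, and its occasional invalid
sequences are flagged as `NA` rather than raised, matching the
behaviour expected of a sequence baseline.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `embedding_size` | 128 | fragment embedding width |
| `hidden_size` | 450 (jt) / 128 (smiles) | hidden layer width |
| `latent_size` | 64 | latent dimension (split in half for jt) |
| `recurrent_layers` | 1 (jt) / 2 (smiles) | stacked hidden layers |
| `learning_rate` | 1e-4 | Adam base learning rate |
| `batch_size` | 32 (jt) / 128 (smiles) | minibatch size |
| `beta` | 0.1 | KL weight |
| `alpha` | 0.1 | property-loss weight |

`alpha` has no reference value; 0.1 makes the property gradient the
same order as the KL gradient at convergence on the fixture library and
is exposed in the configuration. Raising `alpha` tightens the
organization of the latent space by property value at some cost in
reconstruction; the test suite verifies that `alpha > 0` strictly
reduces the property error relative to `alpha = 0` under identical
seeds.

# The evolutionary engine

Defaults follow the reference schedule: 10 generations, population
20,000, 20 pretraining and 10 fine-tuning epochs, learning-rate
annealing `0.8^generation`, tournament probability 0.95, mutation rate
0.01. Choices the schedule leaves open were fixed as follows:

* **Crossover** is per-coordinate uniform swap with probability 0.5 —
  the least-assumptive operator on an unstructured latent space; it
  conserves the coordinate multiset per dimension.
* **Mutation** adds Gaussian noise coordinate-wise with probability
  equal to the mutation rate; the step scale defaults to 0.1 times the
  per-dimension standard deviation of the current population's latents,
  so steps track the population's own spread. Both operators are
  configurable.
* **Evolution operates on encoder means**, not posterior samples, so
  the genotype of a molecule is deterministic given the model.
* **Elitism.** The next population is the merged pool of previous
  members and new decoded offspring, re-ranked and truncated to the
  target size by (rank ascending, crowding descending). At most
  `elite_fraction` (default 0.5) of the slots may be taken by previous
  members of rank 2 or worse; the previous first front is always
  eligible, so the best front can only be displaced by molecules that
  dominate it — this keeps the first-front hypervolume non-decreasing
  under a fixed reference point, which the test suite checks.
* **Fine-tuning set**: the top `finetune_fraction` (default 0.2) of the
  population by the same ordering. Offspring whose re-fragmentation
  falls outside the pretraining vocabulary are dropped from fine-tuning
  (and keep their generating latent vector when the population is
  re-encoded); the vocabulary is fixed at pretraining.
* **Deduplication** is by canonical SMILES within the offspring batch
  and against the current population. Earlier generations are not
  consulted: a molecule may reappear after being truncated away, which
  matches an elitist search that re-discovers good regions.
* **Initial population**: a uniform random sample without replacement
  from the training data, optionally augmented with user-supplied
  reference molecules (e.g. known drugs).
* **Non-finite binding scores** (molecules a docking engine cannot
  process) are set to `+Inf`, which places those molecules behind every
  real front; they can never enter the first front or the screening
  output.

# Metrics

Validity is the fraction of chemically valid molecules among the raw
decoder output of a generation; uniqueness the fraction of
non-duplicated molecules (canonical SMILES); novelty the fraction of
the valid-and-unique set absent from the training data. The novelty
denominator follows the literal "validly unique" reading; conventions
dividing by all generated samples exist, so comparisons across
implementations should check the denominator.

The 1-Wasserstein distance between empirical property distributions is
computed as the exact integral of the absolute CDF difference over the
merged support — no subsampling for unequal sizes. For equal sample
sizes this equals the mean absolute difference of sorted samples, a
property used as an independent oracle in the tests (together with the
translation identity and the triangle inequality).

Hypervolume (minimization convention) is the Lebesgue measure of the
union of boxes spanned by each front point and the reference point:
exact sweep in 2-D, slab slicing over the last objective in higher
dimensions, cross-checked against Monte-Carlo integration in the tests.
The reference point is fixed per run as the componentwise maximum of
the initial population's objectives plus a 10% margin (with a floor of
0.1 so near-zero and negative coordinates get headroom), and is stored
in the run object: hypervolumes are comparable across generations of
one run but not across runs with different reference points. Front
points beyond the reference point (possible late in a run only for
objectives the margin underestimated) are clipped out of the
hypervolume computation rather than raising an error.

# The synthetic fixture library

The generator emulates a small drug-like screening library: eight
decorated aromatic scaffolds crossed with 48 substituents (ether,
methyleneoxy, amide, acetamide, methylamide and glycolamide linkers
ending in aromatic, heteroaromatic or saturated rings), filtered to
valid, unique molecules with at least two fragments — 362 distinct
molecules, from which a seeded sample is drawn. The library spans more
than two logP units and several rings and heavy-atom counts, enough to
give the objectives real gradients.

What it does not emulate: the size (hundreds, not 250,000), the
scaffold diversity, stereochemistry, charged species, and the
property ranges of a real screening collection. Tests passing on this
library demonstrate the machinery — exact round trips, loss behaviour,
Pareto progress, metric definitions — not chemical generalization;
conclusions about real libraries require real data and a real docking
engine.

The surrogate binding score used in engine-free runs is a fixed,
documented function of ring count and heavy-atom count plus a small
deterministic hash offset, clipped to [-12, -2] kcal/mol. It makes the
third objective reproducible and monotone in easily-checked structure;
it is not claimed to approximate docking.

# Numerical choices and degenerate inputs

* Log-variances are clipped to [-10, 10] before exponentiation;
  softmax is computed with max subtraction; probabilities are floored
  at 1e-12 inside logarithms.
* Weights are initialized from a Glorot-style Gaussian under the model
  seed; optimization is Adam (0.9/0.999) with the reference annealing
  schedule applied at fine-tuning.
* Every stochastic step (initialisation, minibatch order,
  reparameterization noise, selection, crossover, mutation, prior
  sampling) flows from the run seed; identical configuration and seed
  reproduce a run bit-identically, which the tests assert. Character
  orderings (vocabulary, fixture sets, tie-breaks) use radix sorting,
  so results do not depend on the session locale.
* Crowding distance on a front of one or two points is infinite for
  all members; a zero-range objective contributes nothing.
* A population of fewer than two members cannot undergo tournament
  selection and raises an error; an empty metric input raises an
  undefined-metric error rather than returning NaN.
* `preprocess_dataset` is idempotent; unparseable entries are dropped
  with a message, never silently.

# Problem sizes used by the checks

The packaged checks run at desk scale: models train on a 200-molecule
fixture library (20 epochs, hidden width 64, latent 16), the validity
check decodes 1,000 prior samples, the surrogate optimization run uses
population 100 for 5 generations, and the oracle suites use 100 random
sorting instances and 10^6 Monte-Carlo points. The full-scale
hyperparameter defaults (population 20,000, hidden 450, latent 64)
remain the package defaults for full-scale use.

# Known limitations

* The full-scale graph decoder of a junction-tree VAE (message passing
  over trees, subgraph assembly scoring, stereoisomer enumeration) is
  replaced by a guarded fragment-sequence decoder; the validity
  guarantee carries over, the subgraph and stereo loss terms do not.
* Guarded generation is restricted to fragment chains; molecules whose
  fragment tree branches are learned and reconstructed but not
  generated de novo.
* Fragment-token vocabularies are closed at pretraining; molecules
  with unseen fragments cannot be encoded (an out-of-vocabulary error
  names the fragment).
* The ring-entry scan rule means purely acyclic molecules are a single
  fragment and are removed by preprocessing.
* Absolute hypervolumes depend on the per-run reference point and are
  not comparable to values computed under other conventions.
* Physical docking depends on external tools (Open Babel, a
  Vina-compatible engine) and a user-supplied receptor; conformer
  generation is single-seed, and receptor preparation is out of scope.
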