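---
title: "Methods: contrastive reaction embeddings with human-in-the-loop search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrastive reaction embeddings with human-in-the-loop search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Searching a chemical reaction database traditionally means writing explicit
query rules (exact, similarity or substructure matching plus attribute
filters) and refining them by hand. `rxnsearch` implements an alternative:
every reaction record is embedded as a numeric vector, queries are embedded
into the same space, retrieval is nearest-neighbor search, and binary
relevance ratings on retrieved records (+1 / −1 / 0) drive an automatic
model update that re-ranks subsequent searches toward the user's implicit
preferences.

## The model

A reaction record is a tuple of molecule sets (product $\mathcal G^P$,
reactants $\mathcal G^R$, optional reagents $\mathcal G^A$), each featurized
as an attributed graph over heavy atoms. A shared graph isomorphism network
(GIN) encoder $f$ with edge features and **sum pooling** maps each graph to
a vector; sum pooling makes the readout additive over disconnected
components, so stoichiometry is preserved (`encode(A.A) = 2 encode(A)`).
Three projection heads produce the **target vector** $z = g_P(f(\mathcal
G^P))$ and the **prediction vector** $\hat z = g_R(f(\mathcal G^R)) +
g_A(f(\mathcal G^A))$, both in $\mathbb R^p$.

Each head is two affine layers with a ReLU after the first. **Neither layer
carries a bias.** A common head design omits the bias only in the
final layer, to approximately zero-center embeddings over the database; but
the missing-reagent rule — an absent reagent set must contribute *exactly*
a zero vector to $\hat z$ — only holds bit-exactly if $g_A(0) = 0$, which
requires the first layer to be bias-free too. We chose exactness of that
contract over literal layer bookkeeping; the zero-centering argument is
unaffected.

Training minimizes a Euclidean NT-Xent objective: with a minibatch of $M$
records stacked as $2M$ vectors ($z_{M+i} \equiv \hat z_i$),

$$ l_c(i,j) = -\log \frac{\exp(-d^2(z_i,z_j)/\tau)}
   {\sum_{k \ne i} \exp(-d^2(z_i,z_k)/\tau)}, \qquad
   J = \frac{1}{2M} \sum_{i=1}^M [\,l_c(i, M{+}i) + l_c(M{+}i, i)\,], $$

giving $M$ positive and $2M(M-1)$ negative pairs. The cosine similarity of
standard NT-Xent is replaced by the negative squared Euclidean distance so
that retrieval-time distances and the training geometry agree. Log-sum-exp
stabilization guards the softmax. No data augmentation is used: perturbing
molecular graphs can change the chemistry.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gnn_layers`, `gnn_hidden` | 5, 300 | GIN depth and width |
| `projection_hidden`, `p` | 512, 512 | head width and embedding size |
| `tau` | 100 | NT-Xent temperature (distance scale of the softmax) |
| `M` | 4096 | contrastive minibatch (more negatives per step) |
| learning rate / weight decay | 1e-4 / 1e-8 | Adam |
| stopping | 200 epochs, patience 20 | on validation J |
| `evr_threshold` | 0.95 | explained-variance cutoff selecting q |
| `delta` | 100 | ranking margin (units of embedding distance) |
| `lambda` | 0.01 | ranking-vs-contrastive trade-off |
| feedback iterations | 100 | SGD steps per update (momentum 0.9) |
| `K` | 30 | retrieved records per query |

The fine-tuning minibatch size is left open by the full-scale protocol; we
default to 256 (`feedback_config(minibatch=)`), large enough to keep the
contrastive stabilizer informative at desk scale.

Validation loss is computed per batch of size `M` in evaluation mode and
averaged with batch-size weights; whether the original protocol used
full-set or batched validation is unstated.

## Dimensionality reduction

The $2N \times p$ matrix $Z$ stacking all target then all prediction vectors
is factorized by SVD **without mean-centering** — the bias-free heads
already approximately zero-center the embeddings, and skipping centering
keeps the projection $z' = zV$ a pure linear map, so
$d^2(z'_i, z'_j) = (z_i - z_j)^\top V V^\top (z_i - z_j)$ is exactly the
full-space distance at $q = p$ and a non-expansive approximation below it.
Explained variance is computed from squared singular values of the
uncentered $Z$, the same convention recorded in the basis manifest. Column
signs are fixed (largest-magnitude entry positive) so bases are reproducible
across SVD implementations. The default threshold 0.95 selects $q$; at the
full scale ($p = 512$, $q = 26$) the stored-dimension reduction is
94.9%.

A record is stored as $x_i = [z'_i \,\|\, \hat z'_i] \in \mathbb R^{2q}$.
Queries embed to $x_*$ the same way; if only one side is given, it is used
for both halves. Distance on the concatenation is plain Euclidean — no
reweighting between halves, since no principled reweighting presents itself. Substructure queries
average the stored embeddings of matching records rather than embedding the
pattern itself, because patterns need not be valence-complete molecules;
when both roles carry patterns we require records matching *both*
(conjunction — the disjunctive reading would anchor on records that match
only half the constraint).

## Feedback updates

Rated hits enter a margin ranking loss over all ordered pairs $i<j$ of the
$K$ retrieved records,

$$ l_r(x_*) = \frac{2}{K(K-1)} \sum_{i<j}
   \max\big(0, (r_i - r_j)(d(x_*, x_i) - d(x_*, x_j)) + |r_i - r_j|\,\delta\big), $$

blended as $\tilde J = J + \lambda \cdot \overline{l_r}$ and minimized for a
fixed number of SGD-with-momentum iterations with **batch normalization
frozen** (evaluation statistics). Design choices that are genuinely open,
and what we chose:

* Distances in $l_r$ are computed in the reduced space $\mathbb R^{2q}$
  with $V$ held fixed, because that is the space in which $x_*$ and $x_i$
  are defined by the search algorithm; gradients flow through the model
  only. Refitting $V$ mid-update would silently change the geometry the
  ratings refer to, so the basis is only refit as an explicit maintenance
  step.
* The query set $Q$ accumulates across update rounds within a session
  (`accumulate = TRUE`); holding only the latest round is supported.
* Rated records are pinned by id and re-embedded from the live model each
  iteration — the loss always reflects current geometry, never cached
  vectors.

After fine-tuning, the whole database is re-embedded with the updated model
and the same basis.

## Synthetic fixtures: what they emulate, what they do not

The generator emulates the structure of the curated patent-reaction corpus
used at full scale: 1–5 reactants (weighted toward two-reactant couplings,
as in real corpora), exactly one product per record, optional reagents
(default rate 0.3), and optional numeric attributes (yield in percent from
a Beta(5,2) scaled to 0–100, temperature in °C from N(80, 30) clamped to
0–200). Records are built by template joins — ester, amide, ether and amine
couplings plus single-reactant halide hydrolysis — so reactant core
fragments literally appear as substructures of the product. This gives the
contrastive task recoverable structure at 2000 records, where random SMILES
would not train. Default scale is 2000 train / 200 val / 200 test:
large enough for metric movement, small enough for CPU minutes.

What the fixtures do **not** emulate: realistic reaction-class coverage,
yield chemistry, stereochemistry, atom-mapped data, or the scale (478k
records) and diversity of the real corpus. A green test therefore
establishes that the machinery optimizes what it claims to optimize — not
that full-scale accuracy numbers are reproduced. The generator asserts at
generation time that every preference scenario admits both positive and
negative ratings.

## Numerical choices

* **SMILES toolkit.** No R cheminformatics toolkit is available, so the
  package carries a minimal one: organic-subset parser with implicit-H
  valence rules, Morgan-style canonical ranking with tie branching, a
  non-induced subgraph monomorphism matcher, and ECFP-like circular
  fingerprints (radius 2, 2048 bits — frozen for scenario 3). Aromaticity
  is taken from the input notation (no kekulization/aromatization), so the
  kekulé and aromatic spellings of a ring are distinct molecules to the
  canonicalizer; the fixture generator always emits aromatic forms.
  Canonical strings omit stereo descriptors (equality checks are
  constitution-level); stereo is still parsed and featurized (E/Z from
  directional bonds, CW/CCW from chirality tags).
* **Ring perception** uses the cycle basis from non-tree edges; ring-size
  features are a multi-hot over sizes {3,4,5,6,7,8+}. Every categorical
  feature has an explicit "other" bucket so rare elements never crash
  featurization.
* **Gradients** are hand-written reverse-mode over the batched graph
  (sparse neighbor/incidence/pooling operators); they are verified against
  central finite differences in the development checks and the loss
  oracles in the test suite.
* **Batch norm**: biased variance for batch statistics, unbiased for
  running statistics, momentum 0.1; zero-node graphs skip message passing
  entirely and return an empty-sum readout, avoiding degenerate statistics.
* **Tie-breaks**: retrieval ties by record id, product-prediction rank ties
  by candidate-pool index — continuous embeddings make ties measure-zero,
  but determinism demands a rule.
* **Tolerances**: invariance tests 1e-5 relative; basis orthonormality and
  distance identities 1e-8; loss-oracle agreement 1e-6 relative.
* Attribute-range filtering treats a missing attribute as out of range
  (conservative); `keep_missing = TRUE` inverts this.
* Duplicate products in one raw record yield duplicate single-product
  records; no database-level deduplication is performed (a user-level
  filter).
* "Same halogen atoms" (scenario 1) is read as equality of halogen
  element-type *sets* — the phrase names atom kinds, and set semantics makes
  the empty case well-defined; a count-based variant is available
  (`halogen_semantics = "count"`). Astatine is not a halogen here.

## Known limitations

* Pure-R training: desk-scale configurations train in minutes, but the
  full corpus scale (478k reactions, M = 4096, p = 512) needs GPU-class
  throughput this package does not target.
* The SMILES toolkit is not a full chemistry kernel: no
  kekulization/aromatization, no tautomer or salt normalization, coarse
  hybridization and conjugation rules. It is sufficient for the fixture
  chemistry and for patent-style reaction SMILES that already carry
  aromatic notation.
* Substructure-mode queries cannot currently be fine-tuned against
  directly (their anchors would need re-embedding each iteration); rate
  similarity-mode queries instead.
* Retrieval is exact brute-force distance computation; approximate
  nearest-neighbor indexing is out of scope.
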