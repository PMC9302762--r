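---
title: "Hierarchical graph convolutions for compound-protein interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical graph convolutions for compound-protein interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgcncpi)
```

## The problem

Predicting whether a small molecule interacts with a protein (CPI) from the
two most widely available representations — the compound's SMILES string and
the protein's amino-acid sequence — is a core task in virtual screening and
drug repurposing. `hgcncpi` implements a hierarchical graph convolutional
network (HGCN) for the compound side, a 1D convolutional encoder for the
protein side, and a softmax classification head, together with per-residue
Grad-CAM saliency that points at the sequence regions driving each
prediction.

## The hierarchical compound representation

Small molecules share recurring substructures — rings, linkers, functional
groups — and the central modelling idea is to let message passing operate
*within* substructures before information is exchanged *between* them.

The decomposition (`decompose()`) is purely structural:

1. Partition the bonds into aromatic and non-aromatic sets, as flagged by
   the SMILES parser's aromaticity perception.
2. Find connected components independently within each bond set. Each
   component is a substructure; an atom incident to both bond kinds is
   copied into one substructure per kind, and the copies evolve
   independently during message passing.
3. Add one unweighted *virtual edge* between every pair of substructures
   that share at least one atom of the original molecule.

A molecule whose bonds are all of one kind reduces to a single node. Atoms
with no bonds at all (isolated ions in multi-fragment SMILES) each form a
single-atom non-aromatic substructure; this case is a convention of this
package — the decomposition rule itself is silent about bond-less atoms.

Aromaticity is delegated to OpenBabel's perception model (recorded in the
output metadata), reading the `ar` bond flags of its MOL2 output. Hydrogens
are implicit and excluded, the standard heavy-atom graph convention.

```{r decompose}
decompose("Cc1ccccc1")       # toluene: ring + (methyl C, ring-C copy)
decompose("c1ccccc1-c1ccccc1") # biphenyl: two rings bridged by a linker
```

## The compound encoder

Each atom copy starts as a one-hot vector over the element vocabulary
(built from the training compounds plus a reserved unknown slot) and is
mapped through a learned linear embedding to width 64. Message passing then
runs in two levels, with neighbor-sum messages and concatenation updates:

* atom level, 2 steps, restricted to intra-substructure bonds:
  `m_v = sum of neighbor states`, `h_v <- ReLU(W [h_v, m_v] + b)`, each
  step followed by batch normalization over the atom copies;
* substructure states initialized by a coordinate-wise max over each
  substructure's atoms;
* subgraph level, 1 step of the same scheme over the virtual edges
  (no normalization), widening to 128;
* a final coordinate-wise max over substructures gives the 128-wide
  compound embedding.

Concatenating the node state with the message (rather than adding) lets the
update layer weigh "self" and "neighborhood" separately. Sum aggregation
and max readouts make the embedding invariant to atom relabeling, which the
test suite verifies against a naive per-node loop implementation on every
labeled connected graph of up to five nodes.

Width choices between the stated endpoints (64 in, 128 out) are constant at
64 until the subgraph layer, which maps directly to 128 — the minimal chain
consistent with the endpoint widths. Batch normalization uses batch
statistics over all atom copies in the minibatch during training and
running statistics at inference; with a single atom copy the batch variance
degenerates to zero and the epsilon guard takes over. During training the
normalization couples atoms across substructures through the shared batch
statistics; the locality property (atom messages never cross substructure
boundaries) therefore holds exactly in evaluation mode.

The `nosplit` ablation treats the whole molecule as one substructure over
all bonds; the subgraph level then degenerates to a single node updated
with a zero message.

## The protein encoder

Sequences are tokenized over a 24-word vocabulary: the 20 standard amino
acids, Selenocysteine (U), Pyrrolysine (O), and begin/end markers; padding
uses a reserved id that embeds to the zero vector. The token length is
fixed to the longest training sequence plus two; longer sequences keep
their N-terminal prefix and still receive the end token (a convention —
whether the markers survive truncation is not specified by the design being
followed).

The stack is: embedding (width 64), convolution with kernel 3, convolution
with kernel *k*, max pool with kernel *k*, convolution with kernel *k*,
max pool with kernel 12, flatten, then two fully-connected layers
(512 then 128). The first convolution kernel (3) and last pooling kernel
(12) are fixed; *k* defaults to 6 and is the tunable that matters — it sets
how many adjacent residues a filter sees, the sequence analogue of a k-mer
length. Pooling is non-overlapping (stride = kernel), convolutions use
stride 1 without padding. The conv-conv-pool-conv-pool arrangement is the
one consistent with "three convolutions, two of which are followed by
pooling" plus the two fixed kernels; the exact interleaving is otherwise a
documented assumption. Dropout (0.2) acts on the two fully-connected
layers only, and only during training.

A minimum token length follows from the receptive field: with `k = 6` the
last pooling layer needs `max_len >= 109`; the configuration constructor
reports the bound when violated.

## Classification and training

The 128-wide compound and protein embeddings are concatenated and passed
through a four-layer fully-connected head (widths 256, 128, 64, 2 — only
"four layers" is prescribed, the interior widths are this package's
choice), and a softmax turns the two logits into class probabilities.
Training minimizes cross-entropy with Adam at learning rate 1e-4 and
weight decay 1e-4 (applied uniformly, including the normalization
parameters), dropout 0.2, and early stopping: when the validation loss
fails to improve for 10 successive epochs, training halts and the
best-validation weights are kept. The early-stopping metric is the
validation loss; "based on validation data" leaves loss-vs-AUC open, and
loss is the logged, reproducible choice here. All randomness
(initialization, shuffling, dropout) is driven by the single `seed` of
`train_config()`, so histories are bit-reproducible.

Evaluation reports AUC (rank-based concordance), F1 at threshold 0.5, and
MSE between the class-1 probability and the 0/1 label (a Brier-style score
— the natural reading of "MSE" for a binary classifier).

## Grad-CAM explanation

For a chosen class, the gradient of the *pre-softmax* logit (standard
Grad-CAM practice; "class score" does not specify pre- or post-softmax) is
backpropagated to the activations of the protein encoder's last
convolutional layer. Channel weights are the length-averaged gradients
(`alpha_k = mean_i dy/dA[i,k]`), the localization map is
`ReLU(sum_k alpha_k A^k)`, and the map is linearly interpolated onto the
token positions, cropped to the residue span (begin/end/pad are masked
out), and min-max normalized per sequence to [0, 1] so that the 0.2
highlighting cutoff is meaningful across sequences. An all-zero map is
reported as flat rather than divided by zero. A smaller kernel gives a
longer last-conv map on the same input length, hence finer-grained
saliency. The base model is never modified or retrained.

## The synthetic data generator

No deposited datasets ship with the package; `generate_synthetic_dataset()`
emulates a binary CPI screen at desk scale:

* compounds are assembled from ring templates (benzene, pyridine, furan,
  pyrimidine) joined by aliphatic linkers, so every molecule mixes aromatic
  and non-aromatic bonds and decomposes nontrivially;
* proteins are uniform random sequences over the 20 standard residues
  (default length 120), with a fixed 6-mer motif planted in a subset;
* a pair is positive iff the compound contains the designated positive
  ring (pyrimidine) and the protein contains the motif, flipped with
  probability `label_noise`.

Defaults (60 compounds, 40 proteins, 500 pairs, fragment and motif
prevalence 0.7 each) give approximately balanced labels, mirroring the
balanced benchmark CPI datasets, with enough unique molecules that held-out
pairs are informative. The rule is a detectable conjunction, chosen so that
the model class can provably separate it; passing the learning-signal test
therefore shows the training pipeline extracts a planted structure-sequence
interaction, *not* that the model reaches any particular accuracy on real
screens, where binding depends on 3D structure, activity cliffs and assay
noise that this generator deliberately omits.

## Problem sizes and numerical choices

The test suite and the acceptance script train on the 500-pair generator
default (60 epochs, batch 32, about 3 minutes on a single core), and run
the permuted-label null on a 900-pair variant so its held-out evaluation
uses 400 pairs — large enough that the null AUC's sampling error (about
0.03) sits well inside the 0.5 +/- 0.1 acceptance band. Message-passing
oracle checks enumerate all 771 labeled connected graphs on up to five
nodes. Gradient agreement is checked by central finite differences at
epsilon 1e-5 on inputs kept away from ReLU and max-pool tie plateaus,
where finite differences are invalid subgradient averages. Batch
normalization uses epsilon 1e-5 and momentum 0.1; max-pool ties break to
the first position; checkpoints serialize to JSON at full double
precision under a `format_version` field.

## Known limitations

Only the element symbol feeds the atom features (charge, degree and
stereochemistry are ignored); edge features are unused in the message
passing; the compound branch has no saliency; and affinity regression is
out of scope — IC50 values enter only through the binary labelling rules
(`label_from_ic50()`: bindingdb strict <100 / >10000 nM, chembl27
inclusive <=100 / >=1000 nM). Near-duplicate compounds or sequences are
treated as distinct by the exact-identity "known/new" scenario tagging.
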