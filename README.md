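# hgcncpi

Compound–protein interaction (CPI) prediction from SMILES strings and
amino-acid sequences, for computational chemists and bioinformaticians who
need a screening model that is trainable at desk scale and whose
predictions can be traced back to sequence regions.

## Method

The compound is decomposed into a *reduced graph*: bonds are partitioned
into aromatic and non-aromatic sets, connected components of each set
become substructure nodes (atoms on the boundary are copied into both), and
virtual edges link substructures sharing an atom. A hierarchical graph
convolutional network (HGCN) then passes messages in two levels — within
substructures and, after a max-pool readout, between them:

```
m_v^t = Σ_{u ∈ N(v)} h_u^{t-1}
h_v^t = ReLU(W_t [h_v^{t-1}, m_v^t] + b_t)       (2 atom-level steps + batchnorm)
h_c^0 = max_pool({h_v^T : v ∈ c})                 (substructure readout)
                                                  (1 subgraph-level step)
h_G   = max_pool({h_c : c ∈ G})                   (graph readout, width 128)
```

Proteins are tokenized over a 24-word vocabulary (20 standard residues, U,
O, begin/end) and encoded by a 1D-CNN: embedding (64) → conv(3) → conv(k) →
maxpool(k) → conv(k) → maxpool(12) → flatten → FC(512) → FC(128), with
k = 6 by default. The two 128-wide embeddings are concatenated and a
four-layer fully-connected head with a softmax gives

```
P(y = k | x) = exp(z_k) / Σ_i exp(z_i),  z ∈ R².
```

Training uses Adam (lr 1e-4, weight decay 1e-4), dropout 0.2 on the two
protein FC layers, and early stopping 10 epochs past the best validation
loss. Per-residue explanations use 1D Grad-CAM: channel weights
`α_k = (1/L) Σ_i ∂y_c/∂A_i^k` on the last convolutional layer, map
`ReLU(Σ_k α_k A^k)`, interpolated onto the sequence, min-max normalized,
and thresholded at 0.2.

## Worked example

```r
library(hgcncpi)

decompose("Cc1ccccc1")
#> <hierarchical_graph> Cc1ccccc1
#>   2 substructures (1 aromatic), 1 virtual edges

# synthetic planted-rule screen: positive iff the compound contains a
# pyrimidine ring AND the protein contains a planted 6-mer motif
df <- generate_synthetic_dataset(synthetic_spec(seed = 11))
parts <- split_dataset(df, "holdout", seed = 11)
model <- train_model(parts$train, parts$validation,
                     train_config(seed = 11, max_epochs = 60, batch_size = 32))
m <- evaluate(predict_table(model, parts$test), parts$test$label)
sprintf("AUC %.3f  F1 %.3f  MSE %.3f", m$auc, m$f1, m$mse)
#> [1] "AUC 1.000  F1 1.000  MSE 0.000"
```

The held-out AUC/F1 of 1.0 say the pipeline recovers the planted
fragment-and-motif rule exactly; the MSE near 0 says the predicted
probabilities are confident and calibrated to the noise-free labels. On a
pair level:

```r
r <- predict_proba(model, df$smiles[1], df$sequence[1])
r$probability   # P(interaction) for this pair
sal <- explain(model, df$smiles[1], df$sequence[1], class = 1)
head(saliency_table(sal))   # position, residue, saliency, highlighted
```

A command-line wrapper with `decompose`, `simulate`, `train`, `predict`
and `explain` subcommands is installed at
`system.file("cli", "hgcncpi.R", package = "hgcncpi")`.

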