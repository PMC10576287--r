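# cpifuse

Compound-protein interaction (CPI) modelling in R with Kronecker feature
fusion: a Y-shaped neural network that encodes a compound as an
attributed molecular graph (GraphSAGE or GCN over 78-bit atom features),
encodes a protein as a variable-length recurrent pass (LSTM/GRU/RNN) over
per-residue embeddings, fuses the two branches by a Kronecker product,
and predicts either binding affinity (pIC50 regression) or a binary
interaction/mechanism label. A seeded training engine (Adam, early
stopping, checkpoint ensembling), rigorous split schemes (random,
cold-protein, cold-compound, blind), the full metric suite (MSE, Pearson,
rm², AUC, AUPR, ...), and a fine-tuning workflow for assessing drug
*selectivity* across closely related targets complete the pipeline. A
synthetic benchmark generator with planted ground truth makes the whole
stack testable end to end on one CPU.

**Who it is for.** Computational chemists and ML practitioners who want a
self-contained, inspectable implementation of the graph + recurrence +
product-fusion CPI architecture — for method study, ablation
(encoders, embeddings and fusion modes are all swappable), or screening
experiments on their own pair tables.

## The model

For a pair (compound *c*, protein *p*):

- **Compound branch** — SMILES → heavy-atom graph; each atom gets a
  78-bit feature vector (element one-hot 44 | degree one-hot 11 |
  total-H one-hot 11 | implicit-H one-hot 11 | aromatic flag 1). Three
  GraphSAGE layers with mean aggregation,
  `h_v = σ(W · [h_v ; mean_{u∈N(v)} h_u])`, then mean pooling and a
  linear map to `h_c ∈ R^{d_c}`.
- **Protein branch** — sequence → L×h per-residue embedding (one-hot,
  k-mer, or cached language-model matrices) → recurrent cell over the
  residues; `h_p ∈ R^{d_p}` is the arithmetic mean of the hidden states.
- **Fusion** — `h_K = flatten([h_p;1] ⊗ [h_c;1])`, width
  `(d_p+1)(d_c+1)` (16,641 at the 128/128 defaults), so every pairwise
  product of protein and compound features is available to the head;
  plain concatenation and a literal triple product are provided for
  ablation.
- **Head** — two affine layers with LeakyReLU and dropout 0.2;
  one real output (pIC50) or two softmax logits.

Training minimizes MSE or cross-entropy with minibatch Adam
(batch 32, lr 1e-4 defaults from the documented grid), stopping early
after 10 epochs without validation improvement. The *parameter ensemble*
averages the predictions of the last ten epochs' checkpoints; the *NN
ensemble* averages independently trained networks. Everything —
encoders, fusion, backpropagation, the optimizer — is implemented in
vectorized base R + `Matrix` sparse algebra and verified against
numerical gradients and hand-computed forward passes.

## Worked example

Generate a small synthetic benchmark (6 targets × 30 compounds with a
planted linear structure), train a compact model, and score held-out
pairs:

```r
library(cpifuse)

syn     <- generate_synthetic(synthetic_spec(n_proteins = 6, n_compounds = 30,
                                             seed = 42))
backend <- embedding_backend("kmer")
data    <- build_dataset(syn$pairs, backend)

model <- cpi_model("regression",
  compound = compound_encoder_config("graphsage", hidden = 32, out_dim = 16),
  protein  = protein_encoder_config("lstm", hidden = 16,
                                    input_width = backend$width),
  head_hidden = 64, seed = 1)
model
#> <cpi_model> task=regression  graphsage(3 layers) + lstm  fusion=kronecker_pair  d_K=289  params=35825

set.seed(7)
n     <- nrow(data$pairs)
test  <- sample(n, 36); rest <- setdiff(seq_len(n), test)
val   <- sample(rest, 18); train <- setdiff(rest, val)

fit <- train_cpi(model, subset_dataset(data, train), subset_dataset(data, val),
                 train_config(batch_size = 32, lr = 3e-3, max_epochs = 60,
                              patience = 10, seed = 1))
fit
#> <cpi_train_result> epochs=48 best_epoch=38 best_val=0.84311 ring=10

pred <- predict(fit$model, data, test)
str(regression_metrics(pred, data$pairs$label[test]))
#> List of 3
#>  $ mse    : num 0.922
#>  $ pearson: num 0.891
#>  $ rm2    : num 0.725
```

The held-out Pearson correlation of 0.89 means the model recovered most
of the planted compound-fragment × target-sensitivity structure from 144
training pairs; the MSE is on the squared-pIC50 scale (label noise alone
contributes 0.09). `selectivity_report()` scores a compound set against
two targets at once and ranks compounds by the predicted pIC50
difference; `missing_entry_sweep()` reproduces the fine-tuning-vs-missing
-data experiment on a panel.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/cpifuse.R simulate --out-dir sim --seed 4
Rscript inst/cli/cpifuse.R train --pairs sim/pairs.tsv --backend kmer \
        --out-dir run --epochs 60 --seed 1
Rscript inst/cli/cpifuse.R evaluate --pairs sim/pairs.tsv --scheme blind \
        --out-dir eval --seed 1
```

Every run writes a `manifest.json` with the configuration, seeds and
input digests.

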