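# gaitmood

Emotion recognition from motion-capture gait: who is walking angrily,
happily, sadly, or neutrally? `gaitmood` is an R implementation of a
lightweight *bi-modular sequential neural network* for skeleton-based gait
emotion recognition, together with the handcrafted geometric features,
training recipe, evaluation metrics and a synthetic gait generator that
make the whole pipeline testable end to end with no external data.

It is aimed at researchers in movement analysis / affective computing who
want a small, fully inspectable, dependency-light reference
implementation: every stage — from CSV parsing to backpropagation through
time — is plain R, seeded, and covered by tests against independent
oracles.

## The method in brief

A gait sequence is a `T × V × C` tensor of joint coordinates (reference
setting: `T = 240` frames at 60 Hz, `V = 16` joints, `C = 3`). Each frame
is expanded into a feature vector of width `D = V·C + F`:

* raw flattened coordinates (48 values),
* **JRA** — joint relative angles at the mid-spine `S`:
  `θ = arccos( SA·SB / (|SA||SB|) )` for every unordered pair of
  non-mid-spine joints — `C(15,2) = 105` values,
* **JRD** — Euclidean joint relative distances for every unordered joint
  pair — `C(16,2) = 120` values,

giving `D = 273`. The classifier is two tapered sub-networks: a 3-layer
LSTM (128/64/64 units, tanh) for spatio-temporal feature extraction,
then a 3-layer MLP (64/32/32, tanh, optional batch-norm after the first
layer, dropout 0.2 after the second) and a 4-class softmax. Training uses
categorical cross-entropy with RMSprop (momentum 0.5, ρ = 0.3, ε = 1e-7,
learning rate 1e-4), batch 64, 75 epochs, on a stratified 80:10:10 split.
Evaluation reports per-class average precision, micro-mAP
(= `ΣTP / (ΣTP + ΣFP)`, i.e. accuracy for single-label prediction) and
macro-mAP (mean per-class AP).

The network is deliberately small:

```r
library(gaitmood)
count_parameters(network_config(input_dim = 273, sequence_length = 240))
#> [1] 295684
count_parameters(network_config(input_dim = 273, sequence_length = 240,
                                batchnorm_after_first_mlp = TRUE))
#> [1] 295940
count_parameters(network_config(input_dim = 48, sequence_length = 240))
#> [1] 180484
```

## Worked example

Generate a small synthetic corpus, train at desk scale, evaluate:

```r
library(gaitmood)

gc <- generator_config(
  class_counts = c(angry = 30, happy = 30, sad = 30, neutral = 30),
  n_frames = 40, seed = 7)
ds <- generate_dataset(gc)
ds
#> <gait_dataset> 120 sequences, T=40, 16 joints
#>   angry   happy     sad neutral
#>      30      30      30      30

fm <- assemble_input(ds$sequences[[1]], ds$topology, feature_config())
dim(fm)                     # 40 frames x 273 features (48 raw + 105 + 120)

nc <- network_config(input_dim = 273, sequence_length = 40,
                     lstm_units = c(16, 8, 8), mlp_units = c(16, 8, 8),
                     batchnorm_after_first_mlp = TRUE)
run <- train_model(ds, net_config = nc,
                   train_config = training_config(batch_size = 32,
                                                  epochs = 10, seed = 7))
run
#> <gait_run> 10 epochs; final train loss 1.3688, val loss 1.3660, val micro-mAP 0.750

evaluate_model(run, run$split$test)
#> <eval_report> n=12  micro-mAP=0.5833  macro-mAP=0.6917
#> per-class ranked AP / precision:
#>   angry    1.0000 / 0.5000
#>   happy    0.3833 / NA
#>   sad      1.0000 / 0.6000
#>   neutral  0.3833 / 1.0000
#> confusion (rows = true):
#>          predicted
#> true      angry happy sad neutral
#>   angry       3     0   0       0
#>   happy       3     0   0       0
#>   sad         0     0   3       0
#>   neutral     0     0   2       1
```

Reading the report: 12 held-out sequences; micro-mAP is the fraction
classified correctly (7/12 here — a 10-epoch run at the selected learning
rate 1e-4 has barely begun to move, see the vignette); ranked AP of 1.0
for *angry* and *sad* says their class scores already order perfectly even
though the argmax is not yet right; `NA` precision for *happy* means
nothing was predicted happy. The `run` object carries the full per-epoch
history, the exact split membership and a manifest with every seed and
configuration needed to reproduce it.

A command-line surface wraps the same pipeline
(`simulate`, `features`, `train`, `evaluate`, `params`, and `repro` for an
end-to-end desk-scale reproduction):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "gaitmood", package = "gaitmood"))')
Rscript "$CLI" params
Rscript "$CLI" repro --out /tmp/run1 --scale 0.1 --seed 1
```

## Status

All module, property and integration tests pass. Of the acceptance
criteria implemented in `tests/testthat/test-acceptance.R`, the
desk-scale learning criterion (micro-mAP ≥ 0.9 within 20 epochs at
learning rate 1e-4 on 320 training sequences) is implemented verbatim and
**fails by design of the optimizer**: RMSprop's normalized steps bound the
total per-weight displacement over those 100 updates to ~0.02, which
cannot rotate a randomly initialized readout onto the separating solution
(which provably exists — a converged linear probe on the frozen features
reaches accuracy 1.0). The analysis, with measurements, is in
`vignettes/gaitmood-methods.Rmd`; the criterion is left red rather than
weakened.
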