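# sepnet

Early sepsis detection from hourly clinical time series with a
residual-attention convolutional network, written for R.

## The problem

Sepsis kills more people each year than most infectious diseases, and every
hour of delayed treatment raises mortality. ICUs already record what an
early-warning model needs: hourly vital signs, sparse laboratory values,
demographics, and a per-timestep binary `SepsisLabel` that switches to 1 at
onset and stays 1 until discharge. `sepnet` builds, trains and evaluates a
classifier that scores every patient-hour for sepsis using a sliding window
of the patient's recent history. It is aimed at methodologists who want a
fully inspectable, dependency-light implementation of this model family —
every layer's forward *and* backward pass is implemented in the package
(im2col + GEMM convolutions in compiled code, hand-derived backpropagation)
and verified against finite differences, with no deep-learning framework
underneath.

## The model

Windows of the `T = 8` most recent hourly rows of `F` features (shape
`T x F x 1`) pass through four blocks and a dense head:

1. **ECLF** — 64@3x3 entry convolution, batch norm, ReLU, then parallel
   3/5/7-kernel branches (64 filters each) concatenated to 192 channels,
   ReLU, batch norm, one 2x2 max-pool. Multi-scale feature extraction:
   `Y_i = Conv_i(X, K_i)`, `X = Concat(Y_1, Y_2, Y_3)`.
2. **SCAN** — sequential spatial and channel attention,
   `X_final = (X ⊙ A_spatial) ⊙ A_channel`, with
   `A_spatial = σ(Conv_{7x7}(Conv_{1x1}(X)))` and
   `A_channel = σ(FC_2(ReLU(FC_1(GAP(X)))))`; both maps lie strictly in
   (0, 1).
3. **HDCB** — parallel 3x3/64 convolutions at dilation rates 1, 2, 3
   (`Y_{i,j} = Σ_{m,n} X_{i+m·d, j+n·d} W_{m,n}`), concatenated and fused
   by a 1x1 convolution with 128 filters, batch norm, ReLU.
4. **RPCC** — two residual blocks `X_k = X_{k-1} + F_k(X_{k-1})` with
   `F = Conv→BN→ReLU→Conv` (128 filters), identity skip or 1x1 projection.
5. **Head** — global average pooling, dense 512 → 256 with ReLU and 0.5
   dropout, one sigmoid unit.

Batch normalization uses the `(x − μ_B)/(σ_B + ε)` form by default (a
variance-form toggle exists). Training is Adam on binary cross-entropy with
early stopping on validation loss and best-weight restoration. A built-in
African-vulture metaheuristic (`avoaOptimize()`, `tuneHyperparameters()`)
searches learning rate and dropout. All splits — 80/10/10 and k-fold — are
patient-wise to prevent identity leakage, and a synthetic cohort generator
(`simulateCohort()`) emulates the hourly-EHR schema (1.8% positive
timesteps, AR(1) vitals, 85%-missing labs, pre-onset physiological drift)
so everything runs without any data download.

## Worked example

Simulate a 500-patient cohort, split it patient-wise, preprocess with
training-split statistics, train the full model briefly, and evaluate:

```r
library(sepnet)

co  <- simulateCohort(simConfig(nPatients = 500, seed = 11))
sp  <- patientWiseSplit(co, seed = 1)
trC <- splitCohort(co, sp, "train"); vaC <- splitCohort(co, sp, "val")
fit <- fitPreprocessor(trC)
trW <- tensorizeWindows(transformCohort(trC, fit), 8)
vaW <- tensorizeWindows(transformCohort(vaC, fit), 8)

model <- buildModel(modelConfig(features = dim(trW$x)[2]), seed = 1)
out <- trainModel(model, trW$x, trW$y, vaW$x, vaW$y,
                  trainConfig(lr = 1e-3, batch_size = 64, max_epochs = 4,
                              balanced = TRUE, steps_per_epoch = 15,
                              seed = 1))
out$history
#>   epoch train_loss train_acc   val_loss   val_acc
#> 1     1 0.21358582 0.9270833 4.68274262 0.6502959
#> 2     2 0.05370651 0.9906250 0.31735143 0.9715976
#> 3     3 0.08322846 0.9822917 0.07407438 0.9893491
#> 4     4 0.04623986 0.9906250 0.11254693 0.9857988

rocAuc(predictProb(out$model, vaW$x), vaW$y)
#> [1] 0.9991623
```

The history shows the balanced-minibatch run converging within four short
epochs; the validation AUC of 0.999 says the model recovered the planted
pre-onset drift (HR +20 bpm, Temp +1.2 °C, MAP −15 mmHg over the 12 h
before onset) almost perfectly on held-out patients. On this synthetic
cohort that demonstrates the pipeline and gradients work — not real-world
performance (see the methods vignette for what the generator does and does
not emulate).

`runAblation()` retrains the model with each block bypassed
(`without_SCAN`, `without_HDCB`, `without_RPCC`, `without_ECLF`) under an
identical budget, `kfoldCv()` runs stratified patient-wise k-fold
cross-validation, and `inst/scripts/sepnet-cli.R` exposes
`simulate | preprocess | train | tune | evaluate | cv | ablate` from the
shell.

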