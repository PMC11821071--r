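# fgdae — Fully-Gated Denoising Autoencoder for ECG Artifact Removal

Ambulatory ECG recordings are degraded by baseline wander (BW), muscle
artifact (MA) and electrode motion (EM) — the last with abrupt steps and
spikes that overlap the ECG's own spectrum and morphology, where classical
filters fail. `fgdae` is an R implementation of a compact, fully gated
denoising autoencoder for single-lead ECG segments (512 samples at 360 Hz,
in mV), together with everything needed to train and judge it: the
random-mixed-noise benchmark construction, a seven-metric evaluation suite
with stratified reporting and paired Wilcoxon tests, classical zero-phase
high-pass baselines, and a synthetic ECG/artifact generator so the entire
pipeline runs without downloading any data.

## The model

A U-Net-style encoder/decoder `x̂ = g(f(x̃))` trained to recover the clean
segment `x` from an additively corrupted `x̃ = x + β`:

* **Self-ONN encoder layers.** Each kernel tap applies a learnable degree-q
  polynomial: `y = b + Σₙ crosscorr(x∘ⁿ, Wₙ)`, n = 1..q (q = 1 is an
  ordinary convolution).
* **Gating in every layer**: `y = ONNᵢ(x) ⊗ η(σ(ONN_g(x)))` in the encoder
  and the transpose-convolution analogue in the decoder (stride 2, kernel
  9, exact length doubling).
* **Channel attention** from global max- and average-pooled descriptors
  through one shared kernel-3 convolution: `ω = η(σ(Conv(x_max)) +
  σ(Conv(x_avg)))`, a per-channel mask in (0, 2).
* **Residual gates** instead of concatenating skips:
  `y = x_in ⊗ σ(Conv_in(x_in) + η(Conv_res(x_res)))`.
* **Composite loss** `J = J_recon + J_grad + J_morph + J_reg` with
  `J_recon = SSD + 50·MAD`, `J_grad = max |Δx − Δx̂|`,
  `J_morph = 10·(1 − min_i corr(x_i, x̂_i))` over the batch, and an L1
  penalty (λ = 0.01) on the encoder weights.
* **Training**: Adam (1e-3, batch 64), learning rate halved after 2 stale
  validation epochs (min improvement 0.05, floor 1e-10), early stop after
  10 stale epochs, best-validation checkpoint kept.

The forward and backward passes (including all gradients) are implemented
in vectorized R over BLAS with small compiled kernels; gradient correctness
is pinned by finite-difference tests.

## Worked example

```r
library(fgdae)

# architecture and exact parameter accounting
model <- build_fgdae(model_config(q = 1), seed = 1)
print(model)
#> fgdae model (q = 1)
#>   input: 512 x 1
#>   encoder channels: 16 -> 32 -> 64 -> 64 -> 1
#>   decoder channels: 64 -> 64 -> 32 -> 16 -> 1
#>   trainable parameters: 263248 (263.25k)

# a small synthetic random-mixed-noise benchmark (no data download)
bm <- make_synthetic_benchmark(synth_config(), n_train = 128, n_test = 64, seed = 7)

# classical zero-phase high-pass baseline on the test pairs
res <- evaluate(function(x) iir_highpass_denoise(x), bm$test)
print(res$aggregate, digits = 3)
#>    metric   mean      sd
#> 1     ssd 22.479 25.5974
#> 2     mad  0.533  0.4104
#> 3     prd 97.947 69.1919
#> 4 cos_sim  0.729  0.2050
#> 5    rmse  0.172  0.1203
#> 6     mae  0.135  0.0943
#> 7     snr  4.019 10.2225

# one corrupted pair before/after the baseline filter
p <- Filter(function(p) p$recipe$combination != 1, bm$test$pairs)[[1]]
compute_metrics(p$clean, p$noisy)
#> SSD 19.9  MAD 0.4111  PRD 106.600%  CosSim 0.7116  RMSE 0.1971  MAE 0.1528  SNR -0.555 dB
compute_metrics(p$clean, iir_highpass_denoise(p$noisy))
#> SSD 2.753  MAD 0.2227  PRD 39.650%  CosSim 0.9389  RMSE 0.07333  MAE 0.05079  SNR 8.035 dB
```

The first pair happens to be dominated by baseline wander, which a 0.67 Hz
zero-phase high-pass removes well (−0.6 dB → 8.0 dB SNR); in-band MA/EM
mixtures are where the learned model earns its keep. Training follows the
same surfaces:

```r
fit <- train(build_fgdae(model_config(q = 1), seed = 1), bm$train,
             tc = train_config(max_epochs = 20))
evaluate(fit$best, bm$test)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/fgdae.R` (`simulate`, `prepare`, `train`, `denoise`, `evaluate`,
`count-params`).

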