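# freqlens

Tools for measuring the **spatial-frequency bias** of image classifiers and
relating it to robustness. Vision models that survive random corruptions and
adversarial attacks tend to lean on the low spatial frequencies of their
input; `freqlens` packages the measurements behind that claim so the effect
can be demonstrated, end to end, on synthetic data with derivable ground
truth — one CPU, no downloads.

## What it measures

**Reversal frequency `f_rev` (hybrid-image probing).** A hybrid image mixes
two seed images from different classes through a radial binary mask in the
Fourier domain,

    I_hybrid = F^-1[ F(I_low) * M + F(I_high) * (1 - M) ],
    M(f) = 1 if ||f|| <= f_mix else 0,

so frequencies below `f_mix` come from one class and those above from
another. Sweeping `f_mix` and recording how often a model reports each
seed's class gives a probe curve; `f_rev` is the mixing frequency where the
two probabilities cross. Models that trust low frequencies reverse early.

**Half-power frequency `f_0.5` (perturbation spectra).** For each image,
`minimal_perturbation()` searches for the smallest targeted L-infinity
perturbation that flips the prediction (PGD engines inside a bisection on
the budget, candidates aggregated over engines and restarts). The average
power spectrum of those minimal perturbations is summarized by `f_0.5`, the
radius below which half the spectral power lies. Fragile models are flipped
by high-frequency perturbations.

**Frequency-grouped corruption accuracy.** A procedural 13-family
common-corruption suite (severities 1–5) grouped low/mid/high by the
spectral content of the corruption's difference image.

**Interventions.** Fixed Gaussian-blur and PCA-projection preprocessing
layers (`blur_defense()`, `pca_defense()`) with exact adjoints, so composed
models remain attackable through the defense via `compose()`.

**Representational geometry.** Cosine-similarity eigenanalysis of stimulus
× neuron response matrices and ridge regression of eigenvector scores onto
pixels (`rf_maps()`), recovering the linear receptive fields behind the
dominant response dimensions.

All inputs can be generated in-package: band-structured image classes with
controllable spectral decay, oracle classifiers with analytically known
frequency preference, tiny trainable CNNs with exact input gradients, and
V1-like synthetic response sets with planted Gabor receptive fields.

## Worked example

Train a small CNN on a synthetic dataset whose class content has
natural-image-like 1/f amplitude decay, then probe it with and without a
blur front-end:

```r
library(freqlens)

ds <- make_band_dataset(band_dataset_spec(
  n_classes = 4, images_per_class = 150, size = c(32, 32),
  class_bands = matrix(rep(c(0.08, 1.0), each = 4), ncol = 2),
  template_components = 12, amplitude_decay = 0.5, noise_std = 0.04,
  seed = 21))
keep <- seq_along(ds$images) %% 4 != 0
train <- list(images = ds$images[keep],  labels = ds$labels[keep])
test  <- list(images = ds$images[!keep], labels = ds$labels[!keep])

plain   <- train_tiny_cnn(train, epochs = 40, seed = 3)
blurred <- train_tiny_cnn(train, epochs = 40, seed = 3,
                          preprocess = blur_defense(1.5))

probe_reversal(plain,   test$images, test$labels, n_pairs = 80, seed = 5)$f_rev
#> [1] 0.1708316
probe_reversal(blurred, test$images, test$labels, n_pairs = 80, seed = 5)$f_rev
#> [1] 0.1195367
```

The blur-composed model reverses at a lower mixing frequency — it relies on
lower spatial frequencies than the same architecture trained without the
front-end. The same pair of models shows the matching robustness ordering:
larger minimal adversarial perturbations (mean epsilon 0.083 vs 0.073 in
pixel units over 100 attacked test images, i.e. about 21/255 vs 19/255) and
lower-frequency perturbation spectra (`f_0.5` 0.067 vs 0.099 in sampling
units) for the blurred model.

A single hybrid image, if you just want the construction:

```r
h <- make_hybrid(test$images[[1]], test$images[[2]], f_mix = 0.4)
rp <- radial_profile(power_spectrum(h$pixels, mode = "nyquist"))
rp$f_half      # half-power frequency of the hybrid itself
plot(rp)
```

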