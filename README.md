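# mfishsrc

Sparse representation classification of multicolour fluorescence
in-situ hybridization (M-FISH) chromosome images.

M-FISH labels each of the 24 human chromosome types with a distinct
combination of five fluorochromes (plus a DAPI counterstain), so every
pixel carries a 5-channel intensity vector whose ideal value is its
class's binary labelling code. Imaging noise and spectral mixing corrupt
these signatures, and the resulting per-pixel misclassifications are what
limit automated karyotyping. This package is for people building or
studying pixel classifiers for combinatorially labelled cytogenetic
images — and, more generally, for anyone who needs a compact, tested
OMP/SOMP greedy sparse-coding core with an exhaustively verified oracle
suite.

## The model

A dictionary `A` (5 × N) holds the channel vectors of labelled training
pixels, partitioned into class blocks `A = [A_1, ..., A_m]`.

**Pixelwise SRC.** A test pixel `y` is sparse-coded by orthogonal
matching pursuit,

    x̂ = argmin_x ||A x − y||_2   s.t.  ||x||_0 ≤ K0,

and assigned `Class(y) = argmin_i ||y − A_i x̂_i||_2`.

**Neighborhood-joint SRC.** The `s` pixels of a square window around a
central pixel are coded jointly with a shared row support
(multiple-measurement-vector model), by simultaneous OMP:

    X̂ = argmin_X ||A X − Y||_F   s.t.  ||X||_{0,2} ≤ K0,

where `||X||_{0,2}` counts nonzero rows; the central pixel receives
`argmin_i ||Y − A_i X̂_i||_F`. The shared support is the structural
assumption that neighboring pixels belong to the same chromosome; it is
what suppresses the isolated one-pixel errors of the pixelwise model.
Recommended operating point: `s = 9` (3×3 window), `K0 ≤ 5`.

The package provides the greedy solvers (`somp()`, `omp()`), dictionary
fitting with held-out test partition and optional sparsity-concentration
screening (`mfish_src()`), window extraction (`extract_patch()`),
classification (`predict()`, `classify_image()`, `classify_pixel()`,
`classify_patch()`), evaluation (`rcc()`, `paired_model_test()`,
`isolated_spot_count()`, `parameter_sweep()`), a synthetic M-FISH cell
generator (`simulate_mfish_cell()`), TIFF/YAML cell IO, and a CLI
(`inst/cli/mfish-src` with `simulate / train / classify / evaluate /
compare / sweep` subcommands).

## Worked example

```r
library(mfishsrc)

cell <- simulate_mfish_cell(seed = 1)   # 24 classes, calibration noise
fit  <- mfish_src(cell, fraction = 0.1, seed = 1)
fit
#> M-FISH sparse representation classifier
#>   dictionary: 5 channels x 193 atoms, 24 classes (fraction 0.1, seed 1)
#>   held-out test pixels: 1637

p1 <- predict(fit, cell, s = 1)         # pixelwise model
p9 <- predict(fit, cell, s = 9)         # neighborhood-joint model
rcc(p1, cell$truth, fit$test_coords)$overall_rcc
#> [1] 0.6426
rcc(p9, cell$truth, fit$test_coords)$overall_rcc
#> [1] 0.89
isolated_spot_count(p1, cell$truth, cell$truth != 0)
#> [1] 66
isolated_spot_count(p9, cell$truth, cell$truth != 0)
#> [1] 16
```

On this cell the joint model lifts held-out accuracy (RCC, the fraction
of correctly classified chromosomal pixels) from 64.3% to 89.0% and cuts
the isolated single-pixel errors from 66 to 16 — the qualitative
signature of incorporating neighborhood structure. `rcc()` also returns
per-class accuracies and the confusion matrix; `paired_model_test()`
turns per-cell RCC vectors for the two models into a paired t-test.

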