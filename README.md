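# sinusplan

Automated surgical planning for maxillary sinus floor augmentation from
cone-beam CT (CBCT) volumes of the posterior maxilla.

When a dental implant is planned in the posterior maxilla, the choice of
surgical approach hinges on the **residual bone height** (RBH) — the
distance between the alveolar bone crest and the maxillary sinus floor —
and on the presence of horizontal or vertical ridge defects.  A modified
ABC classification maps these measurements to five surgical approaches:

| Class | Criterion                         | Recommended procedure              |
|-------|-----------------------------------|------------------------------------|
| A     | RBH > 10 mm                       | Implant placement                  |
| B     | RBH 6–9 mm                        | Osteotome                          |
| B′    | RBH 6–9 mm with ridge defect      | Osteotome + GBR                    |
| C     | RBH ≤ 5 mm                        | Lateral wall sinus elevation       |
| C′    | RBH ≤ 5 mm with ridge defect      | Lateral wall sinus elevation + GBR |

`sinusplan` implements a two-stage deep-learning pipeline for this task,
together with everything needed to exercise it at desk scale:

1. **Landmark detection (D-Net).**  Five anatomical landmarks — alveolar
   crest (AC), sinus floor (SF), medial and lateral points of the
   horizontal bone width (MH, LH), and the adjacent cementoenamel
   junction (CEJ) — are detected by a coarse-to-fine cascade of 3D
   encoder–decoder heatmap-regression networks.  A landmark at position
   *x* is encoded as the Gaussian heatmap *H* = exp(−D²/2σ²), with *D*
   the voxel distance to *x*; the network regresses these soft labels
   with voxel-wise cross-entropy, deep supervision over three decoder
   side outputs (FL = CE₁ + CE₂ + CE₃), multi-scale inputs, and a
   bidirectional convolutional LSTM over axial slices at the bottleneck.
   The coarse stage works on the downsampled whole volume; a 3D volume of
   interest is then cropped around each coarse peak and re-predicted at
   native resolution by the fine stage.
2. **Classification (C-Net).**  A 3D convolutional classifier consumes a
   two-channel input (the CBCT intensities and the fused predicted
   heatmaps) and, after 3D global average pooling, concatenates three
   **distance priors** — the absolute distances |AC−SF|, |MH−LH| and
   |AC−CEJ| in mm — before a softmax over the five classes.

Because clinical CBCT volumes cannot be redistributed, the package ships a
**synthetic phantom generator** that produces CBCT-like volumes of the
posterior maxilla with analytically known landmark positions and
rule-derived class labels, so the entire pipeline is trainable and
testable from scratch.  The networks themselves are implemented in the
package (im2col-free direct 3D convolutions in C++ with BLAS-free
register-blocked kernels and runtime AVX2 dispatch; exact hand-derived
backpropagation; RMSprop with reduce-on-plateau scheduling), so no
external deep-learning framework is required.

Also included: the modified-ABC rule engine, and the evaluation toolbox —
mean radial error (MRE), successful detection rate (SDR at 2.0/2.5/3.0/
3.5 mm), per-class accuracy/sensitivity/specificity, one-vs-rest ROC AUC,
majority-vote ground-truth derivation, and Fleiss kappa with standard
errors and agreement bands.

## Worked example

```r
library(sinusplan)

## a phantom with 12 mm of residual bone and a healthy ridge
s <- generatePhantom(phantomSpec(rbh = 12, ridgeWidth = 8,
                                 verticalStep = 0, seed = 7))
sampleLabel(s)
#> [1] "A"

plan <- planFromLandmarks(sampleLandmarks(s))
str(plan[c("class", "procedure", "rbh_mm", "defect_kind")])
#> List of 4
#>  $ class      : chr "A"
#>  $ procedure  : chr "Implant placement"
#>  $ rbh_mm     : num 12
#>  $ defect_kind: chr "none"

priorValues(computeDistancePriors(sampleLandmarks(s)))
#>  dAcSf  dMhLh dAcCej
#>     12      8      0
```

Training the full two-stage model on a phantom cohort (about 4 minutes on
one CPU at the desk-scale settings):

```r
base <- phantomSpec(spacing = 0.4, shape = 64L)
cohort <- generateDataset(200, baseSpec = base, seed = 1)$samples
test   <- generateDataset(40,  baseSpec = base, seed = 2)$samples

dcfgC <- dnetConfig(baseChannels = 4, inputSize = 16, coarseDownsample = 4,
                    finePatchSize = 12, sigmaCoarse = 2, sigmaFine = 2)
dcfgF <- dnetConfig(levels = 3, baseChannels = 4, inputSize = 12,
                    finePatchSize = 12, sigmaCoarse = 2, sigmaFine = 2)
tcfg  <- trainConfig(epochs = 30, initialLr = 1e-3, seed = 11)

coarse <- trainDNet("coarse", cohort[1:180], cohort[181:200], dcfgC, tcfg)
fine   <- trainDNet("fine",   cohort[1:180], cohort[181:200], dcfgF, tcfg)

det <- detectLandmarks(coarse, fine, sampleVolume(test[[1]]))
mre(det$landmarks, sampleLandmarks(test[[1]]))$mean   # mm
```

Across the three training seeds exercised by the acceptance suite, this
configuration reached held-out MRE 0.52–0.81 mm and SDR(≤2 mm)
93–95.5 % on the 40 test phantoms, and the distance-guided classifier
recovered the rule-derived surgical class for 87.5–92.5 % of them.
Individual desk-scale runs vary: an occasional training seed leaves one
landmark channel under-converged, which shows up as an SDR ladder
plateauing near 80 % (one `scripts/acceptance.R` run printed MRE
2.49 mm / SDR(≤2 mm) 73.5 % for detection while still classifying
87.5 % of test phantoms correctly).

A command-line interface covering phantom generation, training,
detection, classification, rule-based planning and evaluation is
installed at `inst/scripts/sinusplan.R`:

```sh
Rscript inst/scripts/sinusplan.R phantom --n 10 --seed 1 --out phantoms/
Rscript inst/scripts/sinusplan.R plan --landmarks phantoms/phantom_001_landmarks.csv
```

## Package layout

- `R/` — S4 classes (`CBCTVolume`, `LandmarkSet`, `HeatmapStack`,
  `PhantomSpec`, …), phantom generator, heatmap codec, network engine,
  rule engine, metrics, CLI.
- `src/` — compiled tensor primitives (direct 3D convolution with
  hand-written forward/backward kernels, pooling, transposed-convolution
  scatter/gather, fused batch-norm + ReLU).
- `vignettes/sinusplan-methods.Rmd` — the model, its assumptions, every
  tunable parameter, and the design decisions behind the phantom and the
  desk-scale study.
- `tests/testthat/` — unit, property and acceptance suites.
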