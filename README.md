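# erpmass

Mass-univariate scalp×time analysis of ERP repetition effects.

When an object is shown repeatedly, the brain's evoked response changes —
mostly shrinking (repetition suppression), sometimes growing (repetition
enhancement). `erpmass` asks *when* and *where* on the scalp these changes
happen, and *what temporal law* they follow, without pre-selecting
electrodes or time windows. It does so by treating the full set of scalp
channels × post-stimulus time points as a 3-D image and running
voxelwise statistics over it, for EEG studies of the common design:
multiple subjects, multiple blocks, each object repeated several times in
a row.

## The model

Per subject, the 24 condition-mean ERPs (6 presentation indices × 4
blocks) are interpolated to 32×32-pixel scalp maps for every sample of
the 50–500 ms window (226 frames at 500 Hz), smoothed with a
[16 mm 16 mm 16 ms] FWHM Gaussian, and modelled voxelwise by

    Y = Xβ + ε,   X = [block indicators | block-wise centred modulators g(r)]

with three candidate repetition dynamics g over presentations r = 1…6:
exponential exp(−(r−1)/τ), linear, and a categorical "change detection"
first-presentation indicator. Group inference on the block-pooled
modulator betas uses a voxelwise one-sample test, F = t² with
df = (1, S−1), corrected for family-wise error at the voxel level via
random field theory (expected Euler characteristic of the F excursion
set, smoothness estimated from standardized residuals). Models are
compared per voxel through the Bayesian information criterion
approximation of the log model evidence,

    LME ≈ −(n/2)·ln(RSS/n) − (k/2)·ln(n),   n = 24, k = 8,

summed over subjects into log group Bayes factors (fixed-effects
comparison), summarized with Wilcoxon signed-rank and Kolmogorov–Smirnov
statistics.

A synthetic multi-subject ERP generator with known ground-truth effects
(four space–time regions with exponential dynamics, spatially correlated
1–30 Hz noise, between-subject amplitude variability, injectable
artifacts) makes the whole pipeline testable end to end.

## Worked example

```r
library(erpmass)

cfg <- simulationConfig(nObjectsPerBlock = 2,       # scaled-down demo
                        noiseSd = 12 * sqrt(2/60),  # keeps cell-mean SNR
                        seed = 7)
montage <- makeDefaultMontage()
grid <- scalpGrid(montage)

pooled <- NULL
for (s in 1:17) {
  averages <- preprocess(simulateSubject(cfg, s, montage))
  Y <- subjectVoxelMatrix(averages, grid)          # 24 x 88592 voxels
  fit <- fitGLM(Y, buildDesign("exponential"), subject = s)
  pooled <- rbind(pooled, poolBlocks(fit))
}
times <- seq(50, 500, by = 2)
spm <- oneSampleF(pooled,
                  maskDim = c(32, 32, 226),
                  maskIdx = which(rep(scalpMask(grid), 226)),
                  times = times)
fw  <- estimateSmoothness(sweep(pooled, 2, colMeans(pooled)),
                          spm@maskDim, spm@maskIdx)
thr <- fweThreshold(spm@df, fw, spm@maskDim, spm@maskIdx, alpha = 0.05)
extractClusters(spm, thr, grid, fw)[1:3, ]
```

Output from this exact script (seed 7; the FWE F threshold is 44.69):

```
  activation size latency_ms        p_fwe        F        Z
1          1 2097        100 2.094618e-05 189.3710 6.203404
2          1 2097         90 4.038014e-05 169.5165 6.073528
3          1 2097        126 2.540340e-04 123.4261 5.693228
```

The largest activation (2097 voxels, peaks at 90–126 ms) recovers the
injected early occipital suppression: the peak latencies fall inside the
generative 86–140 ms window, `F` is the group statistic at the peak
voxel, `Z` its equivalent standard-normal deviate, and `p_fwe` the
voxel-level family-wise-error-corrected p value from random field theory.
Eight activations are suprathreshold in total, covering all four injected
ground-truth regions.

`runPipeline(pipelineConfig(), outDir)` wraps all stages (simulate →
preprocess → volumes → fit → group → compare) into one logged,
hash-manifested run, and `reportPipeline()` emits the cluster table,
model-comparison table and scalp-map images.

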