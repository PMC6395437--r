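# aptwcest

Quantification of amide proton transfer weighted (APTW) CEST MRI, with
a multi-pool Bloch–McConnell simulator that makes every processing
stage testable against known ground truth.

## The problem

Amide protons of mobile proteins and peptides resonate ~3.5 ppm
downfield of water and exchange with it at a base-catalyzed,
pH-sensitive rate. Saturating them with off-resonance RF and watching
the water signal drop (chemical exchange saturation transfer, CEST)
yields a pH-weighted contrast: in ischemic stroke, intracellular
acidosis slows the exchange and lowers the signal, and its recovery
tracks clinical improvement under treatment. The standard clinical
quantity is the magnetization-transfer-ratio asymmetry of the
z-spectrum at 3.5 ppm,

    MTRasym(3.5 ppm) = [S_sat(−3.5 ppm) − S_sat(+3.5 ppm)] / S_0
                     = APTR + MTR′asym(3.5 ppm),

reported in percent of the bulk water signal S₀ — the APTW signal. The
package is for imaging scientists who need the full chain from a
saturated image series to cohort statistics, and for methodologists who
need simulated data with exact ground truth to validate it.

The pipeline implements the clinical processing convention:

1. rigid-body registration of all 61 frames to the saturated image at
   +3.5 ppm (`registerSeries`),
2. averaging of repeated acquisitions and normalization by the
   unsaturated image (`averageRepeats`, `normalizeSeries`),
3. voxel-by-voxel B0 correction by locating the water minimum of the
   spline-interpolated z-spectrum (`estimateB0`, `correctB0`),
4. APTW mapping (`computeAPTWMap`, `mtrAsym`, `mtrAsymSpectrum`),
5. lesion quantification by the lowest-of-several-small-ROIs rule with
   a mirrored contralateral (CNAWM) reference and the lesion − CNAWM
   contrast (`measureLesion`),
6. cohort statistics: onset/post-treatment time bins, Pearson
   correlation, one-way ANOVA with LSD post-hoc tests, pooled-variance
   t-tests (`assignTimeBin`, `pearsonCor`, `anovaLSD`, `ttestInd`,
   `buildCohortTables`).

The simulator (`phantomSpec`, `buildPhantom`, `simulateCohort`) solves
the coupled Bloch–McConnell equations for configurable proton pools
(water, semisolid MT, amide, NOE) under continuous-wave saturation
(800 ms, 2 μT by default), renders lesion phantoms with B0
inhomogeneity, Rician noise and motion jitter, and generates whole
cohorts with a specified APTW–NIHSS correlation.

## Worked example

Embed a known lesion APTW of −1.10 % in a 64×64 phantom with a
±0.3 ppm B0 field, then recover it with the pipeline:

```r
library(aptwcest)

k  <- calibrateAmideExchange(-1.10)        # amide exchange rate, 1/s
ph <- buildPhantom(phantomSpec(lesion_amide_k = k,
                               b0_amplitude_ppm = 0.3, seed = 17))
ph$series
#> ZSpectrumSeries: 64 x 64 pixels, 61 frames (31 unique offsets)

res <- processSeries(ph$series, register = FALSE)
res$aptw
#> VoxelMap (%): 64 x 64, 4096 masked voxels, range [-1.1, -0.986]

measureLesion(res$aptw, ph$rois)
#> Lesion measurement (APTW, % of bulk water signal)
#>   lesion (lowest of 2 ROIs, #2): -1.097
#>   whole-lesion mean:             -1.098
#>   CNAWM:                         -0.995
#>   contrast (lesion - CNAWM):     -0.102
```

The lowest-ROI lesion value lands within 0.01 pp of the embedded
−1.10 %. (The CNAWM value here reflects the default background pool
set, not a clinical reference range.) Cohort-level machinery works the
same way from simulated ground truth:

```r
co <- simulateCohort(n = 43, seed = 1)     # APTW–NIHSS linkage r = −0.491
pearsonCor(co$lesion_aptw_pct, co$nihss)
#> Pearson correlation: statistic = -2.549, p = 0.01463

table(assignTimeBin(demographicsTable()$onset_time_h))
#> <=96h  4-7d 8-21d >=22d
#>    30    13     0     0
```

The bundled per-patient demographics reproduce the reference cohort's
onset-bin sizes (30 and 13) exactly.

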