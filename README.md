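# EmbryoSynchrony

Quantifies cell-division synchrony in time-lapse fluorescence recordings of
preimplantation embryos, and relates it to transfer outcome.

## The problem

After in-vitro fertilization, one embryo must be picked from several for
transfer. Morphology-based grading leaves most of the outcome variance
unexplained. When embryos expressing a fluorescent histone label are imaged
in 3D every 10 minutes, every nucleus can be followed from the zygote to the
32-cell stage, and the timing of each blastomere's division becomes
measurable. The discriminative signal is *asynchrony within a division
round*: for each embryo the package measures the per-blastomere duration of
the 4-to-8-cell round (the "third duration", four values) and summarizes
them as a coefficient of variation,

    CV3 = sd(d1..d4) / mean(d1..d4)      (sample SD, n - 1)

Embryos with CV3 >= 0.15 ("high-CV", asynchronous) abort after transfer far
more often than synchronous ones. The package implements the whole chain:

* **Nucleus detection** in anisotropic 3D stacks (0.8 x 0.8 x 2.0 um
  voxels): 3D median denoising, rolling-ball background subtraction,
  optional clip-limited equalization, z-attenuation correction, recursive
  Otsu thresholding, and iterative watershed subdivision of merged nuclei.
  Centroids are reported in isotropic units with z pre-scaled by
  dz/dx = 2.5 (divide by 2.5 to recover the slice index).
* **Lineage reconstruction**: optimal frame-to-frame assignment
  (Jonker-Volgenant) with a midpoint-based division hypothesis; division
  times to half a frame interval.
* **Morphokinetics**: count curves aligned to first mitosis, intra/inter
  stage durations (2/4/8/16/32-cell stages and the bands between),
  second/third/fourth-round duration statistics, high/low classification.
* **Morphometrics**: distance CV to the embryo barycenter, full Procrustes
  shape distance (reflection-free, correspondence resolved for unlabeled
  nuclei), embryo motility.
* **Outcome statistics**: the normality -> variance -> test selection
  policy (Lilliefors, F, Student/Welch/Wilcoxon), Yates-corrected
  two-proportion test, Spearman correlation, per-time count-curve
  comparison, and ROC cutoff analysis of the synchrony index.
* **A synthetic embryo generator** (lineages with controllable per-round
  duration CVs, confined excluded-volume nucleus motion, Gaussian-blob
  volume rendering with depth attenuation and noise) so every stage is
  testable without imaging data.

## Worked example

Simulate a small cohort whose third-round CVs alternate between synchronous
(0.05) and asynchronous (0.25), run the full pipeline, and read the report:

```r
library(EmbryoSynchrony)

cfg <- runConfig("simulate",
                 simulation = simulationConfig(nEmbryos = 6, seed = 7),
                 thirdCVGrid = c(0.05, 0.25))
run <- runPipeline(cfg)
run$profiles
#>   embryo_id second_diff_norm   third_cv  fourth_cv synchrony_class
#> 1    sim001       0.09395973 0.07815731 0.05726338             low
#> 2    sim002       0.05333333 0.30977525 0.02762456            high
#> 3    sim003       0.09790210 0.04878049 0.06595317             low
#> 4    sim004       0.01360544 0.20665530 0.06242485            high
#> 5    sim005       0.08108108 0.02675575 0.05061246             low
#> 6    sim006       0.04255319 0.14580296 0.02981064             low
run$truth$true_third_cv
#> [1] 0.08203796 0.31263994 0.04571387 0.20184387 0.02423187 0.14124855
print(run)
#> pipelineRun: 6 embryo(s) analyzed, 0 failed (seed 7, config 28bfb207)
#> Cohort of 6 embryos (cutoff 0.15): 2 high-CV, 4 abort
#>   high-CV fraction: 50.0% of aborts, 33.3% of all
#>   born rate: high 0.000 vs low 0.500 (prop-test p = 0.7595)
```

The tracked estimates follow each embryo's true sample CV to a few
thousandths (0.082 to 0.078, 0.313 to 0.310, 0.202 to 0.207, ...), and the
two embryos at or above the 0.15 cutoff are classed high. The generator
draws four log-normal durations per embryo, so an embryo configured at
population CV 0.25 can land a *sample* CV below the cutoff (sim006 at
0.141) — with six embryos the cohort's proportion test is far from
significant, which is the honest small-n answer. On a real recording you
would start from `detectFrame()` on each TIFF stack (or
`readCoordinates()` on an exported coordinate table), then `linkTracks()`,
`synchronyProfile()` and `cohortReport()` exactly as the pipeline does
internally.

The prospective-arm statistics are one call each:

```r
twoProportionTest(4, 34, 19, 40)   # born rates 11.8% vs 47.5%
#> [1] 0.002227868
```

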