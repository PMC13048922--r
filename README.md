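# phenocube

Mapping invasive **buffel grass** (*Cenchrus ciliaris*) occurrence from
dense satellite image time series.

## The problem

Buffel grass is an introduced pastoral grass that invades arid rangelands,
outcompetes native plants and fuels severe fires. Controlling it requires
occurrence maps at the resolution of individual stands, over landscapes of
thousands of km². Single-date imagery cannot deliver them — dry buffel looks
spectrally like dry native grass — but its *phenology* is distinctive: with
an extensive shallow root system and dense mats, buffel grass greens up
faster after rain, peaks higher, and stays green longer than native tussock
grasses or spinifex. phenocube is for remote-sensing analysts and land
managers who want to exploit that temporal fingerprint.

## The method

For each vegetation index V ∈ {EVI, NBR, NDVI, NDWI} computed from a
quality-filtered stack of 5-band reflectance mosaics (kept only when cloud
cover < 3% and non-null fraction > 90%), the dated imagery is arranged as a
spatiotemporal matrix **M** (rows = acquisition dates, columns = pixels) and
decomposed by truncated singular value decomposition,

    M ≈ U Σ Vᵀ,

where the columns of U are temporal modes and the columns of V are per-pixel
spatial loadings. The six leading loadings of each index — 24 features per
pixel — summarise each pixel's multi-year phenological history. A forward
stepwise logistic regression selected by BIC is trained on ground-truth
waypoints (presence / absence),

    Lin(n) = β₀ + Σ βᵢ Xᵢ,      P(buffel) = 1 / (1 + e^(−Lin)),

evaluated by 10 stratified 2/3–1/3 train/validation splits (sensitivity,
specificity, accuracy, ROC-AUC as mean ± SE), projected to every pixel as a
probability surface, thresholded into an occurrence map, and summarised per
landscape stratum (p50/p75 occurrence fractions, per-stratum accuracy). A
single-hidden-layer tanh neural network over all 24 features serves as a
nonlinearity check.

Because field waypoints and full imagery archives cannot be redistributed, a
seeded synthetic-scene generator (rainfall-pulse phenology, fire scars with
NBR response, cloud/nodata dropout, a stratified cover-class mosaic) provides
a fully reproducible test substrate; every stage of the pipeline is exercised
end-to-end on it.

## A worked example

```r
library(phenocube)

scene <- simulateScene(sceneConfig(seed = 42))
scene
#> SyntheticScene
#> ReflectanceCube: 64 x 64 pixels, 192 acquisition dates (2016-01-01 .. 2024-12-24)
#>   bands: BLUE,GREEN,RED,NIR,SWIR1 | valid 98.8%, cloud 0.5%, nodata 0.7%
#>   buffel prevalence 16.2%; 3 strata; 32 rain events; 2 fires

waypoints <- sampleWaypoints(scene, 400, stratified = TRUE, seed = 1)
matrices  <- buildIndexMatrices(reflectanceCube(scene))   # QC filter + 4 matrices
decomps   <- lapply(matrices, decomposeMatrix, k = 6)
decomps$ndvi
#> DecompositionResult [NDVI, exact]: rank-6, cumulative variance 97.4%

features <- extractFeatures(decomps)                      # 4096 x 24 table
labelled <- featuresAtWaypoints(features, waypoints)
X <- as.matrix(labelled[, colnames(featureMatrix(features))])

model <- stepwiseLogistic(X, labelled$label)
model
#> LogisticMapModel: intercept -9.305, 1 selected of 24 candidates
#>    ndwi_3 = -697.2
#>   BIC: 364.29 -> 11.98 over 1 steps

bootstrapEvaluate(function(x, y) stepwiseLogistic(x, y),
                  X, labelled$label, nBoot = 10, seed = 1, modelLabel = "LR")
#> EvaluationReport (LR): 10 bootstraps, train fraction 0.667
#>   training   sensitivity 1.000+/-0.000  specificity 1.000+/-0.000  accuracy 1.000+/-0.000  auc 1.000+/-0.000
#>   validation sensitivity 1.000+/-0.000  specificity 1.000+/-0.000  accuracy 1.000+/-0.000  auc 1.000+/-0.000

surface <- predictSurface(model, features)
strataSummary(surface, strataMap(scene))
#>   stratum name n_pixels area_km2   p50   p75
#> 1       1    1      401   0.0401 0.446 0.446
#> 2       2    2     3175   0.3175 0.152 0.152
#> 3       3    3      520   0.0520 0.000 0.000
```

Reading the output: on this synthetic landscape one SVD feature (the third
NDWI spatial loading) already separates buffel from everything else, so the
stepwise model stops after one step and validation metrics saturate at 1.0 —
synthetic scenes are cleanly separable by construction and give an upper
bound on real-data performance. The stratum table mirrors the intended
landscape structure: the riparian floodplain corridor (stratum 1) has the
highest modelled occurrence fraction at the 50% threshold, the sandplain is
intermediate, the rocky hills are effectively buffel-free.

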