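# SwarmSeg

Comparative intensity-based medical image segmentation in R: six
segmentation pipelines behind one preprocessing front-end, a synthetic
phantom generator with exact ground truth, and a nine-metric evaluation
suite with a benchmark runner and CLI.

## Who this is for

Researchers comparing classical clustering segmentation against
swarm-optimized and CNN-refined variants on bright-ROI medical imagery
(tumors in MRI, blast nuclei in microscopy, lesions in dermoscopy, nodules
in CT) — and anyone who needs a fully reproducible, download-free testbed
for segmentation method development.

## The methods

All six scenarios share one front-end: luma grayscale conversion
(G = 0.3R + 0.59G + 0.11B), clip-limited adaptive histogram enhancement
(per-tile histograms clipped at a multiple of the average bin occupancy,
excess redistributed uniformly, mappings blended bilinearly), and
morphological hair removal for dermoscopic input.

1. **FCM** — fuzzy C-means on pixel intensities. Memberships
   μ<sub>ij</sub> = 1 / Σ<sub>m</sub> (|x<sub>i</sub> − C<sub>j</sub>| /
   |x<sub>i</sub> − C<sub>m</sub>|)<sup>2/(k−1)</sup> and centers
   C<sub>j</sub> = Σ μ<sub>ij</sub><sup>k</sup> x<sub>i</sub> /
   Σ μ<sub>ij</sub><sup>k</sup> are alternated to minimize
   J = Σ<sub>i</sub> Σ<sub>j</sub> μ<sub>ij</sub><sup>k</sup>
   (x<sub>i</sub> − C<sub>j</sub>)².
2. **K-means** — Lloyd iteration on intensities minimizing the
   within-cluster sum of squares.
3. **FCM + PSO** / 4. **K-means + PSO** — a particle swarm searches the
   space of center vectors (fitness = the clustering objective itself);
   the global best then seeds a final FCM/Lloyd refinement, which can only
   lower the objective further.
5. **FCM + CNN** / 6. **K-means + CNN** — a small fully-convolutional
   network (two input channels: preprocessed image + clustering proposal
   mask; dilated 3×3 kernels; Dice + cross-entropy loss) refines the
   clustering-proposed mask.

The ROI is the brightest cluster (configurable), post-processed by
largest-connected-component selection and hole filling. Every prediction
is scored against ground truth with precision, recall, F-measure,
accuracy %, error %, MCC, Dice, and Jaccard, plus wall time.

## Worked example

```r
library(SwarmSeg)

spec <- phantomSpec(width = 96, height = 96, noiseSigma = 25,
                    illuminationGradient = 0.3, seed = 7)
sample <- generatePhantom(spec)            # image + exact truth mask
pre  <- preprocessImage(phantomImage(sample))
part <- kmeansSegment(pre, nClusters = 2, seed = 1)
part
#> HardPartition: 2 clusters, centers [61.64, 167.70]
#>   inertia 1.01149e+07 after 6 iteration(s)
mask <- partitionToMask(part)
scoreMasks(mask, truthMask(sample))
#> MetricReport
#>   precision 0.9659  recall 1.0000  F 0.9827
#>   accuracy 99.6419%  error 0.3581%
#>   MCC 0.9808  Dice 0.9827  Jaccard 0.9659  time NAs
```

The two recovered centers straddle the (noise- and ramp-corrupted)
background and blob levels, and the extracted mask overlaps the generating
truth at Dice 0.98 despite noise σ = 25 and a 30 % illumination drop.

Benchmarks over method × set-size sweeps run through `runBenchmark()`:

```r
cfg <- runConfig(methods = c("fcm", "kmeans", "kmeans-cnn"),
                 input = list(type = "phantom",
                              spec = list(width = 96, height = 96,
                                          noiseSigma = 25,
                                          illuminationGradient = 0.3),
                              counts = c(10, 20)),
                 seed = 42, outDir = "bench_out")
res <- runBenchmark(cfg)   # masks/, metrics_long.csv, metrics_pivot.csv,
res$summary                # manifest.json
```

## Command line

```sh
swarmseg phantoms  --count 50 --out phantoms/ --seed 1 --modality skin
swarmseg run       --method fcm,kmeans --input phantoms/ --out results/
swarmseg train-cnn --proposal kmeans --out refiner.rds
swarmseg score     --pred results/masks --truth phantoms/
```

(`swarmseg` is installed under `exec/` in the package library; invoke it as
`Rscript $(Rscript -e 'cat(system.file("exec","swarmseg",package="SwarmSeg"))') ...`
or add it to your `PATH`.)

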