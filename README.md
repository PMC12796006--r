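# spotniche

Spatial niche analysis for spot-based transcriptomics of leukemic bone
marrow and extramedullary tissue.

Acute myeloid leukemia (AML) organizes itself within the marrow
microenvironment: primitive (stem-like) leukemic cells concentrate near
endosteal (trabecular bone) surfaces, committed progeny sit distally, and
inflammatory niches harbor distinct leukemic states. Visium-style spot
transcriptomics (55 µm spots on a 100 µm hexagonal lattice) observes this
geography only through per-spot mixtures, so the analysis must run on
cell-type scores, gene-set activities and spatial statistics. `spotniche`
is the toolchain for that analysis, aimed at computational biologists
working with spot-level spatial transcriptomics of marrow or other
structured tissues.

## What it computes

* **Spot QC** — retain spots within ±3 (unscaled) median absolute
  deviations of the median for total counts, detected genes (both on the
  log1p scale) and mitochondrial fraction; depth normalization to the
  median total with log1p.
* **Clustering & agreement** — PCA → kNN → shared-nearest-neighbor Jaccard
  graph → Louvain modularity; adjusted Rand index
  `ARI = (Σᵢⱼ C(nᵢⱼ,2) − E) / (½(Σᵢ C(aᵢ,2) + Σⱼ C(bⱼ,2)) − E)` against
  reference annotations.
* **Deconvolution & stratification** — non-negative least squares of each
  spot on reference signatures (proportions on the simplex); high/low
  leukemic score split at the median summed AML score (HLS strictly above,
  ties LLS); differential co-localization (Wilcoxon rank-sum, BH),
  k = 6 neighborhood enrichment, Pearson co-localization matrix with
  `***` |r| > 0.7 and `**` 0.5 < |r| ≤ 0.7.
* **Inflammation niches** — AUCell-style rank-based gene-set activity
  (area under the recovery curve in the top 5 % of ranked genes), a
  composite inflammation score (mean of seven min–max-normalized
  inflammatory pathway scores), and exact Jenks natural breaks (Fisher
  dynamic programming) into Low / Medium-Low / Medium-High / High niches.
* **SpatialTime** — exact distance from each spot center to the nearest
  trabecular polygon boundary, scaled to [0, 1] (0 = adjacent), median
  proximal/distal split, Spearman trends and binned profiles of leukemic
  differentiation states.
* **Protein integration** — single-cell marker intensities
  arcsinh-transformed (cofactor 5) and averaged per capture disc; Lee's L
  bivariate spatial association with a 6-nearest-neighbor weight matrix,
  `L = n/Σᵢ(Σⱼwᵢⱼ)² · Σᵢ(W(x−x̄))ᵢ(W(y−ȳ))ᵢ / (‖x−x̄‖‖y−ȳ‖)`,
  with seeded permutation inference.
* **Synthetic generator** — seeded hex lattices, trabecular polygons,
  Dirichlet compositions with a bone-proximity gradient
  (`exp(−d/λ)`, λ = 100 µm) for primitive-like AML and hotspot enrichment
  for committed-like AML, negative-binomial counts with annotated gene
  sets, and a matched protein cell layer. All layers byte-reproducible
  from one seed; writers for MTX, Visium-style positions, GeoJSON bone
  contours, CSV cell tables and YAML configs.

## Worked example

```r
library(spotniche)

sim <- simulate_spot_dataset(sim_config(seed = 1))
flt <- mad_filter(qc_metrics(sim$counts))
scores <- nnls_deconvolve(normalize_log(sim$counts, log = FALSE),
                          sim$profiles * sim$config$depth_mean)
labs <- classify_hls_lls(scores, grep("^AML_", colnames(scores), value = TRUE))
ps <- score_pathways(normalize_log(sim$counts),
                     sim$gene_sets[inflammation_set_names()], seed = 1)
niches <- assign_inflammation_classes(composite_inflammation(ps))
stann <- spatialtime_scale(distance_to_bone(sim$lattice, sim$bone))
gradient_trend(sim$composition, stann, states = "AML_primitive")$trend
```

This prints:

```
retained 1449 of 1553 spots
HLS threshold: 0.505 | HLS spots: 776

        Low  Medium-Low Medium-High        High
        608         264         349         332

          state    rho p_rho median_proximal median_distal        p        q
1 AML_primitive -0.931     0         0.00699      6.99e-39 5.5e-214 5.5e-214
```

Reading it: ~7 % of simulated spots fall outside the 3-MAD QC band (pure
sampling noise — no artifacts are planted); exactly half the spots minus
median ties are HLS; the Jenks classes partition the composite inflammation
score with the two top classes covering the planted hotspots; and the
primitive-like state declines steeply with distance from bone
(Spearman ρ = −0.93, proximal median ≫ distal median), the endosteal
pattern the pipeline is built to detect.

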