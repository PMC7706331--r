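# grapecolor

Image-based phenotyping and QTL mapping of grape berry color.

Grape skin color is driven by two major anthocyanin-pathway regulators, but
visual scores (OIV descriptor 225: six classes from green-yellow to
blue-black) flatten the continuous variation that minor loci produce.
`grapecolor` implements a photographic pipeline instead: cluster images are
color corrected against a reference card, segmented into berry / rachis /
background with a nearest-prototype color classifier trained from 3x3 pixel
picks, and summarized as eleven quantitative traits

- R, G, B (0-255), and average grey = I = (R + G + B) / 3,
- weighted grey = 0.299 R + 0.587 G + 0.114 B,
- CIELAB L*, a*, b* (sRGB decoding, D65 / 2 degrees),
- HSI hue (degrees, arccos formulation) and saturation,

which feed pseudo-testcross QTL scans: simple interval mapping by
Haley-Knott regression (LOD = (n/2) log10(RSS0/RSS1)), a rank-based
Kruskal-Wallis-type scan for nonnormal traits (LOD = H / (2 ln 10)), and a
binary logistic scan for noir/nonnoir (LOD = (LL1 - LL0) / ln 10), with
seeded permutation thresholds at alpha = 0.05 (genome- or chromosome-wide),
1.5-LOD support intervals, and percent variance explained,
PVE = 100 (1 - 10^(-2 LOD / n)). Genotype probabilities between markers come
from a two-state HMM under the Haldane map function with a symmetric
genotyping-error channel.

Synthetic data generators (`generate_cluster_image`, `simulate_cross`,
`render_genotype`) provide ground-truthed images and crosses so every stage
is testable without any photograph leaving the package.

## Worked example

Simulate a 110-individual F1 carrying a major noir locus at 63 cM on
maternal chromosome 2, scan green intensity with the rank-based method, and
summarize significant QTL:

```r
library(grapecolor)

cross <- simulate_cross(sim_cross_spec(seed = 2025))
gp    <- calc_genoprob(cross, step = 1, error_prob = 1e-4)
scan  <- scan_np(gp, cross$pheno$G, trait = "G")
thr   <- permutation_threshold(cross, "G", method = "np", n_perm = 1000,
                               alpha = 0.05, seed = 2025, genoprob = gp)
summarize_qtl(scan, thr)
#>  trait method   parent chr max_lod   marker pos interval_lo interval_hi   pve
#>      G     np maternal   2   15.24 mat2_013  61          55          69 47.17
```

The genome-wide threshold from 1000 permutations is 2.51 LOD; the only
significant peak sits at 61 cM on maternal chromosome 2 (planted at 63 cM),
with a 1.5-LOD interval of 55-69 cM and an implied 47% of trait variance.
The population's noir segregation is consistent with 1:1
(`chi_square_1to1(60, 50)` gives chi-square 0.91, p = 0.34).

The imaging side, end to end on one rendered genotype (twelve images,
training picks taken from the first image's ground-truth mask):

```r
g  <- render_genotype(cross, "ind001", template = cluster_spec(seed = 1),
                      n_images = 12, seed = 11)
ts <- build_training_set(g$images[[1]],
        training_picks_from_truth(g$images[[1]], g$masks[[1]], n_per_class = 2))
sums <- lapply(seq_len(12), function(k)
  summarize_cluster(g$images[[k]], segment_image(g$images[[k]], ts),
                    unit_id = "ind001"))
aggregate_genotype(sums)
#>  unit_id     R     G     B     L    a     b     H      S     I weighted_grey
#>   ind001 167.5 125.1 93.25 55.86 12.3 23.76 25.28 0.2755 128.6         134.2
#>  average_grey n_berry_pixels
#>         128.6          77289
```

The genotype's simulated mean berry color is R/G/B = 182.4/136.8/101.5; the
extracted means are uniformly about 8% darker because the renderer shades
berry rims (`cluster_spec(shading = 0.15)`), a constant factor that leaves
across-genotype correlations at r > 0.99. With flat disks
(`shading = 0`, no jitter or highlights) extraction reproduces the simulated
colors to numerical precision.

A thin CLI over the same functions is installed at
`inst/scripts/grapecolor` (subcommands `correct`, `train`, `segment`,
`extract`, `aggregate`, `stats`, `scan`, `simulate-cross`,
`simulate-images`).

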