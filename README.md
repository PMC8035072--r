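# ryescan

Tools for tracking rye (*Secale cereale*) chromatin and reticulate
evolution in Triticeae genomics, for breeders and population geneticists
who work with wheat–rye introgressions or structured rye diversity panels.

Wheat breeding programs segregate for the 1AL.1RS and 1BL.1RS whole-arm
translocations, which trade yield against bread-making quality, so panels
must be screened for rye chromatin. Within rye itself, gene flow between
domesticated and wild groups leaves reticulate signatures along
chromosomes. `ryescan` implements the computational pipeline for both
problems, end to end, together with seeded simulators that generate inputs
with the statistical structure each stage assumes — so everything is
testable and reproducible offline.

## What it computes

**Depth karyotyping.** Per-bin counts on a combined wheat + rye reference
become `rpmm = log2(reads per bin per million mapped)`, normalized against
a reference sample (`r = rpmm − rpmm_ref`). Two features summarise arm-scale
gains and losses,

    featureA = −log[ (mean r(1A, I) − mean r(1A, N)) · (mean r(1R, I) − mean r(1R, N)) ]

(I = terminal 200 Mb of the normally introgressed end, N = terminal 300 Mb
of the opposite end; featureB uses 1B), with undefined logs substituted by
the cohort minimum of the defined values. An RBF-kernel SVM (C = 1)
classifies samples as `none`, `introgressed_1A1R`, `introgressed_1B1R` or
`ambiguous`, with a train-size cross-validation experiment (50–600 training
samples × 100 repeats).

**Hi-C SV scanning.** Per-bin link asymmetry `a = log2((left+1)/(right+1))`
— inversions against the reference appear as monotone ramps crossing zero —
with an automated ramp-fitting caller and a one-tailed permutation test
(`P = (1 + #{null ≥ obs}) / (1 + n_sim)`, 10,000 placements) for regional
enrichment of calls.

**Windowed population genetics.** In sliding windows of 100 SNPs (step 25):
identity-by-state to a focal line; variance-components Fst between groups
(ratio-of-sums form); Pn/Ps of derived variants segregating per group
(outgroup-consensus polarization, bins with Pn + Ps < 10 suppressed); and
Patterson's D (ABBA-BABA) with a 5-Mb block jackknife.

**Synteny identity profiles.** Reciprocal-best-hit selection from BLAST
tabular tables (E-value, then bitscore, then length) and mean-identity
profiles in bins of 100 matches stepping by 20.

**Flow-cytometric genome size.** `2C = sample G1 mean × standard 2C /
standard G1 mean`, converted at 1 pg = 0.978 Gb.

## Worked example

Simulate a labelled cohort, extract features, classify, and run the
train-size experiment:

```r
library(ryescan)

cohort   <- simulate_depth_cohort(depth_sim_config(n_per_class = 25, seed = 1))
features <- cohort_features(cohort)           # rpmm -> r -> featureA/featureB
labels   <- cohort$labels[features$sample_id]

features[c(1, 26, 51, 76), ]
#>                sample_id   featureA   featureB substitutedA substitutedB
#> 1:         ambiguous_001 0.81903309  0.5457424        FALSE        FALSE
#> 2: introgressed_1A1R_001 0.01177727  0.1132418         TRUE        FALSE
#> 3: introgressed_1B1R_001 0.18213190 -0.1292658        FALSE         TRUE
#> 4:              none_001 2.22078690  1.9751068        FALSE        FALSE
```

The 1AL.1RS carrier is flagged `substitutedA`: its 1A depletion times its
1R gain makes the log argument negative, which is itself diagnostic. The
SVM separates the classes:

```r
model <- fit_karyotype_classifier(features, labels)
table(truth = labels, predicted = classify_karyotypes(model, features))
#>                    predicted
#> truth               ambiguous introgressed_1A1R introgressed_1B1R none
#>   ambiguous                25                 0                 0    0
#>   introgressed_1A1R         0                25                 0    0
#>   introgressed_1B1R         0                 1                24    0
#>   none                      0                 0                 0   25

cross_validate_classifier(features, labels, train_sizes = c(25L, 50L, 75L),
                          repeats = 25L, seed = 2)$summary
#>    train_size      mean       q25    median       q75
#> 1:         25 0.9098667 0.8933333 0.9466667 0.9733333
#> 2:         50 0.9672000 0.9400000 0.9800000 0.9800000
#> 3:         75 0.9792000 0.9600000 1.0000000 1.0000000
```

Mean held-out accuracy climbs with training size — at full scale (200
samples per class, training size 600) it reaches ≈ 99.7%. A planted 50-Mb
inversion is recovered by the Hi-C ramp scanner with near-exact boundaries:

```r
links <- simulate_hic_links(hic_sim_config(
  8e8, sv_set = data.frame(start = 650e6, end = 700e6),
  n_links = 2e6, seed = 3))
detect_inversions(compute_asymmetry_track(links, chrom_length = 8e8))
#>     chrom    start      end      type    score amplitude
#> 1:    chr 6.51e+08 6.99e+08 inversion 0.986345  2.139577
```

The `score` is the fraction of within-window variance explained by the
fitted ramp; `amplitude` its rise in log2 units.

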