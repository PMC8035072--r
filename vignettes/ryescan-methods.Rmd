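---
title: "Methods: depth karyotyping, Hi-C SV scanning and windowed population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth karyotyping, Hi-C SV scanning and windowed population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryescan)
```

`ryescan` implements a set of computational procedures used to study rye
(*Secale cereale*) chromatin: detecting wheat–rye introgressions from binned
read depth on a combined reference, scanning Hi-C contact maps for large
structural variants, and measuring reticulate evolution within a structured
panel through windowed population-genetic statistics. Every stage has a
matching seeded simulator, so the whole pipeline can be exercised and
calibrated without any external data. This vignette records the models, the
parameters that matter, and the design decisions taken where the procedures
left genuine freedom.

## 1. Read-depth karyotyping

### Model

Wheat samples are mapped to a combined wheat + rye reference and read counts
are tabulated in 1-Mb bins. Counts are expressed as

$$\mathrm{rpmm} = \log_2\!\left(\frac{\text{reads in bin}}{\text{million reads mapped}}\right),$$

and normalized against a designated reference sample (the package never
hard-codes which): \(r = \mathrm{rpmm}_{\text{sample}} -
\mathrm{rpmm}_{\text{reference}}\), cancelling bin-level mappability biases
shared with the reference.

A 1BL.1RS whole-arm translocation replaces the wheat 1B short arm with the
rye 1R short arm, which appears as a depletion of \(r\) on the lost arm and
a gain on 1R. Two features summarise this: with \(\bar r^{c}_{I}\) the mean
of \(r\) over all bins wholly inside the terminal *I* window (200 Mb, the
normally introgressed end) of chromosome \(c\), and \(\bar r^{c}_{N}\) the
mean over the terminal 300 Mb of the opposite (*N*) end,

$$\mathrm{featureA} = -\log\!\left[(\bar r^{1A}_I - \bar r^{1A}_N)\,
(\bar r^{1R}_I - \bar r^{1R}_N)\right],$$

and featureB analogously with 1B. Whenever the product inside the log is
not positive the feature is set to the minimum of the defined values of that
feature across the cohort, and flagged. Karyotypes are then assigned by a
soft-margin SVM with an RBF kernel and cost 1, and the classifier is
evaluated by drawing random training sets of 50–600 samples (100 repeats per
size) and scoring the held-out remainder.

### Numerical choices

* **Zero-count bins** receive a pseudocount of 0.5 reads before the log, so
  every bin has a finite rpmm. The pseudocount is a fixed read equivalent:
  it deliberately does not scale with library size, which limits the
  shift-equivariance of rpmm to bins with nonzero counts.
* **Logarithm base in the features** is natural. The base rescales the
  feature axes monotonically and cannot change what an RBF-SVM can
  separate; it is exposed as an argument.
* **Bins straddling a window boundary are excluded** from window means:
  windows are defined in bp, bins in whole Mb, and exclusion is the
  conservative reading.
* **RBF bandwidth** uses the median heuristic on pairwise feature
  distances, making the fit deterministic given the data.

### What the depth simulator emulates — and the feature geometry

`simulate_depth_cohort()` draws per-bin counts for four classes (`none`,
`introgressed_1A1R`, `introgressed_1B1R`, `ambiguous`) from a
negative-binomial with variance \(\mu + \phi\mu^2\) (`dispersion` \(\phi\);
\(\phi = 0\) returns exact expectations for closed-form tests).

The features are products of *differences* of window means, so their
geometry hinges on the sign structure of those differences. If sample noise
around the reference were strictly zero-mean, the sign of each difference
would be a coin flip for every non-introgressed sample, scattering all four
classes onto the substitution value — and no classifier could reach high
accuracy on a balanced cohort. Real panels are not like that: two
systematic, one-signed sample-versus-reference effects dominate, and the
simulator models both explicitly.

1. **Homology-graded cross-mapping.** Reads from chromatin the sample does
   not carry still land sparsely on its bins. Panel samples mismatch the
   reference genome slightly and therefore cross-map *more* than the
   reference sample itself does, preferentially onto the homoeologous 1R
   short arm (defaults: 2.5× the baseline rate on the short arm, 1.25×
   elsewhere, baseline 2% of full depth). This gives every non-carrier a
   consistent positive \(\bar r^{1R}_I - \bar r^{1R}_N\).
2. **Distal library bias.** Reduced-representation libraries are enriched
   for reads near chromosome ends relative to a deeper reference library.
   Each sample draws a strictly positive amplitude (log-normal, mean 1,
   sdlog 0.15) for a terminal enrichment decaying over 150 Mb. Because the
   *I* window (200 Mb) is shorter than the *N* window (300 Mb), the same
   end effect averages larger over *I*, making
   \(\bar r^{1A}_I - \bar r^{1A}_N\) consistently positive for samples with
   intact wheat arms.

Under these defaults the classes occupy distinct regions: 1AL.1RS carriers
always substitute on featureA (depletion × gain makes the argument
negative), 1BL.1RS on featureB, while `none` and `ambiguous` remain defined
at separated positions along the diagonal. One structural collision is
unavoidable: the sample that *defines* each substitution minimum sits
exactly on the corner shared with the other translocation class, costing at
most a couple of samples per cohort. Held-out accuracy at the default
settings is ≈ 99.7% (200 samples per class, training size 600, 100
repeats) — computed by `scripts/acceptance.R`, not quoted from anywhere.

What the simulator does **not** model: GC and fragment-length biases,
segmental aneuploidy, partial-arm translocations, copy-number variation
within arms, or mapping-quality heterogeneity along the genome. Passing
tests therefore show the procedure recovers planted whole-arm karyotypes
under realistic overdispersion and one-signed panel biases — not that it is
robust to every artefact of a production panel.

## 2. Hi-C link-asymmetry SV scanning

For each 1-Mb bin, intra-chromosomal links are split into `left_links`
(partner at a smaller coordinate) and `right_links`, and summarised as

$$a = \log_2\frac{L + \psi}{R + \psi}, \qquad \psi = 1 .$$

Each retained link increments exactly one left and one right counter, so
\(\sum L = \sum R = \#\text{links}\) holds as an identity (tested exactly).
Links shorter than two bins are discarded as self-ligation/short-range
noise. The *sign convention* (left:right, not right:left) is a choice and
is documented here and in the function help: under it, an inversion
relative to the reference produces an *ascending* ramp — `a` strongly
negative at the proximal edge, rising monotonically and crossing zero near
the middle, positive at the distal edge. The crossing sits slightly
proximal of the midpoint when the inversion lies near a chromosome end,
because partner space beyond the end is truncated.

The detector scans windows of ≥ 10 bins (geometric length ladder, factor
1.15, capped at 60% of the chromosome) and fits a straight line to the
mean-subtracted `a` values. A window becomes a candidate when

* fitted rise ≥ 2 log2 units (`amplitude_threshold`),
* \(R^2\) ≥ 0.6 (`score_threshold`, the reported call score),
* |window mean| ≤ 0.25 × amplitude (`balance_threshold`).

The balance condition encodes the antisymmetry of a true inversion ramp and
rejects the one-sided ramps that chromosome ends produce; the length cap
exists because the end-truncation trend is itself globally antisymmetric, so
a full-length window would mimic a whole-chromosome inversion — which is
anyway indistinguishable from a relabelling of the sequence. Overlapping
candidates are resolved greedily by score, and call boundaries are snapped
to the local extrema of a lightly smoothed track (the asymmetry minimum and
maximum mark the true edges). On planted inversions of ≥ 20 bins at two
million simulated links the caller reaches recall and precision 1.0 with
boundary reciprocal overlap ≈ 0.93–0.96.

Regional enrichment of calls (e.g. in pericentromeric low-collinearity
regions) is tested by a one-tailed permutation: the statistic is the number
of call *midpoints* inside the region set; the null re-places each call
uniformly within its chromosome, length preserved; and
\(P = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{sim}})\) with
\(n_{\text{sim}} = 10{,}000\). Midpoints (rather than bp overlap) make the
null exactly simulable and match the "calls occur preferentially in"
phrasing of the claim being tested; the add-one form is the standard
bias-avoiding convention and makes \(P = 1\) exact for an empty call set.

The link simulator draws distances from a truncated power law (exponent −1
by default — the standard contact-decay shape; the asymmetry logic does not
depend on its exact form) and maps coordinates through the planted
inversions by reflection. It does not model coverage heterogeneity,
restriction-site density, or matrix normalisation (ICE etc.), which operate
upstream of the link lists this module consumes.

## 3. Windowed population genetics

All windowed statistics share one binning scheme: sliding windows of 100
consecutive SNPs advanced by 25, never spanning chromosomes, trailing
partial windows dropped, each window positioned at the mean genomic
position of its variants.

* **Filtering.** Two presets cover the usual regimes: permissive (≤ 30%
  missing, MAF ≥ 1%) for clustering, stringent (per-call depth ≥ 6,
  ≤ 5% missing, site quality ≥ 250) for windowed statistics. The depth
  filter masks calls *before* site missingness is computed, which is the
  order that makes the two criteria interact correctly.
* **Clustering.** Sites are mean-imputed, centred and decomposed by SVD;
  k-means (k = 7, first three components) uses 25 restarts under a fixed
  seed because single-start k-means is seed-fragile.
* **IBS** to a focal sample: mean over co-called sites of
  \(1 - |d_1 - d_2|/2\) on dosages; pairwise-complete within each window.
* **Fst** between groups uses the unequal-sample-size variance-components
  (ANOVA) estimator on allele frequencies, and each window reports the
  *ratio of sums* of per-site numerator and denominator components — not a
  mean of per-site ratios — which is the stabler and accepted reading of
  the method. Per site, both groups must have called genotypes
  (complete-within-group frequencies).
* **Polarization.** The ancestral state is the allele claiming a strict
  majority of the three outgroup-subgenome alleles; triples with three
  distinct alleles are omitted, as are majorities matching neither ref nor
  alt (flagged separately).
* **Pn/Ps** counts polarizable *sites* (not alleles) whose derived allele
  segregates in the group — by default present *and* polymorphic within the
  group, configurable to mere presence — split by effect class. Bins with
  \(P_n + P_s < 10\) are suppressed; \(P_s = 0\) above the threshold is
  reported as an infinite ratio with its own flag rather than silently
  dropped.
* **Patterson's D** uses group derived-allele frequencies:
  \(D = \sum[(1-p_1)p_2p_3 - p_1(1-p_2)p_3] \big/
  \sum[(1-p_1)p_2p_3 + p_1(1-p_2)p_3]\), with a delete-one block jackknife
  over contiguous 5-Mb intervals for the standard error (blocks without
  informative sites are skipped; fewer than two informative blocks flags
  the s.e. as undefined).

The genotype simulator is a Balding–Nichols model: cluster frequencies are
Beta-distributed around shared ancestral frequencies with spread set by
`divergence`; gene-flow tracts copy the donor cluster's frequencies into
the recipient within an interval; nonsynonymous derived-allele frequencies
in a designated cluster can be shrunk by `sel_differential` to emulate
stronger purifying selection; the outgroup triple's majority equals the
ancestral allele except at an `outgroup_error` fraction of sites. It does
not simulate linkage disequilibrium, recombination maps or coalescent
genealogies — sites are exchangeable given their frequencies — so
calibration results speak to estimator correctness, not to LD-driven
variance inflation in real data (the block jackknife exists precisely for
the latter).

Calibration at the suite's fixed conditions: windowed Fst on a panmictic
panel (50 per group) is centred within ±0.02 of zero; across 200
no-gene-flow replicates (3 clusters × 15 samples, 3000 sites spread over 60
jackknife blocks) the jackknife Z has s.d. ≈ 0.98 and lies within ±2 in
95% of replicates. The block count matters: with only ~15 blocks the
jackknife visibly underestimates the standard error (Z s.d. ≈ 1.14), an
estimator property worth remembering when applying 5-Mb blocks to small
genomic regions. A planted tract copying 60% of the genome from P3 into P2
at divergence 0.3 yields \(D \approx 0.19\) with \(Z > 5\).

## 4. Synteny identity profiles

Best hits are selected per query and subject (sub)genome by E-value, ties
broken by higher bitscore, then longer alignment, then (flagged)
lexicographic subject id; pairs are kept only when reciprocal. Mean percent
identity is profiled in sliding bins of 100 consecutive reciprocal matches
advanced by 20 — the phrase "increments of 20" is read as a
20-match step between successive 100-match bins, which yields the smooth
overlapping profiles the analysis style implies; the step is a parameter,
not a constant, in case the coarser reading (non-overlapping blocks of 20
bins) is wanted. Bin positions are mean match positions; genes are located
by their annotated start coordinate, not alignment coordinates; bins never
span chromosomes.

## 5. Flow-cytometric genome size

\(2C_{\text{pg}} = \text{sample G1 mean} \times 2C_{\text{standard}} /
\text{standard G1 mean}\), aggregated across replicate runs as a mean of
per-replicate ratios (replicates are run on different days, so
per-replicate ratios absorb day effects; ratio-of-means is available), then
converted at 1 pg = 0.978 Gb; 1C is half of 2C.

## Problem sizes used by the test suite

The suite regenerates everything from seeded simulators at sizes chosen to
make each property measurable while keeping a single run light: 200
samples/class for the classifier experiment; 1–2 million links per Hi-C
track; 200 replicate panels for jackknife calibration; toy matrices of ≤ 10
sites wherever a hand count or brute-force oracle is the comparison.
Oracles (direct-summation features, per-site ANOVA Fst, looped D, counted
link asymmetry) are independent re-derivations living in the test helpers,
agreeing with the package paths to 1e-9 relative tolerance.

## Known limitations

* The feature-space geometry is inherited from the feature definitions,
  including the substitution rule's corner collision; the classifier, not
  the features, carries the burden of separating `ambiguous` from `none`.
* The inversion caller assumes a single clean ramp per event; nested or
  overlapping rearrangements, translocations and duplications are out of
  scope, and calls near chromosome ends lean on the balance filter rather
  than an explicit edge-effect model.
* Fst, D and Pn/Ps operate on the genotype matrix as given; no imputation,
  no variant calling, no effect prediction — effects and outgroup states
  are inputs.
* Pericentromeric region boundaries are user inputs; nothing in the
  package derives them.
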