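test_that("rpmm matches hand-computed values and handles zeros", {
  expect_equal(compute_rpmm(1, 1e6), 0)
  expect_equal(compute_rpmm(1000, 1e6), log2(1000))
  z <- compute_rpmm(0, 1e6)
  expect_true(is.finite(z))
  expect_equal(z, log2(0.5))
  expect_error(compute_rpmm(5, 0), "total_mapped")
  expect_error(compute_rpmm(-1, 1e6), ">= 0")
})

test_that("scaling counts shifts rpmm by log2(c) and leaves r unchanged", {
  # positive counts: the zero-count pseudocount is a fixed read equivalent
  # and intentionally does not scale with the library
  counts <- c(10, 250, 3, 4, 77)
  ref <- c(12, 240, 5, 1, 60)
  c_fac <- 8
  expect_equal(compute_rpmm(counts * c_fac, 1e6 * c_fac),
               compute_rpmm(counts, 1e6))
  expect_equal(compute_rpmm(counts * c_fac, 1e6),
               compute_rpmm(counts, 1e6) + log2(c_fac))
  # scaling sample and reference together cancels in r
  mk <- function(ct, tot) data.frame(chrom = "1A",
                                     bin_start = (seq_along(ct) - 1) * 1e6,
                                     rpmm = compute_rpmm(ct, tot))
  r1 <- normalize_to_reference(mk(counts, 1e6), mk(ref, 1e6))
  r2 <- normalize_to_reference(mk(counts * c_fac, 1e6),
                               mk(ref * c_fac, 1e6))
  expect_equal(r2$r, r1$r)
})

test_that("reference normalization: identity, doubling, bin mismatch", {
  tr <- data.frame(chrom = "1A", bin_start = 0:4 * 1e6,
                   rpmm = c(1, 2, 3, 4, 5))
  expect_equal(normalize_to_reference(tr, tr)$r, rep(0, 5))
  tr2 <- tr; tr2$rpmm <- tr$rpmm + 1  # double the counts at equal library
  expect_equal(normalize_to_reference(tr2, tr)$r, rep(1, 5))
  bad <- tr; bad$bin_start <- bad$bin_start + 5e5
  expect_error(normalize_to_reference(tr, bad), "same bins")
})

# r tracks with constant r inside each terminal window, for exact feature
# arithmetic. Windows: I = first 2 Mb, N = last 3 Mb of 10-Mb chromosomes.
toy_track <- function(sample_id, mA_I, mA_N, mB_I, mB_N, mR_I, mR_N) {
  one <- function(ch, mi, mn) {
    data.frame(sample_id = sample_id, chrom = ch, bin_start = 0:9 * 1e6,
               r = c(rep(mi, 2), rep(0, 5), rep(mn, 3)))
  }
  rbind(one("1A", mA_I, mA_N), one("1B", mB_I, mB_N), one("1R", mR_I, mR_N))
}
toy_spec <- arm_region_spec(c("1A" = 1e7, "1B" = 1e7, "1R" = 1e7),
                            i_window = 2e6, n_window = 3e6)

test_that("features follow the printed formulas with natural log", {
  rt <- rbind(toy_track("a", 1, 0, 3, 0, 2, 0),
              toy_track("b", 0.5, 0, 1, 0, 1, 0))
  ft <- extract_karyotype_features(rt, toy_spec)
  expect_equal(ft$featureA[ft$sample_id == "a"], -log(1 * 2))
  expect_equal(ft$featureB[ft$sample_id == "a"], -log(3 * 2))
  expect_equal(ft$featureA[ft$sample_id == "b"], -log(0.5 * 1))
  expect_false(any(ft$substitutedA))
})

test_that("negative or zero log arguments trigger the min-substitution rule", {
  rt <- rbind(toy_track("neg", -3, 0, 1, 0, 0, -6),   # argA = (-3)(6) < 0
              toy_track("pos", 1, 0, 2, 0, 2, 0),
              toy_track("flat", 0, 0, 0, 0, 0, 0))    # argument exactly 0
  ft <- extract_karyotype_features(rt, toy_spec)
  get <- function(id, col) ft[[col]][ft$sample_id == id]
  expect_true(get("neg", "substitutedA"))
  expect_true(get("flat", "substitutedA"))
  expect_false(get("pos", "substitutedA"))
  min_defined <- min(ft$featureA[!ft$substitutedA])
  expect_equal(get("neg", "featureA"), min_defined)
  expect_equal(get("flat", "featureA"), min_defined)
  # after substitution the overall minimum equals the defined minimum
  expect_equal(min(ft$featureA), min_defined)
  # cohort-wide undefined feature is an error
  rt_bad <- toy_track("only", -1, 0, 1, 0, 1, 0)
  expect_error(extract_karyotype_features(rt_bad, toy_spec),
               "featureA undefined")
})

test_that("features agree with the direct-summation oracle to 1e-9", {
  cohort <- simulate_depth_cohort(depth_sim_config(n_per_class = 4,
                                                   seed = 31))
  ref <- cohort$reference
  ref$rpmm <- compute_rpmm(ref$count, sum(ref$count))
  prof <- cohort$profiles
  prof <- prof[order(prof$sample_id, prof$chrom, prof$bin_start)]
  prof[, rpmm := compute_rpmm(count, sum(count)), by = sample_id]
  ref <- ref[order(ref$chrom, ref$bin_start)]
  prof[, r := rpmm - rep(ref$rpmm, length.out = .N)]
  lens <- c("1A" = 594e6, "1B" = 690e6, "1R" = 980e6)
  ft <- extract_karyotype_features(prof, arm_region_spec(lens))
  orc <- oracle_features(prof, lens)
  m <- match(ft$sample_id, orc$sample_id)
  expect_equal(ft$featureA, orc$featureA[m], tolerance = 1e-9)
  expect_equal(ft$featureB, orc$featureB[m], tolerance = 1e-9)
})

test_that("SVM separates a clean two-cluster toy set and rejects one class", {
  ftr <- data.frame(featureA = c(rnorm(20, -5, 0.1), rnorm(20, 5, 0.1)),
                    featureB = c(rnorm(20, -5, 0.1), rnorm(20, 5, 0.1)))
  lab <- rep(c("x", "y"), each = 20)
  m <- fit_karyotype_classifier(ftr, lab)
  expect_equal(classify_karyotypes(m, ftr), lab)
  expect_error(fit_karyotype_classifier(ftr, rep("x", 40)),
               "at least two classes")
  expect_error(classify_karyotypes(m, data.frame(featureA = NA_real_,
                                                 featureB = 1)),
               "non-finite")
})

test_that("shuffled labels drop cross-validated accuracy to chance", {
  set.seed(7)
  ftr <- data.frame(featureA = c(rnorm(60, -5), rnorm(60, 5)),
                    featureB = rnorm(120))
  lab <- sample(rep(c("x", "y"), each = 60))  # labels carry no signal
  cv <- cross_validate_classifier(ftr, lab, train_sizes = 60L,
                                  repeats = 30L, seed = 8)
  expect_lt(abs(mean(cv$accuracy$accuracy) - 0.5), 0.12)
})

test_that("train-size cross-validation bookkeeping and errors", {
  ftr <- data.frame(featureA = c(rnorm(30, -5, .1), rnorm(30, 5, .1)),
                    featureB = c(rnorm(30, -5, .1), rnorm(30, 5, .1)))
  lab <- rep(c("x", "y"), each = 30)
  cv <- cross_validate_classifier(ftr, lab, train_sizes = c(10L, 20L),
                                  repeats = 5L, seed = 3)
  expect_equal(nrow(cv$accuracy), 10)
  expect_equal(table(cv$accuracy$train_size)[["10"]], 5)
  expect_equal(cv$summary$mean, c(1, 1))  # separable at every size
  expect_error(cross_validate_classifier(ftr, lab, train_sizes = 60L),
               "smaller than the dataset")
})

test_that("noise-free simulated profiles classify to their true labels", {
  cfg <- depth_sim_config(n_per_class = 8, dispersion = 0.005, seed = 12)
  cohort <- simulate_depth_cohort(cfg)
  ft <- cohort_features(cohort)
  lab <- cohort$labels[ft$sample_id]
  m <- fit_karyotype_classifier(ft, lab)
  # the samples defining the two substitution minima sit at the shared
  # corner point by construction, so allow at most those two to miss
  expect_gte(mean(classify_karyotypes(m, ft) == unname(lab)),
             1 - 2 / length(lab))
})

test_that("sqrt percent-difference matrix endpoints and missing pairs", {
  calls <- rbind(a = c(0, 0, 2, 2), b = c(0, 0, 2, 2),
                 c = c(2, 2, 0, 0), d = c(0, 2, 0, 2))
  m <- sqrt_diff_heatmap_matrix(calls)
  expect_equal(m["a", "b"], 0)
  expect_equal(m["a", "c"], 10)          # differ everywhere: sqrt(100)
  expect_equal(m["a", "d"], sqrt(50))    # half the sites differ
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 0, b = 0, c = 0, d = 0))
  calls2 <- rbind(a = c(0, NA), b = c(NA, 2))
  expect_true(is.na(sqrt_diff_heatmap_matrix(calls2)["a", "b"]))
})
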