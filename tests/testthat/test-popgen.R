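test_that("site filters reproduce hand-counted survivor sets", {
  # 10 sites; sites 1-3 carry 40% missing data (2 of 5 samples)
  calls <- matrix(1L, 5, 10)
  calls[1:2, 1:3] <- NA_integer_
  calls[, 10] <- 0L            # monomorphic site
  calls[1, 10] <- 1L           # one het -> maf 0.1
  gm <- make_toy_gm(calls)
  kept <- filter_genotypes(gm, max_missing = 0.3, maf = NULL)
  expect_equal(attr(kept, "n_kept"), 7L)
  # a monomorphic site fails any positive MAF threshold
  mono <- make_toy_gm(cbind(matrix(1L, 5, 3), matrix(0L, 5, 1)))
  expect_equal(attr(filter_genotypes(mono, maf = 0.01), "n_kept"), 3L)
  # filtering is idempotent
  once <- filter_genotypes(gm, max_missing = 0.3, maf = 0.01)
  twice <- filter_genotypes(once, max_missing = 0.3, maf = 0.01)
  expect_equal(once$calls, twice$calls)
  # when every site carries some missingness, a zero tolerance removes all
  all_miss <- calls
  all_miss[1, ] <- NA_integer_
  expect_warning(filter_genotypes(make_toy_gm(all_miss), max_missing = 0),
                 "all sites removed")
})

test_that("depth filter masks calls before missingness is assessed", {
  calls <- matrix(2L, 4, 2)
  depth <- matrix(10L, 4, 2)
  depth[1:2, 1] <- 3L   # two shallow calls push site 1 to 50% missing
  gm <- genotype_matrix(calls, data.frame(chrom = "c", pos = 1:2,
                                          ref = "A", alt = "G"),
                        depth = depth)
  kept <- filter_genotypes(gm, max_missing = 0.3, maf = NULL, min_depth = 6)
  expect_equal(attr(kept, "n_kept"), 1L)
  expect_equal(kept$sites$pos, 2)
})

test_that("stringent preset applies depth 6 / missing 5% / quality 250", {
  sim <- simulate_structured_genotypes(pop_sim_config(
    n_clusters = 2, samples_per_cluster = 30, n_sites = 400, seed = 44))
  gm <- sim$genotypes
  out <- stringent_filter_preset(gm)
  expect_true(all(out$quality >= 250))
  masked <- gm$calls
  masked[gm$depth < 6] <- NA_integer_
  expect_true(all(colMeans(is.na(masked[, match(
    paste(out$sites$chrom, out$sites$pos),
    paste(gm$sites$chrom, gm$sites$pos))])) <= 0.05))
  expect_lt(n_sites(out), n_sites(gm))
})

test_that("PCA + k-means recovers planted clusters", {
  sim <- simulate_structured_genotypes(pop_sim_config(
    n_clusters = 2, samples_per_cluster = 15, n_sites = 600,
    divergence = 0.3, seed = 3))
  cm <- pca_and_kmeans(sim$genotypes, n_components = 3, k = 2)
  tab <- table(cm$assignments, sim$cluster)
  expect_equal(sum(apply(tab, 2, max)), 30)  # perfect up to label swap
  expect_error(pca_and_kmeans(sim$genotypes, k = 31), "exceed")
})

test_that("duplicated samples receive identical PC scores", {
  sim <- simulate_structured_genotypes(pop_sim_config(
    n_clusters = 2, samples_per_cluster = 5, n_sites = 300, seed = 9))
  gm <- sim$genotypes
  calls <- rbind(gm$calls, dup = gm$calls[1, ])
  gm2 <- genotype_matrix(calls, gm$sites)
  cm <- pca_and_kmeans(gm2, k = 2)
  expect_equal(cm$pc_scores[1, ], cm$pc_scores["dup", ],
               ignore_attr = TRUE)
})

test_that("seven simulated clusters are recovered from three PCs", {
  sim <- simulate_structured_genotypes(pop_sim_config(seed = 3))
  cm <- pca_and_kmeans(sim$genotypes)  # defaults: 3 PCs, k = 7
  tab <- table(cm$assignments, sim$cluster)
  agreement <- sum(apply(tab, 2, max)) / length(sim$cluster)
  expect_gt(agreement, 0.9)
})

test_that("windowed IBS endpoints, window arithmetic and range", {
  calls <- rbind(focal = rep(0L, 250), same = rep(0L, 250),
                 opp = rep(2L, 250), mixed = rep(c(0L, 2L), 125))
  gm <- make_toy_gm(calls)
  ibs <- windowed_ibs(gm, "focal")
  # 250 sites, window 100, step 25 -> 7 windows per sample
  expect_equal(nrow(ibs), 7 * 3)
  expect_true(all(ibs$value[ibs$sample_id == "same"] == 1))
  expect_true(all(ibs$value[ibs$sample_id == "opp"] == 0))
  expect_true(all(ibs$value >= 0 & ibs$value <= 1))
  expect_equal(unique(ibs$value[ibs$sample_id == "mixed"]), 0.5)
  # window position is the mean position of its variants
  expect_equal(sort(unique(ibs$mean_pos))[1], mean((1:100) * 1000))
})

test_that("windowed Fst hits the 0 and 1 endpoints", {
  fixed <- make_toy_gm(rbind(matrix(0L, 5, 120), matrix(2L, 5, 120)))
  f <- windowed_fst(fixed, list(a = sprintf("s%02d", 1:5),
                                b = sprintf("s%02d", 6:10)))
  expect_true(all(f$value == 1))
  sim <- simulate_structured_genotypes(pop_sim_config(
    n_clusters = 2, samples_per_cluster = 50, n_sites = 500,
    divergence = 0, missing_rate = 0, seed = 5))
  f0 <- windowed_fst(sim$genotypes, split(names(sim$cluster), sim$cluster))
  expect_lt(abs(mean(f0$value, na.rm = TRUE)), 0.02)
})

test_that("Fst equals the brute-force variance-components oracle", {
  set.seed(41)
  for (rep_i in 1:5) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1); S <- sample(1:5, 1)
    c1 <- matrix(sample(c(0:2, NA), n1 * S, TRUE, c(.3, .3, .3, .1)), n1, S)
    c2 <- matrix(sample(c(0:2, NA), n2 * S, TRUE, c(.3, .3, .3, .1)), n2, S)
    gm <- make_toy_gm(rbind(c1, c2))
    groups <- list(a = rownames(gm$calls)[1:n1],
                   b = rownames(gm$calls)[(n1 + 1):(n1 + n2)])
    f <- windowed_fst(gm, groups, window = S, step = S)
    orc <- oracle_fst(c1, c2)
    if (is.finite(orc) && nrow(f)) {
      expect_equal(f$value, orc, tolerance = 1e-9)
    }
    # allele-label swap leaves the estimator unchanged
    gm_sw <- make_toy_gm(rbind(2L - c1, 2L - c2))
    f_sw <- windowed_fst(gm_sw, groups, window = S, step = S)
    if (nrow(f)) expect_equal(f_sw$value, f$value, tolerance = 1e-12)
  }
})

test_that("outgroup consensus polarization follows the majority rule", {
  ann <- data.frame(chrom = "c", pos = 1:4,
                    out1 = c("A", "A", "G", "C"),
                    out2 = c("A", "G", "G", "C"),
                    out3 = c("G", "T", "G", "C"))
  sites <- data.frame(chrom = "c", pos = 1:4,
                      ref = c("A", "A", "G", "A"),
                      alt = c("G", "G", "A", "G"))
  pol <- polarize_by_outgroup(ann, sites)
  expect_equal(pol$ancestral, c("A", NA, "G", NA))
  expect_equal(pol$status,
               c("ok", "no_majority", "ok", "allele_mismatch"))
})

test_that("Pn/Ps reporting threshold and infinity flag", {
  # 120 sites in one window; group of 4 samples; derived = alt (ancestral
  # = ref everywhere via a clean triple)
  S <- 120
  calls <- matrix(0L, 4, S)
  calls[1, 1:10] <- 1L   # sites 1-10 segregate
  effect <- rep("other", S)
  effect[1:5] <- "nonsynonymous"; effect[6:10] <- "synonymous"
  gm <- make_toy_gm(calls)
  ann <- data.frame(chrom = "chr1", pos = gm$sites$pos, effect = effect,
                    out1 = "A", out2 = "A", out3 = "A")
  pn <- windowed_pnps(gm, ann, rownames(gm$calls), window = S, step = S)
  expect_equal(pn$pn, 5L)
  expect_equal(pn$ps, 5L)
  expect_equal(pn$value, 1)          # 5 + 5 meets the >= 10 rule
  expect_false(pn$suppressed)
  # 4 + 5 = 9 falls below the threshold -> suppressed
  effect9 <- effect; effect9[5] <- "other"
  ann9 <- ann; ann9$effect <- effect9
  pn9 <- windowed_pnps(gm, ann9, rownames(gm$calls), window = S, step = S)
  expect_true(pn9$suppressed)
  expect_true(is.na(pn9$value))
  # Ps = 0 with the threshold met reports an infinite ratio, flagged
  calls2 <- matrix(0L, 4, S); calls2[1, 1:10] <- 1L
  effect_inf <- rep("nonsynonymous", S)
  gm2 <- make_toy_gm(calls2)
  ann_inf <- data.frame(chrom = "chr1", pos = gm2$sites$pos,
                        effect = effect_inf,
                        out1 = "A", out2 = "A", out3 = "A")
  pninf <- windowed_pnps(gm2, ann_inf, rownames(gm2$calls),
                         window = S, step = S)
  expect_true(pninf$infinite)
  expect_equal(pninf$value, Inf)
})

test_that("selection differential lowers the selected group's Pn/Ps", {
  sim <- simulate_structured_genotypes(pop_sim_config(
    n_clusters = 2, samples_per_cluster = 12, n_sites = 2000,
    divergence = 0.1, sel_differential = 0.2, sel_cluster = 1, seed = 8))
  gm <- sim$genotypes
  pol <- polarize_by_outgroup(sim$annotation, gm$sites)
  g <- split(names(sim$cluster), sim$cluster)
  v1 <- windowed_pnps(gm, sim$annotation, g[[1]], polarized = pol)
  v2 <- windowed_pnps(gm, sim$annotation, g[[2]], polarized = pol)
  expect_lt(mean(v1$value, na.rm = TRUE), mean(v2$value, na.rm = TRUE))
  expect_error(pop_sim_config(sel_differential = 0), "sel_differential")
  expect_error(pop_sim_config(sel_differential = 1.2), "sel_differential")
})

test_that("Patterson's D endpoints, symmetry and the brute-force oracle", {
  pol_clean <- function(gm) data.frame(chrom = gm$sites$chrom,
                                       pos = gm$sites$pos,
                                       ancestral = gm$sites$ref,
                                       status = "ok")
  # p1 = p2 (both segregating) at every site -> D = 0
  gm <- make_toy_gm(rbind(rep(1L, 20), rep(1L, 20), rep(2L, 20)))
  ids <- rownames(gm$calls)
  d0 <- patterson_d(gm, ids[1], ids[2], ids[3], pol_clean(gm))
  expect_equal(d0$D, 0)
  # pure ABBA -> D = 1
  gmA <- make_toy_gm(rbind(rep(0L, 20), rep(2L, 20), rep(2L, 20)))
  idsA <- rownames(gmA$calls)
  expect_equal(patterson_d(gmA, idsA[1], idsA[2], idsA[3],
                           pol_clean(gmA))$D, 1)
  # swap of P1 and P2 flips the sign; |D| <= 1
  set.seed(14)
  calls <- matrix(sample(c(0:2, NA), 6 * 40, TRUE, c(.3, .3, .3, .1)), 6, 40)
  gmr <- make_toy_gm(calls)
  idr <- rownames(gmr$calls)
  g1 <- idr[1:2]; g2 <- idr[3:4]; g3 <- idr[5:6]
  pol <- pol_clean(gmr)
  d12 <- patterson_d(gmr, g1, g2, g3, pol)
  d21 <- patterson_d(gmr, g2, g1, g3, pol)
  expect_equal(d12$D, -d21$D)
  expect_lte(abs(d12$D), 1)
  # matches the direct-loop oracle to 1e-9
  expect_equal(d12$D, oracle_d(calls[1:2, ], calls[3:4, ], calls[5:6, ]),
               tolerance = 1e-9)
  # a single informative block cannot support a jackknife
  expect_true(is.na(d12$se) || d12$n_blocks >= 2)
})

test_that("jackknife flags datasets with fewer than two blocks", {
  gm <- make_toy_gm(rbind(rep(0L, 10), rep(2L, 10), rep(2L, 10)),
                    pos = 1:10 * 100)  # all sites in one 5-Mb block
  ids <- rownames(gm$calls)
  pol <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                    ancestral = "A", status = "ok")
  d <- patterson_d(gm, ids[1], ids[2], ids[3], pol)
  expect_equal(d$n_blocks, 1L)
  expect_true(is.na(d$se) && is.na(d$Z))
})

test_that("a gene-flow tract raises IBS between donor and recipient lines", {
  tr <- list(list(donor = 3, recipient = 4, start = 20e6, end = 60e6))
  sim <- simulate_structured_genotypes(pop_sim_config(
    n_clusters = 4, samples_per_cluster = 8, n_sites = 2000,
    divergence = 0.3, tracts = tr, seed = 77))
  gm <- sim$genotypes
  focal <- names(sim$cluster)[sim$cluster == 3][1]
  ibs <- windowed_ibs(gm, focal)
  c4 <- names(sim$cluster)[sim$cluster == 4]
  vals <- ibs[ibs$sample_id %in% c4, ]
  inside <- vals$mean_pos >= 20e6 & vals$mean_pos <= 60e6
  expect_gt(mean(vals$value[inside]), mean(vals$value[!inside]) + 0.05)
})

test_that("genotype simulator is seed-deterministic", {
  cfg <- pop_sim_config(n_clusters = 2, samples_per_cluster = 4,
                        n_sites = 100, seed = 21)
  expect_identical(simulate_structured_genotypes(cfg),
                   simulate_structured_genotypes(cfg))
})
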