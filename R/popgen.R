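#' Filter a genotype matrix on missingness, frequency, depth and quality
#'
#' Implements the two standard filtering regimes for this kind of panel: a permissive
#' regime (maximum 30% missing data, minor allele frequency >= 1%) used for
#' clustering, and a stringent regime (per-call read depth >= 6, maximum 5%
#' missing data, site call quality >= 250) used for windowed statistics
#' ([stringent_filter_preset()]). The per-call depth filter sets calls to
#' missing *before* site-level missingness is computed.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Maximum fraction of missing calls per site.
#' @param maf Minimum minor allele frequency (among called genotypes);
#'   `NULL` disables.
#' @param min_depth Minimum per-call read depth; calls below it are set to
#'   missing. `NULL` disables (or when `gm` has no depth).
#' @param min_quality Minimum site call quality; `NULL` disables.
#' @return The filtered `genotype_matrix`, with attributes `n_input`,
#'   `n_kept` and `n_removed` recording site counts.
#' @export
filter_genotypes <- function(gm, max_missing = 0.3, maf = 0.01,
                             min_depth = NULL, min_quality = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (max_missing < 0 || max_missing > 1) {
    stop("`max_missing` must be in [0, 1]", call. = FALSE)
  }
  calls <- gm$calls
  if (!is.null(min_depth) && !is.null(gm$depth)) {
    calls[gm$depth < min_depth] <- NA_integer_
  }
  miss <- colMeans(is.na(calls))
  keep <- miss <= max_missing
  if (!is.null(maf)) {
    p <- colMeans(calls, na.rm = TRUE) / 2
    p[is.nan(p)] <- 0
    keep <- keep & pmin(p, 1 - p) >= maf
  }
  if (!is.null(min_quality) && !is.null(gm$quality)) {
    keep <- keep & gm$quality >= min_quality
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("all sites removed by filtering", call. = FALSE)
  out <- genotype_matrix(calls[, keep, drop = FALSE], gm$sites[keep, ],
                         if (!is.null(gm$depth))
                           gm$depth[, keep, drop = FALSE],
                         if (!is.null(gm$quality)) gm$quality[keep])
  attr(out, "n_input") <- length(keep)
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' The stringent filter preset
#'
#' Depth >= 6, missingness <= 5%, site quality >= 250 — the regime used for
#' the windowed IBS and Fst analyses.
#'
#' @param gm A [genotype_matrix()].
#' @return Filtered matrix, as from [filter_genotypes()].
#' @export
stringent_filter_preset <- function(gm) {
  filter_genotypes(gm, max_missing = 0.05, maf = NULL,
                   min_depth = 6, min_quality = 250)
}

#' PCA and k-means clustering of a genotype panel
#'
#' Mean-imputes missing dosages per site, centers, takes the top principal
#' components by singular value decomposition and clusters the component
#' scores with k-means. Defaults: the first
#' three components and k = 7. k-means uses many random restarts under a
#' fixed seed, keeping the best within-cluster sum of squares, because a
#' single start is seed-fragile.
#'
#' @param gm A [genotype_matrix()].
#' @param n_components Number of leading principal components to keep.
#' @param k Number of clusters.
#' @param restarts k-means restarts (`nstart`).
#' @param seed RNG seed for k-means.
#' @return List of class `cluster_model` with `pc_scores` (samples x
#'   components), `assignments` (named integer vector), `kmeans` (the
#'   underlying fit) and `var_explained`.
#' @export
pca_and_kmeans <- function(gm, n_components = 3L, k = 7L, restarts = 25L,
                           seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- n_samples(gm)
  if (k > n) stop("`k` cannot exceed the number of samples", call. = FALSE)
  x <- gm$calls
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(gm$calls)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  local_seed(seed)
  km <- kmeans(scores, centers = k, nstart = restarts, iter.max = 100)
  assignments <- km$cluster
  names(assignments) <- rownames(scores)
  structure(list(pc_scores = scores, assignments = assignments, kmeans = km,
                 var_explained = sv$d^2 / sum(sv$d^2)),
            class = "cluster_model")
}

# Sliding site-index windows within one chromosome: starts of `window`
# consecutive sites every `step` sites; trailing partial windows dropped.
.site_windows <- function(n, window, step) {
  if (n < window) return(integer(0))
  seq(1L, n - window + 1L, by = step)
}

#' Windowed identity-by-state against a focal sample
#'
#' IBS between the focal sample and every other sample, in sliding windows
#' of consecutive SNPs (defaults: 100 SNP loci at intervals of 25). Per
#' co-called site the similarity is `1 - |dosage difference| / 2`; the
#' window value is its mean. Windows never span chromosomes; trailing
#' windows with fewer than `window` sites are dropped.
#'
#' @param gm A [genotype_matrix()].
#' @param focal_sample Sample id of the reference line.
#' @param window,step Window length and step in SNP loci.
#' @return `data.table` with `chrom`, `mean_pos` (mean position of the
#'   window's variants), `sample_id`, `value`, `n_sites` (co-called sites;
#'   `value` is `NA` when zero) and `statistic = "IBS"`.
#' @export
windowed_ibs <- function(gm, focal_sample, window = 100L, step = 25L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!focal_sample %in% rownames(gm$calls)) {
    stop("focal sample not in the matrix", call. = FALSE)
  }
  others <- setdiff(rownames(gm$calls), focal_sample)
  out <- list()
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    idx <- idx[order(gm$sites$pos[idx])]
    starts <- .site_windows(length(idx), window, step)
    foc <- gm$calls[focal_sample, idx]
    pos <- gm$sites$pos[idx]
    for (s in starts) {
      w <- s:(s + window - 1L)
      fw <- foc[w]
      for (id in others) {
        sw <- gm$calls[id, idx[w]]
        ok <- !is.na(fw) & !is.na(sw)
        out[[length(out) + 1L]] <- data.table(
          chrom = ch, mean_pos = mean(pos[w]), sample_id = id,
          value = if (any(ok)) mean(1 - abs(fw[ok] - sw[ok]) / 2)
                  else NA_real_,
          n_sites = sum(ok), statistic = "IBS")
      }
    }
  }
  if (!length(out)) {
    return(data.table(chrom = character(), mean_pos = numeric(),
                      sample_id = character(), value = numeric(),
                      n_sites = integer(), statistic = character()))
  }
  rbindlist(out)
}

# Per-site Weir-Hill variance-component quantities for a set of groups.
# calls: samples x sites; groups: list of row-index vectors.
# Returns per-site numerator (MSP - MSG) and denominator
# (MSP + (n_c - 1) MSG) of the ANOVA Fst estimator; NA where undefined.
.fst_site_components <- function(calls, groups) {
  r <- length(groups)
  S <- ncol(calls)
  n_g <- matrix(0, r, S)   # called allele counts per group
  p_g <- matrix(NA_real_, r, S)
  for (g in seq_len(r)) {
    sub <- calls[groups[[g]], , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    n_g[g, ] <- 2 * n_called
    p_g[g, ] <- colSums(sub, na.rm = TRUE) / (2 * n_called)
  }
  N <- colSums(n_g)
  ok <- colSums(n_g > 0) == r & (N - r) > 0
  pbar <- colSums(n_g * p_g) / N
  MSP <- colSums(n_g * (p_g - rep(pbar, each = r))^2) / (r - 1)
  MSG <- colSums(n_g * p_g * (1 - p_g)) / (N - r)
  n_c <- (N - colSums(n_g^2) / N) / (r - 1)
  num <- MSP - MSG
  den <- MSP + (n_c - 1) * MSG
  num[!ok] <- NA_real_
  den[!ok] <- NA_real_
  list(num = num, den = den)
}

#' Windowed Fst between groups (Weir-Hill variance components)
#'
#' Pairwise Fst between designated sample groups in the same sliding
#' windows as [windowed_ibs()]. Per site, allele-frequency variance
#' components are computed from the called genotypes of the two groups
#' (the unequal-sample-size ANOVA estimator of Weir & Hill 2002); the
#' window value is the ratio of the summed numerator to the summed
#' denominator over the window's sites ("ratio of sums"), not a mean of
#' per-site ratios.
#'
#' @param gm A [genotype_matrix()].
#' @param groups Named list of character vectors of sample ids.
#' @param window,step Window length and step in SNP loci.
#' @return `data.table` with `chrom`, `mean_pos`, `pair`, `value`,
#'   `n_sites` (sites contributing), `statistic = "Fst"`.
#' @export
windowed_fst <- function(gm, groups, window = 100L, step = 25L) {
  stopifnot(inherits(gm, "genotype_matrix"), length(groups) >= 2)
  if (is.null(names(groups))) {
    names(groups) <- paste0("G", seq_along(groups))
  }
  idx_of <- function(ids) {
    i <- match(ids, rownames(gm$calls))
    if (anyNA(i)) stop("group sample not in the matrix", call. = FALSE)
    i
  }
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  out <- list()
  for (pr in pairs) {
    comp <- .fst_site_components(gm$calls,
                                 list(idx_of(groups[[pr[1]]]),
                                      idx_of(groups[[pr[2]]])))
    for (ch in unique(gm$sites$chrom)) {
      idx <- which(gm$sites$chrom == ch)
      idx <- idx[order(gm$sites$pos[idx])]
      starts <- .site_windows(length(idx), window, step)
      pos <- gm$sites$pos[idx]
      for (s in starts) {
        w <- idx[s:(s + window - 1L)]
        num <- comp$num[w]; den <- comp$den[w]
        ok <- !is.na(num)
        value <- if (any(ok) && sum(den[ok]) != 0)
          sum(num[ok]) / sum(den[ok]) else NA_real_
        out[[length(out) + 1L]] <- data.table(
          chrom = ch, mean_pos = mean(pos[s:(s + window - 1L)]),
          pair = paste(pr, collapse = ":"), value = value,
          n_sites = sum(ok), statistic = "Fst")
      }
    }
  }
  rbindlist(out)
}

#' Assign ancestral alleles by outgroup consensus
#'
#' The ancestral state of each variant is the allele occurring at least
#' twice in the three outgroup-subgenome alleles; when the triple carries
#' three distinct alleles no allele claims a majority and the variant is
#' omitted. A majority allele matching neither `ref` nor `alt` is also
#' omitted (flagged separately).
#'
#' @param annotation `data.frame` with `chrom`, `pos`, `out1`, `out2`,
#'   `out3`.
#' @param sites `data.frame` with `chrom`, `pos`, `ref`, `alt` (the
#'   variants to polarize, e.g. `gm$sites`).
#' @return `data.table` with `chrom`, `pos`, `ancestral` (`NA` when
#'   omitted) and `status` in `ok`, `no_majority`, `allele_mismatch`,
#'   `unannotated`.
#' @export
polarize_by_outgroup <- function(annotation, sites) {
  ann <- as.data.table(annotation)
  st <- as.data.table(sites)[, .(chrom, pos, ref, alt)]
  m <- merge(st, ann, by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
  maj <- apply(as.matrix(m[, .(out1, out2, out3)]), 1, function(tr) {
    if (anyNA(tr)) return(NA_character_)
    tab <- table(tr)
    if (max(tab) >= 2) names(tab)[which.max(tab)] else NA_character_
  })
  status <- rep("ok", nrow(m))
  status[is.na(m$out1)] <- "unannotated"
  status[!is.na(m$out1) & is.na(maj)] <- "no_majority"
  mismatch <- !is.na(maj) & maj != m$ref & maj != m$alt
  status[mismatch] <- "allele_mismatch"
  ancestral <- maj
  ancestral[status != "ok"] <- NA_character_
  data.table(chrom = m$chrom, pos = m$pos, ancestral = ancestral,
             status = status)
}

# Derived-allele dosage matrix: flips dosages where the ancestral allele is
# the alt allele; NA columns where unpolarized.
.derived_dosage <- function(gm, polarized) {
  key_gm <- paste(gm$sites$chrom, gm$sites$pos)
  key_pol <- paste(polarized$chrom, polarized$pos)
  anc <- polarized$ancestral[match(key_gm, key_pol)]
  d <- gm$calls
  flip <- !is.na(anc) & anc == gm$sites$alt
  d[, flip] <- 2L - d[, flip]
  d[, is.na(anc)] <- NA_integer_
  d
}

#' Windowed Pn/Ps for a sample group
#'
#' Counts nonsynonymous (Pn) and synonymous (Ps) polarizable sites whose
#' derived allele segregates within the group, in the same windows as
#' [windowed_fst()], and reports their ratio. Windows where
#' `Pn + Ps < min_total` are suppressed (`value` `NA`, `suppressed` flag);
#' `Ps = 0` with the threshold met is reported as an infinite ratio with
#' the `infinite` flag set.
#'
#' @param gm A [genotype_matrix()].
#' @param annotation Site annotation with `effect` plus outgroup triple
#'   columns (as from the simulator), or pre-polarized via `polarized`.
#' @param group Character vector of sample ids forming the group.
#' @param polarized Optional result of [polarize_by_outgroup()]; computed
#'   from `annotation` when absent.
#' @param window,step Window length and step in SNP loci.
#' @param min_total Minimum `Pn + Ps` for a reported bin (default 10, i.e.
#'   the combined count must exceed nine).
#' @param segregating `"polymorphic"` (default) counts sites whose derived
#'   allele frequency in the group lies strictly between 0 and 1;
#'   `"present"` merely requires the derived allele to occur.
#' @return `data.table` with `chrom`, `mean_pos`, `value`, `pn`, `ps`,
#'   `n_sites`, `suppressed`, `infinite`, `statistic = "PnPs"`.
#' @export
windowed_pnps <- function(gm, annotation, group, polarized = NULL,
                          window = 100L, step = 25L, min_total = 10L,
                          segregating = c("polymorphic", "present")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  segregating <- match.arg(segregating)
  rows <- match(group, rownames(gm$calls))
  if (anyNA(rows)) stop("group sample not in the matrix", call. = FALSE)
  if (is.null(polarized)) {
    polarized <- polarize_by_outgroup(annotation, gm$sites)
  }
  d <- .derived_dosage(gm, polarized)[rows, , drop = FALSE]
  ann <- as.data.table(annotation)
  key_gm <- paste(gm$sites$chrom, gm$sites$pos)
  eff <- ann$effect[match(key_gm, paste(ann$chrom, ann$pos))]

  n_called <- colSums(!is.na(d))
  freq <- colSums(d, na.rm = TRUE) / (2 * n_called)
  seg <- if (segregating == "polymorphic") {
    n_called > 0 & freq > 0 & freq < 1
  } else {
    n_called > 0 & freq > 0
  }
  seg[is.na(seg)] <- FALSE
  is_n <- seg & !is.na(eff) & eff == "nonsynonymous"
  is_s <- seg & !is.na(eff) & eff == "synonymous"

  out <- list()
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    idx <- idx[order(gm$sites$pos[idx])]
    starts <- .site_windows(length(idx), window, step)
    pos <- gm$sites$pos[idx]
    for (s in starts) {
      w <- idx[s:(s + window - 1L)]
      pn <- sum(is_n[w]); ps <- sum(is_s[w])
      suppressed <- (pn + ps) < min_total
      infinite <- !suppressed && ps == 0
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, mean_pos = mean(pos[s:(s + window - 1L)]),
        value = if (suppressed) NA_real_ else pn / ps,
        pn = pn, ps = ps, n_sites = pn + ps,
        suppressed = suppressed, infinite = infinite, statistic = "PnPs")
    }
  }
  rbindlist(out)
}

#' Patterson's D (ABBA-BABA) with block jackknife
#'
#' Allele-frequency D statistic for three test groups against a polarized
#' outgroup:
#' `D = sum((1-p1) p2 p3 - p1 (1-p2) p3) / sum((1-p1) p2 p3 + p1 (1-p2) p3)`
#' where `p` are derived-allele frequencies per group and the sums run over
#' polarizable sites with data in all three groups. The standard error is
#' estimated by a delete-one block jackknife over contiguous genomic blocks
#' (default 5 Mb); `Z = D / se`.
#'
#' @param gm A [genotype_matrix()].
#' @param p1,p2,p3 Character vectors of sample ids for the three test
#'   groups (P1, P2 sisters; P3 the candidate donor).
#' @param polarized Result of [polarize_by_outgroup()] covering `gm$sites`.
#' @param block Jackknife block length in bp (default 5e6).
#' @return List with `D`, `se`, `Z`, `n_sites` (informative sites),
#'   `n_blocks`, `abba`, `baba`. `se`/`Z` are `NA` with fewer than two
#'   informative blocks.
#' @export
patterson_d <- function(gm, p1, p2, p3, polarized, block = 5e6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- .derived_dosage(gm, polarized)
  gfreq <- function(ids) {
    rows <- match(ids, rownames(gm$calls))
    if (anyNA(rows)) stop("group sample not in the matrix", call. = FALSE)
    sub <- d[rows, , drop = FALSE]
    n <- colSums(!is.na(sub))
    f <- colSums(sub, na.rm = TRUE) / (2 * n)
    f[n == 0] <- NA_real_
    f
  }
  f1 <- gfreq(p1); f2 <- gfreq(p2); f3 <- gfreq(p3)
  abba <- (1 - f1) * f2 * f3
  baba <- f1 * (1 - f2) * f3
  ok <- !is.na(abba) & !is.na(baba)
  num <- abba - baba
  den <- abba + baba
  D <- sum(num[ok]) / sum(den[ok])
  blk <- paste(gm$sites$chrom, floor((gm$sites$pos - 1) / block))
  blocks <- unique(blk[ok & den > 0])
  if (length(blocks) < 2) {
    return(list(D = D, se = NA_real_, Z = NA_real_, n_sites = sum(ok),
                n_blocks = length(blocks),
                abba = sum(abba[ok]), baba = sum(baba[ok])))
  }
  tot_num <- sum(num[ok]); tot_den <- sum(den[ok])
  Dj <- vapply(blocks, function(b) {
    inb <- ok & blk == b
    (tot_num - sum(num[inb])) / (tot_den - sum(den[inb]))
  }, numeric(1))
  B <- length(blocks)
  se <- sqrt((B - 1) / B * sum((Dj - mean(Dj))^2))
  list(D = D, se = se, Z = D / se, n_sites = sum(ok), n_blocks = B,
       abba = sum(abba[ok]), baba = sum(baba[ok]))
}
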