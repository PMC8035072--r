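# Independent brute-force oracles, written as direct transliterations of the
# defining formulas (explicit loops, no shared code with the package paths
# they check).

# Karyotype features by naive direct summation over bins.
oracle_features <- function(r_tracks, chrom_lengths, i_window = 200e6,
                            n_window = 300e6, bin_size = 1e6) {
  r_tracks <- as.data.frame(r_tracks)
  samples <- unique(r_tracks$sample_id)
  wmean <- function(df, ch, from_start, width) {
    L <- chrom_lengths[[ch]]
    vals <- c()
    for (k in seq_len(nrow(df))) {
      if (df$chrom[k] != ch) next
      b0 <- df$bin_start[k]; b1 <- b0 + bin_size
      inside <- if (from_start) b1 <= width else b0 >= L - width
      if (inside) vals <- c(vals, df$r[k])
    }
    mean(vals)
  }
  argA <- argB <- numeric(length(samples))
  for (i in seq_along(samples)) {
    df <- r_tracks[r_tracks$sample_id == samples[i], ]
    dA <- wmean(df, "1A", TRUE, i_window) - wmean(df, "1A", FALSE, n_window)
    dB <- wmean(df, "1B", TRUE, i_window) - wmean(df, "1B", FALSE, n_window)
    dR <- wmean(df, "1R", TRUE, i_window) - wmean(df, "1R", FALSE, n_window)
    argA[i] <- dA * dR
    argB[i] <- dB * dR
  }
  fa <- rep(NA_real_, length(samples)); fb <- fa
  fa[argA > 0] <- -log(argA[argA > 0])
  fb[argB > 0] <- -log(argB[argB > 0])
  fa[!(argA > 0)] <- min(fa, na.rm = TRUE)
  fb[!(argB > 0)] <- min(fb, na.rm = TRUE)
  data.frame(sample_id = samples, featureA = fa, featureB = fb)
}

# Two-population variance-components Fst over a set of sites, from raw
# per-sample dosages, looping over everything.
oracle_fst <- function(calls1, calls2) {
  num_sum <- 0; den_sum <- 0
  r <- 2
  for (s in seq_len(ncol(calls1))) {
    g1 <- calls1[, s]; g1 <- g1[!is.na(g1)]
    g2 <- calls2[, s]; g2 <- g2[!is.na(g2)]
    n1 <- 2 * length(g1); n2 <- 2 * length(g2)
    if (n1 == 0 || n2 == 0 || (n1 + n2 - 2) <= 0) next
    p1 <- sum(g1) / n1; p2 <- sum(g2) / n2
    N <- n1 + n2
    pbar <- (n1 * p1 + n2 * p2) / N
    MSP <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
    MSG <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - r)
    nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
    num_sum <- num_sum + (MSP - MSG)
    den_sum <- den_sum + (MSP + (nc - 1) * MSG)
  }
  num_sum / den_sum
}

# Patterson's D from per-group derived-allele frequencies, looping over
# sites.
oracle_d <- function(derived1, derived2, derived3) {
  num <- 0; den <- 0
  for (s in seq_len(ncol(derived1))) {
    f <- function(m) {
      g <- m[, s]; g <- g[!is.na(g)]
      if (!length(g)) return(NA_real_)
      sum(g) / (2 * length(g))
    }
    p1 <- f(derived1); p2 <- f(derived2); p3 <- f(derived3)
    if (is.na(p1) || is.na(p2) || is.na(p3)) next
    num <- num + ((1 - p1) * p2 * p3 - p1 * (1 - p2) * p3)
    den <- den + ((1 - p1) * p2 * p3 + p1 * (1 - p2) * p3)
  }
  num / den
}

# Left/right link counting by a plain loop over links.
oracle_asymmetry_counts <- function(pos1, pos2, chrom_length, bin_size,
                                    min_distance) {
  n_bins <- ceiling(chrom_length / bin_size)
  left <- integer(n_bins); right <- integer(n_bins)
  for (k in seq_along(pos1)) {
    if (abs(pos1[k] - pos2[k]) < min_distance) next
    for (end in c("a", "b")) {
      x <- if (end == "a") pos1[k] else pos2[k]
      partner <- if (end == "a") pos2[k] else pos1[k]
      b <- min(floor(x / bin_size), n_bins - 1) + 1
      if (partner < x) left[b] <- left[b] + 1L
      else right[b] <- right[b] + 1L
    }
  }
  list(left = left, right = right)
}

# Small helpers used across test files ---------------------------------

# A clean-limit depth configuration: deterministic counts, no cross-mapping,
# no library bias.
noise_free_cfg <- function(...) {
  depth_sim_config(dispersion = 0, crossmap_rate = 0, dist_grad_amp = 0, ...)
}

make_toy_gm <- function(calls, pos = NULL, chrom = "chr1") {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("s%02d", seq_len(nrow(calls)))
  }
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000
  genotype_matrix(calls, data.frame(chrom = chrom, pos = pos,
                                    ref = "A", alt = "G"))
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}
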