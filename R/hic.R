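#' Per-bin Hi-C left:right link asymmetry track
#'
#' Bins intra-chromosomal Hi-C link ends and counts, for each bin, partners
#' mapping at a smaller coordinate (`left_links`) versus a larger one
#' (`right_links`). The asymmetry statistic is
#' `a = log2((left + psi) / (right + psi))`: positive where most contacts
#' point left, negative where they point right. Inversions relative to the
#' reference produce a diagonal ramp in `a` crossing zero near the
#' inversion midpoint.
#'
#' Each retained link contributes exactly one left and one right increment
#' (at its larger- and smaller-coordinate end respectively), so the track
#' satisfies `sum(left_links) == sum(right_links) == links retained`.
#'
#' @param links `data.frame` with columns `pos1`, `pos2` (and optionally
#'   `chrom1`, `chrom2`; inter-chromosomal rows are skipped and their count
#'   reported in the `skipped_interchrom` attribute).
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @param min_distance Links shorter than this are ignored (self-ligation /
#'   short-range noise; default two bins).
#' @param pseudocount `psi` in the log-ratio (default 1) keeps `a` finite in
#'   bins with zero links on one side.
#' @return `data.table` of class `hic_asymmetry_track` with columns `chrom`,
#'   `bin_start`, `left_links`, `right_links`, `a`. Attributes:
#'   `skipped_interchrom`, `links_retained`, `bin_size`.
#' @export
compute_asymmetry_track <- function(links, chrom_length, bin_size = 1e6,
                                    min_distance = 2 * bin_size,
                                    pseudocount = 1) {
  stop_if_not_scalar_pos(bin_size, "bin_size")
  stop_if_not_scalar_pos(chrom_length, "chrom_length")
  lk <- as.data.table(links)
  skipped <- 0L
  if (all(c("chrom1", "chrom2") %in% names(lk))) {
    inter <- lk$chrom1 != lk$chrom2
    skipped <- sum(inter)
    lk <- lk[!inter]
  }
  lk <- lk[abs(pos1 - pos2) >= min_distance]
  n_bins <- ceiling(chrom_length / bin_size)
  ends <- c(lk$pos1, lk$pos2)
  partners <- c(lk$pos2, lk$pos1)
  bin <- pmin(floor(ends / bin_size), n_bins - 1) + 1L
  left <- partners < ends
  left_counts <- tabulate(bin[left], nbins = n_bins)
  right_counts <- tabulate(bin[!left], nbins = n_bins)
  chrom <- if ("chrom1" %in% names(lk) && nrow(lk)) lk$chrom1[1] else "chr"
  out <- data.table(chrom = chrom,
                    bin_start = (seq_len(n_bins) - 1) * bin_size,
                    left_links = left_counts,
                    right_links = right_counts,
                    a = log2((left_counts + pseudocount) /
                             (right_counts + pseudocount)))
  setattr(out, "skipped_interchrom", skipped)
  setattr(out, "links_retained", nrow(lk))
  setattr(out, "bin_size", bin_size)
  setattr(out, "class", c("hic_asymmetry_track", class(out)))
  out[]
}

# Ramp fit over window [i, i+len-1] of a track, via prefix sums.
# Returns slope, signed amplitude (fitted end minus fitted start) and R^2.
.ramp_scan <- function(a, lens, step_frac = 0.05) {
  n <- length(a)
  cs_a <- c(0, cumsum(a))
  cs_a2 <- c(0, cumsum(a^2))
  cs_ta <- c(0, cumsum(seq_len(n) * a))
  out <- vector("list", length(lens))
  for (li in seq_along(lens)) {
    len <- lens[li]
    if (len > n) next
    step <- max(1L, as.integer(round(len * step_frac)))
    starts <- unique(c(seq(1L, n - len + 1L, by = step), n - len + 1L))
    i <- starts; j <- starts + len - 1L
    S_a <- cs_a[j + 1] - cs_a[i]
    S_a2 <- cs_a2[j + 1] - cs_a2[i]
    S_ta <- cs_ta[j + 1] - cs_ta[i]
    tbar <- (i + j) / 2
    Stt <- len * (len^2 - 1) / 12         # sum of (t - tbar)^2
    Sta <- S_ta - tbar * S_a              # sum of (t - tbar) a
    Saa <- S_a2 - S_a^2 / len
    slope <- Sta / Stt
    r2 <- ifelse(Saa > 0, (Sta^2 / Stt) / Saa, 0)
    out[[li]] <- data.table(start_bin = i, len = len, slope = slope,
                            amplitude = slope * (len - 1), r2 = r2,
                            win_mean = S_a / len)
  }
  rbindlist(out)
}

#' Detect candidate inversions from an asymmetry track
#'
#' Scans windows of varying length for the diagonal ramp signature an
#' inversion leaves in the left:right asymmetry statistic: within the
#' inverted interval, `a` ramps linearly from negative (contacts point
#' right) at the proximal edge to positive at the distal edge, crossing
#' zero near the midpoint. For every candidate window the mean-subtracted
#' `a` values are fitted with a straight line; windows whose fitted
#' amplitude (rise over the window, in log2 units) reaches
#' `amplitude_threshold` and whose fit score (R^2) reaches
#' `score_threshold` become calls, and overlapping calls are resolved
#' greedily by score.
#'
#' Automated ramp fitting replaces visual identification of the signature;
#' the score is the fraction of within-window variance explained by the
#' ramp, in [0, 1].
#'
#' @param track A [compute_asymmetry_track()] result.
#' @param min_len Minimum call length in bins (default 10).
#' @param amplitude_threshold Minimum fitted rise in `a` across the window
#'   (log2 units; default 2).
#' @param score_threshold Minimum R^2 of the ramp fit (default 0.6).
#' @param balance_threshold An inversion's ramp is antisymmetric about zero,
#'   so the window mean of `a` must satisfy
#'   `|mean| <= balance_threshold * amplitude`; this rejects one-sided ramps
#'   at chromosome ends where partners can only lie inward (default 0.25).
#' @param max_len_frac Longest scanned window as a fraction of the
#'   chromosome (default 0.6). End-of-chromosome truncation gives the null
#'   track a smooth antisymmetric trend, so a full-length window mimics a
#'   whole-chromosome inversion — which is in any case indistinguishable
#'   from a relabelling of the sequence.
#' @param len_factor Geometric spacing of scanned window lengths.
#' @return `data.table` of calls: `chrom`, `start`, `end` (bp), `type`
#'   (`"inversion"`), `score`, `amplitude`. Empty (zero rows) when nothing
#'   passes.
#' @export
detect_inversions <- function(track, min_len = 10L, amplitude_threshold = 2,
                              score_threshold = 0.6, balance_threshold = 0.25,
                              max_len_frac = 0.6, len_factor = 1.15) {
  stopifnot(inherits(track, "hic_asymmetry_track"))
  bin_size <- attr(track, "bin_size")
  a <- track$a
  n <- length(a)
  empty <- data.table(chrom = character(), start = numeric(),
                      end = numeric(), type = character(),
                      score = numeric(), amplitude = numeric())
  if (n < min_len) return(empty)
  max_len <- max(min_len, as.integer(floor(n * max_len_frac)))
  lens <- unique(pmin(max_len, as.integer(round(
    min_len * len_factor^(0:ceiling(log(max_len / min_len) /
                                      log(len_factor)))))))
  cand <- .ramp_scan(a, lens)
  cand <- cand[amplitude >= amplitude_threshold & r2 >= score_threshold &
               abs(win_mean) <= balance_threshold * amplitude]
  if (!nrow(cand)) return(empty)
  setorder(cand, -r2, -amplitude)
  keep <- logical(nrow(cand))
  taken_start <- numeric(0); taken_end <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    s <- cand$start_bin[k]; e <- s + cand$len[k] - 1L
    if (!length(taken_start) || all(e < taken_start | s > taken_end)) {
      keep[k] <- TRUE
      taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
    }
  }
  calls <- cand[keep]
  # Boundary refinement: within the inverted interval `a` runs from its
  # local minimum (start) to its local maximum (end); snap call edges to
  # those extrema of a lightly smoothed track near the fitted window.
  sm <- stats::filter(a, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- a[is.na(sm)]
  for (k in seq_len(nrow(calls))) {
    s <- calls$start_bin[k]; len <- calls$len[k]; e <- s + len - 1L
    mid <- s + len %/% 2L
    pad <- max(3L, len %/% 2L)
    lo <- max(1L, s - pad); hi <- min(n, e + pad)
    new_s <- lo + which.min(sm[lo:mid]) - 1L
    new_e <- mid + which.max(sm[mid:hi]) - 1L
    if (new_e - new_s + 1L >= min_len) {
      calls$start_bin[k] <- new_s
      calls$len[k] <- new_e - new_s + 1L
    }
  }
  setorder(calls, start_bin)
  data.table(chrom = track$chrom[1],
             start = (calls$start_bin - 1) * bin_size,
             end = (calls$start_bin - 1 + calls$len) * bin_size,
             type = "inversion",
             score = calls$r2,
             amplitude = calls$amplitude)
}

#' Permutation test for regional enrichment of SV calls
#'
#' Tests whether SV calls fall inside a designated region set (for example
#' the pericentromeric low-collinearity regions) more often than expected by
#' chance. The statistic is the number of calls whose midpoint lies in the
#' region set. Under the null each call is placed uniformly at random within
#' its own chromosome with its length preserved; the one-tailed empirical P
#' uses the add-one convention
#' `P = (1 + #{replicates >= observed}) / (1 + n_sim)`.
#'
#' @param calls `data.frame` with `chrom`, `start`, `end`.
#' @param regions `data.frame` with `chrom`, `start`, `end` (the region
#'   set; overlapping rows are allowed and treated as their union).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_sim Number of random placements (default 10000).
#' @param seed RNG seed.
#' @return List with `p_value`, `observed`, `null_stats` (length `n_sim`).
#' @export
regional_enrichment_test <- function(calls, regions, chrom_lengths,
                                     n_sim = 10000L, seed = 1L) {
  calls <- as.data.table(calls)
  regions <- as.data.table(regions)
  if (!all(calls$chrom %in% names(chrom_lengths))) {
    stop("call chromosome missing from `chrom_lengths`", call. = FALSE)
  }
  if (!all(regions$chrom %in% names(chrom_lengths))) {
    stop("region chromosome missing from `chrom_lengths`", call. = FALSE)
  }
  genome <- sum(chrom_lengths)
  cover <- sum(pmin(regions$end, chrom_lengths[regions$chrom]) -
               pmax(regions$start, 0))
  if (cover <= 0 || cover >= genome) {
    stop("region set must cover strictly between 0 and 100% of the genome",
         call. = FALSE)
  }
  in_regions <- function(chrom, pos) {
    hit <- logical(length(pos))
    for (k in seq_len(nrow(regions))) {
      hit <- hit | (chrom == regions$chrom[k] &
                    pos >= regions$start[k] & pos < regions$end[k])
    }
    hit
  }
  n_calls <- nrow(calls)
  if (n_calls == 0) {
    return(list(p_value = 1, observed = 0L,
                null_stats = integer(n_sim)))
  }
  mid <- (calls$start + calls$end) / 2
  observed <- sum(in_regions(calls$chrom, mid))
  local_seed(seed)
  null_stats <- integer(n_sim)
  half <- (calls$end - calls$start) / 2
  lo <- half
  hi <- chrom_lengths[calls$chrom] - half
  if (any(hi <= lo)) stop("a call is longer than its chromosome",
                          call. = FALSE)
  # n_sim x n_calls random midpoints, column-wise per call
  hits <- matrix(FALSE, n_sim, n_calls)
  for (j in seq_len(n_calls)) {
    m <- runif(n_sim, lo[j], hi[j])
    hits[, j] <- in_regions(calls$chrom[j], m)
  }
  null_stats <- as.integer(rowSums(hits))
  p <- (1 + sum(null_stats >= observed)) / (1 + n_sim)
  list(p_value = p, observed = observed, null_stats = null_stats)
}
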