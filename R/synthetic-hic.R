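#' Configuration for the Hi-C link simulator
#'
#' Simulates intra-chromosomal Hi-C contact pairs for a query genotype whose
#' chromosome differs from the reference by a set of inversions. Link
#' distances follow a truncated power law (standard contact-decay shape) in
#' the query's own coordinates; both link ends are then mapped through the
#' inversions (coordinate reflection within each interval) into reference
#' coordinates, which is what produces the diagonal ramp signature in the
#' left:right asymmetry track.
#'
#' @param chrom_length Chromosome length in bp.
#' @param sv_set `data.frame` with `start`, `end` (bp, half-open) giving the
#'   true inversion intervals; must not overlap.
#' @param n_links Number of links to simulate.
#' @param decay_exponent Power-law exponent of the link-distance density
#'   (must be < 0; default -1).
#' @param min_dist Smallest simulated link distance in bp (default one
#'   megabase bin).
#' @param seed RNG seed.
#' @return Object of class `hic_sim_config`.
#' @export
hic_sim_config <- function(chrom_length, sv_set = NULL, n_links = 1e6,
                           decay_exponent = -1, min_dist = 1e6, seed = 1L) {
  stop_if_not_scalar_pos(chrom_length, "chrom_length")
  if (n_links <= 0) stop("`n_links` must be positive", call. = FALSE)
  if (decay_exponent >= 0) stop("`decay_exponent` must be < 0", call. = FALSE)
  if (!is.null(sv_set) && nrow(sv_set)) {
    sv <- sv_set[order(sv_set$start), , drop = FALSE]
    if (any(sv$start >= sv$end)) stop("sv intervals need start < end",
                                      call. = FALSE)
    if (any(sv$start < 0) || any(sv$end > chrom_length)) {
      stop("sv intervals must lie within the chromosome", call. = FALSE)
    }
    if (nrow(sv) > 1 && any(sv$start[-1] < sv$end[-nrow(sv)])) {
      stop("overlapping truth SVs are not supported", call. = FALSE)
    }
    sv_set <- sv
  }
  structure(list(chrom_length = chrom_length, sv_set = sv_set,
                 n_links = n_links, decay_exponent = decay_exponent,
                 min_dist = min_dist, seed = seed),
            class = "hic_sim_config")
}

# Inverse-CDF sampling of distances with density ~ d^alpha on
# [min_dist, max_dist].
.rpowerlaw <- function(n, alpha, d_min, d_max) {
  u <- runif(n)
  if (alpha == -1) {
    d_min * (d_max / d_min)^u
  } else {
    a1 <- alpha + 1
    (d_min^a1 + u * (d_max^a1 - d_min^a1))^(1 / a1)
  }
}

# Map query coordinates through a set of non-overlapping inversions:
# x within [start, end) is reflected to start + end - x.
.map_through_inversions <- function(x, sv_set) {
  if (is.null(sv_set) || !nrow(sv_set)) return(x)
  for (i in seq_len(nrow(sv_set))) {
    s <- sv_set$start[i]; e <- sv_set$end[i]
    inside <- x >= s & x < e
    x[inside] <- s + e - x[inside]
  }
  x
}

#' Simulate intra-chromosomal Hi-C links
#'
#' @param cfg A [hic_sim_config()].
#' @return `data.table` with columns `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (reference coordinates, one row per link).
#' @examples
#' links <- simulate_hic_links(hic_sim_config(1e8, n_links = 1e4, seed = 3))
#' @export
simulate_hic_links <- function(cfg) {
  stopifnot(inherits(cfg, "hic_sim_config"))
  local_seed(cfg$seed)
  L <- cfg$chrom_length
  n <- cfg$n_links
  pos1 <- numeric(n); pos2 <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    p1 <- runif(m, 0, L)
    d <- .rpowerlaw(m, cfg$decay_exponent, cfg$min_dist, L)
    p2 <- p1 + ifelse(runif(m) < 0.5, -1, 1) * d
    ok <- p2 >= 0 & p2 < L
    pos1[todo[ok]] <- p1[ok]
    pos2[todo[ok]] <- p2[ok]
    todo <- todo[!ok]
  }
  data.table(chrom1 = "chr", pos1 = .map_through_inversions(pos1, cfg$sv_set),
             chrom2 = "chr", pos2 = .map_through_inversions(pos2, cfg$sv_set))
}
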