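#' Configuration for the structured-genotype simulator
#'
#' Emulates a genotyping-by-sequencing panel of a structured species
#' complex: samples fall into genetic clusters whose allele frequencies
#' diverge around shared ancestral frequencies (a Balding-Nichols model),
#' optionally connected by gene-flow tracts in which the recipient
#' cluster's frequencies copy the donor's. Each site carries an effect
#' label (synonymous/nonsynonymous) and a triple of outgroup-subgenome
#' alleles whose majority equals the ancestral (reference) allele except at
#' a configurable error fraction of sites, mirroring polarization against a
#' triplicated outgroup genome.
#'
#' @param n_clusters Number of genetic clusters (default 7).
#' @param samples_per_cluster Samples simulated per cluster.
#' @param n_sites Number of biallelic sites.
#' @param divergence Balding-Nichols F parameter controlling cluster
#'   allele-frequency spread around the ancestral frequency (0 = panmixia).
#' @param tracts List of gene-flow tracts, each a list with elements
#'   `donor`, `recipient` (cluster indices) and `start`, `end` (bp interval
#'   on the simulated chromosome); within a tract the recipient cluster's
#'   frequencies are copied from the donor.
#' @param prop_nonsyn Fraction of sites labelled nonsynonymous (the rest
#'   are synonymous).
#' @param sel_differential Factor in (0, 1] multiplying the derived-allele
#'   frequency of nonsynonymous sites in `sel_cluster`; values < 1 emulate
#'   stronger purifying selection in that cluster.
#' @param sel_cluster Cluster index subject to `sel_differential`.
#' @param outgroup_error Per-site probability that the outgroup triple
#'   carries three distinct alleles (no majority, site unpolarizable).
#' @param site_spacing Genomic spacing between consecutive sites in bp
#'   (sites sit on one chromosome, `chr1`, at positions
#'   `site_spacing * 1:n_sites`).
#' @param missing_rate Per-call missing probability.
#' @param mean_depth Mean per-call read depth (negative-binomial).
#' @param seed RNG seed.
#' @return Object of class `pop_sim_config`.
#' @export
pop_sim_config <- function(n_clusters = 7L, samples_per_cluster = 10L,
                           n_sites = 2000L, divergence = 0.15,
                           tracts = list(), prop_nonsyn = 0.4,
                           sel_differential = 1, sel_cluster = 1L,
                           outgroup_error = 0.02, site_spacing = 5e4,
                           missing_rate = 0.03, mean_depth = 12,
                           seed = 1L) {
  probs <- c(divergence, prop_nonsyn, outgroup_error, missing_rate)
  if (any(probs < 0) || any(probs > 1)) {
    stop("divergence, prop_nonsyn, outgroup_error and missing_rate must be ",
         "probabilities in [0, 1]", call. = FALSE)
  }
  if (sel_differential <= 0 || sel_differential > 1) {
    stop("`sel_differential` must be in (0, 1]", call. = FALSE)
  }
  max_pos <- site_spacing * n_sites
  for (tr in tracts) {
    stopifnot(all(c("donor", "recipient", "start", "end") %in% names(tr)))
    if (tr$start < 0 || tr$end > max_pos || tr$start >= tr$end) {
      stop("tract interval outside the site coordinate range", call. = FALSE)
    }
    if (tr$donor > n_clusters || tr$recipient > n_clusters) {
      stop("tract cluster index out of range", call. = FALSE)
    }
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 samples_per_cluster = as.integer(samples_per_cluster),
                 n_sites = as.integer(n_sites),
                 divergence = divergence, tracts = tracts,
                 prop_nonsyn = prop_nonsyn,
                 sel_differential = sel_differential,
                 sel_cluster = as.integer(sel_cluster),
                 outgroup_error = outgroup_error,
                 site_spacing = site_spacing,
                 missing_rate = missing_rate, mean_depth = mean_depth,
                 seed = seed),
            class = "pop_sim_config")
}

#' Simulate a structured genotype panel with annotations
#'
#' @param cfg A [pop_sim_config()].
#' @return List of class `sim_genotypes` with
#'   \describe{
#'     \item{genotypes}{a [genotype_matrix()] (calls, depth, quality).}
#'     \item{annotation}{`data.table` per site: `chrom`, `pos`, `effect`,
#'       `out1`, `out2`, `out3` (the outgroup triple).}
#'     \item{cluster}{named integer vector, sample id -> true cluster.}
#'     \item{freqs}{clusters x sites matrix of the allele frequencies the
#'       genotypes were drawn from (simulation truth).}
#'   }
#' @examples
#' sim <- simulate_structured_genotypes(pop_sim_config(
#'   n_clusters = 2, samples_per_cluster = 5, n_sites = 200, seed = 9))
#' sim$genotypes
#' @export
simulate_structured_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "pop_sim_config"))
  local_seed(cfg$seed)
  S <- cfg$n_sites
  K <- cfg$n_clusters
  pos <- cfg$site_spacing * seq_len(S)

  # ancestral (reference-allele-is-ancestral) derived frequencies
  p0 <- runif(S, 0.02, 0.98)
  freqs <- matrix(0, K, S)
  for (k in seq_len(K)) {
    freqs[k, ] <- if (cfg$divergence == 0) p0 else {
      f <- cfg$divergence
      rbeta(S, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    }
  }
  for (tr in cfg$tracts) {
    in_tract <- pos >= tr$start & pos <= tr$end
    freqs[tr$recipient, in_tract] <- freqs[tr$donor, in_tract]
  }

  nucs <- c("A", "C", "G", "T")
  ref <- sample(nucs, S, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1), character(1))
  effect <- ifelse(runif(S) < cfg$prop_nonsyn, "nonsynonymous", "synonymous")

  # purifying-selection differential on nonsynonymous derived alleles
  nonsyn <- effect == "nonsynonymous"
  if (cfg$sel_differential < 1) {
    freqs[cfg$sel_cluster, nonsyn] <-
      freqs[cfg$sel_cluster, nonsyn] * cfg$sel_differential
  }

  n <- K * cfg$samples_per_cluster
  cluster <- rep(seq_len(K), each = cfg$samples_per_cluster)
  ids <- sprintf("C%d_%02d", cluster, sequence(rep(cfg$samples_per_cluster, K)))
  calls <- matrix(NA_integer_, n, S, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    calls[i, ] <- rbinom(S, 2L, freqs[cluster[i], ])
  }
  calls[matrix(runif(n * S) < cfg$missing_rate, n, S)] <- NA_integer_

  depth <- matrix(rnbinom(n * S, mu = cfg$mean_depth, size = 5), n, S,
                  dimnames = list(ids, NULL))
  quality <- rgamma(S, shape = 8, scale = 50)

  # outgroup triple: majority equals ancestral (= ref) except at error sites,
  # which carry three distinct alleles and therefore no majority
  third <- vapply(seq_len(S), function(s) {
    sample(setdiff(nucs, c(ref[s], alt[s])), 1)
  }, character(1))
  err <- runif(S) < cfg$outgroup_error
  o3 <- ifelse(runif(S) < 0.5, ref, alt)
  out_triple <- cbind(ref, ref, o3)
  out_triple[err, ] <- cbind(ref[err], alt[err], third[err])
  perm <- replicate(S, sample.int(3L))  # shuffle triple column order per site
  for (s in seq_len(S)) out_triple[s, ] <- out_triple[s, perm[, s]]

  sites <- data.table(chrom = "chr1", pos = pos, ref = ref, alt = alt)
  names(cluster) <- ids
  structure(list(
    genotypes = genotype_matrix(calls, sites, depth, quality),
    annotation = data.table(chrom = "chr1", pos = pos, effect = effect,
                            out1 = out_triple[, 1], out2 = out_triple[, 2],
                            out3 = out_triple[, 3]),
    cluster = cluster,
    freqs = freqs),
    class = "sim_genotypes")
}
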