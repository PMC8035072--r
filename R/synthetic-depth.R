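#' Configuration for the binned read-depth simulator
#'
#' Describes a cohort of wheat samples sequenced and mapped to a combined
#' wheat + rye reference, summarised as per-bin read counts. Four karyotype
#' classes are simulated: `none` (no rye chromatin), `introgressed_1A1R`
#' (1AL.1RS whole-arm translocation: the terminal 1A short arm replaced by
#' the 1R short arm), `introgressed_1B1R` (1BL.1RS, analogous on 1B) and
#' `ambiguous` (a mild excess of 1R short-arm reads without a clear
#' depletion of 1A or 1B).
#'
#' Besides the karyotype signal itself, two systematic sample-versus-
#' reference effects of real panels are emulated, because the downstream
#' features are products of window-mean *differences* and their geometry
#' depends on them:
#' \itemize{
#'   \item \emph{Homology-graded cross-mapping}: reads from chromatin absent
#'     in the reference's own library still land sparsely on the absent
#'     chromatin's bins. Panel samples (whose reads mismatch the reference
#'     genome slightly) cross-map more than the reference sample does, and
#'     preferentially onto the homoeologous short arm of 1R
#'     (`crossmap_excess_i` within the terminal `introgressed_window`,
#'     `crossmap_excess_n` elsewhere).
#'   \item \emph{Distal library bias}: reduced-representation libraries are
#'     slightly enriched for reads near chromosome ends relative to the
#'     reference library; per sample the enrichment amplitude is drawn
#'     log-normally (strictly positive), giving every sample a small,
#'     one-signed terminal excess that decays over `dist_grad_len` bp.
#' }
#'
#' Counts are drawn per bin from a negative-binomial distribution with mean
#' equal to the expectation and variance `mu + dispersion * mu^2`;
#' `dispersion = 0` returns the expectation itself (noise-free), which makes
#' closed-form checks exact.
#'
#' @param n_per_class Samples simulated per karyotype class.
#' @param bin_size Bin width in bp (1 Mb by default, matching the analysis).
#' @param chrom_lengths Named vector of chromosome lengths in bp. Must
#'   contain `1A`, `1B` and `1R`. Defaults approximate the wheat group-1
#'   pseudomolecules and the rye 1R pseudomolecule.
#' @param total_reads Mean mapped library size per sample.
#' @param dispersion Negative-binomial overdispersion of per-bin counts
#'   (variance `mu + dispersion * mu^2`); 0 gives deterministic expectations.
#' @param introgression_fraction Fraction of the reference (wheat) per-bin
#'   depth attained by rye chromatin that is present in the sample; rye
#'   reads map somewhat less efficiently than the host's own, so values
#'   slightly below 1 are realistic.
#' @param introgressed_window Length in bp of the terminal window swapped by
#'   a whole-arm translocation (the short arm), at the "I" end of each
#'   chromosome (coordinate 0 here).
#' @param ambiguous_fraction Fraction of `introgression_fraction` attained
#'   on the 1R short arm by `ambiguous` samples.
#' @param crossmap_rate Baseline fraction of reference depth observed on
#'   absent chromatin through cross-mapping (the reference sample's own
#'   rate).
#' @param crossmap_excess_i,crossmap_excess_n Multipliers of
#'   `crossmap_rate` for panel samples on the homoeologous short arm
#'   (within `introgressed_window`) and on the rest of absent chromatin.
#' @param dist_grad_amp Mean per-sample amplitude of the distal library
#'   bias (0 disables it; the reference sample always has 0).
#' @param dist_grad_sdlog Log-normal sdlog of the per-sample amplitude.
#' @param dist_grad_len Decay length of the distal bias in bp.
#' @param seed RNG seed; identical configurations and seeds reproduce
#'   bitwise-identical cohorts.
#' @return An object of class `depth_sim_config`.
#' @seealso [simulate_depth_cohort()]
#' @export
depth_sim_config <- function(n_per_class = 50L,
                             bin_size = 1e6,
                             chrom_lengths = c("1A" = 594e6, "1B" = 690e6,
                                               "1R" = 980e6),
                             total_reads = 4e6,
                             dispersion = 0.02,
                             introgression_fraction = 0.9,
                             introgressed_window = 250e6,
                             ambiguous_fraction = 0.3,
                             crossmap_rate = 0.02,
                             crossmap_excess_i = 2.5,
                             crossmap_excess_n = 1.25,
                             dist_grad_amp = 1.0,
                             dist_grad_sdlog = 0.15,
                             dist_grad_len = 150e6,
                             seed = 1L) {
  stop_if_not_scalar_pos(bin_size, "bin_size")
  if (total_reads <= 0) stop("`total_reads` must be positive", call. = FALSE)
  if (dispersion < 0) stop("`dispersion` must be >= 0", call. = FALSE)
  if (!all(c("1A", "1B", "1R") %in% names(chrom_lengths))) {
    stop("`chrom_lengths` must name chromosomes 1A, 1B and 1R", call. = FALSE)
  }
  if (any(chrom_lengths[c("1A", "1B", "1R")] < 2 * introgressed_window)) {
    stop("each chromosome must be at least twice `introgressed_window` long",
         call. = FALSE)
  }
  if (introgression_fraction < 0 || introgression_fraction > 1) {
    stop("`introgression_fraction` must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 bin_size = bin_size,
                 chrom_lengths = chrom_lengths,
                 total_reads = total_reads,
                 dispersion = dispersion,
                 introgression_fraction = introgression_fraction,
                 introgressed_window = introgressed_window,
                 ambiguous_fraction = ambiguous_fraction,
                 crossmap_rate = crossmap_rate,
                 crossmap_excess_i = crossmap_excess_i,
                 crossmap_excess_n = crossmap_excess_n,
                 dist_grad_amp = dist_grad_amp,
                 dist_grad_sdlog = dist_grad_sdlog,
                 dist_grad_len = dist_grad_len,
                 seed = seed),
            class = "depth_sim_config")
}

#' Karyotype class vocabulary
#'
#' The closed set of labels assigned by the classifier.
#' @return Character vector of the four labels.
#' @export
karyotype_classes <- function() {
  c("none", "introgressed_1A1R", "introgressed_1B1R", "ambiguous")
}

# Chromatin-presence depth multipliers for one sample of a given class.
# `is_reference` switches off the panel-specific cross-mapping excess.
.depth_multipliers <- function(bins, label, cfg, is_reference = FALSE) {
  if (!label %in% karyotype_classes()) {
    stop(sprintf("unknown karyotype class '%s'", label), call. = FALSE)
  }
  iw <- cfg$introgressed_window
  in_i <- bins$bin_start < iw  # I end is coordinate 0 on every chromosome
  f <- cfg$introgression_fraction
  # cross-mapping rate profile for absent chromatin
  cm <- if (is_reference) {
    rep(cfg$crossmap_rate, nrow(bins))
  } else {
    cfg$crossmap_rate *
      ifelse(in_i, cfg$crossmap_excess_i, cfg$crossmap_excess_n)
  }
  w <- ifelse(bins$chrom == "1R", cm, 1)
  if (label == "introgressed_1A1R") {
    w[bins$chrom == "1A" & in_i] <- cm[bins$chrom == "1A" & in_i]
    w[bins$chrom == "1R" & in_i] <- f
  } else if (label == "introgressed_1B1R") {
    w[bins$chrom == "1B" & in_i] <- cm[bins$chrom == "1B" & in_i]
    w[bins$chrom == "1R" & in_i] <- f
  } else if (label == "ambiguous") {
    w[bins$chrom == "1R" & in_i] <- cfg$ambiguous_fraction * f
  }
  w
}

# Distal library-bias factor per bin: 1 + gamma * G(x), G decaying linearly
# from 1 at either chromosome end to 0 over `dist_grad_len`.
.dist_grad_factor <- function(bins, gamma, cfg) {
  if (gamma == 0) return(rep(1, nrow(bins)))
  mid <- bins$bin_start + (bins$bin_end - bins$bin_start) / 2
  d_end <- pmin(mid, cfg$chrom_lengths[bins$chrom] - mid)
  1 + gamma * pmax(0, 1 - d_end / cfg$dist_grad_len)
}

.make_bins <- function(chrom_lengths, bin_size) {
  rbindlist(lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, chrom_lengths[[ch]] - 1, by = bin_size)
    data.table(chrom = ch, bin_start = starts,
               bin_end = pmin(starts + bin_size, chrom_lengths[[ch]]))
  }))
}

.draw_counts <- function(mu, dispersion) {
  if (dispersion == 0) return(mu)
  rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate a labelled cohort of binned depth profiles
#'
#' Generates per-bin read counts for `n_per_class` samples of each karyotype
#' class, plus a nonintrogressed reference profile (playing the role of the
#' normalisation cultivar, drawn without the panel-specific biases). Expected
#' depth combines chromatin presence (present chromatin at full or
#' `introgression_fraction` depth, absent chromatin at the cross-mapping
#' rate) with the per-sample distal library bias; see [depth_sim_config()].
#'
#' @param cfg A [depth_sim_config()].
#' @param classes Karyotype classes to include (default: all four).
#' @return A list of class `simulated_cohort` with elements
#'   \describe{
#'     \item{profiles}{`data.table` with columns `sample_id`, `chrom`,
#'       `bin_start`, `count` (long format, all samples).}
#'     \item{labels}{named character vector, sample id -> class.}
#'     \item{truth_regions}{`data.table` of gained/lost intervals per
#'       introgressed sample (`sample_id`, `chrom`, `start`, `end`, `kind`).}
#'     \item{reference}{profile `data.table` for the reference sample
#'       (`sample_id = "reference"`), same columns as `profiles`.}
#'     \item{total_mapped}{named vector of total mapped reads per sample
#'       (including the reference).}
#'   }
#' @examples
#' cohort <- simulate_depth_cohort(depth_sim_config(n_per_class = 2, seed = 7))
#' table(cohort$labels)
#' @export
simulate_depth_cohort <- function(cfg, classes = karyotype_classes()) {
  stopifnot(inherits(cfg, "depth_sim_config"))
  bad <- setdiff(classes, karyotype_classes())
  if (length(bad)) {
    stop("unknown karyotype class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  local_seed(cfg$seed)
  bins <- .make_bins(cfg$chrom_lengths, cfg$bin_size)

  one_sample <- function(id, label, is_reference = FALSE) {
    gamma <- if (is_reference || cfg$dist_grad_amp == 0) 0 else
      stats::rlnorm(1, log(cfg$dist_grad_amp), cfg$dist_grad_sdlog)
    w <- .depth_multipliers(bins, label, cfg, is_reference) *
      .dist_grad_factor(bins, gamma, cfg)
    mu <- cfg$total_reads * w / sum(w)
    data.table(sample_id = id, chrom = bins$chrom, bin_start = bins$bin_start,
               count = .draw_counts(mu, cfg$dispersion))
  }

  profiles <- vector("list", length(classes) * cfg$n_per_class)
  labels <- character(0)
  truth <- list()
  k <- 0L
  iw <- cfg$introgressed_window
  for (cl in classes) {
    for (i in seq_len(cfg$n_per_class)) {
      k <- k + 1L
      id <- sprintf("%s_%03d", cl, i)
      profiles[[k]] <- one_sample(id, cl)
      labels[id] <- cl
      if (cl == "introgressed_1A1R") {
        truth[[id]] <- data.table(sample_id = id, chrom = c("1A", "1R"),
                                  start = 0, end = iw,
                                  kind = c("lost", "gained"))
      } else if (cl == "introgressed_1B1R") {
        truth[[id]] <- data.table(sample_id = id, chrom = c("1B", "1R"),
                                  start = 0, end = iw,
                                  kind = c("lost", "gained"))
      } else if (cl == "ambiguous") {
        truth[[id]] <- data.table(sample_id = id, chrom = "1R", start = 0,
                                  end = iw, kind = "gained")
      }
    }
  }
  reference <- one_sample("reference", "none", is_reference = TRUE)
  profiles <- rbindlist(profiles)
  totals <- c(tapply(profiles$count, profiles$sample_id, sum),
              reference = sum(reference$count))
  structure(list(profiles = profiles,
                 labels = labels,
                 truth_regions = if (length(truth)) rbindlist(truth)
                                 else data.table(),
                 reference = reference,
                 total_mapped = totals),
            class = "simulated_cohort")
}
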