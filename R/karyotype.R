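#' Log2 reads-per-bin per million mapped (rpmm)
#'
#' Converts raw per-bin read counts into `rpmm = log2(count / (total / 1e6))`.
#' Zero-count bins would give `-Inf`; they are given a pseudocount
#' (default 0.5 reads) so every bin carries a finite value.
#'
#' @param counts Numeric vector of per-bin read counts (>= 0).
#' @param total_mapped Total mapped reads for the sample (> 0).
#' @param pseudocount Reads substituted for zero-count bins.
#' @return Numeric vector of rpmm values, same length as `counts`.
#' @examples
#' compute_rpmm(c(1, 1000, 0), total_mapped = 1e6)
#' @export
compute_rpmm <- function(counts, total_mapped, pseudocount = 0.5) {
  stop_if_not_scalar_pos(total_mapped, "total_mapped")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be >= 0", call. = FALSE)
  eff <- ifelse(counts == 0, pseudocount, counts)
  log2(eff / (total_mapped / 1e6))
}

#' Normalize an rpmm track against a reference sample
#'
#' Subtracts, bin by bin, the rpmm attained by a designated reference sample
#' (typically the cultivar the reference genome was built from, e.g. 'Chinese Spring'), controlling for mappability biases:
#' `r = rpmm_sample - rpmm_reference`.
#'
#' @param sample_track,reference_track `data.frame`s with columns `chrom`,
#'   `bin_start` and `rpmm`, on an identical binning.
#' @return `data.table` with `chrom`, `bin_start`, `r`.
#' @export
normalize_to_reference <- function(sample_track, reference_track) {
  s <- as.data.table(sample_track)[order(chrom, bin_start)]
  f <- as.data.table(reference_track)[order(chrom, bin_start)]
  if (nrow(s) != nrow(f) || !all(s$chrom == f$chrom) ||
      !all(s$bin_start == f$bin_start)) {
    stop("sample and reference tracks are not on the same bins", call. = FALSE)
  }
  data.table(chrom = s$chrom, bin_start = s$bin_start, r = s$rpmm - f$rpmm)
}

#' Terminal-window specification for the karyotype features
#'
#' Defines, per chromosome, which end is the "normally introgressed" (I) end
#' and the lengths of the terminal I and N windows over which mean normalized
#' depth is taken. Defaults: a 200-Mb I window
#' and a 300-Mb N window taken from opposite chromosome ends.
#'
#' @param chrom_lengths Named bp lengths for chromosomes 1A, 1B, 1R.
#' @param i_end Named orientation per chromosome: `"start"` if the I end is
#'   at coordinate 0, `"end"` otherwise. Default: all at the start (the
#'   convention used by the bundled simulator).
#' @param i_window,n_window Window lengths in bp.
#' @return An object of class `arm_region_spec`.
#' @export
arm_region_spec <- function(chrom_lengths,
                            i_end = c("1A" = "start", "1B" = "start",
                                      "1R" = "start"),
                            i_window = 200e6, n_window = 300e6) {
  need <- c("1A", "1B", "1R")
  if (!all(need %in% names(chrom_lengths))) {
    stop("`chrom_lengths` must name 1A, 1B and 1R", call. = FALSE)
  }
  if (any(chrom_lengths[need] < pmax(i_window, n_window))) {
    stop("windows longer than a chromosome", call. = FALSE)
  }
  structure(list(chrom_lengths = chrom_lengths[need],
                 i_end = i_end[need],
                 i_window = i_window, n_window = n_window),
            class = "arm_region_spec")
}

# Mean r over bins lying wholly inside the terminal `width` bp at the given
# end. Bins straddling the window boundary are excluded. Plain-vector
# subsetting on purpose: `track` may be a data.table and bracket-`i`
# expressions would capture column names.
.window_mean <- function(track, chrom_name, end, width, chrom_len, bin_size) {
  on_chrom <- track[["chrom"]] == chrom_name
  starts <- track[["bin_start"]]
  sel <- if (end == "start") {
    on_chrom & (starts + bin_size <= width)
  } else {
    on_chrom & (starts >= chrom_len - width)
  }
  if (!any(sel)) {
    stop(sprintf("no bins wholly inside the %s-window of %s", end,
                 chrom_name), call. = FALSE)
  }
  mean(track[["r"]][sel])
}

#' Extract the two karyotype features from normalized depth tracks
#'
#' For each sample, computes the mean normalized depth `r` over the terminal
#' I and N windows of chromosomes 1A, 1B and 1R and combines them as
#' \deqn{featureA = -\log[(\bar r^{1A}_I - \bar r^{1A}_N)
#'                       (\bar r^{1R}_I - \bar r^{1R}_N)]}
#' and analogously `featureB` with 1B in place of 1A. When the product
#' inside the log is not positive (undefined log), the feature is set to the
#' minimum of the defined values of that feature across the cohort, and the
#' substitution is flagged.
#'
#' The log is natural by default; the base only rescales the feature axes
#' monotonically and cannot affect class separability.
#'
#' @param r_tracks Long `data.frame` with columns `sample_id`, `chrom`,
#'   `bin_start`, `r` covering chromosomes 1A, 1B and 1R for every sample.
#' @param spec An [arm_region_spec()].
#' @param bin_size Bin width in bp.
#' @param log_base Base of the logarithm (default `exp(1)`).
#' @return `data.table` with columns `sample_id`, `featureA`, `featureB`,
#'   `substitutedA`, `substitutedB`.
#' @export
extract_karyotype_features <- function(r_tracks, spec, bin_size = 1e6,
                                       log_base = exp(1)) {
  stopifnot(inherits(spec, "arm_region_spec"))
  rt <- as.data.table(r_tracks)
  if (nrow(rt) == 0) stop("empty cohort", call. = FALSE)
  samples <- unique(rt$sample_id)

  wmean <- function(tr, ch, which) {
    e <- spec$i_end[[ch]]
    if (which == "N") e <- if (e == "start") "end" else "start"
    width <- if (which == "I") spec$i_window else spec$n_window
    .window_mean(tr, ch, e, width, spec$chrom_lengths[[ch]], bin_size)
  }

  args <- lapply(samples, function(id) {
    tr <- rt[rt$sample_id == id, ]
    dR <- wmean(tr, "1R", "I") - wmean(tr, "1R", "N")
    c(A = (wmean(tr, "1A", "I") - wmean(tr, "1A", "N")) * dR,
      B = (wmean(tr, "1B", "I") - wmean(tr, "1B", "N")) * dR)
  })
  argA <- vapply(args, `[[`, numeric(1), "A")
  argB <- vapply(args, `[[`, numeric(1), "B")

  substitute_min <- function(arg, name) {
    defined <- arg > 0
    if (!any(defined)) {
      stop(sprintf("feature%s undefined for every sample in the cohort", name),
           call. = FALSE)
    }
    val <- rep(NA_real_, length(arg))
    val[defined] <- -log(arg[defined], base = log_base)
    val[!defined] <- min(val[defined])
    list(value = val, substituted = !defined)
  }
  fa <- substitute_min(argA, "A")
  fb <- substitute_min(argB, "B")
  data.table(sample_id = samples,
             featureA = fa$value, featureB = fb$value,
             substitutedA = fa$substituted, substitutedB = fb$substituted)
}

#' End-to-end feature extraction from a simulated cohort
#'
#' Convenience wrapper: computes rpmm for every sample and the reference,
#' normalizes, and extracts the karyotype features.
#'
#' @param cohort A [simulate_depth_cohort()] result.
#' @param spec An [arm_region_spec()]; defaults to the spec implied by the
#'   cohort's chromosome lengths.
#' @param bin_size Bin width in bp.
#' @return Feature `data.table` as from [extract_karyotype_features()].
#' @export
cohort_features <- function(cohort, spec = NULL, bin_size = 1e6) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  ref <- copy(cohort$reference)
  ref[, rpmm := compute_rpmm(count, cohort$total_mapped[["reference"]])]
  prof <- as.data.table(cohort$profiles)
  prof[, rpmm := compute_rpmm(count, sum(count)), by = sample_id]
  setorder(prof, sample_id, chrom, bin_start)
  setorder(ref, chrom, bin_start)
  prof[, r := rpmm - rep(ref$rpmm, length.out = .N)]
  if (is.null(spec)) {
    lens <- tapply(prof$bin_start, prof$chrom, max) + bin_size
    spec <- arm_region_spec(lens)
  }
  extract_karyotype_features(prof[, .(sample_id, chrom, bin_start, r)],
                             spec, bin_size = bin_size)
}

# Median-heuristic RBF bandwidth: sigma for kernlab's rbfdot
# k(x, y) = exp(-sigma * |x - y|^2), from the median pairwise squared
# distance of the feature rows.
.median_sigma <- function(x) {
  d2 <- as.numeric(stats::dist(x))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m == 0) 1 else 1 / m
}

#' Fit the karyotype SVM classifier
#'
#' A soft-margin support vector machine with a radial-basis-function kernel
#' and cost 1 (`kernlab::ksvm`, `type = "C-svc"`, `kernel = "rbfdot"`,
#' `C = 1`), as used to replicate human karyotype assignment. The RBF
#' bandwidth is set by the median heuristic on pairwise feature distances,
#' which makes the fit deterministic given the data.
#'
#' @param features `data.frame` with `featureA` and `featureB` columns (and
#'   optionally `sample_id`).
#' @param labels Character vector or factor of class labels, one per row.
#' @return Object of class `karyotype_svm` wrapping the fitted model.
#' @export
fit_karyotype_classifier <- function(features, labels) {
  x <- as.matrix(as.data.frame(features)[, c("featureA", "featureB")])
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2) {
    stop("need at least two classes to fit a classifier", call. = FALSE)
  }
  sigma <- .median_sigma(x)
  model <- kernlab::ksvm(x, y, type = "C-svc", kernel = "rbfdot",
                         kpar = list(sigma = sigma), C = 1, scaled = FALSE)
  structure(list(model = model, sigma = sigma, levels = levels(y)),
            class = "karyotype_svm")
}

#' Predict karyotype labels
#'
#' @param model A fitted [fit_karyotype_classifier()] model.
#' @param features Feature `data.frame` with `featureA`, `featureB`.
#' @return Character vector of predicted labels.
#' @export
classify_karyotypes <- function(model, features) {
  stopifnot(inherits(model, "karyotype_svm"))
  x <- as.matrix(as.data.frame(features)[, c("featureA", "featureB")])
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  as.character(kernlab::predict(model$model, x))
}

#' Train-size cross-validation of the karyotype classifier
#'
#' For each training-set size, repeatedly draws a random subset of that size,
#' fits the SVM on it and scores prediction accuracy on all remaining
#' samples. Default design: training sizes between
#' 50 and 600, each repeated 100 times.
#'
#' @param features Feature `data.frame` (rows aligned with `labels`).
#' @param labels Class labels.
#' @param train_sizes Integer vector of training-set sizes.
#' @param repeats Random redraws per size.
#' @param seed RNG seed.
#' @return A list with
#'   \describe{
#'     \item{accuracy}{`data.table` of every replicate
#'       (`train_size`, `repeat_id`, `accuracy`).}
#'     \item{summary}{`data.table` per size: mean, quartiles.}
#'   }
#' @export
cross_validate_classifier <- function(features, labels,
                                      train_sizes = seq(50L, 600L, by = 50L),
                                      repeats = 100L, seed = 1L) {
  x <- as.data.frame(features)[, c("featureA", "featureB")]
  labels <- as.character(labels)
  n <- nrow(x)
  if (max(train_sizes) >= n) {
    stop("largest training size must be smaller than the dataset",
         call. = FALSE)
  }
  local_seed(seed)
  res <- rbindlist(lapply(train_sizes, function(ts) {
    acc <- vapply(seq_len(repeats), function(rep_i) {
      idx <- sample.int(n, ts)
      m <- fit_karyotype_classifier(x[idx, ], labels[idx])
      mean(classify_karyotypes(m, x[-idx, ]) == labels[-idx])
    }, numeric(1))
    data.table(train_size = ts, repeat_id = seq_len(repeats), accuracy = acc)
  }))
  summary <- res[, .(mean = mean(accuracy),
                     q25 = quantile(accuracy, 0.25, names = FALSE),
                     median = stats::median(accuracy),
                     q75 = quantile(accuracy, 0.75, names = FALSE)),
                 by = train_size]
  list(accuracy = res, summary = summary)
}

#' Square-root percent-difference matrix for heatmaps
#'
#' For every pair of samples, the percentage of co-called sites at which the
#' genotype calls differ, square-root transformed:
#' `sqrt(100 * fraction different)`. Used to display relatedness within a
#' panel (e.g. predicted 1RS carriers) as a heatmap.
#'
#' @param calls Samples x sites matrix of genotype calls (`NA` = missing).
#' @return Symmetric matrix with zero diagonal; `NA` where a pair shares no
#'   co-called site.
#' @export
sqrt_diff_heatmap_matrix <- function(calls) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  out <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      out[i, j] <- out[j, i] <- if (!any(ok)) NA_real_ else
        sqrt(100 * mean(calls[i, ok] != calls[j, ok]))
    }
  }
  out
}
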