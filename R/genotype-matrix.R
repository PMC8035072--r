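#' Genotype matrix container
#'
#' Holds biallelic calls for a panel: a samples x sites matrix of alt-allele
#' dosages (0, 1, 2 or `NA` for missing), site metadata, optional per-call
#' read depth and per-site call quality.
#'
#' @param calls Integer samples x sites matrix, values in `{0, 1, 2, NA}`;
#'   row names are sample ids.
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, one row per column of `calls`.
#' @param depth Optional samples x sites matrix of per-call read depths.
#' @param quality Optional per-site call quality vector.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, depth = NULL, quality = NULL) {
  calls <- as.matrix(calls)
  sites <- as.data.table(sites)
  if (ncol(calls) != nrow(sites)) {
    stop("`calls` columns must match `sites` rows", call. = FALSE)
  }
  if (!all(calls %in% c(0L, 1L, 2L, NA), na.rm = FALSE)) {
    if (any(!is.na(calls) & !(calls %in% 0:2))) {
      stop("calls must be dosages 0, 1, 2 or NA", call. = FALSE)
    }
  }
  if (!is.null(depth) && !all(dim(depth) == dim(calls))) {
    stop("`depth` must have the same shape as `calls`", call. = FALSE)
  }
  if (!is.null(quality) && length(quality) != nrow(sites)) {
    stop("`quality` must have one value per site", call. = FALSE)
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("S%04d", seq_len(nrow(calls)))
  }
  structure(list(calls = calls, sites = sites, depth = depth,
                 quality = quality),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$sites$chrom))))
  invisible(x)
}

#' Number of samples / sites
#' @param gm A [genotype_matrix()].
#' @return Integer count.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_sites <- function(gm) ncol(gm$calls)

# Subset a genotype matrix by site index (logical or integer).
subset_sites <- function(gm, idx) {
  genotype_matrix(gm$calls[, idx, drop = FALSE],
                  gm$sites[idx, ],
                  if (!is.null(gm$depth)) gm$depth[, idx, drop = FALSE],
                  if (!is.null(gm$quality)) gm$quality[idx])
}
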