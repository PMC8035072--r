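#' Select the best alignment hit per query
#'
#' Orders hits by E-value (ascending), breaking ties by bitscore
#' (descending) and then alignment length (descending); any residual tie is
#' broken by subject id (lexicographic) and flagged.
#'
#' @param hits `data.frame` of BLAST-tabular-style hits with columns
#'   `query_id`, `subject_id`, `identity`, `align_len`, `evalue`,
#'   `bitscore`.
#' @return `data.table` with one row per query (the winning hit) and a
#'   logical `tie_broken` column marking arbitrary (subject-id) tie breaks.
#' @export
select_best_hit <- function(hits) {
  h <- as.data.table(hits)
  if (!nrow(h)) return(h)
  setorder(h, query_id, evalue, -bitscore, -align_len, subject_id)
  best <- h[, {
    tb <- .N > 1 && evalue[2] == evalue[1] && bitscore[2] == bitscore[1] &&
      align_len[2] == align_len[1]
    c(.SD[1], list(tie_broken = tb))
  }, by = query_id]
  best
}

#' Reciprocal-best-hit selection
#'
#' Keeps pairs `(q, s)` such that `s` is `q`'s best hit in the forward
#' direction and `q` is `s`'s best hit in the reverse direction, within one
#' subject (sub)genome. Best hits are determined by [select_best_hit()] in
#' each direction independently.
#'
#' @param forward Hits of queries against the subject set.
#' @param reverse Hits of subjects against the query set (`query_id` and
#'   `subject_id` swapped relative to `forward`).
#' @return `data.table` of reciprocal pairs (forward rows), with attributes
#'   `n_forward_best`, `n_reciprocal` and `n_dropped`.
#' @export
select_reciprocal_best <- function(forward, reverse) {
  fb <- select_best_hit(forward)
  rb <- select_best_hit(reverse)
  rev_best <- stats::setNames(rb$subject_id, rb$query_id)
  keep <- !is.na(rev_best[fb$subject_id]) &
    rev_best[fb$subject_id] == fb$query_id
  out <- fb[keep]
  setattr(out, "n_forward_best", nrow(fb))
  setattr(out, "n_reciprocal", nrow(out))
  setattr(out, "n_dropped", nrow(fb) - nrow(out))
  out[]
}

#' Binned percent-identity profile along a genome
#'
#' Mean percent identity of reciprocal best matches in sliding bins of
#' consecutive matches ordered by query genomic position (defaults: bins of
#' 100 matches in increments of 20). The bin position is the mean match
#' position of its members. Bins never span chromosomes; trailing bins with
#' fewer than `bin` matches are dropped.
#'
#' @param rbh `data.frame` of RBH records with columns `chrom`, `pos`
#'   (query gene position), `identity`, and optionally `subject_genome`.
#' @param bin,step Bin size and increment, in matches.
#' @return `data.table` with `chrom`, `mean_pos`, `value` (mean identity),
#'   `n_sites` (= `bin`), `subject_genome`, `statistic = "identity"`.
#' @export
binned_identity_profile <- function(rbh, bin = 100L, step = 20L) {
  rb <- as.data.table(rbh)
  if (!"subject_genome" %in% names(rb)) rb$subject_genome <- "subject"
  out <- list()
  for (sg in unique(rb$subject_genome)) {
    for (ch in unique(rb$chrom[rb$subject_genome == sg])) {
      seg <- rb[subject_genome == sg & chrom == ch][order(pos)]
      starts <- .site_windows(nrow(seg), bin, step)
      for (s in starts) {
        w <- s:(s + bin - 1L)
        out[[length(out) + 1L]] <- data.table(
          chrom = ch, mean_pos = mean(seg$pos[w]),
          value = mean(seg$identity[w]), n_sites = bin,
          subject_genome = sg, statistic = "identity")
      }
    }
  }
  if (!length(out)) {
    return(data.table(chrom = character(), mean_pos = numeric(),
                      value = numeric(), n_sites = integer(),
                      subject_genome = character(), statistic = character()))
  }
  rbindlist(out)
}
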