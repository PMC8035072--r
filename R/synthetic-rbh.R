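#' Simulate mosaic reciprocal-best-hit tables
#'
#' Emulates a query CDS set aligned against the transcriptomes of several
#' subject (sub)genomes, where the mean identity to each subject varies
#' along the query genome in segments (a "mosaic"). For every gene and
#' subject genome a true ortholog hit is emitted in both directions with
#' identity drawn around the planted segment mean, plus optional decoy
#' secondary hits at worse E-value and lower bitscore. Reciprocal-best-hit
#' selection recovers exactly the planted pairs, and binned identity
#' profiles recover the planted segment means.
#'
#' @param n_genes Number of query genes; gene `i` sits at position
#'   `gene_spacing * i` on chromosome `chr1`.
#' @param segments Integer vector of segment ends (gene indices); segments
#'   partition `1:n_genes`, e.g. `c(300, 700, 1000)`.
#' @param identities Matrix (or vector for one subject) of mean percent
#'   identities, segments x subject genomes; column names label the
#'   subjects.
#' @param sd_identity Within-segment standard deviation of identity.
#' @param decoy_rate Fraction of genes additionally given a decoy hit with
#'   higher E-value and lower bitscore than the true hit.
#' @param gene_spacing Genomic spacing between genes in bp.
#' @param seed RNG seed.
#' @return List of class `sim_rbh` with `forward` and `reverse` hit tables
#'   (per subject genome, stacked, column `subject_genome`), `gene_pos`
#'   (`data.table` of query gene positions) and `truth` (planted identity
#'   per gene and subject genome).
#' @export
simulate_rbh_mosaic <- function(n_genes, segments, identities,
                                sd_identity = 1, decoy_rate = 0.3,
                                gene_spacing = 1e5, seed = 1L) {
  if (is.vector(identities)) identities <- matrix(identities, ncol = 1)
  if (is.null(colnames(identities))) {
    colnames(identities) <- paste0("subject", seq_len(ncol(identities)))
  }
  if (any(identities < 0) || any(identities > 100)) {
    stop("identities must lie in [0, 100]", call. = FALSE)
  }
  if (tail(segments, 1) != n_genes || is.unsorted(segments, strictly = TRUE)) {
    stop("`segments` must strictly increase and end at `n_genes`",
         call. = FALSE)
  }
  if (length(segments) != nrow(identities)) {
    stop("one identity row per segment required", call. = FALSE)
  }
  local_seed(seed)
  seg_of <- findInterval(seq_len(n_genes) - 1L, c(0L, segments),
                         rightmost.closed = FALSE)
  qid <- sprintf("gene%05d", seq_len(n_genes))
  pos <- gene_spacing * seq_len(n_genes)
  fwd <- list(); rev <- list(); truth <- list()
  for (sg in colnames(identities)) {
    sid <- sprintf("%s_t%05d", sg, seq_len(n_genes))
    ident <- pmin(100, pmax(0, rnorm(
      n_genes, identities[seg_of, sg], sd_identity)))
    alen <- round(runif(n_genes, 600, 1800))
    escore <- 10^(-runif(n_genes, 50, 180))
    bits <- round(alen * ident / 100 * 2)
    f <- data.table(query_id = qid, subject_id = sid, identity = ident,
                    align_len = alen, evalue = escore, bitscore = bits,
                    chrom = "chr1", pos = pos, subject_genome = sg)
    r <- data.table(query_id = sid, subject_id = qid, identity = ident,
                    align_len = alen, evalue = escore, bitscore = bits,
                    subject_genome = sg)
    n_decoy <- round(decoy_rate * n_genes)
    if (n_decoy > 0) {
      pick <- sample.int(n_genes, n_decoy)
      wrong <- sample.int(n_genes, n_decoy)  # decoy pairs with another gene
      dec <- data.table(query_id = qid[pick],
                        subject_id = sid[wrong],
                        identity = pmax(0, ident[pick] - runif(n_decoy, 5, 15)),
                        align_len = round(alen[pick] * 0.7),
                        evalue = escore[pick] * 10^runif(n_decoy, 5, 20),
                        bitscore = round(bits[pick] * 0.6),
                        chrom = "chr1", pos = pos[pick], subject_genome = sg)
      f <- rbind(f, dec)
    }
    fwd[[sg]] <- f
    rev[[sg]] <- r
    truth[[sg]] <- data.table(query_id = qid, subject_genome = sg,
                              segment = seg_of,
                              planted_identity = identities[seg_of, sg])
  }
  structure(list(forward = rbindlist(fwd), reverse = rbindlist(rev),
                 gene_pos = data.table(query_id = qid, chrom = "chr1",
                                       pos = pos),
                 truth = rbindlist(truth)),
            class = "sim_rbh")
}
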