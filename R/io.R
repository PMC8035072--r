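#' Read and write the pipeline's tabular formats
#'
#' Plain-TSV readers and writers for each input the pipeline consumes:
#' per-bin read counts (`sample_id`, `chrom`, `bin_start`, `count`),
#' pairs-style Hi-C links (`chrom1`, `pos1`, `chrom2`, `pos2`), a
#' genotype table (site columns `chrom`, `pos`, `ref`, `alt`, `qual`, then
#' one `dosage:depth` column per sample, `.` for missing) and BLAST
#' tabular (outfmt-6-compatible) hit tables. Generated artifacts are
#' written in the same formats the pipeline reads, so simulator output
#' doubles as a format round-trip check.
#'
#' @param x Object to write (see details per function).
#' @param path File path.
#' @return Readers return `data.table`s (or a [genotype_matrix()]);
#'   writers return `path` invisibly.
#' @name ryescan-io
NULL

#' @rdname ryescan-io
#' @export
write_bin_counts <- function(x, path) {
  fwrite(as.data.table(x)[, .(sample_id, chrom, bin_start, count)],
         path, sep = "\t")
  invisible(path)
}

#' @rdname ryescan-io
#' @export
read_bin_counts <- function(path) {
  fread(path, sep = "\t", colClasses = list(character = c("sample_id",
                                                          "chrom")))
}

#' @rdname ryescan-io
#' @export
write_hic_links <- function(x, path) {
  fwrite(as.data.table(x)[, .(chrom1, pos1, chrom2, pos2)], path, sep = "\t")
  invisible(path)
}

#' @rdname ryescan-io
#' @export
read_hic_links <- function(path) {
  fread(path, sep = "\t", colClasses = list(character = c("chrom1",
                                                          "chrom2")))
}

#' @rdname ryescan-io
#' @param gm A [genotype_matrix()] (for `write_genotype_tsv`).
#' @export
write_genotype_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  depth <- gm$depth %||% matrix(0L, nrow(gm$calls), ncol(gm$calls))
  cells <- matrix(sprintf("%d:%d", gm$calls, depth), nrow(gm$calls))
  cells[is.na(gm$calls)] <- sprintf(".:%d", depth[is.na(gm$calls)])
  tab <- data.table(chrom = gm$sites$chrom, pos = gm$sites$pos,
                    ref = gm$sites$ref, alt = gm$sites$alt,
                    qual = gm$quality %||% rep(NA_real_, ncol(gm$calls)))
  for (i in seq_len(nrow(gm$calls))) {
    tab[[rownames(gm$calls)[i]]] <- cells[i, ]
  }
  fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' @rdname ryescan-io
#' @export
read_genotype_tsv <- function(path) {
  tab <- fread(path, sep = "\t")
  fixed <- c("chrom", "pos", "ref", "alt", "qual")
  ids <- setdiff(names(tab), fixed)
  parse_col <- function(v) {
    parts <- strsplit(v, ":", fixed = TRUE)
    g <- vapply(parts, `[[`, character(1), 1)
    d <- as.integer(vapply(parts, `[[`, character(1), 2))
    call <- rep(NA_integer_, length(g))
    ok <- g != "."
    call[ok] <- as.integer(g[ok])
    list(call = call, depth = d)
  }
  calls <- matrix(NA_integer_, length(ids), nrow(tab),
                  dimnames = list(ids, NULL))
  depth <- matrix(0L, length(ids), nrow(tab), dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    p <- parse_col(tab[[ids[i]]])
    calls[i, ] <- p$call
    depth[i, ] <- p$depth
  }
  genotype_matrix(calls, tab[, .(chrom, pos, ref, alt)], depth,
                  quality = tab$qual)
}

#' @rdname ryescan-io
#' @export
write_blast_tab <- function(x, path) {
  h <- as.data.table(x)
  # outfmt 6 column order; unused alignment coordinates written as zeros
  tab <- data.table(qseqid = h$query_id, sseqid = h$subject_id,
                    pident = h$identity, length = h$align_len,
                    mismatch = 0L, gapopen = 0L,
                    qstart = 1L, qend = h$align_len,
                    sstart = 1L, send = h$align_len,
                    evalue = h$evalue, bitscore = h$bitscore)
  fwrite(tab, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname ryescan-io
#' @export
read_blast_tab <- function(path) {
  tab <- fread(path, sep = "\t", header = FALSE,
               col.names = c("qseqid", "sseqid", "pident", "length",
                             "mismatch", "gapopen", "qstart", "qend",
                             "sstart", "send", "evalue", "bitscore"))
  data.table(query_id = tab$qseqid, subject_id = tab$sseqid,
             identity = tab$pident, align_len = tab$length,
             evalue = tab$evalue, bitscore = tab$bitscore)
}

#' Read biallelic SNPs from a VCF into a genotype matrix
#'
#' Thin wrapper over `vcfR`: keeps biallelic SNP records, converts GT to
#' alt-dosages, honours per-call DP and site QUAL.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  dosage <- function(g) {
    g <- sub("\\|", "/", g)
    ifelse(is.na(g) | g == "./.", NA_integer_,
           (g == "0/1" | g == "1/0") + 2L * (g == "1/1"))
  }
  calls <- t(apply(gt, 2, dosage))
  dim(calls) <- c(ncol(gt), nrow(gt))
  rownames(calls) <- colnames(gt)
  dp <- tryCatch(
    t(vcfR::extract.gt(v, element = "DP",
                       as.numeric = TRUE)[biallelic, , drop = FALSE]),
    error = function(e) NULL)
  genotype_matrix(
    calls,
    data.table(chrom = fix$CHROM[biallelic],
               pos = as.integer(fix$POS[biallelic]),
               ref = fix$REF[biallelic], alt = fix$ALT[biallelic]),
    depth = dp,
    quality = suppressWarnings(as.numeric(fix$QUAL[biallelic])))
}
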