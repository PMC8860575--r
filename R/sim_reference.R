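#' Generate a toy reference genome with one 3'UTR per gene
#'
#' Builds a few small contigs (<= 100 kb each) carrying one non-overlapping
#' 3'UTR interval per gene, on both strands, with transcript-strand T
#' content of at least 20% so that T>C conversions are observable in
#' simulated SLAM-seq reads.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (named [Biostrings::DNAStringSet]) and `utrs`
#'   (GRanges, 1-based closed in memory; written as 0-based half-open BED by
#'   [write_reference()]), with a `gene_id` metadata column.
#' @export
gen_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  if (n < 1L) stop("n_genes must be >= 1")
  contig_cap <- 100000L
  max_contigs <- 20L
  gap <- 200L
  max_utr <- max(cfg$utr_length_range)
  if (n * (max_utr + gap) > contig_cap * max_contigs) {
    stop("n_genes exceeds toy genome capacity (",
         contig_cap * max_contigs, " bp)")
  }
  with_seed(derive_seed(cfg$seed, "reference"), {
    lens <- sample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]),
                   n, replace = TRUE)
    strands <- ifelse(stats::runif(n) < cfg$minus_strand_fraction, "-", "+")
    # genome-strand base frequencies; A/T enriched so both strands carry
    # enough transcript-strand T
    draw_seq <- function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    }
    utr_seq <- character(n)
    for (i in seq_len(n)) {
      t_base <- if (strands[i] == "+") "T" else "A" # genomic base read as transcript T
      repeat {
        s <- draw_seq(lens[i])
        tc <- sum(strsplit(s, "")[[1]] == t_base) / lens[i]
        if (tc >= 0.20) break
      }
      utr_seq[i] <- s
    }
    # pack UTRs onto contigs left to right with random filler between them
    chrom <- character(n); start <- integer(n)
    contigs <- list(); cur <- character(0); cursor <- 0L; ci <- 1L
    for (i in seq_len(n)) {
      need <- gap + lens[i]
      if (cursor + need + gap > contig_cap) {
        contigs[[paste0("contig", ci)]] <-
          paste0(paste(cur, collapse = ""), draw_seq(gap))
        ci <- ci + 1L; cur <- character(0); cursor <- 0L
      }
      cur <- c(cur, draw_seq(gap), utr_seq[i])
      chrom[i] <- paste0("contig", ci)
      start[i] <- cursor + gap + 1L # 1-based
      cursor <- cursor + need
    }
    contigs[[paste0("contig", ci)]] <-
      paste0(paste(cur, collapse = ""), draw_seq(gap))
    genome <- Biostrings::DNAStringSet(unlist(contigs))
    gene_id <- sprintf("gene%03d", seq_len(n))
    utrs <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start, width = lens),
      strand = strands,
      gene_id = gene_id,
      seqlengths = stats::setNames(Biostrings::width(genome), names(genome)))
    list(genome = genome, utrs = utrs)
  })
}

#' Write a simulated reference to FASTA + BED
#' @param reference output of [gen_reference()].
#' @param dir output directory (created if needed).
#' @return named character vector of the two file paths.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  bed <- file.path(dir, "utrs.bed")
  Biostrings::writeXStringSet(reference$genome, fa)
  write_bed(reference$utrs, bed)
  c(fasta = fa, bed = bed)
}
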