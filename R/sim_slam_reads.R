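#' Simulate SLAM-seq reads over the 3'UTRs of a toy reference
#'
#' Emulates metabolic labeling of nascent RNA with 4-thiouridine: each read
#' is drawn from a labeled transcript with probability `labeled_fraction`;
#' labeled reads carry T>C conversions at transcript-strand T positions
#' (genomic T on plus-strand genes, genomic A -> G on minus-strand genes),
#' each independently with probability `conversion_rate`. All reads
#' additionally carry uniform sequencing errors at `seq_error_rate` per
#' base. Optionally, per-gene homozygous SNP positions are planted that
#' mimic conversions in every read; their coordinates are returned so a
#' mask can be exercised downstream. The labeled/unlabeled flag is ground
#' truth only and is never written into the SAM.
#'
#' @param cfg a [sim_config()].
#' @param reference output of [gen_reference()].
#' @param sample_id sample label attached to the reads.
#' @param labeled_fraction scalar or per-gene vector overriding the config.
#' @param snp_per_gene number of conversion-mimicking SNP positions planted
#'   per gene (default 0).
#' @return list with `reads` (data.frame of SAM-shaped records), `truth`
#'   (per-read `truth_labeled`, per-gene `truth_labeled_fraction`) and
#'   `snps` (data.frame chrom/pos of planted SNPs).
#' @export
gen_slam_reads <- function(cfg, reference, sample_id = "s1",
                           labeled_fraction = cfg$labeled_fraction,
                           snp_per_gene = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  utrs <- reference$utrs
  n <- length(utrs)
  lf <- rep_len(labeled_fraction, n)
  if (cfg$conversion_rate == 0 && any(lf > 0)) {
    warning("conversion_rate is 0 with labeled_fraction > 0: ",
            "labeled reads are indistinguishable from unlabeled reads")
  }
  rl <- cfg$read_length
  if (any(GenomicRanges::width(utrs) < rl)) {
    stop("all UTRs must be at least read_length long")
  }
  with_seed(derive_seed(cfg$seed, paste0("slam_reads:", sample_id)), {
    out <- vector("list", n)
    truth_reads <- vector("list", n)
    snps <- list()
    for (i in seq_len(n)) {
      chrom <- as.character(GenomeInfoDb::seqnames(utrs)[i])
      ustart <- GenomicRanges::start(utrs)[i]
      uend <- GenomicRanges::end(utrs)[i]
      strand <- as.character(GenomicRanges::strand(utrs)[i])
      gid <- utrs$gene_id[i]
      contig <- as.character(reference$genome[[chrom]])
      t_base <- if (strand == "+") "T" else "A"
      c_base <- if (strand == "+") "C" else "G"
      # plant homozygous SNPs at conversion-mimicking positions
      snp_pos <- integer(0)
      if (snp_per_gene > 0L) {
        cand <- ustart:uend
        cand <- cand[substring(contig, cand, cand) == t_base]
        snp_pos <- sort(sample(cand, min(snp_per_gene, length(cand))))
        for (p in snp_pos) substr(contig, p, p) <- c_base
        snps[[length(snps) + 1L]] <-
          data.frame(chrom = chrom, pos = snp_pos, gene_id = gid)
      }
      ndepth <- cfg$depth
      starts <- sample(seq(ustart, uend - rl + 1L), ndepth, replace = TRUE)
      labeled <- stats::runif(ndepth) < lf[i]
      seqs <- character(ndepth)
      for (j in seq_len(ndepth)) {
        s <- strsplit(substring(contig, starts[j], starts[j] + rl - 1L),
                      "")[[1]]
        if (labeled[j] && cfg$conversion_rate > 0) {
          tpos <- which(s == t_base)
          conv <- tpos[stats::runif(length(tpos)) < cfg$conversion_rate]
          s[conv] <- c_base
        }
        if (cfg$seq_error_rate > 0) {
          err <- which(stats::runif(rl) < cfg$seq_error_rate)
          for (e in err) {
            s[e] <- sample(setdiff(c("A", "C", "G", "T"), s[e]), 1L)
          }
        }
        seqs[j] <- paste(s, collapse = "")
      }
      ref_sub <- substring(as.character(reference$genome[[chrom]]),
                           starts, starts + rl - 1L)
      mdnm <- mapply(md_nm_tags, ref_sub, seqs,
                     SIMPLIFY = FALSE, USE.NAMES = FALSE)
      out[[i]] <- data.frame(
        qname = sprintf("%s_%s_r%04d", sample_id, gid, seq_len(ndepth)),
        flag = if (strand == "+") 0L else 16L,
        chrom = chrom, pos = starts, mapq = 255L,
        cigar = paste0(rl, "M"),
        seq = seqs, qual = strrep("I", rl),
        nm = vapply(mdnm, `[[`, integer(1), "nm"),
        md = vapply(mdnm, `[[`, character(1), "md"),
        sample_id = sample_id, gene_id = gid,
        stringsAsFactors = FALSE)
      truth_reads[[i]] <- data.frame(
        qname = out[[i]]$qname, truth_gene = gid,
        truth_labeled = labeled, stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, out)
    reads <- reads[order(reads$chrom, reads$pos), , drop = FALSE]
    rownames(reads) <- NULL
    truth <- list(
      reads = do.call(rbind, truth_reads),
      genes = data.frame(gene_id = utrs$gene_id,
                         truth_labeled_fraction = lf,
                         stringsAsFactors = FALSE))
    snps <- if (length(snps)) do.call(rbind, snps) else
      data.frame(chrom = character(0), pos = integer(0),
                 gene_id = character(0))
    list(reads = reads, truth = truth, snps = snps)
  })
}

# MD/NM tags for a gapless (all-M) alignment
md_nm_tags <- function(ref, read) {
  r <- utf8ToInt(ref); q <- utf8ToInt(read)
  mm <- which(r != q)
  if (length(mm) == 0L) {
    return(list(md = as.character(nchar(ref)), nm = 0L))
  }
  parts <- character(0); prev <- 0L
  for (p in mm) {
    parts <- c(parts, as.character(p - prev - 1L), substring(ref, p, p))
    prev <- p
  }
  parts <- c(parts, as.character(nchar(ref) - prev))
  list(md = paste(parts, collapse = ""), nm = length(mm))
}

#' Write simulated reads as a SAM file
#'
#' Emits a header with one `@SQ` line per contig followed by the read
#' records with `NM` and `MD` tags.
#'
#' @param reads data.frame from [gen_slam_reads()].
#' @param reference output of [gen_reference()] (for contig lengths).
#' @param path output `.sam` path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(reads, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference$genome),
                   Biostrings::width(reference$genome)))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d\tMD:Z:%s",
                 reads$qname, reads$flag, reads$chrom, reads$pos, reads$mapq,
                 reads$cigar, reads$seq, reads$qual, reads$nm, reads$md)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write planted SNP positions as a minimal VCF mask
#' @param snps data.frame with `chrom`, `pos` columns.
#' @param path output `.vcf` path.
#' @return invisibly, `path`.
#' @export
write_snp_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- if (nrow(snps)) {
    sprintf("%s\t%d\t.\tN\tN\t.\tPASS\t.", snps$chrom, snps$pos)
  } else character(0)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
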