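#' Load aligned reads from SAM or BAM into a flat table
#'
#' SAM input is converted on the fly via [Rsamtools::asBam()]. Only
#' primary-alignment fields needed for conversion counting are kept.
#'
#' @param path `.sam` or `.bam` file.
#' @param sample_id sample label to attach (default: file base name).
#' @return data.frame with columns qname, flag, chrom, pos, cigar, seq,
#'   qual, sample_id.
#' @export
load_reads <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(sam|bam)$", "", basename(path))
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(qname = x$qname, flag = x$flag,
             chrom = as.character(x$rname), pos = x$pos, cigar = x$cigar,
             seq = as.character(x$seq), qual = as.character(x$qual),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# aligned (ref_pos, read_idx) pairs from a CIGAR string; M/=/X consume
# both, I/S consume the read, D/N consume the reference
cigar_pairs <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("[0-9]+", "", ops)
  ref <- integer(0); idx <- integer(0)
  rp <- pos; qi <- 1L
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "=", "X")) {
      ref <- c(ref, seq.int(rp, length.out = len[k]))
      idx <- c(idx, seq.int(qi, length.out = len[k]))
      rp <- rp + len[k]; qi <- qi + len[k]
    } else if (op[k] %in% c("I", "S")) {
      qi <- qi + len[k]
    } else if (op[k] %in% c("D", "N")) {
      rp <- rp + len[k]
    }
  }
  list(ref_pos = ref, read_idx = idx)
}

#' Count T>C conversion events of one read within a 3'UTR
#'
#' Counts reference-T to read-C mismatches for plus-strand genes and
#' reference-A to read-G mismatches for minus-strand genes (the
#' transcript-strand T>C), restricted to aligned positions inside the UTR,
#' excluding masked positions and read bases below `min_base_quality`.
#'
#' @param read one-row data.frame with chrom, pos, cigar, seq, qual.
#' @param utr one-element GRanges with strand and `gene_id`.
#' @param reference named [Biostrings::DNAStringSet].
#' @param snp_mask optional data.frame with `chrom`, `pos` of positions to
#'   exclude.
#' @param min_base_quality minimum Phred base quality (default 27).
#' @return integer count of T>C events.
#' @export
count_read_conversions <- function(read, utr, reference, snp_mask = NULL,
                                   min_base_quality = 27L) {
  stopifnot(nrow(read) == 1L, length(utr) == 1L)
  strand <- as.character(GenomicRanges::strand(utr))
  if (!strand %in% c("+", "-")) stop("UTR strand must be + or -")
  if (is.na(read$cigar) || read$cigar == "*") {
    stop("read has no resolvable alignment (CIGAR '*')")
  }
  tc_events_one(read$chrom, read$pos, read$cigar, read$seq, read$qual,
                strand, GenomicRanges::start(utr), GenomicRanges::end(utr),
                reference, snp_mask, min_base_quality)
}

tc_events_one <- function(chrom, pos, cigar, seq, qual, strand,
                          utr_start, utr_end, reference, snp_mask,
                          min_base_quality) {
  ap <- cigar_pairs(pos, cigar)
  if (length(ap$ref_pos) == 0L) return(0L)
  refseq <- as.character(Biostrings::subseq(
    reference[[chrom]], min(ap$ref_pos), max(ap$ref_pos)))
  refb <- utf8ToInt(refseq)[ap$ref_pos - min(ap$ref_pos) + 1L]
  readb <- utf8ToInt(seq)[ap$read_idx]
  qualb <- utf8ToInt(qual)[ap$read_idx] - 33L
  from <- if (strand == "+") utf8ToInt("T") else utf8ToInt("A")
  to <- if (strand == "+") utf8ToInt("C") else utf8ToInt("G")
  ok <- refb == from & readb == to &
    ap$ref_pos >= utr_start & ap$ref_pos <= utr_end &
    qualb >= min_base_quality
  if (!is.null(snp_mask) && nrow(snp_mask) > 0L) {
    masked <- snp_mask$pos[snp_mask$chrom == chrom]
    ok <- ok & !(ap$ref_pos %in% masked)
  }
  sum(ok)
}

#' Count total and labeled reads per 3'UTR and sample
#'
#' A read is assigned to a UTR when at least one aligned base overlaps it;
#' when several UTRs overlap a read, the largest overlap wins and ties go
#' to the lexicographically smaller gene id. A read is labeled when it
#' carries one or more T>C conversions (transcript strand, see
#' [count_read_conversions()]).
#'
#' @param reads data.frame as returned by [load_reads()] or
#'   [gen_slam_reads()], with a `sample_id` column.
#' @param utrs GRanges of non-overlapping 3'UTRs with `gene_id`.
#' @param reference named [Biostrings::DNAStringSet].
#' @param snp_mask optional data.frame (`chrom`, `pos`) of masked positions.
#' @param min_base_quality minimum Phred base quality (default 27).
#' @param samples sample ids defining the output grid (default: those seen
#'   in `reads`; pass explicitly to get an all-zero grid for empty input).
#' @return data.frame with gene_id, sample_id, total_reads, labeled_reads,
#'   tc_events; one row per gene x sample (genes with a UTR but no reads
#'   get zeros).
#' @export
quantify <- function(reads, utrs, reference, snp_mask = NULL,
                     min_base_quality = 27L,
                     samples = sort(unique(reads$sample_id))) {
  genes <- utrs$gene_id
  grid <- expand.grid(gene_id = genes, sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$total_reads <- 0L; grid$labeled_reads <- 0L; grid$tc_events <- 0L
  if (nrow(reads) == 0L) return(grid)
  width <- vapply(seq_len(nrow(reads)), function(i) {
    ops <- regmatches(reads$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", reads$cigar[i]))[[1]]
    len <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("[0-9]+", "", ops)
    sum(len[op %in% c("M", "=", "X", "D", "N")])
  }, integer(1))
  rgr <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$pos, width = width))
  hits <- GenomicRanges::findOverlaps(rgr, utrs, ignore.strand = TRUE)
  if (length(hits) == 0L) return(grid)
  ov <- GenomicRanges::pintersect(
    rgr[S4Vectors::queryHits(hits)], utrs[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE)
  h <- data.frame(read = S4Vectors::queryHits(hits),
                  utr = S4Vectors::subjectHits(hits),
                  ovw = GenomicRanges::width(ov),
                  gene = genes[S4Vectors::subjectHits(hits)])
  h <- h[order(h$read, -h$ovw, h$gene), ]
  h <- h[!duplicated(h$read), ]
  tc <- vapply(seq_len(nrow(h)), function(k) {
    i <- h$read[k]; u <- h$utr[k]
    tc_events_one(reads$chrom[i], reads$pos[i], reads$cigar[i],
                  reads$seq[i], reads$qual[i],
                  as.character(GenomicRanges::strand(utrs)[u]),
                  GenomicRanges::start(utrs)[u],
                  GenomicRanges::end(utrs)[u],
                  reference, snp_mask, min_base_quality)
  }, integer(1))
  agg <- stats::aggregate(
    cbind(total_reads = rep(1L, nrow(h)),
          labeled_reads = as.integer(tc >= 1L), tc_events = tc),
    by = list(gene_id = h$gene, sample_id = reads$sample_id[h$read]),
    FUN = sum)
  key <- paste(grid$gene_id, grid$sample_id)
  akey <- paste(agg$gene_id, agg$sample_id)
  m <- match(akey, key)
  grid$total_reads[m] <- agg$total_reads
  grid$labeled_reads[m] <- agg$labeled_reads
  grid$tc_events[m] <- agg$tc_events
  grid
}

#' Reshape a long conversion-count table to a genes x samples matrix
#' @param counts data.frame from [quantify()].
#' @param value one of `"total_reads"` or `"labeled_reads"`.
#' @return integer matrix, genes x samples.
#' @export
counts_matrix <- function(counts, value = c("total_reads",
                                            "labeled_reads")) {
  value <- match.arg(value)
  genes <- sort(unique(counts$gene_id))
  samples <- sort(unique(counts$sample_id))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(counts$gene_id, genes),
          match(counts$sample_id, samples))] <- counts[[value]]
  m
}

#' Median-of-ratios size factors
#'
#' For each library, the size factor is the median over genes (restricted
#' to genes with positive counts in every library) of the ratio between the
#' library's count and the gene's geometric mean across libraries. The
#' median of an even-length list is the mean of the central pair.
#'
#' @param counts numeric matrix, genes x samples.
#' @param source_assay label recording which assay the factors were learned
#'   from (`"total"` or `"labeled"`).
#' @return named numeric vector of factors with attribute `source_assay`.
#' @export
size_factors <- function(counts, source_assay = "total") {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("cannot estimate size factors: no gene has positive counts in ",
         "every sample")
  }
  gm <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  f <- apply(counts[pos, , drop = FALSE] / gm, 2, stats::median)
  attr(f, "source_assay") <- source_assay
  f
}

#' Normalize labeled (nascent) counts with total-RNA size factors
#'
#' Applies the size factors learned from the total-RNA (QuantSeq-style)
#' counts to the labeled-read matrix without re-estimating them, so the
#' nascent signal inherits the global normalization of the steady-state
#' assay.
#'
#' @param labeled_counts numeric matrix, genes x samples.
#' @param factors_from_total output of [size_factors()] on total counts.
#' @return numeric matrix of normalized labeled counts.
#' @export
cross_normalize <- function(labeled_counts, factors_from_total) {
  src <- attr(factors_from_total, "source_assay")
  if (!is.null(src) && src != "total") {
    stop("size factors must be learned from the total assay, got: ", src)
  }
  labeled_counts <- as.matrix(labeled_counts)
  if (!setequal(colnames(labeled_counts), names(factors_from_total))) {
    stop("sample mismatch between labeled counts and size factors")
  }
  f <- factors_from_total[colnames(labeled_counts)]
  sweep(labeled_counts, 2, f, "/")
}

#' Per-gene probability that a labeled read shows at least one conversion
#'
#' With a per-T conversion probability well below 1, many labeled reads
#' carry no observable T>C event, so the raw labeled/total ratio
#' underestimates the labeled fraction. This computes, per gene, the exact
#' detection probability by enumerating every read window over the UTR:
#' `P(detect | labeled) = mean over windows of 1 - (1 - p_C)^nT`, where
#' `nT` counts countable transcript-strand T positions in the window
#' (masked positions excluded) and `p_C = c(1-e) + (1-c)e/3` combines the
#' conversion rate `c` with the sequencing error rate `e`. The error-floor
#' probability for unlabeled reads (`p_C = e/3`) is returned alongside.
#'
#' @param utrs GRanges of 3'UTRs with `gene_id`.
#' @param reference named [Biostrings::DNAStringSet].
#' @param read_length read length in bases.
#' @param conversion_rate per-T conversion probability.
#' @param seq_error_rate per-base sequencing error rate.
#' @param snp_mask optional data.frame (`chrom`, `pos`) of excluded
#'   positions.
#' @return data.frame with gene_id, p_detect, p_error.
#' @export
detection_probability <- function(utrs, reference, read_length,
                                  conversion_rate, seq_error_rate = 0,
                                  snp_mask = NULL) {
  c_ <- conversion_rate; e <- seq_error_rate
  p_conv <- c_ * (1 - e) + (1 - c_) * e / 3
  p_err <- e / 3
  out <- lapply(seq_along(utrs), function(i) {
    chrom <- as.character(GenomeInfoDb::seqnames(utrs)[i])
    st <- GenomicRanges::start(utrs)[i]
    en <- GenomicRanges::end(utrs)[i]
    strand <- as.character(GenomicRanges::strand(utrs)[i])
    t_base <- if (strand == "+") "T" else "A"
    seqv <- strsplit(as.character(
      Biostrings::subseq(reference[[chrom]], st, en)), "")[[1]]
    is_t <- seqv == t_base
    if (!is.null(snp_mask) && nrow(snp_mask) > 0L) {
      masked <- snp_mask$pos[snp_mask$chrom == chrom]
      is_t[(st:en) %in% masked] <- FALSE
    }
    cs <- cumsum(is_t)
    starts <- seq_len(en - st + 1L - read_length + 1L)
    nT <- cs[starts + read_length - 1L] - c(0, cs)[starts]
    data.frame(gene_id = utrs$gene_id[i],
               p_detect = mean(1 - (1 - p_conv)^nT),
               p_error = mean(1 - (1 - p_err)^nT))
  })
  do.call(rbind, out)
}

#' Estimate the labeled (nascent) fraction per gene and sample
#'
#' Method-of-moments deconvolution of the observed labeled-read rate: with
#' per-gene detection probability `p_detect` and error floor `p_error`
#' (see [detection_probability()]), the observed rate is
#' `q = f * p_detect + (1 - f) * p_error`, so
#' `f = (q - p_error) / (p_detect - p_error)`, clipped to \[0, 1\].
#'
#' @param quant output of [quantify()].
#' @param detect output of [detection_probability()].
#' @return `quant` with added columns labeled_rate, labeled_fraction and
#'   se (delta-method binomial standard error of the estimate).
#' @export
labeled_fraction_estimate <- function(quant, detect) {
  m <- match(quant$gene_id, detect$gene_id)
  pd <- detect$p_detect[m]; pe <- detect$p_error[m]
  q <- ifelse(quant$total_reads > 0,
              quant$labeled_reads / quant$total_reads, NA)
  f <- pmin(pmax((q - pe) / (pd - pe), 0), 1)
  se <- sqrt(pmax(q * (1 - q), 0) / pmax(quant$total_reads, 1)) / (pd - pe)
  quant$labeled_rate <- q
  quant$labeled_fraction <- f
  quant$se <- se
  quant
}
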