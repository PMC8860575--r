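# Shared fixture builders. Everything is generated in code at test time.

# a tiny hand-written reference: one contig, one + gene, one - gene
tiny_reference <- function() {
  #           1234567890123456789012345678901234567890
  seq <- paste0("ACGTTTACGTACGTTACGTAACGTAACGTTAACGTACGTA",
                "TTTTAAAACCCCGGGGTTAATTAAGGCCAATTGGAACCTT")
  genome <- Biostrings::DNAStringSet(c(chrT = seq))
  utrs <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(start = c(3, 45), end = c(30, 75)),
    strand = c("+", "-"), gene_id = c("geneP", "geneM"),
    seqlengths = c(chrT = 80L))
  list(genome = genome, utrs = utrs)
}

# one aligned read as the flat table row quantify()/count_read_conversions()
# expect; qual defaults to Q40 everywhere
make_read <- function(chrom, pos, seq, qual = strrep("I", nchar(seq)),
                      flag = 0L, sample_id = "s1",
                      cigar = paste0(nchar(seq), "M")) {
  data.frame(qname = "r1", flag = flag, chrom = chrom, pos = pos,
             cigar = cigar, seq = seq, qual = qual,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# minimal peptide evidence row using the generator's column schema
make_record <- function(record_id = "p1", sequence = "AAKAA",
                        protein_id = "P1", peptide_start = 1L,
                        sumo_positions = "3", sumo_loc_probs = "0.95",
                        delta_score = 80, decoy = 0L,
                        diagnostic_ions = "QQ", is_sumo_family = 0L,
                        intensities = c(`d-2_1` = 100, d7_1 = 200)) {
  df <- data.frame(record_id = record_id, sequence = sequence,
                   protein_id = protein_id, peptide_start = peptide_start,
                   sumo_positions = sumo_positions,
                   sumo_loc_probs = sumo_loc_probs,
                   delta_score = delta_score, decoy = decoy,
                   diagnostic_ions = diagnostic_ions,
                   is_sumo_family = is_sumo_family,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df[names(intensities)] <- as.list(intensities)
  df
}

# independent per-read, per-base mismatch enumeration oracle for T>C
# counting (never calls package internals)
oracle_tc_count <- function(read, utr_strand, utr_start, utr_end,
                            genome_seq, snp_mask_pos = integer(0),
                            min_bq = 27L) {
  rl <- nchar(read$seq)
  refv <- strsplit(substring(genome_seq, read$pos,
                             read$pos + rl - 1L), "")[[1]]
  readv <- strsplit(read$seq, "")[[1]]
  qualv <- utf8ToInt(read$qual) - 33L
  from <- if (utr_strand == "+") "T" else "A"
  to <- if (utr_strand == "+") "C" else "G"
  n <- 0L
  for (k in seq_len(rl)) {
    gpos <- read$pos + k - 1L
    if (refv[k] == from && readv[k] == to &&
        gpos >= utr_start && gpos <= utr_end &&
        qualv[k] >= min_bq && !(gpos %in% snp_mask_pos)) {
      n <- n + 1L
    }
  }
  n
}

# independent median-of-ratios oracle (median of an even list = mean of
# the central pair, computed by explicit sorting)
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  gm <- apply(counts[keep, , drop = FALSE], 1,
              function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(counts)), function(s) {
    ratios <- sort(counts[keep, s] / gm)
    n <- length(ratios)
    if (n %% 2 == 1) ratios[(n + 1) / 2]
    else mean(ratios[c(n / 2, n / 2 + 1)])
  }, numeric(1))
}

# naive left-to-right sweep merge oracle over 1-based closed intervals,
# merging touching intervals
oracle_sweep_merge <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1L) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# brute-force upper-tail hypergeometric by explicit summation
oracle_hyper_upper <- function(k, n, m, N) {
  kk <- k:min(n, m)
  sum(choose(m, kk) * choose(N - m, n - kk)) / choose(N, n)
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
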