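#' Union peak set across time points
#'
#' Merges overlapping or bookended intervals from any number of peak sets
#' into a disjoint, sorted union (BEDtools-merge semantics: touching
#' intervals are merged). The result is independent of input order and
#' idempotent.
#'
#' @param peak_sets a GRanges, or a list of GRanges (one per time point).
#' @return GRanges of disjoint, sorted union peaks with an `n_members`
#'   column counting the source peaks merged into each.
#' @export
union_peaks <- function(peak_sets) {
  if (inherits(peak_sets, "GRanges")) peak_sets <- list(peak_sets)
  all_peaks <- suppressWarnings(do.call(c, lapply(unname(peak_sets),
                                                  GenomicRanges::granges)))
  if (any(GenomicRanges::width(all_peaks) < 1L)) {
    stop("malformed interval: start must be < end")
  }
  GenomicRanges::strand(all_peaks) <- "*"
  u <- GenomicRanges::reduce(sort(all_peaks), min.gapwidth = 1L)
  hits <- GenomicRanges::countOverlaps(u, all_peaks)
  u$n_members <- hits
  u$peak_id <- sprintf("union%05d", seq_along(u))
  u
}

# 5'-most aligned genomic base of each read: leftmost base for forward
# reads, rightmost for reverse reads
five_prime_anchor <- function(reads) {
  if (inherits(reads, "GRanges")) {
    s <- as.character(GenomicRanges::strand(reads))
    pos <- ifelse(s == "-", GenomicRanges::end(reads),
                  GenomicRanges::start(reads))
    return(GenomicRanges::GRanges(GenomeInfoDb::seqnames(reads),
                                  IRanges::IRanges(pos, width = 1L)))
  }
  # flat read table (see load_reads): flag bit 0x10 marks reverse strand
  width <- vapply(reads$cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("[0-9]+", "", ops)
    sum(len[op %in% c("M", "=", "X", "D", "N")])
  }, integer(1), USE.NAMES = FALSE)
  rev <- bitwAnd(reads$flag, 16L) != 0L
  pos <- ifelse(rev, reads$pos + width - 1L, reads$pos)
  GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(pos, width = 1L))
}

#' Count reads per union peak across libraries
#'
#' A read counts for the union peak containing its 5'-most aligned base
#' (so a read spanning two peaks is assigned once, by convention).
#'
#' @param read_sets named list of per-library reads (GRanges of alignments
#'   or flat read tables from [load_reads()]).
#' @param union GRanges from [union_peaks()].
#' @return integer matrix, union peaks x libraries.
#' @export
count_in_union <- function(read_sets, union) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  m <- sapply(read_sets, function(r) {
    GenomicRanges::countOverlaps(union, five_prime_anchor(r),
                                 ignore.strand = TRUE)
  })
  rownames(m) <- if (!is.null(union$peak_id)) union$peak_id else
    as.character(seq_along(union))
  m
}

#' Flag regions varying over the time course
#'
#' Normalizes counts with median-of-ratios size factors (learned from the
#' count matrix itself unless supplied), tests each region for a time
#' effect with the negative-binomial likelihood-ratio stand-in
#' ([nb_lrt()], full model: one mean per time point; reduced: grand mean),
#' adjusts p-values by Benjamini-Hochberg, and flags regions with
#' `padj <= padj_cutoff` and max/min normalized mean fold change (with a
#' pseudocount of 1) above `fc_cutoff`.
#'
#' @param counts integer matrix, regions x libraries (columns
#'   `<timepoint>_<rep>`).
#' @param time factor of time points per library (default: parsed from
#'   column names).
#' @param sf size factors (default: estimated from `counts`).
#' @param padj_cutoff adjusted-p threshold (default 0.05).
#' @param fc_cutoff fold-change threshold (default 1.5, exclusive).
#' @return data.frame with region, p_value, padj, fold_change, flagged.
#' @export
differential_regions <- function(counts, time = NULL, sf = NULL,
                                 padj_cutoff = 0.05, fc_cutoff = 1.5) {
  counts <- as.matrix(counts)
  if (is.null(time)) time <- sample_time_point(colnames(counts))
  time <- as.factor(time)
  if (nlevels(time) < 2L) stop("need at least 2 time points")
  if (any(table(time) < 2L)) {
    stop("need at least 2 replicates per time point ",
         "(dispersion inestimable)")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  res <- lapply(seq_len(nrow(counts)), function(i) {
    fit <- nb_lrt(norm[i, ], time)
    gm <- tapply(norm[i, ], time, mean) + 1
    data.frame(p_value = fit$p_value, fold_change = max(gm) / min(gm))
  })
  res <- do.call(rbind, res)
  res$padj <- bh_adjust(res$p_value)
  res$flagged <- res$padj <= padj_cutoff & res$fold_change > fc_cutoff
  data.frame(region = rownames(counts) %||% seq_len(nrow(counts)),
             res[c("p_value", "padj", "fold_change", "flagged")],
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a gene-model object for peak annotation
#'
#' @param genes data.frame with gene_id, chrom, strand, start, end
#'   (1-based closed gene body).
#' @param exons GRanges of exons with a `gene_id` column (non-overlapping
#'   within a gene).
#' @return list of class `gene_models` with `genes` (TSS added: `start` on
#'   plus strand, `end` on minus) and `exons`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Annotate peaks relative to genomic features
#'
#' Classifies each peak by its summit position with precedence
#' promoter-TSS > exon > intron > distant promoter > intergenic, and
#' reports the nearest gene by summit-to-TSS distance (ties to the smaller
#' gene id). The promoter window is `promoter` around the TSS (strand
#' aware, default -1000..+100) and the distant-promoter window is
#' `distal` upstream (default -10000..-1000).
#'
#' @param peaks GRanges with a `summit` column (offset from peak start;
#'   defaults to the peak midpoint when absent).
#' @param models a [gene_models()] object.
#' @param promoter numeric length-2 window around the TSS.
#' @param distal numeric length-2 upstream window.
#' @return data.frame with peak_id, summit_pos, category, nearest_gene,
#'   distance_to_tss.
#' @export
annotate_peaks <- function(peaks, models,
                           promoter = c(-1000, 100),
                           distal = c(-10000, -1000)) {
  g <- models$genes
  summit_off <- if (!is.null(peaks$summit)) peaks$summit else
    as.integer(floor(GenomicRanges::width(peaks) / 2))
  summit <- GenomicRanges::start(peaks) + summit_off
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  n <- length(peaks)
  category <- character(n); nearest <- character(n); dist <- integer(n)
  exon_gr <- models$exons
  for (i in seq_len(n)) {
    on_chr <- g[g$chrom == chrom[i], , drop = FALSE]
    if (nrow(on_chr) == 0L) {
      category[i] <- "intergenic"; nearest[i] <- NA_character_
      dist[i] <- NA_integer_
      next
    }
    # signed distance in the gene's reading direction
    sdist <- ifelse(on_chr$strand == "+", summit[i] - on_chr$tss,
                    on_chr$tss - summit[i])
    adist <- abs(summit[i] - on_chr$tss)
    ord <- order(adist, on_chr$gene_id)
    nearest[i] <- on_chr$gene_id[ord[1L]]
    dist[i] <- adist[ord[1L]]
    in_prom <- any(sdist >= promoter[1] & sdist <= promoter[2])
    pt <- GenomicRanges::GRanges(chrom[i],
                                 IRanges::IRanges(summit[i], width = 1L))
    in_exon <- length(GenomicRanges::findOverlaps(pt, exon_gr)) > 0L
    in_body <- any(summit[i] >= on_chr$start & summit[i] <= on_chr$end)
    in_distal <- any(sdist >= distal[1] & sdist < distal[2])
    category[i] <- if (in_prom) "promoter-TSS" else if (in_exon) "exon"
      else if (in_body) "intron" else if (in_distal) "distant promoter"
      else "intergenic"
  }
  data.frame(peak_id = peaks$peak_id %||% sprintf("peak%05d", seq_len(n)),
             summit_pos = summit, category = category,
             nearest_gene = nearest, distance_to_tss = dist,
             stringsAsFactors = FALSE)
}

#' Mean CPM coverage profile around anchor points
#'
#' Computes per-library coverage in counts-per-million mapped reads at
#' positions `-window/2 .. +window/2` (step `step`) around each anchor,
#' averaged over anchors, strand-obliviously. Anchors closer than
#' `window/2` to a contig edge are skipped.
#'
#' @param read_sets named list of per-library reads (GRanges alignments
#'   with seqlengths, or flat read tables plus `seqlen`).
#' @param anchors GRanges of anchor points (e.g. peak summits; midpoint of
#'   each range is used).
#' @param window total window size in bp (even, divisible by `step`).
#' @param step position step in bp (default 10).
#' @return list with `position` (offsets) and `profile` (matrix, positions
#'   x libraries, CPM units), plus `n_anchors` used.
#' @export
mean_profile <- function(read_sets, anchors, window = 4000L, step = 10L) {
  stopifnot(window %% 2L == 0L, window %% step == 0L)
  half <- window %/% 2L
  offs <- seq(-half, half, by = step)
  centers <- as.integer(floor((GenomicRanges::start(anchors) +
                                 GenomicRanges::end(anchors)) / 2))
  chrom <- as.character(GenomeInfoDb::seqnames(anchors))
  prof <- matrix(0, length(offs), length(read_sets),
                 dimnames = list(offs, names(read_sets)))
  n_used <- 0L
  covs <- lapply(read_sets, function(r) {
    gr <- if (inherits(r, "GRanges")) r else
      GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos, width = 1L))
    list(cov = GenomicRanges::coverage(gr), n = length(gr))
  })
  seqlens <- vapply(covs[[1L]]$cov, length, integer(1))
  keep <- centers - half >= 1L & centers + half <= seqlens[chrom]
  if (any(!keep)) {
    message("skipping ", sum(!keep), " anchor(s) nearer than window/2 ",
            "to a contig edge")
  }
  centers <- centers[keep]; chrom <- chrom[keep]
  n_used <- length(centers)
  if (n_used > 0L) {
    for (l in seq_along(covs)) {
      cv <- covs[[l]]$cov
      acc <- numeric(length(offs))
      for (a in seq_len(n_used)) {
        pos <- centers[a] + offs
        len <- length(cv[[chrom[a]]])
        v <- numeric(length(pos))
        inside <- pos >= 1L & pos <= len
        v[inside] <- as.numeric(cv[[chrom[a]]][pos[inside]])
        acc <- acc + v
      }
      prof[, l] <- if (covs[[l]]$n > 0L) {
        acc / n_used * 1e6 / covs[[l]]$n
      } else 0
    }
  }
  list(position = offs, profile = prof, n_anchors = n_used)
}
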