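#' Derive a reproducible child seed for a named random stream
#'
#' Each fixture family (reference, reads, peptides, counts, peaks, ...)
#' consumes its own random stream derived from the master seed, so adding
#' one generator never perturbs the output of another.
#'
#' @param seed master integer seed.
#' @param stream character label of the stream.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) %% 1000003L) * 1009L + (h %% 99991L) + 1L)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed} so package functions never leak
#' RNG state into the caller's session.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Write a data frame as tab-separated text
#' @param x data.frame. @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tab-separated text into a data frame
#' @param path input path.
#' @return data.frame (characters kept as characters).
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "")
}

#' Write genomic intervals as BED6
#'
#' Coordinates are 0-based half-open on disk, matching the in-memory
#' convention used throughout the package for interval arithmetic
#' (GRanges objects are converted at the boundary).
#'
#' @param gr GRanges with a `gene_id` (or `name`) metadata column.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  name <- if (!is.null(gr$gene_id)) gr$gene_id else
    if (!is.null(gr$name)) gr$name else rep(".", length(gr))
  score <- if (!is.null(gr$score)) gr$score else rep(0L, length(gr))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name, score = score,
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*",
                    ".", as.character(GenomicRanges::strand(gr))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a GRanges
#' @param path BED3/BED6 file.
#' @return GRanges; BED name column is exposed as `gene_id`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) gr$gene_id <- gr$name
  gr
}

#' Read a VCF of positions to mask from conversion counting
#'
#' Only CHROM/POS are used; the mask is a set of 1-based genomic positions
#' (e.g. known SNPs that would otherwise masquerade as T>C conversions).
#'
#' @param path VCF file.
#' @return data.frame with columns `chrom`, `pos` (1-based).
#' @export
read_snp_mask <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  data.frame(chrom = as.character(v@fix[, "CHROM"]),
             pos = as.integer(v@fix[, "POS"]),
             stringsAsFactors = FALSE)
}

# shared sample naming: "<timepoint>_<rep>"
sample_names <- function(time_points, n_replicates) {
  as.vector(vapply(time_points, function(tp)
    paste0(tp, "_", seq_len(n_replicates)), character(n_replicates)))
}

sample_time_point <- function(sample_ids) {
  sub("_[0-9]+$", "", sample_ids)
}
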