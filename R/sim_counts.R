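#' Generate a time-course count matrix with planted stage modules
#'
#' Draws gene-level counts from a negative-binomial model
#' `count ~ NB(mean = size_factor[sample] * profile[gene, time], dispersion)`
#' where per-gene mean profiles come from the planted PA/CE/MA module
#' specification. `nb_dispersion = 0` gives the Poisson limit. True
#' per-sample size factors are drawn log-uniformly in \[0.5, 2\] (or supplied)
#' and recorded in the truth sidecar.
#'
#' @param cfg a [sim_config()].
#' @param size_factors optional numeric vector of true per-sample factors
#'   (length `time points * replicates`); drawn if `NULL`.
#' @return list with `counts` (integer matrix, genes x samples, columns
#'   `<timepoint>_<rep>`), and `truth` (list with `modules` data.frame of
#'   per-gene stage/module labels and mean profiles, and `size_factors`).
#' @export
gen_timecourse_counts <- function(cfg, size_factors = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  tp <- cfg$time_points
  samples <- sample_names(tp, cfg$n_replicates)
  ms <- cfg$module_spec
  mean_cols <- paste0("mean_", tp)
  with_seed(derive_seed(cfg$seed, "counts"), {
    if (is.null(size_factors)) {
      size_factors <- exp(stats::runif(length(samples), log(0.5), log(2)))
    }
    stopifnot(length(size_factors) == length(samples),
              all(size_factors > 0))
    names(size_factors) <- samples
    gene_id <- sprintf("gene%03d", seq_len(cfg$n_genes))
    stage <- rep(ms$stage, ms$n_genes)
    module <- rep(seq_len(nrow(ms)), ms$n_genes)
    prof <- as.matrix(ms[module, mean_cols, drop = FALSE])
    rownames(prof) <- gene_id
    # per-gene multiplicative wobble so genes within a module are not
    # identical in scale
    gene_scale <- exp(stats::rnorm(cfg$n_genes, 0, 0.15))
    counts <- matrix(0L, cfg$n_genes, length(samples),
                     dimnames = list(gene_id, samples))
    tp_of_sample <- sample_time_point(samples)
    for (s in seq_along(samples)) {
      mu <- size_factors[s] * gene_scale *
        prof[, paste0("mean_", tp_of_sample[s])]
      counts[, s] <- if (cfg$nb_dispersion == 0) {
        stats::rpois(cfg$n_genes, mu)
      } else {
        stats::rnbinom(cfg$n_genes, mu = mu, size = 1 / cfg$nb_dispersion)
      }
    }
    truth_modules <- data.frame(gene_id = gene_id,
                                truth_module = module,
                                truth_stage = stage,
                                stringsAsFactors = FALSE)
    truth_modules[paste0("truth_", mean_cols)] <- prof
    list(counts = counts,
         truth = list(modules = truth_modules,
                      size_factors = size_factors))
  })
}

#' Generate per-time-point ChIP peak sets with stage-specific intensities
#'
#' Places disjoint peaks on a toy contig, assigns each peak a stage from
#' `cfg$peak_spec`, and simulates per-library single-base read anchors so
#' that the expected read count of a peak in a library follows the stage's
#' intensity profile at that library's time point (Poisson counts, reads
#' uniform within the peak). Two ChIP replicate libraries per time point.
#'
#' @param cfg a [sim_config()].
#' @param n_replicates ChIP libraries per time point (default 2).
#' @param peak_width width of every planted peak in bp (default 400).
#' @return list with `peaks` (GRanges of planted peaks with `gene_id` used
#'   as peak id, plus `summit` offset), `peak_calls` (named list of GRanges,
#'   one per time point: the peaks "called" there, i.e. those with high
#'   intensity at that time point plus all baseline peaks), `reads` (named
#'   list of GRanges read anchors per library), `seqlen` (contig length)
#'   and `truth` (per-peak stage and intensity profile).
#' @export
gen_peak_sets <- function(cfg, n_replicates = 2L, peak_width = 400L) {
  stopifnot(inherits(cfg, "sim_config"))
  spec <- cfg$peak_spec
  tp <- cfg$time_points
  mean_cols <- paste0("mean_", tp)
  n_peaks <- sum(spec$n_peaks)
  gapw <- 600L
  seqlen <- (peak_width + gapw) * (n_peaks + 2L)
  with_seed(derive_seed(cfg$seed, "peaks"), {
    ord <- sample(n_peaks) # interleave stages along the contig
    stage <- rep(spec$stage, spec$n_peaks)[ord]
    prof <- as.matrix(spec[rep(seq_len(nrow(spec)), spec$n_peaks),
                           mean_cols, drop = FALSE])[ord, , drop = FALSE]
    starts <- gapw + (seq_len(n_peaks) - 1L) * (peak_width + gapw) + 1L
    peak_id <- sprintf("peak%03d", seq_len(n_peaks))
    peaks <- GenomicRanges::GRanges(
      "chipContig",
      IRanges::IRanges(start = starts, width = peak_width),
      gene_id = peak_id,
      summit = as.integer(round(peak_width / 2)),
      seqlengths = c(chipContig = seqlen))
    rownames(prof) <- peak_id
    libs <- sample_names(tp, n_replicates)
    reads <- vector("list", length(libs))
    names(reads) <- libs
    for (l in seq_along(libs)) {
      tpl <- sample_time_point(libs[l])
      lambda <- prof[, paste0("mean_", tpl)]
      nread <- stats::rpois(n_peaks, lambda)
      pos <- unlist(mapply(function(st, k) {
        if (k == 0L) integer(0) else
          st + sample.int(peak_width, k, replace = TRUE) - 1L
      }, starts, nread, SIMPLIFY = FALSE))
      # background reads scattered over the contig
      bg <- sample.int(seqlen, max(1L, round(0.05 * sum(nread))),
                       replace = TRUE)
      pos <- sort(c(pos, bg))
      reads[[l]] <- GenomicRanges::GRanges(
        "chipContig", IRanges::IRanges(start = pos, width = 1L),
        seqlengths = c(chipContig = seqlen))
    }
    # per-time-point "peak calls": peaks whose profile at that time point
    # exceeds the stage baseline
    peak_calls <- lapply(tp, function(t) {
      hi <- prof[, paste0("mean_", t)] >= stats::median(prof)
      peaks[hi]
    })
    names(peak_calls) <- tp
    truth <- data.frame(peak_id = peak_id, truth_stage = stage,
                        stringsAsFactors = FALSE)
    truth[paste0("truth_", mean_cols)] <- prof
    list(peaks = peaks, peak_calls = peak_calls, reads = reads,
         seqlen = seqlen, truth = truth)
  })
}
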