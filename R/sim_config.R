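#' Simulation configuration for synthetic multi-omics fixtures
#'
#' Collects every knob of the synthetic-data generators into one validated
#' object. Defaults emulate the structure of a 3T3-L1 adipocyte
#' differentiation time course: four sampling days spanning the
#' pre-adipocyte (PA), clonal-expansion (CE) and mature-adipocyte (MA)
#' stages, three RNA replicates, negative-binomial count noise and three
#' planted stage-specific expression modules.
#'
#' @param seed master integer seed; every generator derives its own
#'   sub-stream from it (see [derive_seed()]).
#' @param n_genes number of genes. Must equal the module sizes summed.
#' @param time_points ordered character vector of time-point labels.
#' @param n_replicates replicates per time point.
#' @param module_spec data.frame with columns `stage` (PA/CE/MA), `n_genes`
#'   and one mean-expression column per time point (`mean_<tp>`). The
#'   default plants one module per stage whose mean profile peaks at that
#'   stage's time points with roughly four within-module standard deviations
#'   of separation between module centroids on the z-score scale.
#' @param nb_dispersion negative-binomial dispersion (Var = mu + disp*mu^2);
#'   `0` requests the Poisson limit.
#' @param labeled_fraction probability that a read derives from a 4sU
#'   labeled (nascent) transcript; scalar or per-gene vector.
#' @param conversion_rate probability that a transcript-strand T in a
#'   labeled read reports as C.
#' @param seq_error_rate per-base probability of a random sequencing error.
#' @param read_length read length in bases.
#' @param depth reads generated per gene per sample.
#' @param utr_length_range 3'UTR lengths, drawn uniformly from this range.
#' @param minus_strand_fraction fraction of genes placed on the minus strand.
#' @param proteomics_spec named list of planted peptide-record counts, see
#'   [gen_peptide_table()].
#' @param peak_spec data.frame with columns `stage`, `n_peaks` and one
#'   `mean_<tp>` column per time point giving the per-stage ChIP intensity
#'   profile, see [gen_peak_sets()].
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 90L,
                       time_points = c("d-2", "d1", "d3", "d7"),
                       n_replicates = 3L,
                       module_spec = NULL,
                       nb_dispersion = 0.05,
                       labeled_fraction = 0.3,
                       conversion_rate = 0.02,
                       seq_error_rate = 0.001,
                       read_length = 50L,
                       depth = 200L,
                       utr_length_range = c(300L, 1500L),
                       minus_strand_fraction = 0.5,
                       proteomics_spec = NULL,
                       peak_spec = NULL) {
  if (length(time_points) < 2L) stop("need at least 2 time points")
  if (is.null(module_spec)) {
    module_spec <- default_module_spec(time_points, n_genes)
  }
  if (is.null(proteomics_spec)) proteomics_spec <- default_proteomics_spec()
  if (is.null(peak_spec)) peak_spec <- default_peak_spec(time_points)
  mean_cols <- paste0("mean_", time_points)
  if (!all(c("stage", "n_genes", mean_cols) %in% names(module_spec))) {
    stop("module_spec needs columns: stage, n_genes, ",
         paste(mean_cols, collapse = ", "))
  }
  if (sum(module_spec$n_genes) != n_genes) {
    stop("module gene counts (", sum(module_spec$n_genes),
         ") must sum to n_genes (", n_genes, ")")
  }
  if (!all(module_spec$stage %in% c("PA", "CE", "MA"))) {
    stop("module stages must be PA, CE or MA")
  }
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  probs <- c(labeled_fraction, conversion_rate, seq_error_rate,
             minus_strand_fraction)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    time_points = as.character(time_points),
    n_replicates = as.integer(n_replicates),
    module_spec = module_spec, nb_dispersion = nb_dispersion,
    labeled_fraction = labeled_fraction, conversion_rate = conversion_rate,
    seq_error_rate = seq_error_rate, read_length = as.integer(read_length),
    depth = as.integer(depth),
    utr_length_range = as.integer(utr_length_range),
    minus_strand_fraction = minus_strand_fraction,
    proteomics_spec = proteomics_spec, peak_spec = peak_spec)
  class(cfg) <- "sim_config"
  cfg
}

# One module per differentiation stage. Profiles are strongly
# stage-polarised so that module centroids on the z-score scale sit about
# four within-module SDs apart at the default dispersion.
default_module_spec <- function(time_points, n_genes) {
  ntp <- length(time_points)
  base <- rep(round(n_genes / 3), 3)
  base[3] <- n_genes - sum(base[1:2])
  peak_at <- function(idx, high = 600, low = 60) {
    p <- rep(low, ntp); p[idx] <- high; p
  }
  pa <- peak_at(1)
  ce <- peak_at(seq(2, max(2, ntp - 1)))
  ma <- peak_at(ntp)
  spec <- data.frame(stage = c("PA", "CE", "MA"), n_genes = base)
  prof <- rbind(pa, ce, ma)
  colnames(prof) <- paste0("mean_", time_points)
  cbind(spec, as.data.frame(prof, row.names = FALSE))
}

default_proteomics_spec <- function() {
  list(n_true = 25L,            # singly-modified peptides passing all filters
       n_decoy = 10L,           # reverse-database hits
       n_low_loc = 10L,         # localization probability <= 0.75
       n_no_diag = 10L,         # no diagnostic remnant ion observed
       n_low_delta = 10L,       # delta <= 40 on C-terminal K not before D/E
       n_multi_supported = 5L,  # doubly-modified, both sites singly seen
       n_multi_unsupported = 5L,# doubly-modified, one site never singly seen
       n_equilibrium_each = 5L) # SUMO-derived peptides per equilibrium class
}

default_peak_spec <- function(time_points) {
  ntp <- length(time_points)
  prof <- function(idx, high = 400, low = 40) {
    p <- rep(low, ntp); p[idx] <- high; p
  }
  spec <- data.frame(stage = c("PA", "CE", "MA"),
                     n_peaks = c(30L, 30L, 30L))
  m <- rbind(prof(1), prof(seq(2, max(2, ntp - 1))), prof(ntp))
  colnames(m) <- paste0("mean_", time_points)
  cbind(spec, as.data.frame(m, row.names = FALSE))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      length(x$time_points), "time points x", x$n_replicates,
      "replicates, seed", x$seed, "\n")
  invisible(x)
}
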