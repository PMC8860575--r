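PIPELINE_KEYS <- c("version", "seed", "out_dir", "thresholds",
                   "simulation", "slam", "proteomics", "modules")
REQUIRED_THRESHOLDS <- c("loc_prob", "delta", "padj", "fc")

#' Validate a pipeline configuration
#'
#' Checks the YAML-shaped configuration before any stage runs: unknown
#' top-level keys are rejected and all thresholds must be present.
#'
#' @param config list (parsed YAML) or path to a YAML file.
#' @return the validated config list (with defaults filled in).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in c("seed", "out_dir", "thresholds")) {
    if (is.null(config[[key]])) stop("missing config key: ", key)
  }
  missing_thr <- setdiff(REQUIRED_THRESHOLDS, names(config$thresholds))
  if (length(missing_thr)) {
    stop("missing threshold key(s): ", paste(missing_thr, collapse = ", "))
  }
  config$version <- config$version %||% 1L
  config$simulation <- config$simulation %||% list()
  config$slam <- config$slam %||% list(n_genes = 4L, depth = 200L,
                                       min_base_quality = 27L)
  config$proteomics <- config$proteomics %||% list(input_mg = 1.0)
  config$modules <- config$modules %||% list(k = 3L)
  config
}

#' Run the full synthetic-data pipeline
#'
#' Orchestrates the stages in dependency order on simulated inputs:
#' time-course counts (generation, size factors, normalization, replicate
#' averaging, log2, row Z-score, module clustering, stage assignment),
#' SLAM-seq (toy reference, simulated reads written as SAM and re-read,
#' conversion counting, cross-normalization), proteomics (peptide table,
#' filtering, site mapping, density, equilibrium) and ChIP peaks (union,
#' per-library counts, differential regions). Writes TSV/JSON outputs plus
#' a manifest recording the config hash, seed, package version and
#' per-file MD5 checksums. All randomness flows from the config seed, so a
#' rerun with the same config is bit-identical.
#'
#' @param config list or YAML path, see [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  sim_args <- config$simulation
  sim_args$seed <- seed
  cfg <- do.call(sim_config, sim_args)
  log_stage <- function(name, nin, nout) {
    message(sprintf("[%s] in=%d out=%d", name, nin, nout))
  }
  outputs <- character(0)

  ## counts stage -----------------------------------------------------------
  tc <- gen_timecourse_counts(cfg)
  sf <- size_factors(tc$counts)
  norm <- cross_normalize(tc$counts, sf)
  tp <- sample_time_point(colnames(norm))
  avg <- sapply(unique(tp), function(t)
    rowMeans(norm[, tp == t, drop = FALSE]))
  z <- zscore_rows(log2(avg + 1))
  k <- config$modules$k %||% 3L
  assign <- cluster_modules(z$matrix, k = k, seed = seed)
  assign <- assign_stages(assign, default_stage_map(cfg$time_points))
  f_counts <- file.path(out, "counts.tsv")
  write_tsv(data.frame(gene_id = rownames(tc$counts), tc$counts,
                       check.names = FALSE), f_counts)
  f_modules <- file.path(out, "modules.json")
  jsonlite::write_json(
    list(k = k,
         module_stage = as.list(assign$module_stage),
         centroids = as.data.frame(assign$centroids),
         members = split(names(assign$cluster), assign$cluster)),
    f_modules, auto_unbox = TRUE, digits = 10)
  outputs <- c(outputs, f_counts, f_modules)
  log_stage("counts", nrow(tc$counts), nrow(tc$counts))

  ## slam stage -------------------------------------------------------------
  slam_cfg <- sim_config(
    seed = seed, n_genes = config$slam$n_genes %||% 4L,
    time_points = cfg$time_points[1:2], n_replicates = 1L,
    module_spec = NULL, depth = config$slam$depth %||% 200L,
    labeled_fraction = cfg$labeled_fraction,
    conversion_rate = cfg$conversion_rate)
  slam_cfg$module_spec <- default_module_spec(slam_cfg$time_points,
                                              slam_cfg$n_genes)
  ref <- gen_reference(slam_cfg)
  ref_files <- write_reference(ref, file.path(out, "slam"))
  sam_paths <- character(0)
  read_tabs <- list()
  for (s in sample_names(slam_cfg$time_points, 1L)) {
    rs <- gen_slam_reads(slam_cfg, ref, sample_id = s)
    p <- file.path(out, "slam", paste0(s, ".sam"))
    write_sam(rs$reads, ref, p)
    sam_paths <- c(sam_paths, p)
    read_tabs[[s]] <- load_reads(p, sample_id = s)
  }
  reads <- do.call(rbind, read_tabs)
  qc <- quantify(reads, ref$utrs, ref$genome,
                 min_base_quality = config$slam$min_base_quality %||% 27L)
  f_slam <- file.path(out, "slam_counts.tsv")
  write_tsv(qc, f_slam)
  outputs <- c(outputs, ref_files, sam_paths, f_slam)
  log_stage("slam", nrow(reads), nrow(qc))

  ## proteomics stage --------------------------------------------------------
  pep <- gen_peptide_table(cfg)
  pep_files <- write_peptide_fixture(pep, file.path(out, "ms"))
  flt <- filter_peptides(pep$table, pep$proteins,
                         loc_prob = config$thresholds$loc_prob,
                         delta = config$thresholds$delta)
  res <- resolve_multiply_sumoylated(flt$accepted)
  sm <- map_sites(res, pep$proteins)
  dens <- sumo_density(sm$sites, config$proteomics$input_mg %||% 1.0)
  eq <- classify_equilibrium(res)
  f_sites <- file.path(out, "ms", "sites.tsv")
  write_tsv(sm$sites, f_sites)
  f_dens <- file.path(out, "ms", "density.tsv")
  write_tsv(dens$summary, f_dens)
  f_eq <- file.path(out, "ms", "equilibrium.tsv")
  write_tsv(data.frame(class = rownames(eq$fractions), eq$fractions,
                       check.names = FALSE), f_eq)
  outputs <- c(outputs, pep_files, f_sites, f_dens, f_eq)
  log_stage("proteomics", nrow(pep$table), nrow(sm$sites))

  ## peaks stage --------------------------------------------------------------
  pk <- gen_peak_sets(cfg)
  u <- union_peaks(pk$peak_calls)
  cm <- count_in_union(pk$reads, u)
  diff <- differential_regions(cm, padj_cutoff = config$thresholds$padj,
                               fc_cutoff = config$thresholds$fc)
  f_union <- file.path(out, "union_peaks.bed")
  ub <- u; ub$gene_id <- ub$peak_id
  write_bed(ub, f_union)
  f_diff <- file.path(out, "peaks_diff.tsv")
  write_tsv(diff, f_diff)
  outputs <- c(outputs, f_union, f_diff)
  log_stage("peaks", length(u), sum(diff$flagged))

  ## manifest -----------------------------------------------------------------
  # hash covers the analytic configuration, not the output location
  cfg_for_hash <- config[setdiff(sort(names(config)), "out_dir")]
  cfg_tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_for_hash, cfg_tmp)
  manifest <- list(
    tool = "sumowaves",
    version = as.character(utils::packageVersion("sumowaves")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_tmp)),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))))
  f_manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE)
  invisible(manifest)
}
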