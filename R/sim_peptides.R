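# Diagnostic remnant ions of the SUMO-2/3 DVFQQQTGG stub
DIAGNOSTIC_IONS <- c("b2-DV", "b3-DVF", "b4-DVFQ", "b5-DVFQQ", "b6-DVFQQQ",
                     "b7-DVFQQQT", "b9-DVFQQQTGG", "QQ", "FQ", "FQQ")

# propeptide tails distinguishing the immature SUMO isoforms
SUMO2_TAIL <- "VY"
SUMO3_TAIL <- "SASRGSVPTPNRCP"

#' Generate a search-engine-style SUMO peptide evidence table
#'
#' Builds a modification-specific peptide table with known truth labels.
#' Planted record families: peptides passing every filter (including
#' C-terminal-lysine cases both exempt from and passing the delta-score
#' rule), peptides failing exactly one rule each (localization probability
#' <= 75%, no diagnostic remnant ion, decoy hit, delta score <= 40 on a
#' C-terminal lysine not preceding Asp/Glu), multiply-SUMOylated peptides
#' with and without single-peptide support for all their sites, and
#' SUMO-2/3-derived peptides of every equilibrium class (mature free,
#' immature SUMO-2, immature SUMO-3, internal, and SUMO-on-SUMO chains).
#'
#' Protein sequences are assembled from the planted peptides, so peptide
#' start positions, modified-lysine positions and the residue following a
#' C-terminal lysine are consistent by construction. Truth labels live only
#' in the returned `truth` sidecar, never in the evidence table itself.
#'
#' @param cfg a [sim_config()]; uses `cfg$proteomics_spec`, `cfg$time_points`,
#'   `cfg$n_replicates` and the `peptides` random stream of `cfg$seed`.
#' @return list with `table` (the analysis-facing evidence data.frame),
#'   `proteins` (named character vector of protein sequences; SUMO-family
#'   entries are named `SUMO2`/`SUMO3`), and `truth` (sidecar data.frame
#'   with `truth_`-prefixed columns).
#' @export
gen_peptide_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  spec <- cfg$proteomics_spec
  samples <- sample_names(cfg$time_points, cfg$n_replicates)
  with_seed(derive_seed(cfg$seed, "peptides"), {
    aa_pool <- strsplit("ADEFHILMNPRSVWY", "")[[1]] # no K/G/Q/T>QQTGG risk
    rand_core <- function(len) {
      paste(sample(aa_pool, len, replace = TRUE), collapse = "")
    }
    proteins <- new.env(parent = emptyenv())
    proteins$seqs <- list()
    # append a peptide to a protein, followed by `next_res` then a spacer;
    # returns the 1-based start of the peptide within the protein
    add_peptide <- function(protein_id, pep, next_res = "A") {
      cur <- proteins$seqs[[protein_id]]
      if (is.null(cur)) cur <- ""
      start <- nchar(cur) + 1L
      proteins$seqs[[protein_id]] <-
        paste0(cur, pep, next_res, rand_core(3L))
      start
    }
    rows <- list()
    truth <- list()
    rid <- 0L
    intensity_draw <- function() {
      stats::setNames(round(stats::rlnorm(length(samples),
                                          meanlog = log(1e6), sdlog = 0.4)),
                      samples)
    }
    emit <- function(sequence, protein_id, peptide_start, sumo_pos,
                     loc_probs, delta, decoy, diag, is_sumo_family,
                     t_accept_filter, t_reason, t_accept_final, t_class,
                     t_sites) {
      rid <<- rid + 1L
      id <- sprintf("pep%04d", rid)
      rows[[rid]] <<- data.frame(
        record_id = id, sequence = sequence, protein_id = protein_id,
        peptide_start = peptide_start,
        sumo_positions = paste(sumo_pos, collapse = ";"),
        sumo_loc_probs = paste(format(loc_probs, digits = 6),
                               collapse = ";"),
        delta_score = delta, decoy = as.integer(decoy),
        diagnostic_ions = paste(diag, collapse = ";"),
        is_sumo_family = as.integer(is_sumo_family),
        t(intensity_draw()),
        stringsAsFactors = FALSE, check.names = FALSE)
      truth[[rid]] <<- data.frame(
        record_id = id,
        truth_accept_filter = t_accept_filter,
        truth_reject_reason = ifelse(is.na(t_reason), NA_character_,
                                     t_reason),
        truth_accept_final = t_accept_final,
        truth_class = ifelse(is.na(t_class), NA_character_, t_class),
        truth_sites = t_sites, stringsAsFactors = FALSE)
      id
    }
    # a singly-modified peptide with an internal lysine
    single_pep <- function() {
      left <- rand_core(sample(3:6, 1L))
      right <- rand_core(sample(3:6, 1L))
      list(seq = paste0(left, "K", right), kpos = nchar(left) + 1L)
    }
    good_diag <- function() sample(DIAGNOSTIC_IONS, sample(1:4, 1L))

    n_targ <- 6L
    targ_ids <- sprintf("TARG%02d", seq_len(n_targ))

    ## --- records passing every filter -------------------------------------
    for (i in seq_len(spec$n_true)) {
      pid <- sample(targ_ids, 1L)
      kind <- i %% 4L
      if (kind == 1L) {           # C-terminal K, next residue D/E: exempt
        p <- rand_core(sample(5:8, 1L))
        seqn <- paste0(p, "K"); kpos <- nchar(seqn)
        start <- add_peptide(pid, seqn, next_res = sample(c("D", "E"), 1L))
        delta <- stats::runif(1, 15, 35) # low delta, but rule exempt
      } else if (kind == 2L) {    # C-terminal K, next residue A, delta > 40
        p <- rand_core(sample(5:8, 1L))
        seqn <- paste0(p, "K"); kpos <- nchar(seqn)
        start <- add_peptide(pid, seqn, next_res = "A")
        delta <- stats::runif(1, 45, 120)
      } else {                    # internal K
        sp <- single_pep(); seqn <- sp$seq; kpos <- sp$kpos
        start <- add_peptide(pid, seqn)
        delta <- stats::runif(1, 45, 120)
      }
      emit(seqn, pid, start, kpos, stats::runif(1, 0.80, 0.999), delta,
           FALSE, good_diag(), FALSE,
           TRUE, NA, TRUE, "conjugated_to_targets",
           paste0(pid, ":", start + kpos - 1L))
    }
    ## --- one-rule rejections ----------------------------------------------
    for (i in seq_len(spec$n_low_loc)) {
      pid <- sample(targ_ids, 1L); sp <- single_pep()
      start <- add_peptide(pid, sp$seq)
      emit(sp$seq, pid, start, sp$kpos, stats::runif(1, 0.30, 0.74),
           stats::runif(1, 45, 120), FALSE, good_diag(), FALSE,
           FALSE, "localization", FALSE, NA, NA_character_)
    }
    for (i in seq_len(spec$n_no_diag)) {
      pid <- sample(targ_ids, 1L); sp <- single_pep()
      start <- add_peptide(pid, sp$seq)
      emit(sp$seq, pid, start, sp$kpos, stats::runif(1, 0.80, 0.999),
           stats::runif(1, 45, 120), FALSE, character(0), FALSE,
           FALSE, "diagnostic", FALSE, NA, NA_character_)
    }
    for (i in seq_len(spec$n_decoy)) {
      pid <- sample(targ_ids, 1L); sp <- single_pep()
      start <- add_peptide(pid, sp$seq)
      emit(sp$seq, pid, start, sp$kpos, stats::runif(1, 0.80, 0.999),
           stats::runif(1, 45, 120), TRUE, good_diag(), FALSE,
           FALSE, "decoy", FALSE, NA, NA_character_)
    }
    for (i in seq_len(spec$n_low_delta)) {
      pid <- sample(targ_ids, 1L)
      p <- rand_core(sample(5:8, 1L))
      seqn <- paste0(p, "K"); kpos <- nchar(seqn)
      start <- add_peptide(pid, seqn, next_res = "A")
      emit(seqn, pid, start, kpos, stats::runif(1, 0.80, 0.999),
           stats::runif(1, 10, 40), FALSE, good_diag(), FALSE,
           FALSE, "delta", FALSE, NA, NA_character_)
    }
    ## --- multiply-SUMOylated peptides -------------------------------------
    multi_region <- function(pid, supported) {
      s1 <- single_pep(); s2 <- single_pep()
      region <- paste0(s1$seq, s2$seq)
      start <- add_peptide(pid, region)
      k1 <- s1$kpos; k2 <- nchar(s1$seq) + s2$kpos
      site1 <- start + k1 - 1L
      site2 <- start + k2 - 1L
      # singly-modified support: always for site 1, only if `supported`
      # for site 2
      emit(s1$seq, pid, start, s1$kpos, stats::runif(1, 0.80, 0.999),
           stats::runif(1, 45, 120), FALSE, good_diag(), FALSE,
           TRUE, NA, TRUE, "conjugated_to_targets",
           paste0(pid, ":", site1))
      if (supported) {
        emit(s2$seq, pid, start + nchar(s1$seq), s2$kpos,
             stats::runif(1, 0.80, 0.999), stats::runif(1, 45, 120),
             FALSE, good_diag(), FALSE,
             TRUE, NA, TRUE, "conjugated_to_targets",
             paste0(pid, ":", site2))
      }
      emit(region, pid, start, c(k1, k2),
           stats::runif(2, 0.80, 0.999), stats::runif(1, 45, 120),
           FALSE, good_diag(), FALSE,
           TRUE, NA, supported,
           if (supported) "conjugated_to_targets" else NA,
           if (supported) paste(paste0(pid, ":", c(site1, site2)),
                                collapse = ";") else NA_character_)
    }
    for (i in seq_len(spec$n_multi_supported)) {
      multi_region(sample(targ_ids, 1L), supported = TRUE)
    }
    for (i in seq_len(spec$n_multi_unsupported)) {
      multi_region(sample(targ_ids, 1L), supported = FALSE)
    }
    ## --- SUMO-2/3-derived peptides: equilibrium classes -------------------
    for (i in seq_len(spec$n_equilibrium_each)) {
      # mature free SUMO-2/3: ends in QQTGG
      start <- add_peptide("SUMO2", "DVFQQQTGG", next_res = "V")
      emit("DVFQQQTGG", "SUMO2", start, integer(0), numeric(0),
           stats::runif(1, 45, 120), FALSE, good_diag(), TRUE,
           TRUE, NA, TRUE, "free_mature", NA_character_)
      # immature SUMO-2: QQTGG followed by the SUMO-2 propeptide tail
      s2 <- paste0("DVFQQQTGG", SUMO2_TAIL)
      start <- add_peptide("SUMO2", s2, next_res = "A")
      emit(s2, "SUMO2", start, integer(0), numeric(0),
           stats::runif(1, 45, 120), FALSE, good_diag(), TRUE,
           TRUE, NA, TRUE, "immature_sumo2", NA_character_)
      # immature SUMO-3: QQTGG followed by the SUMO-3 propeptide tail
      s3 <- paste0("DVFQQQTGG", SUMO3_TAIL)
      start <- add_peptide("SUMO3", s3, next_res = "A")
      emit(s3, "SUMO3", start, integer(0), numeric(0),
           stats::runif(1, 45, 120), FALSE, good_diag(), TRUE,
           TRUE, NA, TRUE, "immature_sumo3", NA_character_)
      # internal SUMO-2/3 peptide (no QQTGG)
      internal <- rand_core(sample(8:12, 1L))
      start <- add_peptide("SUMO2", internal)
      emit(internal, "SUMO2", start, integer(0), numeric(0),
           stats::runif(1, 45, 120), FALSE, good_diag(), TRUE,
           TRUE, NA, TRUE, "internal", NA_character_)
      # SUMO-on-SUMO: a SUMO-family peptide itself carrying a SUMO site
      sp <- single_pep()
      start <- add_peptide("SUMO2", sp$seq)
      emit(sp$seq, "SUMO2", start, sp$kpos, stats::runif(1, 0.80, 0.999),
           stats::runif(1, 45, 120), FALSE, good_diag(), TRUE,
           TRUE, NA, TRUE, "chains",
           paste0("SUMO2:", start + sp$kpos - 1L))
    }
    table <- do.call(rbind, rows)
    rownames(table) <- NULL
    truth <- do.call(rbind, truth)
    prot <- unlist(proteins$seqs)
    list(table = table, proteins = prot, truth = truth)
  })
}

#' Write a simulated peptide fixture to disk
#' @param pep output of [gen_peptide_table()].
#' @param dir output directory.
#' @return named character vector of paths (table TSV, protein FASTA,
#'   truth sidecar TSV).
#' @export
write_peptide_fixture <- function(pep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- file.path(dir, "peptides.tsv")
  fa <- file.path(dir, "proteins.fa")
  tr <- file.path(dir, "peptides_truth.tsv")
  write_tsv(pep$table, tab)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(pep$proteins), fa)
  write_tsv(pep$truth, tr)
  c(table = tab, fasta = fa, truth = tr)
}
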