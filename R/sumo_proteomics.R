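# columns of the peptide evidence schema that are not per-sample intensities
PEPTIDE_META_COLS <- c("record_id", "sequence", "protein_id",
                       "peptide_start", "sumo_positions", "sumo_loc_probs",
                       "delta_score", "decoy", "diagnostic_ions",
                       "is_sumo_family")

intensity_cols <- function(records) {
  setdiff(colnames(records), PEPTIDE_META_COLS)
}

split_chr <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  lapply(strsplit(x, ";"),
         function(v) if (all(is.na(v))) character(0) else v)
}

split_int <- function(x) lapply(split_chr(x), as.integer)

split_num <- function(x) lapply(split_chr(x), as.numeric)

#' Read a protein FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of protein sequences.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*", "", names(aa)))
}

#' Filter SUMO peptide evidence by the manual post-search rules
#'
#' A SUMO-modified record is accepted iff (i) every SUMO localization
#' probability exceeds `loc_prob`, (ii) at least `min_diag_ions` diagnostic
#' remnant ions were observed, (iii) it is not a decoy hit, and (iv) when a
#' SUMO modification sits on the peptide's C-terminal lysine and the next
#' residue in the protein is neither aspartate nor glutamate, its delta
#' score exceeds `delta`. Records without SUMO modifications (e.g. peptides
#' derived from SUMO itself) are subject only to the decoy rule. Each
#' rejection carries exactly one primary reason: the first failing rule in
#' the order localization, diagnostic, decoy, delta.
#'
#' @param records peptide evidence data.frame (see [gen_peptide_table()]
#'   for the column schema).
#' @param proteins named character vector of protein sequences; required to
#'   resolve the residue following a C-terminal lysine.
#' @param loc_prob localization-probability threshold (default 0.75,
#'   exclusive).
#' @param delta delta-score threshold (default 40, exclusive).
#' @param min_diag_ions minimum number of observed diagnostic ions
#'   (default 1).
#' @return list with `accepted` (subset of `records`) and `rejected`
#'   (subset with an added `reason` column).
#' @export
filter_peptides <- function(records, proteins, loc_prob = 0.75, delta = 40,
                            min_diag_ions = 1L) {
  n <- nrow(records)
  mods <- split_int(records$sumo_positions)
  probs <- split_num(records$sumo_loc_probs)
  diags <- split_chr(records$diagnostic_ions)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    has_mod <- length(mods[[i]]) > 0L
    if (has_mod && any(probs[[i]] <= loc_prob)) {
      reason[i] <- "localization"
    } else if (has_mod && length(diags[[i]]) < min_diag_ions) {
      reason[i] <- "diagnostic"
    } else if (records$decoy[i] == 1L) {
      reason[i] <- "decoy"
    } else if (has_mod) {
      seqn <- records$sequence[i]
      cterm <- mods[[i]] == nchar(seqn) &
        substring(seqn, nchar(seqn)) == "K"
      if (any(cterm)) {
        prot <- proteins[records$protein_id[i]]
        if (is.na(prot)) {
          stop("protein sequence context missing for record ",
               records$record_id[i], " (", records$protein_id[i], ")")
        }
        nxt_pos <- records$peptide_start[i] + nchar(seqn)
        nxt <- substring(prot, nxt_pos, nxt_pos)
        if (!nxt %in% c("D", "E") && records$delta_score[i] <= delta) {
          reason[i] <- "delta"
        }
      }
    }
  }
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(accepted = records[is.na(reason), , drop = FALSE],
       rejected = rejected)
}

#' Resolve multiply-SUMOylated peptides against single-site evidence
#'
#' A peptide carrying two or more SUMO modifications is kept only when
#' every one of its protein sites is also evidenced by some accepted
#' singly-SUMOylated peptide; otherwise it is discarded.
#'
#' @param accepted accepted records from [filter_peptides()].
#' @return subset of `accepted` with unsupported multiply-modified peptides
#'   removed.
#' @export
resolve_multiply_sumoylated <- function(accepted) {
  mods <- split_int(accepted$sumo_positions)
  nmod <- lengths(mods)
  site_keys <- function(i) {
    paste0(accepted$protein_id[i], ":",
           accepted$peptide_start[i] + mods[[i]] - 1L)
  }
  singly <- unlist(lapply(which(nmod == 1L), site_keys))
  keep <- vapply(seq_len(nrow(accepted)), function(i) {
    if (nmod[i] < 2L) return(TRUE)
    all(site_keys(i) %in% singly)
  }, logical(1))
  accepted[keep, , drop = FALSE]
}

#' Map accepted peptides to protein SUMO sites and target proteins
#'
#' The site position is `peptide_start + position-in-peptide - 1`; the site
#' intensity per sample is the sum of its supporting peptide intensities.
#' Proteins with at least one site are the SUMO target set.
#'
#' @param accepted resolved records from [resolve_multiply_sumoylated()].
#' @param proteins optional named character vector; when given, each site
#'   residue is validated to be a lysine.
#' @return list with `sites` (data.frame: protein_id, residue_position,
#'   n_supporting, one intensity column per sample) and `targets`
#'   (character vector of protein ids).
#' @export
map_sites <- function(accepted, proteins = NULL) {
  icols <- intensity_cols(accepted)
  mods <- split_int(accepted$sumo_positions)
  idx <- rep(seq_len(nrow(accepted)), lengths(mods))
  if (length(idx) == 0L) {
    sites <- data.frame(protein_id = character(0),
                        residue_position = integer(0),
                        n_supporting = integer(0))
    sites[icols] <- numeric(0)
    return(list(sites = sites, targets = character(0)))
  }
  pos <- accepted$peptide_start[idx] + unlist(mods) - 1L
  prot <- accepted$protein_id[idx]
  if (!is.null(proteins)) {
    res <- substring(proteins[prot], pos, pos)
    bad <- res != "K"
    if (any(bad)) {
      stop("inconsistent peptide/protein mapping: non-lysine residue at ",
           paste(unique(paste0(prot[bad], ":", pos[bad])), collapse = ", "))
    }
  }
  key <- paste0(prot, ":", pos)
  inten <- as.matrix(accepted[idx, icols, drop = FALSE])
  agg <- rowsum(inten, key)
  uk <- rownames(agg)
  n_sup <- as.vector(table(key)[uk])
  sites <- data.frame(
    protein_id = sub(":[0-9]+$", "", uk),
    residue_position = as.integer(sub("^.*:", "", uk)),
    n_supporting = n_sup, stringsAsFactors = FALSE)
  sites[icols] <- agg
  sites <- sites[order(sites$protein_id, sites$residue_position), ]
  rownames(sites) <- NULL
  list(sites = sites, targets = sort(unique(sites$protein_id)))
}

#' Total SUMO site intensity per mg of input protein
#'
#' Divides the summed intensity of all SUMO sites in each sample by that
#' sample's protein starting material (mg), then summarizes replicates of
#' each time point as mean and standard deviation.
#'
#' @param sites site table from [map_sites()].
#' @param input_mg named numeric vector of input protein (mg) per sample,
#'   or a scalar applied to all samples. Must be positive.
#' @return list with `per_sample` (named densities) and `summary`
#'   (data.frame time_point, mean, sd, n).
#' @export
sumo_density <- function(sites, input_mg) {
  icols <- setdiff(colnames(sites),
                   c("protein_id", "residue_position", "n_supporting"))
  totals <- if (nrow(sites)) colSums(as.matrix(sites[icols])) else
    stats::setNames(rep(0, length(icols)), icols)
  if (length(input_mg) == 1L && is.null(names(input_mg))) {
    input_mg <- stats::setNames(rep(input_mg, length(icols)), icols)
  }
  if (any(input_mg <= 0)) stop("input_mg must be positive")
  if (!all(icols %in% names(input_mg))) {
    stop("input_mg missing for samples: ",
         paste(setdiff(icols, names(input_mg)), collapse = ", "))
  }
  dens <- totals / input_mg[icols]
  tp <- sample_time_point(names(dens))
  summ <- do.call(rbind, lapply(unique(tp), function(t) {
    d <- dens[tp == t]
    data.frame(time_point = t, mean = mean(d),
               sd = if (length(d) > 1L) stats::sd(d) else 0,
               n = length(d))
  }))
  list(per_sample = dens, summary = summ)
}

EQUILIBRIUM_CLASSES <- c("conjugated_to_targets", "chains", "free_mature",
                         "immature_sumo2", "immature_sumo3", "internal")

#' Partition SUMO-related peptide intensity into equilibrium classes
#'
#' Classifies each relevant record into exactly one pool: SUMO-modified
#' peptides from SUMO-family proteins are chains; SUMO-modified peptides
#' from any other protein are target conjugation; unmodified SUMO-derived
#' peptides ending in QQTGG are mature free SUMO-2/3; those containing but
#' not ending in QQTGG are immature SUMO-2 (propeptide tail starting VY) or
#' immature SUMO-3 (tail starting SASRGSVPTPNRCP); all other SUMO-derived
#' peptides are internal. A SUMO-derived peptide whose post-QQTGG tail
#' matches neither propeptide is classed internal and reported as an
#' unclassifiable tail. Decoy records and peptides unrelated to SUMO are
#' ignored.
#'
#' @param records peptide evidence data.frame (typically the accepted set).
#' @return list with `class` (per-record class, NA for ignored records),
#'   `fractions` (classes x time points matrix of intensity fractions,
#'   columns summing to 1) and `unclassifiable` (record ids logged as
#'   unclassifiable tails).
#' @export
classify_equilibrium <- function(records) {
  n <- nrow(records)
  mods <- split_int(records$sumo_positions)
  cls <- rep(NA_character_, n)
  unclassifiable <- character(0)
  for (i in seq_len(n)) {
    if (records$decoy[i] == 1L) next
    modified <- length(mods[[i]]) > 0L
    fam <- records$is_sumo_family[i] == 1L
    if (modified) {
      cls[i] <- if (fam) "chains" else "conjugated_to_targets"
    } else if (fam) {
      seqn <- records$sequence[i]
      if (grepl("QQTGG$", seqn)) {
        cls[i] <- "free_mature"
      } else if (grepl("QQTGG", seqn)) {
        tail <- sub("^.*QQTGG", "", seqn)
        if (startsWith(tail, SUMO2_TAIL)) {
          cls[i] <- "immature_sumo2"
        } else if (startsWith(tail, SUMO3_TAIL) ||
                   startsWith(SUMO3_TAIL, tail)) {
          cls[i] <- "immature_sumo3"
        } else {
          cls[i] <- "internal"
          unclassifiable <- c(unclassifiable, records$record_id[i])
        }
      } else {
        cls[i] <- "internal"
      }
    }
  }
  if (length(unclassifiable)) {
    message(length(unclassifiable),
            " SUMO-derived record(s) with unclassifiable post-QQTGG tail ",
            "classed as internal")
  }
  icols <- intensity_cols(records)
  tp <- unique(sample_time_point(icols))
  fractions <- matrix(NA_real_, length(EQUILIBRIUM_CLASSES), length(tp),
                      dimnames = list(EQUILIBRIUM_CLASSES, tp))
  used <- !is.na(cls)
  for (t in tp) {
    cols <- icols[sample_time_point(icols) == t]
    tot_by_class <- vapply(EQUILIBRIUM_CLASSES, function(cl) {
      sum(as.matrix(records[used & cls == cl, cols, drop = FALSE]))
    }, numeric(1))
    total <- sum(tot_by_class)
    fractions[, t] <- if (total > 0) tot_by_class / total else 0
  }
  list(class = cls, fractions = fractions,
       unclassifiable = unclassifiable)
}

#' Average, log-transform, impute and row-standardize LFQ intensities
#'
#' Replicate intensities are averaged per time point with zeros treated as
#' missing; averages are log2-transformed; remaining missing values are
#' imputed by draws from a downshifted Gaussian (mean shifted down by
#' `downshift` row SDs, width `width` times the row SD; rows with fewer
#' than two observed values fall back on the global SD of all observed
#' log2 values); finally rows are Z-score standardized. Rows with no
#' observed value in any time point are dropped.
#'
#' @param intensities numeric matrix, features x samples, with columns
#'   named `<timepoint>_<rep>`.
#' @param seed integer seed for the imputation draws.
#' @param width imputation width as a multiple of the row SD (default 0.3).
#' @param downshift imputation downshift in row SDs (default 1.8).
#' @return list with `zscore` (row-standardized matrix, features x time
#'   points), `log2` (the imputed log2 matrix) and `dropped` (ids of
#'   all-missing rows).
#' @export
lfq_summarize <- function(intensities, seed = 1L, width = 0.3,
                          downshift = 1.8) {
  intensities <- as.matrix(intensities)
  tp <- sample_time_point(colnames(intensities))
  tps <- unique(tp)
  avg <- do.call(cbind, lapply(tps, function(t) {
    m <- intensities[, tp == t, drop = FALSE]
    m[m == 0] <- NA
    rowMeans(m, na.rm = TRUE)
  }))
  dimnames(avg) <- list(rownames(intensities), tps)
  avg[is.nan(avg)] <- NA
  l2 <- log2(avg)
  all_missing <- rowSums(!is.na(l2)) == 0L
  if (any(all_missing)) {
    message("dropping ", sum(all_missing), " all-missing row(s): ",
            paste(utils::head(rownames(l2)[all_missing], 5), collapse = ", "))
    l2 <- l2[!all_missing, , drop = FALSE]
  }
  global_sd <- stats::sd(l2[!is.na(l2)])
  if (!is.finite(global_sd) || global_sd == 0) global_sd <- 1
  with_seed(seed, {
    for (i in seq_len(nrow(l2))) {
      miss <- is.na(l2[i, ])
      if (!any(miss)) next
      obs <- l2[i, !miss]
      s <- if (length(obs) >= 2L) stats::sd(obs) else global_sd
      if (!is.finite(s) || s == 0) s <- global_sd
      l2[i, miss] <- stats::rnorm(sum(miss), mean(obs) - downshift * s,
                                  width * s)
    }
  })
  z <- zscore_rows(l2)
  list(zscore = z$matrix, log2 = l2,
       dropped = rownames(avg)[all_missing])
}
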