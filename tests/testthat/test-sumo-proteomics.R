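test_that("remnant mass reproduces known stub masses and compositions", {
  r <- remnant_mass("DVFQQQTGG")
  expect_equal(r$mass, 960.4301, tolerance = 0.001)
  expect_identical(r$formula, "C41H60N12O15")
  expect_identical(unname(r$composition[c("C", "H", "N", "O")]),
                   c(41L, 60L, 12L, 15L))

  expect_equal(remnant_mass("")$mass, 0)
  expect_equal(remnant_mass("GG")$mass, 114.0429, tolerance = 0.001)
  expect_error(remnant_mass("DVFX"), "unknown residue")
})

test_that("remnant mass is additive over concatenation", {
  set.seed(77)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    a <- paste(sample(aas, sample(1:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:8, 1), replace = TRUE), collapse = "")
    expect_equal(remnant_mass(paste0(a, b))$mass,
                 remnant_mass(a)$mass + remnant_mass(b)$mass,
                 tolerance = 1e-9)
    expect_equal(remnant_mass(paste0(a, b))$composition,
                 remnant_mass(a)$composition + remnant_mass(b)$composition)
  }
})

test_that("filter rules fire individually and in the documented order", {
  proteins <- c(P1 = "AAKAAKAAAKDEAAAAKAAA")

  # localization probability at exactly 0.75 or below is rejected
  r <- make_record(sumo_loc_probs = "0.74")
  out <- filter_peptides(r, proteins)
  expect_equal(out$rejected$reason, "localization")
  out <- filter_peptides(make_record(sumo_loc_probs = "0.75"), proteins)
  expect_equal(out$rejected$reason, "localization")

  # missing diagnostic ions
  out <- filter_peptides(make_record(diagnostic_ions = ""), proteins)
  expect_equal(out$rejected$reason, "diagnostic")

  # decoy (and decoy outranks delta)
  out <- filter_peptides(make_record(decoy = 1L), proteins)
  expect_equal(out$rejected$reason, "decoy")

  # C-terminal K not before D/E: delta 45 accepted, delta 35 rejected
  ctk <- make_record(sequence = "AAK", peptide_start = 4L,
                     sumo_positions = "3", delta_score = 45)
  # protein P1 position 4..6 = "AAK", next residue (7) = "A"
  expect_equal(nrow(filter_peptides(ctk, proteins)$rejected), 0L)
  ctk$delta_score <- 35
  expect_equal(filter_peptides(ctk, proteins)$rejected$reason, "delta")

  # C-terminal K before D: delta rule exempt even at low delta
  ctk_de <- make_record(sequence = "AAAK", peptide_start = 7L,
                        sumo_positions = "4", delta_score = 12)
  # position 7..10 = "AAAK", next residue (11) = "D"
  expect_equal(nrow(filter_peptides(ctk_de, proteins)$rejected), 0L)

  # localization outranks every later rule
  multi_fail <- make_record(sumo_loc_probs = "0.5", decoy = 1L,
                            diagnostic_ions = "")
  expect_equal(filter_peptides(multi_fail, proteins)$rejected$reason,
               "localization")

  # missing protein context for the C-terminal-K rule is an evidence error
  orphan <- make_record(sequence = "AAK", protein_id = "NOPE",
                        sumo_positions = "3", delta_score = 30)
  expect_error(filter_peptides(orphan, proteins), "context")

  # unmodified records are only subject to the decoy rule
  plain <- make_record(sumo_positions = "", sumo_loc_probs = "",
                       diagnostic_ions = "")
  expect_equal(nrow(filter_peptides(plain, proteins)$rejected), 0L)
})

test_that("multiply-SUMOylated resolution follows single-site support", {
  proteins <- c(P1 = strrep("AAKAA", 10))
  single1 <- make_record("s1", "AAKAA", "P1", 1L, "3")
  single2 <- make_record("s2", "AAKAA", "P1", 6L, "3")
  both <- make_record("m1", "AAKAAAAKAA", "P1", 1L, "3;8",
                      sumo_loc_probs = "0.9;0.9")
  acc <- filter_peptides(rbind(single1, single2, both), proteins)$accepted
  expect_equal(nrow(resolve_multiply_sumoylated(acc)), 3L)

  # drop one support: the doubly-modified peptide is discarded
  acc2 <- filter_peptides(rbind(single1, both), proteins)$accepted
  res2 <- resolve_multiply_sumoylated(acc2)
  expect_setequal(res2$record_id, c("s1"))
})

test_that("site mapping aggregates supporting peptides", {
  # peptide at start 10, mod at position 3 -> residue 12
  proteins <- c(P1 = paste0(strrep("A", 11), "K", strrep("A", 10)))
  p1 <- make_record("a", "AAKAA", "P1", 10L, "3",
                    intensities = c(`d-2_1` = 5, d7_1 = 1))
  p2 <- make_record("b", "AKAAA", "P1", 11L, "2",
                    intensities = c(`d-2_1` = 7, d7_1 = 2))
  sm <- map_sites(rbind(p1, p2), proteins)
  expect_equal(nrow(sm$sites), 1L)
  expect_equal(sm$sites$residue_position, 12L)
  expect_equal(sm$sites$`d-2_1`, 12) # 5 + 7
  expect_equal(sm$sites$n_supporting, 2L)
  expect_equal(sm$targets, "P1")

  # non-lysine residue at the mapped position is a validation error
  bad <- make_record("c", "AAKAA", "P1", 1L, "2")
  expect_error(map_sites(bad, proteins), "non-lysine")
})

test_that("SUMO density divides intensity by input and summarizes", {
  sites <- data.frame(protein_id = "P1", residue_position = 1L,
                      n_supporting = 1L, check.names = FALSE)
  sites[c("d-2_1", "d-2_2")] <- list(6e8, 1e9)
  d <- sumo_density(sites, c(`d-2_1` = 2, `d-2_2` = 2))
  expect_equal(unname(d$per_sample["d-2_2"]), 5e8)
  expect_equal(d$summary$n, 2L)

  # equal replicates -> SD 0
  sites[c("d-2_1", "d-2_2")] <- list(1e9, 1e9)
  d2 <- sumo_density(sites, c(`d-2_1` = 2, `d-2_2` = 2))
  expect_equal(d2$summary$sd, 0)

  # zero sites -> density 0
  d0 <- sumo_density(sites[0, ], c(`d-2_1` = 2, `d-2_2` = 2))
  expect_equal(unname(d0$per_sample), c(0, 0))

  expect_error(sumo_density(sites, c(`d-2_1` = 0, `d-2_2` = 2)),
               "positive")
})

test_that("equilibrium classification follows the QQTGG rules", {
  mk <- function(id, seqn, fam, mods = "", probs = "") {
    make_record(id, seqn, if (fam) "SUMO2" else "P1", 1L, mods, probs,
                is_sumo_family = as.integer(fam),
                intensities = c(`d-2_1` = 100, d7_1 = 100))
  }
  recs <- rbind(
    mk("free", "DVFQQQTGG", TRUE),
    mk("imm2", "DVFQQQTGGVY", TRUE),
    mk("imm3", "DVFQQQTGGSASRGSVPTPNRCP", TRUE),
    mk("int", "AFILMNPRSV", TRUE),
    mk("chain", "AAKAA", TRUE, mods = "3", probs = "0.9"),
    mk("conj", "AAKAA", FALSE, mods = "3", probs = "0.9"))
  eq <- classify_equilibrium(recs)
  expect_identical(eq$class,
                   c("free_mature", "immature_sumo2", "immature_sumo3",
                     "internal", "chains", "conjugated_to_targets"))
  expect_true(all(abs(colSums(eq$fractions) - 1) < 1e-9))

  # unclassifiable post-QQTGG tail -> internal, logged
  odd <- mk("odd", "DVFQQQTGGWWWW", TRUE)
  expect_message(eq2 <- classify_equilibrium(rbind(recs, odd)),
                 "unclassifiable")
  expect_identical(eq2$class[7], "internal")
  expect_identical(eq2$unclassifiable, "odd")

  # decoys and non-SUMO unmodified records are ignored
  ignored <- rbind(mk("dec", "AAKAA", FALSE, mods = "3", probs = "0.9"),
                   mk("plain", "AAAAA", FALSE))
  ignored$decoy[1] <- 1L
  eq3 <- classify_equilibrium(ignored)
  expect_true(all(is.na(eq3$class)))
})

test_that("LFQ summarization averages, imputes and standardizes", {
  m <- matrix(c(2, 4, 8, 16), 1,
              dimnames = list("s1", c("d-2_1", "d1_1", "d3_1", "d7_1")))
  out <- lfq_summarize(m, seed = 1)
  expect_equal(unname(out$log2[1, ]), c(1, 2, 3, 4))
  expect_equal(unname(out$zscore[1, ]),
               c(-1.1619, -0.3873, 0.3873, 1.1619), tolerance = 1e-4)

  # replicate averaging with zeros treated as missing
  m2 <- matrix(c(4, 0, 8, 8), 1,
               dimnames = list("s1", c("d-2_1", "d-2_2", "d7_1", "d7_2")))
  out2 <- lfq_summarize(m2, seed = 1)
  expect_equal(unname(out2$log2[1, ]), c(2, 3))

  # no missing values: imputation is the identity; fixed seed reproduces
  set.seed(9)
  m3 <- matrix(2^stats::rnorm(40, 8), 10, 4,
               dimnames = list(paste0("s", 1:10),
                               c("d-2_1", "d1_1", "d3_1", "d7_1")))
  out3a <- lfq_summarize(m3, seed = 5)
  expect_equal(out3a$log2, log2(m3), ignore_attr = TRUE)
  m3[2, 2] <- 0; m3[7, c(1, 4)] <- 0
  out3b <- lfq_summarize(m3, seed = 5)
  out3c <- lfq_summarize(m3, seed = 5)
  expect_identical(out3b$log2, out3c$log2)

  # all-missing rows are dropped with a message
  m4 <- rbind(m3, zz = c(0, 0, 0, 0))
  expect_message(out4 <- lfq_summarize(m4, seed = 5), "all-missing")
  expect_identical(out4$dropped, "zz")
})

test_that("the full evidence chain reproduces generator truth exactly", {
  cfg <- sim_config(seed = 13, n_genes = 6)
  pep <- gen_peptide_table(cfg)
  flt <- filter_peptides(pep$table, pep$proteins)
  truth <- pep$truth

  expect_setequal(flt$accepted$record_id,
                  truth$record_id[truth$truth_accept_filter])
  m <- match(flt$rejected$record_id, truth$record_id)
  expect_identical(flt$rejected$reason, truth$truth_reject_reason[m])

  res <- resolve_multiply_sumoylated(flt$accepted)
  expect_setequal(res$record_id,
                  truth$record_id[truth$truth_accept_final])

  sm <- map_sites(res, pep$proteins)
  truth_sites <- unique(unlist(strsplit(
    truth$truth_sites[!is.na(truth$truth_sites)], ";")))
  expect_setequal(paste0(sm$sites$protein_id, ":",
                         sm$sites$residue_position), truth_sites)

  eq <- classify_equilibrium(res)
  m2 <- match(res$record_id, truth$record_id)
  expect_identical(eq$class, truth$truth_class[m2])
})

test_that("the evidence chain is invariant under record permutation", {
  cfg <- sim_config(seed = 14, n_genes = 6)
  pep <- gen_peptide_table(cfg)
  run_chain <- function(tab) {
    acc <- resolve_multiply_sumoylated(
      filter_peptides(tab, pep$proteins)$accepted)
    sm <- map_sites(acc, pep$proteins)
    list(ids = sort(acc$record_id),
         sites = sm$sites[order(sm$sites$protein_id,
                                sm$sites$residue_position), ])
  }
  a <- run_chain(pep$table)
  set.seed(1)
  b <- run_chain(pep$table[sample(nrow(pep$table)), ])
  expect_identical(a$ids, b$ids)
  expect_equal(a$sites, b$sites, ignore_attr = TRUE)
})
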