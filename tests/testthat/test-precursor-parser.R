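# A hand-built precursor used in several blocks:
#   signal (18)  MKLVVLFIVLFLVIFSSA
#   propeptide   SENDALSEEAR            (11, ends in canonical PQM EEAR)
#   peptide 1    GLFKKAWKKVFKGL + G     (amidated)
#   linker       RNEAR
#   peptide 2    FKKLAKKVLKAVL          (not amidated)
HAND_SIGNAL <- "MKLVVLFIVLFLVIFSSA"
HAND_PRECURSOR <- paste0(HAND_SIGNAL, "SENDALSEEAR",
                         "GLFKKAWKKVFKGLG", "RNEAR", "FKKLAKKVLKAVL")

test_that("a hand-built binary precursor is segmented exactly", {
  m <- parse_precursor(HAND_PRECURSOR, id = "hand1", signal_cut = 18)
  expect_s3_class(m, "precursor_model")
  expect_equal(m$ptype, "binary")
  expect_equal(m$propeptide$sequence, "SENDALSEEAR")
  expect_equal(m$propeptide$terminal_pqm$signature, "EEAR")
  expect_equal(length(m$peptides), 2)
  expect_equal(m$peptides[[1]]$sequence, "GLFKKAWKKVFKGL")
  expect_true(m$peptides[[1]]$amidated)
  expect_equal(m$peptides[[2]]$sequence, "FKKLAKKVLKAVL")
  expect_false(m$peptides[[2]]$amidated)
  expect_equal(m$linkers[[1]]$sequence, "RNEAR")
  expect_equal(classify_precursor(m), "binary")
})

test_that("segments tile the precursor exactly (reconstruction identity)", {
  set.seed(31)
  cfg <- lp_sim_config()
  for (i in 1:40) {
    gp <- generate_precursor(cfg)
    m <- parse_precursor(gp$record$residues, signal_cut = gp$truth$signal_cut)
    parts <- c(m$signal$sequence, m$propeptide$sequence)
    k <- 0
    for (j in seq_along(m$peptides)) {
      parts <- c(parts, m$peptides[[j]]$encoded)
      if (j < length(m$peptides)) parts <- c(parts, m$linkers[[j]]$sequence)
    }
    expect_identical(paste(parts, collapse = ""), gp$record$residues)
    # intervals map back to the emitted residues
    for (p in m$peptides)
      expect_identical(substr(gp$record$residues, p$interval$start + 1,
                              p$interval$end), p$encoded)
  }
})

test_that("segmentation equals the exhaustive-enumeration oracle on short precursors", {
  set.seed(32)
  cfg <- short_sim_config()
  n_checked <- 0
  while (n_checked < 60) {
    gp <- generate_precursor(cfg)
    if (nchar(gp$record$residues) > 120) next
    m <- segment_precursor(gp$record$residues, gp$truth$signal_cut)
    or <- oracle_enumerate(gp$record$residues, gp$truth$signal_cut)
    expect_equal(m$score, or$score, tolerance = 1e-9)
    expect_equal(m$n_optima, or$n_optima)
    expect_equal(or$n_optima, 1)  # clean mode guarantees uniqueness
    opt <- or$optima[[1]]
    off <- gp$truth$signal_cut
    expect_equal(m$propeptide$interval$end, off + opt$prop_end)
    expect_equal(length(m$peptides), length(opt$peps))
    for (j in seq_along(opt$peps)) {
      expect_equal(m$peptides[[j]]$interval$start, off + opt$peps[[j]][1] - 1)
      expect_equal(m$peptides[[j]]$interval$end, off + opt$peps[[j]][2])
    }
    n_checked <- n_checked + 1
  }
})

test_that("sequences without a downstream PQM yield the no-architecture outcome", {
  # no Arg at all downstream of the signal
  seq <- paste0(HAND_SIGNAL, strrep("ASLNG", 8))
  out <- parse_precursor(seq, signal_cut = 18)
  expect_s3_class(out, "lp_no_architecture")
  expect_equal(out$reason, "no_valid_propeptide_pqm")
  # too short downstream
  out2 <- segment_precursor(paste0(HAND_SIGNAL, "SEEARGLFKK"), 18)
  expect_s3_class(out2, "lp_no_architecture")
})

test_that("signal cleavage heuristic recovers planted cut sites", {
  set.seed(33)
  cfg <- lp_sim_config()
  hits <- 0; n <- 200
  for (i in 1:n) {
    gp <- generate_precursor(cfg, n_peptides = 1)
    cand <- propose_signal_cleavage(gp$record$residues)
    if (nrow(cand) && cand$cut[1] == gp$truth$signal_cut) hits <- hits + 1
  }
  expect_gte(hits / n, 0.9)  # top-1 recovery of the planted cut
  # degenerate inputs
  expect_equal(nrow(propose_signal_cleavage(strrep("K", 20))), 0)
  low <- propose_signal_cleavage(paste0(strrep("K", 30)))
  expect_true(all(low$score < 0))
  # externally annotated cut overrides the heuristic
  m <- parse_precursor(HAND_PRECURSOR, signal_cut = 18)
  expect_equal(m$signal$source, "annotation")
  expect_equal(m$signal$interval$end, 18)
})

test_that("amidation rule strips the Gly signal and records the flag", {
  a <- predict_amidation("FLGKKAIG", "linker")
  expect_true(a$amidated)
  expect_equal(a$sequence, "FLGKKAI")
  b <- predict_amidation("FLGKKAI", "stop")
  expect_false(b$amidated)
  expect_equal(b$sequence, "FLGKKAI")
})

test_that("acceptance rule requires motif-grade flanks", {
  # internal peptide between two valid linkers
  expect_true(accept_lp("NEAR", "RNEA"))
  # transcript-terminal peptide after a valid linker
  expect_true(accept_lp("SEER", NULL))
  # degenerate-tier N-flank fails in strict mode
  expect_false(accept_lp("SSSR", "RNEA"))
  expect_false(accept_lp("NEAK", "RNEA"))  # no Arg anchor
  expect_false(accept_lp("NEAR", "RSSS"))  # degenerate C-flank
})

test_that("fusion events are flagged: acidic head and planted iPQM-Arg deletion", {
  # propeptide fusion: first peptide with an acidic N-terminal head
  seq <- paste0(HAND_SIGNAL, "SENDALSEEAR",
                "EDDESDEDALKKVAKKLFKKWG", "RNEAR", "FKKLAKKVLKAVL")
  m <- parse_precursor(seq, signal_cut = 18)
  expect_s3_class(m, "precursor_model")
  expect_equal(m$peptides[[1]]$fusion_flag, "propeptide_fusion")

  # linker fusion: delete the leading Arg of a generated linker and the
  # flanking peptide pair collapses into one flagged peptide
  set.seed(34)
  cfg <- lp_sim_config()
  flagged <- 0; total <- 0
  while (total < 20) {
    gp <- generate_precursor(cfg, n_peptides = 2)
    lk_start <- gp$truth$linker_bounds[[1]][1] + gp$truth$signal_cut
    mutated <- paste0(substr(gp$record$residues, 1, lk_start - 1),
                      substr(gp$record$residues, lk_start + 1,
                             nchar(gp$record$residues)))
    m <- parse_precursor(mutated, signal_cut = gp$truth$signal_cut)
    if (inherits(m, "lp_no_architecture")) next
    total <- total + 1
    flags <- vapply(m$peptides, function(p) p$fusion_flag, character(1))
    if (length(m$peptides) < 2 && any(flags == "linker_fusion"))
      flagged <- flagged + 1
  }
  expect_gte(flagged / total, 0.8)

  # clean precursors carry no flags
  set.seed(35)
  for (i in 1:20) {
    gp <- generate_precursor(cfg)
    m <- parse_precursor(gp$record$residues, signal_cut = gp$truth$signal_cut)
    expect_true(all(vapply(m$peptides, function(p) p$fusion_flag,
                           character(1)) == "none"))
  }
})

test_that("precursor classification follows the peptide count", {
  set.seed(36)
  cfg <- lp_sim_config()
  for (np in c(1, 2, 5)) {
    gp <- generate_precursor(cfg, n_peptides = np)
    m <- parse_precursor(gp$record$residues, signal_cut = gp$truth$signal_cut)
    expect_equal(classify_precursor(m),
                 c("simple", "binary", rep("complex", 11))[np])
    expect_equal(m$ptype, classify_precursor(m))
  }
})
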