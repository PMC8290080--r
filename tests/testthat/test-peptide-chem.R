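test_that("average mass matches glycine, amidation and the atomic oracle", {
  expect_equal(average_mass("G"), 75.07, tolerance = 0.005)
  expect_equal(average_mass("G", amidated = TRUE) - average_mass("G"),
               -0.98, tolerance = 0.005)
  set.seed(21)
  for (i in 1:50) {
    s <- random_protein(30)
    expect_equal(average_mass(s), oracle_mass(s), tolerance = 0.01)
    expect_equal(average_mass(s, TRUE), oracle_mass(s, TRUE),
                 tolerance = 0.01)
  }
  expect_error(average_mass("GXG"), "non-canonical")
  expect_error(average_mass("GG*"), "non-canonical")
})

test_that("mass additivity: condensation identity holds for random splits", {
  set.seed(22)
  for (i in 1:60) {
    s <- random_protein(sample(4:40, 1))
    k <- sample(nchar(s) - 1, 1)
    a <- substr(s, 1, k); b <- substr(s, k + 1, nchar(s))
    expect_equal(average_mass(s),
                 average_mass(a) + average_mass(b) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("pI behaves at the extremes and is charge-consistent", {
  expect_gt(isoelectric_point(strrep("K", 10)), 10)
  expect_lt(isoelectric_point(strrep("D", 10)), 4.5)
  # self-consistency: net charge at the reported pI is ~0
  set.seed(23)
  for (i in 1:1000) {
    s <- random_protein(sample(5:40, 1))
    amid <- runif(1) < 0.5
    pi <- isoelectric_point(s, amid)
    if (pi > 0 && pi < 14)
      expect_lt(abs(peptide_charge(s, pi, amid)), 1e-3)
  }
})

test_that("pI strictly increases when an Asp is replaced by a Lys", {
  set.seed(24)
  n_checked <- 0
  while (n_checked < 500) {
    s <- random_protein(sample(8:30, 1))
    pos <- which(strsplit(s, "")[[1]] == "D")
    if (!length(pos)) next
    s2 <- s
    substr(s2, pos[1], pos[1]) <- "K"
    expect_gt(isoelectric_point(s2), isoelectric_point(s))
    n_checked <- n_checked + 1
  }
})

test_that("composition fractions, ratio and partition identity", {
  cs <- composition_stats("KKDD")
  expect_equal(cs$cationic_fraction, 0.5)
  expect_equal(cs$anionic_fraction, 0.5)
  expect_equal(cs$hydrophobic_fraction, 0)

  cs <- composition_stats("LLLLKK")
  expect_equal(cs$hydrophobic_fraction, 4 / 6)
  expect_equal(cs$cationic_fraction, 2 / 6)
  expect_equal(cs$hydrophobic_to_cationic_ratio, 2.0)

  expect_true(is.na(composition_stats("LLDD")$hydrophobic_to_cationic_ratio))

  # remainder partition: under the default classes the four shares sum to 1
  set.seed(25)
  for (i in 1:50) {
    s <- random_protein(sample(5:60, 1))
    cs <- composition_stats(s)
    ch <- strsplit(s, "")[[1]]
    remainder <- mean(!ch %in% c("K","R","D","E","A","I","L","M","F","W","V"))
    expect_equal(cs$cationic_fraction + cs$anionic_fraction +
                   cs$hydrophobic_fraction + remainder, 1)
  }

  # His/Cys/Gly class options
  expect_equal(composition_stats("HHLL", include_his = TRUE)$cationic_fraction,
               0.5)
  expect_equal(composition_stats("CG", include_cys_gly = TRUE)$hydrophobic_fraction,
               1)
})

test_that("length classes use the printed boundaries", {
  expect_equal(length_class(strrep("A", 29)), "short")
  expect_equal(length_class(strrep("A", 30)), "middle")
  expect_equal(length_class(strrep("A", 60)), "middle")
  expect_equal(length_class(strrep("A", 61)), "long")
})

test_that("frequency matrix equals brute-force counting and handles gaps", {
  fm <- frequency_matrix("ACDEF")
  expect_equal(dim(fm), c(20, 5))
  expect_equal(unname(colSums(fm)), rep(1, 5))
  expect_equal(unname(fm["A", 1]), 1)

  fm2 <- frequency_matrix(c("ACDEF", "ACDEG"))
  expect_equal(unname(fm2["F", 5]), 0.5)
  expect_equal(unname(fm2["G", 5]), 0.5)

  # random alignment vs direct counting
  set.seed(26)
  aln <- vapply(1:30, function(i) {
    s <- random_protein(12)
    if (runif(1) < 0.5) substr(s, sample(12, 1), sample(12, 1)) <- "-"
    s
  }, character(1))
  fm3 <- frequency_matrix(aln)
  chars <- do.call(rbind, strsplit(aln, ""))
  for (j in sample(12, 4)) {
    col <- chars[, j]; col <- col[col != "-"]
    for (a in unique(col))
      expect_equal(unname(fm3[a, j]), sum(col == a) / length(col))
  }
  expect_error(frequency_matrix(c("AA", "AAA")), "ragged")
})

test_that("peptide_profile assembles the full characterisation", {
  p <- peptide_profile("GLFKKAWKKVF", amidated = TRUE)
  expect_equal(p$length, 11)
  expect_equal(p$length_class, "short")
  expect_true(p$pi > 9)
  expect_equal(p$average_mass, oracle_mass("GLFKKAWKKVF", TRUE),
               tolerance = 0.01)
  expect_equal(p$cys_count, 0)
})
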