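test_that("census arithmetic reproduces the reference overview shares", {
  ref <- reference_census()
  expect_equal(sum(ref$analyzed), 133)
  peps <- c(simple = sum(ref$simple), binary = sum(ref$binary),
            complex = sum(ref$complex))
  expect_equal(unname(peps), c(83, 10, 719))
  cen <- census_from_counts(peps, reference_family_counts())
  expect_equal(unname(cen$printed$precursor_pct), c(35, 65))
  expect_equal(unname(cen$printed$peptide_pct[c("simple", "binary")]),
               c(10.2, 1.2))
  expect_equal(cen$printed$mean_peptides_per_binary_complex_family, 8.4)
  expect_equal(cen$n_peptides, 812)
})

test_that("census percentages sum to 100 within rounding on random counts", {
  set.seed(41)
  for (i in 1:30) {
    peps <- c(simple = sample(0:50, 1), binary = sample(0:20, 1),
              complex = sample(1:900, 1))
    fams <- c(simple = sample(0:50, 1), binary_complex = sample(1:90, 1))
    cen <- census_from_counts(peps, fams)
    expect_equal(sum(cen$precursor_pct), 100)
    expect_equal(sum(cen$peptide_pct), 100)
    expect_lte(abs(sum(cen$printed$peptide_pct) - 100), 0.3)
  }
})

test_that("catalog census agrees exactly with generator bookkeeping", {
  cfg <- lp_sim_config(seed = 42, n_species = 3, n_precursors = 5)
  gc <- generate_catalog(cfg)
  cen <- census(gc$catalog)
  # truth-side tallies
  truth_types <- vapply(gc$truth, function(t)
    c("simple", "binary", rep("complex", 11))[t$n_peptides], character(1))
  expect_equal(unname(cen$families[["simple"]]),
               sum(truth_types == "simple"))
  expect_equal(unname(cen$families[["binary_complex"]]),
               sum(truth_types != "simple"))
  # unique peptides per species by type, recomputed from the truth
  prec_species <- sub("_prec.*$", "", names(gc$truth))
  for (sp in unique(prec_species)) {
    keys <- list(simple = character(), binary = character(),
                 complex = character())
    for (id in names(gc$truth)[prec_species == sp]) {
      t <- gc$truth[[id]]
      ty <- c("simple", "binary", rep("complex", 11))[t$n_peptides]
      keys[[ty]] <- union(keys[[ty]], paste0(t$peptides$sequence, "#",
                                             t$peptides$amidated))
    }
    row <- cen$per_species[cen$per_species$species == sp, ]
    expect_equal(row$simple, length(keys$simple))
    expect_equal(row$binary, length(keys$binary))
    expect_equal(row$complex, length(keys$complex))
  }
})

test_that("species totals work on catalogs and printed tables", {
  ref <- reference_census()
  tot <- species_totals(ref)
  expect_equal(tot$total[tot$species == "Oxyopes heterophthalmus"], 62)
  expect_equal(tot$total[tot$species == "Pardosa palustris"], 60)
  # empty species contributes zero rows of peptides
  cat0 <- new_catalog(list(list(id = "empty", models = list())))
  expect_equal(census(cat0)$n_peptides, 0)
})

test_that("shared peptides: worked two-population example and brute force", {
  # plant the Hogna radiata arithmetic: 16 shared, totals 27 and 33
  mk_model <- function(id, seqs) {
    # minimal one-peptide-per-model stand-in built through the parser
    structure(list(id = id, ptype = "complex",
                   peptides = lapply(seqs, function(s)
                     list(sequence = s, amidated = TRUE, cys_count = 0,
                          fusion_flag = "none",
                          interval = list(start = 0L, end = nchar(s)))),
                   linkers = list()),
              class = "precursor_model")
  }
  set.seed(43)
  shared <- replicate(16, random_protein(20))
  only_a <- replicate(11, random_protein(21))
  only_b <- replicate(17, random_protein(22))
  cat2 <- new_catalog(list(
    list(id = "italy", models = list(mk_model("i1", c(shared, only_a)))),
    list(id = "spain", models = list(mk_model("s1", c(shared, only_b))))))
  sh <- shared_peptides(cat2)
  expect_equal(sh$pairs$shared, 16)
  expect_equal(sh$specific$total, c(27, 33))
  expect_equal(sh$specific$specific, c(11, 17))

  # disjoint species: all multiplicity 1; duplicated species: all shared
  cat_dis <- new_catalog(list(
    list(id = "a", models = list(mk_model("a1", only_a))),
    list(id = "b", models = list(mk_model("b1", only_b)))))
  expect_true(all(shared_peptides(cat_dis)$peptides$multiplicity == 1))
  cat_dup <- new_catalog(list(
    list(id = "a", models = list(mk_model("a1", shared))),
    list(id = "b", models = list(mk_model("b1", shared)))))
  expect_true(all(shared_peptides(cat_dup)$peptides$multiplicity == 2))
  expect_equal(shared_peptides(cat_dup)$specific$specific, c(0, 0))

  # symmetry + brute force on a generated catalog with planted sharing
  cfg <- lp_sim_config(seed = 44, n_species = 3, n_precursors = 3,
                       sharing_rate = 0.3)
  gc <- generate_catalog(cfg)
  sh2 <- shared_peptides(gc$catalog)
  sets <- lapply(gc$catalog$species, function(sp) {
    tab <- venomLP:::species_peptides(sp)
    unique(paste0(tab$sequence, "#", tab$amidated))
  })
  for (r in seq_len(nrow(sh2$pairs))) {
    a <- sh2$pairs$species_a[r]; b <- sh2$pairs$species_b[r]
    expect_equal(sh2$pairs$shared[r],
                 length(intersect(sets[[a]], sets[[b]])))
  }
  # amidation must match by default: flipping it breaks sharing
  cat_amid <- new_catalog(list(
    list(id = "a", models = list(mk_model("a1", "GLFKKAWKKVF"))),
    list(id = "b", models = list(structure(list(
      id = "b1", ptype = "simple",
      peptides = list(list(sequence = "GLFKKAWKKVF", amidated = FALSE,
                           cys_count = 0, fusion_flag = "none",
                           interval = list(start = 0L, end = 11L))),
      linkers = list()), class = "precursor_model")))))
  expect_equal(shared_peptides(cat_amid)$pairs$shared, 0)
  expect_equal(shared_peptides(cat_amid, match_amidation = FALSE)$pairs$shared,
               1)
})

test_that("linker inventory de-duplicates and recovers planted Glu-less rates", {
  cfg <- lp_sim_config(seed = 45, n_species = 4, n_precursors = 8)
  gc <- generate_catalog(cfg)
  inv <- linker_inventory(gc$catalog)
  expect_gt(inv$n_unique, 30)
  expect_false(anyDuplicated(inv$linkers$sequence) > 0)
  expect_true(all(inv$linkers$net_charge <= 0))
  # planted rate recovery within a binomial 99% interval around the truth
  p <- cfg$gluless_ipqm_rate
  n <- inv$n_unique
  expect_lt(abs(inv$gluless_ipqm_rate - p), 2.58 * sqrt(p * (1 - p) / n) + 0.02)
  expect_lt(inv$gluless_pqm_rate, 0.15)
})
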