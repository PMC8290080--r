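## Catalogs and census arithmetic.
##
## A catalog is a per-species collection of parsed precursor models. The
## census reproduces the bookkeeping of the transcriptome survey: precursor
## families by type (simple / binary / complex), unique peptides by the
## precursor type that encodes them, mean peptides per binary-or-complex
## family, per-species totals, PQM signature shares, cross-species peptide
## sharing, and the unique-linker inventory. A "unique LP" is a unique
## (sequence, amidation) pair within a species.

#' Construct a catalog
#'
#' @param species list of species entries; each entry is a list with `id`
#'   and `models` (list of `precursor_model` / `lp_no_architecture`
#'   objects).
#' @return object of class `lp_catalog`.
#' @export
new_catalog <- function(species) {
  stopifnot(is.list(species))
  ids <- vapply(species, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate species ids in catalog")
  names(species) <- ids
  structure(list(species = species), class = "lp_catalog")
}

## Unique (sequence, amidation) peptides of one species, with the precursor
## type(s) encoding them.
species_peptides <- function(sp) {
  rows <- list()
  for (model in sp$models) {
    if (inherits(model, "lp_no_architecture")) next
    for (pep in model$peptides) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = pep$sequence, amidated = pep$amidated,
        ptype = model$ptype, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sequence = character(), amidated = logical(),
                      ptype = character(), stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  tab[!duplicated(tab[, c("sequence", "amidated")]), , drop = FALSE]
}

#' Census arithmetic from per-species counts
#'
#' The core bookkeeping, usable directly on a printed overview table:
#' precursor-level shares are over analysed precursor families, peptide-level
#' shares over all unique peptides, and the mean peptides per
#' binary-or-complex family divides the peptides of those types by their
#' family count. Printed percentages are rounded half-up (whole percent at
#' precursor level, one decimal at peptide level).
#'
#' @param peptides named numeric vector `c(simple=, binary=, complex=)` of
#'   unique peptide counts by encoding precursor type.
#' @param families named numeric vector `c(simple=, binary_complex=)` of
#'   precursor family counts.
#' @return list of class `lp_census` with raw and printed shares.
#' @export
#' @examples
#' census_from_counts(c(simple = 83, binary = 10, complex = 719),
#'                    c(simple = 46, binary_complex = 87))
census_from_counts <- function(peptides, families) {
  stopifnot(all(c("simple", "binary", "complex") %in% names(peptides)),
            all(c("simple", "binary_complex") %in% names(families)))
  n_fam <- sum(families[c("simple", "binary_complex")])
  n_pep <- sum(peptides[c("simple", "binary", "complex")])
  prec_pct <- if (n_fam > 0)
    100 * families[c("simple", "binary_complex")] / n_fam else
      stats::setNames(numeric(2), c("simple", "binary_complex"))
  pep_pct <- if (n_pep > 0)
    100 * peptides[c("simple", "binary", "complex")] / n_pep else
      stats::setNames(numeric(3), c("simple", "binary", "complex"))
  mean_bc <- if (families[["binary_complex"]] > 0)
    (peptides[["binary"]] + peptides[["complex"]]) /
      families[["binary_complex"]] else NA_real_
  structure(list(
    n_precursor_families = n_fam,
    n_peptides = n_pep,
    families = families,
    peptides = peptides,
    precursor_pct = prec_pct,
    peptide_pct = pep_pct,
    mean_peptides_per_binary_complex_family = mean_bc,
    printed = list(
      precursor_pct = round_half_up(prec_pct, 0),
      peptide_pct = round_half_up(pep_pct, 1),
      mean_peptides_per_binary_complex_family = round_half_up(mean_bc, 1)
    )
  ), class = "lp_census")
}

#' Census of a parsed catalog
#'
#' Tallies precursor families and unique peptides by precursor type across
#' all species of a catalog, plus the PQM-signature frequency table of
#' propeptide terminal motifs, and delegates the share arithmetic to
#' [census_from_counts()]. An empty catalog yields an empty report.
#'
#' @param catalog an `lp_catalog`.
#' @return an `lp_census` with additional elements `per_species` (data.frame
#'   of unique-peptide totals by type) and `pqm_signatures` (relative
#'   frequencies of EEAR/XEER/XXER/XXDR/other).
#' @export
census <- function(catalog) {
  stopifnot(inherits(catalog, "lp_catalog"))
  per_species <- list(); sigs <- character()
  fam <- c(simple = 0, binary_complex = 0)
  peps <- c(simple = 0, binary = 0, complex = 0)
  for (sp in catalog$species) {
    for (model in sp$models) {
      if (inherits(model, "lp_no_architecture")) next
      if (model$ptype == "simple") fam[["simple"]] <- fam[["simple"]] + 1
      else fam[["binary_complex"]] <- fam[["binary_complex"]] + 1
      sigs <- c(sigs, model$propeptide$terminal_pqm$signature)
    }
    ptab <- species_peptides(sp)
    by_type <- table(factor(ptab$ptype,
                            levels = c("simple", "binary", "complex")))
    peps <- peps + as.numeric(by_type)
    per_species[[sp$id]] <- data.frame(
      species = sp$id, simple = as.integer(by_type[["simple"]]),
      binary = as.integer(by_type[["binary"]]),
      complex = as.integer(by_type[["complex"]]),
      total = nrow(ptab), stringsAsFactors = FALSE)
  }
  rep <- census_from_counts(peps, fam)
  rep$per_species <- if (length(per_species)) do.call(rbind, per_species)
    else data.frame(species = character(), simple = integer(),
                    binary = integer(), complex = integer(),
                    total = integer(), stringsAsFactors = FALSE)
  rownames(rep$per_species) <- NULL
  rep$pqm_signatures <- if (length(sigs))
    prop.table(table(factor(sigs, levels = c("EEAR", "XEER", "XXER", "XXDR",
                                             "other"))))
    else table(factor(character(), levels = c("EEAR", "XEER", "XXER",
                                              "XXDR", "other")))
  rep
}

#' Per-species unique-peptide totals by precursor type
#'
#' @param x an `lp_catalog`, or a data.frame with columns `species`,
#'   `simple`, `binary`, `complex` (unique peptide counts, as in a printed
#'   overview table).
#' @return data.frame with a `total` column appended (catalog input reuses
#'   [census()] tallies).
#' @export
species_totals <- function(x) {
  if (inherits(x, "lp_catalog")) return(census(x)$per_species)
  stopifnot(is.data.frame(x),
            all(c("species", "simple", "binary", "complex") %in% names(x)))
  x$total <- x$simple + x$binary + x$complex
  x
}

#' Cross-species shared-peptide analysis
#'
#' Exact amino-acid identity matching of unique peptides across species
#' (amidation required to match by default). Reports the per-peptide species
#' multiplicity, per-pair shared counts, and per-species specific counts
#' (multiplicity 1).
#'
#' @param catalog an `lp_catalog` with at least two species.
#' @param match_amidation require equal amidation state (default `TRUE`).
#' @return list with `peptides` (sequence, amidated, multiplicity, species
#'   list), `pairs` (species_a, species_b, shared), `specific` (per-species
#'   count of species-specific peptides).
#' @export
shared_peptides <- function(catalog, match_amidation = TRUE) {
  stopifnot(inherits(catalog, "lp_catalog"))
  if (length(catalog$species) < 2L)
    stop("shared_peptides() needs at least two species")
  sets <- lapply(catalog$species, function(sp) {
    tab <- species_peptides(sp)
    key <- if (match_amidation)
      paste0(tab$sequence, ifelse(tab$amidated, "#NH2", "")) else
        tab$sequence
    unique(key)
  })
  ids <- names(sets)
  all_keys <- unlist(sets, use.names = FALSE)
  mult <- table(all_keys)
  pep_tab <- data.frame(
    key = names(mult),
    sequence = sub("#NH2$", "", names(mult)),
    amidated = grepl("#NH2$", names(mult)),
    multiplicity = as.integer(mult),
    stringsAsFactors = FALSE)
  pep_tab$species <- lapply(pep_tab$key, function(k)
    ids[vapply(sets, function(s) k %in% s, logical(1))])
  pairs <- list()
  if (length(ids) >= 2L) {
    cmb <- utils::combn(ids, 2L)
    pairs <- data.frame(
      species_a = cmb[1L, ], species_b = cmb[2L, ],
      shared = apply(cmb, 2L, function(p)
        length(intersect(sets[[p[1L]]], sets[[p[2L]]]))),
      stringsAsFactors = FALSE)
  }
  specific <- vapply(ids, function(id)
    sum(sets[[id]] %in% names(mult)[mult == 1L]), integer(1))
  list(peptides = pep_tab[, c("sequence", "amidated", "multiplicity",
                              "species")],
       pairs = pairs,
       specific = data.frame(species = ids,
                             total = lengths(sets)[ids],
                             specific = specific,
                             shared = lengths(sets)[ids] - specific,
                             row.names = NULL, stringsAsFactors = FALSE))
}

#' Unique-linker inventory with Glu-less terminus rates
#'
#' Collects linkers from all parsed models, de-duplicates by sequence, and
#' reports the fraction of iPQM and PQM termini below canonical tier (i.e.
#' lacking Glu in the motif window).
#'
#' @param catalog an `lp_catalog`.
#' @return list with `linkers` (sequence, ipqm_tier, pqm_tier, net_charge,
#'   length), `n_unique`, `gluless_ipqm_rate`, `gluless_pqm_rate`.
#' @export
linker_inventory <- function(catalog) {
  stopifnot(inherits(catalog, "lp_catalog"))
  rows <- list()
  for (sp in catalog$species) {
    for (model in sp$models) {
      if (inherits(model, "lp_no_architecture")) next
      for (lk in model$linkers) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = lk$sequence, ipqm_tier = lk$ipqm_tier,
          pqm_tier = lk$pqm_tier, net_charge = lk$net_charge,
          length = nchar(lk$sequence), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(list(linkers = data.frame(), n_unique = 0L,
                gluless_ipqm_rate = NA_real_, gluless_pqm_rate = NA_real_))
  tab <- do.call(rbind, rows)
  tab <- tab[!duplicated(tab$sequence), , drop = FALSE]
  rownames(tab) <- NULL
  list(linkers = tab,
       n_unique = nrow(tab),
       gluless_ipqm_rate = mean(tab$ipqm_tier != "canonical"),
       gluless_pqm_rate = mean(tab$pqm_tier != "canonical"))
}

#' @export
print.lp_census <- function(x, ...) {
  cat("<lp_census>", x$n_precursor_families, "precursor families,",
      x$n_peptides, "unique peptides\n")
  p <- x$printed
  cat(sprintf("  precursors: %s%% simple, %s%% binary+complex\n",
              p$precursor_pct[["simple"]],
              p$precursor_pct[["binary_complex"]]))
  cat(sprintf("  peptides: %s%% simple, %s%% binary, %s%% complex\n",
              p$peptide_pct[["simple"]], p$peptide_pct[["binary"]],
              p$peptide_pct[["complex"]]))
  cat("  mean peptides per binary/complex family:",
      p$mean_peptides_per_binary_complex_family, "\n")
  invisible(x)
}
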