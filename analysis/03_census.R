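#!/usr/bin/env Rscript
# Step 3: census arithmetic. First on the parsed synthetic catalog from
# step 2 (shares, per-species totals, sharing, linker inventory, PQM
# signatures), then on the bundled reference overview table, reproducing
# the published precursor and peptide shares.

suppressPackageStartupMessages(library(venomLP))
stopifnot(file.exists("scratch/catalog.rds"))
catalog <- readRDS("scratch/catalog.rds")
dir.create("results", showWarnings = FALSE)

cen <- census(catalog)
print(cen)
sh <- shared_peptides(catalog)
inv <- linker_inventory(catalog)
cat("synthetic catalog:", sum(sh$peptides$multiplicity > 1),
    "peptides shared across species;", inv$n_unique, "unique linkers,",
    round(100 * inv$gluless_ipqm_rate, 1), "% Glu-less iPQM termini\n")

write.table(cen$per_species, "results/census_per_species.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(synthetic = list(
         families = as.list(cen$families),
         peptides = as.list(cen$peptides),
         printed = cen$printed,
         pqm_signatures = as.list(round(as.numeric(cen$pqm_signatures), 3))),
       sharing = list(pairs = sh$pairs, specific = sh$specific),
       linkers = list(n_unique = inv$n_unique,
                      gluless_ipqm_rate = inv$gluless_ipqm_rate,
                      gluless_pqm_rate = inv$gluless_pqm_rate)),
  "results/census_synthetic.json", auto_unbox = TRUE, digits = NA)

# reference overview table
ref <- reference_census()
rc <- census_from_counts(
  c(simple = sum(ref$simple), binary = sum(ref$binary),
    complex = sum(ref$complex)), reference_family_counts())
cat("\nreference survey:", rc$n_precursor_families, "precursor families,",
    rc$n_peptides, "unique LPs\n")
print(rc)
tot <- species_totals(ref)
write.table(tot, "results/census_reference_totals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(printed = rc$printed,
       totals = tot[order(-tot$total), c("species", "total")]),
  "results/census_reference.json", auto_unbox = TRUE, digits = NA)
cat("census tables written under results/\n")
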