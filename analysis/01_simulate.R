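#!/usr/bin/env Rscript
# Step 1: simulate a multi-species venom-gland catalog with known ground
# truth, plus a per-contig counts table, and write the fixtures other steps
# consume. Everything downstream of this script treats these files exactly
# like real transcriptome inputs: a protein FASTA of precursor candidates,
# a signal-annotation table, and a counts/effective-length table.

suppressPackageStartupMessages(library(venomLP))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

cfg <- lp_sim_config(seed = 20260923, n_species = 5, n_precursors = 8,
                     sharing_rate = 0.15)
gc <- generate_catalog(cfg)

write_fasta(data.frame(id = gc$records$id, alphabet = "protein",
                       residues = gc$records$residues),
            "results/sim/precursors.fa")

sig <- data.frame(
  id = names(gc$truth),
  signal_cut = vapply(gc$truth, function(t) t$signal_cut, integer(1)))
write.table(sig, "results/sim/signal_annotations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth_json <- lapply(gc$truth, function(t) list(
  signal_cut = t$signal_cut, prop_end = t$prop_end,
  n_peptides = t$n_peptides, peptides = t$peptides, linkers = t$linkers))
jsonlite::write_json(truth_json, "results/sim/truth.json",
                     auto_unbox = TRUE, digits = NA)

set.seed(20260923)
gen <- generate_counts(n_contigs = 500, lp_fraction = 0.25)
write.table(gen$table, "results/sim/counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(gen$truth, "results/sim/counts_truth.json",
                     auto_unbox = TRUE, digits = NA)

npep <- vapply(gc$truth, function(t) t$n_peptides, integer(1))
cat("simulated", nrow(gc$records), "precursors across",
    cfg$n_species, "species;",
    sum(npep), "planted peptides (", sum(npep == 1), "simple /",
    sum(npep == 2), "binary /", sum(npep >= 3), "complex )\n")
cat("counts table:", nrow(gen$table), "contigs, planted B/A quotient",
    round(gen$truth$quotient, 3), "\n")
cat("fixtures written under results/sim/\n")
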