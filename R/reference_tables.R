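## Bundled reference dataset: the published overview tables of a
## venom-gland transcriptome survey of 48 spider species (20 of them with
## linear-peptide precursors). These printed counts are inputs to the
## census and abundance arithmetic and to the workflow scripts under
## analysis/.

#' Reference census table: unique peptides by precursor type and species
#'
#' Per species (two Hogna radiata populations listed separately): the
#' number of analysed N-terminal precursor sequences and the unique
#' peptides derived from simple, binary and complex precursors. Column
#' sums are 133 analysed precursors and 83 / 10 / 719 peptides. At the
#' family level the 133 analysed precursors comprise 46 simple and 87
#' binary-or-complex families (see [reference_family_counts()]).
#'
#' @return data.frame with columns `family`, `species`, `analyzed`,
#'   `simple`, `binary`, `complex`.
#' @export
reference_census <- function() {
  tab <- read.table(header = TRUE, sep = ",", strip.white = TRUE,
                    stringsAsFactors = FALSE, text = "
family,species,analyzed,simple,binary,complex
Lycosidae,Alopecosa cuneata,5,0,0,36
Lycosidae,Alopecosa marikovskyi,3,0,0,15
Lycosidae,Geolycosa vultuosa,4,0,0,46
Lycosidae,Hogna radiata (Spain),3,0,0,33
Lycosidae,Hogna radiata (Italy),3,0,0,27
Lycosidae,Lycosa hispanica,1,0,0,26
Lycosidae,Lycosa praegrandis,2,0,0,16
Lycosidae,Pardosa amentata,5,0,0,32
Lycosidae,Pardosa palustris,5,0,0,60
Lycosidae,Trochosa ruricola,5,0,0,41
Lycosidae,Vesubia jugorum,2,0,0,20
Trechaleidae,Cupiennius getazi,5,1,0,58
Trechaleidae,Cupiennius salei,9,1,0,179
Ctenidae,Ancylometes rufus,1,1,0,0
Ctenidae,Macroctenus kingsleyi,4,0,0,4
Ctenidae,Phoneutria fera,2,0,0,8
Ctenidae,Piloctenus haematostoma,3,0,0,21
Oxyopidae,Oxyopes heterophthalmus,15,12,0,50
Oxyopidae,Oxyopes takobius,5,4,2,3
Oxyopidae,Oxyopes lineatus,11,9,0,25
Oxyopidae,Peucetia striata,9,4,0,13
Pisauridae,Dolomedes fimbriatus,3,5,2,0
Pisauridae,Dolomedes okefinokensis,3,0,4,0
Zodariidae,Lachesana tarabaevi,14,27,2,6
Zodariidae,Zodarion cyrenaicum,1,1,0,0
Zodariidae,Zodarion styliferum,10,18,0,0")
  tab
}

#' Reference precursor-family counts by type
#'
#' Of the 133 analysed N-terminal precursor families, 46 are simple and 87
#' binary or complex (the per-species split by family type is not part of
#' the printed per-species table, so the family-level counts are carried
#' separately).
#'
#' @return named numeric vector `c(simple = 46, binary_complex = 87)`.
#' @export
reference_family_counts <- function() {
  c(simple = 46, binary_complex = 87)
}

#' Reference abundance table: [A] and [B] TPM percentages per species
#'
#' `A` is the TPM percentage of all LP-encoding contigs in the species'
#' transcriptome; `B` the summed per-peptide TPM percentage (see
#' [summarize_lp_abundance()]); `quotient_printed` the published [B]/[A]
#' value.
#'
#' @return data.frame with columns `family`, `species`, `A`, `B`,
#'   `quotient_printed`.
#' @export
reference_abundance <- function() {
  read.table(header = TRUE, sep = ",", strip.white = TRUE,
             stringsAsFactors = FALSE, text = "
family,species,A,B,quotient_printed
Lycosidae,Alopecosa cuneata,27.4,76.4,2.8
Lycosidae,Alopecosa marikovskyi,1.1,1.8,1.6
Lycosidae,Geolycosa vultuosa,38.5,74.1,1.9
Lycosidae,Hogna radiata (Spain),19.9,52.0,2.6
Lycosidae,Hogna radiata (Italy),23.5,45.5,1.9
Lycosidae,Lycosa hispanica,40.3,112.6,2.8
Lycosidae,Lycosa praegrandis,39.9,97.2,2.4
Lycosidae,Pardosa amentata,19.4,35.8,1.8
Lycosidae,Pardosa palustris,16.1,25.3,1.6
Lycosidae,Trochosa ruricola,27.5,43.3,1.6
Lycosidae,Vesubia jugorum,30.8,78.2,2.5
Trechaleidae,Cupiennius getazi,44.2,71.0,1.6
Trechaleidae,Cupiennius salei,31.3,38.9,1.2
Ctenidae,Ancylometes rufus,0.021,0.020,0.95
Ctenidae,Macroctenus kingsleyi,0.3,0.6,1.8
Ctenidae,Phoneutria fera,7.9,20,2.5
Ctenidae,Piloctenus haematostoma,36.6,78.1,2.1
Oxyopidae,Oxyopes heterophthalmus,52.1,52.6,1.0
Oxyopidae,Oxyopes lineatus,31.2,24.5,0.8
Oxyopidae,Peucetia striata,47.8,54.4,1.1
Pisauridae,Dolomedes okefinokensis,1.2,0.7,0.6
Zodariidae,Zodarion styliferum,2.8,1.4,0.5
Zodariidae,Zodarion cyrenaicum,0.2,0.2,1")
}

#' Reference per-species LP totals with family assignment
#'
#' Total unique linear peptides per investigated species (zero for the
#' species in which no LP precursor was detected), with the spider family
#' used to look up phylogenetic depth for the Poisson regression. Species
#' marked `external = TRUE` were analysed from externally deposited
#' transcripts.
#'
#' @return data.frame with columns `species`, `family`, `n_lps`,
#'   `external`.
#' @export
reference_species_lps <- function() {
  read.table(header = TRUE, sep = ",", strip.white = TRUE,
             stringsAsFactors = FALSE, text = "
species,family,n_lps,external
Alopecosa cuneata,Lycosidae,36,FALSE
Alopecosa marikovskyi,Lycosidae,15,FALSE
Geolycosa vultuosa,Lycosidae,46,FALSE
Hogna radiata (Spain),Lycosidae,33,FALSE
Hogna radiata (Italy),Lycosidae,27,FALSE
Lycosa hispanica,Lycosidae,26,FALSE
Lycosa praegrandis,Lycosidae,16,FALSE
Pardosa amentata,Lycosidae,32,FALSE
Pardosa palustris,Lycosidae,60,FALSE
Trochosa ruricola,Lycosidae,41,FALSE
Vesubia jugorum,Lycosidae,20,FALSE
Cupiennius getazi,Trechaleidae,59,FALSE
Cupiennius salei,Trechaleidae,180,FALSE
Ancylometes rufus,Ctenidae,1,FALSE
Macroctenus kingsleyi,Ctenidae,4,FALSE
Phoneutria fera,Ctenidae,8,FALSE
Piloctenus haematostoma,Ctenidae,21,FALSE
Oxyopes heterophthalmus,Oxyopidae,62,FALSE
Oxyopes takobius,Oxyopidae,9,TRUE
Oxyopes lineatus,Oxyopidae,34,FALSE
Peucetia striata,Oxyopidae,17,FALSE
Dolomedes fimbriatus,Pisauridae,7,TRUE
Dolomedes okefinokensis,Pisauridae,4,FALSE
Lachesana tarabaevi,Zodariidae,35,TRUE
Zodarion cyrenaicum,Zodariidae,1,FALSE
Zodarion styliferum,Zodariidae,18,FALSE
Linothele megatheloides,Dipluridae,0,FALSE
Atypus piceus,Atypidae,0,FALSE
Uroctea durandi,Oecobiidae,0,FALSE
Araneus angulatus,Araneidae,0,FALSE
Larinioides sclopetarius,Araneidae,0,FALSE
Nephila pilipes,Nephilidae,0,FALSE
Meta menardi,Tetragnathidae,0,FALSE
Latrodectus tredecimguttatus,Theridiidae,0,FALSE
Anyphaena accentuata,Anyphaenidae,0,FALSE
Drassodes lapidosus,Gnaphosidae,0,FALSE
Viridasius fasciatus,Viridasiidae,0,FALSE
Evarcha arcuata,Salticidae,0,FALSE
Marpissa muscosa,Salticidae,0,FALSE
Cheiracanthium sp.,Eutichuridae,0,FALSE
Tibellus macellus,Philodromidae,0,FALSE
Eusparassus dufouri,Sparassidae,0,FALSE
Heteropoda venatoria,Sparassidae,0,FALSE
Isopeda villosa,Sparassidae,0,FALSE
Amaurobius ferox,Amaurobiidae,0,FALSE
Eratigena atrica,Agelenidae,0,FALSE
Zoropsis spinimana,Zoropsidae,0,FALSE
Thomisus onustus,Thomisidae,0,FALSE
Xysticus cristatus,Thomisidae,0,FALSE
Pisaura mirabilis,Pisauridae,0,FALSE
Trechaleoides biocellata,Trechaleidae,0,FALSE")
}

#' Path to the bundled synthetic family-level tree
#'
#' A rooted family-level topology assembled from the survey's narrative
#' description of spider phylogeny (mygalomorphs basal; Araneoidea;
#' Oecobiidae at the base of the RTA clade; Zodariidae basal within it;
#' Dionycha; then the lycosoid families with Lycosidae most derived). It is
#' a synthetic stand-in for the survey's figure topology, which is not
#' machine-readable, so depths derived from it are illustrative.
#'
#' @return file path to a newick file.
#' @export
synthetic_family_tree <- function() {
  system.file("extdata", "family_tree_synthetic.nwk", package = "venomLP",
              mustWork = TRUE)
}
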