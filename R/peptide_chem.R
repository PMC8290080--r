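## Physicochemical characterisation of mature peptides: average mass,
## isoelectric point, charge/hydrophobicity composition, length classes and
## position frequency matrices for sequence logos.

## Average (not monoisotopic) residue masses in Da; a peptide's mass is the
## sum of residue masses plus one water. Printed masses for venom peptides
## (e.g. 4,274.1 Da for a 35-mer) are on this scale.
AVERAGE_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
MASS_WATER <- 18.0153
MASS_AMIDATION <- -0.9847  # C-terminal OH -> NH2

## Side-chain and terminal pKa sets. EMBOSS values are the default; the
## Bjellqvist set is selectable. Positive groups: N-terminus, K, R, H;
## negative groups: C-terminus, D, E, C, Y.
PKA_SETS <- list(
  emboss = c(nterm = 8.6, cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
             D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
  bjellqvist = c(nterm = 7.5, cterm = 3.55, K = 10.0, R = 12.0, H = 5.98,
                 D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
)

#' Average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water (18.02 Da); C-terminal
#' amidation replaces the terminal carboxyl OH by NH2 (-0.98 Da). Satisfies
#' the condensation identity `mass(AB) = mass(A) + mass(B) - 18.02` for any
#' split of a free-acid peptide.
#'
#' @param seq protein string over the 20 canonical residues.
#' @param amidated logical; is the C-terminus amidated?
#' @return mass in Da.
#' @export
#' @examples
#' average_mass("G")  # 75.07, free glycine
average_mass <- function(seq, amidated = FALSE) {
  ch <- seq_chars(seq)
  bad <- setdiff(unique(ch), names(AVERAGE_RESIDUE_MASS))
  if (length(bad))
    stop("average_mass(): non-canonical residue(s): ",
         paste(bad, collapse = ", "))
  sum(AVERAGE_RESIDUE_MASS[ch]) + MASS_WATER +
    if (amidated) MASS_AMIDATION else 0
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch charge over the ionisable groups (N-terminus, Lys,
#' Arg, His positive; C-terminus, Asp, Glu, Cys, Tyr negative). Amidation
#' removes the C-terminal carboxyl group.
#'
#' @param seq protein string.
#' @param ph pH value (vectorised).
#' @param amidated logical; amidated C-terminus has no carboxyl charge.
#' @param pka_set `"emboss"` (default) or `"bjellqvist"`.
#' @return numeric net charge, same length as `ph`.
#' @export
peptide_charge <- function(seq, ph, amidated = FALSE, pka_set = "emboss") {
  pka <- PKA_SETS[[match.arg(pka_set, names(PKA_SETS))]]
  ch <- seq_chars(seq)
  pos_pk <- c(pka[["nterm"]],
              rep(pka[["K"]], sum(ch == "K")),
              rep(pka[["R"]], sum(ch == "R")),
              rep(pka[["H"]], sum(ch == "H")))
  neg_pk <- c(if (!amidated) pka[["cterm"]],
              rep(pka[["D"]], sum(ch == "D")),
              rep(pka[["E"]], sum(ch == "E")),
              rep(pka[["C"]], sum(ch == "C")),
              rep(pka[["Y"]], sum(ch == "Y")))
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - pos_pk))) - sum(1 / (1 + 10^(neg_pk - p)))
  }, numeric(1))
}

#' Isoelectric point of a peptide
#'
#' pH at which the net charge of [peptide_charge()] is zero, found by
#' bisection on \[0, 14\] to a tolerance of 1e-4 pH units.
#'
#' @inheritParams peptide_charge
#' @return pI in pH units.
#' @export
#' @examples
#' isoelectric_point(strrep("K", 10)) > 10   # purely basic
#' isoelectric_point(strrep("D", 10)) < 4.5  # purely acidic
isoelectric_point <- function(seq, amidated = FALSE, pka_set = "emboss") {
  lo <- 0; hi <- 14
  f_lo <- peptide_charge(seq, lo, amidated, pka_set)
  f_hi <- peptide_charge(seq, hi, amidated, pka_set)
  if (f_lo <= 0) return(lo)  # degenerate: negative even at pH 0
  if (f_hi >= 0) return(hi)
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (peptide_charge(seq, mid, amidated, pka_set) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Charge and hydrophobicity composition of a peptide
#'
#' Fractions of cationic (Lys/Arg; His optional), anionic (Asp/Glu) and
#' hydrophobic (Ala/Ile/Leu/Met/Phe/Trp/Val; Cys and Gly optional) residues,
#' and the hydrophobic-to-cationic ratio used to characterise amphipathic
#' venom peptide families (observed between 4 and 9 for several lycosid
#' families). The ratio is `NA` when the peptide has no cationic residue.
#'
#' @param seq protein string.
#' @param include_his count His as cationic (default `FALSE`).
#' @param include_cys_gly count Cys and Gly as hydrophobic (default `FALSE`).
#' @return list with `cationic_fraction`, `anionic_fraction`,
#'   `hydrophobic_fraction`, `hydrophobic_to_cationic_ratio`, `net_charge`
#'   (integer K/R minus D/E count), `cys_count`.
#' @export
#' @examples
#' composition_stats("LLLLKK")$hydrophobic_to_cationic_ratio  # 2
composition_stats <- function(seq, include_his = FALSE,
                              include_cys_gly = FALSE) {
  ch <- seq_chars(seq)
  n <- length(ch)
  cat_set <- c(residue_classes$cationic, if (include_his) "H")
  hyd_set <- c(residue_classes$hydrophobic, if (include_cys_gly) c("C", "G"))
  cationic <- sum(ch %in% cat_set) / n
  anionic <- sum(ch %in% residue_classes$anionic) / n
  hydrophobic <- sum(ch %in% hyd_set) / n
  list(
    cationic_fraction = cationic,
    anionic_fraction = anionic,
    hydrophobic_fraction = hydrophobic,
    hydrophobic_to_cationic_ratio =
      if (cationic > 0) hydrophobic / cationic else NA_real_,
    net_charge = sum(ch %in% residue_classes$cationic) -
      sum(ch %in% residue_classes$anionic),
    cys_count = sum(ch == "C")
  )
}

#' Length class of a linear peptide
#'
#' Short < 30 residues, middle 30-60 residues (both bounds inclusive),
#' long > 60 residues.
#'
#' @param seq protein string (or an integer length).
#' @return `"short"`, `"middle"` or `"long"`.
#' @export
length_class <- function(seq) {
  n <- if (is.character(seq)) nchar(seq) else as.integer(seq)
  ifelse(n < 30L, "short", ifelse(n <= 60L, "middle", "long"))
}

#' Position frequency matrix of an alignment
#'
#' Column-normalised residue counts over equal-length sequences, the matrix
#' behind a sequence logo. Gap characters (`-`) are excluded from column
#' totals.
#'
#' @param aligned character vector of equal-length (gapped) sequences.
#' @return 20 x L numeric matrix; each column with at least one residue sums
#'   to 1.
#' @export
frequency_matrix <- function(aligned) {
  if (!length(aligned)) stop("frequency_matrix(): empty input")
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L)
    stop("frequency_matrix(): ragged input (lengths ",
         paste(unique(lens), collapse = ", "), ")")
  L <- lens[1]
  mat <- matrix(0, nrow = 20L, ncol = L,
                dimnames = list(residue_classes$canonical, NULL))
  chars <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  for (j in seq_len(L)) {
    col <- chars[, j]
    col <- col[col != "-"]
    if (!length(col)) next
    tab <- table(factor(col, levels = residue_classes$canonical))
    mat[, j] <- as.numeric(tab) / length(col)
  }
  mat
}

#' Full physicochemical profile of one mature peptide
#'
#' Convenience wrapper combining [average_mass()], [isoelectric_point()],
#' [composition_stats()] and [length_class()].
#'
#' @inheritParams average_mass
#' @inheritParams composition_stats
#' @return list of class `peptide_profile`.
#' @export
peptide_profile <- function(seq, amidated = FALSE, include_his = FALSE,
                            include_cys_gly = FALSE) {
  comp <- composition_stats(seq, include_his, include_cys_gly)
  structure(c(list(
    sequence = seq,
    length = nchar(seq),
    amidated = amidated,
    average_mass = average_mass(seq, amidated),
    pi = isoelectric_point(seq, amidated),
    length_class = length_class(seq)
  ), comp), class = "peptide_profile")
}
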