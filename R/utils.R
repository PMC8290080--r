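## Shared residue alphabets, composition counters and small numeric helpers.

#' Amino-acid residue classes used throughout the pipeline
#'
#' The grammar and the biochemistry both reason over fixed residue classes:
#' cationic = Lys/Arg (His optional), anionic = Asp/Glu, hydrophobic =
#' Ala/Ile/Leu/Met/Phe/Trp/Val (Cys and Gly optional). These are the defaults
#' of every composition-based function in the package and can be overridden
#' per call.
#'
#' @format Named list of character vectors with elements `canonical`,
#'   `cationic`, `anionic`, `hydrophobic`.
#' @export
residue_classes <- list(
  canonical   = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  cationic    = c("K", "R"),
  anionic     = c("D", "E"),
  hydrophobic = c("A", "I", "L", "M", "F", "W", "V")
)

#' Round half away from zero to a fixed number of decimals
#'
#' Printed census percentages in the field are conventionally rounded half-up
#' (e.g. 34.586\% is reported as 35\%), whereas base [round()] rounds half to
#' even. All human-facing percentages in this package use this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(0.5)        # 1
#' round_half_up(34.586, 0)  # 35
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Split a protein string into a character vector of single residues.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

## Signed charge count of a protein string: K,R = +1; D,E = -1.
## This is the integer bookkeeping charge of the grammar, not a pH-dependent
## charge (see isoelectric_point() for the latter).
net_charge_count <- function(seq) {
  ch <- seq_chars(seq)
  sum(ch %in% residue_classes$cationic) - sum(ch %in% residue_classes$anionic)
}

## 0-based half-open interval constructor (internal convention).
interval <- function(start, end, frame = NA_integer_) {
  stopifnot(start >= 0, end > start)
  list(start = as.integer(start), end = as.integer(end),
       frame = as.integer(frame))
}

## Convert an internal 0-based half-open interval to 1-based inclusive
## (the convention of every report this package writes).
interval_onebased <- function(iv) {
  c(start = iv$start + 1L, end = iv$end)
}

## Extract the residues covered by a 0-based half-open interval.
interval_residues <- function(seq, iv) {
  substr(seq, iv$start + 1L, iv$end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
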