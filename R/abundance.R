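## Transcript abundance: TPM computation and the LP abundance summary
## ([A], [B] and the quotient [B]/[A]).

#' Transcripts per kilobase million
#'
#' `tpm_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j)` with read counts `c` and
#' effective lengths `l` in bases. The vector always sums to 1e6.
#'
#' @param counts non-negative read counts (at least one positive).
#' @param eff_lengths positive effective lengths.
#' @return numeric TPM vector.
#' @export
#' @examples
#' compute_tpm(c(10, 10), c(1000, 2000))  # 666666.67, 333333.33
compute_tpm <- function(counts, eff_lengths) {
  stopifnot(length(counts) == length(eff_lengths))
  if (any(eff_lengths <= 0)) stop("compute_tpm(): non-positive length(s)")
  if (any(counts < 0)) stop("compute_tpm(): negative count(s)")
  if (all(counts == 0)) stop("compute_tpm(): all counts are zero")
  rate <- counts / eff_lengths
  1e6 * rate / sum(rate)
}

#' LP abundance summary: [A], [B] and the quotient [B]/[A]
#'
#' `A` is the percentage of total TPM on LP-encoding contigs (those with at
#' least one identified peptide); `B` sums, over every identified peptide,
#' the TPM percentage of its encoding contig — a contig with `k` peptides
#' contributes `k` times its TPM percent. The quotient `B/A` is therefore
#' the TPM-weighted mean number of peptides per LP-encoding contig: about 1
#' when one contig encodes one peptide, larger where complex precursors
#' dominate expression.
#'
#' @param table data.frame with columns `count`, `eff_length`, `n_lps`
#'   (distinct identified peptides per contig; 0 for non-LP contigs). A
#'   precomputed `tpm` column is used if present.
#' @return list of class `lp_abundance` with `A`, `B`, `quotient` (raw) and
#'   `printed` (rounded half-up to one decimal; quotient to two decimals
#'   when below 1).
#' @export
summarize_lp_abundance <- function(table) {
  stopifnot(is.data.frame(table), "n_lps" %in% names(table))
  tpm <- if ("tpm" %in% names(table)) table$tpm
         else compute_tpm(table$count, table$eff_length)
  lp <- table$n_lps >= 1L
  A <- 100 * sum(tpm[lp]) / 1e6
  B <- 100 * sum(table$n_lps[lp] * tpm[lp]) / 1e6
  quotient <- if (A > 0) B / A else NA_real_
  structure(list(
    A = A, B = B, quotient = quotient,
    printed = list(A = round_half_up(A, 1), B = round_half_up(B, 1),
                   quotient = abundance_quotient(A, B))
  ), class = "lp_abundance")
}

#' Printed abundance quotient from [A] and [B] percentages
#'
#' Division plus the report rounding convention: one decimal, or two
#' decimals for quotients below 1 (printed tables show e.g. 2.8 and 0.95).
#'
#' @param A,B TPM percentages.
#' @return rounded quotient, `NA` when `A` is 0.
#' @export
abundance_quotient <- function(A, B) {
  q <- ifelse(A > 0, B / A, NA_real_)
  ifelse(!is.na(q) & q < 1, round_half_up(q, 2), round_half_up(q, 1))
}
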