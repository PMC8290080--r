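## Precursor segmentation.
##
## A linear-peptide precursor reads
##
##   signal peptide | propeptide ...PQM | peptide ( linker | peptide )* stop
##
## where the propeptide ends at the Arg of a PQM and every linker opens with
## an iPQM and closes with a PQM. Segmentation is posed as an exact
## optimisation over all legal tilings of the region downstream of the
## signal peptide: peptide segments are rewarded for being cationic and
## hydrophobic, linker segments for being anionic, and each motif used
## contributes a tier bonus. The optimum is found by dynamic programming
## over Arg-anchored cut points; the number of co-optimal tilings is counted
## so callers can detect ambiguity.

#' Segmentation parameters
#'
#' @param min_prop,max_prop propeptide length bounds in residues (defaults
#'   8 and 90, covering observed 10-86).
#' @param min_pep minimum encoded peptide segment length (default 10; the
#'   shortest observed mature peptides are 11-residue tachykinin-like
#'   peptides).
#' @param max_linker maximum linker length (default 45; longest observed
#'   linkers are 42/43 residues).
#' @param lambda weight of the hydrophobic fraction in the peptide score.
#' @param tier_bonus named vector of motif tier bonuses.
#' @param mode `"strict"` requires every motif at Asp-variant tier or
#'   better; `"permissive"` additionally accepts one Glu-less linker
#'   terminus when the linker's net charge is non-positive.
#' @return list of class `lp_params`.
#' @export
lp_params <- function(min_prop = 8L, max_prop = 90L, min_pep = 10L,
                      max_linker = 45L, lambda = 2,
                      tier_bonus = c(canonical = 2, asp_variant = 1,
                                     degenerate = 0),
                      mode = c("strict", "permissive")) {
  structure(list(min_prop = as.integer(min_prop),
                 max_prop = as.integer(max_prop),
                 min_pep = as.integer(min_pep),
                 max_linker = as.integer(max_linker),
                 lambda = lambda, tier_bonus = tier_bonus,
                 mode = match.arg(mode)),
            class = "lp_params")
}

## Kyte-Doolittle hydropathy, used by the signal-cleavage heuristic.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)
SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

#' Propose signal-peptide cleavage positions
#'
#' A transparent stand-in for neural signal-peptide predictors: candidate
#' cut sites are restricted to positions 18-24 (the observed signal length
#' range); each candidate is scored by the mean Kyte-Doolittle hydropathy of
#' the core window (positions 5 to cut-6) plus a bonus of 0.5 for a small
#' residue (A,G,S,C,T) at each of the -3 and -1 positions. An externally
#' annotated cut always overrides this heuristic (see [parse_precursor()]).
#'
#' @param seq full precursor protein string.
#' @return data.frame with columns `cut` (1-based last signal residue) and
#'   `score`, sorted by decreasing score; empty for sequences of 25 residues
#'   or fewer.
#' @export
propose_signal_cleavage <- function(seq) {
  n <- nchar(seq)
  empty <- data.frame(cut = integer(), score = numeric())
  if (n <= 25L) return(empty)
  ch <- seq_chars(seq)
  cuts <- 18:24
  cuts <- cuts[cuts < n]
  score <- vapply(cuts, function(cut) {
    core <- ch[5:(cut - 6L)]
    mean(KYTE_DOOLITTLE[core]) +
      0.5 * (ch[cut - 2L] %in% SMALL_RESIDUES) +
      0.5 * (ch[cut] %in% SMALL_RESIDUES)
  }, numeric(1))
  out <- data.frame(cut = cuts, score = score)
  out[order(-out$score, out$cut), , drop = FALSE]
}

SCORE_TOL <- 1e-9

#' Segment a precursor downstream of its signal peptide
#'
#' Chooses, among all tilings `[propeptide ending in PQM][peptide]
#' ([linker][peptide])*` of the region after `signal_cut`, the one
#' maximising
#'
#'   sum over peptides of (cationic - anionic + lambda * hydrophobic
#'   fraction) + sum over linkers of (anionic - cationic) + motif tier
#'   bonuses,
#'
#' subject to propeptide length bounds, strict linker validation and the
#' minimum peptide length. Ties are broken toward fewer (hence longer)
#' peptides, then toward the earlier propeptide cut. The count of co-optimal
#' tilings (within a 1e-9 score tolerance) is reported as `n_optima`.
#'
#' @param seq full precursor protein string (no internal `*`; one trailing
#'   `*` is tolerated and stripped).
#' @param signal_cut 1-based position of the last signal-peptide residue.
#' @param params an [lp_params()] object.
#' @return an object of class `precursor_model`, or of class
#'   `lp_no_architecture` (with a `reason`) when no legal tiling exists —
#'   the outcome for species without linear-peptide precursors.
#' @export
segment_precursor <- function(seq, signal_cut, params = lp_params()) {
  seq <- sub("\\*$", "", seq)
  if (grepl("*", seq, fixed = TRUE))
    stop("segment_precursor(): internal stop codon in sequence")
  n <- nchar(seq)
  stopifnot(signal_cut >= 1L, signal_cut < n)
  d <- substr(seq, signal_cut + 1L, n)
  m <- nchar(d)
  no_arch <- function(reason)
    structure(list(sequence = seq, signal_cut = signal_cut, reason = reason),
              class = "lp_no_architecture")
  if (m < params$min_prop + params$min_pep)
    return(no_arch("downstream_too_short"))

  ch <- seq_chars(d)
  is_cat <- as.numeric(ch %in% residue_classes$cationic)
  is_acid <- as.numeric(ch %in% residue_classes$anionic)
  is_hyd <- as.numeric(ch %in% residue_classes$hydrophobic)
  Ccum <- c(0, cumsum(is_cat))
  Acum <- c(0, cumsum(is_acid))
  Hcum <- c(0, cumsum(is_hyd))

  ## Motif tier ranks anchored at each Arg (-Inf where no motif).
  pqm_rank <- rep(-Inf, m)   # PQM ending at i
  ipqm_rank <- rep(-Inf, m)  # iPQM starting at i
  r_pos <- which(ch == "R")
  for (i in r_pos[r_pos >= 4L]) {
    pqm_rank[i] <- tier_rank[[motif_tier(substr(d, i - 3L, i - 1L))]]
  }
  for (i in r_pos[r_pos <= m - 3L]) {
    ipqm_rank[i] <- tier_rank[[motif_tier(substr(d, i + 1L, i + 3L))]]
  }
  bonus_of_rank <- function(rank) {
    # rank 0/1/2 -> degenerate/asp_variant/canonical bonus
    unname(params$tier_bonus[c("degenerate", "asp_variant",
                               "canonical")][rank + 1L])
  }
  min_rank <- 1L  # Asp-variant or better for accepted motifs in both modes
  permissive <- params$mode == "permissive"

  ## DP arrays. g[i]: best tiling of d[i..m] beginning with a peptide at i.
  ## h[a]: best tiling of d[a..m] beginning with a linker at a.
  NEG <- -Inf
  g_score <- rep(NEG, m + 2L); g_npep <- rep(NA_integer_, m + 2L)
  g_j <- rep(NA_integer_, m + 2L); g_count <- rep(0, m + 2L)
  h_score <- rep(NEG, m + 2L); h_npep <- rep(NA_integer_, m + 2L)
  h_b <- rep(NA_integer_, m + 2L); h_count <- rep(0, m + 2L)

  for (pos in seq(m, 1L)) {
    ## h[pos]: linker starting at pos (R, valid iPQM), ending at some b (R,
    ## valid PQM), followed by a peptide at b + 1.
    if (ch[pos] == "R" && is.finite(ipqm_rank[pos])) {
      b_hi <- min(pos + params$max_linker - 1L, m - params$min_pep)
      bs <- if (b_hi >= pos + 4L) seq.int(pos + 4L, b_hi) else integer()
      if (length(bs)) {
        ok_motif <- is.finite(pqm_rank[bs]) &
          ((ipqm_rank[pos] >= min_rank & pqm_rank[bs] >= min_rank) |
             (permissive &
                (ipqm_rank[pos] >= min_rank | pqm_rank[bs] >= min_rank)))
        if (permissive) {
          lk_charge <- (Ccum[bs + 1L] - Ccum[pos]) -
            (Acum[bs + 1L] - Acum[pos])
          ok_motif <- ok_motif &
            (pmin(ipqm_rank[pos], pqm_rank[bs]) >= min_rank | lk_charge <= 0)
        }
        ok <- ok_motif & is.finite(g_score[bs + 1L])
        bs <- bs[ok]
        if (length(bs)) {
          lscore <- (Acum[bs + 1L] - Acum[pos]) -
            (Ccum[bs + 1L] - Ccum[pos]) +
            bonus_of_rank(ipqm_rank[pos]) + bonus_of_rank(pqm_rank[bs]) +
            g_score[bs + 1L]
          best <- max(lscore)
          tied <- bs[lscore >= best - SCORE_TOL]
          np <- g_npep[tied + 1L]
          pick <- tied[np == min(np)]
          pick <- pick[length(pick)]  # prefer the longer linker
          h_score[pos] <- best
          h_b[pos] <- pick
          h_npep[pos] <- g_npep[pick + 1L]
          h_count[pos] <- sum(g_count[tied + 1L])
        }
      }
    }

    ## g[pos]: peptide from pos to j, then end of sequence or a linker.
    if (pos <= m - params$min_pep + 1L) {
      js <- seq.int(pos + params$min_pep - 1L, m)
      len <- js - pos + 1L
      pscore <- (Ccum[js + 1L] - Ccum[pos]) - (Acum[js + 1L] - Acum[pos]) +
        params$lambda * (Hcum[js + 1L] - Hcum[pos]) / len
      tail_score <- ifelse(js == m, 0, h_score[js + 1L])
      cand <- pscore + tail_score
      if (any(is.finite(cand))) {
        best <- max(cand[is.finite(cand)])
        tied <- js[is.finite(cand) & cand >= best - SCORE_TOL]
        tail_np <- ifelse(tied == m, 0L, h_npep[tied + 1L])
        pick <- tied[tail_np == min(tail_np)]
        pick <- pick[length(pick)]  # prefer the longer peptide
        g_score[pos] <- best
        g_j[pos] <- pick
        g_npep[pos] <- 1L + (if (pick == m) 0L else h_npep[pick + 1L])
        g_count[pos] <- sum(ifelse(tied == m, 1, h_count[tied + 1L]))
      }
    }
  }

  ## Propeptide: d[1..p] ending at the Arg of a PQM at tier >= Asp-variant
  ## (strict) or any PQM Arg (permissive), within the length bounds.
  min_rank_prop <- if (permissive) 0L else min_rank
  ps <- seq.int(params$min_prop, min(params$max_prop, m))
  ps <- ps[ch[ps] == "R" & pqm_rank[ps] >= min_rank_prop &
             is.finite(g_score[ps + 1L])]
  if (!length(ps)) return(no_arch("no_valid_propeptide_pqm"))
  totals <- bonus_of_rank(pqm_rank[ps]) + g_score[ps + 1L]
  best <- max(totals)
  tied_p <- ps[totals >= best - SCORE_TOL]
  np <- g_npep[tied_p + 1L]
  cand_p <- tied_p[np == min(np)]
  p_star <- cand_p[1L]  # earlier propeptide cut
  n_optima <- sum(g_count[tied_p + 1L])

  ## Traceback.
  pep_bounds <- list(); linker_bounds <- list()
  i <- p_star + 1L
  repeat {
    j <- g_j[i]
    pep_bounds[[length(pep_bounds) + 1L]] <- c(i, j)
    if (j == m) break
    a <- j + 1L; b <- h_b[a]
    linker_bounds[[length(linker_bounds) + 1L]] <- c(a, b)
    i <- b + 1L
  }

  build_model(seq, signal_cut, p_star, pep_bounds, linker_bounds,
              score = best, n_optima = n_optima, params = params)
}

## Assemble a precursor_model from downstream-local segment bounds.
build_model <- function(seq, signal_cut, prop_end, pep_bounds, linker_bounds,
                        score, n_optima, params,
                        signal_source = "heuristic") {
  off <- signal_cut  # d-local 1-based k -> global 0-based (off + k - 1)
  glob <- function(b) interval(off + b[1] - 1L, off + b[2])
  d_sub <- function(b) substr(seq, off + b[1], off + b[2])

  prop_seq <- d_sub(c(1L, prop_end))
  prop_interior <- substr(prop_seq, 1L, nchar(prop_seq) - 4L)
  internal <- rbind(
    if (nchar(prop_interior) >= 4L) scan_pqm(prop_interior),
    if (nchar(prop_interior) >= 4L) scan_ipqm(prop_interior))

  n_pep <- length(pep_bounds)
  peptides <- vector("list", n_pep)
  for (k in seq_len(n_pep)) {
    enc <- d_sub(pep_bounds[[k]])
    amidated <- endsWith(enc, "G")
    mature <- if (amidated) substr(enc, 1L, nchar(enc) - 1L) else enc
    peptides[[k]] <- list(
      interval = glob(pep_bounds[[k]]),
      encoded = enc,
      sequence = mature,
      amidated = amidated,
      cys_count = sum(seq_chars(mature) == "C"),
      fusion_flag = "none"
    )
  }
  linkers <- lapply(linker_bounds, function(b) {
    s <- d_sub(b)
    list(interval = glob(b), sequence = s,
         ipqm_tier = motif_tier(substr(s, 2L, 4L)),
         pqm_tier = motif_tier(substr(s, nchar(s) - 3L, nchar(s) - 1L)),
         net_charge = net_charge_count(s))
  })
  last_pep <- peptides[[n_pep]]$encoded
  trailing_anomaly <- inherits(
    validate_linker(last_pep, max_len = params$max_linker),
    "linker_candidate")

  model <- structure(list(
    id = NULL,
    sequence = seq,
    signal = list(interval = interval(0L, signal_cut),
                  sequence = substr(seq, 1L, signal_cut),
                  source = signal_source),
    propeptide = list(
      interval = interval(off, off + prop_end),
      sequence = prop_seq,
      terminal_pqm = list(
        motif = substr(prop_seq, nchar(prop_seq) - 3L, nchar(prop_seq)),
        tier = motif_tier(substr(prop_seq, nchar(prop_seq) - 3L,
                                 nchar(prop_seq) - 1L)),
        signature = classify_pqm_signature(
          substr(prop_seq, nchar(prop_seq) - 3L, nchar(prop_seq)))),
      internal_motifs = internal,
      pi = isoelectric_point(prop_seq)),
    peptides = peptides,
    linkers = linkers,
    ptype = c("simple", "binary")[match(n_pep, 1:2, nomatch = NA)],
    score = score,
    n_optima = n_optima,
    trailing_anomaly = trailing_anomaly
  ), class = "precursor_model")
  if (is.na(model$ptype)) model$ptype <- "complex"
  model
}

#' Classify a precursor by its peptide count
#'
#' Simple = 1 peptide, binary = 2, complex = 3 or more.
#'
#' @param model a `precursor_model`.
#' @return `"simple"`, `"binary"` or `"complex"`.
#' @export
classify_precursor <- function(model) {
  stopifnot(inherits(model, "precursor_model"))
  n <- length(model$peptides)
  if (n == 1L) "simple" else if (n == 2L) "binary" else "complex"
}

#' Amidation rule for an encoded peptide segment
#'
#' A genome-encoded segment ending in Gly immediately before a processing
#' boundary (a linker's Arg or the stop codon) signals C-terminal amidation:
#' the Gly is consumed by the amidating enzyme and excluded from the mature
#' sequence.
#'
#' @param segment encoded peptide segment string.
#' @param next_boundary_kind `"linker"` or `"stop"`; recorded but not used
#'   by the default rule, which treats both boundaries alike.
#' @return list with `sequence` (mature), `amidated`, `encoded`.
#' @export
#' @examples
#' predict_amidation("FLGKKAIG", "linker")  # mature FLGKKAI, amidated
predict_amidation <- function(segment, next_boundary_kind = c("linker",
                                                              "stop")) {
  next_boundary_kind <- match.arg(next_boundary_kind)
  amidated <- endsWith(segment, "G")
  list(
    sequence = if (amidated) substr(segment, 1L, nchar(segment) - 1L)
               else segment,
    amidated = amidated,
    encoded = segment
  )
}

#' Flag propeptide- and linker-fusion events in a parsed model
#'
#' Mutations that destroy a processing site fuse neighbouring segments into
#' one aberrant peptide. Two signatures are flagged: `propeptide_fusion` when
#' the first peptide's N-terminal 10 residues carry a net charge of -2 or
#' less (an acidic head inherited from an uncleaved propeptide remnant), and
#' `linker_fusion` when a near-linker — an anionic window bounded by a PQM
#' whose partner Arg is missing or mutated — is detected inside a peptide.
#'
#' @param model a `precursor_model`.
#' @param min_flank minimum residues required on each side of a near-linker
#'   (default 10, the minimum peptide length).
#' @return the model with `fusion_flag` set on affected peptides.
#' @export
flag_fusion_events <- function(model, min_flank = 10L) {
  stopifnot(inherits(model, "precursor_model"))
  for (k in seq_along(model$peptides)) {
    pep <- model$peptides[[k]]
    s <- pep$sequence
    if (k == 1L && nchar(s) >= min_flank &&
        net_charge_count(substr(s, 1L, 10L)) <= -2L) {
      model$peptides[[k]]$fusion_flag <- "propeptide_fusion"
      next
    }
    if (detect_near_linker(s, min_flank = min_flank))
      model$peptides[[k]]$fusion_flag <- "linker_fusion"
  }
  model
}

## TRUE when `s` contains an internal anionic near-linker: either a window
## ending at a PQM Arg whose leading iPQM Arg is absent (deleted), or a
## window starting at an iPQM Arg whose closing PQM Arg is mutated.
detect_near_linker <- function(s, min_flank = 10L, max_linker = 45L) {
  n <- nchar(s)
  if (n < 2L * min_flank + 4L) return(FALSE)
  ch <- seq_chars(s)
  ## Branch A: iPQM Arg deleted; remnant = linker minus its first residue.
  pqm <- scan_pqm(s)
  for (p in pqm$anchor_arg + 1L) {  # 1-based Arg position
    if (n - p < min_flank) next
    for (l in 4:(max_linker - 1L)) {
      a <- p - l + 1L
      if (a - 1L < min_flank) break
      w <- substr(s, a, p)
      if (net_charge_count(w) <= -1L &&
          motif_tier(substr(s, a, a + 2L)) != "degenerate") return(TRUE)
    }
  }
  ## Branch B: PQM Arg mutated; remnant keeps its leading iPQM Arg.
  ipqm <- scan_ipqm(s)
  for (q in ipqm$anchor_arg + 1L) {
    if (q - 1L < min_flank) next
    for (l in 4:(max_linker - 1L)) {
      b <- q + l - 1L
      if (n - b < min_flank) break
      w <- substr(s, q, b)
      if (net_charge_count(w) <= -1L) return(TRUE)
    }
  }
  FALSE
}

#' Linear-peptide acceptance rule
#'
#' A candidate segment is accepted as a linear peptide when its N-terminal
#' flank ends with a PQM (contributed by the propeptide or the preceding
#' linker) and its C-terminal flank begins with an iPQM (the following
#' linker) or the segment is transcript-terminal.
#'
#' @param n_flank4 the 4 residues immediately N-terminal of the segment.
#' @param c_flank4 the 4 residues immediately C-terminal, or `NULL` when the
#'   segment is transcript-terminal.
#' @param min_tier minimum motif tier (default `"asp_variant"`, the strict
#'   rule).
#' @return logical.
#' @export
accept_lp <- function(n_flank4, c_flank4 = NULL, min_tier = "asp_variant") {
  min_r <- tier_rank[[min_tier]]
  n_ok <- nchar(n_flank4) == 4L && endsWith(n_flank4, "R") &&
    tier_rank[[motif_tier(substr(n_flank4, 1L, 3L))]] >= min_r
  c_ok <- is.null(c_flank4) ||
    (nchar(c_flank4) == 4L && startsWith(c_flank4, "R") &&
       tier_rank[[motif_tier(substr(c_flank4, 2L, 4L))]] >= min_r)
  n_ok && c_ok
}

#' Parse one precursor end to end
#'
#' Strips a trailing stop, chooses the signal cleavage site (an external
#' annotation always overrides the heuristic), segments the downstream
#' region, applies the amidation rule and fusion flagging, and classifies
#' the precursor.
#'
#' @param seq full precursor protein string.
#' @param id precursor identifier.
#' @param signal_cut optional externally annotated cut (1-based last signal
#'   residue); when `NULL` the top [propose_signal_cleavage()] candidate is
#'   used.
#' @param params an [lp_params()] object.
#' @return a `precursor_model`, or an `lp_no_architecture` object.
#' @export
parse_precursor <- function(seq, id = NULL, signal_cut = NULL,
                            params = lp_params()) {
  seq <- sub("\\*$", "", toupper(seq))
  source <- "annotation"
  if (is.null(signal_cut)) {
    cand <- propose_signal_cleavage(seq)
    if (!nrow(cand))
      return(structure(list(id = id, sequence = seq,
                            reason = "no_signal_candidate"),
                       class = "lp_no_architecture"))
    signal_cut <- cand$cut[1L]
    source <- "heuristic"
  }
  model <- segment_precursor(seq, signal_cut, params)
  if (inherits(model, "lp_no_architecture")) {
    model$id <- id
    return(model)
  }
  model$id <- id
  model$signal$source <- source
  flag_fusion_events(model, min_flank = params$min_pep)
}

#' @export
print.precursor_model <- function(x, ...) {
  cat("<precursor_model>", x$id %||% "(unnamed)", "\n")
  cat("  type:", x$ptype, "|", length(x$peptides), "peptide(s),",
      length(x$linkers), "linker(s)\n")
  cat("  signal 1-", x$signal$interval$end, "; propeptide ",
      x$propeptide$interval$start + 1L, "-", x$propeptide$interval$end,
      " (PQM ", x$propeptide$terminal_pqm$motif, ", ",
      x$propeptide$terminal_pqm$tier, ")\n", sep = "")
  for (p in x$peptides) {
    iv <- interval_onebased(p$interval)
    cat(sprintf("  peptide %d-%d %s%s%s\n", iv[["start"]], iv[["end"]],
                p$sequence, if (p$amidated) "-NH2" else "",
                if (p$fusion_flag != "none")
                  paste0(" [", p$fusion_flag, "]") else ""))
  }
  invisible(x)
}
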