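## Seeded generator of synthetic precursor transcripts with known ground
## truth. The generator emulates the structural statistics observed in
## venom-gland transcriptomes: signal peptides of 18-24 residues with a
## hydrophobic core, acidic propeptides of 10-86 residues ending in a PQM
## (signature classes sampled at the observed 38/27/31/4 shares), cationic
## amphipathic mature peptides (most 19-28 residues, tails to 11 and 58),
## anionic linkers of 5-43 residues with iPQM/PQM termini (14.6% of iPQMs
## and 2.9% of PQMs drawn Glu-less, realised as Asp variants), C-terminal
## amidation at rate 0.78, and per-precursor peptide counts up to 13 with
## type weights matching the observed family census (simple 46 : binary 5 :
## complex 82 over sizes 3-13).

#' Generator configuration
#'
#' Defaults encode the study conditions described above. `mode = "clean"`
#' rejects any emission whose segmentation is not uniquely optimal and equal
#' to the planted truth, so downstream boundary-recovery tests have exact
#' ground truth; `"ambiguous"` emits every draw.
#'
#' @param seed integer seed used by [generate_catalog()].
#' @param n_species number of species in a generated catalog.
#' @param n_precursors precursor families per species.
#' @param npep_weights unnormalised weights for 1..13 peptides per
#'   precursor.
#' @param amidation_prob per-peptide C-terminal amidation probability.
#' @param gluless_ipqm_rate,aspvar_pqm_rate rates of Asp-variant (Glu-less)
#'   linker iPQM and PQM termini.
#' @param sharing_rate probability that a generated peptide is copied from
#'   another species' pool (plants cross-species sharing).
#' @param mode `"clean"` or `"ambiguous"`.
#' @param params [lp_params()] used for the clean-mode acceptance check.
#' @param max_tries rejection-sampling cap per precursor.
#' @param pep_len,linker_len,signal_len,prop_len functions drawing one
#'   length from the respective distribution (defaults match the printed
#'   ranges).
#' @return list of class `lp_sim_config`.
#' @export
lp_sim_config <- function(seed = 1L,
                          n_species = 4L,
                          n_precursors = 6L,
                          npep_weights = c(46, 5, rep(82 / 11, 11)),
                          amidation_prob = 0.78,
                          gluless_ipqm_rate = 0.146,
                          aspvar_pqm_rate = 0.029,
                          sharing_rate = 0,
                          mode = c("clean", "ambiguous"),
                          params = lp_params(),
                          max_tries = 200L,
                          pep_len = default_pep_len,
                          linker_len = default_linker_len,
                          signal_len = function() sample(18:24, 1L),
                          prop_len = default_prop_len) {
  stopifnot(length(npep_weights) == 13L, all(npep_weights >= 0))
  structure(list(seed = as.integer(seed), n_species = n_species,
                 n_precursors = n_precursors, npep_weights = npep_weights,
                 amidation_prob = amidation_prob,
                 gluless_ipqm_rate = gluless_ipqm_rate,
                 aspvar_pqm_rate = aspvar_pqm_rate,
                 sharing_rate = sharing_rate,
                 mode = match.arg(mode), params = params,
                 max_tries = as.integer(max_tries),
                 pep_len = pep_len, linker_len = linker_len,
                 signal_len = signal_len, prop_len = prop_len),
            class = "lp_sim_config")
}

## Mature peptide length: mass at 19-28 aa with tails to 11 and 58.
default_pep_len <- function() {
  u <- stats::runif(1)
  if (u < 0.10) sample(11:18, 1L)
  else if (u < 0.90) sample(19:28, 1L)
  else sample(29:58, 1L)
}

## Linker length: mostly short, occasionally up to 43 residues.
default_linker_len <- function() {
  u <- stats::runif(1)
  if (u < 0.70) sample(5:10, 1L)
  else if (u < 0.95) sample(11:24, 1L)
  else sample(25:43, 1L)
}

## Propeptide length: most 22-39 aa, range 10-86.
default_prop_len <- function() {
  u <- stats::runif(1)
  if (u < 0.20) sample(10:21, 1L)
  else if (u < 0.80) sample(22:39, 1L)
  else sample(40:86, 1L)
}

samp <- function(x, n, prob = NULL)
  paste(sample(x, n, replace = TRUE, prob = prob), collapse = "")

## Signal peptide: Met, a basic n-region residue, hydrophobic core through
## position L-6, then a c-region whose small residues (A,G,S,T) sit only at
## the -3 and -1 positions of the true cut, so the planted site carries the
## signal-peptidase signature and flanking positions do not.
gen_signal <- function(L) {
  core <- strsplit(samp(c("L", "V", "I", "F"), L - 7L), "")[[1]]
  creg <- sample(c("N", "Q", "P"), 5L, replace = TRUE)
  creg[3L] <- sample(c("A", "S", "G", "T"), 1L)  # position -3 of the cut
  creg[5L] <- sample(c("A", "S", "G"), 1L)       # position -1 of the cut
  paste0("M", sample(c("K", "R", "N"), 1L), paste(core, collapse = ""),
         paste(creg, collapse = ""))
}

## Propeptide: acidic Arg-free interior plus a terminal PQM whose signature
## class is sampled at the observed shares EEAR 38 / XEER 27 / XXER 31 /
## XXDR 4 (percent).
PROP_INTERIOR <- c("E", "D", "A", "S", "N", "L", "V", "G", "T", "P")
PROP_W <- c(0.24, 0.10, 0.15, 0.14, 0.10, 0.10, 0.05, 0.05, 0.04, 0.03)
gen_propeptide <- function(L) {
  sig <- sample(c("EEAR", "XEER", "XXER", "XXDR"), 1L,
                prob = c(0.38, 0.27, 0.31, 0.04))
  x_non_e <- c("A", "S", "N", "G", "T", "D")
  x_non_ed <- c("A", "S", "N", "G", "T")
  pqm <- switch(sig,
    EEAR = "EEAR",
    XEER = paste0(sample(x_non_e, 1L), "EER"),
    XXER = paste0(samp(x_non_e, 2L), "ER"),
    XXDR = paste0(samp(x_non_ed, 2L), "DR"))
  paste0(samp(PROP_INTERIOR, L - 4L, PROP_W), pqm)
}

## Mature peptide: Lys/Arg every 2-4 positions, hydrophobic/polar elsewhere,
## no Asp/Glu, never ending in Gly (Gly is the amidation signal).
PEP_FILLER <- c("L", "A", "I", "F", "V", "W", "G", "S", "T", "N")
PEP_W <- c(0.22, 0.16, 0.13, 0.10, 0.12, 0.04, 0.08, 0.07, 0.05, 0.03)
gen_peptide <- function(L) {
  ch <- character(L)
  i <- 1L + sample(0:1, 1L)
  while (i <= L) {
    ch[i] <- sample(c("K", "R"), 1L, prob = c(0.75, 0.25))
    i <- i + sample(2:4, 1L)
  }
  open <- which(ch == "")
  ch[open] <- sample(PEP_FILLER, length(open), replace = TRUE, prob = PEP_W)
  if (ch[L] %in% c("G", "R", "K")) ch[L] <- sample(c("L", "I", "V", "F"), 1L)
  if (!any(ch %in% c("K", "R"))) ch[sample(L, 1L)] <- "K"
  paste(ch, collapse = "")
}

## Linker: R + iPQM window, anionic middle, PQM window + R. A 5-mer's two
## motif windows coincide, so the Glu-less draw then applies to both
## termini jointly; for length >= 6 the windows are placed feasibly (a
## Glu-less window gets Asp, the canonical partner gets its Glu outside the
## shared positions). Net charge is forced to <= 0 by Asp conversions,
## which never change a window's tier (Asp neither adds nor removes Glu).
LINK_MIDDLE <- c("E", "D", "S", "A", "N", "G", "T")
LINK_MID_W <- c(0.34, 0.14, 0.16, 0.12, 0.12, 0.07, 0.05)
LINK_NONACID <- c("S", "A", "N", "G", "T")
gen_linker <- function(L, gluless_ipqm, aspvar_pqm) {
  if (L == 5L) aspvar_pqm <- gluless_ipqm
  ch <- c("R", sample(LINK_NONACID, L - 2L, replace = TRUE), "R")
  ip <- 2:4
  pq <- (L - 3L):(L - 1L)
  middle <- setdiff(seq(2L, L - 1L), c(ip, pq))
  if (length(middle))
    ch[middle] <- sample(LINK_MIDDLE, length(middle), replace = TRUE,
                         prob = LINK_MID_W)
  pick1 <- function(pos) if (length(pos) == 1L) pos else sample(pos, 1L)
  if (gluless_ipqm) {
    ch[ip][ch[ip] == "E"] <- "D"
    ch[pick1(ip)] <- "D"
  } else {
    ch[pick1(if (aspvar_pqm) setdiff(ip, pq) else ip)] <- "E"
  }
  if (aspvar_pqm) {
    ch[pq][ch[pq] == "E"] <- "D"
    if (!any(ch[pq] == "D")) ch[pick1(pq)] <- "D"
  } else if (!any(ch[pq] == "E")) {
    ch[pick1(if (gluless_ipqm) setdiff(pq, ip) else pq)] <- "E"
  }
  # enforce net charge <= 0 (two terminal Arg to compensate)
  fixable <- setdiff(which(!(ch %in% c("R", "E", "D"))), c(1L, L))
  while (sum(ch %in% c("K", "R")) - sum(ch %in% c("D", "E")) > 0 &&
         length(fixable)) {
    k <- pick1(fixable); fixable <- setdiff(fixable, k)
    ch[k] <- "D"
  }
  paste(ch, collapse = "")
}

#' Generate one synthetic precursor with ground truth
#'
#' Draws from the current RNG stream (seed management belongs to the
#' caller). In clean mode the emission is rejected and redrawn until
#' [segment_precursor()] recovers exactly the planted segmentation as the
#' unique optimum.
#'
#' @param config an [lp_sim_config()].
#' @param n_peptides optionally fix the peptide count (overrides the
#'   configured distribution).
#' @param peptide_pool optional data.frame (`sequence`, `amidated`) of
#'   peptides from other species; entries are reused with probability
#'   `config$sharing_rate` to plant cross-species sharing.
#' @return list with `record` (id, alphabet, residues) and `truth`:
#'   `signal_cut`, `prop_end` (1-based, local to the downstream region),
#'   `pep_bounds`, `linker_bounds` (lists of local 1-based (start,end)
#'   pairs), `peptides` data.frame (`sequence`, `amidated`), `n_peptides`.
#' @export
generate_precursor <- function(config = lp_sim_config(), n_peptides = NULL,
                               peptide_pool = NULL) {
  for (try in seq_len(config$max_tries)) {
    npep <- n_peptides %||%
      sample(1:13, 1L, prob = config$npep_weights)
    sig <- gen_signal(config$signal_len())
    prop <- gen_propeptide(config$prop_len())
    mature <- character(npep); amid <- logical(npep); enc <- character(npep)
    for (k in seq_len(npep)) {
      reuse <- !is.null(peptide_pool) && nrow(peptide_pool) > 0 &&
        stats::runif(1) < config$sharing_rate
      if (reuse) {
        r <- peptide_pool[sample(nrow(peptide_pool), 1L), ]
        mature[k] <- r$sequence; amid[k] <- r$amidated
      } else {
        mature[k] <- gen_peptide(config$pep_len())
        amid[k] <- stats::runif(1) < config$amidation_prob
      }
      enc[k] <- if (amid[k]) paste0(mature[k], "G") else mature[k]
    }
    links <- if (npep > 1L)
      vapply(seq_len(npep - 1L), function(i)
        gen_linker(config$linker_len(),
                   gluless_ipqm = stats::runif(1) < config$gluless_ipqm_rate,
                   aspvar_pqm = stats::runif(1) < config$aspvar_pqm_rate),
        character(1))
    else character()

    parts <- character(0)
    pep_bounds <- vector("list", npep)
    linker_bounds <- if (npep > 1L) vector("list", npep - 1L) else list()
    pos <- nchar(prop)
    for (k in seq_len(npep)) {
      pep_bounds[[k]] <- c(pos + 1L, pos + nchar(enc[k]))
      pos <- pos + nchar(enc[k])
      if (k < npep) {
        linker_bounds[[k]] <- c(pos + 1L, pos + nchar(links[k]))
        pos <- pos + nchar(links[k])
      }
    }
    body <- prop
    for (k in seq_len(npep)) {
      body <- paste0(body, enc[k])
      if (k < npep) body <- paste0(body, links[k])
    }
    seq <- paste0(sig, body)

    truth <- list(signal_cut = nchar(sig), prop_end = nchar(prop),
                  pep_bounds = pep_bounds, linker_bounds = linker_bounds,
                  peptides = data.frame(sequence = mature, amidated = amid,
                                        stringsAsFactors = FALSE),
                  linkers = links,
                  n_peptides = npep)

    if (config$mode == "ambiguous")
      return(list(record = list(id = NA_character_, alphabet = "protein",
                                residues = seq), truth = truth))

    model <- segment_precursor(seq, truth$signal_cut, config$params)
    if (inherits(model, "lp_no_architecture")) next
    if (model$n_optima != 1L) next
    if (model_matches_truth(model, truth)) {
      return(list(record = list(id = NA_character_, alphabet = "protein",
                                residues = seq), truth = truth))
    }
  }
  stop("generate_precursor(): rejection-sampling cap reached (",
       config$max_tries, " tries); last draw had ", npep, " peptide(s)")
}

#' Do a model's boundaries equal the planted truth?
#'
#' @param model a `precursor_model`.
#' @param truth a truth entry from [generate_precursor()].
#' @return logical.
#' @export
model_matches_truth <- function(model, truth) {
  off <- truth$signal_cut
  glob <- function(b) c(off + b[1] - 1L, off + b[2])
  if (model$propeptide$interval$end != off + truth$prop_end) return(FALSE)
  if (length(model$peptides) != truth$n_peptides) return(FALSE)
  for (k in seq_along(model$peptides)) {
    iv <- model$peptides[[k]]$interval
    tb <- glob(truth$pep_bounds[[k]])
    if (iv$start != tb[1] || iv$end != tb[2]) return(FALSE)
    if (model$peptides[[k]]$sequence != truth$peptides$sequence[k])
      return(FALSE)
    if (model$peptides[[k]]$amidated != truth$peptides$amidated[k])
      return(FALSE)
  }
  TRUE
}

#' Generate a multi-species catalog with ground truth
#'
#' Seeds the RNG from `config$seed`, generates `n_species x n_precursors`
#' precursors, optionally planting cross-species peptide sharing, and
#' assembles an `lp_catalog` plus the full ground truth.
#'
#' @param config an [lp_sim_config()].
#' @return list with `catalog` (an `lp_catalog`), `records` (data.frame of
#'   all precursor sequences), and `truth` (per-precursor truth entries,
#'   named by precursor id).
#' @export
generate_catalog <- function(config = lp_sim_config()) {
  set.seed(config$seed)
  species <- list(); records <- list(); truths <- list()
  pool <- data.frame(sequence = character(), amidated = logical(),
                     species = character(), stringsAsFactors = FALSE)
  for (s in seq_len(config$n_species)) {
    sp_id <- sprintf("species_%02d", s)
    models <- list()
    other_pool <- pool[pool$species != sp_id, c("sequence", "amidated")]
    for (f in seq_len(config$n_precursors)) {
      prec_id <- sprintf("%s_prec_%02d", sp_id, f)
      gp <- generate_precursor(config, peptide_pool = other_pool)
      gp$record$id <- prec_id
      model <- parse_precursor(gp$record$residues, id = prec_id,
                               signal_cut = gp$truth$signal_cut,
                               params = config$params)
      models[[prec_id]] <- model
      records[[prec_id]] <- gp$record
      truths[[prec_id]] <- gp$truth
      pool <- rbind(pool, cbind(gp$truth$peptides, species = sp_id))
    }
    species[[sp_id]] <- list(id = sp_id, models = models)
  }
  catalog <- new_catalog(species)
  list(catalog = catalog,
       records = do.call(rbind, lapply(records, as.data.frame)),
       truth = truths)
}

#' Generate a counts table with planted LP annotation
#'
#' Per-contig counts are negative-binomial draws around planted expression
#' levels; `n_lps` is the planted number of distinct identified peptides per
#' contig (`k`). The truth records the exact TPM-weighted mean `k`, which
#' equals the abundance quotient [B]/[A].
#'
#' @param n_contigs number of contigs.
#' @param lp_fraction fraction of contigs encoding at least one LP.
#' @param k_weights unnormalised weights over k = 1..13 for LP contigs.
#' @param size negative-binomial dispersion parameter.
#' @return list with `table` (contig_id, count, eff_length, n_lps) and
#'   `truth` (`A`, `B`, `quotient` computed from the drawn counts).
#' @export
generate_counts <- function(n_contigs = 200L, lp_fraction = 0.3,
                            k_weights = c(46, 5, rep(82 / 11, 11)),
                            size = 5) {
  n_lp <- max(1L, round(n_contigs * lp_fraction))
  k <- c(sample(1:13, n_lp, replace = TRUE, prob = k_weights),
         rep(0L, n_contigs - n_lp))
  mu <- stats::rlnorm(n_contigs, meanlog = 4, sdlog = 1.5)
  counts <- stats::rnbinom(n_contigs, mu = mu, size = size)
  if (all(counts == 0)) counts[1] <- 1L
  eff_len <- round(stats::runif(n_contigs, 300, 3000))
  tab <- data.frame(contig_id = sprintf("contig_%04d", seq_len(n_contigs)),
                    count = counts, eff_length = eff_len, n_lps = k,
                    stringsAsFactors = FALSE)
  tpm <- compute_tpm(tab$count, tab$eff_length)
  lp <- tab$n_lps >= 1L
  A <- 100 * sum(tpm[lp]) / 1e6
  B <- 100 * sum(tab$n_lps[lp] * tpm[lp]) / 1e6
  list(table = tab,
       truth = list(A = A, B = B,
                    quotient = if (A > 0) B / A else NA_real_))
}
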