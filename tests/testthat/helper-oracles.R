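# Independent oracles used by the tests. Each re-derives an expected value
# by a different route than the implementation under test: literal codon
# lookup for translation, regular expressions for motif scanning, explicit
# enumeration for segmentation, atomic composition for masses, direct
# likelihood maximisation for the GLM.

# --- codon-table oracle (standard genetic code, hand-written lookup) -----
ORACLE_CODONS <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_revcomp <- function(nt) {
  comp <- c(A="T", C="G", G="C", T="A", N="N")
  paste(rev(comp[strsplit(nt, "")[[1]]]), collapse = "")
}

oracle_translate_frame <- function(nt, offset) {
  n <- nchar(nt) - offset
  n <- n - n %% 3
  if (n < 3) return("")
  codons <- substring(nt, seq(offset + 1, offset + n, 3),
                      seq(offset + 3, offset + n + 2, 3))
  aa <- ORACLE_CODONS[codons]
  aa[is.na(aa)] <- "X"   # codons containing N
  paste(aa, collapse = "")
}

oracle_six_frames <- function(nt) {
  rc <- oracle_revcomp(nt)
  c(vapply(0:2, function(o) oracle_translate_frame(nt, o), character(1)),
    vapply(0:2, function(o) oracle_translate_frame(rc, o), character(1)))
}

# --- regex motif oracle --------------------------------------------------
# Window positions (1-based starts) where a canonical / Asp-variant motif
# begins. The lookahead keeps overlapping hits.
oracle_pqm_starts <- function(s, tier = c("canonical", "asp_variant")) {
  tier <- match.arg(tier)
  pat <- if (tier == "canonical") "(?=(?:E..|.E.|..E)R)"
         else "(?=(?:D[^E][^E]|[^E]D[^E]|[^E][^E]D)R)"
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

oracle_ipqm_starts <- function(s, tier = c("canonical", "asp_variant")) {
  tier <- match.arg(tier)
  pat <- if (tier == "canonical") "(?=R(?:E..|.E.|..E))"
         else "(?=R(?:D[^E][^E]|[^E]D[^E]|[^E][^E]D))"
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

# --- literal-rule PQM signature oracle -----------------------------------
oracle_pqm_signature <- function(m) {
  if (m == "EEAR") return("EEAR")
  if (grepl("^.EER$", m)) return("XEER")
  if (grepl("^..ER$", m)) return("XXER")
  if (grepl("^[^E][^E]DR$", m)) return("XXDR")
  "other"
}

# --- exhaustive segmentation oracle --------------------------------------
# Enumerates every legal tiling [propeptide..PQM][peptide]([linker][peptide])*
# of the region downstream of signal_cut and scores it with the same
# objective as the DP, but by brute force. Returns the optimum, the number
# of co-optimal tilings (score within tol) and the optimal boundaries.
oracle_enumerate <- function(seq, signal_cut, params = lp_params(),
                             tol = 1e-9) {
  d <- substr(seq, signal_cut + 1, nchar(seq))
  m <- nchar(d)
  ch <- strsplit(d, "")[[1]]
  cationic <- ch %in% c("K", "R"); anionic <- ch %in% c("D", "E")
  hydrophobic <- ch %in% c("A", "I", "L", "M", "F", "W", "V")
  seg_count <- function(i, j, what)
    sum(switch(what, cat = cationic, acid = anionic,
               hyd = hydrophobic)[i:j])
  tier3 <- function(three) {
    if (grepl("E", three)) "canonical"
    else if (grepl("D", three)) "asp_variant" else "degenerate"
  }
  bonus <- function(tier) unname(params$tier_bonus[tier])
  pep_score <- function(i, j)
    seg_count(i, j, "cat") - seg_count(i, j, "acid") +
      params$lambda * seg_count(i, j, "hyd") / (j - i + 1)
  linker_ok <- function(a, b) {
    len <- b - a + 1
    if (ch[a] != "R" || ch[b] != "R") return(FALSE)
    if (len < 5 || len > params$max_linker) return(FALSE)
    it <- tier3(substr(d, a + 1, a + 3)); pt <- tier3(substr(d, b - 3, b - 1))
    it != "degenerate" && pt != "degenerate"
  }
  linker_score <- function(a, b)
    seg_count(a, b, "acid") - seg_count(a, b, "cat") +
      bonus(tier3(substr(d, a + 1, a + 3))) +
      bonus(tier3(substr(d, b - 3, b - 1)))

  # all tilings of d[i..m] starting with a peptide
  tilings_from <- function(i) {
    out <- list()
    if (i > m - params$min_pep + 1) return(out)
    for (j in (i + params$min_pep - 1):m) {
      s1 <- pep_score(i, j)
      if (j == m) {
        out[[length(out) + 1]] <- list(score = s1, peps = list(c(i, j)),
                                       links = list())
        next
      }
      a <- j + 1
      if (ch[a] != "R") next
      b_hi <- min(a + params$max_linker - 1, m - params$min_pep)
      if (b_hi < a + 4) next
      for (b in (a + 4):b_hi) {
        if (!linker_ok(a, b)) next
        s2 <- linker_score(a, b)
        for (tl in tilings_from(b + 1)) {
          out[[length(out) + 1]] <- list(
            score = s1 + s2 + tl$score,
            peps = c(list(c(i, j)), tl$peps),
            links = c(list(c(a, b)), tl$links))
        }
      }
    }
    out
  }

  results <- list()
  for (p in params$min_prop:min(params$max_prop, m)) {
    if (ch[p] != "R" || p < 4) next
    pt <- tier3(substr(d, p - 3, p - 1))
    if (pt == "degenerate") next
    for (tl in tilings_from(p + 1)) {
      results[[length(results) + 1]] <- list(
        score = bonus(pt) + tl$score, prop_end = p,
        peps = tl$peps, links = tl$links)
    }
  }
  if (!length(results)) return(list(n = 0))
  scores <- vapply(results, function(r) r$score, numeric(1))
  best <- max(scores)
  opt <- results[scores >= best - tol]
  list(n = length(results), score = best, n_optima = length(opt),
       optima = opt)
}

# --- atomic-composition mass oracle --------------------------------------
ORACLE_ATOMS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
# residue formulas (amino acid minus water): counts of C,H,N,O,S
ORACLE_RESIDUE_FORMULA <- list(
  G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))

oracle_mass <- function(seq, amidated = FALSE) {
  ch <- strsplit(seq, "")[[1]]
  atoms <- Reduce(`+`, ORACLE_RESIDUE_FORMULA[ch])
  atoms <- atoms + c(0, 2, 0, 1, 0)                    # + H2O
  if (amidated) atoms <- atoms + c(0, 1, 1, -1, 0)     # OH -> NH2
  sum(atoms * ORACLE_ATOMS[c("C", "H", "N", "O", "S")])
}

# --- direct likelihood-maximisation GLM oracle ---------------------------
oracle_poisson_fit <- function(y, x) {
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * x
    sum(exp(eta)) - sum(y * eta)
  }
  gr <- function(beta) {
    mu <- exp(beta[1] + beta[2] * x)
    c(sum(mu) - sum(y), sum(mu * x) - sum(y * x))
  }
  opt <- stats::optim(c(log(mean(y) + 0.1), 0), nll, gr, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000))
  opt$par
}

# --- random sequence helpers ---------------------------------------------
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
random_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")
random_dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE),
                                collapse = "")

# small-precursor generator config for enumeration cross-checks
short_sim_config <- function(mode = "clean") {
  lp_sim_config(
    mode = mode,
    npep_weights = c(1, 1, rep(0, 11)),
    pep_len = function() sample(11:16, 1),
    linker_len = function() sample(5:8, 1),
    signal_len = function() sample(18:20, 1),
    prop_len = function() sample(10:16, 1))
}
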