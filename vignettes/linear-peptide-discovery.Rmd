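---
title: "Linear-peptide discovery in spider venom-gland transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-peptide discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomLP)
```

## The biological model

Linear peptides (LPs) are short, mostly cationic, membrane-active venom
peptides of modern (RTA-clade) spiders. They are not translated one gene per
peptide: a single precursor protein carries a signal peptide, an acidic
propeptide, and then one or more mature peptides separated by short anionic
linkers. Maturation is driven by a venom protease that recognises a
*processing quadruplet motif* (PQM): a four-residue window ending in Arg
with at least one Glu among the three preceding positions. The propeptide
ends at the Arg of a PQM; every linker opens with the inverted motif (iPQM:
Arg first, Glu among the next three) and closes with a PQM, so a linker
always begins and ends with Arg. Precursors encoding one peptide are called
*simple*, two *binary*, three or more *complex*; complex precursors with up
to 13 peptides have been observed. In a small minority of motifs Glu is
replaced by Asp; the package grades every motif window into tiers
(`canonical` ≥ 1 Glu, `asp_variant` Asp but no Glu, `degenerate` neither)
and keeps the tier on record so strict analyses can filter.

One published acceptance clause attaches "(12 bps)" to the flanking-motif
rule. Twelve nucleotides are four codons, i.e. exactly one motif window, so
this package treats the acceptance unit as the 4-residue motif
(`accept_lp()`); the phrase has no other consistent reading.

## Segmentation as an explicit optimisation

Manual annotation of precursors follows rules (terminal-Arg linkers, motif
grades, length ranges) but leaves tie-breaking implicit. To make the
procedure reproducible and testable, `segment_precursor()` poses it as an
optimisation over all legal tilings

```
[propeptide ... PQM] [peptide] ( [linker] [peptide] )*
```

of the region downstream of the signal peptide, maximising

```
sum over peptides  ( #cationic - #anionic + lambda * hydrophobic fraction )
+ sum over linkers ( #anionic - #cationic )
+ motif tier bonuses
```

subject to: propeptide length within bounds (default 8–90, covering the
observed 10–86), linker length 5–45 (a 5-mer such as RNEAR has its two
motifs overlapping; the longest observed linkers are 42/43 residues), every
motif at Asp-variant tier or better (strict mode), and peptide segments of
at least 10 residues (the shortest observed mature peptides are 11-residue
tachykinin-like peptides). Ties break toward fewer (hence longer) peptides,
then toward the earlier propeptide cut.

The optimum is found by dynamic programming over Arg-anchored cut points,
right to left, with prefix sums making each segment score O(1). The DP also
*counts* co-optimal tilings (scores within 1e-9), so callers can detect
ambiguous architectures; `n_optima == 1` certifies a unique optimum. The
same objective is implemented a second time in the test suite as a plain
exhaustive enumeration, and the two agree on hundreds of short synthetic
precursors — the DP is never checked against itself.

Numerical choices: the score tolerance (1e-9) treats sums of small integers
plus one rational term, where true ties are exact and accidental near-ties
essentially impossible; `lambda = 2.0` and tier bonuses (canonical 2,
Asp-variant 1, degenerate 0) are fixed, exposed in `lp_params()`, and
irrelevant on clean synthetic data (the planted tiling wins by a wide
margin); they matter only for genuinely ambiguous real sequences, where the
tier on record lets the user re-filter. Architectures must end at the stop
codon (or sequence end); a final peptide that itself validates as a linker
is reported as `trailing_anomaly` rather than silently dropped.

In permissive mode one Glu-less linker terminus is tolerated when the
linker's net charge (K,R = +1; D,E = −1) is non-positive — mirroring the
observation that a sizeable minority of linker iPQMs lack Glu while linkers
remain anionic overall.

## Signal peptides, amidation, fusion events

Signal-peptide prediction by neural models is out of scope;
`propose_signal_cleavage()` is a transparent stand-in restricted to the
observed 18–24 residue range, scoring mean Kyte–Doolittle hydropathy of the
core window plus a small-residue (A,G,S,C,T) bonus at the −3/−1 positions —
the classical signal-peptidase signature. An externally annotated cut
always overrides it.

C-terminal amidation is predicted by the standard peptidylglycine
α-amidating convention: an encoded segment ending in Gly immediately before
a processing boundary donates that Gly and the mature peptide is amidated.
The flag is recorded per peptide so an alternative rule can be swapped in.

Mutated processing sites fuse neighbouring segments. `flag_fusion_events()`
flags two signatures: a first peptide whose N-terminal 10 residues carry
net charge ≤ −2 (`propeptide_fusion`: an uncleaved acidic propeptide
remnant), and an internal anionic "near-linker" — a window at a PQM whose
partner Arg is absent or mutated — inside a peptide (`linker_fusion`). The
near-linker rule requires at least 10 residues of peptide on each side and
net charge ≤ −1 in the window; on clean synthetic peptides (cationic, with
essentially no Asp/Glu) false positives are structurally unlikely, which
the tests confirm.

## Peptide biochemistry

Masses are *average* masses (sum of residue masses + 18.02 for water;
amidation −0.98), matching the scale of published venom-peptide masses.
Isoelectric points solve net charge = 0 by bisection on [0, 14] to 1e-4 pH
units over Henderson–Hasselbalch group charges; the default pKa set is
EMBOSS, with Bjellqvist selectable. Published pI values for these peptides
depend on an unstated pKa choice, so printed pIs are matched only
approximately and are never asserted. Composition statistics use declared
residue classes — cationic K/R (His optional), anionic D/E, hydrophobic
A/I/L/M/F/W/V (Cys/Gly optional) — because the published "content of
charged and hydrophobic amino acids" does not define its classes; ours are
explicit arguments. Length classes are short < 30, middle 30–60, long > 60
residues, with both boundary values in `middle`. `frequency_matrix()`
computes the column-normalised counts behind a sequence logo; rendering is
out of scope.

## Census, sharing, abundance

A "unique LP" is a unique (sequence, amidation) pair within a species;
cross-species sharing is exact sequence identity with amidation required to
match (configurable). Percentages are rounded half-up to the printed
precision; note that 719/812 = 88.55 rounds to 88.5 while the published
table prints 88.6 — a denominator or rounding drift in the source that this
package does not chase. The reference overview table bundled in
`reference_census()` carries per-species peptide counts; the 46/87 split of
precursor families by type is carried separately
(`reference_family_counts()`) because it is not derivable from the
per-species rows.

TPM follows the standard definition `1e6 * (c_i/l_i) / sum_j (c_j/l_j)`.
The abundance summary defines `[A]` as the TPM percentage of LP-encoding
contigs and `[B]` as the per-peptide sum — each identified LP counts once
per encoding contig at that contig's TPM percent — making `[B]/[A]`
algebraically the TPM-weighted mean number of peptides per expressed LP
contig: 1 when every contig encodes one peptide, larger where complex
precursors dominate. This is the only reading under which the quotient
measures the impact of complex precursors, and the package's synthetic
tables verify the identity to 1e-9. Quotients recomputed from the bundled
printed `[A]`/`[B]` pairs match the printed quotients except for one
species whose printed `[A]` (0.3%) is so small that its own one-decimal
rounding dominates the ratio; report rounding is one decimal, or two when
the quotient is below 1.

## The phylogenetic trend

Per-species LP counts are modelled as Poisson with log link in
nodes-from-root depth, fitted by IRLS written from first principles
(convergence at relative deviance change < 1e-10, max 100 iterations; Wald
SEs from the final weighted information; likelihood-ratio test against the
intercept-only model). `stats::glm()` and a direct BFGS maximisation of the
likelihood serve as independent oracles in the tests, agreeing to 1e-6 and
better. Depth counts internal nodes on the root-to-tip path, tip excluded,
root included; congeneric species share their family's depth (family-level
tips), the default adopted because species-level depth assignment is not
specified in the source material. The bundled family topology
(`synthetic_family_tree()`) is a synthetic transcription assembled from the
narrative description of spider phylogeny, because the original figure is
not machine-readable; any chi-squared computed from it is therefore
illustrative of the exponential trend, never a reproduction of the
published statistic. One extreme species (180 peptides) is kept in the fit
by default, with an exclusion flag, matching how the published analysis
treated it.

## The synthetic-data generator

`generate_precursor()` emulates the observed structural statistics, and its
defaults *are* the study conditions: signal peptides 18–24 residues
(hydrophobic core, small residues at −3/−1 of the cut); acidic propeptides
10–86 residues (60% mass on 22–39) ending in a PQM whose signature class is
drawn at the observed shares EEAR 38% / XEER 27% / XXER 31% / XXDR 4%;
cationic amphipathic peptides — Lys/Arg every 2–4 positions — with 80% of
mature lengths in 19–28 and tails to 11 and 58; anionic linkers of 5–43
residues (70% in 5–10) with valid iPQM/PQM termini, drawn Glu-less (as Asp
variants) at 14.6% / 2.9%; amidation probability 0.78; peptides per
precursor 1–13 with weights 46 : 5 : 82/11 each for 3–13, taken from the
observed family census (simple : binary : complex, complex sizes spread
uniformly, giving a mean near the observed 8.4 per multi-peptide family).

Clean mode guarantees exact ground truth by rejection sampling: an emission
is kept only when the DP recovers the planted segmentation as the *unique*
optimum (co-optima counted inside the DP, cross-checked against exhaustive
enumeration in the tests). Rejection, rather than constructive avoidance,
keeps the generator simple enough to verify. Two consequences are worth
stating plainly. First, boundary-recovery rates on clean-mode data certify
the internal consistency of grammar, generator and solver — not performance
on real transcriptomes, where signal cuts are uncertain, motifs drift
beyond the Asp tier, and assembly errors truncate precursors. Second, small
biases are accepted by design: a 5-residue linker's two motif windows
coincide, so its Glu-less draw applies to both termini jointly, and
charge-fixing conversions use Asp (which can never change a window's tier);
measured Glu-less rates on unique linkers therefore sit slightly above the
per-draw rate. The generator does not emulate codon usage, expression-level
sequence error, truncated assemblies, or peptide-family structure beyond
optional cross-species copying of whole peptides (`sharing_rate`).

Counts tables come from `generate_counts()`: log-normal expression,
negative-binomial reads (dispersion 5), planted per-contig peptide counts
`k`, and an exactly bookkept `[B]/[A]` truth.

## Problem sizes and reproducibility

The shipped tests run the segmentation-vs-enumeration comparison on 500
clean short precursors (≤ 120 residues), boundary recovery on 1,000
full-size precursors, pI self-consistency and mass additivity on 1,000
random peptides each, GLM recovery at n = 200 and Wald coverage over 200
replicates at n = 48 — sizes chosen so the whole suite completes in about a
minute and a half on one core while keeping binomial error bars tight
enough to be meaningful. All randomness flows through explicit seeds;
identical seeds give byte-identical catalogs. The numbered scripts under
`analysis/` re-run the full workflow (simulate → parse → census → abundance
→ regression) and write their tables under `results/`;
`scripts/acceptance.R` recomputes the headline quantities from scratch into
a flat JSON file.

## Known limitations

The signal-cleavage heuristic is deliberately simple and should not be
used as a predictor on real proteomes. Strict-mode segmentation cannot
recover architectures whose true motifs are degenerate (no Glu or Asp);
permissive mode recovers some at the cost of ambiguity, reported through
`n_optima`. Two-chain peptides are only flagged via `cys_count`; disulfide
connectivity, peptide family nomenclature, secondary-structure prediction
and read quantification are out of scope, as are BLAST searches and
assembly.
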