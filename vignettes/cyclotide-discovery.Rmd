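---
title: "Mass-spectrometric characterization of cyclic cystine-knot peptides with cycloMS"
author: "cycloMS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-spectrometric characterization of cyclic cystine-knot peptides with cycloMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloMS)
```

## The problem

Cyclotides are plant defence peptides of ~28–37 residues whose backbone is
head-to-tail cyclic and whose six cysteines form three disulfide bonds in a
knotted arrangement (the cyclic cystine knot, CCK: CysI–CysIV and CysII–CysV
thread a macrocycle closed by CysIII–CysVI). They have no free termini, so
Edman degradation and standard database proteomics do not apply; their
characterization is a chain of mass-spectrometric inferences. `cycloMS`
implements that chain as composable, tested functions, together with seeded
synthetic-data generators so that each inference can be validated against
known ground truth without instrument data.

## The mass model

All arithmetic rests on a residue-mass table (20 standard amino acids,
monoisotopic and average scales) and a modification registry. The neutral
mass of a species is

$$M = \sum_i m_{r_i} \;+\; w\,[\text{linear}] \;+\; \sum_j \delta_j \;-\;
2.015650\,n_{SS}$$

with $w = 18.010565$ Da the terminal water a head-to-tail cycle lacks,
$\delta_j$ the modification deltas (carbamidomethyl $+57.021464$, amidation
$-0.984016$, ring-opening hydration $+18.010565$) and $n_{SS}$ the disulfide
count (each bond removes two hydrogens). Adducted ions follow
$m/z = (M + z\,m_c)/z$ with proton $1.007276$ and sodium $22.989218$ Da.
These constants are stored to six decimals; they are standard physical
values, not fitted quantities.

Three consequences of the model are the workflow's diagnostics:

1. **Cysteine counting.** Reduction adds one hydrogen per half-cystine and
   alkylation adds one carbamidomethyl group, so the observed shift divided
   by $58.029289$ Da estimates the cysteine count; the residual to the
   nearest integer multiple is a quality measure (`inferCysCount`).
2. **Cyclicity.** A single endoproteolytic cut of a cyclic backbone yields
   *one* product *heavier* than its parent by one water; a linear peptide
   cut internally yields *two* products, each lighter (`inferCyclic`).
3. **Dereplication.** Candidate sequences (e.g. transcriptome-derived
   mature domains) are confirmed by matching their predicted cyclic,
   fully oxidized $[M+H]^+$ against observed MS1 signals (`dereplicate`).

## Digestion of cyclic backbones

`digestPeptide` treats a cyclic peptide as a ring of bonds: a cleavage rule
(residue set cleaved after, optional blocking residue before, e.g. trypsin
K/R unless before P) marks sites anywhere on the ring, including between the
last and first stored residue. Products are arcs between ordered site pairs;
coordinates are 1-based on the stored rotation and wrap-around arcs are
written start > end (26–7). Each product is a linear peptide — it gains the
terminal water — and inherits the parent's per-site modifications inside its
arc. Missed cleavages are counted as uncut internal sites; the default bound
is unlimited, because partial time-course digests of knotted substrates
accumulate high-missed-cleavage fragments, and a bound of 2 is conventional
for prospective complete digests.

Two conventions deserve explanation:

- **Chymotrypsin default** cleaves after F/Y/W/L/M with *no* proline block.
  The broad specificity is deliberate: partial chymotryptic digests of
  knotted peptides show cleavage after Leu even before Pro (the PTCF-type
  fragment requires a Leu–Pro cut), which the classic strict rule would
  forbid. A strict F/Y/W, P-blocked variant ships as
  `chymotrypsin_strict`.
- **GluC defaults to Glu-only** specificity (its behaviour in ammonium
  bicarbonate buffers); a Glu+Asp variant ships as `gluc_de`.

Complete digests satisfy two checked invariants: the 0-missed products tile
the ring exactly once, and their mass sum minus one water per cut equals the
parent's cyclic mass.

## MS/MS annotation

Only singly protonated b/y ions are modelled, the dominant series in MALDI
post-source-decay/LIFT spectra; a/x ions and neutral losses are out of
scope. The complementarity identity $b_i + y_{n-i} = [M+H]^+ + m_p$ is
enforced to $10^{-6}$ Da in tests. `annotateSpectrum` performs greedy
nearest matching within a tolerance (default ±0.3 Da, typical for
MALDI-TOF/TOF fragments): candidate (ion, peak) pairs are ranked by absolute
error with ties to the lower ion index, and accepted while both the ion and,
within its series, the peak are unused. The package deliberately does *not*
enumerate candidate sequences de novo: it scores candidate sequences against
spectra, which is how manual de novo annotations are validated, and flags
positions indistinguishable by mass (`isobaricFlags`: Ile/Leu always,
Lys/Gln only above their 0.0364 Da difference) as needing orthogonal
evidence such as a differential digest.

## Precursor mining

`scanPrecursors` six-frame translates contigs (standard genetic code, stops
as `*`, fuzzy codons as `X`), splits frames into stop-free ORF segments of
at least 20 residues, and locally aligns query mature sequences against each
segment. The aligner is Smith–Waterman via `Biostrings::pairwiseAlignment`
with a flat +2/−1 identity matrix and gap open/extend −5/−1 — an internal
replacement for an external tblastn step with the same discovery semantics
at package scale. The default `minScore = 30` demands roughly 15 identities,
far above random-alignment scores for 20–40-mer queries.

Mature domains are then extracted by *configurable* processing rules
(`processingRules()`), defaulting to the classic cyclotide
asparaginyl-endopeptidase convention: the domain starts with Gly immediately
after the propeptide, ends with Asn/Asp followed by a small residue
(G/A/S/L) opening the C-terminal tail, spans 25–40 residues and contains
exactly six cysteines. These defaults are a field convention, not a
property of all precursors, which is why they are configuration. Among
qualifying spans the one overlapping the alignment hit most (ties: start
closest to the hit start) is chosen. A crude ER-signal heuristic (≥8
hydrophobic residues in the first 25) is reported as a flag and clearly
labelled heuristic. Predicted masses assume a cyclic, fully oxidized
product.

## Loop analysis

The canonical rotation of a cyclic sequence starts at the Gly following an
Asn/Asp–Gly junction (the AEP cyclization scar) when one exists, otherwise
at the lexicographically smallest rotation; the choice is deterministic and
idempotent, and all downstream decompositions are rotation-invariant.
`decomposeLoops` numbers the cysteines I–VI on that rotation and returns the
six intercysteine loops (loop 6 wraps across the junction). Loop-wise
comparison against a reference set uses exact string matching per loop —
whether published loop comparisons used exact matching or per-loop alignment
is generally unstated, so the simplest reproducible convention was chosen
and is documented here. `globalAlign` provides Needleman–Wunsch statistics
(BLOSUM62, gap open 10 / extend 0.5, EMBOSS-Stretcher-like defaults);
percent identity counts identical aligned pairs over alignment length, and
similarity additionally counts positive-scoring pairs. Web-tool percentages
from unstated parameter sets are not reproduced numerically; the package
guarantees only the definitional ordering identity ≤ similarity.

## Assay fitting

Initial velocities are the slope of the first recorded interval
($v = (F_{t_2}-F_{t_1})/(t_2-t_1)$, three-minute plate intervals typical),
after optional background subtraction; discarding a lag read is a flag,
default off. Percent inhibition is $100 - v_i/v_0 \times 100$. IC50s come
from the four-parameter logistic constrained to bottom 0 / top 100,

$$y = \frac{100}{1 + 10^{(\log_{10} c - \log_{10} IC_{50})\,h}},$$

fitted by Levenberg–Marquardt (`minpack.lm::nlsLM`) on
$(\log_{10} IC_{50}, h)$ with start values at the concentration nearest 50 %
remaining and $h = 1$; standard errors on the linear scale use the delta
method, and non-convergence is reported as a flagged fit with the optimizer
message — never a silent fallback. Elimination time-courses are fitted with
one-phase decay $y = 100\,e^{-kt}$ (plateau fixed at zero) and half-life
$\ln 2 / k$; a series that increases overall is rejected as not a decay.
`rankExtracts` orders extracts by IC50 and reports the Spearman correlation
between peptide-signal count and IC50 (more peptides with lower IC50 gives
$\rho = -1$).

## What the synthetic generators emulate — and what they do not

The generators define the package's study conditions:

- `genCyclotide` draws loop lengths uniformly from per-loop ranges
  (defaults 2–4/3–5/3–5/1–2/4–6/6–8) bracketing the 3/4/4/1/5/7 pattern of
  psysol 3 and keeping total length within 25–40; sequences are built in
  canonical rotation with a single Asn/Asp–Gly junction (rejection-sampled)
  and knot connectivity recorded as ground truth.
- `genMS1` places peaks at theoretical $[M+H]^+$ with Gaussian error,
  optional sodium satellites and uniform noise peaks in the 2000–4000
  window; `genMSMS` drops b/y ions independently at a configured rate.
- `genTranscripts` reverse-translates an oak1-style precursor (Met +
  hydrophobic signal stretch, 20-residue pro-region, mature domain,
  small-residue tail) with uniformly random synonymous codons and embeds it
  at a random frame and strand between stop-free random-codon flanks.
- `genAssay`/`genDecay` produce linear kinetic traces whose slopes follow
  the 4PL curve, and exponential time-courses; published potency and
  half-life scales (an IC50 of 1.35 on the micromolar scale, 42.7 on the
  µg/mL extract scale; half-lives of 6.7 and 23.4 h) are used as *generator
  settings* whose recovery is tested — they are not reproduction targets,
  since raw plate data are not available.

Not emulated: isotope envelopes (peak lists are assumed
monoisotopic-picked; deisotoping is out of scope), ionization efficiency
and chromatographic behaviour, enzyme kinetics of partial digests (time
courses are represented only through the missed-cleavage bound), sequencing
errors or polymorphism in contigs, and multiply charged ESI fragment
spectra. Passing recovery tests therefore demonstrates the correctness of
the inference arithmetic under clean, known-truth conditions — not
robustness to every artefact of real instrument data.

## Numerical choices and degenerate inputs

- MS1 match tolerance defaults to ±0.25 Da: printed MALDI values of intact
  peptides deviate from theory by up to ~0.2 Da in this mass range. MS/MS
  tolerance defaults to ±0.3 Da. Both are configurable everywhere they
  appear; comparisons use full precision internally and print to four
  decimals.
- The cysteine-count step is $58.029289 = 57.021464 + 1.007825$ Da exactly.
- A cyclic peptide with no cleavage sites digests to the empty set (the
  intact ring is not a digest product); an empty spectrum annotates to zero
  coverage rather than erroring; an empty reference set makes every loop
  "unique".
- Greedy MS/MS matching breaks ties toward smaller absolute error, then
  lower ion index; the assignment is one-to-one per series, so coverage
  never exceeds 1.
- Disulfide "all" pairing uses knot order (first three cysteines to last
  three); reduction removes bonds from the end of the list. Mass is
  unaffected by pairing order.
- All generators are deterministic under a fixed seed, and the test suite
  runs every stochastic check under fixed seeds at desk scale (50 planted
  contigs, hundreds of random peptides, 100-replicate fit recoveries).

## Known limitations

Disulfide *connectivity* is annotated by convention, never inferred from
data — distinguishing knotted from laddered isomers requires orthogonal
chemistry. The aligner-based precursor scan is meant for package-scale
mining, not for screening millions of contigs. Average-mass calibration of
MALDI spectra is not modelled. MGF and two-column TSV are the only spectrum
formats (no mzML). De novo sequence enumeration from spectra is explicitly
out of scope; the package validates candidate sequences against spectra.
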