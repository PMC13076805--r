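# cycloMS

Mass-spectrometric discovery workflow for cyclic cystine-knot peptides
(cyclotides) in R.

Cyclotides are ~28–37-residue plant peptides with a head-to-tail cyclic
backbone and three disulfide bonds in a knotted arrangement (CysI–CysIV and
CysII–CysV thread a ring closed by CysIII–CysVI). Because the backbone has
no termini, their characterization rests almost entirely on mass arithmetic:
a cyclic peptide weighs one water (18.010565 Da) less than its linear
counterpart, reduction and iodoacetamide alkylation shift the mass by
58.029289 Da per cysteine (+1.007825 reduction, +57.021464
carbamidomethylation), and a single endoproteolytic cut of a cyclic backbone
produces **one** product that is heavier than its parent by one water — the
diagnostic ring-opening signature that distinguishes cyclic from linear
peptides. `cycloMS` implements this arithmetic and everything the discovery
workflow around it needs:

- **Mass arithmetic** for linear and cyclic species with disulfides and
  chemical modifications (`PeptideSpecies`, `peptideMass`, `ionMz`,
  `modificationDelta`, `applyProtocol`);
- **In-silico proteolysis** of cyclic and linear backbones with
  missed-cleavage enumeration and wrap-around arc coordinates
  (`cleavageSites`, `digestPeptide`);
- **MS/MS support**: singly charged b/y ion series, greedy spectrum
  annotation with coverage statistics, isobaric-residue flags
  (`ionSeries`, `annotateSpectrum`, `isobaricFlags`);
- **Cystine-knot inference** from observed mass ladders: cysteine counting,
  cyclicity classification, MS1 fingerprinting, and dereplication of
  candidate masses against peak lists (`inferCysCount`, `inferCyclic`,
  `ms1Fingerprint`, `dereplicate`);
- **Precursor mining**: six-frame translation of transcript contigs, local
  alignment against known mature sequences, and rule-based extraction of
  mature domains with predicted cyclic masses (`sixFrameTranslate`,
  `scanPrecursors`, `extractMature`, `detectionTable`);
- **Loop analysis**: canonical rotation, intercysteine-loop decomposition,
  loop-wise comparison, global alignment statistics (`canonicalRotation`,
  `decomposeLoops`, `loopUniqueness`, `globalAlign`);
- **Assay fitting**: kinetic velocities, percent inhibition, constrained
  four-parameter logistic IC50 (bottom 0, top 100), one-phase decay
  half-lives, extract ranking (`fit4PL`, `fitDecay`, `rankExtracts`);
- **Seeded synthetic-data generators** with ground truth for every input
  class (`genCyclotide`, `genMS1`, `genMSMS`, `genTranscripts`, `genAssay`,
  `genDecay`), so the whole pipeline is testable without instrument data.

Audience: peptide chemists and natural-product researchers characterizing
cyclic, disulfide-rich peptides by MALDI-TOF/ESI mass spectrometry, and
bioinformaticians mining transcriptomes for cyclotide precursor genes.

## Worked example: psysol 3

The package ships its worked example, psysol 3 — a prolyl-oligopeptidase
inhibitor from *Psychotria solitudinum* with sequence
cyclo-GLPTCFETCILGTCYTPGCSCSTYRLCLNN and three knotted disulfides:

```r
library(cycloMS)
p3 <- psysol3()
ionMz(peptideMass(p3), "H", 1)
#> [1] 3209.333                      # native [M+H]+ (observed: 3209.2)

# reduction of 3 disulfides + alkylation of 6 Cys
modificationDelta(p3, reductionAlkylation(3, 6))
#> [1] 348.1757                      # the +348.2 Da six-cysteine signature

alk <- applyProtocol(p3, reductionAlkylation(3, 6))
digestPeptide(alk, enzymeRule("trypsin"))[, c("sequence", "n_missed", "mh")]
#>                         sequence n_missed       mh
#> 1 LCLNNGLPTCFETCILGTCYTPGCSCSTYR        0 3575.519
# one product, +18.011 vs the alkylated ring: the backbone is cyclic

digestPeptide(alk, list(enzymeRule("gluc"), enzymeRule("trypsin")),
              maxMissed = 0)[, c("start", "end", "sequence", "mh", "mna")]
#>   start end           sequence       mh      mna
#> 1     8  25 TCILGTCYTPGCSCSTYR 2156.887 2178.869
#> 2    26   7       LCLNNGLPTCFE 1437.650 1459.632

decomposeLoops(p3)$loops
#>     loop1     loop2     loop3     loop4     loop5     loop6
#>     "FET"    "ILGT"    "YTPG"       "S"   "STYRL" "LNNGLPT"
```

The digest m/z values sit within 0.2 Da of the observed MALDI signals
(3575.5, 2156.8 and the 1459.5/1459.8 sodium adduct), and the inference
utilities turn the observed ladder into a verdict:

```r
inferCysCount(psysol3Ladder())
#> $n_cys [1] 6        $residual [1] 0.024
inferCyclic(psysol3Ladder(), nProducts = 1)
#> [1] TRUE  (single product, +18.0 Da vs alkylated: ring opening)
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/cycloms-cli.R` (subcommands `mass`, `digest`, `annotate`,
`cck`, `mine`, `dereplicate`, `loops`, `fit-ic50`, `fit-decay`, `simulate`,
`run`).

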