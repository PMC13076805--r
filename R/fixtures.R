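## The worked example the package ships: psysol 3, a 30-residue
## head-to-tail cyclic cystine-knot peptide from Psychotria solitudinum,
## with its full reduction/alkylation/digestion mass ladder.

#' The psysol 3 peptide
#'
#' cyclo-GLPTCFETCILGTCYTPGCSCSTYRLCLNN with three disulfide bonds in the
#' cyclic-cystine-knot connectivity (CysI-CysIV, CysII-CysV, CysIII-CysVI)
#' — the package's worked example.  The native monoisotopic [M+H]+ is
#' 3209.33.
#'
#' @return A cyclic \code{PeptideSpecies}.
#' @examples
#' ionMz(peptideMass(psysol3()), "H", 1)
#' @export
psysol3 <- function() {
  PeptideSpecies("GLPTCFETCILGTCYTPGCSCSTYRLCLNN", "cyclic",
                 disulfides = "all")
}

#' Human oxytocin
#'
#' The nonapeptide CYIQNCPLG with a Cys1-Cys6 disulfide and a C-terminal
#' amide — the substrate of the prolyl-oligopeptidase protection assay.
#' Its monoisotopic [M+2H]2+ is 504.23.
#'
#' @return A linear \code{PeptideSpecies}.
#' @export
oxytocin <- function() {
  PeptideSpecies("CYIQNCPLG", "linear", disulfides = list(c(1L, 6L)),
                 modifications = data.frame(name = "amidation",
                                            site = NA_integer_))
}

#' The observed psysol 3 MALDI mass ladder
#'
#' The printed [M+H]+ signals of psysol 3 and its derivatives: native
#' 3209.2, reduced 3215.3, S-alkylated 3557.4, GluC ring-opened 3575.4 —
#' the inputs of the cysteine-count and cyclicity inference.
#'
#' @return A \code{modificationLadder}.
#' @export
psysol3Ladder <- function() {
  modificationLadder(native = 3209.2, alkylated = 3557.4,
                     reduced = 3215.3, enzyme_opened = 3575.4)
}
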