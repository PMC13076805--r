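## Physical constants used throughout the package.  Residue and modification
## tables are shipped as TSV under inst/extdata and loaded lazily (see
## residueMassTable(), modificationRegistry()); the constants here are the
## ones every mass expression needs.

#' Mass constants
#'
#' Monoisotopic masses (Da) of the chemical species that recur in peptide
#' mass arithmetic: water (gained by a linear backbone, or on enzymatic ring
#' opening of a cyclic one), the proton charge carrier, the sodium cation,
#' the hydrogen atom (two of which are lost per disulfide bond), and the
#' combined per-cysteine step of reduction plus carbamidomethylation used
#' for cysteine counting.
#'
#' @format Named numeric vector.
#' @export
MASS_CONST <- c(
  water     = 18.010565,
  proton    = 1.007276,
  sodium    = 22.989218,
  hydrogen  = 1.007825,
  # reduction (+1 H per half-cystine) + carbamidomethyl (+57.021464)
  cys_step  = 58.029289
)

# average-mass counterparts where they differ enough to matter
MASS_CONST_AVG <- c(water = 18.01528, proton = 1.00728, sodium = 22.98922,
                    hydrogen = 1.00794)

.pkg_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "cycloMS")
  if (!nzchar(path)) stop("shipped data file not found: ", file)
  path
}
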