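## Inference of cysteine count and backbone cyclicity from chemical
## mass-shift ladders, MS1 fingerprinting, and dereplication of candidate
## sequences against observed peak lists.

#' A reduction/alkylation/ring-opening mass ladder
#'
#' Observed [M+H]+ values of the native species and its chemical
#' derivatives: after disulfide reduction (optional), after cysteine
#' alkylation, and after single-site endoproteolysis of the alkylated
#' species.
#'
#' @param native,alkylated observed [M+H]+ (Da); both required for cysteine
#'   counting.
#' @param reduced,enzyme_opened optional observed [M+H]+ values.
#' @return A named list of class \code{"modificationLadder"}.
#' @export
modificationLadder <- function(native, alkylated, reduced = NA_real_,
                               enzyme_opened = NA_real_) {
  stopifnot(native > 0, alkylated > 0)
  if (alkylated < native)
    stop("alkylated m/z below native: reduction/alkylation adds mass")
  structure(list(native = native, reduced = reduced, alkylated = alkylated,
                 enzyme_opened = enzyme_opened),
            class = "modificationLadder")
}

#' Infer the cysteine count from a reduction/alkylation shift
#'
#' Reduction opens each disulfide (+1.007825 Da per cysteine) and
#' iodoacetamide alkylation caps each thiol (+57.021464 Da), so the total
#' shift is 58.029289 Da per cysteine.  The estimate is the nearest integer
#' multiple; the residual is the distance to it.
#'
#' @param ladder a \code{modificationLadder} with native and alkylated
#'   values.
#' @return List with \code{n_cys} (integer estimate) and \code{residual}
#'   (Da).
#' @examples
#' inferCysCount(modificationLadder(3209.3, 3557.5))  # 6 cysteines
#' @export
inferCysCount <- function(ladder) {
  delta <- ladder$alkylated - ladder$native
  if (delta < 0) stop("negative reduction/alkylation shift")
  step <- MASS_CONST[["cys_step"]]
  n <- round(delta / step)
  list(n_cys = as.integer(n), residual = abs(delta - n * step))
}

#' Infer backbone cyclicity from a single-site ring-opening digest
#'
#' A head-to-tail cyclic peptide cut at exactly one site stays in one piece
#' and gains one water (+18.011 Da): observing a single product whose mass
#' exceeds the alkylated species by that shift is the diagnostic signature
#' of a cyclic backbone.  A linear peptide cut internally yields two
#' products, each lighter than the parent.
#'
#' @param ladder a \code{modificationLadder} with alkylated and
#'   enzyme_opened values.
#' @param nProducts number of products observed after the single-site
#'   digestion.
#' @param tol mass tolerance (Da) on the +water shift.
#' @return Logical: evidence for a cyclic backbone.  The decision rationale
#'   is attached as attribute \code{"rationale"}.
#' @export
inferCyclic <- function(ladder, nProducts, tol = 0.25) {
  if (is.na(ladder$enzyme_opened))
    stop("ladder lacks the enzyme-opened mass")
  shift <- ladder$enzyme_opened - ladder$alkylated
  ok <- nProducts == 1L && abs(shift - MASS_CONST[["water"]]) <= tol
  rationale <- if (ok)
    sprintf("single product, +%.3f Da vs alkylated (water gain): ring opening",
            shift)
  else if (nProducts != 1L)
    sprintf("%d products after a single-site digest: linear backbone",
            nProducts)
  else
    sprintf("single product but shift %.3f Da is not a water gain", shift)
  structure(ok, rationale = rationale)
}

#' Count MS1 signals in the cyclotide mass window
#'
#' Cysteine-rich peptide natural products cluster in the m/z 2000-4000
#' window of MALDI MS1 fingerprints; the count of distinct signals there is
#' a crude peptide-richness measure used to rank extracts.
#'
#' @param peaks data.frame with columns mz, intensity (a peak list).
#' @param window numeric length-2 inclusive m/z window.
#' @param minIntensity intensity threshold (default 0: all peaks).
#' @return List with \code{count} and \code{peaks} (the in-window subset).
#' @export
ms1Fingerprint <- function(peaks, window = c(2000, 4000), minIntensity = 0) {
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  sel <- peaks$mz >= window[1] & peaks$mz <= window[2] &
    peaks$intensity >= minIntensity
  sub <- peaks[sel, , drop = FALSE]
  list(count = sum(!duplicated(sub$mz)), peaks = sub)
}

.candidateMz <- function(candidates) {
  # accepts PeptideSpecies list or character sequences; sequences are
  # assumed cyclic and fully oxidized (all Cys paired)
  if (is.character(candidates))
    candidates <- lapply(candidates, function(s) {
      n_cys <- sum(strsplit(s, "")[[1]] == "C")
      if (n_cys %% 2L != 0L)
        stop("odd cysteine count in '", s, "': cannot assume full oxidation")
      PeptideSpecies(s, "cyclic", disulfides = "all")
    })
  vapply(candidates, function(p) ionMz(peptideMass(p), "H", 1L), numeric(1))
}

#' Dereplicate candidate peptides against an MS1 peak list
#'
#' Marks each candidate detected ("y") if any observed peak lies within
#' \code{tol} of its theoretical [M+H]+.  Character sequences are treated
#' as head-to-tail cyclic and fully oxidized (all cysteines paired — three
#' disulfides for a 6-Cys cyclotide), matching native-extract measurements.
#'
#' @param candidates list of \code{PeptideSpecies}, or character vector of
#'   sequences.
#' @param peaks data.frame(mz, intensity).
#' @param tol match tolerance in Da (default 0.25, MALDI MS1 scale).
#' @return Detection table: data.frame(sequence, mz_theoretical, matched_mz,
#'   error, detected) with detected in {"y","n"}.
#' @export
dereplicate <- function(candidates, peaks, tol = 0.25) {
  stopifnot(tol > 0)
  seqs <- if (is.character(candidates)) candidates
          else vapply(candidates, pepSequence, character(1))
  mz <- .candidateMz(candidates)
  matched <- vapply(mz, function(m) {
    d <- abs(peaks$mz - m)
    if (length(d) && min(d) <= tol) peaks$mz[which.min(d)] else NA_real_
  }, numeric(1))
  data.frame(sequence = seqs,
             mz_theoretical = mz,
             matched_mz = matched,
             error = matched - mz,
             detected = ifelse(is.na(matched), "n", "y"),
             stringsAsFactors = FALSE)
}
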