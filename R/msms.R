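## b/y fragment-ion series, spectrum annotation, isobaric-residue flags.
## Only singly protonated b and y ions are modelled: MALDI post-source
## decay produces predominantly singly charged fragments.

.siteMassVector <- function(p, scale = "monoisotopic") {
  res <- strsplit(p@sequence, "")[[1]]
  m <- .residueMasses(scale)[res]
  mods <- p@modifications
  persite <- mods[!is.na(mods$site), , drop = FALSE]
  if (nrow(persite))
    for (i in seq_len(nrow(persite)))
      m[persite$site[i]] <- m[persite$site[i]] +
        .modDelta(persite$name[i], scale)
  unname(m)
}

#' Theoretical b/y ion series of a linear peptide
#'
#' b_i is the first i residues (with their modifications) plus a proton;
#' y_j is the last j residues plus water and a proton.  The complementarity
#' identity b_i + y_(n-i) = [M+H]+ + 1.007276 holds for every i.
#'
#' @param p a linear \code{PeptideSpecies} (ring-open a cyclic species
#'   first).
#' @return data.frame with columns series ("b"/"y"), index (1..n-1), mz
#'   (singly protonated), sequence (composing residues).
#' @examples
#' ionSeries(PeptideSpecies("ETCIL", modifications = "cam"))
#' @export
ionSeries <- function(p) {
  stopifnot(is(p, "PeptideSpecies"))
  if (p@topology != "linear")
    stop("ion series are defined for linear peptides; ring-open the ",
         "cyclic species first")
  res <- strsplit(p@sequence, "")[[1]]
  n <- length(res)
  if (n < 2L) stop("need at least two residues for a fragment series")
  m <- .siteMassVector(p)
  pr <- MASS_CONST[["proton"]]; wat <- MASS_CONST[["water"]]
  idx <- seq_len(n - 1L)
  b <- cumsum(m)[idx] + pr
  y <- cumsum(rev(m))[idx] + wat + pr   # y_j = sum of last j residues
  rbind(
    data.frame(series = "b", index = idx, mz = b,
               sequence = vapply(idx, function(i)
                 paste(res[1:i], collapse = ""), character(1))),
    data.frame(series = "y", index = idx,
               mz = y,
               sequence = vapply(idx, function(j)
                 paste(res[(n - j + 1L):n], collapse = ""), character(1)))
  )
}

#' Annotate an observed MS/MS spectrum with a candidate sequence
#'
#' Matches the candidate's theoretical b/y ions to observed peaks by greedy
#' nearest assignment within a mass tolerance: candidate (ion, peak) pairs
#' are ranked by absolute error (ties toward the lower ion index) and
#' accepted while both the ion and, within its series, the peak are still
#' free.  Coverage is the matched ion count over n-1 per series.
#'
#' @param spectrum a \code{Spectrum} (an empty peak list gives a
#'   zero-coverage annotation, not an error).
#' @param candidate a linear \code{PeptideSpecies}.
#' @param tol match tolerance in Da (default 0.3, typical for MALDI-TOF/TOF
#'   fragment spectra).
#' @return List with elements \code{matches} (data.frame: series, index,
#'   mz_theoretical, mz_observed, error, peak), \code{b_coverage},
#'   \code{y_coverage}, \code{n_residues}.
#' @export
annotateSpectrum <- function(spectrum, candidate, tol = 0.3) {
  stopifnot(is(spectrum, "Spectrum"), tol > 0)
  ions <- ionSeries(candidate)
  pk <- spectrum@peaks
  n <- nchar(candidate@sequence)
  matches <- data.frame(series = character(0), index = integer(0),
                        mz_theoretical = numeric(0), mz_observed = numeric(0),
                        error = numeric(0), peak = integer(0))
  if (nrow(pk)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(ions)), function(i) {
      err <- pk$mz - ions$mz[i]
      hit <- which(abs(err) <= tol)
      if (!length(hit)) return(NULL)
      data.frame(ion = i, peak = hit, error = err[hit])
    }))
    if (!is.null(cand)) {
      cand <- cand[order(abs(cand$error), ions$index[cand$ion]), , drop = FALSE]
      used_ion <- logical(nrow(ions))
      used_peak <- list(b = logical(nrow(pk)), y = logical(nrow(pk)))
      keep <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        i <- cand$ion[r]; s <- ions$series[i]; pkx <- cand$peak[r]
        if (!used_ion[i] && !used_peak[[s]][pkx]) {
          used_ion[i] <- TRUE; used_peak[[s]][pkx] <- TRUE; keep[r] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      matches <- data.frame(series = ions$series[cand$ion],
                            index = ions$index[cand$ion],
                            mz_theoretical = ions$mz[cand$ion],
                            mz_observed = pk$mz[cand$peak],
                            error = cand$error, peak = cand$peak)
      matches <- matches[order(matches$series, matches$index), , drop = FALSE]
      rownames(matches) <- NULL
    }
  }
  list(matches = matches,
       b_coverage = sum(matches$series == "b") / (n - 1L),
       y_coverage = sum(matches$series == "y") / (n - 1L),
       n_residues = n)
}

#' Flag residues indistinguishable by mass
#'
#' For every position, lists other standard residues whose substitution
#' changes the peptide mass by less than \code{tol} Da.  Ile/Leu are exact
#' isobars and are always flagged; Lys/Gln differ by 0.036385 Da and are
#' flagged only at tolerances above that.
#'
#' @param candidate a \code{PeptideSpecies}.
#' @param tol mass tolerance in Da (>= 0).
#' @return data.frame with columns position, residue, alternatives
#'   (collapsed string of indistinguishable residues); positions without
#'   alternatives are omitted.
#' @export
isobaricFlags <- function(candidate, tol = 0.3) {
  stopifnot(is(candidate, "PeptideSpecies"), tol >= 0)
  res <- strsplit(candidate@sequence, "")[[1]]
  masses <- .residueMasses("monoisotopic")
  out <- lapply(seq_along(res), function(i) {
    d <- abs(masses - masses[[res[i]]])
    alt <- names(masses)[(d < tol | d < 1e-9) & names(masses) != res[i]]
    if (!length(alt)) return(NULL)
    data.frame(position = i, residue = res[i],
               alternatives = paste(sort(alt), collapse = "/"))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(position = integer(0), residue = character(0),
                      alternatives = character(0))
  out
}

#' Write a spectrum annotation report as TSV
#'
#' @param annotation result of \code{annotateSpectrum}.
#' @param path output file.
#' @return Invisibly, the formatted table.
#' @export
writeAnnotationReport <- function(annotation, path) {
  m <- annotation$matches
  out <- data.frame(ion = paste0(m$series, m$index),
                    mz_theoretical = sprintf("%.4f", m$mz_theoretical),
                    mz_observed = sprintf("%.4f", m$mz_observed),
                    error = sprintf("%.4f", m$error))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
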