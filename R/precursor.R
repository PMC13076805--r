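## Cyclotide precursor mining: six-frame translation of transcript contigs,
## local-alignment ORF scanning against known mature sequences, and
## extraction of mature-peptide candidates with predicted cyclic masses.

#' Six-frame translation of a nucleotide contig
#'
#' Translates frames +1..+3 of the contig and -1..-3 of its reverse
#' complement under the standard genetic code.  Stop codons are rendered as
#' \code{"*"}; codons containing N translate to \code{"X"}.
#'
#' @param contig nucleotide string (ACGTN) or \code{DNAString}.
#' @return Named character vector of six translations ("+1".."-3"); frame
#'   -1 of S equals frame +1 of revcomp(S).
#' @examples
#' sixFrameTranslate("ATGGGA")[["+1"]]  # "MG"
#' @export
sixFrameTranslate <- function(contig) {
  s <- toupper(as.character(contig))
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0)
    stop("invalid nucleotide '", substr(s, bad, bad), "' at position ", bad)
  fwd <- Biostrings::DNAString(s)
  rev <- Biostrings::reverseComplement(fwd)
  tr1 <- function(x, off) {
    n <- length(x) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, off + 1L, off + n),
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
  }
  out <- c(vapply(0:2, function(o) tr1(fwd, o), character(1)),
           vapply(0:2, function(o) tr1(rev, o), character(1)))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

.orfSegments <- function(protein, min_len = 20L) {
  # maximal stop-free segments of a translated frame with protein coords
  if (!nzchar(protein)) return(NULL)
  parts <- strsplit(protein, "*", fixed = TRUE)[[1]]
  starts <- cumsum(c(1L, nchar(parts) + 1L))[seq_along(parts)]
  keep <- nchar(parts) >= min_len
  if (!any(keep)) return(NULL)
  data.frame(protein = parts[keep], aa_start = starts[keep],
             aa_end = starts[keep] + nchar(parts[keep]) - 1L,
             stringsAsFactors = FALSE)
}

.aaSubstMatrix <- function(match = 2, mismatch = -1) {
  aa <- unique(c(residueMassTable()$residue, "X"))
  m <- matrix(mismatch, length(aa), length(aa), dimnames = list(aa, aa))
  diag(m) <- match
  m["X", ] <- 0; m[, "X"] <- 0
  m
}

#' Scan contigs for cyclotide precursor genes
#'
#' Six-frame translates each contig, splits frames into stop-free ORF
#' segments, and locally aligns each query mature sequence against each
#' segment (Smith-Waterman via \code{Biostrings::pairwiseAlignment}; match
#' +2, mismatch -1, gap open -5, gap extend -1 by default).  Segments
#' scoring at or above \code{minScore} are reported as precursor hits.
#'
#' @param contigs named character vector or \code{DNAStringSet} of
#'   assembled transcript contigs (>= 60 nt to be scanned).
#' @param queries character vector of mature cyclotide sequences.
#' @param minScore minimum local alignment score (default 30, i.e. at
#'   least ~15 identities for the default scoring).
#' @param match,mismatch,gapOpening,gapExtension alignment parameters
#'   (penalties positive, as in Biostrings).
#' @return data.frame of hits: contig, frame, orf protein sequence, ORF
#'   protein-level span in the frame (aa_start/aa_end), hit span within the
#'   ORF (hit_start/hit_end, 1-based), query, score.  One row per
#'   (contig, ORF) with the best query hit; empty data.frame when nothing
#'   scores.
#' @export
scanPrecursors <- function(contigs, queries, minScore = 30,
                           match = 2, mismatch = -1,
                           gapOpening = 5, gapExtension = 1) {
  if (!length(queries)) stop("queries must be non-empty")
  if (is(contigs, "DNAStringSet")) contigs <- as.character(contigs)
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig", seq_along(contigs))
  sm <- .aaSubstMatrix(match, mismatch)
  out <- list()
  for (id in names(contigs)) {
    if (nchar(contigs[[id]]) < 60L) next
    frames <- sixFrameTranslate(contigs[[id]])
    for (fr in names(frames)) {
      orfs <- .orfSegments(frames[[fr]])
      if (is.null(orfs)) next
      for (k in seq_len(nrow(orfs))) {
        pa <- Biostrings::pairwiseAlignment(
          queries, orfs$protein[k], type = "local",
          substitutionMatrix = sm,
          gapOpening = gapOpening, gapExtension = gapExtension)
        sc <- Biostrings::score(pa)
        best <- NULL
        if (max(sc) >= minScore) {
          w <- which.max(sc)
          best <- list(score = sc[w], query = queries[w],
                       hit_start = Biostrings::start(Biostrings::subject(pa))[w],
                       hit_end = Biostrings::end(Biostrings::subject(pa))[w])
        }
        if (!is.null(best))
          out[[length(out) + 1L]] <- data.frame(
            contig = id, frame = fr, protein = orfs$protein[k],
            aa_start = orfs$aa_start[k], aa_end = orfs$aa_end[k],
            hit_start = best$hit_start, hit_end = best$hit_end,
            query = best$query, score = best$score,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), frame = character(0),
                      protein = character(0), aa_start = integer(0),
                      aa_end = integer(0), hit_start = integer(0),
                      hit_end = integer(0), query = character(0),
                      score = numeric(0)))
  res <- do.call(rbind, out)
  res[order(-res$score), , drop = FALSE]
}

#' Default mature-peptide processing rules
#'
#' The classic cyclotide convention for asparaginyl-endopeptidase
#' processing: the mature domain starts with Gly immediately after the
#' propeptide boundary and ends with Asn or Asp followed by a small residue
#' (G/A/S/L) at the start of the C-terminal tail, spans 25-40 residues and
#' contains exactly six cysteines.  These rules are configuration, not a
#' fixed property of all cyclotides.
#'
#' @return A rules list understood by \code{extractMature}.
#' @export
processingRules <- function() {
  list(start_residue = "G", end_residues = c("N", "D"),
       tail_residues = c("G", "A", "S", "L"),
       length_range = c(25L, 40L), n_cys = 6L)
}

.hasSignalHeuristic <- function(protein) {
  # crude ER-signal heuristic: >= 8 hydrophobic residues among the first 25
  hydro <- c("A", "V", "L", "I", "M", "F", "W", "C")
  head25 <- strsplit(substr(protein, 1, 25), "")[[1]]
  sum(head25 %in% hydro) >= 8L
}

#' Extract the mature cyclotide domain from a precursor hit
#'
#' Within the hit ORF, enumerates spans satisfying the processing rules
#' (start residue, C-terminal residue + following tail residue, length
#' range, cysteine count) and returns the one overlapping the alignment
#' hit best (ties: start closest to the hit start).  The predicted mass
#' assumes a head-to-tail cyclic, fully oxidized product (three disulfides
#' for six cysteines).
#'
#' @param annotation one row of the \code{scanPrecursors} result.
#' @param rules processing rules, see \code{\link{processingRules}}.
#' @return List with \code{sequence}, \code{start}/\code{end} (protein
#'   coords within the ORF), \code{mz} (predicted cyclic oxidized [M+H]+),
#'   \code{has_signal} (heuristic flag), \code{contig}, \code{frame}; or
#'   \code{NULL} with a warning naming the reason when no span qualifies.
#' @export
extractMature <- function(annotation, rules = processingRules()) {
  prot <- annotation$protein
  res <- strsplit(prot, "")[[1]]
  n <- length(res)
  gs <- which(res == rules$start_residue)
  es <- which(res %in% rules$end_residues)
  es <- es[es < n & res[es + 1L] %in% rules$tail_residues]
  cand <- expand.grid(g = gs, e = es)
  cand <- cand[cand$e - cand$g + 1L >= rules$length_range[1] &
               cand$e - cand$g + 1L <= rules$length_range[2], , drop = FALSE]
  if (nrow(cand)) {
    ncys <- vapply(seq_len(nrow(cand)), function(i)
      sum(res[cand$g[i]:cand$e[i]] == "C"), integer(1))
    cand <- cand[ncys == rules$n_cys, , drop = FALSE]
  }
  if (!nrow(cand)) {
    warning("no span satisfies the processing rules in ",
            annotation$contig, " ", annotation$frame)
    return(NULL)
  }
  ov <- pmin(cand$e, annotation$hit_end) -
        pmax(cand$g, annotation$hit_start) + 1L
  cand <- cand[order(-ov, abs(cand$g - annotation$hit_start)), , drop = FALSE]
  g <- cand$g[1]; e <- cand$e[1]
  seqstr <- substr(prot, g, e)
  sp <- PeptideSpecies(seqstr, "cyclic", disulfides = "all")
  list(sequence = seqstr, start = g, end = e,
       mz = ionMz(peptideMass(sp), "H", 1L),
       has_signal = .hasSignalHeuristic(prot),
       contig = annotation$contig, frame = annotation$frame)
}

#' Detection table for mined candidates
#'
#' Dereplicates mined mature-peptide candidates against an MS1 peak list
#' and reports one row per distinct sequence with precursor provenance —
#' the transcriptome-to-mass confirmation table.
#'
#' @param candidates list of \code{extractMature} results (NULLs dropped).
#' @param peaks data.frame(mz, intensity).
#' @param tol MS1 match tolerance (Da).
#' @return data.frame(sequence, contig, frame, mz_theoretical, matched_mz,
#'   error, detected).
#' @export
detectionTable <- function(candidates, peaks, tol = 0.25) {
  candidates <- Filter(Negate(is.null), candidates)
  if (!length(candidates))
    return(data.frame(sequence = character(0), contig = character(0),
                      frame = character(0), mz_theoretical = numeric(0),
                      matched_mz = numeric(0), error = numeric(0),
                      detected = character(0)))
  seqs <- vapply(candidates, `[[`, character(1), "sequence")
  first <- !duplicated(seqs)
  candidates <- candidates[first]
  tab <- dereplicate(vapply(candidates, `[[`, character(1), "sequence"),
                     peaks, tol)
  cbind(tab[, "sequence", drop = FALSE],
        contig = vapply(candidates, `[[`, character(1), "contig"),
        frame = vapply(candidates, `[[`, character(1), "frame"),
        tab[, setdiff(names(tab), "sequence"), drop = FALSE])
}
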