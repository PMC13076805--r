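## Intercysteine-loop analysis: canonical rotation of cyclic sequences,
## loop decomposition, loop-wise comparison against a reference set, and
## global pairwise alignment statistics.

.rotations <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n), function(i)
    paste0(substr(s, i, n), substr(s, 1, i - 1L)), character(1))
}

#' Canonical rotation of a cyclic sequence
#'
#' Cyclotides are cyclized by asparaginyl endopeptidase at an Asn/Asp-Gly
#' junction, so the conventional linear representation starts at the Gly
#' following that junction.  If the cyclic sequence contains one or more
#' Asn/Asp-Gly motifs, the rotation starting at such a Gly is chosen
#' (lexicographically smallest if several); otherwise the lexicographically
#' smallest rotation.  Deterministic and idempotent.
#'
#' @param p a cyclic \code{PeptideSpecies} or a plain sequence string.
#' @return The canonical rotation as a character string.
#' @examples
#' canonicalRotation("CLNNGLPTCFETCILGTCYTPGCSCSTYRL")  # starts "GLPT"
#' @export
canonicalRotation <- function(p) {
  s <- if (is(p, "PeptideSpecies")) {
    if (p@topology != "cyclic") stop("canonical rotation applies to cyclic peptides")
    p@sequence
  } else as.character(p)
  rots <- .rotations(s)
  n <- nchar(s)
  res <- strsplit(s, "")[[1]]
  prev <- res[c(n, seq_len(n - 1L))]
  junction <- which(res == "G" & prev %in% c("N", "D"))
  cand <- if (length(junction)) rots[junction] else rots
  sort(cand)[1]
}

#' Decompose a cyclotide into intercysteine loops
#'
#' Numbers the six cysteines I-VI in cyclic order starting from the
#' canonical rotation and returns the residues between consecutive
#' cysteines: loop k spans Cys k to Cys k+1 and loop 6 wraps from Cys VI
#' back to Cys I across the cyclization junction.  The decomposition is
#' rotation-invariant: any rotation of the input yields the same loops.
#'
#' @param p a cyclic \code{PeptideSpecies} (or sequence string) with
#'   exactly six cysteines.
#' @return List with \code{cys_positions} (on the canonical rotation),
#'   \code{loops} (named character vector loop1..loop6) and
#'   \code{canonical} (the rotation used).
#' @examples
#' decomposeLoops(psysol3())$loops  # loop3 "YTPG", loop5 "STYRL"
#' @export
decomposeLoops <- function(p) {
  s <- canonicalRotation(p)
  res <- strsplit(s, "")[[1]]
  cys <- which(res == "C")
  if (length(cys) != 6L)
    stop("loop decomposition needs exactly 6 cysteines, found ", length(cys))
  n <- length(res)
  loops <- character(6)
  for (k in 1:6) {
    from <- cys[k] + 1L
    to <- if (k < 6L) cys[k + 1L] - 1L else cys[1L] - 1L + n  # wrap VI -> I
    loops[k] <- if (to < from) "" else
      paste(res[((seq(from, to) - 1L) %% n) + 1L], collapse = "")
  }
  names(loops) <- paste0("loop", 1:6)
  list(cys_positions = cys, loops = loops, canonical = s)
}

#' Loop-wise uniqueness against a reference set
#'
#' Counts, for each of the six loops of the query decomposition, how many
#' reference decompositions carry the identical loop string (exact match,
#' same loop position).  A zero count marks the loop as unique within the
#' reference set.
#'
#' @param d query decomposition from \code{decomposeLoops}.
#' @param reference list of decompositions (same convention).
#' @return Named integer vector loop1..loop6 of match counts.
#' @export
loopUniqueness <- function(d, reference) {
  counts <- integer(6)
  names(counts) <- names(d$loops)
  for (k in 1:6)
    counts[k] <- sum(vapply(reference, function(r)
      identical(unname(r$loops[k]), unname(d$loops[k])), logical(1)))
  counts
}

#' Global pairwise alignment statistics
#'
#' Needleman-Wunsch global alignment with affine gaps (default BLOSUM62,
#' gap open 10, gap extend 0.5 — EMBOSS-Stretcher-like).  Percent identity
#' is identical aligned pairs over alignment length (gaps included);
#' percent similarity additionally counts substitution pairs with a
#' positive matrix score, so identity <= similarity always.
#'
#' @param a,b peptide sequences (character).
#' @param substitutionMatrix matrix name or matrix (default "BLOSUM62").
#' @param gapOpening,gapExtension gap penalties (positive).
#' @return List: percent_identity, percent_similarity, length (alignment
#'   columns), gaps (gap columns), score, aligned (two aligned strings).
#' @export
globalAlign <- function(a, b, substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5) {
  stopifnot(nzchar(a), nzchar(b))
  if (is.character(substitutionMatrix)) {
    e <- new.env()
    utils::data(list = substitutionMatrix, package = "Biostrings", envir = e)
    substitutionMatrix <- get(substitutionMatrix, envir = e)
  }
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = substitutionMatrix,
                                      gapOpening = gapOpening,
                                      gapExtension = gapExtension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  len <- length(pat)
  gap <- pat == "-" | sub == "-"
  ident <- sum(!gap & pat == sub)
  simil <- sum(substitutionMatrix[cbind(
    match(pat[!gap], rownames(substitutionMatrix)),
    match(sub[!gap], colnames(substitutionMatrix)))] > 0)
  list(percent_identity = 100 * ident / len,
       percent_similarity = 100 * simil / len,
       length = len, gaps = sum(gap),
       score = Biostrings::score(pa),
       aligned = c(paste(pat, collapse = ""), paste(sub, collapse = "")))
}

#' Position-wise residue counts of an aligned set
#'
#' Column-wise residue counts across equal-length aligned strings — the
#' logo-ready frequency matrix.  Every column's counts sum to the number of
#' sequences.
#'
#' @param aligned character vector of equal-length (aligned) sequences.
#' @return Integer matrix, residues (and "-") x positions.
#' @export
frequencyCounts <- function(aligned) {
  if (!length(aligned)) stop("empty alignment")
  w <- unique(nchar(aligned))
  if (length(w) != 1L)
    stop("aligned sequences must have equal length; found lengths ",
         paste(w, collapse = ", "))
  mat <- do.call(rbind, strsplit(aligned, ""))
  letters_seen <- sort(unique(as.vector(mat)))
  counts <- vapply(seq_len(w), function(j)
    table(factor(mat[, j], levels = letters_seen)), integer(length(letters_seen)))
  rownames(counts) <- letters_seen
  colnames(counts) <- seq_len(w)
  counts
}
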