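#' @import methods
NULL

#' PeptideSpecies: a peptide with topology, disulfides and modifications
#'
#' The unit of all mass arithmetic in the package.  A species is a residue
#' string in N-to-C order (for a cyclic backbone, one chosen rotation), a
#' topology flag, a set of disulfide bonds given as residue-index pairs
#' (1-based on the stored rotation), and a table of chemical modifications,
#' each attached either to a specific residue index or globally to the
#' peptide (site \code{NA}).
#'
#' Validity enforces that disulfide indices point at cysteines, that no
#' cysteine is simultaneously disulfide-bonded and alkylated, and that a
#' head-to-tail cyclic backbone carries no terminal modification (it has no
#' termini).
#'
#' @slot sequence single-letter residue string.
#' @slot topology \code{"linear"} or \code{"cyclic"}.
#' @slot disulfides two-column integer matrix of bonded Cys index pairs.
#' @slot modifications data.frame with columns \code{name} (registry
#'   identifier) and \code{site} (integer residue index, or \code{NA} for a
#'   whole-peptide modification such as C-terminal amidation).
#' @export
setClass("PeptideSpecies",
  representation(sequence = "character", topology = "character",
                 disulfides = "matrix", modifications = "data.frame"),
  prototype(topology = "linear",
            disulfides = matrix(integer(0), ncol = 2L),
            modifications = data.frame(name = character(0),
                                       site = integer(0))))

setValidity("PeptideSpecies", function(object) {
  msg <- character(0)
  seq <- object@sequence
  if (length(seq) != 1L || !nzchar(seq))
    return("sequence must be a single non-empty string")
  res <- strsplit(seq, "")[[1]]
  tab <- residueMassTable()
  bad <- which(!res %in% tab$residue)
  if (length(bad))
    msg <- c(msg, sprintf("unknown residue '%s' at position %d",
                          res[bad[1]], bad[1]))
  if (!object@topology %in% c("linear", "cyclic"))
    msg <- c(msg, "topology must be 'linear' or 'cyclic'")
  ss <- object@disulfides
  if (ncol(ss) != 2L) msg <- c(msg, "disulfides must have two columns")
  idx <- as.integer(ss)
  if (length(idx)) {
    if (any(idx < 1L | idx > length(res)))
      msg <- c(msg, "disulfide index out of range")
    else if (any(res[idx] != "C"))
      msg <- c(msg, "disulfide indices must point at Cys residues")
    if (anyDuplicated(idx))
      msg <- c(msg, "a Cys cannot take part in two disulfide bonds")
  }
  mods <- object@modifications
  if (!all(c("name", "site") %in% names(mods)))
    msg <- c(msg, "modifications needs columns 'name' and 'site'")
  else if (nrow(mods)) {
    reg <- modificationRegistry()
    unknown <- setdiff(mods$name, reg$name)
    if (length(unknown))
      msg <- c(msg, paste0("unknown modification: ", unknown[1]))
    cam <- mods$site[mods$name == "carbamidomethyl"]
    cam <- cam[!is.na(cam)]
    if (length(cam) && any(res[cam] != "C"))
      msg <- c(msg, "carbamidomethyl may only attach to Cys")
    if (any(cam %in% idx))
      msg <- c(msg, "a Cys cannot be both disulfide-bonded and alkylated")
    if (object@topology == "cyclic" && "amidation" %in% mods$name)
      msg <- c(msg, "a cyclic backbone has no terminus to modify")
  }
  if (length(msg)) msg else TRUE
})

#' CleavageRule: endoprotease specificity
#'
#' Cleavage occurs C-terminal to any residue in \code{cleaveAfter} unless the
#' following residue is in \code{blockedBefore}.
#'
#' @slot enzyme name of the protease.
#' @slot cleaveAfter character vector of P1 residues.
#' @slot blockedBefore character vector of blocking P1' residues (may be
#'   empty).
#' @export
setClass("CleavageRule",
  representation(enzyme = "character", cleaveAfter = "character",
                 blockedBefore = "character"),
  prototype(blockedBefore = character(0)))

setValidity("CleavageRule", function(object) {
  if (!length(object@cleaveAfter)) "cleaveAfter must be non-empty" else TRUE
})

#' Spectrum: an observed MS/MS spectrum
#'
#' @slot precursorMz precursor m/z (Da).
#' @slot precursorCharge positive integer charge state.
#' @slot peaks data.frame with columns \code{mz} and \code{intensity}, sorted
#'   by m/z, intensities non-negative.  May be empty.
#' @export
setClass("Spectrum",
  representation(precursorMz = "numeric", precursorCharge = "integer",
                 peaks = "data.frame"),
  prototype(precursorMz = NA_real_, precursorCharge = 1L,
            peaks = data.frame(mz = numeric(0), intensity = numeric(0))))

setValidity("Spectrum", function(object) {
  pk <- object@peaks
  msg <- character(0)
  if (!all(c("mz", "intensity") %in% names(pk)))
    return("peaks needs columns 'mz' and 'intensity'")
  if (nrow(pk)) {
    if (is.unsorted(pk$mz)) msg <- c(msg, "peaks must be sorted by m/z")
    if (any(pk$intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  }
  if (!is.na(object@precursorCharge) && object@precursorCharge < 1L)
    msg <- c(msg, "precursor charge must be >= 1")
  if (length(msg)) msg else TRUE
})

## ---- constructors ---------------------------------------------------------

#' Construct a PeptideSpecies
#'
#' @param sequence residue string (N to C; for cyclic, one chosen rotation).
#' @param topology \code{"linear"} (default) or \code{"cyclic"}.
#' @param disulfides list of length-2 integer vectors, or a two-column
#'   matrix, of bonded Cys positions; \code{"all"} pairs cysteines in the
#'   cystine-knot convention I-IV, II-V, III-VI (requires an even Cys count).
#' @param modifications data.frame(name, site) of modifications; helper
#'   shorthand \code{"cam"} carbamidomethylates every free cysteine.
#' @return A validated \code{PeptideSpecies}.
#' @examples
#' p <- PeptideSpecies("GLPTCFETCILGTCYTPGCSCSTYRLCLNN", "cyclic",
#'                     disulfides = "all")
#' peptideMass(p)
#' @export
PeptideSpecies <- function(sequence, topology = c("linear", "cyclic"),
                           disulfides = list(), modifications = NULL) {
  topology <- match.arg(topology)
  sequence <- toupper(as.character(sequence))
  res <- strsplit(sequence, "")[[1]]
  cys <- which(res == "C")
  if (identical(disulfides, "all")) {
    if (length(cys) %% 2L != 0L)
      stop("'all' disulfides needs an even number of cysteines, found ",
           length(cys))
    h <- length(cys) / 2L
    disulfides <- if (h) cbind(cys[seq_len(h)], cys[h + seq_len(h)])
                  else matrix(integer(0), ncol = 2L)
  } else if (is.list(disulfides)) {
    disulfides <- if (length(disulfides))
      do.call(rbind, lapply(disulfides, function(x) as.integer(x[1:2])))
    else matrix(integer(0), ncol = 2L)
  }
  storage.mode(disulfides) <- "integer"
  if (identical(modifications, "cam")) {
    free <- setdiff(cys, as.integer(disulfides))
    modifications <- data.frame(name = rep("carbamidomethyl", length(free)),
                                site = as.integer(free))
  }
  if (is.null(modifications))
    modifications <- data.frame(name = character(0), site = integer(0))
  modifications$site <- as.integer(modifications$site)
  new("PeptideSpecies", sequence = sequence, topology = topology,
      disulfides = disulfides, modifications = modifications)
}

#' Construct a Spectrum
#' @param mz,intensity numeric peak vectors (reordered by m/z).
#' @param precursorMz,precursorCharge precursor ion description.
#' @return A \code{Spectrum}.
#' @export
Spectrum <- function(mz = numeric(0), intensity = rep(1, length(mz)),
                     precursorMz = NA_real_, precursorCharge = 1L) {
  o <- order(mz)
  new("Spectrum", precursorMz = precursorMz,
      precursorCharge = as.integer(precursorCharge),
      peaks = data.frame(mz = as.numeric(mz)[o],
                         intensity = as.numeric(intensity)[o]))
}

#' Construct a CleavageRule
#'
#' \code{cleavageRule()} builds a rule from residue sets;
#' \code{enzymeRule(name)} loads a named default from the shipped enzyme
#' table (trypsin, gluc, gluc_de, chymotrypsin, chymotrypsin_strict).
#'
#' @param enzyme name of the protease.
#' @param cleaveAfter residues cleaved after (vector or collapsed string).
#' @param blockedBefore residues blocking cleavage when next in sequence.
#' @return A \code{CleavageRule}.
#' @export
cleavageRule <- function(enzyme, cleaveAfter, blockedBefore = character(0)) {
  split1 <- function(x) if (length(x) == 1L && nchar(x) > 1L)
    strsplit(x, "")[[1]] else as.character(x)
  new("CleavageRule", enzyme = enzyme, cleaveAfter = split1(cleaveAfter),
      blockedBefore = split1(blockedBefore))
}

#' @rdname cleavageRule
#' @param name enzyme identifier in the shipped table.
#' @param path optional user enzyme TSV (enzyme, cleave_after,
#'   blocked_before) overriding the shipped one.
#' @export
enzymeRule <- function(name, path = NULL) {
  tab <- utils::read.delim(if (is.null(path)) .extdata("enzymes.tsv") else path,
                           stringsAsFactors = FALSE, na.strings = NULL)
  row <- tab[tab$enzyme == name, , drop = FALSE]
  if (!nrow(row))
    stop("unknown enzyme '", name, "'; available: ",
         paste(tab$enzyme, collapse = ", "))
  cleavageRule(name, row$cleave_after[1],
               if (is.na(row$blocked_before[1]) || !nzchar(row$blocked_before[1]))
                 character(0) else row$blocked_before[1])
}

## ---- show methods ---------------------------------------------------------

setMethod("show", "PeptideSpecies", function(object) {
  cat(sprintf("PeptideSpecies: %s %s (%d aa)\n",
              if (object@topology == "cyclic") "cyclo-" else "",
              object@sequence, nchar(object@sequence)))
  if (nrow(object@disulfides))
    cat("  disulfides:",
        paste(apply(object@disulfides, 1, paste, collapse = "-"),
              collapse = ", "), "\n")
  if (nrow(object@modifications))
    cat("  modifications:",
        paste(object@modifications$name,
              ifelse(is.na(object@modifications$site), "(global)",
                     paste0("@", object@modifications$site)),
              collapse = ", "), "\n")
  cat(sprintf("  monoisotopic M = %.4f Da\n", peptideMass(object)))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d peaks, precursor m/z %.4f (%d+)\n",
              nrow(object@peaks), object@precursorMz,
              object@precursorCharge))
})

setMethod("show", "CleavageRule", function(object) {
  cat(sprintf("CleavageRule '%s': after [%s]%s\n", object@enzyme,
              paste(object@cleaveAfter, collapse = ""),
              if (length(object@blockedBefore))
                paste0(" unless before [",
                       paste(object@blockedBefore, collapse = ""), "]")
              else ""))
})

## ---- accessors ------------------------------------------------------------

#' Accessors for PeptideSpecies and Spectrum
#'
#' @param x a \code{PeptideSpecies} or \code{Spectrum}.
#' @return The slot contents: residue string, topology string, disulfide
#'   matrix, modification data.frame, or peak data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
pepSequence <- function(x) x@sequence
#' @rdname accessors
#' @export
topology <- function(x) x@topology
#' @rdname accessors
#' @export
disulfides <- function(x) x@disulfides
#' @rdname accessors
#' @export
modifications <- function(x) x@modifications
#' @rdname accessors
#' @export
peaks <- function(x) x@peaks
#' @rdname accessors
#' @export
isCyclic <- function(x) x@topology == "cyclic"
#' @rdname accessors
#' @export
nResidues <- function(x) nchar(x@sequence)
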