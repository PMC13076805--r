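## Seeded generators for every input class the pipeline consumes, each
## with known ground truth so recovery can be tested end to end.  All
## generators draw from R's RNG; passing `seed` makes output reproducible.

.AA_NO_CYS <- c("G", "A", "S", "P", "V", "T", "L", "I", "N", "D", "Q", "K",
                "E", "M", "H", "F", "R", "Y", "W")

.sampleResidues <- function(n, exclude = character(0)) {
  if (n < 1L) return("")
  pool <- setdiff(.AA_NO_CYS, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

.sampleInt <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1L)

.countJunctions <- function(s) {
  res <- strsplit(s, "")[[1]]
  n <- length(res)
  prev <- res[c(n, seq_len(n - 1L))]
  sum(res == "G" & prev %in% c("N", "D"))
}

#' Generate synthetic cyclotides
#'
#' Head-to-tail cyclic sequences with exactly six cysteines and three
#' disulfides in the cyclic-cystine-knot connectivity (I-IV, II-V, III-VI),
#' built directly in canonical rotation: an Asn/Asp-Gly cyclization
#' junction, loop lengths drawn uniformly from per-loop ranges whose
#' defaults bracket the 3/4/4/1/5/7 pattern of psysol 3 and keep the mature
#' length within the 25-40 residue cyclotide range.  Sequences are
#' rejection-sampled to carry a single junction motif so that the canonical
#' rotation (and hence the loop ground truth) is unambiguous.
#'
#' @param n number of peptides.
#' @param loopMin,loopMax integer length-6 vectors of per-loop length
#'   bounds (loop 6 includes the junction Asn-Gly pair).
#' @param seed optional RNG seed.
#' @return List of cyclic \code{PeptideSpecies}; each carries its loop
#'   decomposition as attribute \code{"truth"}.
#' @export
genCyclotide <- function(n = 1, loopMin = c(2L, 3L, 3L, 1L, 4L, 6L),
                         loopMax = c(4L, 5L, 5L, 2L, 6L, 8L),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(loopMin) == 6L, length(loopMax) == 6L,
            all(loopMax >= loopMin), all(loopMin >= 1L), loopMin[6] >= 3L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      len <- vapply(1:6, function(k)
        .sampleInt(loopMin[k], loopMax[k]), integer(1))
      l <- lapply(len[1:5], .sampleResidues)
      # loop6 = pre-junction segment + [N|D] + G + post-G segment (wraps)
      n_free <- len[6] - 2L
      n_post <- .sampleInt(0L, n_free)
      pre <- .sampleResidues(n_free - n_post)
      post <- .sampleResidues(n_post)
      junction <- sample(c("N", "D"), 1L)
      s <- paste0("G", post, "C", l[[1]], "C", l[[2]], "C", l[[3]],
                  "C", l[[4]], "C", l[[5]], "C", pre, junction)
      if (.countJunctions(s) == 1L) break
    }
    p <- PeptideSpecies(s, "cyclic", disulfides = "all")
    attr(p, "truth") <- decomposeLoops(p)
    out[[i]] <- p
  }
  out
}

#' Generate a synthetic MS1 peak list
#'
#' Peaks at the theoretical [M+H]+ of each species (Gaussian mass error of
#' sd \code{mzSigma}), sodium-adduct satellites with probability
#' \code{naProb}, and \code{nNoise} uniform noise peaks in the m/z window.
#'
#' @param species list of \code{PeptideSpecies} (non-empty).
#' @param mzSigma mass-error sd in Da (0 = exact).
#' @param naProb probability of an accompanying [M+Na]+ satellite.
#' @param nNoise number of uniform noise peaks.
#' @param window m/z window for noise peaks.
#' @param seed optional RNG seed.
#' @return data.frame(mz, intensity) sorted by m/z, with the true [M+H]+
#'   values attached as attribute \code{"truth"}.
#' @export
genMS1 <- function(species, mzSigma = 0, naProb = 0.3, nNoise = 0,
                   window = c(2000, 4000), seed = NULL) {
  if (!length(species)) stop("species must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  mh <- vapply(species, function(p) ionMz(peptideMass(p), "H", 1L),
               numeric(1))
  mz <- mh + stats::rnorm(length(mh), 0, mzSigma)
  intensity <- stats::runif(length(mz), 0.5, 1)
  sat <- stats::runif(length(mh)) < naProb
  if (any(sat)) {
    mna <- vapply(species[sat], function(p) ionMz(peptideMass(p), "Na", 1L),
                  numeric(1))
    mz <- c(mz, mna + stats::rnorm(sum(sat), 0, mzSigma))
    intensity <- c(intensity, stats::runif(sum(sat), 0.05, 0.3))
  }
  if (nNoise > 0) {
    mz <- c(mz, stats::runif(nNoise, window[1], window[2]))
    intensity <- c(intensity, stats::runif(nNoise, 0.01, 0.2))
  }
  o <- order(mz)
  structure(data.frame(mz = mz[o], intensity = intensity[o]), truth = mh)
}

#' Generate a synthetic MS/MS spectrum from a candidate sequence
#'
#' Builds the theoretical singly charged b/y series of a linear candidate,
#' drops each ion independently with probability \code{dropout}, perturbs
#' the surviving m/z values with Gaussian error, and returns a
#' \code{Spectrum} whose precursor is the candidate's [M+H]+.
#'
#' @param candidate linear \code{PeptideSpecies}.
#' @param dropout per-ion dropout probability in [0, 1).
#' @param mzSigma fragment mass-error sd (Da).
#' @param seed optional RNG seed.
#' @return A \code{Spectrum}; the surviving ion table is attribute
#'   \code{"truth"}.
#' @export
genMSMS <- function(candidate, dropout = 0, mzSigma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ions <- ionSeries(candidate)
  keep <- stats::runif(nrow(ions)) >= dropout
  kept <- ions[keep, , drop = FALSE]
  mz <- kept$mz + stats::rnorm(nrow(kept), 0, mzSigma)
  sp <- Spectrum(mz = mz, intensity = stats::runif(length(mz), 0.1, 1),
                 precursorMz = ionMz(peptideMass(candidate), "H", 1L),
                 precursorCharge = 1L)
  attr(sp, "truth") <- kept
  sp
}

.reverseTranslate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(protein, "")[[1]], function(aa) {
    sample(names(gc)[gc == aa], 1L)
  }, character(1)), collapse = "")
}

.randomCodingDNA <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Generate transcript contigs embedding cyclotide precursor genes
#'
#' For each species, assembles an oak1-style precursor protein — Met start,
#' a hydrophobic ER-signal stretch, a pro-region, the mature domain (the
#' species' canonical rotation, which starts with Gly and ends at the
#' Asn/Asp junction), and a small-residue C-terminal tail — then
#' reverse-translates it with uniformly random synonymous codons, embeds
#' it at a random frame on a random strand between stop-free random-codon
#' flanks, and records the ground truth.
#'
#' @param species list of cyclic \code{PeptideSpecies} from
#'   \code{genCyclotide}.
#' @param flankCodons range of flanking codon counts on each side.
#' @param seed optional RNG seed.
#' @return List with \code{contigs} (named character vector) and
#'   \code{truth} (data.frame: contig, frame, mature, precursor protein,
#'   nt_start of the precursor on the given frame's strand).
#' @export
genTranscripts <- function(species, flankCodons = c(8L, 25L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hydro <- c("A", "V", "L", "I", "F", "M", "W")
  contigs <- character(length(species))
  truth <- vector("list", length(species))
  for (i in seq_along(species)) {
    mature <- canonicalRotation(species[[i]])
    signal <- paste0("M", paste(sample(hydro, 14, replace = TRUE),
                                collapse = ""),
                     .sampleResidues(5))
    pro <- .sampleResidues(20, exclude = "C")
    tail <- paste0(sample(c("S", "A", "L", "G"), 1L), .sampleResidues(4))
    precursor <- paste0(signal, pro, mature, tail)
    cds <- .reverseTranslate(precursor)
    left <- .randomCodingDNA(.sampleInt(flankCodons[1], flankCodons[2]))
    extra <- sample(0:2, 1L)                       # shifts the frame
    left <- paste0(left, substr("AC", 1, extra))
    right <- .randomCodingDNA(.sampleInt(flankCodons[1], flankCodons[2]))
    fwd <- paste0(left, cds, right)
    minus <- stats::runif(1) < 0.5
    contig <- if (minus)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
      else fwd
    frame <- paste0(if (minus) "-" else "+", (nchar(left) %% 3L) + 1L)
    contigs[i] <- contig
    truth[[i]] <- data.frame(contig = paste0("synthetic_contig", i),
                             frame = frame, mature = mature,
                             precursor = precursor,
                             nt_start = nchar(left) + 1L,
                             stringsAsFactors = FALSE)
  }
  names(contigs) <- paste0("synthetic_contig", seq_along(species))
  list(contigs = contigs, truth = do.call(rbind, truth))
}

#' Generate synthetic protease-inhibition plate data
#'
#' Kinetic traces linear in time whose slope is scaled by the remaining
#' activity of a constrained 4PL curve at each tested concentration, plus
#' uninhibited (max_activity) and substrate-only background wells.
#'
#' @param ic50 true IC50 (same unit as \code{concentrations}).
#' @param hill true Hill slope.
#' @param concentrations tested inhibitor concentrations.
#' @param v0 uninhibited slope (RFU/min).
#' @param times read times (min).
#' @param rfuSigma additive RFU noise sd.
#' @param nrep replicates per concentration.
#' @param seed optional RNG seed.
#' @return List with \code{plate} (data.frame well, time_min, rfu),
#'   \code{layout} (well, sample, concentration, role) and \code{truth}.
#' @export
genAssay <- function(ic50, hill = 1, concentrations, v0 = 100,
                     times = seq(0, 15, by = 3), rfuSigma = 0,
                     nrep = 1L, seed = NULL) {
  stopifnot(ic50 > 0, all(concentrations > 0))
  if (!is.null(seed)) set.seed(seed)
  wells <- list(); layout <- list()
  addWell <- function(id, sample, conc, role, slope) {
    rfu <- slope * times + stats::rnorm(length(times), 0, rfuSigma)
    wells[[length(wells) + 1L]] <<-
      data.frame(well = id, time_min = times, rfu = rfu)
    layout[[length(layout) + 1L]] <<-
      data.frame(well = id, sample = sample, concentration = conc,
                 role = role)
  }
  w <- 0L
  for (r in seq_len(nrep)) {
    for (cc in concentrations) {
      w <- w + 1L
      remaining <- 100 / (1 + 10^((log10(cc) - log10(ic50)) * hill))
      addWell(sprintf("S%02d", w), "inhibitor", cc, "sample",
              v0 * remaining / 100)
    }
    w <- w + 1L
    addWell(sprintf("C%02d", w), "control", 0, "max_activity", v0)
    w <- w + 1L
    addWell(sprintf("B%02d", w), "background", 0, "substrate_control", 0)
  }
  list(plate = do.call(rbind, wells), layout = do.call(rbind, layout),
       truth = list(ic50 = ic50, hill = hill, v0 = v0))
}

#' Generate a synthetic elimination time-course
#'
#' Percent-remaining series following one-phase decay with the given
#' half-life, with optional Gaussian noise.
#'
#' @param half_life true half-life (h).
#' @param times sampling times (h).
#' @param sigma additive noise sd (percent points).
#' @param seed optional RNG seed.
#' @return data.frame(time_h, remaining) with \code{truth} attribute.
#' @export
genDecay <- function(half_life, times = c(0, 5/60, 1/6, 1/3, 2/3, 1, 2, 4, 24),
                     sigma = 0, seed = NULL) {
  stopifnot(half_life > 0)
  if (!is.null(seed)) set.seed(seed)
  y <- 100 * 2^(-times / half_life) + stats::rnorm(length(times), 0, sigma)
  structure(data.frame(time_h = times, remaining = y),
            truth = list(half_life = half_life))
}
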