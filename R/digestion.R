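## In-silico proteolysis of linear and head-to-tail cyclic peptides.
##
## Coordinates are 1-based inclusive on the stored rotation; cyclic arcs
## that cross the junction are written start > end (e.g. 26-7).

#' Cleavage sites of an endoprotease on a peptide
#'
#' A site is the position of the residue after which the backbone is cut.
#' On a cyclic peptide the bond between the last and first residue is a
#' candidate like any other (site = n).  The \code{blockedBefore} set of the
#' rule suppresses cleavage when the following residue matches (e.g. no
#' tryptic cleavage of a Lys-Pro bond).
#'
#' @param p a \code{PeptideSpecies}.
#' @param rule a \code{CleavageRule}, or a list of rules whose site sets are
#'   combined (sequential multi-enzyme digestion).
#' @return Sorted integer vector of cleavage positions (possibly empty).
#' @examples
#' cleavageSites(psysol3(), enzymeRule("trypsin"))  # single Arg site
#' @export
cleavageSites <- function(p, rule) {
  stopifnot(is(p, "PeptideSpecies"))
  if (is(rule, "CleavageRule")) rule <- list(rule)
  res <- strsplit(p@sequence, "")[[1]]
  n <- length(res)
  sites <- integer(0)
  cand <- if (p@topology == "cyclic") seq_len(n) else seq_len(max(0L, n - 1L))
  for (r in rule) {
    validObject(r)
    nxt <- if (p@topology == "cyclic") res[cand %% n + 1L] else res[cand + 1L]
    hit <- res[cand] %in% r@cleaveAfter & !nxt %in% r@blockedBefore
    sites <- union(sites, cand[hit])
  }
  sort(sites)
}

.arcSequence <- function(res, start, end) {
  n <- length(res)
  idx <- if (start <= end) start:end else c(start:n, 1:end)
  paste(res[idx], collapse = "")
}

.arcLength <- function(n, start, end) {
  if (start <= end) end - start + 1L else n - start + 1L + end
}

.arcProduct <- function(p, start, end, n_missed, full_length = FALSE) {
  res <- strsplit(p@sequence, "")[[1]]
  n <- length(res)
  idx <- if (start <= end) start:end else c(start:n, 1:end)
  seqstr <- paste(res[idx], collapse = "")
  # carry the parent's per-site modifications that fall inside the arc
  mods <- p@modifications
  inside <- !is.na(mods$site) & mods$site %in% idx
  mods <- mods[inside, , drop = FALSE]
  if (nrow(mods)) mods$site <- match(mods$site, idx)
  frag <- new("PeptideSpecies", sequence = seqstr, topology = "linear",
              disulfides = matrix(integer(0), ncol = 2L),
              modifications = mods)
  m <- peptideMass(frag)
  data.frame(start = start, end = end, sequence = seqstr,
             n_missed = n_missed, mass = m,
             mh = ionMz(m, "H", 1L), mna = ionMz(m, "Na", 1L),
             ring_opened_full_length = full_length,
             stringsAsFactors = FALSE)
}

#' Digest a peptide in silico
#'
#' Enumerates proteolytic products of a linear or cyclic peptide under one
#' or several cleavage rules, up to a missed-cleavage bound.  Products of a
#' cyclic parent are arcs between cleavage sites; a cyclic parent with
#' exactly one site yields the single ring-opened full-length linear
#' peptide (mass gain +18.010565 Da, the diagnostic cyclicity signature).
#' Full-circle arcs (ring-opened full length at one of k sites, carrying
#' k-1 missed cleavages) are included when the bound permits and flagged in
#' the \code{ring_opened_full_length} column.  A cyclic peptide with no
#' sites yields no products (the intact ring is not a digest product).
#'
#' Each product is a linear peptide (it gains the terminal water) and
#' carries the parent's per-site modifications that fall inside its arc.
#'
#' @param p a \code{PeptideSpecies}.
#' @param rule a \code{CleavageRule} or list of rules.
#' @param maxMissed maximum internal uncut sites per product; \code{Inf}
#'   (default) enumerates all, matching partial time-course digests.  Use 2
#'   for prospective complete digests.
#' @return data.frame with columns start, end, sequence, n_missed, mass,
#'   mh ([M+H]+), mna ([M+Na]+), ring_opened_full_length.  Arc coordinates
#'   wrap start > end across the cyclic junction.
#' @examples
#' p <- applyProtocol(psysol3(), reductionAlkylation(3, 6))
#' digestPeptide(p, list(enzymeRule("gluc"), enzymeRule("trypsin")),
#'               maxMissed = 0)
#' @export
digestPeptide <- function(p, rule, maxMissed = Inf) {
  stopifnot(is(p, "PeptideSpecies"))
  sites <- cleavageSites(p, rule)
  n <- nchar(p@sequence)
  empty <- .arcProduct(p, 1L, 1L, 0L)[0, ]
  k <- length(sites)
  out <- list()
  if (p@topology == "cyclic") {
    if (k == 0L) return(empty)
    if (k == 1L) {
      s <- sites
      start <- s %% n + 1L
      return(.arcProduct(p, start, s, 0L, full_length = TRUE))
    }
    for (i in seq_len(k)) for (j in seq_len(k)) {
      a <- sites[i]; b <- sites[j]
      start <- a %% n + 1L
      if (i == j) {                      # full circle: k-1 missed
        if (k - 1L <= maxMissed)
          out[[length(out) + 1L]] <-
            .arcProduct(p, start, a, k - 1L, full_length = TRUE)
      } else {
        len <- .arcLength(n, start, b)
        inside <- vapply(sites, function(s2) {
          pos <- if (s2 >= start) s2 - start + 1L else n - start + 1L + s2
          pos < len
        }, logical(1))
        missed <- sum(inside)            # sites strictly inside the arc
        if (missed <= maxMissed)
          out[[length(out) + 1L]] <- .arcProduct(p, start, b, missed)
      }
    }
  } else {
    bounds <- c(0L, sites, n)
    nb <- length(bounds)
    for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
      start <- bounds[i] + 1L; end <- bounds[j]
      missed <- j - i - 1L
      if (missed <= maxMissed)
        out[[length(out) + 1L]] <- .arcProduct(p, start, end, missed)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a digest table as TSV
#'
#' Emits arc, sequence, missed-cleavage count, neutral mass, [M+H]+ and
#' [M+Na]+ with m/z to four decimals.
#'
#' @param digest data.frame from \code{digestPeptide}.
#' @param path output file.
#' @return Invisibly, the formatted table.
#' @export
writeDigestTable <- function(digest, path) {
  out <- data.frame(arc = paste0(digest$start, "-", digest$end),
                    sequence = digest$sequence,
                    n_missed = digest$n_missed,
                    neutral_mass = sprintf("%.4f", digest$mass),
                    mh = sprintf("%.4f", digest$mh),
                    mna = sprintf("%.4f", digest$mna))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
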