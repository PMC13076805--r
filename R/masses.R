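## Residue/modification tables and mass arithmetic for linear and
## head-to-tail cyclic peptides.

#' Residue mass table
#'
#' The 20 standard amino-acid residue masses (monoisotopic and average, Da),
#' loaded from the shipped TSV.  Users may supply their own table with the
#' same columns (residue, monoisotopic_mass, average_mass) to extend the
#' alphabet, e.g. for non-standard residues.
#'
#' @param path optional path to a user table overriding the shipped one.
#' @return data.frame with columns residue, monoisotopic_mass, average_mass.
#' @export
residueMassTable <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.pkg_cache$residues))
      .pkg_cache$residues <- utils::read.delim(.extdata("residue_masses.tsv"),
                                               stringsAsFactors = FALSE)
    return(.pkg_cache$residues)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Modification registry
#'
#' The shipped chemical-modification table: disulfide bond formation
#' (-2.015650 Da per bond, i.e. loss of two hydrogens), cysteine
#' carbamidomethylation by iodoacetamide (+57.021464 Da), hydration on
#' enzymatic ring opening of a cyclic backbone (+18.010565 Da), and
#' C-terminal amidation (-0.984016 Da, linear peptides only).
#'
#' @param path optional path to a user TSV extending/overriding the registry.
#' @return data.frame with columns name, delta_mono, delta_avg, site_rule,
#'   per_site.
#' @export
modificationRegistry <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.pkg_cache$mods))
      .pkg_cache$mods <- utils::read.delim(.extdata("modifications.tsv"),
                                           stringsAsFactors = FALSE)
    return(.pkg_cache$mods)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.residueMasses <- function(scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  tab <- residueMassTable()
  stats::setNames(if (scale == "monoisotopic") tab$monoisotopic_mass
                  else tab$average_mass, tab$residue)
}

.modDelta <- function(name, scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  reg <- modificationRegistry()
  i <- match(name, reg$name)
  if (anyNA(i)) stop("unknown modification: ", name[which(is.na(i))[1]])
  if (scale == "monoisotopic") reg$delta_mono[i] else reg$delta_avg[i]
}

#' Neutral mass of a peptide species
#'
#' Sum of residue masses, plus one water for a linear backbone (none for a
#' head-to-tail cycle), plus all modification deltas, minus 2.015650 Da per
#' disulfide bond.  Rotation of a cyclic sequence does not change the mass.
#'
#' @param p a \code{PeptideSpecies}.
#' @param scale \code{"monoisotopic"} (default) or \code{"average"}.
#' @return Neutral mass in Da.
#' @examples
#' peptideMass(PeptideSpecies("G"))          # 75.0320
#' peptideMass(PeptideSpecies("GG", "cyclic"))  # no terminal water
#' @export
peptideMass <- function(p, scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  stopifnot(is(p, "PeptideSpecies"))
  validObject(p)
  res <- strsplit(p@sequence, "")[[1]]
  masses <- .residueMasses(scale)
  m <- sum(masses[res])
  wat <- if (scale == "monoisotopic") MASS_CONST[["water"]]
         else MASS_CONST_AVG[["water"]]
  if (p@topology == "linear") m <- m + wat
  ss_delta <- .modDelta("disulfide_bond", scale)
  m <- m + nrow(p@disulfides) * ss_delta
  if (nrow(p@modifications))
    m <- m + sum(.modDelta(p@modifications$name, scale))
  unname(m)
}

#' m/z of an adducted ion
#'
#' \code{(M + z * carrier) / z} for a proton or sodium charge carrier.
#'
#' @param mass neutral mass (Da), must be positive.
#' @param adduct \code{"H"} or \code{"Na"}, or a numeric charge-carrier mass.
#' @param charge positive integer charge state.
#' @return m/z value.
#' @examples
#' ionMz(1000, "H", 1)   # 1001.0073
#' @export
ionMz <- function(mass, adduct = c("H", "Na"), charge = 1L) {
  if (any(mass <= 0)) stop("mass must be positive")
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  carrier <- if (is.numeric(adduct)) adduct
             else switch(match.arg(adduct),
                         H = MASS_CONST[["proton"]],
                         Na = MASS_CONST[["sodium"]])
  (mass + charge * carrier) / charge
}

#' Mass change of a modification protocol
#'
#' Total signed mass change of a chemical protocol relative to the
#' unmodified species, without applying it.  A protocol is a data.frame
#' with columns \code{name} (registry identifier) and \code{n} (signed
#' count: negative removes existing modifications, e.g. \code{n = -3}
#' \code{disulfide_bond} is reduction of three disulfides, contributing
#' +2.015650 Da per bond).
#'
#' The protocol is validated against the species: removing more disulfides
#' than exist, alkylating more cysteines than are free after the protocol's
#' own reductions, or ring-opening a linear peptide are rejected.
#'
#' @param p a \code{PeptideSpecies}.
#' @param protocol data.frame(name, n); see Details.
#' @param scale mass scale.
#' @return Signed mass change in Da.
#' @seealso \code{\link{applyProtocol}}, whose result satisfies
#'   \code{peptideMass(applyProtocol(p, pr)) ==
#'   peptideMass(p) + modificationDelta(p, pr)}.
#' @examples
#' p3 <- psysol3()
#' # reduce 3 disulfides, alkylate all 6 Cys: the cysteine-count diagnostic
#' modificationDelta(p3, reductionAlkylation(3, 6))   # +348.18
#' @export
modificationDelta <- function(p, protocol,
                              scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  stopifnot(is(p, "PeptideSpecies"))
  if (!nrow(protocol)) return(0)
  if (!all(c("name", "n") %in% names(protocol)))
    stop("protocol needs columns 'name' and 'n'")
  .checkProtocol(p, protocol)
  sum(.modDelta(protocol$name, scale) * protocol$n)
}

.protocolCount <- function(protocol, what) {
  sum(protocol$n[protocol$name == what])
}

.checkProtocol <- function(p, protocol) {
  res <- strsplit(p@sequence, "")[[1]]
  n_cys <- sum(res == "C")
  d_ss <- .protocolCount(protocol, "disulfide_bond")
  n_ss <- nrow(p@disulfides) + d_ss
  if (n_ss < 0)
    stop("protocol removes more disulfide bonds than the species carries")
  n_cam_existing <- sum(p@modifications$name == "carbamidomethyl")
  n_cam <- n_cam_existing + .protocolCount(protocol, "carbamidomethyl")
  if (n_cam < 0) stop("protocol removes more carbamidomethyl groups than present")
  if (n_cam + 2L * n_ss > n_cys)
    stop("cannot alkylate ", n_cam, " Cys with ", n_ss,
         " disulfide bond(s) still closed: only ", n_cys,
         " cysteines in the sequence")
  n_open <- .protocolCount(protocol, "ring_open_hydration")
  if (n_open > 0 && p@topology != "cyclic")
    stop("ring opening applies to cyclic peptides only")
  if (n_open > 1) stop("a ring can be opened only once")
  invisible(TRUE)
}

#' Apply a modification protocol to a species
#'
#' Returns the chemically modified \code{PeptideSpecies}: disulfide removal
#' drops bond pairs (in knot order: last bond first is reduction order
#' convention, but the result is order-independent for mass purposes),
#' carbamidomethylation attaches to free cysteines, and ring opening turns
#' the topology linear (the +18.010565 Da appears through the linear
#' backbone's terminal water).
#'
#' @inheritParams modificationDelta
#' @return A new \code{PeptideSpecies}.
#' @export
applyProtocol <- function(p, protocol) {
  stopifnot(is(p, "PeptideSpecies"))
  if (!nrow(protocol)) return(p)
  .checkProtocol(p, protocol)
  seqres <- strsplit(p@sequence, "")[[1]]
  ss <- p@disulfides
  mods <- p@modifications
  topo <- p@topology
  d_ss <- .protocolCount(protocol, "disulfide_bond")
  if (d_ss < 0) {
    keep <- seq_len(max(0L, nrow(ss) + d_ss))
    ss <- ss[keep, , drop = FALSE]
  } else if (d_ss > 0) {
    free <- setdiff(which(seqres == "C"), as.integer(ss))
    add <- matrix(free[seq_len(2L * d_ss)], ncol = 2L, byrow = TRUE)
    ss <- rbind(ss, add)
  }
  n_cam <- .protocolCount(protocol, "carbamidomethyl")
  if (n_cam < 0) {
    drop <- which(mods$name == "carbamidomethyl")[seq_len(-n_cam)]
    mods <- mods[-drop, , drop = FALSE]
  } else if (n_cam > 0) {
    taken <- c(as.integer(ss),
               mods$site[mods$name == "carbamidomethyl"])
    free <- setdiff(which(seqres == "C"), taken)
    mods <- rbind(mods, data.frame(name = rep("carbamidomethyl", n_cam),
                                   site = as.integer(free[seq_len(n_cam)])))
  }
  if (.protocolCount(protocol, "ring_open_hydration") > 0) topo <- "linear"
  other <- !protocol$name %in%
    c("disulfide_bond", "carbamidomethyl", "ring_open_hydration")
  if (any(other)) {
    add <- protocol[other & protocol$n > 0, , drop = FALSE]
    mods <- rbind(mods,
                  data.frame(name = rep(add$name, add$n), site = NA_integer_))
  }
  new("PeptideSpecies", sequence = p@sequence, topology = topo,
      disulfides = ss, modifications = mods)
}

#' Shorthand protocols
#'
#' \code{reductionAlkylation(k, c)}: reduce \code{k} disulfide bonds and
#' carbamidomethylate \code{c} cysteines — the standard cysteine-counting
#' chemistry.  \code{ringOpening()}: single enzymatic linearization of a
#' cyclic backbone.
#'
#' @param k number of disulfide bonds reduced.
#' @param c number of cysteines alkylated.
#' @return A protocol data.frame(name, n).
#' @export
reductionAlkylation <- function(k, c) {
  data.frame(name = c("disulfide_bond", "carbamidomethyl"), n = c(-k, c))
}

#' @rdname reductionAlkylation
#' @export
ringOpening <- function() data.frame(name = "ring_open_hydration", n = 1)
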