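## Readers and writers for the plain-text formats the pipeline consumes:
## FASTA (peptides with topology/modification flags, nucleotide contigs),
## MGF spectra, two-column TSV peak lists, plate CSVs, and YAML/JSON
## pipeline configuration.

#' Read and write peptide FASTA with topology flags
#'
#' Peptide FASTA where the description line may carry
#' \code{topology=cyclic}, \code{disulfides=1-14,5-17,...} and
#' \code{mods=carbamidomethyl@5;...} key=value tokens; absent tokens mean
#' a plain linear, unmodified peptide.  \code{disulfides=all} pairs
#' cysteines in knot order.
#'
#' @param path file path.
#' @return \code{readPeptideFasta}: named list of \code{PeptideSpecies}.
#' @export
readPeptideFasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(ss), function(i) {
    desc <- names(ss)[i]
    toks <- strsplit(desc, "\\s+")[[1]]
    kv <- toks[grepl("=", toks, fixed = TRUE)]
    vals <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    topo <- if (identical(unname(vals["topology"]), "cyclic")) "cyclic"
            else "linear"
    ssb <- if (!is.na(vals["disulfides"])) {
      if (vals[["disulfides"]] == "all") "all"
      else lapply(strsplit(vals[["disulfides"]], ",")[[1]],
                  function(x) as.integer(strsplit(x, "-")[[1]]))
    } else list()
    mods <- NULL
    if (!is.na(vals["mods"])) {
      if (vals[["mods"]] == "cam") mods <- "cam"
      else {
        parts <- strsplit(strsplit(vals[["mods"]], ";")[[1]], "@")
        mods <- data.frame(
          name = vapply(parts, `[`, character(1), 1),
          site = as.integer(vapply(parts, function(x)
            if (length(x) > 1) x[2] else NA_character_, character(1))))
      }
    }
    PeptideSpecies(as.character(ss[[i]]), topo, disulfides = ssb,
                   modifications = mods)
  })
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname readPeptideFasta
#' @param species named list of \code{PeptideSpecies}.
#' @return \code{writePeptideFasta}: the path, invisibly.
#' @export
writePeptideFasta <- function(species, path) {
  lines <- unlist(lapply(seq_along(species), function(i) {
    p <- species[[i]]
    id <- if (!is.null(names(species))) names(species)[i] else paste0("pep", i)
    desc <- id
    if (p@topology == "cyclic") desc <- paste0(desc, " topology=cyclic")
    if (nrow(p@disulfides))
      desc <- paste0(desc, " disulfides=",
                     paste(apply(p@disulfides, 1, paste, collapse = "-"),
                           collapse = ","))
    m <- p@modifications
    if (nrow(m))
      desc <- paste0(desc, " mods=",
                     paste(ifelse(is.na(m$site), m$name,
                                  paste0(m$name, "@", m$site)),
                           collapse = ";"))
    c(paste0(">", desc), p@sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read nucleotide contigs
#'
#' @param path FASTA file of assembled transcript contigs.
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
readContigs <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Read and write two-column peak lists
#'
#' Tab- or whitespace-separated \code{m/z intensity} rows; blank lines and
#' \code{#} comments ignored.
#'
#' @param path file path.
#' @return \code{readPeakList}: data.frame(mz, intensity) sorted by m/z.
#' @export
readPeakList <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^(m/?z|mz)\\b", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  fields <- strsplit(lines, "[\t ]+")
  bad <- which(vapply(fields, length, integer(1)) < 2L |
               is.na(suppressWarnings(
                 as.numeric(vapply(fields, `[`, character(1), 1)))))
  if (length(bad))
    stop("malformed peak-list record at line ", bad[1], ": '",
         lines[bad[1]], "'")
  df <- data.frame(mz = as.numeric(vapply(fields, `[`, character(1), 1)),
                   intensity = as.numeric(vapply(fields, `[`, character(1), 2)))
  df[order(df$mz), , drop = FALSE]
}

#' @rdname readPeakList
#' @param peaks data.frame(mz, intensity).
#' @return \code{writePeakList}: the path, invisibly.
#' @export
writePeakList <- function(peaks, path) {
  utils::write.table(
    data.frame(mz = sprintf("%.4f", peaks$mz), intensity = peaks$intensity),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write MGF spectra
#'
#' Minimal Mascot Generic Format support: BEGIN IONS / END IONS blocks
#' with TITLE, PEPMASS, CHARGE headers and m/z-intensity peak rows.  A
#' block with zero peaks is a valid (empty) spectrum.
#'
#' @param path file path.
#' @return \code{readMGF}: named list of \code{Spectrum} objects.
#' @export
readMGF <- function(path) {
  lines <- trimws(readLines(path))
  out <- list(); titles <- character(0)
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (lines[i] == "BEGIN IONS") {
      title <- NA_character_; pmz <- NA_real_; chg <- 1L
      mz <- numeric(0); int <- numeric(0)
      i <- i + 1L
      while (i <= n && lines[i] != "END IONS") {
        ln <- lines[i]
        if (!nzchar(ln)) { i <- i + 1L; next }
        if (grepl("^TITLE=", ln)) title <- sub("^TITLE=", "", ln)
        else if (grepl("^PEPMASS=", ln))
          pmz <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[\t ]+")[[1]][1])
        else if (grepl("^CHARGE=", ln))
          chg <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
        else if (grepl("^[0-9.]", ln)) {
          f <- strsplit(ln, "[\t ]+")[[1]]
          if (length(f) < 2L || is.na(suppressWarnings(as.numeric(f[1]))))
            stop("malformed MGF peak at line ", i, ": '", ln, "'")
          mz <- c(mz, as.numeric(f[1])); int <- c(int, as.numeric(f[2]))
        }
        i <- i + 1L
      }
      if (i > n) stop("MGF block without END IONS (starting near line ", i, ")")
      out[[length(out) + 1L]] <-
        Spectrum(mz, int, precursorMz = pmz, precursorCharge = chg)
      titles <- c(titles, if (is.na(title))
        paste0("spectrum", length(out)) else title)
    }
    i <- i + 1L
  }
  stats::setNames(out, titles)
}

#' @rdname readMGF
#' @param spectra named list of \code{Spectrum} objects.
#' @return \code{writeMGF}: the path, invisibly.
#' @export
writeMGF <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    title <- if (!is.null(names(spectra))) names(spectra)[i]
             else paste0("spectrum", i)
    writeLines(c("BEGIN IONS", paste0("TITLE=", title),
                 if (!is.na(sp@precursorMz))
                   sprintf("PEPMASS=%.4f", sp@precursorMz),
                 sprintf("CHARGE=%d+", sp@precursorCharge),
                 sprintf("%.4f %g", sp@peaks$mz, sp@peaks$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read plate-reader kinetics with a layout map
#'
#' @param platePath CSV with columns well, time_min, rfu.
#' @param layoutPath CSV with columns well, sample, concentration, role
#'   (role in sample / substrate_control / max_activity).
#' @return List with \code{plate} and \code{layout} data.frames; wells in
#'   the plate but missing from the layout are an error.
#' @export
readPlate <- function(platePath, layoutPath) {
  plate <- utils::read.csv(platePath, stringsAsFactors = FALSE)
  layout <- utils::read.csv(layoutPath, stringsAsFactors = FALSE)
  need <- setdiff(c("well", "time_min", "rfu"), names(plate))
  if (length(need)) stop("plate CSV lacks column(s): ",
                         paste(need, collapse = ", "))
  need <- setdiff(c("well", "sample", "concentration", "role"), names(layout))
  if (length(need)) stop("layout CSV lacks column(s): ",
                         paste(need, collapse = ", "))
  orphan <- setdiff(unique(plate$well), layout$well)
  if (length(orphan)) stop("wells missing from layout: ",
                           paste(orphan, collapse = ", "))
  list(plate = plate, layout = layout)
}

#' Pipeline configuration
#'
#' Defaults for every tolerance and rule the pipeline applies; read and
#' write as YAML (or JSON).  Round-trips losslessly.
#'
#' @return A config list: ms1_tol_da, ms2_tol_da, ms1_window, enzymes,
#'   max_missed, alignment (list), processing rules, seed.
#' @export
defaultConfig <- function() {
  list(ms1_tol_da = 0.25, ms2_tol_da = 0.3, ms1_window = c(2000, 4000),
       enzymes = c("trypsin", "gluc", "chymotrypsin"),
       max_missed = Inf,
       alignment = list(substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5),
       processing = processingRules(), seed = 1L)
}

#' @rdname defaultConfig
#' @param config a config list.
#' @param path output file (.yaml/.yml or .json).
#' @export
writeConfig <- function(config, path) {
  if (!is.null(config$max_missed) && is.infinite(config$max_missed))
    config$max_missed <- "unlimited"
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname defaultConfig
#' @export
readConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.character(cfg$max_missed)) cfg$max_missed <- Inf
  bad <- c(cfg$ms1_tol_da, cfg$ms2_tol_da) <= 0
  if (any(bad)) stop("tolerances must be positive")
  cfg
}
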