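## End-to-end orchestration: MS1 fingerprint -> dereplication -> digestion
## and MS/MS annotation -> loop analysis -> assay fits, with a structured
## log of every tolerance and rule actually applied.

#' Run the discovery pipeline
#'
#' Executes the requested stages over in-memory inputs and returns a
#' report bundle.  Stages run only when their inputs are present; any
#' stage failure halts with the stage name and cause.  Deterministic for
#' a given config seed.
#'
#' @param inputs list with any of: \code{peaks} (data.frame mz/intensity),
#'   \code{candidates} (list of \code{PeptideSpecies} or character
#'   sequences), \code{contigs} (named nucleotide vector) with
#'   \code{queries} (mature sequences), \code{msms} (list of
#'   \code{Spectrum}) with \code{msms_candidates} (linear
#'   \code{PeptideSpecies}, recycled by position), \code{assay}
#'   (list(plate, layout)), \code{decay} (data.frame time_h/remaining).
#' @param config list from \code{\link{defaultConfig}}.
#' @return List of stage results plus \code{log}, a data.frame recording
#'   every parameter applied.
#' @export
runPipeline <- function(inputs, config = defaultConfig()) {
  set.seed(config$seed)
  report <- list()
  logs <- list()
  note <- function(stage, param, value)
    logs[[length(logs) + 1L]] <<- data.frame(stage = stage, param = param,
                                             value = as.character(value))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(inputs$peaks)) {
    note("fingerprint", "window",
         paste(config$ms1_window, collapse = "-"))
    report$fingerprint <- stage("fingerprint",
      ms1Fingerprint(inputs$peaks, config$ms1_window))
    if (!is.null(inputs$candidates)) {
      note("dereplicate", "ms1_tol_da", config$ms1_tol_da)
      report$detection <- stage("dereplicate",
        dereplicate(inputs$candidates, inputs$peaks, config$ms1_tol_da))
    }
  }
  if (!is.null(inputs$contigs)) {
    if (is.null(inputs$queries))
      stop("pipeline stage 'mine' failed: contigs supplied without queries")
    report$precursors <- stage("mine",
      scanPrecursors(inputs$contigs, inputs$queries))
    report$mature <- stage("mine", {
      hits <- report$precursors
      lapply(seq_len(nrow(hits)), function(i)
        tryCatch(extractMature(hits[i, ], config$processing),
                 warning = function(w) NULL))
    })
    if (!is.null(inputs$peaks))
      report$mined_detection <- stage("mine",
        detectionTable(report$mature, inputs$peaks, config$ms1_tol_da))
  }
  if (!is.null(inputs$msms)) {
    note("annotate", "ms2_tol_da", config$ms2_tol_da)
    cands <- inputs$msms_candidates
    report$annotations <- stage("annotate",
      lapply(seq_along(inputs$msms), function(i)
        annotateSpectrum(inputs$msms[[i]],
                         cands[[min(i, length(cands))]],
                         config$ms2_tol_da)))
  }
  if (!is.null(inputs$candidates)) {
    six <- Filter(function(p) is(p, "PeptideSpecies") &&
                    isCyclic(p) &&
                    sum(strsplit(pepSequence(p), "")[[1]] == "C") == 6L,
                  if (is.character(inputs$candidates))
                    list() else inputs$candidates)
    if (length(six))
      report$loops <- stage("loops", lapply(six, decomposeLoops))
  }
  if (!is.null(inputs$assay)) {
    report$ic50 <- stage("fit-ic50", {
      a <- inputs$assay
      merged <- merge(a$plate, a$layout, by = "well")
      vel <- vapply(split(merged, merged$well), function(d)
        initialVelocity(d$time_min[order(d$time_min)],
                        d$rfu[order(d$time_min)]), numeric(1))
      lay <- a$layout[match(names(vel), a$layout$well), ]
      v0 <- mean(vel[lay$role == "max_activity"])
      bg <- if (any(lay$role == "substrate_control"))
        mean(vel[lay$role == "substrate_control"]) else 0
      sel <- lay$role == "sample"
      remaining <- (vel[sel] - bg) / (v0 - bg) * 100
      fit4PL(lay$concentration[sel], remaining)
    })
  }
  if (!is.null(inputs$decay))
    report$decay <- stage("fit-decay",
      fitDecay(inputs$decay$time_h, inputs$decay$remaining))
  report$log <- if (length(logs)) do.call(rbind, logs)
                else data.frame(stage = character(0), param = character(0),
                                value = character(0))
  report
}
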