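## Protease-inhibition assay arithmetic: kinetic traces to initial
## velocities, percent inhibition, constrained four-parameter logistic
## IC50 fits, one-phase decay half-lives, and extract ranking.

#' Initial velocity of a kinetic fluorescence trace
#'
#' The slope of the linear initial phase, taken over the first recorded
#' interval after optional background subtraction:
#' v = (F(t2) - F(t1)) / (t2 - t1).  Plate readers in these assays record
#' in three-minute intervals; with \code{dropFirst} the t0 read (mixing
#' lag) is discarded before taking the interval.
#'
#' @param time numeric vector of read times (min), strictly increasing.
#' @param rfu fluorescence readings (RFU), same length.
#' @param background optional background trace (RFU at the same times)
#'   subtracted before the slope is taken.
#' @param dropFirst discard the first read before taking the interval.
#' @return Velocity in RFU/min.
#' @examples
#' initialVelocity(c(0, 3), c(0, 300))  # 100 RFU/min
#' @export
initialVelocity <- function(time, rfu, background = NULL, dropFirst = FALSE) {
  if (length(time) != length(rfu)) stop("time and rfu lengths differ")
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing")
  if (!is.null(background)) rfu <- rfu - background
  if (dropFirst) { time <- time[-1]; rfu <- rfu[-1] }
  if (length(time) < 2L) stop("need at least two reads")
  (rfu[2] - rfu[1]) / (time[2] - time[1])
}

#' Percent inhibition from velocities
#'
#' Remaining activity is v_i / v_0 x 100; inhibition is 100 minus that.
#' Values outside [0, 100] (noise can push a velocity above the
#' uninhibited control) are reported as-is with attribute
#' \code{"clipped"} = TRUE so downstream code can decide.
#'
#' @param v_i velocity with inhibitor.
#' @param v_0 uninhibited control velocity, must be positive.
#' @return Percent inhibition with attribute \code{remaining} (percent
#'   remaining activity) and \code{clipped}.
#' @export
percentInhibition <- function(v_i, v_0) {
  if (any(v_0 <= 0)) stop("control velocity must be positive")
  remaining <- v_i / v_0 * 100
  inhib <- 100 - remaining
  structure(inhib, remaining = remaining,
            clipped = any(inhib < 0 | inhib > 100))
}

#' Constrained four-parameter logistic IC50 fit
#'
#' Fits remaining activity (percent) against concentration with the 4PL
#' model constrained to bottom = 0 and top = 100:
#' \deqn{y = 100 / (1 + 10^{(\log_{10} c - \log_{10} IC_{50}) h})}
#' by Levenberg-Marquardt least squares on (log10 IC50, h).  Start values
#' are the concentration closest to 50 percent remaining and a unit Hill
#' slope.
#'
#' @param concentration concentrations (any consistent unit; at least four
#'   distinct values).
#' @param remaining percent remaining activity at each concentration
#'   (replicates allowed: supply repeated concentrations).
#' @param maxIter maximum optimizer iterations.
#' @return List: \code{ic50}, \code{ic50_se}, \code{hill}, \code{hill_se},
#'   \code{sse}, \code{converged}, \code{in_range} (IC50 inside the tested
#'   concentration range), \code{fit} (the nls object).  Non-convergence
#'   returns \code{converged = FALSE} with diagnostics in
#'   \code{message} — never a silent fallback.
#' @examples
#' conc <- c(0.1, 0.5, 1, 2, 5, 20)
#' rem <- 100 / (1 + 10^((log10(conc) - log10(1.35)) * 1))
#' fit4PL(conc, rem)$ic50  # 1.35
#' @export
fit4PL <- function(concentration, remaining, maxIter = 200) {
  keep <- concentration > 0 & is.finite(remaining)
  concentration <- concentration[keep]; remaining <- remaining[keep]
  if (length(unique(concentration)) < 4L)
    stop("need at least four distinct positive concentrations")
  lc <- log10(concentration)
  start <- list(logIC50 = lc[which.min(abs(remaining - 50))], h = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      remaining ~ 100 / (1 + 10^((lc - logIC50) * h)),
      start = start, control = minpack.lm::nls.lm.control(maxiter = maxIter)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(ic50 = NA_real_, ic50_se = NA_real_, hill = NA_real_,
                hill_se = NA_real_, sse = NA_real_, converged = FALSE,
                in_range = NA, message = conditionMessage(fit), fit = NULL))
  co <- summary(fit)$coefficients
  ic50 <- 10^co["logIC50", "Estimate"]
  # delta-method SE on the linear scale
  ic50_se <- ic50 * log(10) * co["logIC50", "Std. Error"]
  list(ic50 = ic50, ic50_se = ic50_se,
       hill = co["h", "Estimate"], hill_se = co["h", "Std. Error"],
       sse = sum(stats::residuals(fit)^2), converged = TRUE,
       in_range = ic50 >= min(concentration) & ic50 <= max(concentration),
       message = NULL, fit = fit)
}

#' One-phase decay fit and half-life
#'
#' Fits percent-remaining against time with y = 100 exp(-k t) (plateau
#' fixed at zero) and reports the elimination rate and half-life
#' ln(2) / k.  A series that increases overall cannot be an elimination
#' time-course and is rejected.
#'
#' @param time time points in hours (>= 3 points).
#' @param remaining percent remaining analyte at each time.
#' @return List: \code{k} (1/h), \code{half_life} (h), \code{sse},
#'   \code{converged}.
#' @examples
#' t <- c(0, 1, 2, 4, 8, 24)
#' fitDecay(t, 100 * 2^(-t / 6.7))$half_life  # 6.7
#' @export
fitDecay <- function(time, remaining) {
  if (length(time) < 3L) stop("need at least three time points")
  if (length(time) != length(remaining)) stop("length mismatch")
  if (stats::coef(stats::lm(remaining ~ time))[["time"]] > 0)
    stop("remaining analyte increases with time: not a decay series")
  start <- list(k = max(1e-6,
    -stats::coef(stats::lm(log(pmax(remaining, 1e-6) / 100) ~ time + 0))[[1]]))
  fit <- tryCatch(
    minpack.lm::nlsLM(remaining ~ 100 * exp(-k * time), start = start,
                      lower = 1e-12),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(k = NA_real_, half_life = NA_real_, sse = NA_real_,
                converged = FALSE, message = conditionMessage(fit)))
  k <- stats::coef(fit)[["k"]]
  list(k = k, half_life = log(2) / k,
       sse = sum(stats::residuals(fit)^2), converged = TRUE)
}

#' Rank extracts by potency and correlate with peptide content
#'
#' Sorts extracts by IC50 (ascending: most potent first) and reports the
#' Spearman rank correlation between the MS1 peptide-signal count and the
#' IC50.  Sign convention: more peptides associated with lower IC50
#' (higher potency) gives rho = -1.
#'
#' @param extracts data.frame with columns \code{extract}, \code{ic50},
#'   \code{peptide_count}.
#' @return List: \code{table} (sorted data.frame with rank column),
#'   \code{rho} (Spearman correlation of peptide_count vs ic50).
#' @export
rankExtracts <- function(extracts) {
  stopifnot(all(c("extract", "ic50", "peptide_count") %in% names(extracts)))
  if (nrow(extracts) < 3L) stop("need at least three extracts")
  o <- order(extracts$ic50)
  tab <- extracts[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  rho <- stats::cor(extracts$peptide_count, extracts$ic50,
                    method = "spearman")
  list(table = tab, rho = rho)
}
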