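# Independent oracles: hard-coded constants and brute-force routines that
# never touch the package's own mass tables or digestion logic.

ORACLE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

# naive summation: residues + terminal water (linear) + mods - 2H per SS
oracle_mass <- function(seq, cyclic = FALSE, n_ss = 0, n_cam = 0,
                        amide = FALSE) {
  m <- sum(ORACLE_MONO[strsplit(seq, "")[[1]]])
  if (!cyclic) m <- m + 18.010565
  m - n_ss * 2.015650 + n_cam * 57.021464 - amide * 0.984016
}

# position-by-position scan for cleavage sites on a linear or cyclic string
oracle_sites <- function(seq, after, blocked = character(0),
                         cyclic = FALSE) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  last <- if (cyclic) n else n - 1L
  out <- integer(0)
  for (i in seq_len(max(0L, last))) {
    nxt <- res[if (i == n) 1L else i + 1L]
    if (res[i] %in% after && !nxt %in% blocked) out <- c(out, i)
  }
  out
}

# all-rotations substring enumeration of cyclic digest products: every arc
# of the doubled string whose flanks are cleavage sites, with its internal
# missed-cleavage count
oracle_cyclic_digest <- function(seq, after, blocked = character(0),
                                 max_missed = Inf) {
  n <- nchar(seq)
  sites <- oracle_sites(seq, after, blocked, cyclic = TRUE)
  k <- length(sites)
  if (k == 0L) return(data.frame(sequence = character(0),
                                 n_missed = integer(0)))
  doubled <- paste0(seq, seq)
  onarc <- function(a, b) {       # arc opening after site a, ending at b
    end <- if (b > a) b else b + n
    substr(doubled, a + 1L, end)
  }
  out <- list()
  for (a in sites) for (b in sites) {
    arc <- onarc(a, b)
    len <- nchar(arc)
    inside <- vapply(sites, function(s) {
      pos <- if (s > a) s - a else s - a + n
      pos < len
    }, logical(1))
    missed <- if (a == b) k - 1L else sum(inside)
    if (missed <= max_missed)
      out[[length(out) + 1L]] <- data.frame(sequence = arc,
                                            n_missed = missed)
  }
  unique(do.call(rbind, out))
}

# running-sum b/y oracle for an unmodified or CAM-modified linear peptide
oracle_by <- function(seq, cam_sites = integer(0)) {
  res <- strsplit(seq, "")[[1]]
  m <- ORACLE_MONO[res]
  m[cam_sites] <- m[cam_sites] + 57.021464
  n <- length(res)
  list(b = cumsum(m)[-n] + 1.007276,
       y = cumsum(rev(m))[-n] + 18.010565 + 1.007276)
}

random_peptide <- function(len, alphabet = names(ORACLE_MONO)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
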