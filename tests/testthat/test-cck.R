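test_that("cysteine count is inferred from the reduction/alkylation shift", {
  # the printed psysol 3 ladder: +348.2 Da -> six cysteines
  est <- inferCysCount(psysol3Ladder())
  expect_equal(est$n_cys, 6L)
  expect_lt(est$residual, 0.1)
  expect_equal(inferCysCount(modificationLadder(1000, 1000))$n_cys, 0L)
  expect_equal(inferCysCount(modificationLadder(1000, 1232.12))$n_cys, 4L)
  expect_error(modificationLadder(1000, 900), "adds mass")
})

test_that("theoretical ladders give exact counts for n = 0..8", {
  for (n in 0:8) {
    est <- inferCysCount(modificationLadder(2500, 2500 + n * 58.029289))
    expect_equal(est$n_cys, n)
    expect_lt(est$residual, 1e-9)
  }
})

test_that("ring opening with water gain flags a cyclic backbone", {
  # printed values: alkylated 3557.4/3557.5, GluC-opened 3575.4/3575.5
  expect_true(inferCyclic(modificationLadder(3209.2, 3557.5,
                                             enzyme_opened = 3575.5),
                          nProducts = 1))
  # a linear control cut internally yields two lighter products
  expect_false(inferCyclic(modificationLadder(3209.2, 3557.5,
                                              enzyme_opened = 2000.0),
                           nProducts = 2))
})

test_that("noiseless simulated digests classify topology perfectly", {
  # the ring-opening diagnostic uses an enzyme with a single site: only
  # species where GluC cuts exactly once reproduce the Fig-2-style assay
  set.seed(71)
  species <- genCyclotide(30, seed = 71)
  rule <- enzymeRule("gluc")
  correct <- 0; tested <- 0; tested_lin <- 0
  for (p in species) {
    alk <- applyProtocol(p, reductionAlkylation(3, 6))
    if (length(cleavageSites(alk, rule)) != 1L) next
    d <- digestPeptide(alk, rule)
    lad <- modificationLadder(
      native = ionMz(peptideMass(p), "H", 1),
      alkylated = ionMz(peptideMass(alk), "H", 1),
      enzyme_opened = ionMz(d$mass[1], "H", 1))
    tested <- tested + 1
    if (isTRUE(as.logical(inferCyclic(lad, nrow(d))))) correct <- correct + 1
    # linear counterpart with one internal site yields two lighter
    # products and must never classify cyclic
    linp <- PeptideSpecies(pepSequence(alk), "linear",
                           modifications = "cam")
    dl <- digestPeptide(linp, rule, maxMissed = 0)
    if (nrow(dl) == 2) {
      ladl <- modificationLadder(
        native = ionMz(peptideMass(p), "H", 1),
        alkylated = ionMz(peptideMass(linp), "H", 1),
        enzyme_opened = ionMz(max(dl$mass), "H", 1))
      expect_false(as.logical(inferCyclic(ladl, nrow(dl))))
      tested_lin <- tested_lin + 1
    }
  }
  expect_gt(tested, 3)
  expect_gt(tested_lin, 3)
  expect_equal(correct, tested)
})

test_that("MS1 fingerprint counts peaks inside the window", {
  expect_equal(ms1Fingerprint(data.frame(mz = numeric(0),
                                         intensity = numeric(0)))$count, 0)
  pk <- data.frame(mz = c(1500, 2100, 2500, 3000, 3500, 3999, 4200, 5000),
                   intensity = 1)
  expect_equal(ms1Fingerprint(pk)$count, 5)
  expect_equal(nrow(ms1Fingerprint(pk)$peaks), 5)
})

test_that("fingerprint count recovers the Poisson mean of a seeded generator", {
  set.seed(81)
  lambda <- 12
  counts <- vapply(1:500, function(i) {
    n <- rpois(1, lambda)
    pk <- data.frame(mz = c(runif(n, 2000, 4000), runif(3, 500, 1900)),
                     intensity = 1)
    ms1Fingerprint(pk)$count
  }, numeric(1))
  expect_equal(mean(counts), lambda, tolerance = 0.05)
})

test_that("seeded spike-in dereplication marks exactly the expected set", {
  species <- genCyclotide(20, seed = 91)
  spiked <- species[1:12]
  peaks <- genMS1(spiked, mzSigma = 0, naProb = 0, nNoise = 15, seed = 92)
  tab <- dereplicate(species, peaks, tol = 0.25)
  # every spiked candidate is recovered exactly
  expect_true(all(tab$detected[1:12] == "y"))
  expect_true(all(abs(tab$error[1:12]) < 1e-9))
  # detection of the rest is decided purely by true-mass proximity: a
  # non-spiked candidate is flagged iff a peak falls within tolerance of
  # its oracle-computed [M+H]+ (mass dereplication cannot tell such
  # near-isobars apart)
  oracle_mh <- vapply(species, function(p)
    oracle_mass(pepSequence(p), cyclic = TRUE, n_ss = 3) + 1.007276,
    numeric(1))
  expected <- ifelse(vapply(oracle_mh, function(m)
    min(abs(peaks$mz - m)) <= 0.25, logical(1)), "y", "n")
  expect_equal(tab$detected, expected)
})

test_that("dereplication detection is monotone in tolerance", {
  species <- genCyclotide(10, seed = 101)
  peaks <- genMS1(species[1:5], mzSigma = 0.1, naProb = 0, seed = 102)
  tols <- c(0.05, 0.1, 0.25, 0.5)
  dets <- lapply(tols, function(tl)
    dereplicate(species, peaks, tol = tl)$detected == "y")
  for (i in seq_len(length(tols) - 1))
    expect_true(all(dets[[i + 1]][dets[[i]]]))
})
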