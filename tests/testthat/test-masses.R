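test_that("single residues and trivial species match hand values", {
  expect_equal(peptideMass(PeptideSpecies("G")), 75.0320, tolerance = 1e-4)
  # head-to-tail cycle carries no terminal water
  expect_equal(peptideMass(PeptideSpecies("GG", "cyclic")), 114.0429,
               tolerance = 1e-4)
  expect_equal(ionMz(1000, "H", 1), 1001.0073, tolerance = 1e-4)
})

test_that("peptideMass agrees with the naive summation oracle", {
  set.seed(11)
  for (i in 1:100) {
    s <- random_peptide(sample(3:25, 1))
    cyc <- runif(1) < 0.5
    cys <- which(strsplit(s, "")[[1]] == "C")
    n_ss <- if (length(cys) >= 2) sample(0:(length(cys) %/% 2), 1) else 0L
    free <- length(cys) - 2L * n_ss
    n_cam <- if (free > 0) sample(0:free, 1) else 0L
    ssb <- if (n_ss) lapply(seq_len(n_ss), function(k)
      cys[c(2 * k - 1, 2 * k)]) else list()
    camsites <- setdiff(cys, unlist(ssb))[seq_len(n_cam)]
    p <- PeptideSpecies(s, if (cyc) "cyclic" else "linear",
                        disulfides = ssb,
                        modifications = if (n_cam)
                          data.frame(name = "carbamidomethyl",
                                     site = camsites) else NULL)
    expect_equal(peptideMass(p),
                 oracle_mass(s, cyclic = cyc, n_ss = n_ss, n_cam = n_cam),
                 tolerance = 1e-5, info = s)
  }
})

test_that("carbamidomethylated linear peptide matches hand-summed oracle", {
  p <- PeptideSpecies("ACDE",
                      modifications = data.frame(name = "carbamidomethyl",
                                                 site = 2L))
  expect_equal(peptideMass(p), oracle_mass("ACDE", n_cam = 1),
               tolerance = 1e-5)
})

test_that("cyclization removes one water and mass is rotation invariant", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_peptide(sample(5:20, 1))
    lin <- peptideMass(PeptideSpecies(s))
    cyc <- peptideMass(PeptideSpecies(s, "cyclic"))
    expect_equal(lin - cyc, 18.010565, tolerance = 1e-9)
    rots <- vapply(seq_len(nchar(s)), function(k)
      peptideMass(PeptideSpecies(paste0(substr(s, k, nchar(s)),
                                        substr(s, 1, k - 1)), "cyclic")),
      numeric(1))
    expect_true(all(abs(rots - cyc) < 1e-9))
  }
})

test_that("modification protocols are additive with applyProtocol", {
  p3 <- psysol3()
  prots <- list(reductionAlkylation(3, 6),
                rbind(reductionAlkylation(3, 6), ringOpening()),
                reductionAlkylation(1, 2))
  for (pr in prots)
    expect_equal(peptideMass(applyProtocol(p3, pr)),
                 peptideMass(p3) + modificationDelta(p3, pr),
                 tolerance = 1e-6)
  expect_equal(modificationDelta(p3, reductionAlkylation(0, 0)[0, ]), 0)
})

test_that("invalid species and protocols are rejected with positions", {
  expect_error(peptideMass(PeptideSpecies("ACBDE")), "position 3")
  expect_error(PeptideSpecies("ACDE", disulfides = list(c(1, 2))),
               "point at Cys")
  # alkylating a Cys still disulfide-bonded
  expect_error(modificationDelta(psysol3(),
                                 data.frame(name = "carbamidomethyl", n = 1)),
               "still closed")
  expect_error(PeptideSpecies("ACDE", "cyclic",
               modifications = data.frame(name = "amidation",
                                          site = NA_integer_)) |>
                 peptideMass(), "terminus")
  expect_error(ionMz(-5, "H", 1), "positive")
  expect_error(ionMz(100, "H", 0), "charge")
})

test_that("average-mass scale is heavier than monoisotopic", {
  tab <- residueMassTable()
  expect_setequal(tab$residue, names(ORACLE_MONO))
  expect_true(all(tab$monoisotopic_mass < tab$average_mass))
  expect_true(all(tab$monoisotopic_mass > 0))
  p <- PeptideSpecies("ACDEFGHIK")
  expect_gt(peptideMass(p, "average"), peptideMass(p, "monoisotopic"))
})
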