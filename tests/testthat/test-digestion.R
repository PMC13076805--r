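alkylated_psysol3 <- function()
  applyProtocol(psysol3(), reductionAlkylation(3, 6))

test_that("cleavage sites honour specificity, blocking and the cyclic wrap", {
  p3 <- psysol3()
  # single Arg -> one tryptic site; single Glu -> one GluC site
  expect_length(cleavageSites(p3, enzymeRule("trypsin")), 1)
  expect_length(cleavageSites(p3, enzymeRule("gluc")), 1)
  # K-P bond is blocked
  expect_length(cleavageSites(PeptideSpecies("KPAA"), enzymeRule("trypsin")),
                0)
  # wrap: cyclic peptide ending in K has a site between last and first
  expect_equal(cleavageSites(PeptideSpecies("AAK", "cyclic"),
                             enzymeRule("trypsin")), 3L)
  expect_length(cleavageSites(PeptideSpecies("AAK"), enzymeRule("trypsin")),
                0)
})

test_that("cleavage sites equal an independent position scan", {
  set.seed(21)
  rule <- enzymeRule("chymotrypsin")
  expect_equal(cleavageSites(psysol3(), rule),
               oracle_sites(pepSequence(psysol3()), rule@cleaveAfter,
                            rule@blockedBefore, cyclic = TRUE))
  for (i in 1:25) {
    s <- random_peptide(sample(6:15, 1))
    for (cyc in c(TRUE, FALSE)) {
      p <- PeptideSpecies(s, if (cyc) "cyclic" else "linear")
      expect_equal(cleavageSites(p, rule),
                   oracle_sites(s, rule@cleaveAfter, rule@blockedBefore,
                                cyclic = cyc), info = s)
    }
  }
})

test_that("single-site digestion of a ring yields the opened full length", {
  tr <- digestPeptide(alkylated_psysol3(), enzymeRule("trypsin"))
  expect_equal(nrow(tr), 1)
  expect_true(tr$ring_opened_full_length)
  expect_equal(nchar(tr$sequence), 30)
  # ring opening gains exactly one water
  expect_equal(tr$mass - peptideMass(alkylated_psysol3()), 18.010565,
               tolerance = 1e-6)
  # cyclic peptide with zero sites: empty digest
  expect_equal(nrow(digestPeptide(PeptideSpecies("AAGG", "cyclic"),
                                  enzymeRule("trypsin"))), 0)
})

test_that("two-site GluC+trypsin digest yields the two complementary arcs", {
  gt <- digestPeptide(alkylated_psysol3(),
                      list(enzymeRule("gluc"), enzymeRule("trypsin")),
                      maxMissed = 0)
  expect_setequal(gt$sequence, c("TCILGTCYTPGCSCSTYR", "LCLNNGLPTCFE"))
  # wrap-around arc is written start > end
  arc2 <- gt[gt$sequence == "LCLNNGLPTCFE", ]
  expect_gt(arc2$start, arc2$end)
  expect_equal(arc2$start, 26L)
  expect_equal(arc2$end, 7L)
  # fragment masses carry the CAM groups inside each arc
  expect_equal(gt$mass[gt$sequence == "TCILGTCYTPGCSCSTYR"],
               oracle_mass("TCILGTCYTPGCSCSTYR", n_cam = 4),
               tolerance = 1e-4)
  expect_equal(arc2$mass, oracle_mass("LCLNNGLPTCFE", n_cam = 2),
               tolerance = 1e-4)
})

test_that("cyclic digestion equals all-rotations substring enumeration", {
  set.seed(33)
  rule <- enzymeRule("trypsin")
  for (i in 1:30) {
    s <- random_peptide(sample(6:15, 1))
    p <- PeptideSpecies(s, "cyclic")
    for (mm in c(0, 1, Inf)) {
      got <- digestPeptide(p, rule, maxMissed = mm)
      want <- oracle_cyclic_digest(s, rule@cleaveAfter, rule@blockedBefore,
                                   max_missed = mm)
      expect_setequal(paste(got$sequence, got$n_missed),
                      paste(want$sequence, want$n_missed))
    }
  }
})

test_that("linear digestion enumerates bounded sub-peptides", {
  p <- PeptideSpecies("AKGGKAA")
  d0 <- digestPeptide(p, enzymeRule("trypsin"), maxMissed = 0)
  expect_setequal(d0$sequence, c("AK", "GGK", "AA"))
  d1 <- digestPeptide(p, enzymeRule("trypsin"), maxMissed = 1)
  expect_setequal(d1$sequence, c("AK", "GGK", "AA", "AKGGK", "GGKAA"))
  # sub-peptide masses gain the terminal water
  expect_equal(d0$mass[d0$sequence == "GGK"], oracle_mass("GGK"),
               tolerance = 1e-4)
})

test_that("complete digests conserve mass and tile the ring exactly once", {
  set.seed(41)
  rule <- enzymeRule("chymotrypsin")
  tried <- 0
  for (i in 1:40) {
    s <- random_peptide(sample(8:15, 1))
    p <- PeptideSpecies(s, "cyclic")
    k <- length(cleavageSites(p, rule))
    if (k < 2) next
    tried <- tried + 1
    d0 <- digestPeptide(p, rule, maxMissed = 0)
    d0 <- d0[!d0$ring_opened_full_length, ]
    expect_equal(sum(d0$mass) - nrow(d0) * 18.010565, peptideMass(p),
                 tolerance = 1e-4)
    expect_equal(sum(nchar(d0$sequence)), nchar(s))
  }
  expect_gt(tried, 5)
})

test_that("product count is non-decreasing in the missed-cleavage bound", {
  set.seed(55)
  rule <- enzymeRule("trypsin")
  for (i in 1:10) {
    p <- PeptideSpecies(random_peptide(12), "cyclic")
    counts <- vapply(c(0, 1, 2, Inf), function(mm)
      nrow(digestPeptide(p, rule, maxMissed = mm)), numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})
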