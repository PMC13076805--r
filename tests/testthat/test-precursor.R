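test_that("six-frame translation matches a naive codon walk", {
  expect_equal(sixFrameTranslate("ATGGGA")[["+1"]], "MG")
  expect_error(sixFrameTranslate("ATGXGA"), "position 4")

  codon_table <- Biostrings::GENETIC_CODE
  naive_translate <- function(s, off) {
    n <- nchar(s) - off
    n <- n - n %% 3
    if (n < 3) return("")
    codons <- substring(s, off + seq(1, n, 3), off + seq(3, n, 3))
    paste(codon_table[codons], collapse = "")
  }
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  set.seed(111)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(60:120, 1),
                      replace = TRUE), collapse = "")
    fr <- sixFrameTranslate(s)
    rc <- revcomp(s)
    for (o in 0:2) {
      expect_equal(fr[[paste0("+", o + 1)]], naive_translate(s, o), info = s)
      expect_equal(fr[[paste0("-", o + 1)]], naive_translate(rc, o), info = s)
    }
    # strand symmetry: frame -1 of S equals frame +1 of revcomp(S)
    expect_equal(fr[["-1"]], sixFrameTranslate(rc)[["+1"]])
  }
})

test_that("an embedded precursor is found at the planted frame and span", {
  species <- genCyclotide(1, seed = 121)
  tx <- genTranscripts(species, seed = 122)
  hits <- scanPrecursors(tx$contigs,
                         queries = canonicalRotation(species[[1]]))
  expect_gte(nrow(hits), 1)
  expect_equal(hits$frame[1], tx$truth$frame[1])
  mat <- extractMature(hits[1, ])
  expect_equal(mat$sequence, tx$truth$mature[1])
  # predicted mass equals the species' cyclic oxidized [M+H]+
  expect_equal(mat$mz, ionMz(peptideMass(species[[1]]), "H", 1),
               tolerance = 1e-6)
})

test_that("random contigs yield no hits at a stringent score", {
  set.seed(131)
  contigs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = ""),
    character(1))
  names(contigs) <- paste0("rand", 1:5)
  hits <- scanPrecursors(contigs, queries = canonicalRotation(psysol3()),
                         minScore = 40)
  expect_equal(nrow(hits), 0)
})

test_that("reverse-strand embeddings are found at negative frames", {
  set.seed(141)
  found_minus <- FALSE
  for (s in 1:10) {
    species <- genCyclotide(1, seed = 1000 + s)
    tx <- genTranscripts(species, seed = 2000 + s)
    if (!startsWith(tx$truth$frame[1], "-")) next
    hits <- scanPrecursors(tx$contigs,
                           queries = canonicalRotation(species[[1]]))
    expect_gte(nrow(hits), 1)
    expect_equal(hits$frame[1], tx$truth$frame[1])
    found_minus <- TRUE
  }
  expect_true(found_minus)
})

test_that("planted mature domains violating the Cys invariant are rejected", {
  # a 4-Cys mature domain cannot qualify as cyclotide-like
  prot <- paste0("MALLLVVAAAFAAXSSEA", "KDTTLVPE",
                 "GASCGETCVLLPCAAPGCTCLLLHSFRN", "SLPAA")
  prot <- gsub("X", "T", prot)
  ann <- data.frame(contig = "c1", frame = "+1", protein = prot,
                    aa_start = 1, aa_end = nchar(prot),
                    hit_start = 27, hit_end = 54, query = "q", score = 50)
  expect_warning(res <- extractMature(ann), "no span")
  expect_null(res)
})

test_that("planted-precursor recovery across 50 seeded contigs is near-total", {
  species <- genCyclotide(50, seed = 151)
  tx <- genTranscripts(species, seed = 152)
  queries <- vapply(species, canonicalRotation, character(1))
  hits <- scanPrecursors(tx$contigs, queries)
  recovered <- 0
  for (i in seq_along(species)) {
    h <- hits[hits$contig == tx$truth$contig[i], , drop = FALSE]
    if (!nrow(h)) next
    mat <- tryCatch(extractMature(h[1, ]), warning = function(w) NULL)
    if (!is.null(mat) && mat$sequence == tx$truth$mature[i])
      recovered <- recovered + 1
  }
  expect_gte(recovered, 49)
})

test_that("detection table deduplicates and delegates to dereplication", {
  species <- genCyclotide(10, seed = 161)
  tx <- genTranscripts(species, seed = 162)
  hits <- scanPrecursors(tx$contigs,
                         vapply(species, canonicalRotation, character(1)))
  mats <- lapply(seq_len(nrow(hits)), function(i)
    tryCatch(extractMature(hits[i, ]), warning = function(w) NULL))
  # spike 7 of 10 into the peak list: 7 detected, 3 not
  peaks <- genMS1(species[1:7], mzSigma = 0, naProb = 0, seed = 163)
  tab <- detectionTable(c(mats, mats), peaks, tol = 0.25)  # duplicates in
  expect_lte(nrow(tab), 10)
  expect_false(anyDuplicated(tab$sequence) > 0)
  spiked <- vapply(species[1:7], canonicalRotation, character(1))
  expect_setequal(tab$sequence[tab$detected == "y"],
                  intersect(tab$sequence, spiked))
  # empty peak list: all undetected
  tab0 <- detectionTable(mats, data.frame(mz = numeric(0),
                                          intensity = numeric(0)), 0.25)
  expect_true(all(tab0$detected == "n"))
})
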