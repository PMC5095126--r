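test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(trypticDigest("AAAKBBBRCCC"), c("AAAK", "BBBR", "CCC"))
  expect_equal(trypticDigest("AAKPGG"), "AAKPGG")
  # brute-force enumeration of cleavage patterns for AKRC, 1 missed site
  expect_setequal(trypticDigest("AKRC", missedCleavages = 1),
                  c("AK", "R", "C", "AKR", "RC"))

  # zero-missed-cleavage peptides concatenate back to the sequence (the
  # output is duplicate-free, so build sequences with distinct segments)
  set.seed(3)
  for (i in 1:20) {
    segs <- unique(vapply(1:8, function(j)
      paste(c(sample(c("A", "G", "L", "P", "S", "T"),
                     sample(2:6, 1), TRUE),
              sample(c("K", "R"), 1)), collapse = ""), character(1)))
    s <- paste(segs, collapse = "")
    expect_equal(paste(trypticDigest(s), collapse = ""), s)
  }
})

test_that("peptide masses and m/z follow monoisotopic arithmetic", {
  # AAAAAAAK: 7 x Ala (71.03711) + Lys (128.09496) + water
  expect_equal(peptideMass("AAAAAAAK"),
               7 * 71.03711 + 128.09496 + 18.0105646863, tolerance = 1e-9)
  # fixed carbamidomethylation on cysteine
  expect_equal(peptideMass("CK") - peptideMass("AK"),
               103.00919 + 57.02146 - 71.03711, tolerance = 1e-9)
  m <- peptideMass("AAAAAAAK")
  expect_equal(peptideMz("AAAAAAAK", 2), (m + 2 * 1.007276466) / 2)
})

test_that("observable counting applies the m/z window and length range", {
  expect_equal(observableCount(character(0), digest = FALSE), 0)

  # a ~1000 Da peptide at charge 2 sits near m/z 501, inside 300-1250
  pep <- "AAAAAAAAAAAAK"  # 12 x Ala + K + water = 998.54 Da
  expect_equal(observablePeptides(pep, digest = FALSE), pep)
  mz <- peptideMz(pep, 2)
  expect_gt(mz, 300); expect_lt(mz, 1250)

  # dipeptides fall below the minimum length
  expect_equal(observableCount("AK", digest = FALSE), 0)

  seqc <- "AAAAAAAAAAAAKGGGGGGGGGGGRTTK"
  expect_equal(observableCount(seqc),
               length(observablePeptides(seqc)))
})

test_that("emPAI follows its closed form and monotonicity", {
  expect_equal(empaiValue(0, 10), 0)
  expect_equal(empaiValue(10, 10), 9)
  expect_equal(empaiValue(2, 10), 10^0.2 - 1, tolerance = 1e-12)

  # strictly increasing in observed, decreasing in observable
  ks <- 0:10
  vals <- empaiValue(ks, 10)
  expect_true(all(diff(vals) > 0))
  obs <- empaiValue(3, 3:12)
  expect_true(all(diff(obs) < 0))
})

test_that("emPAI fold changes track the generating abundance", {
  expect_equal(empaiFoldChange(
    data.frame(protein_id = "P1", empai = 2),
    data.frame(protein_id = "P1", empai = 2))$log2_fc, 0)
  fc0 <- empaiFoldChange(
    data.frame(protein_id = "P1", empai = 0),
    data.frame(protein_id = "P1", empai = 2))
  expect_false(fc0$defined)
  expect_true(is.na(fc0$log2_fc))

  # at the study's differential fraction (~45% of proteins changing) the
  # emPAI fold change correlates with the truth
  truth <- generateTruth(nProteins = 200, fracDa = 0.45,
                         fracInterference = 0, seed = 9)
  seqs <- generateProteinSequences(truth, seed = 10)
  obs <- simulatePeptideObservations(truth, seqs, seed = 11)
  recs <- lapply(obs, function(o) empaiTable(seqs, o))
  fc <- empaiFoldChange(recs[[2]], recs[[1]])
  tp <- truthProteins(truth)
  i <- match(fc$protein_id[fc$defined], tp$protein_id)
  r <- cor(fc$log2_fc[fc$defined], tp$true_log2_fc[i])
  expect_gt(r, 0.6)
})
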