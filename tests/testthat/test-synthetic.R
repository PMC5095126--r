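test_that("ground truth honours the differential-abundance contract", {
  t0 <- generateTruth(nProteins = 100, fracDa = 0, seed = 1)
  expect_true(all(truthProteins(t0)$true_log2_fc == 0))

  t1 <- generateTruth(nProteins = 100, fracDa = 0.1, fcSet = 2, seed = 1)
  lfc <- truthProteins(t1)$true_log2_fc
  expect_equal(sum(lfc != 0), 10)
  expect_true(all(abs(lfc[lfc != 0]) == 1))

  expect_error(generateTruth(fcSet = c(2, -1)), "positive")

  # determinism and share normalization
  t2 <- generateTruth(nProteins = 100, fracDa = 0.1, fcSet = 2, seed = 1)
  expect_identical(truthFragments(t1), truthFragments(t2))
  shares <- tapply(truthFragments(t1)$share, truthFragments(t1)$peptide, sum)
  expect_equal(as.vector(shares), rep(1, length(shares)))

  # interference trend present iff flagged
  t3 <- generateTruth(nProteins = 50, fracInterference = 0.5, seed = 3)
  fr <- truthFragments(t3)
  expect_true(all((fr$intf_protonema > 0) == fr$interference))
})

test_that("noiseless simulation reproduces exact fold changes", {
  truth <- generateTruth(nProteins = 20, fracDa = 0.5, fcSet = 2,
                         fracInterference = 0, seed = 2)
  nm <- noiseModel(0, 0, 0, runScaleRange = c(1, 1), lod = 0)
  fe <- simulateFragmentTable(truth, defaultRunDesign(), nm, seed = 1)
  x <- intensities(fe)
  cd <- runDesign(fe)
  tp <- truthProteins(truth)
  fk <- fragmentKeys(fe)
  i <- match(fk$protein_id, tp$protein_id)
  # all runs of a sample type agree exactly
  for (s in unique(cd$sample_type)) {
    xs <- x[, cd$sample_type == s]
    expect_equal(apply(xs, 1, max) - apply(xs, 1, min),
                 rep(0, nrow(xs)), ignore_attr = TRUE)
  }
  # type-2 intensities are exactly 2^lfc times type 1
  r <- x[, cd$sample_type == "protoplast"][, 1] /
    x[, cd$sample_type == "protonema"][, 1]
  expect_equal(r, 2^tp$true_log2_fc[i], ignore_attr = TRUE)
})

test_that("simulation is deterministic and rejects bad designs", {
  truth <- generateTruth(nProteins = 10, seed = 1)
  a <- simulateFragmentTable(truth, seed = 4)
  b <- simulateFragmentTable(truth, seed = 4)
  expect_identical(intensities(a), intensities(b))

  one <- defaultRunDesign(sampleTypes = "protonema")
  expect_error(simulateFragmentTable(truth, one), "2 sample types")
})

test_that("empirical injection-level CV matches the configured CV", {
  truth <- generateTruth(nProteins = 40, fracDa = 0,
                         fragmentsPerPeptide = c(6, 8),
                         fracInterference = 0, seed = 5)
  design <- defaultRunDesign(nBio = 1, digReps = 1, nInj = 3)
  nm <- noiseModel(cvInjection = 0.1, cvDigestion = 0, cvBiological = 0,
                   runScaleRange = c(1, 1), lod = 0)
  fe <- simulateFragmentTable(truth, design, nm, seed = 6)
  x <- intensities(fe)
  cd <- runDesign(fe)
  cvs <- unlist(lapply(unique(cd$sample_type), function(s) {
    xs <- x[, cd$sample_type == s]
    apply(xs, 1, sd) / rowMeans(xs)
  }))
  expect_gt(length(cvs), 1000)
  expect_gt(mean(cvs), 0.08)
  expect_lt(mean(cvs), 0.12)
})

test_that("MRM simulation caps the peptide panel at 3 best flyers", {
  truth <- generateTruth(nProteins = 10, peptidesPerProtein = c(5, 6),
                         seed = 1)
  expect_warning(fe <- simulateMrmTable(truth, peptidesPerProtein = 4,
                                        seed = 1), "3 best-flyer")
  fk <- fragmentKeys(fe)
  npep <- tapply(fk$peptide, fk$protein_id, function(p) length(unique(p)))
  expect_true(all(npep <= 3))

  a <- simulateMrmTable(truth, seed = 2)
  b <- simulateMrmTable(truth, seed = 2)
  expect_identical(intensities(a), intensities(b))
})

test_that("simulated transcripts hit the target coupling", {
  truth <- generateTruth(nProteins = 100, fracDa = 0.3, seed = 7)
  e1 <- simulateTranscripts(truth, rho = 1, seed = 1)
  expect_equal(cor(e1$log2_fc, truthProteins(truth)$true_log2_fc), 1)

  t400 <- generateTruth(nProteins = 400, fracDa = 0.1, seed = 8)
  e0 <- simulateTranscripts(t400, rho = 0, seed = 2)
  expect_lt(abs(cor(e0$log2_fc, truthProteins(t400)$true_log2_fc)), 0.1)

  ex <- simulateTranscripts(truth, rho = 0, nExtraGenes = 50, seed = 3)
  expect_equal(sum(!(ex$gene_id %in% truthProteins(truth)$protein_id)), 50)

  expect_error(simulateTranscripts(truth, rho = 1.5), "rho")
})
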