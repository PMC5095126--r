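test_that("transition-list validation enforces the assay constraints", {
  tl <- data.frame(
    protein_id = c("P1", "P1", "P1", "P1"),
    peptide = c("GGGK",                 # too short
                "AAKAAAR",              # internal missed cleavage
                "AAKPAAAR",             # internal K before P: allowed
                "ELVISLIVESR"),
    charge = 2,
    fragment_id = "y3")
  res <- validateTransitionList(tl)
  expect_setequal(res$valid$peptide, c("AAKPAAAR", "ELVISLIVESR"))
  expect_true(any(grepl("length", res$violations$reason)))
  expect_true(any(grepl("missed cleavage", res$violations$reason)))

  # charge outside 2-4 is rejected
  tl$charge <- c(2, 2, 5, 2)
  res2 <- validateTransitionList(tl)
  expect_false("AAKPAAAR" %in% res2$valid$peptide)

  # a protein with 5 peptides keeps its 3 by total area
  tl3 <- data.frame(protein_id = "P9",
                    peptide = paste0(c("AAAAA", "CCCCC", "DDDDD",
                                       "EEEEE", "FFFFF"), "R"),
                    charge = 3, fragment_id = "y4", area = c(5, 4, 3, 2, 1))
  res3 <- validateTransitionList(tl3)
  expect_setequal(res3$valid$peptide, c("AAAAAR", "CCCCCR", "DDDDDR"))
})

test_that("MRM normalization equalizes injections and preserves signal", {
  truth <- generateTruth(nProteins = 12, fracDa = 0.25, fcSet = 2,
                         fracInterference = 0, seed = 21)
  nm0 <- noiseModel(0, 0, 0, runScaleRange = c(1, 1), lod = 0)
  fe <- simulateMrmTable(truth, noise = nm0, seed = 1)

  # identical duplicate injections -> all factors 1
  norm <- normalizeMrm(fe)
  for (f in norm$factors$injection)
    expect_equal(unname(f), rep(1, length(f)), tolerance = 1e-12)

  # scaling one injection 3x leaves the normalized table unchanged up to a
  # global constant (factors keep geometric mean 1), so every fold change
  # and between-sample contrast is untouched
  x <- intensities(fe)
  x[, 3] <- x[, 3] * 3
  fe3 <- FragmentExperiment(x, fragmentKeys(fe), runDesign(fe))
  norm3 <- normalizeMrm(fe3)
  lr <- log(norm3$peptides) - log(norm$peptides)
  expect_lt(max(lr) - min(lr), 1e-12)
  expect_equal(testMrm(norm3)$log2_fc, testMrm(norm)$log2_fc,
               tolerance = 1e-12)

  # noiseless fold changes recover exactly
  q <- testMrm(norm)
  tp <- truthProteins(truth)
  i <- match(q$protein_id, tp$protein_id)
  expect_equal(q$log2_fc, tp$true_log2_fc[i], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("BH control in testMrm matches the brute-force step-up", {
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_brute(p), tolerance = 0)
  }
  # the worked step-up example
  expect_equal(bh_brute(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 4 * 0.04 / 3, 0.5))
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.5), "BH"),
               bh_brute(c(0.01, 0.02, 0.04, 0.5)))
  # single test: FDR equals p
  expect_equal(bh_brute(0.03), 0.03)

  truth <- generateTruth(nProteins = 20, fracDa = 0.2, seed = 22)
  fe <- simulateMrmTable(truth, seed = 2)
  q <- quiet(testMrm(normalizeMrm(fe)))
  expect_equal(q$fdr, bh_brute(q$p_value), tolerance = 0)
  expect_equal(q$significant, !is.na(q$fdr) & q$fdr < 0.05)
})

test_that("group swap flips fold changes and keeps p-values", {
  truth <- generateTruth(nProteins = 15, fracDa = 0.2, seed = 23)
  fe <- simulateMrmTable(truth, seed = 3)
  norm <- normalizeMrm(fe)
  q1 <- testMrm(norm)
  q2 <- testMrm(norm, contrast = rev(attr(q1, "contrast")))
  i <- match(q1$protein_id, q2$protein_id)
  expect_equal(q1$log2_fc, -q2$log2_fc[i], tolerance = 1e-12)
  expect_equal(q1$p_value, q2$p_value[i], tolerance = 1e-12)
})

test_that("platform comparison is a plain Pearson r over shared proteins", {
  sw <- data.frame(protein_id = c("P1", "P2", "P3", "P4"),
                   log_B_fc = c(1, 2, -1, 0.5))
  mr <- data.frame(protein_id = c("P1", "P2", "P3", "P4"),
                   log2_fc = c(1, 2, -1, 0.5) * log(1.4) / log(2))
  expect_equal(comparePlatforms(sw, mr)$r, 1)
  mr$log2_fc <- -mr$log2_fc
  expect_equal(comparePlatforms(sw, mr)$r, -1)
  expect_error(comparePlatforms(sw[1:2, ], mr[1:2, ]), "3 shared")
})
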