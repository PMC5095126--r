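test_that("scale normalization equalizes median log intensities", {
  design <- tiny_design(nBio = 1, nInj = 2)[1:2, ]
  m <- matrix(rlnorm(24, 5, 1), ncol = 2)
  fe <- tiny_fe(m, design)

  # identical runs need no correction
  fe_eq <- tiny_fe(cbind(m[, 1], m[, 1]), design)
  res <- scaleNormalize(fe_eq, minSharedRows = 2)
  expect_equal(unname(res$factors), c(1, 1))

  # run B = 2 x run A: closed-form factors (sqrt(2), 1/sqrt(2))
  fe2 <- tiny_fe(cbind(m[, 1], 2 * m[, 1]), design)
  res2 <- scaleNormalize(fe2, minSharedRows = 2)
  expect_equal(unname(res2$factors), c(sqrt(2), 1 / sqrt(2)),
               tolerance = 1e-12)
  xn <- intensities(res2$fe)
  expect_equal(xn[, 1], xn[, 2])

  # factors always multiply to one; renormalizing is a no-op
  res3 <- scaleNormalize(fe, minSharedRows = 2)
  expect_equal(prod(res3$factors), 1, tolerance = 1e-12)
  res4 <- scaleNormalize(res3$fe, minSharedRows = 2)
  expect_equal(unname(res4$factors), c(1, 1), tolerance = 1e-12)

  expect_warning(scaleNormalize(fe, runs = design$run_id[1]), ">= 2 runs")
  fe_nil <- tiny_fe(matrix(c(1, NA, NA, 1), 2), design)
  expect_error(scaleNormalize(fe_nil, minSharedRows = 1), "no rows shared")
})

test_that("averaging collapses a level by the mean of logs", {
  design <- tiny_design(nBio = 1, nInj = 3)
  m <- matrix(exp(c(1, 2, 3, 1, 2, 3)), nrow = 1) # logs 1,2,3 per type
  fe <- tiny_fe(m, design)
  avg <- averageLevel(fe, "injection")
  expect_equal(ncol(avg), 2)
  expect_equal(unname(intensities(avg)[1, ]), c(exp(2), exp(2)))

  m2 <- rbind(m, rep(NA, 6))
  fe2 <- tiny_fe(m2, design)
  avg2 <- averageLevel(fe2, "injection")
  expect_true(all(is.na(intensities(avg2)[2, ])))

  expect_error(averageLevel(fe, "banana"), "unknown level")

  # identical replicates average to themselves
  fe3 <- tiny_fe(matrix(5, 1, 6), design)
  expect_equal(unname(intensities(averageLevel(fe3, "injection"))[1, ]),
               c(5, 5))
})

test_that("cross-sample normalization removes a pure scale difference", {
  set.seed(13)
  x <- matrix(rlnorm(40, 8, 1), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  x[, 2] <- 3 * x[, 1]
  res <- crossSampleNormalize(x)
  d <- log(res$x[, 1]) - log(res$x[, 2])
  expect_equal(median(d), 0, tolerance = 1e-12)
  expect_equal(prod(res$factors), 1, tolerance = 1e-12)

  one <- x[, 1, drop = FALSE]
  expect_equal(unname(crossSampleNormalize(one)$factors), 1)

  expect_error(crossSampleNormalize(x[1:5, ]), "insufficient overlap")
})

test_that("the median shift shrugs off a differential minority", {
  set.seed(17)
  n <- 200
  base <- rlnorm(n, 8, 1)
  fc <- rep(1, n); fc[1:20] <- 4    # 10% truly 4-fold up
  x <- cbind(s1 = base * exp(rnorm(n, 0, 0.1)),
             s2 = base * fc * exp(rnorm(n, 0, 0.1)))
  res <- crossSampleNormalize(x)
  shift_log2 <- log2(res$factors[2] / res$factors[1])
  expect_lt(abs(shift_log2), 0.05)
})

test_that("the cascade is invariant to rescaling any single run", {
  st <- interference_study()
  filt <- st$pipeline$filtered
  c1 <- quiet(runCascade(filt, levels = c("digestion", "biological")))
  q1 <- callDaps(c1$bioRep)
  for (j in c(1, 7)) {
    x <- intensities(filt)
    x[, j] <- x[, j] * 10
    filt2 <- FragmentExperiment(x, fragmentKeys(filt), runDesign(filt))
    c2 <- quiet(runCascade(filt2, levels = c("digestion", "biological")))
    q2 <- callDaps(c2$bioRep)
    expect_lt(max(abs(q2$log_B_fc - q1$log_B_fc)) * log(1.4), 1e-6)
  }
})

test_that("a design without digestion replicates yields a 3-stage cascade", {
  truth <- generateTruth(nProteins = 15, fracDa = 0, fracInterference = 0,
                         seed = 3)
  design <- defaultRunDesign(nBio = 3, digReps = 1, nInj = 2)
  fe <- simulateFragmentTable(truth, design, noiseModel(lod = 0), seed = 1)
  s1 <- averageLevel(fe, "injection")
  cd <- runDesign(s1)
  cd$dig_rep <- NULL
  s1 <- FragmentExperiment(intensities(s1), fragmentKeys(s1), cd)
  expect_warning(res <- runCascade(s1, levels = c("digestion",
                                                  "biological")),
                 "digestion")
  expect_equal(ncol(res$sampleType), 2)
})
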