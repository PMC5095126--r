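test_that("spectral contrast angle matches its defining geometry", {
  expect_equal(spectralAngle(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(spectralAngle(c(1, 0), c(0, 1)), 0)
  # theta = pi/4 between (1,1) and (1,0), so SA = 1 - 2*(pi/4)/pi = 0.5
  expect_equal(spectralAngle(c(1, 1), c(1, 0)), 0.5)

  expect_error(spectralAngle(c(0, 0), c(1, 1)), "all-zero")
  expect_error(spectralAngle(c(1, 2), c(1, 2, 3)), "length")
})

test_that("spectral angle is symmetric, bounded and scale invariant", {
  set.seed(11)
  for (i in 1:200) {
    a <- rlnorm(3); b <- rlnorm(3); c <- runif(1, 0.1, 10)
    sa <- spectralAngle(a, b)
    expect_gte(sa, 0); expect_lte(sa, 1)
    expect_equal(sa, spectralAngle(b, a))
    expect_equal(sa, spectralAngle(c * a, b), tolerance = 1e-12)
    expect_equal(sa, sa_direct(a, b), tolerance = 1e-12)
  }
})

test_that("condition-level trends reflect sample means and completeness", {
  design <- tiny_design(nBio = 2, nInj = 1)
  m <- rbind(c(5, 5, 5, 5),        # constant
             c(2, 2, 4, 4),        # doubled in type B
             c(NA, NA, 3, 3))      # missing in type A
  fe <- tiny_fe(m, design)
  tr <- fragmentTrends(fe)
  expect_equal(unname(tr$trends[1, ]), c(5, 5))
  expect_equal(unname(tr$trends[2, ]), c(2, 4))
  expect_equal(tr$incomplete, c(FALSE, FALSE, TRUE), ignore_attr = TRUE)
})

test_that("greedy cluster search isolates trend-consistent groups", {
  # five identical trends form one reliable cluster
  tr <- matrix(rep(c(1, 2), each = 5), nrow = 5)
  rownames(tr) <- paste0("f", 1:5)
  cl <- findClusters(tr, tau = 0.95, minTrend = 3)
  expect_length(cl$clusters, 1)
  expect_setequal(cl$reliable, rownames(tr))

  # two consistent + one orthogonal cannot reach the minimum trend count
  tr2 <- rbind(f1 = c(1, 0), f2 = c(2, 0), f3 = c(0, 1))
  cl2 <- findClusters(tr2, tau = 0.95, minTrend = 3)
  expect_length(cl2$reliable, 0)

  # 4 parallel + 3 mutually-parallel orthogonal trends: two clusters, the
  # 4-member one is the reliable set (brute-force confirms maximality)
  tr3 <- rbind(a1 = c(1, 2), a2 = c(2, 4), a3 = c(3, 6), a4 = c(0.5, 1),
               b1 = c(2, 0.1), b2 = c(4, 0.2), b3 = c(6, 0.3))
  cl3 <- findClusters(tr3, tau = 0.95, minTrend = 3)
  expect_length(cl3$clusters[lengths(cl3$clusters) >= 3], 2)
  expect_setequal(cl3$reliable, c("a1", "a2", "a3", "a4"))
  expect_setequal(maxConsistentSubset(tr3, tau = 0.95), cl3$reliable)
})

test_that("raising tau never enlarges the reliable set", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    base <- rlnorm(2)
    tr <- t(vapply(seq_len(n), function(j)
      base * rlnorm(2, 0, 0.12), numeric(2)))
    rownames(tr) <- paste0("f", seq_len(n))
    prev <- NULL
    for (tau in c(0.90, 0.95, 0.99)) {
      rel <- findClusters(tr, tau = tau)$reliable
      if (!is.null(prev)) expect_true(all(rel %in% prev))
      prev <- rel
    }
  }
})

test_that("greedy clustering agrees with exhaustive search on small cases", {
  set.seed(31)
  agree <- 0; total <- 100
  for (i in seq_len(total)) {
    n <- sample(4:8, 1)
    # mixture of a coherent group and scattered directions
    k <- sample(2:n, 1)
    base <- rlnorm(2)
    tr <- rbind(
      t(vapply(seq_len(k), function(j) base * rlnorm(2, 0, 0.05),
               numeric(2))),
      matrix(rlnorm(2 * (n - k)), ncol = 2))
    rownames(tr) <- paste0("f", seq_len(n))
    greedy <- findClusters(tr, tau = 0.95, minTrend = 3)$reliable
    oracle <- maxConsistentSubset(tr, tau = 0.95)
    ok <- if (length(oracle) < 3) length(greedy) == 0 else
      length(greedy) == length(oracle)
    agree <- agree + ok
  }
  expect_gte(agree / total, 0.95)
})

test_that("reliable-fragment filtering applies the minimum-count rules", {
  design <- tiny_design(nBio = 2, nInj = 1)
  set.seed(5)
  # P1: one peptide with 4 consistent fragments + 2-fragment peptide +
  # two more good peptides; P2: only 2 peptides survive
  mk <- function(n, prof) t(vapply(seq_len(n), function(i)
    prof * runif(1, 0.5, 2), numeric(4)))
  m <- rbind(mk(4, c(1, 1, 2, 2)), mk(2, c(1, 1, 2, 2)),
             mk(4, c(1, 1, 2, 2)), mk(4, c(1, 1, 2, 2)),
             mk(4, c(3, 3, 1, 1)), mk(4, c(3, 3, 1, 1)))
  frag <- data.frame(
    protein_id = rep(c("P1", "P1", "P1", "P1", "P2", "P2"),
                     c(4, 2, 4, 4, 4, 4)),
    peptide = rep(c("PA", "PB", "PC", "PD", "PE", "PF"),
                  c(4, 2, 4, 4, 4, 4)),
    charge = 2,
    fragment_id = paste0("y", 1:22))
  colnames(m) <- design$run_id
  fe <- FragmentExperiment(m, frag, design)
  out <- filterReliable(fe)
  fk <- fragmentKeys(out)
  # the 2-fragment peptide is pre-excluded, P2 loses its 2-peptide protein
  expect_false("PB" %in% fk$peptide)
  expect_false("P2" %in% fk$protein_id)
  expect_setequal(unique(fk$peptide), c("PA", "PC", "PD"))
  rej <- S4Vectors::metadata(out)$rejections
  expect_true(any(rej$entity == "PB" & rej$stage == "pre-exclusion"))
  expect_true(any(rej$entity == "P2"))
})

test_that("the filter separates interference from clean fragments", {
  st <- interference_study()
  sc <- scoreInterference(st$pipeline$filtered, st$pipeline$stage1, st$truth)
  expect_gte(sc$interference_rejected, 0.9)
  expect_gte(sc$clean_retained, 0.9)
})
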