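mk_quant <- function(ids, lfc, p, flag) {
  q <- data.frame(protein_id = ids, log_B_fc = lfc, p_value = p,
                  dap_flag = flag)
  attr(q, "config") <- quantConfig()
  q
}

test_that("gene matching reports unmatched and ambiguous proteins", {
  q <- mk_quant(c("Pp1s69_154V6", "Pp1s1_1V6", "Pp1s2_2V6"),
                c(1, 0, 0), c(0.01, 0.5, 0.5),
                c("up", "unchanged", "unchanged"))
  expr <- data.frame(gene_id = c("Pp1s69_154V6", "Pp1s2_2V6", "Pp1s2_2V6"),
                     log2_fc = c(2, 0, 0.1), fdr = c(0.01, 0.9, 0.8))
  m <- matchGenes(q, expr)
  expect_equal(m$paired$gene_id, "Pp1s69_154V6")
  expect_equal(m$unmatched, "Pp1s1_1V6")
  expect_equal(m$ambiguous, "Pp1s2_2V6")

  # a two-column map resolves namespace differences
  expr2 <- data.frame(gene_id = c("G1", "G2"), log2_fc = c(1, 0),
                      fdr = c(0.01, 0.9))
  map <- data.frame(protein_id = c("Pp1s1_1V6"), gene_id = c("G2"))
  m2 <- matchGenes(q, expr2, idMap = map)
  expect_true("Pp1s1_1V6" %in% m2$paired$protein_id)
})

test_that("fold-change correlation converts scales before correlating", {
  q <- mk_quant(paste0("P", 1:10), seq(-2, 2, length.out = 10),
                rep(0.5, 10), rep("unchanged", 10))
  expr <- data.frame(gene_id = paste0("P", 1:10),
                     log2_fc = seq(-2, 2, length.out = 10) *
                       log(1.4) / log(2),
                     fdr = rep(0.5, 10))
  m <- matchGenes(q, expr)
  expect_equal(proteomeTranscriptomeCorrelation(m$paired), 1)

  expr$log2_fc <- 0
  m2 <- matchGenes(q, expr)
  expect_error(proteomeTranscriptomeCorrelation(m2$paired),
               "zero variance")
})

test_that("concordance classes follow both call rules", {
  q <- mk_quant(c("g1", "g2", "g3"),
                c(log(2) / log(1.4), 0.2, 0.1),
                c(0.01, 0.2, 0.6),
                c("up", "unchanged", "unchanged"))
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     log2_fc = c(0.1, 3, 1),
                     fdr = c(0.9, 0.001, 0.01))
  m <- matchGenes(q, expr)
  cc <- classifyConcordance(m$paired)
  rec <- cc$records
  expect_equal(rec$class[rec$gene_id == "g1"], "up:unchanged")
  expect_equal(rec$class[rec$gene_id == "g2"], "unchanged:up")
  # g3: significant FDR but |log2FC| <= 2 fails the stringent rule
  expect_equal(rec$class[rec$gene_id == "g3"], "unchanged:unchanged")
  expect_equal(sum(cc$counts), nrow(m$paired))

  # FDR-only mode relaxes the magnitude rule
  cc2 <- classifyConcordance(m$paired, transcriptLfc = 0)
  expect_equal(cc2$records$transcript_call[rec$gene_id == "g3"], "up")
})

test_that("classification does not depend on the log base", {
  set.seed(31)
  truth <- generateTruth(nProteins = 40, fracDa = 0.2, fracInterference = 0,
                         seed = 31)
  fe <- simulateFragmentTable(truth, seed = 32)
  expr <- simulateTranscripts(truth, rho = 0.5, seed = 33)
  piped <- quiet(runSwathPipeline(fe))
  for (B in c(1.4, 2)) {
    cfgq <- quantConfig(B = B)
    q <- callDaps(piped$bioRep, config = cfgq)
    cl <- classifyConcordance(matchGenes(q, expr)$paired)
    if (B == 1.4) first <- cl$records$class else
      expect_equal(cl$records$class, first)
  }
})
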