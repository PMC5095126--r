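# Independent reference implementations used to validate the package's own
# algorithms, plus small fixture builders and cached heavy simulations.

# Spectral contrast angle by direct evaluation of the defining formula.
sa_direct <- function(a, b) {
  1 - 2 * acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) / pi
}

# Benjamini-Hochberg step-up by brute force: adj_i = min_{j >= rank(i)}
# p_(j) * m / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (k in rev(seq_len(m))) {
    running <- min(running, m / k * p[o[k]])
    adj[o[k]] <- running
  }
  adj
}

# Tiny two-type design: nBio x nDig x nInj per type.
tiny_design <- function(nBio = 2, nDig = 1, nInj = 2,
                        types = c("A", "B")) {
  defaultRunDesign(sampleTypes = types, nBio = nBio, digReps = nDig,
                   nInj = nInj)
}

# FragmentExperiment from an explicit matrix.
tiny_fe <- function(m, design, proteins = "P1",
                    peptides = paste0("PEP", seq_len(nrow(m)))) {
  frag <- data.frame(protein_id = rep(proteins, length.out = nrow(m)),
                     peptide = rep(peptides, length.out = nrow(m)),
                     charge = 2,
                     fragment_id = paste0("y", seq_len(nrow(m))))
  colnames(m) <- design$run_id
  FragmentExperiment(m, frag, design)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# Heavy shared simulations, built once per test run.
.fixtures <- new.env(parent = emptyenv())

# The acceptance reference study: the enumerated recovery conditions
# (300 proteins, 10% DA at FC {0.25, 0.5, 2, 4}, 3 bio x 2-3 dig x 3 inj,
# CVs 10/15/20%, no interference term).
reference_study <- function() {
  if (is.null(.fixtures$reference)) {
    cfg <- studyConfig(seed = 1)
    cfg$synthetic$fracInterference <- 0
    .fixtures$reference <- quiet(runFullStudy(cfg))
  }
  .fixtures$reference
}

# The interference study: same conditions with 30% interference fragments.
interference_study <- function() {
  if (is.null(.fixtures$interference)) {
    truth <- generateTruth(seed = 1)  # default fracInterference = 0.3
    fe <- simulateFragmentTable(truth, seed = 2)
    res <- quiet(runSwathPipeline(fe))
    .fixtures$interference <- list(truth = truth, pipeline = res)
  }
  .fixtures$interference
}
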