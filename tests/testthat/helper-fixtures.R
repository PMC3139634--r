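# Shared fixtures for the suite: small simulated experiments and toy objects.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(Biostrings)
})

# a small noiseless experiment, scaled, with fits (memoised per session)
.fixtureEnv <- new.env()

noiselessBundle <- function() {
  if (is.null(.fixtureEnv$noiseless)) {
    p <- simParams(nGenes = 300, noiseSd = 0, seed = 42)
    truth <- simulateGroundTruth(p)
    de <- globalScale(simulateTimecourse(truth))
    fits <- fitDecay(de)
    .fixtureEnv$noiseless <- list(params = p, truth = truth, de = de,
                                  fits = fits)
  }
  .fixtureEnv$noiseless
}

noisyBundle <- function() {
  if (is.null(.fixtureEnv$noisy)) {
    p <- simParams(nGenes = 800, fracDivergedDecay = 0.2,
                   fracCoupledOpposite = 0.1, fracDivergedExpression = 0.3,
                   fracCis = 0.5, noiseSd = 0.05, seed = 7)
    truth <- simulateGroundTruth(p)
    de <- globalScale(simulateTimecourse(truth))
    fits <- fitDecay(de)
    div <- divergenceTable(de, fits)
    .fixtureEnv$noisy <- list(params = p, truth = truth, de = de,
                              fits = fits, div = div)
  }
  .fixtureEnv$noisy
}

# a tiny DecayExperiment built by hand: nprobe probes, one cer/rep1 sample
toyExperiment <- function(M, gene_id = NULL) {
  M <- as.matrix(M)
  np <- nrow(M)
  if (is.null(gene_id)) gene_id <- sprintf("g%02d", seq_len(np))
  DecayExperiment(lapply(seq_len(ncol(M)), function(k) M[, k, drop = FALSE]),
                  probe_id = sprintf("p%02d", seq_len(np)),
                  gene_id = gene_id,
                  channel = "cer", replicate = 1L)
}

# an informative test PSSM from a consensus string
consensusPssm <- function(cons, id = "toy", p = 0.85) {
  codes <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - p) / 3, 4, length(codes))
  m[cbind(codes, seq_along(codes))] <- p
  Pssm(m, id = id)
}

# exhaustive window/strand enumeration used as the scanner oracle
bruteScan <- function(pssm, s) {
  W <- motifWidth(pssm)
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rows <- list()
  for (off in 0:(L - W)) {
    for (st in c("+", "-")) {
      win <- if (st == "+") substr(s, off + 1, off + W)
             else substr(rc, L - W - off + 1, L - off)
      sc <- lodScore(pssm, win)
      if (!is.na(sc))
        rows[[length(rows) + 1L]] <-
          data.frame(offset = off, strand = st, lod = sc)
    }
  }
  d <- do.call(rbind, rows)
  d <- d[d$lod >= max(d$lod) - 1e-9, , drop = FALSE]  # same tie rule
  d[order(d$offset, d$strand), , drop = FALSE][1, ]
}
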