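test_that("LOD scores follow the log-odds formula", {
  # PSSM equal to background at every position: LOD 0 for any window
  flat <- Pssm(matrix(0.25, 4, 3), id = "flat", pseudocount = 0)
  expect_equal(lodScore(flat, "ACG"), 0)
  expect_equal(lodScore(flat, "TTT"), 0)
  # direct formula: W = 2, P(A) = 0.97 at both positions, no pseudocount
  m <- Pssm(matrix(rep(c(0.97, 0.01, 0.01, 0.01), 2), nrow = 4), id = "AA",
            pseudocount = 0)
  expect_equal(lodScore(m, "AA"), 2 * log2(0.97 / 0.25))
  # pseudocounted probabilities enter the positional sum
  mp <- Pssm(matrix(rep(c(0.97, 0.01, 0.01, 0.01), 2), nrow = 4), id = "AA",
             pseudocount = 0.01)
  pA <- (0.97 + 0.01) / 1.04
  pC <- (0.01 + 0.01) / 1.04
  expect_equal(lodScore(mp, "AC"), log2(pA / 0.25) + log2(pC / 0.25))
  # ambiguous bases leave the window unscored
  expect_true(is.na(lodScore(m, "AN")))
  expect_error(lodScore(m, "AAA"), "width")
})

test_that("the scanner equals the exhaustive window/strand oracle", {
  set.seed(11)
  pm <- consensusPssm("TGACTCA", id = "oracle")
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    h <- scanPromoter(pm, s)
    b <- bruteScan(pm, s)
    expect_identical(h$offset, b$offset)
    expect_identical(h$strand, b$strand)
    expect_equal(h$lod, b$lod, tolerance = 1e-12)
  }
})

test_that("strand symmetry and tie-breaking", {
  pm <- consensusPssm("TGACTCA", id = "sym")
  set.seed(12)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(scanPromoter(pm, s)$lod, scanPromoter(pm, rc)$lod,
                 tolerance = 1e-12)
  }
  # palindromic PSSM: identical scores on both strands, '+' wins the tie
  pal <- consensusPssm("ACGT", id = "pal")
  h <- scanPromoter(pal, "ACGT")
  expect_identical(h$strand, "+")
  expect_identical(h$offset, 0L)
  # planted consensus is found at the planted offset
  s <- paste0("AAAAAAAAAA", "TGACTCA", "AAAAAAAAA")
  expect_identical(scanPromoter(pm, s)$offset, 10L)
  expect_error(scanPromoter(pm, "ACG"), "shorter")
})

test_that("genome maximum over a promoter set", {
  pm <- consensusPssm("TGACTCA", id = "max")
  set.seed(13)
  proms <- Biostrings::DNAStringSet(vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = ""),
    character(1)))
  names(proms) <- sprintf("g%02d", 1:20)
  expect_equal(genomeMaxLod(pm, proms),
               max(vapply(1:20, function(i)
                 bruteScan(pm, as.character(proms[[i]]))$lod, numeric(1))),
               tolerance = 1e-12)
  # a single promoter: equals its best hit
  expect_equal(genomeMaxLod(pm, proms[1]),
               scanPromoter(pm, proms[[1]])$lod)
  # a planted perfect consensus reaches the PSSM's maximal LOD
  pl <- proms
  pl[[1]] <- Biostrings::DNAString(paste0("TGACTCA",
                                          substr(as.character(pl[[1]]), 8, 80)))
  expect_equal(genomeMaxLod(pm, pl), maxLod(pm), tolerance = 1e-12)
  expect_error(genomeMaxLod(pm, Biostrings::DNAStringSet()), "empty")
})

test_that("diverged-site rules are asymmetric and threshold-exact", {
  # construct a fixture with precisely placed best LODs by planting sites in
  # otherwise scoreless (poly-A) promoters and a high-scoring reference gene
  pm <- consensusPssm("TGACTCAT", id = "TF", p = 0.85)
  mx <- maxLod(pm)                      # genome max once a consensus exists
  mut1 <- function(s, i, to) { substr(s, i, i) <- to; s }
  cons <- "TGACTCAT"
  one <- mut1(cons, 3, "C")             # one mismatch: drop ~4.1 units
  bgA <- function(site) paste0(strrep("A", 20), site, strrep("A", 20))
  promC <- Biostrings::DNAStringSet(c(ref = bgA(cons), g1 = bgA(cons),
                                      g2 = bgA(cons)))
  promP <- Biostrings::DNAStringSet(c(ref = bgA(cons), g1 = bgA(one),
                                      g2 = bgA(cons)))
  calls <- callDivergedSites(pm, promC, promP,
                             boundGenes = c("ref", "g1", "g2"))
  # g1: bound, strong cer site (= genome max), ortholog drops > 1 unit
  expect_identical(calls$gene_id[calls$direction == "diverged_in_paradoxus"],
                   "g1")
  # g2 intact: no call; drop below one unit: no call
  promP2 <- promP
  promP2[["g1"]] <- Biostrings::DNAString(bgA(cons))
  expect_identical(nrow(callDivergedSites(pm, promC, promP2,
                                          boundGenes = c("ref", "g1", "g2"))),
                   0L)
  # unbound gene with a strong par site and a mutated cer site: cer direction
  promC3 <- Biostrings::DNAStringSet(c(ref = bgA(cons), g3 = bgA(one)))
  promP3 <- Biostrings::DNAStringSet(c(ref = bgA(cons), g3 = bgA(cons)))
  calls3 <- callDivergedSites(pm, promC3, promP3, boundGenes = "ref")
  expect_identical(calls3$gene_id[calls3$direction == "diverged_in_cerevisiae"],
                   "g3")
  # rule asymmetry: a site whose LOD sits between the two gates (10 < lod,
  # < 12) straddles the thresholds -- callable only in the par direction
  expect_gt(mx, 12)
  weak <- consensusPssm("TGACTCAT", id = "w", p = 0.52)  # max LOD ~ 8.4
  expect_lt(maxLod(weak), 10)
  wc <- callDivergedSites(weak, promC, promP, boundGenes = c("ref", "g1"))
  expect_identical(nrow(wc), 0L)
})

test_that("diverged sites enrich among cis-coupled genes when planted", {
  pm <- consensusPssm("TGACTCAT", id = "TF1")
  genes <- sprintf("g%03d", 1:150)
  cisCoupled <- genes[1:30]
  uncoupled <- genes[31:150]
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    # plant diverged sites at 40% of coupled genes, 10% of uncoupled genes
    divg <- c(sample(cisCoupled, 12), sample(uncoupled, 12))
    prom <- simulatePromoters(genes, pm, divergedGenes = divg,
                              promoterLength = 250, seed = 400 + s)
    calls <- callDivergedSites(pm, prom$cer, prom$par, boundGenes = divg)
    enr <- divergedMotifEnrichment(calls, cisCoupled, uncoupled)
    enr$p_value[enr$direction == "diverged_in_paradoxus"] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("MEME-minimal motifs round-trip", {
  pms <- list(A = consensusPssm("TGACTCA", id = "A"),
              B = consensusPssm("CCAAT", id = "B"))
  f <- tempfile(fileext = ".meme")
  writeMeme(pms, f)
  # files written by writeMeme contain the final (pseudocounted) matrix,
  # so they are read back without adding a second pseudocount
  back <- readMeme(f, pseudocount = 0)
  expect_identical(names(back), c("A", "B"))
  expect_equal(back$A@probs, pms$A@probs, tolerance = 1e-4)
  expect_identical(motifWidth(back$B), 5L)
  expect_error(readMeme(textConnection("no motifs here")))
})
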