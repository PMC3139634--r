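test_that("invalid simulation parameters are rejected", {
  expect_error(simParams(fracDivergedDecay = 1.2), "fractions")
  expect_error(simParams(fracDivergedDecay = -0.1), "fractions")
  expect_error(simParams(fracCoupledOpposite = 0.3, fracDivergedDecay = 0.1),
               "fracCoupledOpposite")
  expect_error(simParams(noiseSd = -1), "noiseSd")
  expect_error(simParams(timePoints = c(0, 20, 20, 60)), "increasing")
})

test_that("ground truth is deterministic and plants effects by exact count", {
  p <- simParams(nGenes = 1000, fracDivergedDecay = 0.11, seed = 1)
  t1 <- simulateGroundTruth(p)
  t2 <- simulateGroundTruth(p)
  expect_identical(as.data.frame(t1@genes), as.data.frame(t2@genes))
  expect_identical(as.data.frame(t1@probes), as.data.frame(t2@probes))
  # planting is by count, not Bernoulli: exactly 110/1000 decay-diverged
  expect_identical(sum(t1@genes$D_cer != t1@genes$D_par), 110L)
  # no planted decay effects => rates identical across species
  t0 <- simulateGroundTruth(simParams(nGenes = 200, fracDivergedDecay = 0,
                                      fracCoupledOpposite = 0, seed = 2))
  expect_identical(t0@genes$D_cer, t0@genes$D_par)
})

test_that("planted effects respect magnitude, sign structure and TR identity", {
  tr <- noiselessBundle()$truth
  g <- tr@genes
  e <- tr@params@effectSizeLog2
  planted <- g$log2_D_ratio != 0
  expect_true(all(abs(g$log2_D_ratio[planted]) >= e))
  expect_equal(g$log2_TR_ratio, g$log2_D_ratio + g$log2_L_ratio)
  expect_equal(g$TR_cer, g$D_cer * g$L_cer)
  # coupled-opposite genes: decay, level and transcription ratios share a sign
  cp <- g[g$class == "coupled-opposite", ]
  expect_true(all(sign(cp$log2_D_ratio) == sign(cp$log2_L_ratio)))
  expect_true(all(sign(cp$log2_D_ratio) == sign(cp$log2_TR_ratio)))
  expect_true(all(abs(cp$log2_TR_ratio) > abs(cp$log2_D_ratio)))
  # decay-only genes keep transcription conserved
  dn <- g[g$class == "decay-only", ]
  expect_true(all(dn$log2_TR_ratio == 0))
})

test_that("hybrid allele truth follows the cis/trans semantics", {
  tr <- noiselessBundle()$truth
  g <- tr@genes
  cis <- g[g$mech_decay == "cis", ]
  expect_identical(cis$D_hyb_cer, cis$D_cer)
  expect_identical(cis$D_hyb_par, cis$D_par)
  trans <- g[g$mech_decay == "trans", ]
  # trans effects are equalized at the log-scale midpoint of the species
  expect_equal(trans$D_hyb_cer, trans$D_hyb_par)
  expect_equal(log2(trans$D_hyb_cer),
               (log2(trans$D_cer) + log2(trans$D_par)) / 2)
})

test_that("timecourse columns are mean-centered (total-RNA masking)", {
  b <- noiselessBundle()
  de <- simulateTimecourse(b$truth)   # raw, pre-scaling
  for (k in 1:4)
    expect_lt(max(abs(colMeans(assay(de, k)))), 1e-9)
  # noisy data are centered too (centering happens after noise)
  nb <- noisyBundle()
  deN <- simulateTimecourse(nb$truth)
  expect_lt(max(abs(colMeans(assay(deN, 1)))), 1e-9)
})

test_that("noiseless end-to-end recovery of species rates is exact", {
  b <- noiselessBundle()
  rates <- suppressMessages(geneDecayRates(b$fits))
  g <- b$truth@genes
  for (ch in c("cer", "par")) {
    Dhat <- DecayCoupling:::.avgRate(rates, ch)
    Dtrue <- setNames(g[[paste0("D_", ch)]], g$gene_id)
    expect_true(all(names(Dhat) %in% names(Dtrue)))
    expect_lt(max(abs(Dhat - Dtrue[names(Dhat)])), 1e-9)
  }
  # every probe passes the gate on noiseless data
  expect_true(all(b$fits$passed_gate))
})

test_that("a gene at the global mean rate is flat after masking", {
  # noiseless, all genes share the global rate -> renormalization removes
  # exactly the average decay and every profile is constant
  p <- simParams(nGenes = 10, probesPerGene = c(2L, 2L), rateLogSd = 0,
                 fracDivergedDecay = 0, fracDivergedExpression = 0,
                 fracCoupledOpposite = 0, noiseSd = 0, seed = 3)
  de <- simulateTimecourse(simulateGroundTruth(p))
  m <- sapply(1:4, function(k) assay(de, k)[, 1])
  expect_lt(max(abs(m - m[, 1])), 1e-12)
})

test_that("noisy estimates track the truth (r >= 0.99 at sd 0.05)", {
  b <- noisyBundle()
  rates <- suppressMessages(geneDecayRates(b$fits))
  Dhat <- DecayCoupling:::.avgRate(rates, "cer")
  Dtrue <- setNames(b$truth@genes$D_cer, b$truth@genes$gene_id)
  expect_gt(cor(Dhat, Dtrue[names(Dhat)]), 0.99)
})

test_that("independent-mode planting draws the two diverged sets independently", {
  p <- simParams(nGenes = 600, fracDivergedDecay = 0.3,
                 fracDivergedExpression = 0.4, couplingMode = "independent",
                 seed = 9)
  g <- simulateGroundTruth(p)@genes
  expect_identical(sum(g$log2_D_ratio != 0), 180L)
  expect_identical(sum(g$log2_L_ratio != 0), 240L)
  both <- g$log2_D_ratio != 0 & g$log2_L_ratio != 0
  expect_identical(unique(g$class[both]), "both-independent")
  # decay effects leave the level untouched in this mode
  dOnly <- g$log2_D_ratio != 0 & !both
  expect_true(all(g$log2_L_ratio[dOnly] == 0))
})

test_that("target-set generator realizes the requested enrichment", {
  p <- simParams(nGenes = 1000, fracCoupledOpposite = 0.2,
                 fracDivergedDecay = 0.25, fracDivergedExpression = 0.3,
                 seed = 4)
  tr <- simulateGroundTruth(p)
  coupled <- tr@genes$gene_id[tr@genes$class == "coupled-opposite"]
  expect_length(coupled, 200)
  sets <- simulateTargetSets(tr, enrichmentFactor = 4, nSets = 10)
  des <- sets[[attr(sets, "designated")]]
  fracDes <- mean(des %in% coupled)
  expect_equal(fracDes, 4 * 0.2, tolerance = 0.05)
  # decoys are uniform draws: coupled fraction near the background rate
  fracDecoy <- mean(vapply(sets[-1], function(s) mean(s %in% coupled),
                           numeric(1)))
  expect_equal(fracDecoy, 0.2, tolerance = 0.1)
  # no coupled genes -> designated set is a plain uniform draw
  tr0 <- simulateGroundTruth(simParams(nGenes = 200, fracCoupledOpposite = 0,
                                       seed = 5))
  sets0 <- simulateTargetSets(tr0, enrichmentFactor = 4, nSets = 3)
  expect_length(sets0[["regulator_coupling"]], length(sets0[["decoy_01"]]))
  expect_error(simulateTargetSets(tr0, enrichmentFactor = 0.5))
})

test_that("promoter generator plants recoverable diverged sites", {
  pm <- consensusPssm("TGACTCAT", id = "TF1")
  genes <- sprintf("g%03d", 1:60)
  prom <- simulatePromoters(genes, pm, divergedGenes = genes[1:10],
                            intactGenes = genes[11:20],
                            promoterLength = 300, lodDrop = 2, seed = 8)
  expect_s4_class(prom$cer, "DNAStringSet")
  expect_identical(nrow(prom$ledger), 10L)
  # planted drop is at least the requested one
  expect_true(all(prom$ledger$lod_cer - prom$ledger$lod_par >= 2))
  # planted consensus achieves the PSSM's maximal LOD -> passes the 75% gate
  expect_equal(unique(prom$ledger$lod_cer), maxLod(pm))
  calls <- callDivergedSites(pm, prom$cer, prom$par, boundGenes = genes[1:20])
  par_calls <- calls$gene_id[calls$direction == "diverged_in_paradoxus"]
  expect_true(all(genes[1:10] %in% par_calls))
  # intact genes never called diverged
  expect_false(any(genes[11:20] %in% calls$gene_id))
  expect_error(simulatePromoters(genes, pm, promoterLength = 4),
               "shorter|smaller")
})
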