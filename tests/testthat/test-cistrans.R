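test_that("the cis/trans rules reproduce the threshold arithmetic", {
  # |delta_hybrid| > log2(1.2) = 0.263, same sign, residuals < log2(1.3)
  expect_equal(classifyCisTrans(0.8, c(0.70, 0.75))$label, "cis")
  # allele ratios collapse, residuals > log2(1.3) = 0.378
  expect_equal(classifyCisTrans(0.8, c(0.05, 0.10))$label, "trans")
  # intermediate: neither rule satisfied for all replicates
  expect_equal(classifyCisTrans(0.8, c(0.50, 0.10))$label, "excluded")
  # residuals are delta_hybrid - delta_species
  r <- classifyCisTrans(0.8, c(0.70, 0.75))
  expect_equal(r$residuals, c(-0.10, -0.05))
  # missing hybrid data -> excluded with a reason code
  r2 <- classifyCisTrans(0.8, c(NA, 0.7))
  expect_equal(r2$label, "excluded")
  expect_equal(r2$reason, "missing_hybrid")
})

test_that("labels are invariant to replicate order", {
  for (dh in list(c(0.7, 0.3), c(0.05, -0.1), c(0.5, 0.1), c(0.9, 0.7))) {
    a <- classifyCisTrans(0.8, dh)$label
    b <- classifyCisTrans(0.8, rev(dh))$label
    expect_identical(a, b)
  }
})

test_that("planted cis and trans mechanisms are recovered from the hybrid", {
  b <- noisyBundle()   # fracCis = 0.5, 2-fold effects, noise 0.05
  ct <- cisTransTable(b$de, b$fits, b$div)
  g <- b$truth@genes
  for (ms in c("decay", "level")) {
    lab <- ct[ct$measure == ms & ct$label %in% c("cis", "trans"), ]
    truthLab <- if (ms == "decay") g$mech_decay else g$mech_expression
    truthLab <- truthLab[match(lab$gene_id, g$gene_id)]
    keep <- truthLab %in% c("cis", "trans")
    expect_gt(mean(lab$label[keep] == truthLab[keep]), 0.9)
  }
  # equal planted cis and trans frequencies: recovered cis fraction ~ 1/2
  dlab <- ct[ct$measure == "decay" & ct$label %in% c("cis", "trans"), ]
  expect_gt(mean(dlab$label == "cis"), 0.4)
  expect_lt(mean(dlab$label == "cis"), 0.6)
})

test_that("high-confidence coupled sets apply the 1.5-fold opposite rule", {
  ct <- data.frame(
    gene_id = rep(c("a", "b", "c", "d"), 2),
    measure = rep(c("decay", "level"), each = 4),
    delta_species = c(0.7, 0.7, 0.7, 0.3,   # decay
                      0.8, 0.8, -0.8, 0.8), # level
    label = c("cis", "cis", "cis", "cis",
              "cis", "trans", "cis", "cis"))
  hc <- highConfidenceCoupled(ct, fold = 1.5)
  expect_identical(hc$cis_coupled, "a")       # both cis, both > 1.5x, same sign
  expect_length(hc$trans_coupled, 0)
  # b: mixed combination; c: same-direction; d: below the fold gate
  expect_false(any(c("b", "c", "d") %in% hc$cis_coupled))
})

test_that("shared mechanisms concentrate coupling in cis-cis and trans-trans", {
  # mechanistic coupling: each coupled gene's decay and transcription effects
  # share one mechanism -> opposite effects only in the matched combinations
  p <- simParams(nGenes = 1200, fracDivergedDecay = 0.2,
                 fracCoupledOpposite = 0.16, fracDivergedExpression = 0.3,
                 fracCis = 0.5, noiseSd = 0.05, mechanismMode = "shared",
                 seed = 21)
  tr <- simulateGroundTruth(p)
  de <- globalScale(simulateTimecourse(tr))
  fits <- fitDecay(de)
  div <- divergenceTable(de, fits)
  ct <- cisTransTable(de, fits, div)
  comb <- combinationAnalysis(ct, div, window = NULL)$summary
  cc <- comb[comb$combination %in% c("cis-cis", "trans-trans"), ]
  mixed <- comb[comb$combination %in% c("cis-trans", "trans-cis"), ]
  expect_true(all(cc$frac_opposite > 0.7))
  # mixed combinations are essentially empty under a shared mechanism
  expect_lte(sum(mixed$n), 0.05 * sum(comb$n))

  # independent-mutation simulation: all four combinations alike
  pI <- simParams(nGenes = 2000, fracDivergedDecay = 0.4,
                  fracDivergedExpression = 0.5, fracCis = 0.5,
                  couplingMode = "independent", noiseSd = 0.05, seed = 22)
  trI <- simulateGroundTruth(pI)
  deI <- globalScale(simulateTimecourse(trI))
  fitsI <- fitDecay(deI)
  divI <- divergenceTable(deI, fitsI)
  ctI <- cisTransTable(deI, fitsI, divI)
  combI <- combinationAnalysis(ctI, divI, window = NULL)$summary
  expect_true(all(combI$n > 10))
  expect_true(all(abs(combI$frac_opposite - 0.5) < 0.2))
})
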