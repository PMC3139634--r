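test_that("global scaling centers columns on the assumed decay", {
  set.seed(1)
  de <- toyExperiment(matrix(rnorm(12, 8), 3, 4))
  sc <- globalScale(de, halfLife = 25)
  means <- sapply(1:4, function(k) colMeans(assay(sc, k)))
  expect_equal(unname(means), c(0, -0.8, -1.6, -2.4), tolerance = 1e-12)
  # 20-min half-life: one log2 unit per 20-min step
  sc20 <- globalScale(de, halfLife = 20)
  expect_equal(unname(sapply(1:4, function(k) colMeans(assay(sc20, k)))),
               c(0, -1, -2, -3), tolerance = 1e-12)
})

test_that("global scaling is a pure additive shift and is idempotent", {
  set.seed(2)
  M <- matrix(rnorm(12, 8), 3, 4)
  de <- toyExperiment(M)
  sc <- globalScale(de)
  # direct arithmetic oracle: subtract column means, add targets
  for (k in 1:4) {
    expected <- M[, k] - mean(M[, k]) - 0.8 * (k - 1)
    expect_equal(unname(assay(sc, k)[, 1]), expected, tolerance = 1e-12)
    # gene-relative differences unchanged
    expect_equal(unname(diff(assay(sc, k)[, 1])), diff(M[, k]),
                 tolerance = 1e-12)
  }
  sc2 <- globalScale(sc)
  expect_equal(assays(sc2), assays(sc), tolerance = 1e-12)
})

test_that("probe decay fits match closed-form examples and the lm oracle", {
  f <- fitProbeDecay(c(10, 9.2, 8.4, 7.6))
  expect_equal(f$slope, -0.04)           # 25-min half-life
  expect_equal(f$r_squared, 1)
  expect_true(f$passed_gate)

  # constant profile: undefined r2, fails the gate
  f0 <- fitProbeDecay(c(5, 5, 5, 5))
  expect_equal(f0$slope, 0)
  expect_true(is.na(f0$r_squared))
  expect_false(f0$passed_gate)

  # independent oracle: stats::lm on 100 random profiles
  set.seed(3)
  t <- c(0, 20, 40, 60)
  for (i in 1:100) {
    M <- rnorm(4, 10 - 0.03 * t, 0.3)
    f <- fitProbeDecay(M)
    o <- lm(M ~ t)
    expect_equal(f$slope, unname(coef(o)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(o)[1]), tolerance = 1e-10)
    expect_equal(f$r_squared, summary(o)$r.squared, tolerance = 1e-10)
  }
  expect_error(fitProbeDecay(c(1, 2, NA, 4)), "finite")
})

test_that("gate boundary passes at equality and noise degrades the fit", {
  # construct a profile with r2 exactly computable; gate is >=
  f <- fitProbeDecay(c(10, 9.1, 8.5, 7.5))
  o <- lm(c(10, 9.1, 8.5, 7.5) ~ c(0, 20, 40, 60))
  expect_equal(f$r_squared, summary(o)$r.squared, tolerance = 1e-12)
  expect_true(fitProbeDecay(c(10, 9.1, 8.5, 7.5),
                            r2Gate = f$r_squared)$passed_gate)
  # monotonicity: added noise weakly decreases expected r2
  set.seed(4)
  t <- c(0, 20, 40, 60)
  base <- 10 - 0.04 * t
  r2 <- function(sd) mean(replicate(300, fitProbeDecay(base +
    rnorm(4, 0, sd))$r_squared))
  expect_gt(r2(0.02), r2(0.2))
})

test_that("gene rates are the absolute median slope of passing probes", {
  fits <- data.frame(
    probe_id = sprintf("p%d", 1:6),
    gene_id = c("a", "a", "a", "b", "b", "c"),
    channel = "cer", replicate = 1L,
    slope = c(-0.03, -0.04, -0.05, -0.03, -0.05, -0.02),
    intercept = 0, r_squared = 1,
    passed_gate = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  r <- geneDecayRates(fits)
  expect_equal(r$D[r$gene_id == "a"], 0.04)
  # even count: mean of the two central values
  expect_equal(r$D[r$gene_id == "b"], 0.04)
  expect_equal(r$D[r$gene_id == "c"], 0.02)
  # failing probes are excluded; empty groups dropped with a message
  fits$passed_gate <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  expect_message(r2 <- geneDecayRates(fits), "dropped")
  expect_equal(r2$D[r2$gene_id == "a"], 0.03)
  expect_false("b" %in% r2$gene_id)
})

test_that("shuffled profiles lose gene-specific decay", {
  b <- noisyBundle()
  # heterogeneous rates: shuffled pass-rate below the real pass-rate
  realPass <- mean(b$fits$passed_gate[b$fits$channel == "cer" &
                                        b$fits$replicate == 1])
  sh <- shuffledProfileNull(b$de, nShuffles = 2000, seed = 1)
  expect_lt(sh$pass_rate, realPass)
  # determinism under a fixed seed
  sh2 <- shuffledProfileNull(b$de, nShuffles = 2000, seed = 1)
  expect_identical(sh$r_squared, sh2$r_squared)
  # rate- and intensity-homogeneous noiseless limit: all probes share one
  # trajectory, so every shuffled profile is that same perfect line
  t <- c(0, 20, 40, 60)
  deH <- globalScale(toyExperiment(matrix(10 - 0.04 * t, nrow = 50, ncol = 4,
                                          byrow = TRUE)))
  shH <- shuffledProfileNull(deH, nShuffles = 500, seed = 2)
  expect_equal(shH$pass_rate, 1.0)
  expect_error(shuffledProfileNull(b$de, nShuffles = 0), "nShuffles")
})

test_that("probe table round-trips through TSV", {
  b <- noiselessBundle()
  f <- tempfile(fileext = ".tsv")
  writeProbeTable(b$de, f)
  back <- readProbeTable(f)
  expect_equal(assay(back, 1), assay(b$de, 1), tolerance = 1e-9)
  expect_identical(as.data.frame(colData(back)), as.data.frame(colData(b$de)))
  expect_identical(rowData(back)$gene_id, rowData(b$de)$gene_id)
  unlink(f)
})
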