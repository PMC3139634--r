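#' Consecutive differences of a decay profile
#'
#' With evenly spaced time points, the differences between consecutive log2
#' mRNA levels (`M20 - M0`, `M40 - M20`, `M60 - M40`) are three estimates of
#' the (negative) per-interval degradation; they feed the per-probe two-sample
#' test for differential degradation.
#'
#' @param M four log2 intensities in time order.
#' @return numeric vector of the three consecutive differences.
#' @examples
#' consecutiveDiffs(c(10, 9.2, 8.4, 7.6))
#' @export
consecutiveDiffs <- function(M) {
  if (length(M) != 4L || !all(is.finite(M)))
    stop("profile must contain exactly 4 finite values")
  diff(M)
}

#' Two-sample t test on per-probe decay estimates
#'
#' Compares the three consecutive-difference estimates of one probe between
#' two channels with a two-sided two-sample t test (pooled variance, 4 df, by
#' default; Welch optional). Noiseless fixtures produce exact ties with zero
#' pooled variance; this degenerate case is resolved as the limit of an
#' infinitesimal variance floor: p = 1 when the group means are equal, p = 0
#' otherwise.
#'
#' @param a,b numeric vectors of exactly 3 estimates each.
#' @param varEqual pooled-variance (Student) test if `TRUE` (default), Welch
#'   otherwise.
#' @return two-sided p-value.
#' @export
probeDifferenceTest <- function(a, b, varEqual = TRUE) {
  if (length(a) != 3L || length(b) != 3L)
    stop("each group must contain exactly 3 estimates")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("estimates must be finite")
  as.numeric(.diffTestRows(matrix(a, 1), matrix(b, 1), varEqual))
}

# vectorized two-sample t test across rows of two n x 3 matrices
.diffTestRows <- function(A, B, varEqual = TRUE) {
  n <- ncol(A)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (n - 1)
  vb <- rowSums((B - mb)^2) / (n - 1)
  if (varEqual) {
    se <- sqrt((va + vb) / 2 * (2 / n))
    df <- rep.int(2 * (n - 1), nrow(A))
  } else {
    se <- sqrt(va / n + vb / n)
    df <- (va / n + vb / n)^2 /
      (((va / n)^2 + (vb / n)^2) / (n - 1))
  }
  p <- ifelse(ma == mb, 1, 0)   # zero-variance floor
  ok <- se > 0
  p[ok] <- 2 * pt(-abs((ma[ok] - mb[ok]) / se[ok]), df[ok])
  p
}

#' Gene-level differential-degradation rule
#'
#' A gene is called differentially degraded when the median p-value of its
#' per-probe tests is below `pGate` (default 0.05) AND the ratio of the faster
#' to the slower degradation rate exceeds `foldGate` (default 1.4). No
#' multiple-testing correction is applied (the raw median p is thresholded).
#'
#' @param medianP median per-probe p-value for the gene.
#' @param Da,Db the gene's degradation rates in the two channels (positive).
#' @param pGate,foldGate the two gates.
#' @return list with `median_p`, `rate_ratio`, `direction`
#'   (sign of `log2(Da/Db)`) and `significant`.
#' @export
geneDifferentialCall <- function(medianP, Da, Db, pGate = 0.05,
                                 foldGate = 1.4) {
  if (Da <= 0 || Db <= 0) stop("degradation rates must be positive")
  ratio <- max(Da, Db) / min(Da, Db)
  list(median_p = medianP,
       rate_ratio = ratio,
       direction = sign(log2(Da / Db)),
       significant = medianP < pGate && ratio > foldGate)
}

#' Differential-degradation calls between two channels
#'
#' For every probe passing the R-squared gate in both channels, the three
#' consecutive-difference estimates of the designated replicate's scaled
#' profiles are compared with [probeDifferenceTest()]; per gene, the median
#' probe p-value and the ratio of replicate-averaged degradation rates are
#' thresholded by [geneDifferentialCall()]'s rule.
#'
#' @param de a scaled [DecayExperiment-class].
#' @param fits output of [fitDecay()] on `de`.
#' @param channels the two channels to compare (ratio is
#'   `channels[1]/channels[2]`).
#' @param testReplicate replicate whose time course feeds the t tests.
#' @param pGate,foldGate significance and fold gates (paper defaults 0.05,
#'   1.4).
#' @param varEqual pooled-variance t test if `TRUE`.
#' @return data.frame per gene: `gene_id`, `median_p`, `D_a`, `D_b`,
#'   `log2_D_ratio`, `rate_ratio`, `direction`, `significant`,
#'   `n_probes_tested`.
#' @export
differentialDecayCalls <- function(de, fits, channels = c("cer", "par"),
                                   testReplicate = 1, pGate = 0.05,
                                   foldGate = 1.4, varEqual = TRUE) {
  stopifnot(is(de, "DecayExperiment"), length(channels) == 2L)
  cd <- colData(de)
  rd <- rowData(de)
  sA <- which(cd$channel == channels[1] & cd$replicate == testReplicate)
  sB <- which(cd$channel == channels[2] & cd$replicate == testReplicate)
  if (length(sA) != 1L || length(sB) != 1L)
    stop("channels/replicate not found in the experiment")
  tp <- metadata(de)$timePoints
  MA <- vapply(seq_along(tp), function(k) assay(de, k)[, sA],
               numeric(nrow(de)))
  MB <- vapply(seq_along(tp), function(k) assay(de, k)[, sB],
               numeric(nrow(de)))
  dA <- MA[, -1, drop = FALSE] - MA[, -ncol(MA), drop = FALSE]
  dB <- MB[, -1, drop = FALSE] - MB[, -ncol(MB), drop = FALSE]

  fkey <- paste(fits$probe_id, fits$channel, fits$replicate)
  pA <- fits$passed_gate[match(paste(rd$probe_id, channels[1], testReplicate),
                               fkey)]
  pB <- fits$passed_gate[match(paste(rd$probe_id, channels[2], testReplicate),
                               fkey)]
  use <- which(pA %in% TRUE & pB %in% TRUE)
  if (!length(use)) stop("no probe passes the gate in both channels")
  pvals <- .diffTestRows(dA[use, , drop = FALSE], dB[use, , drop = FALSE],
                         varEqual)
  medp <- vapply(split(pvals, rd$gene_id[use]), median, numeric(1))
  nprobe <- lengths(split(pvals, rd$gene_id[use]))

  rates <- geneDecayRates(fits)
  Da <- .avgRate(rates, channels[1])
  Db <- .avgRate(rates, channels[2])
  genes <- intersect(names(medp), intersect(names(Da), names(Db)))
  Da <- Da[genes]; Db <- Db[genes]; mp <- medp[genes]
  ratio <- pmax(Da, Db) / pmin(Da, Db)
  data.frame(gene_id = genes,
             median_p = unname(mp),
             D_a = unname(Da), D_b = unname(Db),
             log2_D_ratio = unname(log2(Da / Db)),
             rate_ratio = unname(ratio),
             direction = unname(sign(log2(Da / Db))),
             significant = unname(mp < pGate & ratio > foldGate),
             n_probes_tested = unname(nprobe[genes]),
             row.names = NULL)
}

#' Fraction of differential calls under a sweep of the fold gate
#'
#' Re-applies the differential-degradation rule over a grid of fold gates,
#' reporting the called fraction at each; the fraction is non-increasing in
#' the gate, mirroring the robustness analysis of threshold choice.
#'
#' @param calls output of [differentialDecayCalls()].
#' @param folds fold gates to sweep.
#' @param pGate p-value gate held fixed.
#' @return data.frame `fold`, `fraction_significant`.
#' @export
thresholdSweep <- function(calls, folds = seq(1.1, 2.0, by = 0.1),
                           pGate = 0.05) {
  data.frame(fold = folds,
             fraction_significant = vapply(folds, function(f)
               mean(calls$median_p < pGate & calls$rate_ratio > f),
               numeric(1)))
}
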