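#' @importFrom stats setNames
NULL

#' Steady-state mRNA levels from the pre-arrest time point
#'
#' The time-0 measurement reflects mRNA levels during exponential growth,
#' before transcriptional arrest. To avoid correlated measurement error
#' between level and decay estimates, levels are taken from a replicate NOT
#' used for decay estimation (default replicate 2, with replicate 1 feeding
#' the decay fits). Per gene and channel, the level is the geometric mean over
#' the gene's probes (mean of log2 intensities, then exponentiated), which is
#' robust to probe-specific intensity offsets.
#'
#' @param de a [DecayExperiment-class] (scaled or raw; only cross-channel
#'   ratios of the returned levels are meaningful).
#' @param levelReplicate replicate supplying the time-0 values. If absent, the
#'   lowest available replicate is used with a warning (levels then share the
#'   decay time course).
#' @param channels channels to report (default: all present).
#' @return data.frame `gene_id`, `channel`, `replicate`, `log2_L`, `L`.
#' @export
steadyStateLevels <- function(de, levelReplicate = 2, channels = NULL) {
  stopifnot(is(de, "DecayExperiment"))
  cd <- colData(de)
  rd <- rowData(de)
  if (is.null(channels)) channels <- unique(cd$channel)
  if (!levelReplicate %in% cd$replicate) {
    levelReplicate <- min(cd$replicate)
    warning("requested level replicate not present; falling back to ",
            "replicate ", levelReplicate,
            " (levels share the decay time course)")
  }
  k0 <- which.min(metadata(de)$timePoints)
  t0 <- assay(de, k0)
  out <- lapply(channels, function(ch) {
    s <- which(cd$channel == ch & cd$replicate == levelReplicate)
    if (length(s) != 1L) return(NULL)
    l2 <- vapply(split(t0[, s], rd$gene_id), mean, numeric(1))
    data.frame(gene_id = names(l2), channel = ch,
               replicate = levelReplicate,
               log2_L = unname(l2), L = unname(2^l2), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Differential-expression rule
#'
#' Differential expression between species (or hybrid alleles) is a
#' level ratio above `foldGate` (default 1.5-fold), in either direction.
#'
#' @param La,Lb positive linear-scale levels (vectorized).
#' @param foldGate fold threshold.
#' @return data.frame `log2_L_ratio` (`log2(La/Lb)`), `ratio` (>= 1),
#'   `differential`, `direction` (sign of the log ratio).
#' @examples
#' differentialExpression(3.0, 1.9)  # 1.58-fold: differential
#' @export
differentialExpression <- function(La, Lb, foldGate = 1.5) {
  if (any(La <= 0) || any(Lb <= 0)) stop("levels must be positive")
  ratio <- pmax(La, Lb) / pmin(La, Lb)
  data.frame(log2_L_ratio = log2(La / Lb), ratio = ratio,
             differential = ratio > foldGate,
             direction = sign(log2(La / Lb)))
}

#' Transcription-rate decomposition TR = D x L
#'
#' At steady state the transcription rate balances degradation:
#' `TR = D * L`, so divergence decomposes exactly on the log scale:
#' `log2(TR_a/TR_b) = log2(D_a/D_b) + log2(L_a/L_b)`. Genes whose estimated
#' transcription-rate ratio exceeds `foldGate` are flagged as differential
#' transcription (mirroring the expression gate).
#'
#' @param log2DRatio,log2LRatio log2 degradation-rate and level ratios
#'   (vectorized).
#' @param foldGate fold threshold for the differential-transcription flag.
#' @return data.frame `log2_D_ratio`, `log2_L_ratio`, `log2_TR_ratio`
#'   (exact sum), `diff_transcription`.
#' @examples
#' transcriptionRateRatio(0.6, 0.0)  # degradation change, level conserved:
#'                                   # implied opposite transcription change
#' @export
transcriptionRateRatio <- function(log2DRatio, log2LRatio, foldGate = 1.5) {
  stopifnot(all(is.finite(log2DRatio)), all(is.finite(log2LRatio)))
  tr <- log2DRatio + log2LRatio
  data.frame(log2_D_ratio = log2DRatio, log2_L_ratio = log2LRatio,
             log2_TR_ratio = tr,
             diff_transcription = abs(tr) > log2(foldGate))
}

#' Per-gene divergence table: degradation, level and transcription
#'
#' Combines the differential-degradation calls (decay time course of
#' `testReplicate`), steady-state levels (time-0 of `levelReplicate`) and the
#' TR = D x L decomposition into one per-gene record for a channel pair.
#'
#' @param de a scaled [DecayExperiment-class].
#' @param fits output of [fitDecay()].
#' @param channels channel pair; ratios are `channels[1]/channels[2]`.
#' @param testReplicate replicate feeding decay tests.
#' @param levelReplicate replicate supplying levels.
#' @param pGate,decayFold,exprFold gates (paper defaults 0.05, 1.4, 1.5).
#' @param varEqual pooled-variance t test if `TRUE`.
#' @return data.frame per gene: `gene_id`, `log2_D_ratio`, `log2_L_ratio`,
#'   `log2_TR_ratio`, `median_p`, `rate_ratio`, `sig_decay`,
#'   `diff_expression`, `diff_transcription`.
#' @export
divergenceTable <- function(de, fits, channels = c("cer", "par"),
                            testReplicate = 1, levelReplicate = 2,
                            pGate = 0.05, decayFold = 1.4, exprFold = 1.5,
                            varEqual = TRUE) {
  calls <- differentialDecayCalls(de, fits, channels = channels,
                                  testReplicate = testReplicate,
                                  pGate = pGate, foldGate = decayFold,
                                  varEqual = varEqual)
  lv <- steadyStateLevels(de, levelReplicate = levelReplicate,
                          channels = channels)
  La <- setNames(lv$L[lv$channel == channels[1]],
                 lv$gene_id[lv$channel == channels[1]])
  Lb <- setNames(lv$L[lv$channel == channels[2]],
                 lv$gene_id[lv$channel == channels[2]])
  genes <- intersect(calls$gene_id, intersect(names(La), names(Lb)))
  calls <- calls[match(genes, calls$gene_id), ]
  dx <- differentialExpression(La[genes], Lb[genes], foldGate = exprFold)
  tr <- transcriptionRateRatio(calls$log2_D_ratio, dx$log2_L_ratio,
                               foldGate = exprFold)
  data.frame(gene_id = genes,
             log2_D_ratio = calls$log2_D_ratio,
             log2_L_ratio = dx$log2_L_ratio,
             log2_TR_ratio = tr$log2_TR_ratio,
             median_p = calls$median_p,
             rate_ratio = calls$rate_ratio,
             sig_decay = calls$significant,
             diff_expression = dx$differential,
             diff_transcription = tr$diff_transcription,
             row.names = NULL)
}
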