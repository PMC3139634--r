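# vectorized cis/trans rule; ds = species log2 ratio (length n), dh = n x R
# matrix of per-replicate hybrid log2 ratios
.ctLabel <- function(ds, dh, cisFold = 1.2, residFold = 1.3) {
  cf <- log2(cisFold)
  rf <- log2(residFold)
  resid <- dh - ds
  ok <- is.finite(ds) & apply(is.finite(dh), 1, all)
  sameSign <- sweep(sign(dh), 1, sign(ds), "==")
  cis <- ok &
    apply(sameSign & abs(dh) > cf, 1, all) &
    apply(abs(resid) < rf, 1, all)
  trans <- ok &
    apply((!sameSign) | abs(dh) < cf, 1, all) &
    apply(abs(resid) > rf, 1, all)
  label <- rep("excluded", length(ds))
  label[cis] <- "cis"
  label[trans] <- "trans"
  label[!ok] <- "excluded"
  reason <- rep("", length(ds))
  reason[!ok] <- "missing_hybrid"
  reason[ok & label == "excluded"] <- "intermediate"
  list(label = label, resid = resid, reason = reason)
}

#' Classify one inter-species difference as cis or trans
#'
#' In an interspecific hybrid the two alleles share one nucleus: cis effects
#' (mutations at the gene's own locus) discriminate between the alleles,
#' whereas trans effects (diffusible factors) do not. A significant
#' inter-species difference is `cis` when every hybrid replicate's
#' allele-ratio has the same sign as the species ratio and exceeds
#' `cisFold` (default 1.2-fold), with residuals
#' (`delta_hybrid - delta_species`) below `residFold` (default 1.3-fold); it
#' is `trans` when every replicate shows a sign flip or an allele-ratio below
#' `cisFold`, with residuals above `residFold`. Intermediate cases are
#' `excluded`. All thresholds are interpreted in log2-ratio space.
#'
#' @param deltaSpecies species log2 ratio.
#' @param deltaHybrid per-replicate hybrid allele log2 ratios.
#' @param cisFold,residFold the two fold thresholds.
#' @return list with `label` ("cis"/"trans"/"excluded"), `residuals`, and an
#'   exclusion `reason` ("" when labelled).
#' @examples
#' classifyCisTrans(0.8, c(0.70, 0.75))  # cis
#' classifyCisTrans(0.8, c(0.05, 0.10))  # trans
#' @export
classifyCisTrans <- function(deltaSpecies, deltaHybrid, cisFold = 1.2,
                             residFold = 1.3) {
  r <- .ctLabel(deltaSpecies, matrix(deltaHybrid, nrow = 1),
                cisFold, residFold)
  list(label = r$label, residuals = as.numeric(r$resid), reason = r$reason)
}

#' Cis/trans classification table for degradation and level divergence
#'
#' Builds per-gene [classifyCisTrans()] records for the two measures: decay
#' (species ratio of replicate-averaged degradation rates vs per-replicate
#' hybrid allele rate ratios, for genes with a significant differential-decay
#' call) and level (species steady-state ratio vs per-replicate hybrid allele
#' time-0 ratios, for differentially expressed genes).
#'
#' @param de a scaled [DecayExperiment-class] containing hybrid channels.
#' @param fits output of [fitDecay()].
#' @param div a [divergenceTable()] for the species channels.
#' @param hybridChannels the two allele channels (ratio is first/second).
#' @param cisFold,residFold classification thresholds.
#' @return data.frame: `gene_id`, `measure` ("decay"/"level"),
#'   `delta_species`, `delta_hybrid_rep<k>`, `resid_rep<k>`, `label`,
#'   `reason`; or NULL (with a message) when no hybrid data are present.
#' @export
cisTransTable <- function(de, fits, div,
                          hybridChannels = c("hyb_cer", "hyb_par"),
                          cisFold = 1.2, residFold = 1.3) {
  cd <- colData(de)
  reps <- sort(unique(cd$replicate[cd$channel %in% hybridChannels]))
  if (length(reps) == 0L) {
    message("no hybrid channels present; cis/trans classification skipped")
    return(NULL)
  }
  rates <- suppressMessages(geneDecayRates(fits))

  one <- function(genes, ds, dh, measure) {
    r <- .ctLabel(ds, dh, cisFold, residFold)
    out <- data.frame(gene_id = genes, measure = measure,
                      delta_species = ds, row.names = NULL)
    for (k in seq_along(reps)) out[[paste0("delta_hybrid_rep", k)]] <- dh[, k]
    for (k in seq_along(reps)) out[[paste0("resid_rep", k)]] <- r$resid[, k]
    out$label <- r$label
    out$reason <- r$reason
    out
  }

  # decay measure
  sig <- div[div$sig_decay, ]
  dhD <- sapply(reps, function(r) {
    h1 <- .repRate(rates, hybridChannels[1], r)
    h2 <- .repRate(rates, hybridChannels[2], r)
    g <- sig$gene_id
    log2(h1[g] / h2[g])
  })
  dhD <- matrix(dhD, nrow = nrow(sig))
  decay <- one(sig$gene_id, sig$log2_D_ratio, dhD, "decay")

  # level measure
  dx <- div[div$diff_expression, ]
  dhL <- sapply(reps, function(r) {
    lv <- steadyStateLevels(de, levelReplicate = r,
                            channels = hybridChannels)
    l1 <- setNames(lv$log2_L[lv$channel == hybridChannels[1]],
                   lv$gene_id[lv$channel == hybridChannels[1]])
    l2 <- setNames(lv$log2_L[lv$channel == hybridChannels[2]],
                   lv$gene_id[lv$channel == hybridChannels[2]])
    g <- dx$gene_id
    l1[g] - l2[g]
  })
  dhL <- matrix(dhL, nrow = nrow(dx))
  level <- one(dx$gene_id, dx$log2_L_ratio, dhL, "level")

  rbind(decay, level)
}

#' High-confidence cis- and trans-coupled gene sets
#'
#' A gene is cis-coupled (trans-coupled) with high confidence when both its
#' degradation and its level divergence are classified cis (trans), both
#' species ratios exceed `fold` (default 1.5), and the level difference is
#' opposite to that expected from the degradation difference (same sign of
#' the two log ratios).
#'
#' @param ct a [cisTransTable()] data.frame.
#' @param fold magnitude threshold on both species log2 ratios.
#' @return list with character vectors `cis_coupled` and `trans_coupled`.
#' @export
highConfidenceCoupled <- function(ct, fold = 1.5) {
  d <- ct[ct$measure == "decay" & ct$label %in% c("cis", "trans"), ]
  l <- ct[ct$measure == "level" & ct$label %in% c("cis", "trans"), ]
  m <- merge(d[c("gene_id", "delta_species", "label")],
             l[c("gene_id", "delta_species", "label")],
             by = "gene_id", suffixes = c("_decay", "_level"))
  big <- abs(m$delta_species_decay) > log2(fold) &
         abs(m$delta_species_level) > log2(fold)
  same <- sign(m$delta_species_decay) == sign(m$delta_species_level)
  list(cis_coupled = m$gene_id[big & same & m$label_decay == "cis" &
                                 m$label_level == "cis"],
       trans_coupled = m$gene_id[big & same & m$label_decay == "trans" &
                                   m$label_level == "trans"])
}

#' Opposite-effect fractions per cis/trans combination
#'
#' If coupled changes in degradation and transcription arise from the same
#' individual mutations, opposite effects should concentrate in the cis-cis
#' and trans-trans combinations and be absent from the mixed ones; under
#' independent mutations all four combinations behave alike. For every gene
#' with a (non-excluded) label for both measures, the opposite-effect fraction
#' is reported per combination, with an optional sliding-window profile for
#' combinations with enough genes.
#'
#' @param ct a [cisTransTable()] data.frame.
#' @param div the matching [divergenceTable()].
#' @param window window size for the per-combination sliding windows; set to
#'   `NULL` to skip windows.
#' @return list with `summary` (data.frame: `combination`, `n`,
#'   `frac_opposite`) and `windows` (named list of [slidingWindowStats()]
#'   results for combinations with at least `window` genes).
#' @export
combinationAnalysis <- function(ct, div, window = 200) {
  d <- ct[ct$measure == "decay" & ct$label %in% c("cis", "trans"),
          c("gene_id", "label")]
  l <- ct[ct$measure == "level" & ct$label %in% c("cis", "trans"),
          c("gene_id", "label")]
  m <- merge(d, l, by = "gene_id", suffixes = c("_decay", "_level"))
  combos <- c("cis-cis", "cis-trans", "trans-cis", "trans-trans")
  m$combination <- factor(paste(m$label_decay, m$label_level, sep = "-"),
                          levels = combos)
  i <- match(m$gene_id, div$gene_id)
  m$opposite <- sign(div$log2_D_ratio[i]) == sign(div$log2_L_ratio[i])
  summary <- data.frame(
    combination = combos,
    n = as.integer(table(m$combination)),
    frac_opposite = vapply(combos, function(cc) {
      s <- m$opposite[m$combination == cc]
      if (length(s)) mean(s) else NA_real_
    }, numeric(1)),
    row.names = NULL)
  windows <- list()
  if (!is.null(window)) {
    for (cc in combos) {
      g <- m$gene_id[m$combination == cc]
      if (length(g) >= window)
        windows[[cc]] <- slidingWindowStats(div[div$gene_id %in% g, ],
                                            window = window)
    }
  }
  list(summary = summary, windows = windows)
}
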