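#' Pipeline configuration with the published default thresholds
#'
#' Every constant of the analysis, overridable in one place: the 25-min global
#' half-life, the 0.94 R-squared gate, the p < 0.05 and 1.4-fold differential
#' degradation gates, the 1.5-fold expression gate, the cis 1.2-fold and
#' residual 1.3-fold classification thresholds, the 1.5-fold high-confidence
#' gate, 200-gene windows, 10,000 shuffled profiles, and the asymmetric
#' diverged-site LOD rules.
#'
#' @param seed master seed; all pipeline randomness derives from it.
#' @param r2Gate probe goodness-of-fit gate.
#' @param pGate,decayFold differential-degradation gates.
#' @param exprFold differential expression/transcription fold gate.
#' @param cisFold,residFold cis/trans classification thresholds.
#' @param highConfidenceFold high-confidence coupled-set fold gate.
#' @param window sliding-window size in genes.
#' @param globalHalfLife assumed genome-wide half-life (minutes).
#' @param nShuffles shuffled profiles for the goodness-of-fit null.
#' @param lod diverged-site rule constants, see [divergedSiteThresholds()].
#' @param enrichmentFactor planted enrichment of the designated regulator set
#'   in the synthetic demo.
#' @param varEqual pooled-variance t test if `TRUE`.
#' @return named list of settings.
#' @export
pipelineConfig <- function(seed = 1L, r2Gate = 0.94, pGate = 0.05,
                           decayFold = 1.4, exprFold = 1.5, cisFold = 1.2,
                           residFold = 1.3, highConfidenceFold = 1.5,
                           window = 200L, globalHalfLife = 25,
                           nShuffles = 10000L,
                           lod = divergedSiteThresholds(),
                           enrichmentFactor = 4, varEqual = TRUE) {
  list(seed = as.integer(seed), r2Gate = r2Gate, pGate = pGate,
       decayFold = decayFold, exprFold = exprFold, cisFold = cisFold,
       residFold = residFold, highConfidenceFold = highConfidenceFold,
       window = as.integer(window), globalHalfLife = globalHalfLife,
       nShuffles = as.integer(nShuffles), lod = lod,
       enrichmentFactor = enrichmentFactor, varEqual = varEqual)
}

.paramsList <- function(params) {
  sl <- slotNames(params)
  stats::setNames(lapply(sl, function(s) slot(params, s)), sl)
}

# three informative demo PSSMs (width 8, 0.85/0.05 probabilities)
.demoPssms <- function() {
  mk <- function(id, cons) {
    codes <- match(strsplit(cons, "")[[1]], DNA_BASES)
    m <- matrix(0.05, 4, length(codes))
    m[cbind(codes, seq_along(codes))] <- 0.85
    Pssm(m, id = id)
  }
  list(TF1 = mk("TF1", "TGACTCAT"),
       TF2 = mk("TF2", "ACGCGTAC"),
       TF3 = mk("TF3", "CCAATGGA"))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a two-species + hybrid experiment from `params`, then executes
#' every stage in dependency order: global scaling, probe decay fits, gene
#' rates, differential degradation, steady-state levels and the TR = D x L
#' decomposition, coupling classification and windows, cis/trans
#' classification with high-confidence coupled sets and the combination
#' analysis, target-set enrichment of trans-coupled genes, and diverged-site
#' calling on simulated promoters with enrichment among cis-coupled genes.
#' Stages whose inputs are absent (e.g. no hybrid channels) are skipped with
#' an explicit note while upstream stages still run. Reruns with the same
#' `params` and `config` are identical; every output carries the config hash.
#'
#' @param params a [SimParams-class] describing the synthetic experiment.
#' @param config a [pipelineConfig()] list of thresholds.
#' @param outDir optional directory; when given, stage tables are written as
#'   TSV plus a `summary.json`.
#' @param verbose emit one structured message per stage.
#' @return named list of stage results (`truth`, `experiment`, `fits`,
#'   `rates`, `divergence`, `couplingRecords`, `windows`, `couplingSummary`,
#'   `cisTrans`, `highConfidence`, `combination`, `targetSets`, `enrichment`,
#'   `promoters`, `motifCalls`, `motifEnrichment`, `skipped`, `config`,
#'   `configHash`, `summary`).
#' @export
runPipeline <- function(params = simParams(), config = pipelineConfig(),
                        outDir = NULL, verbose = TRUE) {
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  hash <- rlang::hash(list(.paramsList(params), config))
  skipped <- character(0)

  truth <- simulateGroundTruth(params)
  raw <- simulateTimecourse(truth)
  say("simulate", "%d genes, %d probes, %d samples",
      nrow(truth@genes), nrow(truth@probes), ncol(raw))

  de <- globalScale(raw, halfLife = config$globalHalfLife)
  fits <- fitDecay(de, r2Gate = config$r2Gate)
  say("fit", "%d probe fits, %.1f%% passing the R2 gate",
      nrow(fits), 100 * mean(fits$passed_gate))
  rates <- suppressMessages(geneDecayRates(fits))

  div <- divergenceTable(de, fits, pGate = config$pGate,
                         decayFold = config$decayFold,
                         exprFold = config$exprFold,
                         varEqual = config$varEqual)
  say("differential", "%d genes, %d significant decay, %d differential level",
      nrow(div), sum(div$sig_decay), sum(div$diff_expression))

  rec <- quadrantClassify(div)
  win <- slidingWindowStats(rec, window = min(config$window, nrow(rec)))
  cs <- couplingSummary(rec)
  say("coupling", "%d conservative / %d relaxed coupled genes",
      cs$n_coupled_conservative, cs$n_coupled_relaxed)

  haveHybrid <- any(colData(de)$channel %in% c("hyb_cer", "hyb_par"))
  if (haveHybrid) {
    ct <- cisTransTable(de, fits, div, cisFold = config$cisFold,
                        residFold = config$residFold)
    hc <- highConfidenceCoupled(ct, fold = config$highConfidenceFold)
    comb <- combinationAnalysis(ct, div, window = NULL)
    say("cistrans", "%d records; %d cis-coupled, %d trans-coupled",
        nrow(ct), length(hc$cis_coupled), length(hc$trans_coupled))
  } else {
    ct <- NULL; hc <- NULL; comb <- NULL
    skipped <- c(skipped, "cistrans: no hybrid channels in the experiment")
    say("cistrans", "skipped: no hybrid channels")
  }

  sets <- simulateTargetSets(truth,
                             enrichmentFactor = config$enrichmentFactor)
  universe <- div$gene_id
  query <- if (!is.null(hc) && length(hc$trans_coupled) >= 3)
    hc$trans_coupled else rec$gene_id[rec$coupled_conservative]
  background <- setdiff(rec$gene_id[rec$diff_transcription &
                                      !rec$coupled_conservative], query)
  if (length(query) >= 3 && length(background) >= 3) {
    enr <- enrichmentScan(intersect(query, universe), sets, universe,
                          background = intersect(background, universe))
    say("enrich", "top set %s (p = %.3g)", enr$set_id[1], enr$p_value[1])
  } else {
    enr <- NULL
    skipped <- c(skipped, "enrichment: too few coupled genes to test")
    say("enrich", "skipped: too few coupled genes")
  }

  pssms <- .demoPssms()
  g <- truth@genes
  cisCoupled <- g$gene_id[g$class == "coupled-opposite" &
                            g$mech_decay == "cis"]
  txOnly <- g$gene_id[g$class %in% c("expression-only", "both-independent")]
  set.seed(params@seed + 4000L)
  nDiv <- min(length(cisCoupled),
              max(2L, round(0.4 * length(cisCoupled))))
  divGenes <- c(if (nDiv > 0) sample(cisCoupled, nDiv),
                if (length(txOnly))
                  sample(txOnly, min(length(txOnly),
                                     max(1L, round(0.1 * length(txOnly))))))
  if (length(divGenes) > 0) {
    prom <- simulatePromoters(truth, pssms, divergedGenes = divGenes,
                              intactGenes = character(0),
                              seed = params@seed + 4001L)
    bound <- unique(c(divGenes,
                      sample(g$gene_id, min(nrow(g),
                                            round(0.2 * nrow(g))))))
    calls <- callDivergedSites(pssms, prom$cer, prom$par, boundGenes = bound,
                               thresholds = config$lod)
    menr <- divergedMotifEnrichment(calls, cisCoupled, txOnly)
    say("motifs", "%d diverged-site calls", nrow(calls))
  } else {
    prom <- NULL; calls <- NULL; menr <- NULL
    skipped <- c(skipped, "motifs: no candidate genes for planted divergence")
    say("motifs", "skipped: no candidate genes")
  }

  summary <- list(
    config_hash = hash,
    n_genes = nrow(truth@genes),
    n_probes = nrow(truth@probes),
    frac_probes_passing = mean(fits$passed_gate),
    n_sig_decay = sum(div$sig_decay),
    n_diff_expression = sum(div$diff_expression),
    n_coupled_conservative = cs$n_coupled_conservative,
    n_coupled_relaxed = cs$n_coupled_relaxed,
    n_cis_coupled = if (is.null(hc)) NA else length(hc$cis_coupled),
    n_trans_coupled = if (is.null(hc)) NA else length(hc$trans_coupled),
    n_motif_calls = if (is.null(calls)) NA else nrow(calls),
    skipped = skipped)

  bundle <- list(truth = truth, experiment = de, fits = fits, rates = rates,
                 divergence = div, couplingRecords = rec, windows = win,
                 couplingSummary = cs, cisTrans = ct, highConfidence = hc,
                 combination = comb, targetSets = sets, enrichment = enr,
                 promoters = prom, motifCalls = calls, motifEnrichment = menr,
                 skipped = skipped, config = config, configHash = hash,
                 summary = summary)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, name) if (!is.null(x))
      write.table(x, file.path(outDir, paste0(name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    writeProbeTable(de, file.path(outDir, "scaled_probe_table.tsv"))
    wt(as.data.frame(truth@genes), "truth_genes")
    wt(fits, "probe_fits")
    wt(rates, "gene_rates")
    wt(rec, "divergence")
    wt(win$windows, "sliding_windows")
    wt(ct, "cis_trans")
    wt(enr, "enrichment")
    wt(calls, "motif_calls")
    wt(menr, "motif_enrichment")
    writeGmt(sets, file.path(outDir, "target_sets.gmt"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  bundle
}

#' Validate pipeline input files
#'
#' Checks the schemas of the on-disk inputs -- probe table (columns, time
#' grid, finite values, probe-to-gene mapping), gene sets (GMT parse,
#' membership in the universe), promoters (FASTA parse, paired ids) and PSSMs
#' (MEME parse) -- and returns a machine-readable issue list. Purely a
#' reporting operation: it never throws on malformed content.
#'
#' @param paths named list with any of `probeTable`, `gmt`, `promotersCer`,
#'   `promotersPar`, `pssm`.
#' @param universe optional gene universe used to check GMT membership.
#' @return data.frame `component`, `level` ("error"/"warning"), `message`;
#'   zero rows when everything is well-formed.
#' @export
validateInputs <- function(paths, universe = NULL) {
  issues <- list()
  add <- function(component, level, msg)
    issues[[length(issues) + 1L]] <<- data.frame(component = component,
                                                 level = level, message = msg)
  if (!is.null(paths$probeTable)) {
    df <- tryCatch(read.delim(paths$probeTable, stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) {
      add("probeTable", "error", "cannot read file")
    } else {
      need <- c("probe_id", "gene_id", "channel", "replicate")
      miss <- setdiff(need, names(df))
      if (length(miss))
        add("probeTable", "error",
            paste("missing columns:", paste(miss, collapse = ", ")))
      tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
      if (length(tcols) < 4L)
        add("probeTable", "error",
            sprintf("expected 4 time-point columns, found %d", length(tcols)))
      for (a in tcols)
        if (anyNA(df[[a]]) || any(!is.finite(df[[a]])))
          add("probeTable", "error",
              sprintf("non-finite values in column %s", a))
      if ("gene_id" %in% names(df) && anyNA(df$gene_id))
        add("probeTable", "error", "probes with missing gene annotation")
      if ("channel" %in% names(df) &&
          !all(df$channel %in% c("cer", "par", "hyb_cer", "hyb_par")))
        add("probeTable", "error", "unknown channel values")
    }
  }
  if (!is.null(paths$gmt)) {
    sets <- tryCatch(readGmt(paths$gmt), error = function(e) NULL)
    if (is.null(sets) || length(sets) == 0L) {
      add("gmt", "error", "cannot parse gene sets")
    } else if (!is.null(universe)) {
      absent <- setdiff(unique(unlist(sets)), universe)
      if (length(absent))
        add("gmt", "warning",
            sprintf("%d gene-set members absent from the universe",
                    length(absent)))
    }
  }
  readFasta <- function(p) tryCatch(Biostrings::readDNAStringSet(p),
                                    error = function(e) NULL)
  pc <- pp <- NULL
  if (!is.null(paths$promotersCer)) {
    pc <- readFasta(paths$promotersCer)
    if (is.null(pc)) add("promotersCer", "error", "cannot parse FASTA")
  }
  if (!is.null(paths$promotersPar)) {
    pp <- readFasta(paths$promotersPar)
    if (is.null(pp)) add("promotersPar", "error", "cannot parse FASTA")
  }
  if (!is.null(pc) && !is.null(pp)) {
    unpaired <- length(setdiff(names(pc), names(pp))) +
      length(setdiff(names(pp), names(pc)))
    if (unpaired > 0)
      add("promoters", "warning",
          sprintf("%d promoters without an ortholog partner", unpaired))
  }
  if (!is.null(paths$pssm)) {
    pm <- tryCatch(readMeme(paths$pssm), error = function(e) NULL)
    if (is.null(pm)) add("pssm", "error", "cannot parse MEME motifs")
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(component = character(0), level = character(0),
               message = character(0))
}
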