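#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames colData rowData
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Simulation parameters for a synthetic two-species + hybrid experiment
#'
#' `SimParams` collects every knob of the synthetic-data generator: the size of
#' the experiment, the true degradation-rate and steady-state-level
#' distributions, which fractions of genes diverge in degradation and/or
#' expression (and how often the two are coupled with opposite effects on mRNA
#' level), how diverged genes split into cis and trans mechanisms, measurement
#' noise, and the RNG seed. Use [simParams()] to construct a validated object.
#'
#' @slot nGenes number of genes.
#' @slot probesPerGene integer pair, range of probes per gene (microarrays of
#'   this design carry 2--5 probes per gene).
#' @slot timePoints minutes after transcriptional arrest at which mRNA is
#'   sampled; strictly increasing, default `c(0, 20, 40, 60)`.
#' @slot globalHalfLife assumed genome-wide mRNA half-life in minutes used to
#'   anchor the generator (and later undone by [globalScale()]); default 25.
#' @slot rateLogMean,rateLogSd mean and sd of the per-gene log2 degradation
#'   rate (log2 units/min); the default mean `log2(1/25)` puts the median
#'   half-life at 25 min, self-consistent with `globalHalfLife`.
#' @slot levelLogMean,levelLogSd mean and sd of per-gene log2 steady-state
#'   intensity.
#' @slot fracDivergedDecay,fracDivergedExpression,fracCoupledOpposite fractions
#'   of genes (of all `nGenes`) planted with a degradation effect, an
#'   expression effect, and with coupled opposite effects, respectively.
#' @slot fracCis fraction of planted effects realized in cis (the rest are
#'   trans).
#' @slot effectSizeLog2 minimum |log2 ratio| of planted effects.
#' @slot noiseSd per-measurement log2 noise sd.
#' @slot nReplicates biological replicates per channel (default 2).
#' @slot couplingMode `"classes"` plants disjoint gene classes
#'   (coupled-opposite / decay-only / expression-only / conserved);
#'   `"independent"` plants decay and expression divergence on independently
#'   drawn gene sets (the chance-expectation design).
#' @slot mechanismMode `"shared"` gives each coupled gene one mechanism (cis or
#'   trans) for both its degradation and its transcription effect;
#'   `"independent"` draws the two mechanisms independently.
#' @slot seed integer RNG seed; all generator randomness derives from it.
#'
#' @seealso [simParams()], [simulateGroundTruth()], [simulateTimecourse()]
#' @exportClass SimParams
setClass("SimParams", slots = c(
  nGenes = "integer",
  probesPerGene = "integer",
  timePoints = "numeric",
  globalHalfLife = "numeric",
  rateLogMean = "numeric",
  rateLogSd = "numeric",
  levelLogMean = "numeric",
  levelLogSd = "numeric",
  fracDivergedDecay = "numeric",
  fracDivergedExpression = "numeric",
  fracCoupledOpposite = "numeric",
  fracCis = "numeric",
  effectSizeLog2 = "numeric",
  noiseSd = "numeric",
  nReplicates = "integer",
  couplingMode = "character",
  mechanismMode = "character",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character(0)
  fr <- c(decay = object@fracDivergedDecay,
          expression = object@fracDivergedExpression,
          coupled = object@fracCoupledOpposite,
          cis = object@fracCis)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "all fractions must lie in [0, 1]")
  if (object@couplingMode == "classes" &&
      object@fracCoupledOpposite >
        min(object@fracDivergedDecay, object@fracDivergedExpression) + 1e-9)
    msg <- c(msg, paste("fracCoupledOpposite cannot exceed",
                        "min(fracDivergedDecay, fracDivergedExpression)"))
  if (object@couplingMode == "independent" && object@fracCoupledOpposite > 0)
    msg <- c(msg, "fracCoupledOpposite must be 0 when couplingMode='independent'")
  if (!object@couplingMode %in% c("classes", "independent"))
    msg <- c(msg, "couplingMode must be 'classes' or 'independent'")
  if (!object@mechanismMode %in% c("shared", "independent"))
    msg <- c(msg, "mechanismMode must be 'shared' or 'independent'")
  if (object@nGenes < 4L)
    msg <- c(msg, "nGenes must be at least 4")
  if (length(object@probesPerGene) != 2L ||
      object@probesPerGene[1] < 1L ||
      object@probesPerGene[1] > object@probesPerGene[2])
    msg <- c(msg, "probesPerGene must be an increasing pair of positive integers")
  if (length(object@timePoints) < 3L || any(diff(object@timePoints) <= 0))
    msg <- c(msg, "timePoints must be strictly increasing")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@globalHalfLife <= 0) msg <- c(msg, "globalHalfLife must be positive")
  if (object@effectSizeLog2 <= 0) msg <- c(msg, "effectSizeLog2 must be positive")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' Validated constructor for [SimParams-class]. Defaults emulate the study
#' design the package targets: four time points after transcriptional arrest
#' (0/20/40/60 min), a 25-min genome-wide half-life, 2--5 probes per gene, two
#' biological replicates per channel, ~11% of genes diverged in degradation,
#' ~50% in expression, with roughly half of the degradation changes coupled to
#' opposite transcription changes, and ~60% of effects in cis.
#'
#' @param nGenes number of genes to simulate.
#' @param probesPerGene integer pair giving the probes-per-gene range.
#' @param timePoints sampling times in minutes after transcriptional arrest.
#' @param globalHalfLife assumed genome-wide half-life (minutes).
#' @param rateLogMean,rateLogSd log2-scale mean/sd of true degradation rates
#'   (log2 units/min).
#' @param levelLogMean,levelLogSd log2-scale mean/sd of true steady-state
#'   intensities.
#' @param fracDivergedDecay,fracDivergedExpression,fracCoupledOpposite,fracCis
#'   planted-effect fractions, see [SimParams-class].
#' @param effectSizeLog2 minimum |log2 ratio| of planted effects.
#' @param noiseSd per-measurement log2 noise sd.
#' @param nReplicates replicates per channel.
#' @param couplingMode `"classes"` or `"independent"`, see [SimParams-class].
#' @param mechanismMode `"shared"` or `"independent"`.
#' @param seed integer RNG seed.
#' @return A validated `SimParams` object.
#' @examples
#' p <- simParams(nGenes = 100, seed = 7)
#' p
#' @export
simParams <- function(nGenes = 1000L,
                      probesPerGene = c(2L, 5L),
                      timePoints = c(0, 20, 40, 60),
                      globalHalfLife = 25,
                      rateLogMean = log2(1 / 25),
                      rateLogSd = 0.5,
                      levelLogMean = 10,
                      levelLogSd = 1.5,
                      fracDivergedDecay = 0.11,
                      fracDivergedExpression = 0.5,
                      fracCoupledOpposite = 0.05,
                      fracCis = 0.6,
                      effectSizeLog2 = 1,
                      noiseSd = 0.05,
                      nReplicates = 2L,
                      couplingMode = c("classes", "independent"),
                      mechanismMode = c("shared", "independent"),
                      seed = 1L) {
  couplingMode <- match.arg(couplingMode)
  mechanismMode <- match.arg(mechanismMode)
  if (couplingMode == "independent") fracCoupledOpposite <- 0
  new("SimParams",
      nGenes = as.integer(nGenes),
      probesPerGene = as.integer(probesPerGene),
      timePoints = as.numeric(timePoints),
      globalHalfLife = as.numeric(globalHalfLife),
      rateLogMean = as.numeric(rateLogMean),
      rateLogSd = as.numeric(rateLogSd),
      levelLogMean = as.numeric(levelLogMean),
      levelLogSd = as.numeric(levelLogSd),
      fracDivergedDecay = as.numeric(fracDivergedDecay),
      fracDivergedExpression = as.numeric(fracDivergedExpression),
      fracCoupledOpposite = as.numeric(fracCoupledOpposite),
      fracCis = as.numeric(fracCis),
      effectSizeLog2 = as.numeric(effectSizeLog2),
      noiseSd = as.numeric(noiseSd),
      nReplicates = as.integer(nReplicates),
      couplingMode = couplingMode,
      mechanismMode = mechanismMode,
      seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nGenes, "genes,",
      paste(object@probesPerGene, collapse = "-"), "probes/gene,",
      length(object@timePoints), "time points\n")
  cat("  diverged decay/expression/coupled:",
      sprintf("%.3f / %.3f / %.3f", object@fracDivergedDecay,
              object@fracDivergedExpression, object@fracCoupledOpposite),
      sprintf("(cis %.2f, %s, %s mechanisms)", object@fracCis,
              object@couplingMode, object@mechanismMode), "\n")
  cat(sprintf("  effect >= %.2f log2, noise sd %.3f, %d replicates, seed %d\n",
              object@effectSizeLog2, object@noiseSd, object@nReplicates,
              object@seed))
})

#' Ground truth of a synthetic experiment
#'
#' Per-gene true degradation rates (`D_*`, log2 units/min), steady-state
#' levels (`L_*`, linear intensity units) and transcription rates
#' (`TR = D * L`, exact by construction) for the two species channels and the
#' two hybrid alleles, together with the planted log2 effect ratios, class
#' labels (`coupled-opposite`, `decay-only`, `expression-only`,
#' `both-independent`, `conserved`) and per-measure mechanism labels
#' (`cis`/`trans`/`none`), plus the per-probe intensity offsets.
#'
#' @slot genes a [S4Vectors::DataFrame] with one row per gene.
#' @slot probes a [S4Vectors::DataFrame] with one row per probe
#'   (`probe_id`, `gene_id`, `offset`).
#' @slot params the [SimParams-class] used to generate the truth.
#' @seealso [simulateGroundTruth()]
#' @exportClass GroundTruth
setClass("GroundTruth", slots = c(
  genes = "DataFrame",
  probes = "DataFrame",
  params = "SimParams"
))

setValidity("GroundTruth", function(object) {
  g <- object@genes
  need <- c("gene_id", "class", "mech_decay", "mech_expression",
            "D_cer", "D_par", "D_hyb_cer", "D_hyb_par",
            "L_cer", "L_par", "L_hyb_cer", "L_hyb_par",
            "TR_cer", "TR_par",
            "log2_D_ratio", "log2_L_ratio", "log2_TR_ratio")
  if (!all(need %in% colnames(g)))
    return(paste("genes is missing columns:",
                 paste(setdiff(need, colnames(g)), collapse = ", ")))
  if (any(c(g$D_cer, g$D_par, g$L_cer, g$L_par) <= 0))
    return("all rates and levels must be positive")
  if (!all(c("probe_id", "gene_id", "offset") %in% colnames(object@probes)))
    return("probes must have probe_id, gene_id, offset")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  g <- object@genes
  cat("GroundTruth:", nrow(g), "genes,", nrow(object@probes), "probes\n")
  tab <- table(g$class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  mechanisms (decay):",
      paste(names(table(g$mech_decay)), table(g$mech_decay),
            sep = "=", collapse = ", "), "\n")
})

#' Probe-level transcription-arrest time courses
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' assay of log2 intensities per time point (assays `t0`, `t20`, ...), rows =
#' probes (with `probe_id` and `gene_id` in `rowData`) and columns = one
#' channel/replicate combination each (`channel` in
#' `{cer, par, hyb_cer, hyb_par}` and `replicate` in `colData`). The sampling
#' grid lives in `metadata(x)$timePoints`; `metadata(x)$scaled` records whether
#' [globalScale()] has been applied.
#'
#' @seealso [DecayExperiment()], [globalScale()], [fitDecay()]
#' @exportClass DecayExperiment
setClass("DecayExperiment", contains = "SummarizedExperiment")

setValidity("DecayExperiment", function(object) {
  tp <- metadata(object)$timePoints
  if (is.null(tp) || any(diff(tp) <= 0))
    return("metadata()$timePoints must be strictly increasing")
  if (!identical(assayNames(object), paste0("t", tp)))
    return("assays must be named t<time> and match metadata()$timePoints")
  cd <- colData(object)
  if (!all(c("channel", "replicate") %in% colnames(cd)))
    return("colData must contain 'channel' and 'replicate'")
  if (!all(cd$channel %in% c("cer", "par", "hyb_cer", "hyb_par")))
    return("channel must be one of cer, par, hyb_cer, hyb_par")
  if (!all(c("probe_id", "gene_id") %in% colnames(rowData(object))))
    return("rowData must contain 'probe_id' and 'gene_id'")
  TRUE
})

#' Build a DecayExperiment from per-time-point intensity matrices
#'
#' @param assays list of numeric matrices (probes x samples), one per time
#'   point, in time order.
#' @param probe_id,gene_id per-row probe and gene identifiers.
#' @param channel,replicate per-column channel (`cer`, `par`, `hyb_cer`,
#'   `hyb_par`) and replicate index.
#' @param timePoints sampling times in minutes.
#' @param scaled whether the data are already anchored to the global decay.
#' @return A [DecayExperiment-class] object.
#' @seealso [probeTable()], [readProbeTable()]
#' @export
DecayExperiment <- function(assays, probe_id, gene_id, channel, replicate,
                            timePoints = c(0, 20, 40, 60), scaled = FALSE) {
  names(assays) <- paste0("t", timePoints)
  assays <- lapply(assays, function(a) {
    a <- as.matrix(a)
    dimnames(a) <- NULL
    a
  })
  rd <- DataFrame(probe_id = probe_id, gene_id = gene_id,
                  row.names = probe_id)
  cd <- DataFrame(channel = channel, replicate = as.integer(replicate),
                  row.names = paste(channel, replicate, sep = "_"))
  se <- SummarizedExperiment(assays = assays, rowData = rd, colData = cd,
                             metadata = list(timePoints = as.numeric(timePoints),
                                             scaled = isTRUE(scaled)))
  new("DecayExperiment", se)
}

setMethod("show", "DecayExperiment", function(object) {
  cd <- colData(object)
  cat("DecayExperiment:", nrow(object), "probes,",
      length(unique(rowData(object)$gene_id)), "genes\n")
  cat("  channels x replicates:",
      paste(rownames(cd), collapse = ", "), "\n")
  cat("  time points (min):",
      paste(metadata(object)$timePoints, collapse = ", "),
      if (isTRUE(metadata(object)$scaled)) "[globally scaled]" else "[raw]",
      "\n")
})

#' Position-specific scoring matrix (PSSM)
#'
#' Per-position base probabilities over \{A, C, G, T\} with a pseudocount and a
#' background distribution; log-odds (LOD) scores are
#' `sum_i log2(p_i(base_i) / q(base_i))` over the window. The constructor
#' accepts a 4 x W matrix with rownames A/C/G/T or a W x 4 matrix in MEME row
#' order (positions in rows), applies the pseudocount, and renormalizes each
#' position.
#'
#' @slot id motif identifier.
#' @slot probs 4 x W base-probability matrix (rows A, C, G, T), pseudocounted
#'   and normalized.
#' @slot background length-4 background base frequencies.
#' @slot pseudocount pseudocount added to each probability before
#'   normalization.
#' @seealso [Pssm()], [lodScore()], [scanPromoter()]
#' @exportClass Pssm
setClass("Pssm", slots = c(
  id = "character",
  probs = "matrix",
  background = "numeric",
  pseudocount = "numeric"
))

setValidity("Pssm", function(object) {
  p <- object@probs
  if (nrow(p) != 4L || !identical(rownames(p), DNA_BASES))
    return("probs must be a 4 x W matrix with rows A, C, G, T")
  if (ncol(p) < 1L) return("motif width must be >= 1")
  if (any(p < 0)) return("probabilities must be non-negative")
  if (any(abs(colSums(p) - 1) > 1e-9))
    return("each position's probabilities must sum to 1 (within 1e-9)")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9 || any(object@background <= 0))
    return("background must be 4 positive frequencies summing to 1")
  TRUE
})

#' @rdname Pssm-class
#' @param probs base-probability matrix, 4 x W (rownames A/C/G/T) or W x 4
#'   (MEME orientation, positions in rows).
#' @param id motif identifier.
#' @param background background base frequencies (A, C, G, T).
#' @param pseudocount pseudocount added before per-position renormalization.
#' @return A validated `Pssm`.
#' @examples
#' m <- Pssm(matrix(rep(c(0.85, 0.05, 0.05, 0.05), 3), nrow = 4), id = "ex")
#' maxLod(m)
#' @export
Pssm <- function(probs, id = "motif",
                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                 pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (!is.null(rownames(probs)) && setequal(rownames(probs), DNA_BASES)) {
    probs <- probs[DNA_BASES, , drop = FALSE]
  } else if (nrow(probs) != 4L && ncol(probs) == 4L) {
    probs <- t(probs)
  } else if (nrow(probs) != 4L) {
    stop("probs must have 4 rows (bases) or 4 columns (MEME orientation)")
  }
  rownames(probs) <- DNA_BASES
  colnames(probs) <- NULL
  probs <- probs + pseudocount
  probs <- sweep(probs, 2, colSums(probs), "/")
  background <- unname(as.numeric(background))
  new("Pssm", id = id, probs = probs, background = background,
      pseudocount = as.numeric(pseudocount))
}

setMethod("show", "Pssm", function(object) {
  cat("Pssm", object@id, "- width", ncol(object@probs),
      sprintf("- max LOD %.2f", maxLod(object)), "\n")
  cat("  consensus:", consensusSequence(object), "\n")
})

#' Motif width, maximal LOD and consensus of a PSSM
#'
#' @param pssm a [Pssm-class] object.
#' @return `motifWidth()` the motif width; `maxLod()` the maximal achievable
#'   LOD score (log2); `consensusSequence()` the highest-probability base per
#'   position.
#' @export
motifWidth <- function(pssm) ncol(pssm@probs)

#' @rdname motifWidth
#' @export
maxLod <- function(pssm) sum(apply(.lodMatrix(pssm), 2, max))

#' @rdname motifWidth
#' @export
consensusSequence <- function(pssm) {
  paste(DNA_BASES[apply(pssm@probs, 2, which.max)], collapse = "")
}

.lodMatrix <- function(pssm) log2(pssm@probs / pssm@background)
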