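#' @importFrom stats rnorm runif median
NULL

# round to the nearest even count (effects are planted in +/- pairs)
.evenCount <- function(x) {
  k <- as.integer(round(x))
  if (k %% 2L == 1L) k <- k - 1L
  k
}

# Disjoint gene pairs with matched probe counts, in random order.  Pairing one
# "+" and one "-" gene that share a base value and a probe count makes every
# planted effect cancel exactly in the probe-weighted column sums, which is
# what lets the equal-total-RNA masking be undone without bias.
.plantPairs <- function(used, counts, npairs) {
  if (npairs == 0L) return(matrix(integer(0), nrow = 2L))
  cand <- which(!used)
  grps <- split(cand, counts[cand])
  pairs <- lapply(grps, function(g) {
    g <- g[sample.int(length(g))]
    m <- length(g) %/% 2L
    matrix(g[seq_len(2L * m)], nrow = 2L)
  })
  p <- do.call(cbind, c(pairs, list(matrix(integer(0), nrow = 2L))))
  if (ncol(p) < npairs)
    stop("not enough free genes with matched probe counts to plant the ",
         "requested effects")
  p <- p[, sample.int(ncol(p)), drop = FALSE]
  p[, seq_len(npairs), drop = FALSE]
}

# cis/trans labels for a set of effect pairs, cis planted by exact count
.mechLabels <- function(npairs, fracCis) {
  lab <- rep("trans", npairs)
  ncis <- round(fracCis * npairs)
  if (ncis > 0) lab[seq_len(ncis)] <- "cis"
  lab[sample.int(npairs)]
}

#' Simulate the ground truth of a two-species + hybrid experiment
#'
#' Draws per-gene true degradation rates and steady-state levels, plants
#' inter-species effects by exact count (shuffled assignment, not Bernoulli),
#' assigns cis/trans mechanisms, and derives the hybrid-allele truth: cis
#' effects are preserved between the alleles, trans effects are equalized at
#' the log-scale midpoint of the two species' values.
#'
#' Effects are planted in sign-balanced pairs (one gene up, one gene down, with
#' a shared base value and probe count), and the species-channel rates are then
#' rescaled by a single common factor so that the probe-weighted mean
#' degradation rate equals `1/globalHalfLife` exactly. This makes the
#' generator's equal-total-RNA renormalization exactly invertible by
#' [globalScale()]: with `noiseSd = 0` the pipeline recovers every planted rate
#' to machine precision. The hybrid channels share the species scale factor so
#' that cis-gene allele truth equals the species truth exactly.
#'
#' Gene classes under `couplingMode = "classes"` (disjoint): coupled-opposite
#' genes get same-sign degradation and level effects (so the transcription
#' effect exceeds and opposes the expected level consequence of the
#' degradation effect); decay-only genes keep transcription conserved, so
#' their level follows the degradation change inversely (`L = TR/D`);
#' expression-only genes get a level (= transcription) effect alone. Under
#' `couplingMode = "independent"` the decay-diverged and expression-diverged
#' sets are drawn independently; genes hit by both are labelled
#' `both-independent` and carry independent effect signs -- the design under
#' which 50% of doubly-differential genes are expected to show opposite
#' effects by chance.
#'
#' @param params a [SimParams-class] object.
#' @return A [GroundTruth-class] object. Deterministic given `params@seed`.
#' @examples
#' truth <- simulateGroundTruth(simParams(nGenes = 200, seed = 1))
#' truth
#' @export
simulateGroundTruth <- function(params = simParams()) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  set.seed(params@seed)
  n <- params@nGenes
  gene_id <- sprintf("g%05d", seq_len(n))
  lo <- params@probesPerGene[1L]
  hi <- params@probesPerGene[2L]
  nprobes <- if (lo == hi) rep.int(lo, n) else
    sample(seq.int(lo, hi), n, replace = TRUE)

  baseD <- params@rateLogMean + rnorm(n, 0, params@rateLogSd)  # log2 rate
  baseL <- rnorm(n, params@levelLogMean, params@levelLogSd)    # log2 level

  d_eff <- numeric(n)            # planted log2(D_cer/D_par)
  l_eff <- numeric(n)            # planted log2(L_cer/L_par)
  cls <- rep("conserved", n)
  mech_d <- rep("none", n)       # mechanism of the degradation effect
  mech_e <- rep("none", n)       # mechanism of the level/transcription effect

  e <- params@effectSizeLog2
  mag <- function(k) e * runif(k, 1, 1.25)

  kDec <- .evenCount(params@fracDivergedDecay * n)
  kExp <- .evenCount(params@fracDivergedExpression * n)
  kCpl <- .evenCount(params@fracCoupledOpposite * n)

  plantDecay <- function(pairs, withLevel) {
    i <- pairs[1L, ]; j <- pairs[2L, ]
    m <- mag(ncol(pairs))
    baseD[j] <<- baseD[i]
    baseL[j] <<- baseL[i]
    d_eff[i] <<- m; d_eff[j] <<- -m
    if (withLevel) {                 # coupled: same-sign level effect
      ml <- mag(ncol(pairs))
      l_eff[i] <<- ml; l_eff[j] <<- -ml
    } else {                         # TR conserved: level follows D inversely
      l_eff[i] <<- -m; l_eff[j] <<- m
    }
    invisible(NULL)
  }
  plantLevel <- function(pairs) {
    i <- pairs[1L, ]; j <- pairs[2L, ]
    ml <- mag(ncol(pairs))
    baseL[j] <<- baseL[i]
    l_eff[i] <<- ml; l_eff[j] <<- -ml
    invisible(NULL)
  }

  if (params@couplingMode == "classes") {
    if (kCpl > min(kDec, kExp))
      stop("coupled-opposite count exceeds a diverged-class count")
    used <- logical(n)
    cpl <- .plantPairs(used, nprobes, kCpl %/% 2L); used[cpl] <- TRUE
    dec <- .plantPairs(used, nprobes, (kDec - kCpl) %/% 2L); used[dec] <- TRUE
    exo <- .plantPairs(used, nprobes, (kExp - kCpl) %/% 2L); used[exo] <- TRUE
    if (ncol(cpl)) { plantDecay(cpl, withLevel = TRUE);  cls[cpl] <- "coupled-opposite" }
    if (ncol(dec)) { plantDecay(dec, withLevel = FALSE); cls[dec] <- "decay-only" }
    if (ncol(exo)) { plantLevel(exo);                    cls[exo] <- "expression-only" }

    if (ncol(cpl)) {
      labC <- .mechLabels(ncol(cpl), params@fracCis)
      mech_d[cpl[1L, ]] <- labC; mech_d[cpl[2L, ]] <- labC
      if (params@mechanismMode == "shared") {
        mech_e[cpl[1L, ]] <- labC; mech_e[cpl[2L, ]] <- labC
      } else {
        labE <- .mechLabels(ncol(cpl), params@fracCis)
        mech_e[cpl[1L, ]] <- labE; mech_e[cpl[2L, ]] <- labE
      }
    }
    if (ncol(dec)) {
      labD <- .mechLabels(ncol(dec), params@fracCis)
      mech_d[dec[1L, ]] <- labD; mech_d[dec[2L, ]] <- labD
      # the level response of a decay-only gene is driven by the same mutation
      mech_e[dec[1L, ]] <- labD; mech_e[dec[2L, ]] <- labD
    }
    if (ncol(exo)) {
      labE <- .mechLabels(ncol(exo), params@fracCis)
      mech_e[exo[1L, ]] <- labE; mech_e[exo[2L, ]] <- labE
    }
  } else {
    usedD <- logical(n); usedE <- logical(n)
    dec <- .plantPairs(usedD, nprobes, kDec %/% 2L); usedD[dec] <- TRUE
    exo <- .plantPairs(usedE, nprobes, kExp %/% 2L); usedE[exo] <- TRUE
    if (ncol(dec)) {                 # decay effect only; level untouched
      i <- dec[1L, ]; j <- dec[2L, ]
      m <- mag(ncol(dec))
      baseD[j] <- baseD[i]
      d_eff[i] <- m; d_eff[j] <- -m
      labD <- .mechLabels(ncol(dec), params@fracCis)
      mech_d[dec[1L, ]] <- labD; mech_d[dec[2L, ]] <- labD
    }
    if (ncol(exo)) {
      plantLevel(exo)
      labE <- .mechLabels(ncol(exo), params@fracCis)
      mech_e[exo[1L, ]] <- labE; mech_e[exo[2L, ]] <- labE
    }
    inD <- seq_len(n) %in% dec
    inE <- seq_len(n) %in% exo
    cls[inD & !inE] <- "decay-only"
    cls[!inD & inE] <- "expression-only"
    cls[inD & inE] <- "both-independent"
  }

  # Rescale so the probe-weighted mean species rate equals 1/half-life exactly
  # (self-consistency of the global scaling); one factor for all channels so
  # ratio truth and cis allele identity are untouched.
  Dcer <- 2^(baseD + d_eff / 2)
  Dpar <- 2^(baseD - d_eff / 2)
  w <- nprobes
  sc <- (1 / params@globalHalfLife) / (sum(w * Dcer) / sum(w))
  Dcer <- Dcer * sc
  Dpar <- Dpar * sc
  dCis <- mech_d == "cis"
  eCis <- mech_e == "cis"
  Dhc <- 2^(baseD + ifelse(dCis, d_eff / 2, 0)) * sc
  Dhp <- 2^(baseD - ifelse(dCis, d_eff / 2, 0)) * sc
  Lcer <- 2^(baseL + l_eff / 2)
  Lpar <- 2^(baseL - l_eff / 2)
  Lhc <- 2^(baseL + ifelse(eCis, l_eff / 2, 0))
  Lhp <- 2^(baseL - ifelse(eCis, l_eff / 2, 0))

  genes <- DataFrame(
    gene_id = gene_id, n_probes = nprobes, class = cls,
    mech_decay = mech_d, mech_expression = mech_e,
    D_cer = Dcer, D_par = Dpar, D_hyb_cer = Dhc, D_hyb_par = Dhp,
    L_cer = Lcer, L_par = Lpar, L_hyb_cer = Lhc, L_hyb_par = Lhp,
    TR_cer = Dcer * Lcer, TR_par = Dpar * Lpar,
    TR_hyb_cer = Dhc * Lhc, TR_hyb_par = Dhp * Lhp,
    log2_D_ratio = d_eff, log2_L_ratio = l_eff,
    log2_TR_ratio = d_eff + l_eff,
    row.names = gene_id)

  pg <- rep.int(seq_len(n), nprobes)
  probes <- DataFrame(
    probe_id = paste0(gene_id[pg], "_p", sequence(nprobes)),
    gene_id = gene_id[pg],
    offset = rnorm(length(pg), 0, 2))

  new("GroundTruth", genes = genes, probes = probes, params = params)
}

#' Simulate probe-level transcription-arrest time courses
#'
#' Generates, for every channel (both species and both hybrid alleles) and
#' replicate, each probe's log2 intensity trajectory
#' `log2(L) + offset - D * t`, adds independent per-measurement Gaussian
#' noise, and then renormalizes each column (channel x replicate x time point)
#' to mean 0 -- emulating the experimental protocol in which equal amounts of
#' total RNA are hybridized at every time point, which masks the global decay.
#' [globalScale()] undoes exactly this masking.
#'
#' @param truth a [GroundTruth-class] object.
#' @param noiseSd per-measurement log2 noise sd; defaults to the generating
#'   parameters' value.
#' @return A [DecayExperiment-class] with columns for channels
#'   `cer`, `par`, `hyb_cer`, `hyb_par` times `nReplicates` replicates.
#'   Deterministic given the generating seed.
#' @export
simulateTimecourse <- function(truth, noiseSd = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  p <- truth@params
  if (is.null(noiseSd)) noiseSd <- p@noiseSd
  set.seed(p@seed + 1000L)
  g <- truth@genes
  pr <- truth@probes
  tp <- p@timePoints
  idx <- match(pr$gene_id, g$gene_id)
  chs <- c("cer", "par", "hyb_cer", "hyb_par")
  L2 <- cbind(cer = log2(g$L_cer), par = log2(g$L_par),
              hyb_cer = log2(g$L_hyb_cer), hyb_par = log2(g$L_hyb_par))
  D <- cbind(cer = g$D_cer, par = g$D_par,
             hyb_cer = g$D_hyb_cer, hyb_par = g$D_hyb_par)
  np <- nrow(pr)
  cd <- expand.grid(replicate = seq_len(p@nReplicates), channel = chs,
                    stringsAsFactors = FALSE)
  nsamp <- nrow(cd)
  assays <- lapply(seq_along(tp), function(k) matrix(0, np, nsamp))
  for (s in seq_len(nsamp)) {
    ch <- cd$channel[s]
    mu0 <- L2[idx, ch] + pr$offset
    for (k in seq_along(tp)) {
      m <- mu0 - D[idx, ch] * tp[k]
      if (noiseSd > 0) m <- m + rnorm(np, 0, noiseSd)
      assays[[k]][, s] <- m - mean(m)   # equal-total-RNA masking
    }
  }
  DecayExperiment(assays, probe_id = pr$probe_id, gene_id = pr$gene_id,
                  channel = cd$channel, replicate = cd$replicate,
                  timePoints = tp)
}

#' Simulate orthologous promoter sets with planted diverged binding sites
#'
#' Generates i.i.d. uniform A/C/G/T background promoters for two species. For
#' each gene in `divergedGenes`, the consensus site of one of the supplied
#' PSSMs (assigned round-robin) is planted in the first species' promoter, and
#' a mutated version whose LOD score is lower by at least `lodDrop` is planted
#' at the same position in the ortholog. Genes in `intactGenes` receive the
#' consensus site in both promoters.
#'
#' @param genes character vector of gene ids, or a [GroundTruth-class] (its
#'   gene ids are used).
#' @param pssms a [Pssm-class] or list of them.
#' @param divergedGenes genes to plant a diverged site at.
#' @param intactGenes genes to plant an intact (conserved) site at.
#' @param promoterLength promoter length in nt (default 500).
#' @param lodDrop minimum LOD drop of the mutated ortholog site.
#' @param seed RNG seed (defaults to the truth seed when `genes` is a
#'   `GroundTruth`, else 1).
#' @return list with `cer` and `par` ([Biostrings::DNAStringSet] named by
#'   gene), and `ledger`, a data.frame of planted sites
#'   (gene_id, motif_id, offset, lod_cer, lod_par).
#' @export
simulatePromoters <- function(genes, pssms, divergedGenes = character(0),
                              intactGenes = character(0),
                              promoterLength = 500, lodDrop = 2,
                              seed = NULL) {
  if (is(genes, "GroundTruth")) {
    if (is.null(seed)) seed <- genes@params@seed + 2000L
    genes <- genes@genes$gene_id
  }
  if (is.null(seed)) seed <- 1L
  if (is(pssms, "Pssm")) pssms <- list(pssms)
  wmax <- max(vapply(pssms, motifWidth, integer(1)))
  if (promoterLength < wmax)
    stop("promoter length is smaller than the widest PSSM")
  stopifnot(all(divergedGenes %in% genes), all(intactGenes %in% genes))
  set.seed(seed)
  rnd <- function() paste(sample(DNA_BASES, promoterLength, replace = TRUE),
                          collapse = "")
  cer <- vapply(genes, function(g) rnd(), character(1))
  par_ <- vapply(genes, function(g) rnd(), character(1))

  ledger <- data.frame(gene_id = character(0), motif_id = character(0),
                       offset = integer(0), lod_cer = numeric(0),
                       lod_par = numeric(0))
  plantAt <- function(seqs, gene, site, off) {
    s <- seqs[[gene]]
    substr(s, off + 1L, off + nchar(site)) <- site
    seqs[[gene]] <- s
    seqs
  }
  allPlanted <- c(divergedGenes, intactGenes)
  if (length(allPlanted)) {
    mot <- rep_len(seq_along(pssms), length(allPlanted))
    for (k in seq_along(allPlanted)) {
      g <- allPlanted[k]
      pm <- pssms[[mot[k]]]
      wid <- motifWidth(pm)
      cons <- consensusSequence(pm)
      off <- sample.int(promoterLength - wid + 1L, 1L) - 1L
      cer <- plantAt(cer, g, cons, off)
      if (g %in% divergedGenes) {
        mutated <- .mutateToDrop(pm, lodDrop)
        par_ <- plantAt(par_, g, mutated, off)
        ledger <- rbind(ledger, data.frame(
          gene_id = g, motif_id = pm@id, offset = off,
          lod_cer = lodScore(pm, cons), lod_par = lodScore(pm, mutated)))
      } else {
        par_ <- plantAt(par_, g, cons, off)
      }
    }
  }
  list(cer = Biostrings::DNAStringSet(cer),
       par = Biostrings::DNAStringSet(par_),
       ledger = ledger)
}

# Greedily mutate consensus positions (largest LOD loss first) until the
# site's LOD is at least `drop` below the consensus LOD.
.mutateToDrop <- function(pssm, drop) {
  lm <- .lodMatrix(pssm)
  cons <- apply(pssm@probs, 2, which.max)
  consLod <- sum(lm[cbind(cons, seq_along(cons))])
  worst <- apply(lm, 2, which.min)
  loss <- lm[cbind(cons, seq_along(cons))] - lm[cbind(worst, seq_along(cons))]
  ord <- order(loss, decreasing = TRUE)
  cum <- 0
  site <- cons
  for (j in ord) {
    if (cum >= drop) break
    site[j] <- worst[j]
    cum <- cum + loss[j]
  }
  if (cum < drop) stop("PSSM too uninformative to realize the requested LOD drop")
  paste(DNA_BASES[site], collapse = "")
}

#' Simulate regulator target sets (GMT-style gene sets)
#'
#' Builds `nSets` gene sets over the truth's gene universe. One designated
#' "coupling regulator" set includes coupled-opposite genes at
#' `enrichmentFactor` times the background inclusion rate (by exact count);
#' the remaining sets are uniform draws.
#'
#' @param truth a [GroundTruth-class] object.
#' @param enrichmentFactor fold enrichment of coupled genes in the designated
#'   set; must be >= 1. With factor 1 (or no coupled genes) all sets are
#'   uniform.
#' @param nSets total number of sets.
#' @param setSize genes per set (default 10% of the universe, at least 20).
#' @param seed RNG seed (default derived from the truth seed).
#' @return named list of character vectors; the designated set is named
#'   `"regulator_coupling"` (also in `attr(,"designated")`).
#' @export
simulateTargetSets <- function(truth, enrichmentFactor = 4, nSets = 20,
                               setSize = NULL, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"), enrichmentFactor >= 1)
  universe <- truth@genes$gene_id
  coupled <- universe[truth@genes$class == "coupled-opposite"]
  if (is.null(setSize)) setSize <- max(20L, round(0.1 * length(universe)))
  if (is.null(seed)) seed <- truth@params@seed + 3000L
  set.seed(seed)
  sets <- lapply(seq_len(nSets - 1L), function(k) sample(universe, setSize))
  names(sets) <- sprintf("decoy_%02d", seq_len(nSets - 1L))
  pc <- length(coupled) / length(universe)
  nc <- min(round(enrichmentFactor * pc * setSize), length(coupled), setSize)
  designated <-
    if (nc == 0) sample(universe, setSize)
    else c(sample(coupled, nc),
           sample(setdiff(universe, coupled), setSize - nc))
  sets <- c(list(regulator_coupling = designated), sets)
  attr(sets, "designated") <- "regulator_coupling"
  sets
}
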