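#' Log-odds (LOD) score of a sequence window under a PSSM
#'
#' `sum_i log2(p_i(base_i) / q(base_i))` over the window, with the PSSM's
#' pseudocounted probabilities `p` and background `q`. Windows containing
#' ambiguous bases are unscored (`NA`) rather than worst-case scored.
#'
#' @param pssm a [Pssm-class].
#' @param window character string of width `motifWidth(pssm)`.
#' @return the LOD score (log2), or `NA` for ambiguous windows.
#' @examples
#' m <- Pssm(matrix(rep(c(0.97, 0.01, 0.01, 0.01), 2), nrow = 4), id = "AA")
#' lodScore(m, "AA")
#' @export
lodScore <- function(pssm, window) {
  stopifnot(is(pssm, "Pssm"))
  chars <- strsplit(toupper(window), "")[[1]]
  if (length(chars) != motifWidth(pssm))
    stop("window width must equal the motif width")
  codes <- match(chars, DNA_BASES)
  if (anyNA(codes)) return(NA_real_)
  lm <- .lodMatrix(pssm)
  sum(lm[cbind(codes, seq_along(codes))])
}

# integer base codes (NA for ambiguity) of a promoter sequence
.seqCodes <- function(s) {
  match(strsplit(toupper(as.character(s)), "")[[1]], DNA_BASES)
}

# LOD scores at every offset for one strand given a lod matrix
.scanCodes <- function(codes, lm) {
  W <- ncol(lm)
  npos <- length(codes) - W + 1L
  sc <- numeric(npos)
  for (j in seq_len(W))
    sc <- sc + lm[cbind(codes[j:(j + npos - 1L)], j)]
  sc
}

#' Best PSSM match in a promoter (both strands)
#'
#' Evaluates every offset on the + strand and on the reverse complement and
#' returns the maximum-LOD hit. Coordinates are 0-based on the + strand of the
#' promoter; minus-strand hits are reported by the + strand start of their
#' window. Ties are broken by the smallest offset, then the + strand.
#'
#' @param pssm a [Pssm-class].
#' @param promoter a character string, [Biostrings::DNAString], or an element
#'   of a [Biostrings::DNAStringSet].
#' @return data.frame with one row (`motif_id`, `offset`, `strand`, `lod`),
#'   or zero rows when no window is scorable.
#' @export
scanPromoter <- function(pssm, promoter) {
  stopifnot(is(pssm, "Pssm"))
  codes <- .seqCodes(promoter)
  W <- motifWidth(pssm)
  if (length(codes) < W) stop("promoter is shorter than the motif")
  lm <- .lodMatrix(pssm)
  rc <- lm[4:1, ncol(lm):1, drop = FALSE]   # reverse-complement motif
  plus <- .scanCodes(codes, lm)
  minus <- .scanCodes(codes, rc)
  cand <- data.frame(
    offset = c(seq_along(plus), seq_along(minus)) - 1L,
    strand = rep(c("+", "-"), c(length(plus), length(minus))),
    lod = c(plus, minus))
  cand <- cand[!is.na(cand$lod), , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(motif_id = character(0), offset = integer(0),
                      strand = character(0), lod = numeric(0)))
  # windows with the same base composition can differ by ~1e-16 from float
  # summation order; ties are therefore detected within a small tolerance and
  # broken by smallest offset, then + strand
  best <- cand[cand$lod >= max(cand$lod) - 1e-9, , drop = FALSE]
  best <- best[order(best$offset, best$strand), , drop = FALSE][1L, ]
  data.frame(motif_id = pssm@id, offset = best$offset, strand = best$strand,
             lod = best$lod, row.names = NULL)
}

# best-hit LOD per promoter of a set (named numeric; NA when unscorable)
.bestLods <- function(pssm, promoters) {
  vapply(seq_along(promoters), function(i) {
    h <- scanPromoter(pssm, promoters[[i]])
    if (nrow(h)) h$lod else NA_real_
  }, numeric(1)) |> stats::setNames(names(promoters))
}

#' Maximal LOD score of a PSSM over a promoter set
#'
#' The maximum best-hit LOD over all supplied promoters; the promoter set
#' stands in for "the entire genome" in the 75%/90%-of-maximum rules.
#'
#' @param pssm a [Pssm-class].
#' @param promoters a [Biostrings::DNAStringSet] (or named character vector).
#' @return the maximal LOD (numeric scalar).
#' @export
genomeMaxLod <- function(pssm, promoters) {
  if (length(promoters) == 0L) stop("empty promoter set")
  b <- .bestLods(pssm, promoters)
  if (all(is.na(b))) stop("no scorable window in any promoter")
  max(b, na.rm = TRUE)
}

#' Thresholds of the diverged-binding-site rules
#'
#' The two call directions are deliberately asymmetric: divergence in
#' S. paradoxus is anchored on experimentally bound S. cerevisiae promoters
#' (LOD > 10, >= 75% of the genome maximum, ortholog drop >= 1), while
#' divergence in S. cerevisiae relies on sequence alone and uses stricter
#' constants (LOD > 12, >= 90%, drop >= 1.5).
#'
#' @param parMinLod,parMaxFrac,parMinDrop rule constants for
#'   `diverged_in_paradoxus`.
#' @param cerMinLod,cerMaxFrac,cerMinDrop rule constants for
#'   `diverged_in_cerevisiae`.
#' @return named list of the six constants.
#' @export
divergedSiteThresholds <- function(parMinLod = 10, parMaxFrac = 0.75,
                                   parMinDrop = 1,
                                   cerMinLod = 12, cerMaxFrac = 0.90,
                                   cerMinDrop = 1.5) {
  list(parMinLod = parMinLod, parMaxFrac = parMaxFrac,
       parMinDrop = parMinDrop, cerMinLod = cerMinLod,
       cerMaxFrac = cerMaxFrac, cerMinDrop = cerMinDrop)
}

#' Call diverged transcription-factor binding sites in ortholog pairs
#'
#' For each motif, promoters of both species are scanned for their best hit
#' and the per-species genome-maximal LOD is computed. A site is
#' `diverged_in_paradoxus` when a gene bound by the factor in S. cerevisiae
#' has a strong cer match (above `parMinLod` and at least `parMaxFrac` of the
#' cer genome maximum) whose ortholog's best LOD anywhere in the par promoter
#' is lower by at least `parMinDrop`. A site is `diverged_in_cerevisiae` when
#' a gene NOT bound in S. cerevisiae has a strong par match under the stricter
#' `cerMinLod`/`cerMaxFrac` constants and the cer best LOD drops by at least
#' `cerMinDrop`. Genes missing either ortholog promoter are skipped (reported
#' in `attr(,"skipped")`).
#'
#' @param pssms a [Pssm-class] or named list of them.
#' @param promotersCer,promotersPar promoter sets named by gene id.
#' @param boundGenes genes bound in S. cerevisiae: a character vector (applied
#'   to every motif) or a named list per motif id.
#' @param thresholds see [divergedSiteThresholds()].
#' @return data.frame: `gene_id`, `motif_id`, `direction`, `lod_intact`,
#'   `lod_ortholog_best`.
#' @export
callDivergedSites <- function(pssms, promotersCer, promotersPar,
                              boundGenes = character(0),
                              thresholds = divergedSiteThresholds()) {
  if (is(pssms, "Pssm")) pssms <- stats::setNames(list(pssms), pssms@id)
  if (is.null(names(pssms)))
    names(pssms) <- vapply(pssms, function(p) p@id, character(1))
  genes <- intersect(names(promotersCer), names(promotersPar))
  skipped <- setdiff(union(names(promotersCer), names(promotersPar)), genes)
  th <- thresholds
  rows <- list()
  for (id in names(pssms)) {
    pm <- pssms[[id]]
    bCer <- .bestLods(pm, promotersCer[genes])
    bPar <- .bestLods(pm, promotersPar[genes])
    maxCer <- max(.bestLods(pm, promotersCer), na.rm = TRUE)
    maxPar <- max(.bestLods(pm, promotersPar), na.rm = TRUE)
    bound <- if (is.list(boundGenes)) boundGenes[[id]] else boundGenes
    bound <- intersect(bound, genes)
    inPar <- genes %in% bound &
      !is.na(bCer) & bCer > th$parMinLod & bCer >= th$parMaxFrac * maxCer &
      !is.na(bPar) & (bCer - bPar) >= th$parMinDrop
    inCer <- !(genes %in% bound) &
      !is.na(bPar) & bPar > th$cerMinLod & bPar >= th$cerMaxFrac * maxPar &
      !is.na(bCer) & (bPar - bCer) >= th$cerMinDrop
    if (any(inPar))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes[inPar], motif_id = id,
        direction = "diverged_in_paradoxus",
        lod_intact = unname(bCer[inPar]),
        lod_ortholog_best = unname(bPar[inPar]))
    if (any(inCer))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes[inCer], motif_id = id,
        direction = "diverged_in_cerevisiae",
        lod_intact = unname(bPar[inCer]),
        lod_ortholog_best = unname(bCer[inCer]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), motif_id = character(0),
               direction = character(0), lod_intact = numeric(0),
               lod_ortholog_best = numeric(0))
  attr(out, "skipped") <- skipped
  out
}

#' Enrichment of diverged binding sites among coupled genes
#'
#' Pooled over motifs, tests whether genes carrying a diverged site are
#' over-represented among cis-coupled genes relative to genes whose
#' transcription diverged without coupling, by a one-sided Fisher test on the
#' 2x2 carriage table -- per stratum and per call direction.
#'
#' @param calls output of [callDivergedSites()].
#' @param coupledGenes the coupled query class (e.g. cis-coupled genes).
#' @param uncoupledGenes the contrast class (transcription-diverged,
#'   uncoupled).
#' @param strata optional named list of gene strata (default one stratum
#'   `All` = union of the two classes).
#' @param directions call directions to test.
#' @return data.frame: `stratum`, `direction`, `n_coupled`, `n_uncoupled`,
#'   `coupled_carriers`, `uncoupled_carriers`, `p_value` (NA for empty
#'   strata).
#' @export
divergedMotifEnrichment <- function(calls, coupledGenes, uncoupledGenes,
                                    strata = NULL,
                                    directions = c("diverged_in_paradoxus",
                                                   "diverged_in_cerevisiae")) {
  if (is.null(strata))
    strata <- list(All = union(coupledGenes, uncoupledGenes))
  rows <- list()
  for (sn in names(strata)) {
    q <- intersect(coupledGenes, strata[[sn]])
    b <- intersect(uncoupledGenes, strata[[sn]])
    for (d in directions) {
      carriers <- unique(calls$gene_id[calls$direction == d])
      if (length(q) == 0L || length(b) == 0L) {
        p <- NA_real_
        qc <- bc <- 0L
      } else {
        qc <- length(intersect(q, carriers))
        bc <- length(intersect(b, carriers))
        tab <- matrix(c(qc, length(q) - qc, bc, length(b) - bc), nrow = 2)
        p <- fisher.test(tab, alternative = "greater")$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = sn, direction = d, n_coupled = length(q),
        n_uncoupled = length(b), coupled_carriers = qc,
        uncoupled_carriers = bc, p_value = p)
    }
  }
  do.call(rbind, rows)
}
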