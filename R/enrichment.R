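#' @importFrom stats phyper fisher.test p.adjust
NULL

#' Regulator targets from a deletion expression profile
#'
#' Defines a regulator's target set as the genes whose expression decreases by
#' at least `fold` (default 2-fold, i.e. log2 change <= -1) upon deletion of
#' the regulator. The boundary is inclusive ("at least").
#'
#' @param log2Change named numeric vector of per-gene log2 expression changes
#'   upon deletion.
#' @param fold fold-decrease threshold.
#' @return character vector of target gene ids.
#' @examples
#' targetsFromDeletion(c(a = -1.2, b = -0.9, c = -1.0))  # a and c
#' @export
targetsFromDeletion <- function(log2Change, fold = 2) {
  stopifnot(!is.null(names(log2Change)))
  names(log2Change)[log2Change <= -log2(fold)]
}

#' Gene-set enrichment of a query in a target set
#'
#' One-sided hypergeometric test of the overlap between a query gene set and a
#' target set within a universe: `P(overlap >= observed)` when drawing
#' `|query|` genes without replacement. Optionally, a one-sided Fisher test
#' contrasts the query's target-membership rate against an explicit background
#' gene set (e.g. coupled vs uncoupled genes) instead of the whole universe.
#' Fold enrichment is observed/expected overlap.
#'
#' @param query character vector of query genes (subset of `universe`).
#' @param target character vector of target genes (intersected with the
#'   universe).
#' @param universe all analyzed genes.
#' @param background optional explicit contrast gene set.
#' @return list: `n_query`, `n_target`, `n_overlap`, `expected`,
#'   `fold_enrichment`, `p_value`, and `p_vs_background` when a background is
#'   supplied.
#' @export
setEnrichment <- function(query, target, universe, background = NULL) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0L) stop("empty query set")
  if (!all(query %in% universe)) stop("query must be contained in the universe")
  target <- unique(intersect(target, universe))
  if (length(target) == 0L)
    stop("target set is empty after intersection with the universe")
  ov <- length(intersect(query, target))
  expected <- length(query) * length(target) / length(universe)
  res <- list(
    n_query = length(query), n_target = length(target), n_overlap = ov,
    expected = expected, fold_enrichment = ov / expected,
    p_value = phyper(ov - 1, length(target), length(universe) - length(target),
                     length(query), lower.tail = FALSE))
  if (!is.null(background)) {
    background <- unique(background)
    bt <- length(intersect(background, target))
    tab <- matrix(c(ov, length(query) - ov,
                    bt, length(background) - bt), nrow = 2)
    res$p_vs_background <- fisher.test(tab, alternative = "greater")$p.value
  }
  res
}

#' Enrichment scan over a collection of target sets
#'
#' Applies [setEnrichment()] to every target set and returns the results
#' ranked by p-value. With `exclude`, the named regulators' sets are removed
#' and every gene belonging to them is dropped from the query, the background
#' and the universe before testing (the leave-regulator-out re-analysis). A
#' Benjamini-Hochberg adjusted column is appended for convenience; the primary
#' read-out is the raw p-value, which is what the thresholding rules use.
#'
#' @param query query gene set.
#' @param targetSets named list of target gene sets.
#' @param universe analysis universe.
#' @param background optional contrast gene set (see [setEnrichment()]).
#' @param exclude optional character vector of target-set names whose genes
#'   are removed before testing.
#' @return data.frame sorted by `p_value`: `set_id`, `n_target`, `n_overlap`,
#'   `expected`, `fold_enrichment`, `p_value`, `p_vs_background` (NA without a
#'   background), `p_adjusted_bh`.
#' @export
enrichmentScan <- function(query, targetSets, universe, background = NULL,
                           exclude = NULL) {
  stopifnot(length(targetSets) >= 1L, !is.null(names(targetSets)))
  if (!is.null(exclude)) {
    drop <- unique(unlist(targetSets[intersect(exclude, names(targetSets))]))
    targetSets <- targetSets[setdiff(names(targetSets), exclude)]
    universe <- setdiff(universe, drop)
    query <- setdiff(query, drop)
    if (!is.null(background)) background <- setdiff(background, drop)
  }
  rows <- lapply(names(targetSets), function(id) {
    r <- tryCatch(setEnrichment(query, targetSets[[id]], universe, background),
                  error = function(e) NULL)
    if (is.null(r)) {
      warning("target set '", id, "' dropped: empty after intersection")
      return(NULL)
    }
    data.frame(set_id = id, n_target = r$n_target, n_overlap = r$n_overlap,
               expected = r$expected, fold_enrichment = r$fold_enrichment,
               p_value = r$p_value,
               p_vs_background = if (is.null(r$p_vs_background)) NA_real_
                                 else r$p_vs_background)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable target set")
  out$p_adjusted_bh <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Read and write GMT gene-set files
#'
#' `readGmt()` wraps [fgsea::gmtPathways()]; `writeGmt()` writes one set per
#' line (`name`, description, tab-separated gene ids).
#'
#' @param file path to a GMT file.
#' @return `readGmt()`: named list of character vectors.
#' @export
readGmt <- function(file) {
  fgsea::gmtPathways(file)
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param descriptions optional per-set description column (defaults to the
#'   set names).
#' @export
writeGmt <- function(sets, file, descriptions = NULL) {
  stopifnot(!is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, file)
  invisible(file)
}
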