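#' Quadrant classification of degradation-vs-level divergence
#'
#' "Opposite" coupling means the species with the faster degradation also has
#' the higher mRNA level -- i.e. the observed level difference is opposite to
#' what the degradation difference alone would produce, implying a larger,
#' opposing transcription change. With ratios oriented the same way, this is a
#' shared sign of `log2_D_ratio` and `log2_L_ratio`.
#'
#' Each gene is classified as:
#' * `opposite` -- significant differential degradation AND differential
#'   level, same sign;
#' * `same-direction` -- both differential, opposite signs (the level change
#'   expected from degradation alone);
#' * `decay-only`, `expression-only`, `conserved` otherwise.
#'
#' Two coupled-gene definitions are added: `coupled_conservative` requires the
#' opposite pattern by BOTH mRNA level and estimated transcription rate, while
#' `coupled_relaxed` accepts either. Level-based analysis underestimates the
#' scope of coupling and TR-based analysis may overestimate it, so the two are
#' always reported separately (conservative implies relaxed).
#'
#' @param div a [divergenceTable()] data.frame.
#' @return `div` with `quadrant`, `coupled_conservative`, `coupled_relaxed`
#'   columns appended.
#' @export
quadrantClassify <- function(div) {
  sameL <- sign(div$log2_D_ratio) == sign(div$log2_L_ratio)
  sameTR <- sign(div$log2_D_ratio) == sign(div$log2_TR_ratio)
  sig <- div$sig_decay
  dl <- div$diff_expression
  dt <- div$diff_transcription
  div$quadrant <- ifelse(sig & dl & sameL, "opposite",
                  ifelse(sig & dl, "same-direction",
                  ifelse(sig, "decay-only",
                  ifelse(dl, "expression-only", "conserved"))))
  div$coupled_conservative <- sig & dl & sameL & dt & sameTR
  div$coupled_relaxed <- sig & ((dl & sameL) | (dt & sameTR))
  div
}

# rolling sums of a logical/numeric vector for all starts at step 1
.rollSum <- function(x, window) {
  cs <- cumsum(x)
  cs[window:length(x)] - c(0, cs[seq_len(length(x) - window)])
}

#' Sliding-window coupling statistics over the decay fold-change axis
#'
#' Genes are sorted by the magnitude of their inter-species degradation
#' fold-change; contiguous windows (default 200 genes, step 1) report the
#' fraction of differentially expressed genes, the fraction with differential
#' estimated transcription, and -- among genes differential in both
#' degradation and level ("doubly differential") -- the fraction with opposite
#' effects. Genome-wide baseline fractions (the dashed-line references) are
#' returned alongside.
#'
#' @param div a [divergenceTable()] (or [quadrantClassify()]) data.frame.
#' @param window window size in genes (default 200); when fewer genes are
#'   available a single whole-set window is used, with a warning.
#' @param step step between window starts, in genes.
#' @return list with `windows` (data.frame: `start`, `median_abs_log2_D`,
#'   `fold_change`, `frac_diff_expression`, `frac_diff_transcription`,
#'   `n_doubly`, `frac_opposite`) and `baseline` (named list of the
#'   genome-wide fractions).
#' @export
slidingWindowStats <- function(div, window = 200, step = 1) {
  n <- nrow(div)
  if (n < 1) stop("empty divergence table")
  if (n < window) {
    warning("fewer genes than the window size; using one whole-set window")
    window <- n
  }
  o <- order(abs(div$log2_D_ratio))
  d <- div[o, ]
  absd <- abs(d$log2_D_ratio)
  sameL <- sign(d$log2_D_ratio) == sign(d$log2_L_ratio)
  dd <- d$sig_decay & d$diff_expression
  opp <- dd & sameL

  starts <- seq(1L, n - window + 1L, by = step)
  fde <- .rollSum(d$diff_expression, window)[starts] / window
  fdt <- .rollSum(d$diff_transcription, window)[starts] / window
  ndd <- .rollSum(dd, window)[starts]
  nopp <- .rollSum(opp, window)[starts]
  lomid <- starts + (window - 1L) %/% 2L
  himid <- starts + window %/% 2L
  med <- (absd[lomid] + absd[himid]) / 2

  windows <- data.frame(
    start = starts,
    median_abs_log2_D = med,
    fold_change = 2^med,
    frac_diff_expression = fde,
    frac_diff_transcription = fdt,
    n_doubly = ndd,
    frac_opposite = ifelse(ndd > 0, nopp / ndd, NA_real_))
  baseline <- list(
    frac_diff_expression = mean(d$diff_expression),
    frac_diff_transcription = mean(d$diff_transcription),
    frac_opposite = if (sum(dd) > 0) sum(opp) / sum(dd) else NA_real_,
    n_doubly = sum(dd))
  list(windows = windows, baseline = baseline)
}

#' Category summaries of coupled divergence (pie-chart counts)
#'
#' Summarizes the combinations of degradation and transcription divergence in
#' two complementary views: among genes with differential degradation and
#' among genes with differential transcription. Counts and fractions are given
#' under both the conservative coupled definition (level AND estimated TR) and
#' the relaxed one (level OR TR); fractions within each view sum to 1.
#'
#' @param records output of [quadrantClassify()].
#' @return nested list: `$degradation` and `$transcription`, each with
#'   `$conservative` and `$relaxed` data.frames (`category`, `n`, `fraction`),
#'   plus top-level counts `n_coupled_conservative`, `n_coupled_relaxed`.
#' @export
couplingSummary <- function(records) {
  pie <- function(sub, coupled) {
    sameL <- sign(sub$log2_D_ratio) == sign(sub$log2_L_ratio)
    cat <- ifelse(coupled, "coupled-opposite",
           ifelse(sub$diff_expression & !sameL & sub$sig_decay,
                  "same-direction", "single-process"))
    tab <- table(factor(cat, levels = c("coupled-opposite", "same-direction",
                                        "single-process")))
    data.frame(category = names(tab), n = as.integer(tab),
               fraction = if (nrow(sub)) as.numeric(tab) / nrow(sub)
                          else rep(NA_real_, length(tab)),
               row.names = NULL)
  }
  deg <- records[records$sig_decay, ]
  tx <- records[records$diff_transcription, ]
  list(
    degradation = list(
      conservative = pie(deg, deg$coupled_conservative),
      relaxed = pie(deg, deg$coupled_relaxed)),
    transcription = list(
      conservative = pie(tx, tx$coupled_conservative),
      relaxed = pie(tx, tx$coupled_relaxed)),
    n_coupled_conservative = sum(records$coupled_conservative),
    n_coupled_relaxed = sum(records$coupled_relaxed))
}
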