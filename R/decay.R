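#' @importFrom stats median pt
NULL

#' Rescale time courses to an assumed genome-wide decay
#'
#' Transcription-arrest protocols hybridize equal amounts of total RNA at
#' every time point, which masks the global loss of mRNA. `globalScale()`
#' undoes this by re-anchoring each column (channel x replicate x time point)
#' so that its mean log2 intensity equals `-t / halfLife`: with the default
#' 25-min half-life the four columns at 0/20/40/60 min are centered on 0,
#' -0.8, -1.6 and -2.4 log2 units. The shift is purely additive per column, so
#' gene-relative differences within a column are unchanged, and the operation
#' is idempotent.
#'
#' @param de a [DecayExperiment-class].
#' @param halfLife assumed genome-wide mRNA half-life in minutes (default 25).
#' @return The rescaled `DecayExperiment` (`metadata()$scaled` set to `TRUE`).
#' @export
globalScale <- function(de, halfLife = 25) {
  stopifnot(is(de, "DecayExperiment"), halfLife > 0)
  tp <- metadata(de)$timePoints
  for (k in seq_along(tp)) {
    a <- assay(de, k)
    if (any(colSums(is.finite(a)) < 2L))
      stop("each column needs at least 2 finite values")
    cm <- colMeans(a, na.rm = TRUE)
    assay(de, k) <- sweep(a, 2, cm) - tp[k] / halfLife
  }
  metadata(de)$scaled <- TRUE
  metadata(de)$halfLife <- halfLife
  de
}

# per-row OLS of log2 intensity on time for a profiles x timepoints matrix
.fitRows <- function(M, tp) {
  tc <- tp - mean(tp)
  sxx <- sum(tc^2)
  mbar <- rowMeans(M)
  dev <- M - mbar
  slope <- as.vector(dev %*% tc) / sxx
  sstot <- rowSums(dev^2)
  res <- dev - outer(slope, tc)
  ssres <- rowSums(res^2)
  r2 <- 1 - ssres / sstot
  r2[sstot <= 0] <- NA_real_
  list(slope = slope, intercept = mbar - slope * mean(tp), r_squared = r2)
}

#' Fit per-probe linear decay in log2 space
#'
#' Ordinary least squares of each probe's log2 intensities on time, for every
#' channel and replicate. The slope (log2 units/min) is the negative of the
#' probe's apparent degradation rate; probes are gated on the goodness of fit
#' (`r_squared >= r2Gate`, default 0.94 -- equality passes). A constant
#' profile has `SS_tot = 0`, an undefined R-squared, and fails the gate.
#'
#' @param de a (globally scaled) [DecayExperiment-class].
#' @param r2Gate R-squared threshold for `passed_gate`.
#' @return data.frame with one row per probe x channel x replicate:
#'   `probe_id`, `gene_id`, `channel`, `replicate`, `slope`, `intercept`,
#'   `r_squared`, `passed_gate`.
#' @seealso [fitProbeDecay()] for a single profile, [geneDecayRates()]
#' @export
fitDecay <- function(de, r2Gate = 0.94) {
  stopifnot(is(de, "DecayExperiment"))
  tp <- metadata(de)$timePoints
  np <- nrow(de); ns <- ncol(de)
  rd <- rowData(de); cd <- colData(de)
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    M <- vapply(seq_along(tp), function(k) assay(de, k)[, s], numeric(np))
    f <- .fitRows(M, tp)
    out[[s]] <- data.frame(
      probe_id = rd$probe_id, gene_id = rd$gene_id,
      channel = cd$channel[s], replicate = cd$replicate[s],
      slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
      passed_gate = !is.na(f$r_squared) & f$r_squared >= r2Gate)
  }
  do.call(rbind, out)
}

#' Fit one probe's decay profile
#'
#' @param M log2 intensities, one per time point.
#' @param times sampling times in minutes.
#' @param r2Gate R-squared gate (equality passes).
#' @return list with `slope` (log2 units/min), `intercept`, `r_squared`
#'   (`NA` when the profile is constant) and `passed_gate`.
#' @examples
#' fitProbeDecay(c(10, 9.2, 8.4, 7.6))  # slope -0.04/min, i.e. 25-min half-life
#' @export
fitProbeDecay <- function(M, times = c(0, 20, 40, 60), r2Gate = 0.94) {
  if (length(M) != length(times) || !all(is.finite(M)))
    stop("profile must contain one finite value per time point")
  f <- .fitRows(matrix(M, nrow = 1), times)
  list(slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
       passed_gate = !is.na(f$r_squared) && f$r_squared >= r2Gate)
}

#' Aggregate probe fits to per-gene degradation rates
#'
#' A gene's degradation rate in a channel/replicate is the absolute value of
#' the median slope of its probes that passed the R-squared gate (median of an
#' even number of slopes = mean of the two central values). Gene/channel/
#' replicate groups with no passing probe are dropped, with a message giving
#' the count.
#'
#' @param fits output of [fitDecay()].
#' @return data.frame `gene_id`, `channel`, `replicate`, `D` (log2 units/min),
#'   `n_probes_passing`.
#' @export
geneDecayRates <- function(fits) {
  keyAll <- paste(fits$gene_id, fits$channel, fits$replicate, sep = "\t")
  f <- fits[fits$passed_gate %in% TRUE, ]
  key <- paste(f$gene_id, f$channel, f$replicate, sep = "\t")
  sp <- split(f$slope, key)
  dropped <- length(unique(keyAll)) - length(sp)
  if (dropped > 0)
    message(dropped, " gene/channel/replicate groups had no probe passing ",
            "the gate and were dropped")
  parts <- do.call(rbind, strsplit(names(sp), "\t", fixed = TRUE))
  data.frame(gene_id = parts[, 1], channel = parts[, 2],
             replicate = as.integer(parts[, 3]),
             D = abs(vapply(sp, median, numeric(1), USE.NAMES = FALSE)),
             n_probes_passing = unname(lengths(sp)),
             row.names = NULL)
}

# replicate-averaged rates for one channel, as a named vector
.avgRate <- function(rates, channel) {
  r <- rates[rates$channel == channel, ]
  v <- vapply(split(r$D, r$gene_id), mean, numeric(1))
  v
}

# one replicate's rates for one channel, as a named vector
.repRate <- function(rates, channel, replicate) {
  r <- rates[rates$channel == channel & rates$replicate == replicate, ]
  stats::setNames(r$D, r$gene_id)
}

#' Shuffled-profile null distribution of the goodness of fit
#'
#' Builds profiles in which each time point is taken from a different,
#' uniformly chosen probe's value at that same time point -- retaining the
#' overall mRNA decay but scrambling gene-specific rates -- and returns the
#' R-squared values of their linear fits together with the fraction passing
#' the gate. Used as the control for the claim that well-fit linear profiles
#' reflect genuine gene-specific decay.
#'
#' @param de a scaled [DecayExperiment-class].
#' @param channel,replicate which sample to shuffle.
#' @param nShuffles number of shuffled profiles (default 10000).
#' @param r2Gate R-squared gate.
#' @param seed optional seed for reproducible shuffles.
#' @return list with `r_squared` (length `nShuffles`), `pass_rate`, `r2_gate`.
#' @export
shuffledProfileNull <- function(de, channel = "cer", replicate = 1,
                                nShuffles = 10000, r2Gate = 0.94,
                                seed = NULL) {
  stopifnot(is(de, "DecayExperiment"))
  if (nShuffles < 1) stop("nShuffles must be >= 1")
  cd <- colData(de)
  s <- which(cd$channel == channel & cd$replicate == replicate)
  if (length(s) != 1L) stop("no unique sample for that channel/replicate")
  tp <- metadata(de)$timePoints
  M <- vapply(seq_along(tp), function(k) assay(de, k)[, s],
              numeric(nrow(de)))
  n <- nrow(M)
  if (n < length(tp)) stop("need at least as many probes as time points")
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(0L, nShuffles, length(tp))
  for (i in seq_len(nShuffles)) idx[i, ] <- sample.int(n, length(tp))
  prof <- matrix(M[cbind(as.vector(idx), rep(seq_along(tp), each = nShuffles))],
                 nrow = nShuffles)
  f <- .fitRows(prof, tp)
  pass <- !is.na(f$r_squared) & f$r_squared >= r2Gate
  list(r_squared = f$r_squared, pass_rate = mean(pass), r2_gate = r2Gate)
}
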