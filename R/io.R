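#' @importFrom utils read.delim write.table
NULL

#' Long probe table of a DecayExperiment
#'
#' One row per probe x channel x replicate, with the log2 intensities of the
#' four time points in columns `t0`, `t20`, `t40`, `t60` -- the on-disk
#' exchange format of the package.
#'
#' @param de a [DecayExperiment-class].
#' @return data.frame: `probe_id`, `gene_id`, `channel`, `replicate`,
#'   `t<time>` columns.
#' @seealso [writeProbeTable()], [readProbeTable()]
#' @export
probeTable <- function(de) {
  stopifnot(is(de, "DecayExperiment"))
  rd <- rowData(de)
  cd <- colData(de)
  np <- nrow(de); ns <- ncol(de)
  out <- data.frame(
    probe_id = rep(rd$probe_id, ns),
    gene_id = rep(rd$gene_id, ns),
    channel = rep(cd$channel, each = np),
    replicate = rep(cd$replicate, each = np))
  for (a in assayNames(de)) out[[a]] <- as.vector(assay(de, a))
  out
}

#' Rebuild a DecayExperiment from a long probe table
#'
#' @param df a data.frame in [probeTable()] layout.
#' @return a [DecayExperiment-class].
#' @export
decayExperimentFromTable <- function(df) {
  need <- c("probe_id", "gene_id", "channel", "replicate")
  if (!all(need %in% names(df)))
    stop("probe table must contain columns: ", paste(need, collapse = ", "))
  tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
  if (length(tcols) < 3L) stop("probe table must contain t<time> columns")
  tp <- sort(as.numeric(sub("^t", "", tcols)))
  tcols <- paste0("t", tp)
  samp <- unique(df[c("channel", "replicate")])
  probes <- unique(df[c("probe_id", "gene_id")])
  i <- match(df$probe_id, probes$probe_id)
  j <- match(paste(df$channel, df$replicate),
             paste(samp$channel, samp$replicate))
  assays <- lapply(tcols, function(a) {
    m <- matrix(NA_real_, nrow(probes), nrow(samp))
    m[cbind(i, j)] <- df[[a]]
    m
  })
  DecayExperiment(assays, probe_id = probes$probe_id,
                  gene_id = probes$gene_id,
                  channel = samp$channel, replicate = samp$replicate,
                  timePoints = tp)
}

#' Read/write the probe-level intensity TSV
#'
#' @param file path to a tab-separated probe table.
#' @return `readProbeTable()`: a [DecayExperiment-class].
#' @export
readProbeTable <- function(file) {
  decayExperimentFromTable(read.delim(file, stringsAsFactors = FALSE))
}

#' @rdname readProbeTable
#' @param de a [DecayExperiment-class].
#' @export
writeProbeTable <- function(de, file) {
  write.table(probeTable(de), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Read and write PSSMs in MEME-minimal format
#'
#' A small reader/writer for the MEME minimal motif text dialect: a version
#' line, optional `ALPHABET=`/`strands:`/`Background letter frequencies`
#' blocks, then per motif a `MOTIF <id>` line, a
#' `letter-probability matrix:` header with `w= <width>`, and `w` rows of four
#' probabilities in A/C/G/T order.
#'
#' @param file path to a MEME-minimal text file.
#' @param pseudocount,background passed to [Pssm()] for each parsed motif.
#' @return `readMeme()`: named list of [Pssm-class] objects.
#' @export
readMeme <- function(file, pseudocount = 0.01,
                     background = c(0.25, 0.25, 0.25, 0.25)) {
  lines <- trimws(readLines(file))
  bgLine <- which(startsWith(lines, "Background letter frequencies"))
  if (length(bgLine) == 1L && bgLine < length(lines)) {
    tok <- strsplit(lines[bgLine + 1L], "\\s+")[[1]]
    if (length(tok) >= 8L) {
      v <- suppressWarnings(as.numeric(tok[seq(2, 8, by = 2)]))
      if (!anyNA(v)) background <- v
    }
  }
  starts <- which(startsWith(lines, "MOTIF"))
  if (!length(starts)) stop("no MOTIF entries found in ", file)
  motifs <- list()
  for (s in starts) {
    id <- strsplit(lines[s], "\\s+")[[1]][2]
    h <- s + which(startsWith(lines[(s + 1):length(lines)],
                              "letter-probability matrix"))[1]
    if (is.na(h)) stop("motif ", id, ": missing letter-probability matrix")
    wm <- regmatches(lines[h], regexpr("w=\\s*[0-9]+", lines[h]))
    if (!length(wm)) stop("motif ", id, ": missing w= in matrix header")
    w <- as.integer(sub("w=\\s*", "", wm))
    rows <- lines[(h + 1):(h + w)]
    mat <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    if (ncol(mat) != 4L || anyNA(mat))
      stop("motif ", id, ": malformed probability rows")
    motifs[[id]] <- Pssm(mat, id = id, background = background,
                         pseudocount = pseudocount)
  }
  motifs
}

#' @rdname readMeme
#' @param pssms a [Pssm-class] or named list of them.
#' @export
writeMeme <- function(pssms, file) {
  if (is(pssms, "Pssm")) pssms <- list(pssms)
  con <- file(file, "w")
  on.exit(close(con))
  bg <- pssms[[1]]@background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %g C %g G %g T %g", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (pm in pssms) {
    writeLines(sprintf("MOTIF %s", pm@id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       motifWidth(pm)), con)
    writeLines(apply(t(pm@probs), 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(file)
}
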