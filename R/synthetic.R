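#' Simulate a motif-planted labeled 41-bp dataset
#'
#' Generates background sequences from a per-nucleotide composition
#' and plants a short motif (by substitution, so the window length
#' stays fixed) to create class signal. A positive carries the motif
#' at `motifOffset` with probability `signalStrength`; a negative
#' carries it with probability `1 - signalStrength`. A window that is
#' not planted is guaranteed motif-free at that offset (an incidental
#' background match is mutated away at one non-central position).
#'
#' At `signalStrength = 1` the classes are perfectly separated by the
#' motif; at `signalStrength = 0.5` both classes carry the motif with
#' probability one half, so they are exchangeable by construction —
#' the chance-level null fixture. The central position ((L+1)/2) is
#' forced to adenine when `centralAdenine = TRUE`, mimicking
#' candidate-site windows.
#'
#' @param nPos,nNeg Class sizes.
#' @param motif Planted nucleotide string (default "GAGG", a motif
#'   family enriched around rice 6mA sites — a naming motivation, not
#'   a modeled claim).
#' @param motifOffset 0-based plant position in `[0, L - nchar(motif)]`.
#' @param signalStrength Probability in [0,1] that a positive carries
#'   the motif (and a negative does not). Default 1.
#' @param background Length-4 composition over (A, C, G, T), summing
#'   to 1. Default uniform.
#' @param seqLength Window length (default 41).
#' @param centralAdenine Force A at the central position.
#' @param seed Integer seed; the same seed reproduces the dataset
#'   byte-for-byte.
#' @param name Dataset identifier.
#' @return A [MethSeqSet-class] with positives first.
#' @export
simulateDataset <- function(nPos, nNeg, motif = "GAGG", motifOffset = 4L,
                            signalStrength = 1, background = rep(0.25, 4),
                            seqLength = 41L, centralAdenine = TRUE,
                            seed = 1L, name = "synthetic") {
  nPos <- as.integer(nPos); nNeg <- as.integer(nNeg)
  seqLength <- as.integer(seqLength)
  motif <- toupper(motif)
  motifChars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (!all(motifChars %in% c("A", "C", "G", "T")))
    stop("motif must be over {A,C,G,T}", call. = FALSE)
  motifOffset <- as.integer(motifOffset)
  if (motifOffset < 0L || motifOffset > seqLength - length(motifChars))
    stop("motifOffset out of range [0, ", seqLength - length(motifChars),
         "]", call. = FALSE)
  if (signalStrength < 0 || signalStrength > 1)
    stop("signalStrength must lie in [0,1]", call. = FALSE)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-12 ||
      any(background < 0))
    stop("background must be 4 nonnegative probabilities summing to 1",
         call. = FALSE)
  centre <- (seqLength + 1L) %/% 2L
  motifCols <- motifOffset + seq_along(motifChars)   # 1-based columns
  if (centralAdenine && seqLength %% 2L == 1L && centre %in% motifCols &&
      motifChars[match(centre, motifCols)] != "A")
    stop("motif would place a non-A over the forced central adenine",
         call. = FALSE)

  n <- nPos + nNeg
  bases <- c("A", "C", "G", "T")
  .withSeed(.deriveSeed(seed, "sim"), {
    chars <- matrix(sample(bases, n * seqLength, replace = TRUE,
                           prob = background),
                    nrow = n)
    if (centralAdenine && seqLength %% 2L == 1L) chars[, centre] <- "A"
    planted <- c(stats::rbinom(nPos, 1L, signalStrength),
                 stats::rbinom(nNeg, 1L, 1 - signalStrength)) == 1L
    for (j in seq_along(motifCols))
      chars[planted, motifCols[j]] <- motifChars[j]
    # scrub incidental matches from unplanted windows
    unplanted <- which(!planted)
    if (length(unplanted)) {
      isMatch <- rep(TRUE, length(unplanted))
      for (j in seq_along(motifCols))
        isMatch <- isMatch & chars[unplanted, motifCols[j]] == motifChars[j]
      for (i in unplanted[isMatch]) {
        mutable <- motifCols[motifCols != centre | !centralAdenine]
        pos <- sample(mutable, 1L)
        chars[i, pos] <- sample(setdiff(bases, chars[i, pos]), 1L)
      }
    }
    seqs <- if (n > 0L) apply(chars, 1L, paste0, collapse = "")
            else character(0)
    ids <- c(sprintf("pos_%d", seq_len(nPos)),
             sprintf("neg_%d", seq_len(nNeg)))
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- ids
    MethSeqSet(ss, rep(c(1L, 0L), c(nPos, nNeg)), name = name)
  })
}

#' Count motif occurrences at the planted offset
#'
#' Convenience check used in tests and reports: how many sequences of
#' each class carry `motif` exactly at `motifOffset`.
#'
#' @inheritParams simulateDataset
#' @param dataset A [MethSeqSet-class].
#' @return Named integer vector (positives, negatives).
#' @export
motifCarriage <- function(dataset, motif = "GAGG", motifOffset = 4L) {
  stopifnot(is(dataset, "MethSeqSet"))
  win <- as.character(Biostrings::subseq(sequences(dataset),
                                         motifOffset + 1L,
                                         motifOffset + nchar(motif)))
  hit <- win == toupper(motif)
  y <- classLabels(dataset)
  c(positives = sum(hit & y == 1L), negatives = sum(hit & y == 0L))
}

#' Write a simulated dataset as a FASTA fixture with a manifest
#'
#' Writes the positive/negative FASTA pair via [writeFastaPair()] plus
#' a JSON manifest recording the generation parameters for provenance.
#'
#' @param dataset A [MethSeqSet-class].
#' @param dir Output directory.
#' @param spec Optional named list of generation parameters to record.
#' @return Invisibly, the paths written (pos, neg, manifest).
#' @export
writeFixture <- function(dataset, dir, spec = NULL) {
  paths <- writeFastaPair(dataset, dir)
  manifest <- file.path(dir, paste0(
    gsub("[^A-Za-z0-9._-]", "_", datasetName(dataset)), "_manifest.json"))
  jsonlite::write_json(
    c(list(name = datasetName(dataset),
           nPos = positiveCount(dataset),
           nNeg = negativeCount(dataset),
           width = unique(Biostrings::width(sequences(dataset)))),
      spec),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, manifest))
}
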