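#' Construct a labeled methylation dataset
#'
#' @param sequences A [Biostrings::DNAStringSet] or character vector of
#'   equal-length windows over \{A,C,G,T\}.
#' @param labels Binary 0/1 vector, one label per sequence
#'   (1 = 6mA, 0 = non-6mA).
#' @param name Dataset identifier used in reports.
#' @return A [MethSeqSet-class].
#' @examples
#' MethSeqSet(c(strrep("A", 41), strrep("G", 41)), c(1, 0))
#' @export
MethSeqSet <- function(sequences, labels, name = "dataset") {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  labels <- .stopIfNot01(labels)
  new("MethSeqSet", sequences = sequences, labels = labels,
      datasetName = name)
}

#' Read and validate fixed-length DNA windows from a FASTA file
#'
#' Records are uppercased and validated: every record must have the
#' expected width and contain only A, C, G, T. Ambiguity codes such as
#' N are rejected unless `skipInvalid = TRUE`, in which case offending
#' records are dropped and the dropped count reported in a warning.
#'
#' @param path Path to a FASTA file (records may wrap lines).
#' @param expectedLength Required window width in bp (default 41).
#' @param skipInvalid Drop invalid records instead of failing.
#' @return A [Biostrings::DNAStringSet], record order preserved.
#' @export
readSequences <- function(path, expectedLength = 41L, skipInvalid = FALSE) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e)
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
  )
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  ids[ids == ""] <- as.character(which(ids == ""))
  # first word of the header is the record ID
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1L), 1L)
  names(seqs) <- ids

  badLen <- Biostrings::width(seqs) != expectedLength
  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  badAlpha <- af[, "other"] > 0
  bad <- badLen | badAlpha
  if (any(bad)) {
    detail <- paste0(
      ids[bad][1L],
      if (badLen[bad][1L])
        paste0(" has length ", Biostrings::width(seqs)[bad][1L],
               ", expected ", expectedLength)
      else " contains a non-ACGT character")
    if (!skipInvalid)
      stop("invalid record in '", path, "': ", detail,
           " (", sum(bad), " invalid of ", length(seqs), ")",
           call. = FALSE)
    warning("dropped ", sum(bad), " invalid record(s) from '", path,
            "' (first: ", detail, ")", call. = FALSE)
    seqs <- seqs[!bad]
  }
  seqs
}

#' Load a labeled dataset from a positive/negative FASTA pair
#'
#' Labels are tied to file identity, never to header parsing: every
#' record in `posPath` gets label 1 and every record in `negPath` gets
#' label 0, positives first. Positives whose central base (position
#' (L+1)/2, 1-based) is not adenine trigger a warning, not an error.
#'
#' @inheritParams readSequences
#' @param posPath FASTA of 6mA windows (label 1).
#' @param negPath FASTA of non-6mA windows (label 0).
#' @param name Dataset identifier.
#' @return A [MethSeqSet-class].
#' @export
loadDataset <- function(posPath, negPath, expectedLength = 41L,
                        skipInvalid = FALSE, name = "dataset") {
  pos <- tryCatch(
    readSequences(posPath, expectedLength, skipInvalid),
    error = function(e)
      stop("positive file: ", conditionMessage(e), call. = FALSE))
  neg <- tryCatch(
    readSequences(negPath, expectedLength, skipInvalid),
    error = function(e)
      stop("negative file: ", conditionMessage(e), call. = FALSE))
  if (length(pos) == 0L)
    warning("positive file '", posPath, "' contains no records",
            call. = FALSE)
  if (length(neg) == 0L)
    warning("negative file '", negPath, "' contains no records",
            call. = FALSE)
  if (length(pos) && expectedLength %% 2L == 1L) {
    centre <- (expectedLength + 1L) %/% 2L
    cb <- as.character(Biostrings::subseq(pos, centre, centre))
    if (any(cb != "A"))
      warning(sum(cb != "A"), " positive record(s) lack a central ",
              "adenine at position ", centre, call. = FALSE)
  }
  ds <- MethSeqSet(c(pos, neg), rep(c(1L, 0L), c(length(pos), length(neg))),
                   name = name)
  ds
}

#' Write a labeled dataset as a positive/negative FASTA pair
#'
#' @param dataset A [MethSeqSet-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths written
#'   (`<name>_pos.fasta`, `<name>_neg.fasta`).
#' @export
writeFastaPair <- function(dataset, dir) {
  stopifnot(is(dataset, "MethSeqSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nm <- gsub("[^A-Za-z0-9._-]", "_", datasetName(dataset))
  paths <- file.path(dir, paste0(nm, c("_pos.fasta", "_neg.fasta")))
  pos <- sequences(dataset)[classLabels(dataset) == 1L]
  neg <- sequences(dataset)[classLabels(dataset) == 0L]
  if (is.null(names(pos))) names(pos) <- paste0("pos_", seq_along(pos))
  if (is.null(names(neg))) names(neg) <- paste0("neg_", seq_along(neg))
  Biostrings::writeXStringSet(pos, paths[1L])
  Biostrings::writeXStringSet(neg, paths[2L])
  invisible(paths)
}

#' Write per-sequence prediction scores and calls
#'
#' Emits a CSV with header `id,score,call`; rows keep the input order.
#' Calls are written as `6mA` / `non-6mA`.
#'
#' @param ids Character record identifiers.
#' @param scores Numeric scores in [0,1].
#' @param calls Binary 0/1 calls (e.g. from [classifyScores()]).
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
writePredictions <- function(ids, scores, calls, path) {
  if (length(scores) && (any(scores < 0) || any(scores > 1)))
    stop("scores must lie in [0,1]", call. = FALSE)
  calls <- .stopIfNot01(calls, "calls")
  df <- data.frame(id = as.character(ids),
                   score = as.numeric(scores),
                   call = ifelse(calls == 1L, "6mA", "non-6mA"),
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e)
    stop("cannot write predictions to '", path, "': ",
         conditionMessage(e), call. = FALSE))
  invisible(df)
}

#' Read a predictions CSV written by [writePredictions()]
#'
#' @param path Path to the CSV.
#' @return Data frame with columns id (character), score (numeric),
#'   call (character).
#' @export
readPredictions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "numeric", "character"))
}
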