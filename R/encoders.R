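# Per-nucleotide encoding constants.
#
# one-hot: indicator over (A, T, C, G).
# NCP: ring structure (purine = 1), hydrogen-bond strength (weak = 1),
#      amino/keto group (amino = 1).
# EIIP: electron-ion interaction potential of the nucleotide, stored at
#       the conventional four printed decimals; no rescaling applied.
.ONE_HOT <- rbind(A = c(1, 0, 0, 0),
                  T = c(0, 1, 0, 0),
                  C = c(0, 0, 1, 0),
                  G = c(0, 0, 0, 1))
.NCP <- rbind(A = c(1, 1, 1),
              T = c(0, 1, 0),
              C = c(0, 0, 1),
              G = c(1, 0, 0))
.EIIP <- c(A = 0.1260, T = 0.1335, C = 0.1340, G = 0.0806)

.BLOCK <- cbind(.ONE_HOT, .NCP, .EIIP)
colnames(.BLOCK) <- c("oneA", "oneT", "oneC", "oneG",
                      "ring", "hbond", "amino", "eiip")

.seqToChars <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "DNAStringSet"))
    seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L)
    stop("expected a single DNA sequence", call. = FALSE)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop("non-ACGT residue '", chars[which(bad)[1L]], "' at position ",
         which(bad)[1L], call. = FALSE)
  chars
}

#' One-hot nucleotide encoding
#'
#' Maps each residue to the indicator vector over (A, T, C, G):
#' A = (1,0,0,0), T = (0,1,0,0), C = (0,0,1,0), G = (0,0,0,1).
#'
#' @param seq A single DNA sequence (character, [Biostrings::DNAString]).
#' @return An L x 4 numeric matrix, row i encoding residue i.
#' @examples
#' oneHotEncode("TG")
#' @export
oneHotEncode <- function(seq) {
  chars <- .seqToChars(seq)
  m <- .ONE_HOT[chars, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Nucleotide chemical property (NCP) encoding
#'
#' Three chemical coordinates per residue: ring structure
#' (purine/pyrimidine), hydrogen-bond strength (weak/strong) and
#' amino/keto group. A = (1,1,1), T = (0,1,0), C = (0,0,1),
#' G = (1,0,0).
#'
#' @inheritParams oneHotEncode
#' @return An L x 3 numeric matrix.
#' @export
ncpEncode <- function(seq) {
  chars <- .seqToChars(seq)
  m <- .NCP[chars, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Electron-ion interaction potential (EIIP) encoding
#'
#' One physical scalar per residue: A = 0.1260, T = 0.1335,
#' C = 0.1340, G = 0.0806.
#'
#' @inheritParams oneHotEncode
#' @return An L x 1 numeric matrix.
#' @export
eiipEncode <- function(seq) {
  chars <- .seqToChars(seq)
  matrix(unname(.EIIP[chars]), ncol = 1L)
}

#' Concatenated per-position encoding
#'
#' Column-wise concatenation of the three encodings in the fixed order
#' one-hot (4), NCP (3), EIIP (1), giving an L x 8 matrix — 41 x 8 for
#' the default window size. The encoding is position-local: row i
#' depends only on residue i.
#'
#' @inheritParams oneHotEncode
#' @return An L x 8 numeric matrix with named columns.
#' @export
encodeSequence <- function(seq) {
  chars <- .seqToChars(seq)
  m <- .BLOCK[chars, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Flatten an encoded matrix to the model's input vector
#'
#' Position-major (row-major) flattening: the 8 features of position i
#' occupy consecutive slots, so an L x 8 matrix becomes a vector of
#' length 8L (328 at L = 41). Exactly invertible by
#' [unflattenEncoding()].
#'
#' @param mat An L x k encoded matrix.
#' @return Numeric vector of length L * k.
#' @export
flattenEncoding <- function(mat) {
  stopifnot(is.matrix(mat))
  v <- as.vector(t(mat))
  if (!is.null(colnames(mat)))
    names(v) <- paste0("p", rep(seq_len(nrow(mat)), each = ncol(mat)),
                       ".", rep(colnames(mat), nrow(mat)))
  v
}

#' @rdname flattenEncoding
#' @param vec A flattened feature vector.
#' @param width Number of features per position (default 8).
#' @return `unflattenEncoding()`: the L x width matrix.
#' @export
unflattenEncoding <- function(vec, width = 8L) {
  if (length(vec) %% width != 0L)
    stop("vector length is not a multiple of ", width, call. = FALSE)
  matrix(vec, ncol = width, byrow = TRUE,
         dimnames = list(NULL, colnames(.BLOCK)[seq_len(width)]))
}

#' Encode a whole dataset into the flattened feature matrix
#'
#' Applies [encodeSequence()] + [flattenEncoding()] to every sequence,
#' returning the n x 8L design matrix (n x 328 for 41-bp windows) that
#' the feature selector and network consume.
#'
#' @param x A [MethSeqSet-class], [Biostrings::DNAStringSet] or
#'   character vector of equal-length sequences.
#' @return Numeric matrix, one row per sequence; columns named
#'   `p<position>.<feature>`.
#' @export
encodeDataset <- function(x) {
  if (is(x, "MethSeqSet")) x <- sequences(x)
  if (is(x, "DNAStringSet")) x <- as.character(x)
  x <- toupper(x)
  n <- length(x)
  if (n == 0L) stop("no sequences to encode", call. = FALSE)
  L <- unique(nchar(x))
  if (length(L) != 1L)
    stop("sequences must all have the same length", call. = FALSE)
  chars <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  bad <- matrix(!(chars %in% rownames(.BLOCK)), nrow = n)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-ACGT residue in sequence ", idx[1L], " at position ",
         idx[2L], call. = FALSE)
  }
  out <- matrix(0, nrow = n, ncol = 8L * L)
  for (p in seq_len(L))
    out[, (8L * (p - 1L) + 1L):(8L * p)] <- .BLOCK[chars[, p], , drop = FALSE]
  colnames(out) <- paste0("p", rep(seq_len(L), each = 8L), ".",
                          rep(colnames(.BLOCK), L))
  out
}

#' Encoding constants used by the package
#'
#' @return A list with elements `oneHot` (4 x 4), `ncp` (4 x 3) and
#'   `eiip` (length-4 vector), rows/entries named A, T, C, G.
#' @export
encodingTable <- function() {
  list(oneHot = .ONE_HOT, ncp = .NCP, eiip = .EIIP)
}
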