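# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they
# verify.

# confusion-metric oracle: plain arithmetic on the four counts
oracleMetrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  c(acc = acc, sn = sn, sp = sp, mcc = mcc)
}

# Mann-Whitney all-pairs AUC oracle (ties count one half)
oracleAUC <- function(truth, scores) {
  sp <- scores[truth == 1]
  sn <- scores[truth == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# average-precision oracle by explicit threshold enumeration
oracleAP <- function(truth, scores) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  prevRecall <- 0
  area <- 0
  P <- sum(truth == 1)
  for (t in cuts) {
    calls <- as.integer(scores >= t)
    tp <- sum(truth == 1 & calls == 1)
    fp <- sum(truth == 0 & calls == 1)
    recall <- tp / P
    precision <- tp / (tp + fp)
    area <- area + (recall - prevRecall) * precision
    prevRecall <- recall
  }
  area
}

# random DNA windows
randomWindows <- function(n, L = 41L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""),
    character(1L))
}

writeTempFasta <- function(seqs, ids = NULL, dir = tempdir()) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  path <- tempfile(tmpdir = dir, fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}
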