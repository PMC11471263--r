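# Independent brute-force affine-gap dynamic-programming aligner (Gotoh,
# three-state).  Deliberately written as plain matrix recurrences with no
# shared code with the package's alignment path; used as the scoring
# oracle.  Gap of length L costs go + L * ge.

oracle_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

dp_align_score <- function(query, ref, mode = c("local", "global", "global_query"),
                           go = 11, ge = 1) {
  mode <- match.arg(mode)
  S <- oracle_submat()
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # q[i] aligned to r[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in ref (q[i] vs '-')
  Y <- matrix(NEG, n + 1, m + 1)   # gap in query ('-' vs r[j])

  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(go + (i - 1) * ge)
  if (mode == "global") {
    for (j in 2:(m + 1)) Y[1, j] <- -(go + (j - 1) * ge)
  } else if (mode == "global_query") {
    for (j in 2:(m + 1)) M[1, j] <- 0   # free leading reference overhang
  }
  if (mode == "local") {
    M[, 1] <- pmax(M[, 1], 0); M[1, ] <- 0
    X[, 1] <- pmax(X[, 1], NEG)  # local alignments never start in a gap
  }

  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[q[i - 1], r[j - 1]]
      diag_best <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- diag_best + s
      if (mode == "local") M[i, j] <- max(M[i, j], s, 0)
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    }
  }
  if (mode == "local") {
    return(max(0, max(M[2:(n + 1), 2:(m + 1)])))
  }
  if (mode == "global_query") {
    return(max(M[n + 1, 2:(m + 1)], X[n + 1, 2:(m + 1)]))
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
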