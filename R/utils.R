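## Internal helpers shared across modules.

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

collapse <- function(x) paste(x, collapse = "")

#' Is `sub` obtainable from `full` by deleting characters?
#' @noRd
is_subsequence <- function(sub, full) {
  if (nchar(sub) == 0L) return(TRUE)
  if (nchar(sub) > nchar(full)) return(FALSE)
  s <- chars(sub); f <- chars(full)
  i <- 1L
  for (ch in f) {
    if (ch == s[i]) {
      i <- i + 1L
      if (i > length(s)) return(TRUE)
    }
  }
  FALSE
}

check_aa <- function(seq, what = "sequence", allow_x = TRUE) {
  ok <- AA_1
  if (allow_x) ok <- c(ok, "X")
  bad <- setdiff(unique(chars(seq)), ok)
  if (length(bad) > 0L) {
    abort(sprintf("%s contains non-amino-acid letters: %s",
                  what, paste(bad, collapse = ", ")))
  }
  invisible(seq)
}

## Deterministic seed derivation: keep any derived seed within 32-bit range.
derive_seed <- function(seed, salt) {
  (as.integer(seed) * 1009L + as.integer(salt)) %% 2147483647L
}

rad2deg <- function(x) x * 180 / pi
deg2rad <- function(x) x * pi / 180
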