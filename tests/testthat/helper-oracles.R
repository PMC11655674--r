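# Independent oracles: deliberately naive reimplementations used to verify
# the package's optimized code paths. Kept free of any package internals.

# forward-strand degenerate pattern matching by per-position set membership
oracle_match <- function(pattern, seq, strict_n = TRUE) {
  sets <- IUPAC_CODES
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  w <- length(pat)
  L <- length(s)
  if (w > L) return(integer(0))
  hits <- integer(0)
  for (o in 0:(L - w)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      base <- s[o + j]
      ok <- if (base == "N") {
        if (strict_n) pat[j] == "N" else TRUE
      } else {
        base %in% sets[[pat[j]]]
      }
      if (!ok) break
    }
    if (ok) hits <- c(hits, o)
  }
  hits
}

# score-only Gotoh local alignment, plain R matrices; gap of length k costs
# open + k * ext
oracle_sw_score <- function(a, b, submat = blosum62(), open = 11, ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
                       submat[A[i - 1], B[j - 1]])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# exhaustive 4^w enumeration of the binned score distribution (w <= 8);
# returns a function k -> P(binned score >= k) under the PWM's background
oracle_tail_fun <- function(pwm, eps = 1e-3) {
  K <- round(logodds(pwm) / eps)
  w <- ncol(K)
  stopifnot(w <= 8)
  bg <- pwm$background
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(words))
  lp <- numeric(nrow(words))
  for (j in seq_len(w)) {
    scores <- scores + K[words[, j], j]
    lp <- lp + log(bg[words[, j]])
  }
  probs <- exp(lp)
  function(k) vapply(k, function(k0) sum(probs[scores >= k0]), numeric(1))
}

# edit distance up to reverse complement (strand is unidentifiable when both
# strands are searched)
edit_rc_min <- function(consensus, word) {
  consensus <- as.character(consensus)
  min(utils::adist(consensus, word), utils::adist(revcomp(consensus), word))
}
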