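# Position weight matrices: construction with background-weighted
# pseudocounts, degenerate consensus strings, and log-odds transforms.

.DNA <- c("A", "C", "G", "T")

#' Construct a PWM object
#'
#' @param freq 4 x w matrix of per-position base frequencies, rows A/C/G/T;
#'   every column must sum to 1.
#' @param background Named base probabilities (A/C/G/T), summing to 1.
#' @param alpha Pseudocount used to build `freq` (stored for provenance).
#' @return Object of class `pwm`.
#' @export
new_pwm <- function(freq, background = rep(0.25, 4), alpha = NA_real_) {
  freq <- as.matrix(freq)
  stopifnot(nrow(freq) == 4L)
  dimnames(freq) <- list(.DNA, NULL)
  if (any(abs(colSums(freq) - 1) > 1e-9))
    stop("PWM columns must each sum to 1")
  background <- setNames(as.numeric(background), .DNA)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  structure(list(freq = freq, background = background, alpha = alpha,
                 width = ncol(freq)), class = "pwm")
}

#' Build a PWM from aligned sites
#'
#' Additive smoothing with a total pseudo-mass of `4 * alpha` per column,
#' distributed according to the background:
#' `f[b,i] = (count[b,i] + 4 * alpha * bg[b]) / (n + 4 * alpha)`.
#'
#' @param sites Character vector of equal-length site sequences (A/C/G/T).
#' @param alpha Pseudocount (default 0.25).
#' @param background Base probabilities (default uniform).
#' @return A [new_pwm()] object.
#' @examples
#' build_pwm(c("ACGT", "ACGA"))
#' @export
build_pwm <- function(sites, alpha = 0.25, background = rep(0.25, 4)) {
  if (length(sites) < 1L) stop("need at least one site")
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites must all have the same length")
  background <- setNames(as.numeric(background), .DNA)
  mat <- do.call(rbind, strsplit(toupper(sites), "", fixed = TRUE))
  if (!all(mat %in% .DNA)) stop("sites must be over {A,C,G,T}")
  counts <- apply(mat, 2, function(col) tabulate(match(col, .DNA), 4L))
  freq <- sweep(counts + 4 * alpha * background, 2,
                colSums(counts) + 4 * alpha, "/")
  new_pwm(freq, background, alpha)
}

#' Degenerate IUPAC consensus of a PWM
#'
#' Per column, the bases with frequency >= `rule_threshold` form the
#' candidate set; its IUPAC symbol is emitted when the set captures at least
#' 75% of the column's probability mass, otherwise the column falls back
#' to `N`.
#'
#' @param pwm A `pwm` object.
#' @param rule_threshold Per-base inclusion threshold (default 0.25).
#' @return Expanded pattern of class `iupac_pattern`.
#' @export
consensus_from_pwm <- function(pwm, rule_threshold = 0.25) {
  stopifnot(inherits(pwm, "pwm"))
  eps <- 1e-12
  sym <- vapply(seq_len(pwm$width), function(i) {
    f <- pwm$freq[, i]
    set <- .DNA[f >= rule_threshold - eps]
    if (length(set) == 0L || sum(f[set]) < 0.75 - eps) return("N")
    .SET_TO_SYMBOL[[paste(sort(set), collapse = "")]]
  }, character(1))
  parse_iupac(paste(sym, collapse = ""))
}

#' Log-odds matrix of a PWM
#'
#' `log2(f[b,i] / bg[b])`; the score of a word is the sum over positions.
#'
#' @param pwm A `pwm` object with strictly positive frequencies and
#'   background.
#' @return 4 x w numeric matrix.
#' @export
logodds <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  if (any(pwm$background <= 0)) stop("background entries must be positive")
  if (any(pwm$freq <= 0))
    stop("PWM frequencies must be positive (use a pseudocount)")
  log2(sweep(pwm$freq, 1, pwm$background, "/"))
}

#' Reverse complement of a PWM
#' @param pwm A `pwm` object.
#' @return A `pwm` with columns reversed and bases complemented.
#' @export
revcomp_pwm <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  f <- pwm$freq[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  rownames(f) <- .DNA
  new_pwm(f, pwm$background, pwm$alpha)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM, width %d (alpha = %s)\n", x$width, format(x$alpha)))
  cat("consensus:", as.character(consensus_from_pwm(x)), "\n")
  print(round(x$freq, 3))
  invisible(x)
}

#' Sample a word from a PWM
#' @param pwm A `pwm` object.
#' @return Character scalar of length `pwm$width` (uses the current RNG
#'   stream).
#' @export
sample_pwm <- function(pwm) {
  paste(vapply(seq_len(pwm$width), function(i)
    sample(.DNA, 1L, prob = pwm$freq[, i]), character(1)), collapse = "")
}
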