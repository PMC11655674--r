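# IUPAC nucleotide algebra: the 15 degenerate codes, complementation and
# degenerate pattern matching. All coordinates are 0-based half-open.

#' Base sets of the 15 IUPAC nucleotide codes
#'
#' A named list mapping each IUPAC symbol to the set of unambiguous bases it
#' stands for (e.g. `R` = A/G, `W` = A/T, `N` = any).
#'
#' @format Named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# bit encoding: A=1 C=2 G=4 T=8; bit 16 marks a literal N in a *sequence*
.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)
.PAT_MASK <- vapply(IUPAC_CODES, function(b) sum(.BASE_BITS[b]), integer(1))
.PAT_MASK["N"] <- .PAT_MASK["N"] + 16L  # pattern N always matches sequence N

.IUPAC_FROM <- "ACGTRYSWKMBDHVN"
.IUPAC_TO   <- "TGCAYRSWMKVHDBN"

# canonical symbol for a sorted base subset, e.g. "AG" -> "R"
.SET_TO_SYMBOL <- setNames(
  names(IUPAC_CODES),
  vapply(IUPAC_CODES, function(b) paste(sort(b), collapse = ""), character(1))
)

.check_iupac <- function(x, what = "sequence") {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% names(IUPAC_CODES))
  if (length(bad))
    stop(sprintf("non-IUPAC character '%s' in %s at position %d",
                 ch[bad[1]], what, bad[1]), call. = FALSE)
  invisible(ch)
}

#' Reverse complement of a DNA string or IUPAC pattern
#'
#' Uses the full IUPAC complement table (R<->Y, M<->K, W<->W, S<->S, B<->V,
#' D<->H, N<->N), so degenerate patterns complement correctly; a palindromic
#' degenerate motif is a fixed point.
#'
#' @param x Character vector of sequences/patterns over the IUPAC alphabet
#'   (case-insensitive; returned upper-case).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAGACA")                   # "TGTCTT"
#' revcomp("RACMTGTCYWWWWRGACAKGTY")   # palindromic: equal to its input
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  for (s in x) .check_iupac(s)
  vapply(chartr(.IUPAC_FROM, .IUPAC_TO, x), function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Parse a (possibly compact) IUPAC pattern
#'
#' Accepts the compact run-length notation used for degenerate motifs, e.g.
#' `"TWTM(N6)GAC"` or `"TWTM(N)6GAC"`, expands it and validates every symbol.
#'
#' @param pattern Character scalar.
#' @return The expanded pattern (character scalar of class `iupac_pattern`)
#'   with attribute `width`.
#' @examples
#' parse_iupac("TWTM(N6)GAC")  # "TWTMNNNNNNGAC", width 13
#' @export
parse_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  p <- toupper(gsub("\\s", "", pattern))
  # (X6) and (X)6 both expand to six X's
  for (re in c("\\(([A-Z])([0-9]+)\\)", "\\(([A-Z])\\)_?([0-9]+)")) {
    while (grepl(re, p)) {
      m <- regmatches(p, regexpr(re, p))[[1]]
      sym <- sub(re, "\\1", m)
      n <- as.integer(sub(re, "\\2", m))
      regmatches(p, regexpr(re, p)) <- strrep(sym, n)
    }
  }
  .check_iupac(p, "pattern")
  structure(p, width = nchar(p), class = "iupac_pattern")
}

#' Match a degenerate IUPAC pattern against a DNA sequence
#'
#' Reports every offset where all pattern symbols' base sets contain the
#' corresponding sequence base. Minus-strand matches (of the reverse
#' complement of the pattern) are reported at the forward-strand coordinate
#' of the match start. In strict mode (default) a literal `N` in the
#' *sequence* only matches a pattern `N`; in permissive mode it matches any
#' symbol.
#'
#' @param pattern IUPAC pattern (compact form allowed, see [parse_iupac()]).
#' @param seq DNA sequence (A/C/G/T/N).
#' @param strands `"both"` or `"forward"`.
#' @param strict_n Logical; see above.
#' @return `data.frame` with columns `offset` (0-based) and `strand`.
#'   A pattern longer than the sequence yields zero rows.
#' @export
match_pattern <- function(pattern, seq, strands = c("both", "forward"),
                          strict_n = TRUE) {
  strands <- match.arg(strands)
  p <- as.character(parse_iupac(pattern))
  s <- toupper(seq)
  sch <- .check_iupac(s)
  if (!all(sch %in% c("A", "C", "G", "T", "N")))
    stop("sequence must be over {A,C,G,T,N}; use parse_iupac for patterns")
  hits <- .match_one(p, sch, strict_n)
  out <- data.frame(offset = hits, strand = rep("+", length(hits)),
                    stringsAsFactors = FALSE)
  if (strands == "both") {
    hits_m <- .match_one(revcomp(p), sch, strict_n)
    out <- rbind(out, data.frame(offset = hits_m,
                                 strand = rep("-", length(hits_m)),
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.match_one <- function(p, sch, strict_n) {
  w <- nchar(p)
  L <- length(sch)
  if (w > L || w == 0L) return(integer(0))
  pm <- .PAT_MASK[strsplit(p, "", fixed = TRUE)[[1]]]
  if (!strict_n) pm <- bitwOr(pm, 16L)
  sb <- .BASE_BITS[sch]
  nw <- L - w + 1L
  ok <- rep(TRUE, nw)
  for (j in seq_len(w))
    ok <- ok & bitwAnd(pm[j], sb[j:(j + nw - 1L)]) > 0L
  which(ok) - 1L
}

# integer encoding A=0 C=1 G=2 T=3, anything else -1 (poisons windows)
.encode_dna <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T"))
  as.integer(ifelse(is.na(v), -1L, v - 1L))
}
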