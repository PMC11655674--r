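# PWM scanning with exact p-values. The log-odds matrix is discretized to a
# grid of step eps (integer bins, round-to-nearest, so binned and real word
# scores differ by at most w*eps/2); the full distribution of the binned
# score of a background-generated word is then computed by dynamic
# programming, convolving the four per-position outcomes. Scanning scores
# words with the *same* binned matrix, so their tail probabilities are exact
# for the discretized score.

#' Exact score distribution of a PWM under the background model
#'
#' @param pwm A `pwm` object (positive frequencies and background).
#' @param eps Score discretization step in log2 units (default 1e-3).
#' @param max_bins Guard on the size of the discretized score axis.
#' @return Object of class `score_distribution`: integer score grid
#'   (`kmin:kmax`, in units of `eps`), point probabilities `prob`, tail
#'   probabilities `tail` (`P(S >= k)`), and the binned log-odds matrix `K`.
#' @export
score_distribution <- function(pwm, eps = 1e-3, max_bins = 2e7) {
  stopifnot(inherits(pwm, "pwm"), eps > 0)
  lo <- logodds(pwm)
  K <- round(lo / eps)
  kmin_col <- unname(apply(K, 2, min))
  kmax_col <- unname(apply(K, 2, max))
  if (sum(kmax_col) - sum(kmin_col) + 1 > max_bins)
    stop("discretized score axis exceeds max_bins; increase eps")
  bg <- pwm$background
  cur <- 1
  cur_min <- 0
  for (j in seq_len(pwm$width)) {
    span <- kmax_col[j] - kmin_col[j]
    new <- numeric(length(cur) + span)
    for (b in 1:4) {
      sh <- K[b, j] - kmin_col[j]
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new
    cur_min <- cur_min + kmin_col[j]
  }
  tail <- rev(cumsum(rev(cur)))
  tail <- unname(pmin(pmax(tail, 0), 1))
  cur <- unname(cur)
  structure(list(eps = eps, kmin = cur_min, kmax = cur_min + length(cur) - 1,
                 prob = cur, tail = tail, K = K, width = pwm$width,
                 background = bg),
            class = "score_distribution")
}

# tail probability at integer bin k (vectorized; NA scores stay NA)
.tail_at_k <- function(dist, k) {
  out <- rep(NA_real_, length(k))
  ok <- !is.na(k)
  out[ok & k < dist$kmin] <- 1
  out[ok & k > dist$kmax] <- 0
  inr <- ok & k >= dist$kmin & k <= dist$kmax
  out[inr] <- dist$tail[k[inr] - dist$kmin + 1]
  out
}

#' Exact p-value of a score
#'
#' Returns the tail probability at the nearest discretized score at or below
#' `s` (conservative: the reported p-value is never smaller than the exact
#' tail at `s`).
#'
#' @param dist A [score_distribution()].
#' @param s Numeric score(s) on the log2-odds scale.
#' @return Tail probabilities in `[0, 1]`.
#' @export
pvalue <- function(dist, s) {
  stopifnot(inherits(dist, "score_distribution"))
  .tail_at_k(dist, floor(s / dist$eps + 1e-9))
}

#' Score threshold attaining a p-value
#'
#' The smallest discretized score whose tail probability is <= `p`, so that
#' `pvalue(dist, score_for_pvalue(dist, p)) <= p`.
#'
#' @param dist A [score_distribution()].
#' @param p Target p-value in (0, 1].
#' @return Score on the log2-odds scale.
#' @export
score_for_pvalue <- function(dist, p) {
  stopifnot(inherits(dist, "score_distribution"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    stop("p must be in (0, 1]")
  idx <- which(dist$tail <= p + 1e-15)[1]
  if (is.na(idx)) return((dist$kmax + 1) * dist$eps)
  (dist$kmin + idx - 1) * dist$eps
}

#' Scan regions with a PWM at an exact p-value cutoff
#'
#' Every window (on both strands by default) whose exact p-value is at most
#' `p_cut` is reported. Minus-strand hits are reported at the
#' forward-coordinate start of the matched window, with the matched word
#' given strand-oriented. Windows containing N are skipped. Overlapping hits
#' are all reported.
#'
#' @param pwm A `pwm` object.
#' @param regions Named character vector of sequences, or a promoter
#'   `data.frame` (`region_id`, `seq`), or a single string.
#' @param p_cut P-value cutoff (default 1e-4).
#' @param both_strands Scan both strands (default TRUE).
#' @param dist Optional precomputed [score_distribution()] for `pwm`.
#' @param eps Discretization step when `dist` is NULL.
#' @return `data.frame` of hits: `region_id`, `offset` (0-based forward),
#'   `strand`, `score` (binned log2-odds), `pvalue`, `word`.
#' @export
scan_region <- function(pwm, regions, p_cut = 1e-4, both_strands = TRUE,
                        dist = NULL, eps = 1e-3) {
  stopifnot(inherits(pwm, "pwm"))
  regions <- .as_region_seqs(regions)
  if (is.null(dist)) dist <- score_distribution(pwm, eps = eps)
  w <- pwm$width
  K <- dist$K
  storage.mode(K) <- "double"
  Krc <- K[4:1, rev(seq_len(w)), drop = FALSE]
  out <- list()
  for (id in names(regions)) {
    s <- regions[[id]]
    if (nchar(s) < w) {
      warning("region '", id, "' shorter than the motif width; skipped")
      next
    }
    e <- .encode_dna(s)
    for (strand in if (both_strands) c("+", "-") else "+") {
      k <- window_scores_cpp(e, if (strand == "+") K else Krc)
      pv <- .tail_at_k(dist, k)
      pv[is.na(k)] <- NA_real_
      hit <- which(!is.na(pv) & pv <= p_cut)
      if (!length(hit)) next
      word <- substring(s, hit, hit + w - 1L)
      if (strand == "-") word <- revcomp(word)
      out[[length(out) + 1L]] <-
        data.frame(region_id = id, offset = hit - 1L, strand = strand,
                   score = k[hit] * dist$eps, pvalue = pv[hit], word = word,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(region_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      pvalue = numeric(0), word = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$region_id, res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Aggregate scan hits into sites and region summaries
#'
#' Plus- and minus-strand hits at the same forward offset (the signature of
#' a palindromic matrix) collapse into a single site flagged
#' `palindromic_pair`; regions are ranked by their best p-value.
#'
#' @param hits Output of [scan_region()].
#' @return List with `sites` (one row per distinct forward-coordinate site:
#'   `region_id`, `offset`, `strands`, `palindromic_pair`, `best_pvalue`)
#'   and `regions` (`region_id`, `n_hits`, `n_sites`, `best_pvalue`,
#'   ranked by `best_pvalue`).
#' @export
aggregate_hits <- function(hits) {
  if (nrow(hits) == 0L)
    return(list(sites = data.frame(region_id = character(0),
                                   offset = integer(0), strands = character(0),
                                   palindromic_pair = logical(0),
                                   best_pvalue = numeric(0)),
                regions = data.frame(region_id = character(0),
                                     n_hits = integer(0), n_sites = integer(0),
                                     best_pvalue = numeric(0))))
  key <- interaction(hits$region_id, hits$offset, drop = TRUE)
  sites <- do.call(rbind, lapply(split(hits, key), function(h) {
    data.frame(region_id = h$region_id[1], offset = h$offset[1],
               strands = paste(sort(unique(h$strand)), collapse = ""),
               palindromic_pair = length(unique(h$strand)) == 2L,
               best_pvalue = min(h$pvalue), stringsAsFactors = FALSE)
  }))
  sites <- sites[order(sites$region_id, sites$offset), , drop = FALSE]
  rownames(sites) <- NULL
  regions <- do.call(rbind, lapply(split(hits, hits$region_id), function(h) {
    data.frame(region_id = h$region_id[1], n_hits = nrow(h),
               n_sites = length(unique(h$offset)),
               best_pvalue = min(h$pvalue), stringsAsFactors = FALSE)
  }))
  regions <- regions[order(regions$best_pvalue, regions$region_id), ,
                     drop = FALSE]
  rownames(regions) <- NULL
  list(sites = sites, regions = regions)
}

#' Write scan hits as BED6
#'
#' The BED score is `-10 * log10(pvalue)`, capped at 1000.
#'
#' @param hits Output of [scan_region()].
#' @param path Output path.
#' @param width Motif width (taken from the word column when NULL).
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, width = NULL) {
  if (is.null(width)) width <- if (nrow(hits)) nchar(hits$word[1]) else 0L
  bed <- data.frame(hits$region_id, hits$offset, hits$offset + width,
                    hits$word,
                    round(pmin(-10 * log10(pmax(hits$pvalue, 1e-100)), 1000)),
                    hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
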