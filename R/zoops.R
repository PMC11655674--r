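# Motif discovery under a ZOOPS (zero-or-one occurrence per sequence) model,
# fitted by expectation-maximization. Each sequence carries a site of width w
# with probability q, at a position (and strand) uniform over the candidate
# windows; everything else is 0-order background.

.as_region_seqs <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("seq" %in% names(x))
    ids <- if ("region_id" %in% names(x)) x$region_id else
      sprintf("region_%03d", seq_len(nrow(x)))
    return(setNames(x$seq, ids))
  }
  x <- setNames(as.character(x), names(x))
  if (is.null(names(x)) || !all(nzchar(names(x))))
    names(x) <- sprintf("region_%03d", seq_along(x))
  toupper(x)
}

# log background probability of every forward window
.window_logbg <- function(enc, bg, w) {
  window_scores_cpp(enc, matrix(rep(log(bg), w), 4L, w))
}

.estimate_background <- function(seqs) {
  ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  counts <- tabulate(match(ch, .DNA), 4L)
  bg <- pmax(counts / sum(counts), 1e-6)
  setNames(bg / sum(bg), .DNA)
}

# move the motif register by k columns, refilling with background
.shift_cols <- function(f, k, bg) {
  w <- ncol(f)
  out <- matrix(bg, 4L, w)
  if (k > 0) out[, (k + 1L):w] <- f[, 1L:(w - k), drop = FALSE]
  else out[, 1L:(w + k)] <- f[, (-k + 1L):w, drop = FALSE]
  out
}

# one E-step over a single sequence; returns posteriors and log-likelihood
# contribution. lrr is NULL when scanning one strand only.
.zoops_seq_estep <- function(lrf, lrr, q, m) {
  af <- exp(pmin(lrf, 700)); af[is.na(af)] <- 0
  ar <- NULL; tot <- sum(af)
  if (!is.null(lrr)) {
    ar <- exp(pmin(lrr, 700)); ar[is.na(ar)] <- 0
    tot <- tot + sum(ar)
  }
  denom <- (1 - q) + (q / m) * tot
  list(zf = (q / m) * af / denom,
       zr = if (is.null(ar)) NULL else (q / m) * ar / denom,
       site_post = 1 - (1 - q) / denom,
       ll = log(denom))
}

#' Discover a motif by ZOOPS expectation-maximization
#'
#' Fits a PWM of fixed width `w` under a zero-or-one-occurrence-per-sequence
#' model with a shared occurrence prior `q`, latent site positions (both
#' strands by default), and a background-weighted pseudocount in the M-step.
#' Each restart is seeded from one of the observed w-mers (drawn from the
#' sorted pool of all w-mers, so the result does not depend on sequence
#' order); the best restart by final log-likelihood wins. With
#' `palindrome_constraint` the frequency matrix is averaged with its reverse
#' complement after every M-step.
#'
#' @param seqs Named character vector of sequences, or a promoter
#'   `data.frame` with `region_id` and `seq` columns.
#' @param w Motif width (default 22).
#' @param restarts Number of EM restarts (default 20).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param both_strands Search both strands (default TRUE).
#' @param palindrome_constraint Force a palindromic frequency matrix.
#' @param alpha Pseudocount (default 0.25, background-weighted).
#' @param background Base probabilities; estimated from `seqs` (0-order)
#'   when NULL.
#' @param max_iter,tol EM stopping rule (absolute log-likelihood change).
#' @return Object of class `motif_model`: `pwm`, `q`, `occupancy`
#'   (sequences with posterior site probability >= 0.5, out of total),
#'   `consensus`, `ll` (log-likelihood relative to pure background),
#'   `ll_trace` of the winning restart, and per-sequence best `sites`.
#' @export
discover_motif <- function(seqs, w = 22L, restarts = 20L, seed = 1L,
                           both_strands = TRUE, palindrome_constraint = FALSE,
                           alpha = 0.25, background = NULL,
                           max_iter = 200L, tol = 1e-5) {
  seqs <- .as_region_seqs(seqs)
  w <- as.integer(w)
  ns <- length(seqs)
  if (ns == 0L) stop("no sequences")
  short <- names(seqs)[nchar(seqs) < w]
  if (length(short))
    stop("sequence(s) shorter than the motif width: ",
         paste(short, collapse = ", "))
  bg <- if (is.null(background)) .estimate_background(seqs) else
    setNames(as.numeric(background) / sum(background), .DNA)
  enc <- lapply(seqs, .encode_dna)
  rcenc <- if (both_strands) lapply(unname(seqs), function(s)
    .encode_dna(revcomp(s))) else NULL
  lbg <- lapply(enc, .window_logbg, bg = bg, w = w)
  nw <- unname(vapply(enc, function(e) length(e) - w + 1L, integer(1)))
  m <- nw * if (both_strands) 2L else 1L

  # order-invariant pool of seed words
  pool <- sort(unique(unlist(lapply(unname(seqs), function(s) {
    L <- nchar(s)
    win <- substring(s, 1:(L - w + 1L), w:L)
    win[!grepl("N", win, fixed = TRUE)]
  }))))
  if (length(pool) == 0L) stop("no N-free windows to seed from")

  run_em <- function(f, q) {
    trace <- numeric(0)
    ll_prev <- NA_real_
    for (it in seq_len(max_iter)) {
      lf <- log(f)
      counts <- matrix(0, 4L, w)
      site_post <- numeric(ns)
      ll <- 0
      for (s in seq_len(ns)) {
        lrf <- window_scores_cpp(enc[[s]], lf) - lbg[[s]]
        lrr <- if (both_strands)
          window_scores_cpp(rcenc[[s]], lf) - rev(lbg[[s]]) else NULL
        e <- .zoops_seq_estep(lrf, lrr, q, m[s])
        counts <- counts + weighted_counts_cpp(enc[[s]], e$zf, w)
        if (both_strands)
          counts <- counts + weighted_counts_cpp(rcenc[[s]], e$zr, w)
        site_post[s] <- e$site_post
        ll <- ll + e$ll
      }
      f <- sweep(counts + 4 * alpha * matrix(bg, 4L, w), 2,
                 colSums(counts) + 4 * alpha, "/")
      q <- min(max(mean(site_post), 1e-4), 1 - 1e-4)
      if (palindrome_constraint)
        f <- (f + f[4:1, w:1, drop = FALSE]) / 2
      trace <- c(trace, ll)
      if (!is.na(ll_prev) && abs(ll - ll_prev) < tol) break
      ll_prev <- ll
    }
    list(f = f, q = q, ll = ll, trace = trace)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    rs <- (abs(seed) * 97L + r * 1009L) %% 2147483629L + 1L
    set.seed(rs)
    word <- .encode_dna(pool[sample.int(length(pool), 1L)])
    f0 <- matrix(0.3 * bg, 4L, w)
    f0[cbind(word + 1L, seq_len(w))] <- f0[cbind(word + 1L, seq_len(w))] + 0.7
    fit <- run_em(f0, 0.5)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }

  # register refinement: EM can converge one or a few columns off the optimal
  # alignment; walk the matrix left/right while the likelihood improves
  for (round in 1:10) {
    improved <- FALSE
    for (k in c(-1L, 1L, -2L, 2L, -3L, 3L)) {
      fit <- run_em(.shift_cols(best$f, k, bg), best$q)
      if (fit$ll > best$ll + 1e-8) { best <- fit; improved <- TRUE; break }
    }
    if (!improved) break
  }

  # final posteriors and per-sequence best sites under the winning model
  lf <- log(best$f)
  site_post <- numeric(ns)
  sites <- vector("list", ns)
  for (s in seq_len(ns)) {
    lrf <- window_scores_cpp(enc[[s]], lf) - lbg[[s]]
    lrr <- if (both_strands)
      window_scores_cpp(rcenc[[s]], lf) - rev(lbg[[s]]) else NULL
    e <- .zoops_seq_estep(lrf, lrr, best$q, m[s])
    site_post[s] <- e$site_post
    z <- c(e$zf, e$zr)
    j <- which.max(z)
    if (length(j)) {
      if (j <= nw[s]) { off <- j - 1L; strand <- "+" }
      else { off <- nw[s] - (j - nw[s]); strand <- "-" }
      word <- substr(seqs[[s]], off + 1L, off + w)
      if (strand == "-") word <- revcomp(word)
      sites[[s]] <- data.frame(region_id = names(seqs)[s], offset = off,
                               strand = strand, posterior = z[j],
                               site_posterior = site_post[s], word = word,
                               stringsAsFactors = FALSE)
    }
  }
  pwm <- new_pwm(best$f, bg, alpha)
  structure(list(pwm = pwm, q = best$q,
                 occupancy = c(found = sum(site_post >= 0.5), total = ns),
                 consensus = consensus_from_pwm(pwm),
                 ll = best$ll, ll_trace = best$trace,
                 sites = do.call(rbind, sites),
                 w = w, both_strands = both_strands,
                 palindrome_constraint = palindrome_constraint,
                 seed = seed, restarts = restarts),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("ZOOPS motif model, width %d\n", x$w))
  cat(sprintf("consensus: %s\n", as.character(x$consensus)))
  cat(sprintf("occupancy: %d of %d sequences (q = %.3f)\n",
              x$occupancy[1], x$occupancy[2], x$q))
  cat(sprintf("log-likelihood ratio vs background: %.2f\n", x$ll))
  invisible(x)
}

# posterior-weighted log-likelihood-ratio statistic of a model on a set of
# encoded sequences
.llr_stat <- function(model, encs, w) {
  f <- model$pwm$freq
  bg <- model$pwm$background
  q <- model$q
  lf <- log(f)
  both <- isTRUE(model$both_strands)
  total <- 0
  for (e in encs) {
    lbg <- .window_logbg(e, bg, w)
    m <- (length(e) - w + 1L) * if (both) 2L else 1L
    lrf <- window_scores_cpp(e, lf) - lbg
    lrr <- if (both) {
      rc <- rev(ifelse(e < 0L, -1L, 3L - e))  # reverse complement of the codes
      window_scores_cpp(rc, lf) - rev(lbg)
    } else NULL
    es <- .zoops_seq_estep(lrf, lrr, q, m)
    lr_all <- c(lrf, lrr)
    z_all <- c(es$zf, es$zr)
    keep <- z_all > 0 & is.finite(lr_all)
    total <- total + sum(z_all[keep] * lr_all[keep])
  }
  total
}

#' Approximate significance of a discovered motif
#'
#' The statistic is the posterior-weighted total log-likelihood ratio of
#' sites versus background (natural log). Its null distribution is estimated
#' by Monte-Carlo: background-generated sequence sets of the same lengths
#' are scored with the *fixed* trained model, a normal tail is fitted, and
#' the tail probability is multiplied by the number of candidate
#' (position, strand) start configurations to give an E-value-like quantity.
#'
#' @param model A `motif_model`.
#' @param seqs The sequences the model was trained on.
#' @param n_shuffle Number of Monte-Carlo null datasets (default 1000 for
#'   the fixed null; a few dozen suffice for the refit null).
#' @param seed Integer seed for the null generation.
#' @param null `"fixed"` (default) scores each null dataset with the trained
#'   model; it is fast and separates a real motif from nothing, but is
#'   anti-conservative for a model trained on pure background, because the
#'   observed statistic is maximized by training while the null draws are
#'   not. `"refit"` reruns the same discovery on every null dataset, which
#'   calibrates the null at a much higher cost.
#' @return List: `llr`, `evalue_approx`, `pvalue_tail`, `n_configs`,
#'   `null_mean`, `null_sd`.
#' @export
motif_significance <- function(model, seqs, n_shuffle = 1000L, seed = 1L,
                               null = c("fixed", "refit")) {
  stopifnot(inherits(model, "motif_model"))
  null <- match.arg(null)
  seqs <- .as_region_seqs(seqs)
  w <- model$w
  encs <- lapply(seqs, .encode_dna)
  lens <- vapply(encs, length, integer(1))
  n_configs <- sum((lens - w + 1L) * if (isTRUE(model$both_strands)) 2L else 1L)
  obs <- .llr_stat(model, encs, w)
  bg <- model$pwm$background
  set.seed(abs(seed) %% 2147483647L + 1L)
  null_llr <- vapply(seq_len(n_shuffle), function(b) {
    sim <- lapply(lens, function(L)
      sample.int(4L, L, replace = TRUE, prob = bg) - 1L)
    if (null == "fixed") return(.llr_stat(model, sim, w))
    simseq <- vapply(sim, function(e) paste(.DNA[e + 1L], collapse = ""),
                     character(1))
    names(simseq) <- sprintf("null_%03d", seq_along(simseq))
    refit <- discover_motif(simseq, w = w, restarts = model$restarts,
                            seed = model$seed + b,
                            both_strands = model$both_strands,
                            palindrome_constraint = model$palindrome_constraint,
                            alpha = model$pwm$alpha, background = bg,
                            max_iter = 100L)
    .llr_stat(refit, lapply(simseq, .encode_dna), w)
  }, numeric(1))
  mu <- mean(null_llr)
  sdv <- max(sd(null_llr), 1e-12)
  p <- pnorm(obs, mu, sdv, lower.tail = FALSE)
  list(llr = obs, evalue_approx = n_configs * p, pvalue_tail = p,
       n_configs = n_configs, null_mean = mu, null_sd = sdv)
}
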