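# PWM construction, consensus rules, ZOOPS EM discovery, significance

test_that("build_pwm smoothing arithmetic", {
  p <- build_pwm("ACGT", alpha = 0.25)
  expect_equal(unname(p$freq["A", 1]), 0.625)
  expect_equal(unname(p$freq[c("C", "G", "T"), 1]), rep(0.125, 3))
  expect_equal(colSums(p$freq), rep(1, 4), ignore_attr = TRUE)
  # 10 identical sites, no pseudocount: one-hot columns
  p0 <- build_pwm(rep("ACGT", 10), alpha = 0)
  expect_equal(unname(diag(p0$freq[c("A", "C", "G", "T"), ])), rep(1, 4))
  expect_error(build_pwm(c("ACGT", "ACG")), "same length")
  # background-weighted pseudocount
  pb <- build_pwm("AAAA", alpha = 0.25, background = bg_gc(0.69))
  expect_equal(unname(pb$freq["C", 1]), 0.25 * 4 * 0.345 / 2)
})

test_that("consensus_from_pwm follows the qualifying-set rule", {
  one <- new_pwm(matrix(c(1, 0, 0, 0), 4), rep(0.25, 4))
  expect_equal(as.character(consensus_from_pwm(one)), "A")
  unif <- new_pwm(matrix(0.25, 4, 1), rep(0.25, 4))
  expect_equal(as.character(consensus_from_pwm(unif)), "N")
  ag <- new_pwm(matrix(c(0.5, 0, 0.5, 0), 4), rep(0.25, 4))
  expect_equal(as.character(consensus_from_pwm(ag)), "R")
  # qualifying set too light: falls back to N
  skew <- new_pwm(matrix(c(0.6, 0.2, 0.1, 0.1), 4), rep(0.25, 4))
  expect_equal(as.character(consensus_from_pwm(skew)), "N")
})

test_that("logodds identity, closed form, and monotonicity", {
  flat <- new_pwm(matrix(bg_gc(0.6), 4, 5), bg_gc(0.6))
  expect_equal(logodds(flat), matrix(0, 4, 5), ignore_attr = TRUE)
  # one-hot columns in the alpha -> 0 limit: log2(4 * f) = 2 at the hot base
  one <- build_pwm(rep("AAAA", 4), alpha = 1e-9)
  expect_equal(unname(logodds(one)["A", ]), rep(2, 4), tolerance = 1e-6)
  expect_error(logodds(build_pwm(rep("AAAA", 4), alpha = 0)), "positive")
  p1 <- new_pwm(matrix(c(0.4, 0.2, 0.2, 0.2), 4), rep(0.25, 4))
  p2 <- new_pwm(matrix(c(0.7, 0.1, 0.1, 0.1), 4), rep(0.25, 4))
  expect_gt(logodds(p2)["A", 1], logodds(p1)["A", 1])
})

planted_dataset <- function(seed, n = 24, n_sites = 18, L = 310) {
  onehot <- build_pwm(MBS_WORD22, alpha = 0)
  set.seed(seed + 5000)
  regs <- rand_bg_regions(n, L)
  plant_sites(regs, onehot, occupancy = n_sites / n, seed = seed,
              n_sites = n_sites)
}

test_that("discover_motif is deterministic and order-invariant", {
  pl <- planted_dataset(1)
  m1 <- discover_motif(pl$regions, w = 22, restarts = 3, seed = 7)
  m2 <- discover_motif(pl$regions, w = 22, restarts = 3, seed = 7)
  expect_identical(m1$pwm$freq, m2$pwm$freq)
  expect_identical(m1$ll, m2$ll)
  perm <- sample(length(pl$regions))
  m3 <- discover_motif(pl$regions[perm], w = 22, restarts = 3, seed = 7)
  expect_equal(m3$pwm$freq, m1$pwm$freq, tolerance = 1e-12)
  expect_equal(m3$ll, m1$ll, tolerance = 1e-12)
})

test_that("EM log-likelihood is non-decreasing along the winning trace", {
  pl <- planted_dataset(2)
  m <- discover_motif(pl$regions, w = 22, restarts = 2, seed = 3)
  d <- diff(m$ll_trace)
  expect_true(all(d > -1e-6 * pmax(abs(m$ll_trace[-1]), 1)))
})

test_that("discover_motif recovers a planted motif and its occupancy", {
  for (s in 1:2) {
    pl <- planted_dataset(s)
    m <- discover_motif(pl$regions, w = 22, restarts = 5, seed = s)
    expect_equal(unname(m$occupancy), c(18L, 24L))
    expect_lte(edit_rc_min(m$consensus, MBS_WORD22), 1)
  }
})

test_that("discover_motif names offending short sequences", {
  expect_error(discover_motif(c(ok = rand_bg_seq(50), bad = "ACGT"), w = 10),
               "bad")
})

test_that("palindrome constraint yields a revcomp-invariant consensus", {
  pl <- planted_dataset(3)
  m <- discover_motif(pl$regions, w = 22, restarts = 3, seed = 2,
                      palindrome_constraint = TRUE)
  cons <- as.character(m$consensus)
  expect_equal(revcomp(cons), cons)
})

test_that("llr of a one-hot model on its exact sites matches the closed form", {
  # word long enough that the planted window's posterior is ~1
  word <- "ACGTACGTAC"
  onehot <- build_pwm(word, alpha = 0)
  n <- 6
  set.seed(31)
  regs <- rand_bg_regions(n, 40, bg_gc(0.5))
  pl <- plant_sites(regs, onehot, occupancy = 1, seed = 1, n_sites = n,
                    strand_law = 0)  # the model scans one strand only
  model <- structure(list(pwm = new_pwm(onehot$freq, bg_gc(0.5)), q = 0.5,
                          both_strands = FALSE, w = nchar(word)),
                     class = "motif_model")
  sig <- motif_significance(model, pl$regions, n_shuffle = 10, seed = 1)
  bgv <- bg_gc(0.5)[strsplit(word, "")[[1]]]
  closed <- n * sum(log(1 / bgv))
  expect_lt(abs(sig$llr - closed) / closed, 1e-3)
})

test_that("a planted motif is significant under the fixed MC null", {
  pl <- planted_dataset(4)
  m <- discover_motif(pl$regions, w = 22, restarts = 3, seed = 4)
  sig <- motif_significance(m, pl$regions, n_shuffle = 300, seed = 4)
  expect_lt(sig$evalue_approx, 1e-6)
})

test_that("a background-trained motif is insignificant under the refit null", {
  # scaled down for runtime: 3 seeds x 9 refit shuffles (see methods vignette)
  for (s in 1:3) {
    set.seed(6000 + s)
    regs <- rand_bg_regions(24, 310)
    m0 <- discover_motif(regs, w = 22, restarts = 2, seed = s, max_iter = 60)
    sig <- motif_significance(m0, regs, n_shuffle = 9, seed = s,
                              null = "refit")
    expect_gte(sig$evalue_approx, 0.1)
  }
})

test_that("MEME minimal format round trip", {
  pwm <- pwm_from_consensus("TATCAAGA", dom = 0.85, background = bg_gc(0.69))
  tmp <- tempfile(fileext = ".meme")
  write_meme(pwm, tmp, name = "site", nsites = 18, evalue = 1.1e-48)
  back <- read_meme(tmp)
  expect_equal(back$freq, pwm$freq, tolerance = 1e-4)
  expect_equal(back$background, pwm$background, tolerance = 1e-5)
  expect_equal(attr(back, "nsites"), 18)
  expect_equal(attr(back, "evalue"), 1.1e-48)
})
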