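# Exact p-value score distributions and PWM scanning

test_that("score_distribution matches exhaustive enumeration for all w<=8 fixtures", {
  for (nm in names(fixture_pwms())) {
    pwm <- fixture_pwms()[[nm]]
    dist <- score_distribution(pwm, eps = 1e-3)
    oracle <- oracle_tail_fun(pwm, eps = 1e-3)
    ks <- seq(dist$kmin, dist$kmax, length.out = 50)
    ks <- unique(round(ks))
    expect_equal(.subset2(dist, "tail")[ks - dist$kmin + 1], oracle(ks),
                 tolerance = 1e-12, info = nm)
  }
})

test_that("distribution boundary identities", {
  pwm <- fixture_pwms()$gc_w8
  dist <- score_distribution(pwm)
  expect_equal(pvalue(dist, dist$kmin * dist$eps), 1)
  expect_equal(dist$tail[1], 1)
  # unique argmax word: tail at the max equals its background probability
  amax <- apply(pwm$freq, 2, which.max)
  expect_equal(pvalue(dist, dist$kmax * dist$eps),
               prod(pwm$background[amax]), tolerance = 1e-12)
  # tail is non-increasing
  expect_true(all(diff(dist$tail) <= 1e-15))
})

test_that("pvalue and score_for_pvalue are mutually consistent", {
  pwm <- fixture_pwms()$cons_w5
  dist <- score_distribution(pwm)
  expect_equal(score_for_pvalue(dist, 1), dist$kmin * dist$eps)
  oracle <- oracle_tail_fun(pwm)
  set.seed(51)
  for (p in c(10^runif(40, -6, 0), 1)) {
    s <- score_for_pvalue(dist, p)
    expect_lte(pvalue(dist, s), p)
    # conservative lookup: matches enumeration at the floor bin
    expect_equal(pvalue(dist, s), oracle(floor(s / dist$eps + 1e-9)),
                 tolerance = 1e-12)
  }
  expect_error(score_for_pvalue(dist, 0), "p must be")
  expect_error(score_for_pvalue(dist, 1.2), "p must be")
})

test_that("scan_region finds a planted max-score word with its exact p-value", {
  pwm <- fixture_pwms()$gc_w8
  amax <- apply(pwm$freq, 2, which.max)
  word <- paste(c("A", "C", "G", "T")[amax], collapse = "")
  set.seed(52)
  region <- rand_bg_seq(310, bg_gc(0.69))
  substr(region, 121, 128) <- word
  dist <- score_distribution(pwm)
  hits <- scan_region(pwm, c(r1 = region), p_cut = 1e-4, dist = dist)
  top <- hits[hits$offset == 120 & hits$strand == "+", ]
  expect_equal(nrow(top), 1L)
  expect_equal(top$word, word)
  expect_equal(top$pvalue, prod(pwm$background[amax]), tolerance = 1e-12)
  expect_lte(top$pvalue, 1e-4)
})

test_that("a palindromic PWM produces strand-paired hits", {
  pwm <- pwm_from_consensus("TGTCA", dom = 0.8, background = bg_gc(0.5))
  pal <- new_pwm((cbind(pwm$freq, 0.25) +
                  cbind(pwm$freq, 0.25)[4:1, 6:1]) / 2, bg_gc(0.5))
  set.seed(53)
  regs <- rand_bg_regions(30, 120, bg_gc(0.5))
  hits <- scan_region(pal, regs, p_cut = 1e-2)
  expect_gt(nrow(hits), 0)
  agg <- aggregate_hits(hits)
  expect_true(all(agg$sites$palindromic_pair))
})

test_that("scanning a region and its reverse complement is equivalent", {
  pwm <- fixture_pwms()$gc_w8
  set.seed(54)
  s <- rand_bg_seq(200, bg_gc(0.69))
  hits <- scan_region(pwm, c(r = s), p_cut = 5e-3)
  hits_rc <- scan_region(pwm, c(r = revcomp(s)), p_cut = 5e-3)
  L <- nchar(s); w <- pwm$width
  mapped <- data.frame(offset = L - w - hits_rc$offset,
                       strand = ifelse(hits_rc$strand == "+", "-", "+"),
                       score = hits_rc$score, word = hits_rc$word)
  o1 <- hits[order(hits$offset, hits$strand),
             c("offset", "strand", "score", "word")]
  o2 <- mapped[order(mapped$offset, mapped$strand), ]
  expect_equal(o1, o2, ignore_attr = TRUE)
})

test_that("decreasing p_cut never adds hits; short regions warn", {
  pwm <- fixture_pwms()$cons_w5
  set.seed(55)
  regs <- rand_bg_regions(20, 80, bg_gc(0.5))
  loose <- scan_region(pwm, regs, p_cut = 1e-2)
  strict <- scan_region(pwm, regs, p_cut = 1e-3)
  expect_lte(nrow(strict), nrow(loose))
  key <- function(h) paste(h$region_id, h$offset, h$strand)
  expect_true(all(key(strict) %in% key(loose)))
  expect_warning(out <- scan_region(pwm, c(tiny = "ACG")), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("windows containing N are skipped, not mis-scored", {
  pwm <- fixture_pwms()$cons_w5
  hits <- scan_region(pwm, c(r = "TGTCANTGTCA"), p_cut = 1)
  expect_false(any(grepl("N", hits$word)))
  expect_true(all(c(0, 6) %in% hits$offset))
})

test_that("aggregate_hits collapses strand pairs and ranks regions", {
  hits <- data.frame(
    region_id = c("rA", "rA", "rA", "rB"),
    offset = c(120L, 120L, 10L, 33L),
    strand = c("+", "-", "+", "-"),
    score = c(10, 10, 8, 9),
    pvalue = c(1e-6, 1e-6, 1e-4, 1e-5),
    word = c("AAAA", "TTTT", "CCCC", "GGGG"),
    stringsAsFactors = FALSE)
  agg <- aggregate_hits(hits)
  expect_equal(nrow(agg$sites), 3L)
  pal <- agg$sites[agg$sites$offset == 120, ]
  expect_true(pal$palindromic_pair)
  expect_equal(pal$strands, "+-")
  expect_equal(agg$regions$region_id, c("rA", "rB"))
  expect_equal(agg$regions$n_hits, c(3L, 1L))
  expect_equal(agg$regions$n_sites, c(2L, 1L))
  empty <- aggregate_hits(hits[0, ])
  expect_equal(nrow(empty$sites), 0L)
})

test_that("the null scan hit count matches its exact binomial model", {
  pwm <- fixture_pwms()$gc_w8
  dist <- score_distribution(pwm)
  p_bar <- pvalue(dist, score_for_pvalue(dist, 1e-4))
  set.seed(56)
  regs <- rand_bg_regions(100, 310, bg_gc(0.69))
  hits <- scan_region(pwm, regs, p_cut = 1e-4, dist = dist)
  n_windows <- 100 * 2 * (310 - 8 + 1)
  interval <- qbinom(c(0.005, 0.995), n_windows, p_bar)
  expect_gte(nrow(hits), interval[1])
  expect_lte(nrow(hits), interval[2])
})
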