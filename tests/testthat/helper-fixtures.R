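# Shared fixtures, all built in code.

# complement-symmetric background at a given GC content; 0.69 mimics a
# high-GC alphaproteobacterial genome
bg_gc <- function(gc = 0.69) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

rand_bg_seq <- function(L, bg = bg_gc()) {
  paste(sample(names(bg), L, replace = TRUE, prob = bg), collapse = "")
}

rand_bg_regions <- function(n, L, bg = bg_gc()) {
  setNames(vapply(seq_len(n), function(i) rand_bg_seq(L, bg), character(1)),
           sprintf("r%03d", seq_len(n)))
}

# PWM with one dominant base per column
pwm_from_consensus <- function(word, dom = 0.85, background = rep(0.25, 4)) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  f <- vapply(ch, function(b) {
    v <- setNames(rep((1 - dom) / 3, 4), c("A", "C", "G", "T"))
    v[b] <- dom
    v
  }, numeric(4))
  new_pwm(f, background)
}

# the degenerate 22-bp binding-site consensus and one exact concretization
# (one allowed base picked per degenerate symbol)
GTAR_CONSENSUS <- "RACMTGTCYWWWWRGACAKGTY"
MBS_WORD22 <- "AACATGTCCAATTAGACAGGTC"
BS1 <- "TATCCAAAAAGACAG"

# the seven LuxR/LuxI-homolog domain-score rows (HMM bit scores; NA = domain
# not detected)
table2_scores <- function() {
  data.frame(
    protein_id = c("cerR", "RS15160", "gtaR", "cerM", "g15394", "cerN",
                   "cerI"),
    score_autoind_bind = c(128.1, 77.1, 51.6, 47.5, 38.7, 66.1, NA),
    score_gere_hth = c(63.4, 68.2, 24.6, 42.9, 37.7, NA, NA),
    score_autoind_synth = c(NA, NA, NA, NA, NA, NA, 281.5),
    stringsAsFactors = FALSE)
}

rand_protein <- function(L) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], L, replace = TRUE),
        collapse = "")
}

# mutate a protein at k positions (never to the same residue)
mutate_protein <- function(p, k) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ch <- strsplit(p, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), k)
  for (i in pos) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste(ch, collapse = "")
}

# the fixture PWM set for enumeration-oracle equivalence (all widths <= 8)
fixture_pwms <- function() {
  list(
    toy_w2 = build_pwm(c("AC", "AG", "AT", "CC"), alpha = 0.25),
    cons_w5 = pwm_from_consensus("TGTCA", dom = 0.8, background = bg_gc(0.5)),
    gc_w8 = pwm_from_consensus("TATCAAGA", dom = 0.85, background = bg_gc(0.69)),
    flat_w4 = new_pwm(matrix(0.25, 4, 4), bg_gc(0.6))
  )
}
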