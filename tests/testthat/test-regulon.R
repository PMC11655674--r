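# DE filtering, regulon subtraction, operon collapsing, promoter windows,
# and the domain classifier

test_that("filter_de applies inclusive thresholds and skips NA padj", {
  de <- data.frame(
    gene_id = c("up", "down_weak", "boundary", "na", "insig"),
    log2fc = c(2.8, -1.58, 2.0, 5, 3),
    padj = c(0.001, 0.001, 0.01, NA, 0.2))
  expect_warning(kept <- filter_de(de), "skipped")
  expect_equal(kept, c("up", "boundary"))
  # both tails
  de2 <- data.frame(gene_id = c("a", "b"), log2fc = c(-2.0, -5),
                    padj = c(0.01, 1e-9))
  expect_equal(filter_de(de2), c("a", "b"))
})

test_that("subtract_regulon removes exactly the intersection, keeps order", {
  x <- c("g3", "g1", "g2", "g4")
  out <- subtract_regulon(x, c("g2", "g9"))
  expect_equal(as.character(out), c("g3", "g1", "g4"))
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(as.character(subtract_regulon(x, character(0))), x)
  out2 <- subtract_regulon(x, c("zz"))
  expect_equal(attr(out2, "n_removed"), 0L)
})

gene_df <- function(starts, ends, strands, contig = "c1") {
  data.frame(gene_id = sprintf("g%d", seq_along(starts)), contig = contig,
             start = starts, end = ends, strand = strands,
             stringsAsFactors = FALSE)
}

test_that("call_operons chains by strict gap < max_gap on one strand", {
  # gap 30 < 50: one operon, leader is the 5'-most gene
  ops <- call_operons(gene_df(c(100, 430), c(400, 700), c("+", "+")))
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$leader_gene, "g1")
  # gap exactly 50: two operons ("closer than 50" is strict)
  expect_equal(nrow(call_operons(gene_df(c(100, 450), c(400, 700),
                                         c("+", "+")))), 2L)
  # opposite strands never chain
  expect_equal(nrow(call_operons(gene_df(c(100, 410), c(400, 700),
                                         c("+", "-")))), 2L)
  # minus-strand leader is the last gene in genomic order
  ops <- call_operons(gene_df(c(100, 430), c(400, 700), c("-", "-")))
  expect_equal(ops$leader_gene, "g2")
  # overlap: chained and flagged
  ops <- call_operons(gene_df(c(100, 350), c(400, 700), c("+", "+")))
  expect_equal(nrow(ops), 1L)
  expect_true(ops$has_overlap)
})

test_that("call_operons output partitions the input; gap monotonicity", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    starts <- cumsum(sample(50:1000, n, replace = TRUE))
    lens <- sample(100:900, n, replace = TRUE)
    g <- gene_df(starts, starts + lens,
                 sample(c("+", "-"), n, replace = TRUE),
                 contig = sample(c("c1", "c2"), n, replace = TRUE))
    g <- g[sample(n), ]  # unsorted input
    ops <- call_operons(g, max_gap = 200)
    members <- unlist(ops$gene_ids)
    expect_setequal(members, g$gene_id)
    expect_equal(length(members), n)
    for (k in seq_len(nrow(ops))) {
      idx <- match(ops$gene_ids[[k]], g$gene_id)
      expect_length(unique(g$contig[idx]), 1L)
      expect_length(unique(g$strand[idx]), 1L)
    }
    # raising max_gap never increases the number of operons
    expect_lte(nrow(ops), nrow(call_operons(g, max_gap = 50)))
    # max_gap 0: one operon per gene
    expect_equal(nrow(call_operons(g, max_gap = 0)), n)
  }
})

test_that("extract_promoters windows and strand conventions", {
  set.seed(9)
  genome <- c(c1 = rand_bg_seq(5000, bg_gc(0.5)))
  genes <- gene_df(c(1000, 2000), c(1900, 2900), c("+", "-"))
  ops <- call_operons(genes)
  pr <- extract_promoters(genome, ops, genes)
  plus <- pr[pr$strand == "+", ]
  expect_equal(c(plus$start, plus$end), c(700, 1010))
  expect_equal(nchar(plus$seq), 310L)
  expect_equal(plus$seq, unname(substr(genome, 701, 1010)))
  # minus leader, end = 2900: forward window [2890, 3200), revcomp'd
  minus <- pr[pr$strand == "-", ]
  expect_equal(c(minus$start, minus$end), c(2890, 3200))
  expect_equal(minus$seq, unname(revcomp(substr(genome, 2891, 3200))))
  expect_false(any(pr$clipped))
})

test_that("a minus-strand promoter recovers a planted marker", {
  # marker placed 50 bp upstream of the start codon on the minus strand:
  # on the forward strand that is revcomp(marker) at [end + 50 - 10, ...)
  set.seed(10)
  marker <- "AAACCCGGGTTTAAA"
  genome_chars <- strsplit(rand_bg_seq(2000, bg_gc(0.5)), "")[[1]]
  gene_end <- 1000L
  fwd_start <- gene_end + 50L
  genome_chars[(fwd_start + 1):(fwd_start + nchar(marker))] <-
    strsplit(revcomp(marker), "")[[1]]
  genome <- c(c1 = paste(genome_chars, collapse = ""))
  genes <- gene_df(500, gene_end, "-")
  pr <- extract_promoters(genome, call_operons(genes), genes)
  # promoter reads 5'->3' toward the start codon; the last `down` = 10 bases
  # overlap the coding start, so the marker ends 50 bp before that
  off <- 310 - 10 - 50 - nchar(marker)
  expect_equal(substr(pr$seq, off + 1, off + nchar(marker)), marker)
})

test_that("extract_promoters clips at contig edges and errors usefully", {
  set.seed(11)
  genome <- c(c1 = rand_bg_seq(600, bg_gc(0.5)))
  genes <- gene_df(100, 500, "+")
  pr <- extract_promoters(genome, call_operons(genes), genes)
  expect_true(pr$clipped)
  expect_equal(c(pr$start, pr$end), c(0, 110))
  expect_equal(nchar(pr$seq), 110L)
  ops <- data.frame(operon_id = "opX", leader_gene = "missing")
  expect_error(extract_promoters(genome, ops, genes), "opX")
  # circular mode wraps instead of clipping
  prc <- extract_promoters(genome, call_operons(genes), genes,
                           circular = TRUE)
  expect_false(prc$clipped)
  expect_equal(nchar(prc$seq), 310L)
  wrapped <- paste0(substr(genome, 600 - 200 + 1, 600),
                    substr(genome, 1, 110))
  expect_equal(prc$seq, unname(wrapped))
})

test_that("classify_domains reproduces the seven-homolog table", {
  lab <- classify_domains(table2_scores())
  expect_equal(lab$label[lab$protein_id == "cerR"], "LuxR_full")
  expect_equal(lab$label[lab$protein_id == "cerN"], "LuxR_truncated")
  expect_equal(lab$label[lab$protein_id == "cerI"], "LuxI")
  expect_equal(sum(lab$label %in% c("LuxR_full", "LuxR_truncated")), 6L)
  expect_equal(sum(lab$label == "LuxR_full"), 5L)
  expect_false(any(lab$conflict))
  # below the Autoind_bind cutoff: unclassified even with an HTH score
  row <- data.frame(protein_id = "x", score_autoind_bind = 34.9,
                    score_gere_hth = 25, score_autoind_synth = NA)
  expect_equal(classify_domains(row)$label, "unclassified")
  # a protein passing both family rules keeps LuxR and is flagged
  both <- data.frame(protein_id = "y", score_autoind_bind = 40,
                     score_gere_hth = 30, score_autoind_synth = 60)
  out <- classify_domains(both)
  expect_equal(out$label, "LuxR_full")
  expect_true(out$conflict)
})

test_that("gene tables round-trip through TSV and GFF3", {
  g <- gene_df(c(10, 500), c(400, 900), c("+", "-"))
  tmp <- tempfile(fileext = ".tsv")
  write.table(g, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_gene_table(tmp)[names(g)], g)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t11\t400\t.\t+\t.\tID=g1",
    "c1\tsrc\tgene\t501\t900\t.\t-\t.\tID=g2;locus_tag=lt2"), gff)
  gg <- read_gff_genes(gff)
  expect_equal(gg$gene_id, c("g1", "g2"))
  expect_equal(gg$start, c(10, 500))  # 1-based inclusive -> 0-based half-open
  expect_equal(gg$end, c(400, 900))
})
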