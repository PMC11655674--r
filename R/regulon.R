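# Gene-set construction: differential-expression thresholding, prior-regulon
# subtraction, operon collapsing, promoter-window extraction, and the
# HMM-domain-score classifier for LuxR/LuxI homologs.

#' Threshold a differential-expression table
#'
#' Keeps genes with |log2 fold change| >= `lfc_min` AND adjusted p-value
#' <= `padj_max`, both boundaries inclusive. Records with a missing adjusted
#' p-value are skipped with a warning.
#'
#' @param de `data.frame` with columns `gene_id`, `log2fc`, `padj`.
#' @param lfc_min Minimum absolute log2 fold change (default 2).
#' @param padj_max Maximum adjusted p-value (default 0.01).
#' @return Character vector of gene ids, in input order.
#' @export
filter_de <- function(de, lfc_min = 2, padj_max = 0.01) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(de)))
  if (anyDuplicated(de$gene_id))
    stop("duplicate gene_id in DE table")
  bad <- is.na(de$padj) | !is.finite(de$log2fc)
  if (any(bad)) {
    warning(sum(bad), " DE record(s) with missing padj or non-finite log2fc skipped")
    de <- de[!bad, , drop = FALSE]
  }
  keep <- abs(de$log2fc) >= lfc_min & de$padj <= padj_max
  de$gene_id[keep]
}

#' Remove a prior regulon from a gene list
#'
#' Drops every gene that is a member of `regulon`, preserving input order.
#' The number of removed genes is attached as attribute `n_removed`.
#'
#' @param de_genes Character vector of gene ids.
#' @param regulon Character vector (set) of regulon gene ids.
#' @return Filtered character vector with attribute `n_removed`.
#' @export
subtract_regulon <- function(de_genes, regulon) {
  hit <- de_genes %in% regulon
  structure(de_genes[!hit], n_removed = sum(hit))
}

#' Collapse genes into operons by an intergenic-distance rule
#'
#' Consecutive genes on the same contig and strand whose intergenic gap
#' (next start minus previous end, 0-based half-open) is strictly smaller
#' than `max_gap` are chained transitively into one transcriptional unit.
#' Overlapping genes (negative gap) are treated as gap 0, chained, and
#' flagged in the `has_overlap` column. The output partitions the input.
#'
#' @param genes `data.frame` with columns `gene_id`, `contig`, `start`,
#'   `end` (0-based half-open), `strand` (+/-). May be unsorted.
#' @param max_gap Strict upper bound on the chaining gap in bp (default 50).
#' @return `data.frame` with one row per operon: `operon_id`, `contig`,
#'   `strand`, `start`, `end`, `n_genes`, `leader_gene` (5'-most gene in
#'   transcription order), `has_overlap`, and list-column `gene_ids`
#'   (ordered by genomic position).
#' @export
call_operons <- function(genes, max_gap = 50L) {
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in% names(genes)))
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$start >= genes$end)) stop("need start < end for every gene")
  g <- genes[order(genes$contig, genes$start, genes$end), , drop = FALSE]
  n <- nrow(g)
  if (n == 0L) stop("no genes")
  gap <- c(NA_real_, g$start[-1] - g$end[-n])
  same <- c(FALSE, g$contig[-1] == g$contig[-n] & g$strand[-1] == g$strand[-n])
  overlap <- same & !is.na(gap) & gap < 0
  gap_eff <- pmax(gap, 0)
  new_block <- !(same & gap_eff < max_gap)
  new_block[1] <- TRUE
  block <- cumsum(new_block)
  idx <- split(seq_len(n), block)
  res <- lapply(seq_along(idx), function(k) {
    i <- idx[[k]]
    strand <- g$strand[i[1]]
    leader <- if (strand == "+") g$gene_id[i[1]] else g$gene_id[i[length(i)]]
    data.frame(operon_id = sprintf("opn_%04d", k),
               contig = g$contig[i[1]], strand = strand,
               start = min(g$start[i]), end = max(g$end[i]),
               n_genes = length(i), leader_gene = leader,
               has_overlap = any(overlap[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$gene_ids <- I(lapply(idx, function(i) g$gene_id[i]))
  out
}

#' Extract promoter windows around translational starts
#'
#' For each operon the promoter of its leader (5'-most) gene is taken:
#' `up` bp upstream plus `down` bp downstream of the start codon. For a
#' plus-strand leader with start s this is the forward-strand window
#' \[s-up, s+down); for a minus-strand leader with end e it is
#' \[e-down, e+up) reverse-complemented, so the returned sequence always
#' reads 5'->3' toward the start codon. Windows clipped at a contig edge are
#' flagged; with `circular = TRUE` they wrap around instead.
#'
#' @param genome Named character vector of contig sequences.
#' @param operons Output of [call_operons()] (or any `data.frame` with
#'   `operon_id` and `leader_gene`).
#' @param genes Gene table as in [call_operons()].
#' @param up,down Window extents in bp (defaults 300 and 10).
#' @param circular Wrap windows around contig edges (default FALSE).
#' @return `data.frame`: `region_id`, `source_operon`, `contig`, `start`,
#'   `end` (forward 0-based half-open), `strand`, `clipped`, `seq`.
#' @export
extract_promoters <- function(genome, operons, genes, up = 300L, down = 10L,
                              circular = FALSE) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  rows <- lapply(seq_len(nrow(operons)), function(k) {
    op <- operons[k, ]
    gi <- match(op$leader_gene, genes$gene_id)
    if (is.na(gi))
      stop(sprintf("leader gene '%s' of operon '%s' absent from annotation",
                   op$leader_gene, op$operon_id))
    ge <- genes[gi, ]
    if (!ge$contig %in% names(genome))
      stop(sprintf("contig '%s' absent from genome", ge$contig))
    clen <- nchar(genome[[ge$contig]])
    if (ge$strand == "+") {
      a <- ge$start - up; b <- ge$start + down
    } else {
      a <- ge$end - down; b <- ge$end + up
    }
    clipped <- FALSE
    if (circular) {
      pos <- ((a:(b - 1)) %% clen) + 1L
      s <- paste(strsplit(genome[[ge$contig]], "")[[1]][pos], collapse = "")
      a0 <- a %% clen; b0 <- a0 + (b - a)
    } else {
      a0 <- max(a, 0L); b0 <- min(b, clen)
      clipped <- (a0 != a) || (b0 != b)
      if (b0 <= a0)
        stop(sprintf("promoter window of operon '%s' falls entirely off contig",
                     op$operon_id))
      s <- substr(genome[[ge$contig]], a0 + 1L, b0)
      a <- a0; b <- b0
    }
    if (ge$strand == "-") s <- revcomp(s)
    data.frame(region_id = paste0("prom_", op$operon_id),
               source_operon = op$operon_id, contig = ge$contig,
               start = if (circular) a0 else a, end = if (circular) b0 else b,
               strand = ge$strand, clipped = clipped, seq = s,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify proteins by quorum-sensing domain scores
#'
#' Applies fixed score cutoffs to HMM domain scores for the
#' autoinducer-binding (Autoind_bind), GerE-type helix-turn-helix (HTH) and
#' autoinducer-synthase (Autoind_synth) domains. A protein with
#' Autoind_bind >= `cut_bind` is a LuxR regulator: `LuxR_full` if it also has
#' HTH >= `cut_hth`, `LuxR_truncated` otherwise. Autoind_synth >= `cut_synth`
#' defines `LuxI`. A protein qualifying for both families keeps the LuxR
#' label and is flagged in `conflict`.
#'
#' @param scores `data.frame` with `protein_id`, `score_autoind_bind`,
#'   `score_gere_hth`, `score_autoind_synth` (NA = domain absent).
#' @param cut_bind,cut_hth,cut_synth Score cutoffs (defaults 35, 20, 50).
#' @return Input with columns `label` and `conflict` added.
#' @export
classify_domains <- function(scores, cut_bind = 35, cut_hth = 20,
                             cut_synth = 50) {
  need <- c("protein_id", "score_autoind_bind", "score_gere_hth",
            "score_autoind_synth")
  stopifnot(all(need %in% names(scores)))
  ge <- function(x, cut) !is.na(x) & x >= cut
  is_luxr <- ge(scores$score_autoind_bind, cut_bind)
  has_hth <- ge(scores$score_gere_hth, cut_hth)
  is_luxi <- ge(scores$score_autoind_synth, cut_synth)
  label <- rep("unclassified", nrow(scores))
  label[is_luxi] <- "LuxI"
  label[is_luxr & !has_hth] <- "LuxR_truncated"
  label[is_luxr & has_hth] <- "LuxR_full"
  scores$label <- label
  scores$conflict <- is_luxr & is_luxi
  scores
}

#' Read a tabular gene annotation
#'
#' Expects a TSV with header `gene_id`, `contig`, `start`, `end`, `strand`;
#' coordinates are 0-based half-open.
#'
#' @param path Path to the TSV.
#' @return Gene `data.frame`.
#' @export
read_gene_table <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "start", "end", "strand")
  if (!all(need %in% names(g)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  g$start <- as.integer(g$start); g$end <- as.integer(g$end)
  g
}

#' Read gene records from a GFF3 file
#'
#' Imports features of the requested type via rtracklayer and converts from
#' 1-based inclusive to 0-based half-open coordinates. The gene id is taken
#' from the first available attribute among `id_attr`.
#'
#' @param path GFF3 path.
#' @param feature_type Feature type(s) to keep (default `"gene"`).
#' @param id_attr Attribute(s) used as gene id, in order of preference.
#' @return Gene `data.frame` as used by [call_operons()].
#' @export
read_gff_genes <- function(path, feature_type = "gene",
                           id_attr = c("ID", "locus_tag")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gff_genes requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (length(gr) == 0L) stop("no '", feature_type, "' features in ", path)
  md <- as.data.frame(gr)
  ids <- rep(NA_character_, nrow(md))
  for (a in id_attr) {
    if (a %in% names(md)) {
      v <- as.character(md[[a]])
      ids[is.na(ids) & !is.na(v)] <- v[is.na(ids) & !is.na(v)]
    }
  }
  if (anyNA(ids)) stop("GFF3 features without any of: ",
                       paste(id_attr, collapse = ", "))
  data.frame(gene_id = ids, contig = as.character(md$seqnames),
             start = md$start - 1L, end = md$end,
             strand = as.character(md$strand), stringsAsFactors = FALSE)
}

#' Read a DE table (TSV with gene_id, log2fc, padj)
#' @param path Path to the TSV.
#' @return `data.frame`.
#' @export
read_de_table <- function(path) {
  de <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2fc", "padj") %in% names(de)))
    stop("DE table needs columns gene_id, log2fc, padj")
  de
}
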