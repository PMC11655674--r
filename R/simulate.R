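# Seeded synthetic-data generators. Each generator returns (or attaches) a
# ground-truth record sufficient to score recovery without re-reading the
# generator's internals, and is bit-reproducible under a fixed seed.

.draw_law <- function(law, n, what = "law") {
  if (is.function(law)) return(law(n))
  if (is.numeric(law)) {
    if (length(law) == 1L) return(rep(law, n))
    if (length(law) == n) return(law)
    stop(what, ": numeric spec must have length 1 or n")
  }
  stop(what, ": must be a number, a numeric vector, or a function(n)")
}

.rand_dna <- function(n, gc = 0.5) {
  paste(sample(.DNA, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic bacterial genome with gene annotation
#'
#' Genes of fixed length `mean_gene_len` are laid out on one contig with
#' intergenic gaps drawn from `gap_law` and strands from `strand_law`, over
#' an i.i.d. background of the requested GC content, so that the operon
#' structure induced by an intergenic-distance rule is fully controllable.
#'
#' @param n_genes Number of genes (>= 1).
#' @param gap_law Intergenic gaps: a number (fixed), a length `n_genes - 1`
#'   vector, or a `function(n)`.
#' @param strand_law Probability of the + strand, a strand vector, or a
#'   `function(n)` returning strands.
#' @param mean_gene_len Gene length in bp.
#' @param gc GC content of the background.
#' @param seed Integer seed.
#' @param pad Flanking background on both ends (bp).
#' @return List: `genome` (named character vector, one contig), `genes`
#'   (gene `data.frame`), `seed`.
#' @export
gen_genome <- function(n_genes, gap_law = 100, strand_law = 0.5,
                       mean_gene_len = 900L, gc = 0.69, seed = 1L,
                       pad = 200L) {
  stopifnot(n_genes >= 1L)
  set.seed(seed)
  gaps <- if (n_genes > 1L)
    round(.draw_law(gap_law, n_genes - 1L, "gap_law")) else numeric(0)
  if (any(gaps < -mean_gene_len))
    stop("impossible geometry: gap more negative than a gene length")
  strands <- if (is.character(strand_law)) {
    rep(strand_law, length.out = n_genes)
  } else if (is.function(strand_law)) {
    strand_law(n_genes)
  } else {
    ifelse(runif(n_genes) < strand_law, "+", "-")
  }
  starts <- pad + c(0, cumsum(mean_gene_len + gaps))
  ends <- starts + mean_gene_len
  total <- ends[n_genes] + pad
  genome <- setNames(.rand_dna(total, gc), "chr1")
  genes <- data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                      contig = "chr1", start = as.integer(starts),
                      end = as.integer(ends), strand = strands,
                      stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, seed = seed)
}

#' Generate a differential-expression table with a regulon overlap
#'
#' Exactly `n_de` genes pass the |log2FC| >= 2, padj <= 0.01 thresholds by
#' construction (DE log2FC = sign * (2 + Exp(1)), padj uniform below 0.01;
#' non-DE log2FC from Normal(0, 0.5) truncated to (-2, 2)), and exactly
#' `n_regulon_overlap` of them appear in the returned regulon list, which is
#' padded to `regulon_size` with non-DE genes.
#'
#' @param n_genes,n_de,n_regulon_overlap Counts, with
#'   `n_regulon_overlap <= n_de <= n_genes`.
#' @param regulon_size Total regulon size (default 546).
#' @param seed Integer seed.
#' @return List: `de` (DE `data.frame`), `regulon` (character vector),
#'   `truth` (DE ids, regulon overlap ids, seed).
#' @export
gen_de_table <- function(n_genes, n_de, n_regulon_overlap,
                         regulon_size = 546L, seed = 1L) {
  if (!(n_regulon_overlap <= n_de && n_de <= n_genes))
    stop("need n_regulon_overlap <= n_de <= n_genes")
  if (regulon_size < n_regulon_overlap)
    stop("regulon_size < n_regulon_overlap")
  if (regulon_size - n_regulon_overlap > n_genes - n_de)
    stop("not enough non-DE genes to pad the regulon")
  set.seed(seed)
  ids <- sprintf("g%05d", seq_len(n_genes))
  de_idx <- sort(sample.int(n_genes, n_de))
  lfc <- numeric(n_genes)
  padj <- numeric(n_genes)
  lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * (2 + rexp(n_de))
  padj[de_idx] <- runif(n_de, 0, 0.01)
  ndi <- setdiff(seq_len(n_genes), de_idx)
  x <- rnorm(length(ndi), 0, 0.5)
  while (any(bad <- abs(x) >= 2)) x[bad] <- rnorm(sum(bad), 0, 0.5)
  lfc[ndi] <- x
  padj[ndi] <- runif(length(ndi))
  overlap <- sample(de_idx, n_regulon_overlap)
  pad_reg <- sample(ndi, regulon_size - n_regulon_overlap)
  regulon <- ids[sort(c(overlap, pad_reg))]
  list(de = data.frame(gene_id = ids, log2fc = lfc, padj = padj,
                       stringsAsFactors = FALSE),
       regulon = regulon,
       truth = list(de_ids = ids[de_idx], overlap_ids = ids[sort(overlap)],
                    seed = seed))
}

#' Plant PWM-sampled sites into regions
#'
#' Each selected region receives one site sampled from the PWM, written at a
#' uniform valid offset on a strand drawn from `strand_law` (probability of
#' the minus strand). By default regions are selected independently with
#' probability `occupancy`; with `n_sites` set, exactly that many regions
#' (sampled without replacement) receive a site.
#'
#' @param regions Named character vector of sequences, or a promoter
#'   `data.frame`.
#' @param pwm A `pwm` object.
#' @param occupancy Per-region site probability.
#' @param strand_law Probability that a site is planted on the minus strand
#'   (default 0.5).
#' @param seed Integer seed.
#' @param n_sites Optional exact number of regions to receive a site.
#' @return List: `regions` (named character vector with sites written in),
#'   `truth` (`data.frame`: `region_id`, `offset`, `strand`, `word` - the
#'   sampled site 5'->3' on its strand), `seed`.
#' @export
plant_sites <- function(regions, pwm, occupancy, strand_law = 0.5,
                        seed = 1L, n_sites = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  regions <- .as_region_seqs(regions)
  w <- pwm$width
  if (any(nchar(regions) < w)) stop("region shorter than the PWM width")
  set.seed(seed)
  n <- length(regions)
  chosen <- if (is.null(n_sites)) {
    which(runif(n) < occupancy)
  } else {
    stopifnot(n_sites <= n)
    sort(sample.int(n, n_sites))
  }
  truth <- list()
  for (i in chosen) {
    word <- sample_pwm(pwm)
    off <- sample.int(nchar(regions[[i]]) - w + 1L, 1L) - 1L
    strand <- if (runif(1) < strand_law) "-" else "+"
    ins <- if (strand == "-") revcomp(word) else word
    substr(regions[[i]], off + 1L, off + w) <- ins
    truth[[length(truth) + 1L]] <-
      data.frame(region_id = names(regions)[i], offset = off,
                 strand = strand, word = word, stringsAsFactors = FALSE)
  }
  list(regions = regions,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(region_id = character(0), offset = integer(0),
                    strand = character(0), word = character(0)),
       seed = seed)
}

#' Generate a family of diverged ortholog promoters
#'
#' Each species' promoter is the base promoter with i.i.d. substitutions at
#' rate `divergence` outside the conserved intervals (uniform over the three
#' alternative bases); conserved intervals are untouched. Overlapping
#' conserved intervals are merged with a warning.
#'
#' @param base_promoter Character scalar (A/C/G/T).
#' @param n_species Number of family members (default 24).
#' @param divergence Per-site substitution probability outside conserved
#'   intervals.
#' @param conserve List of 0-based half-open `c(start, end)` intervals.
#' @param seed Integer seed.
#' @return List: `promoters` (named character vector `sp01`, ...),
#'   `truth` (`data.frame`: species, mutable sites, substitutions), `seed`.
#' @export
gen_ortholog_family <- function(base_promoter, n_species = 24L,
                                divergence = 0.3, conserve = list(),
                                seed = 1L) {
  base <- toupper(base_promoter)
  L <- nchar(base)
  cons <- logical(L)
  if (length(conserve)) {
    iv <- do.call(rbind, lapply(conserve, function(x) x[1:2]))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      warning("overlapping conserved intervals merged")
    for (k in seq_len(nrow(iv))) {
      if (iv[k, 1] < 0 || iv[k, 2] > L) stop("conserved interval outside promoter")
      cons[(iv[k, 1] + 1L):iv[k, 2]] <- TRUE
    }
  }
  set.seed(seed)
  ch <- strsplit(base, "", fixed = TRUE)[[1]]
  mutable <- which(!cons)
  proms <- character(n_species)
  truth <- data.frame(species = sprintf("sp%02d", seq_len(n_species)),
                      n_mutable = length(mutable),
                      n_substituted = integer(n_species),
                      stringsAsFactors = FALSE)
  for (s in seq_len(n_species)) {
    x <- ch
    hit <- mutable[runif(length(mutable)) < divergence]
    for (i in hit) x[i] <- sample(setdiff(.DNA, x[i]), 1L)
    truth$n_substituted[s] <- length(hit)
    proms[s] <- paste(x, collapse = "")
  }
  list(promoters = setNames(proms, truth$species), truth = truth, seed = seed)
}

#' Build an artificial promoter carrying a binding site between -35 and -10
#'
#' Concatenates, 5' to 3': a random flank, the -35 element, a spacer of
#' `pad5` bp, the binding site, a spacer of `pad3` bp, the -10 element, and
#' a random 3' flank. The defaults place the 15-bp site inside a
#' -35/-10 spacer of 17 + 15 = 32 bp. Element coordinates (0-based
#' half-open) are attached as attribute `elements`.
#'
#' @param bs Binding-site sequence (default the 15-bp site
#'   `TATCCAAAAAGACAG`).
#' @param minus35,minus10 Promoter consensus elements (defaults `TTGACA` and
#'   `TATAAT`).
#' @param pad5,pad3 Spacer lengths around the site (defaults 9 and 8 bp).
#' @param flank5,flank3 Random flank lengths (default 20 bp each).
#' @param gc GC content of spacers and flanks.
#' @param seed Integer seed.
#' @return Character scalar with attribute `elements`.
#' @export
build_artificial_promoter <- function(bs = "TATCCAAAAAGACAG",
                                      minus35 = "TTGACA",
                                      minus10 = "TATAAT",
                                      pad5 = 9L, pad3 = 8L,
                                      flank5 = 20L, flank3 = 20L,
                                      gc = 0.5, seed = 1L) {
  stopifnot(pad5 >= 0L, pad3 >= 0L)
  set.seed(seed)
  parts <- list(flank5 = if (flank5 > 0) .rand_dna(flank5, gc) else "",
                minus35 = toupper(minus35),
                spacer5 = if (pad5 > 0) .rand_dna(pad5, gc) else "",
                bs = toupper(bs),
                spacer3 = if (pad3 > 0) .rand_dna(pad3, gc) else "",
                minus10 = toupper(minus10),
                flank3 = if (flank3 > 0) .rand_dna(flank3, gc) else "")
  lens <- vapply(parts, nchar, integer(1))
  ends <- cumsum(lens)
  elements <- data.frame(element = names(parts),
                         start = ends - lens, end = ends,
                         stringsAsFactors = FALSE)
  structure(paste(unlist(parts), collapse = ""),
            elements = elements[lens > 0, , drop = FALSE])
}
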