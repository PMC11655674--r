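# Protein alignment and reciprocal-best-hit orthology. The aligner is a
# Gotoh affine-gap local aligner (compiled); a gap of length k costs
# gap_open + k * gap_extend, matching the existence/extension convention of
# the common BLASTp defaults (11/1).

.B62_LETTERS <- strsplit("ARNDCQEGHILKMFPSTWYVX", "")[[1]]
.B62_VALUES <- c(
  4,-1,-2,-2,0,-1,-1,0,-2,-1,-1,-1,-1,-2,-1,1,0,-3,-2,0,-1,
  -1,5,0,-2,-3,1,0,-2,0,-3,-2,2,-1,-3,-2,-1,-1,-3,-2,-3,-1,
  -2,0,6,1,-3,0,0,0,1,-3,-3,0,-2,-3,-2,1,0,-4,-2,-3,-1,
  -2,-2,1,6,-3,0,2,-1,-1,-3,-4,-1,-3,-3,-1,0,-1,-4,-3,-3,-1,
  0,-3,-3,-3,9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-1,
  -1,1,0,0,-3,5,2,-2,0,-3,-2,1,0,-3,-1,0,-1,-2,-1,-2,-1,
  -1,0,0,2,-4,2,5,-2,0,-3,-3,1,-2,-3,-1,0,-1,-3,-2,-2,-1,
  0,-2,0,-1,-3,-2,-2,6,-2,-4,-4,-2,-3,-3,-2,0,-2,-2,-3,-3,-1,
  -2,0,1,-1,-3,0,0,-2,8,-3,-3,-1,-2,-1,-2,-1,-2,-2,2,-3,-1,
  -1,-3,-3,-3,-1,-3,-3,-4,-3,4,2,-3,1,0,-3,-2,-1,-3,-1,3,-1,
  -1,-2,-3,-4,-1,-2,-3,-4,-3,2,4,-2,2,0,-3,-2,-1,-2,-1,1,-1,
  -1,2,0,-1,-3,1,1,-2,-1,-3,-2,5,-1,-3,-1,0,-1,-3,-2,-2,-1,
  -1,-1,-2,-3,-1,0,-2,-3,-2,1,2,-1,5,0,-2,-1,-1,-1,-1,1,-1,
  -2,-3,-3,-3,-2,-3,-3,-3,-1,0,0,-3,0,6,-4,-2,-2,1,3,-1,-1,
  -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4,7,-1,-1,-4,-3,-2,-1,
  1,-1,1,0,-1,0,0,0,-1,-2,-2,0,-1,-2,-1,4,1,-3,-2,-2,-1,
  0,-1,0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1,1,5,-2,-2,0,-1,
  -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1,1,-4,-3,-2,11,2,-3,-1,
  -2,-2,-2,-3,-2,-1,-2,-3,2,-1,-1,-2,-1,3,-3,-2,-2,2,7,-1,-1,
  0,-3,-3,-3,-1,-2,-2,-3,-3,3,1,-2,1,-1,-2,-2,0,-3,-1,4,-1,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1)

#' The BLOSUM62 substitution matrix (20 amino acids plus X)
#'
#' @return Numeric 21x21 matrix with dimnames over `ARNDCQEGHILKMFPSTWYVX`.
#' @export
blosum62 <- function() {
  matrix(.B62_VALUES, 21, 21, byrow = TRUE,
         dimnames = list(.B62_LETTERS, .B62_LETTERS))
}

#' Optimal affine-gap local alignment of two protein sequences
#'
#' Smith-Waterman/Gotoh alignment. Identity is computed over aligned columns
#' *including* internal gap columns; coverage of each sequence is the aligned
#' span on that sequence divided by its length.
#'
#' @param a,b Protein sequences (character scalars over the matrix alphabet).
#' @param gap_open,gap_extend Gap existence and per-residue extension costs
#'   (positive; defaults 11 and 1).
#' @param submat Substitution matrix (default [blosum62()]).
#' @return List: `score`, `identity`, `coverage_q` (of `a`), `coverage_s`
#'   (of `b`), `matches`, `columns`, and the 1-based aligned spans.
#' @export
align_pair <- function(a, b, gap_open = 11, gap_extend = 1,
                       submat = blosum62()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  ai <- .encode_protein(a, submat)
  bi <- .encode_protein(b, submat)
  r <- sw_align_cpp(ai, bi, submat, gap_open, gap_extend)
  if (r$columns == 0L) {
    return(list(score = 0, identity = NA_real_, coverage_q = 0,
                coverage_s = 0, matches = 0L, columns = 0L,
                qstart = NA, qend = NA, sstart = NA, send = NA))
  }
  list(score = r$score,
       identity = r$matches / r$columns,
       coverage_q = (r$qend - r$qstart + 1) / nchar(a),
       coverage_s = (r$send - r$sstart + 1) / nchar(b),
       matches = r$matches, columns = r$columns,
       qstart = r$qstart, qend = r$qend, sstart = r$sstart, send = r$send)
}

.encode_protein <- function(s, submat) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], rownames(submat))
  if (anyNA(v))
    stop("protein sequence contains characters outside the matrix alphabet")
  as.integer(v - 1L)
}

#' Reciprocal best hits between two proteomes
#'
#' Aligns every cross-proteome pair, finds each protein's top-scoring hit
#' (ties broken by lexicographic id and flagged), and reports the pairs that
#' are mutual best hits with both directions passing the identity and
#' query-coverage thresholds.
#'
#' @param proteome_a,proteome_b Named character vectors of protein sequences
#'   (ids unique within each proteome).
#' @param min_cov Minimum query coverage, enforced in both directions
#'   (default 0.70).
#' @param min_id Minimum identity over aligned columns (default 0.35).
#' @param ... Passed to [align_pair()].
#' @return `data.frame`: `gene_a`, `gene_b`, `score`, `identity`,
#'   `coverage_q`, `coverage_s`, `tie` (best hit was tied on either side).
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, min_cov = 0.70,
                                 min_id = 0.35, ...) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage_q = numeric(0), coverage_s = numeric(0),
                      tie = logical(0), stringsAsFactors = FALSE)
  if (length(proteome_a) == 0L || length(proteome_b) == 0L) {
    warning("empty proteome; no reciprocal best hits")
    return(empty)
  }
  stopifnot(!anyDuplicated(names(proteome_a)), !anyDuplicated(names(proteome_b)))
  na <- length(proteome_a); nb <- length(proteome_b)
  ia <- order(names(proteome_a)); ib <- order(names(proteome_b))
  proteome_a <- proteome_a[ia]; proteome_b <- proteome_b[ib]
  sc <- matrix(0, na, nb, dimnames = list(names(proteome_a), names(proteome_b)))
  aln <- vector("list", na * nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      r <- align_pair(proteome_a[[i]], proteome_b[[j]], ...)
      sc[i, j] <- r$score
      aln[[(i - 1L) * nb + j]] <- r
    }
  }
  # with ids sorted, which.max breaks ties lexicographically
  best_a <- apply(sc, 1, which.max)
  best_b <- apply(sc, 2, which.max)
  tie_a <- apply(sc, 1, function(x) sum(x == max(x)) > 1L)
  tie_b <- apply(sc, 2, function(x) sum(x == max(x)) > 1L)
  rows <- list()
  for (i in seq_len(na)) {
    j <- best_a[i]
    if (best_b[j] != i) next
    r <- aln[[(i - 1L) * nb + j]]
    if (is.na(r$identity) || r$identity < min_id) next
    if (r$coverage_q < min_cov || r$coverage_s < min_cov) next
    rows[[length(rows) + 1L]] <-
      data.frame(gene_a = names(proteome_a)[i], gene_b = names(proteome_b)[j],
                 score = r$score, identity = r$identity,
                 coverage_q = r$coverage_q, coverage_s = r$coverage_s,
                 tie = tie_a[i] || tie_b[j], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Harvest ortholog promoter windows across species
#'
#' For each species in the bundle, identifies the reciprocal best hit of
#' `target_gene` between the reference proteome and the species' proteome,
#' and extracts the ortholog's promoter window from that species' genome.
#' Species lacking an RBH are reported as absent; per-species failures do
#' not abort the other species.
#'
#' @param target_gene Id of the reference gene/protein.
#' @param species_bundle Named list; each element a list with `genome`
#'   (named character vector), `genes` (gene `data.frame`), `proteome`
#'   (named character vector, ids matching `genes$gene_id`).
#' @param reference_proteome Named character vector containing `target_gene`.
#' @param up,down Promoter window extents (defaults 300 and 10).
#' @param min_cov,min_id RBH thresholds (defaults 0.70 and 0.35).
#' @return List: `promoters` (promoter `data.frame` with a `species` column),
#'   `absent` (species without an RBH), `errors` (named character vector).
#' @export
harvest_ortholog_promoters <- function(target_gene, species_bundle,
                                       reference_proteome, up = 300L,
                                       down = 10L, min_cov = 0.70,
                                       min_id = 0.35) {
  if (!target_gene %in% names(reference_proteome))
    stop("target gene '", target_gene, "' absent from reference proteome")
  proms <- list(); absent <- character(0); errors <- character(0)
  one_species <- function(sp) {
    bundle <- species_bundle[[sp]]
    rbh <- reciprocal_best_hits(reference_proteome, bundle$proteome,
                                min_cov = min_cov, min_id = min_id)
    hit <- rbh[rbh$gene_a == target_gene, , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    ortho <- hit$gene_b[1]
    if (is.na(match(ortho, bundle$genes$gene_id)))
      stop("ortholog '", ortho, "' absent from annotation")
    op <- data.frame(operon_id = paste0(sp, "_", ortho),
                     leader_gene = ortho, stringsAsFactors = FALSE)
    p <- extract_promoters(bundle$genome, op, bundle$genes,
                           up = up, down = down)
    p$species <- sp
    p$region_id <- paste0(sp, "_", ortho)
    p
  }
  for (sp in names(species_bundle)) {
    res <- tryCatch(one_species(sp), error = function(e) e)
    if (inherits(res, "error")) {
      errors[sp] <- conditionMessage(res)
    } else if (is.null(res)) {
      absent <- c(absent, sp)
    } else {
      proms[[sp]] <- res
    }
  }
  list(promoters = if (length(proms)) do.call(rbind, c(proms, list(make.row.names = FALSE))) else NULL,
       absent = absent, errors = errors)
}
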