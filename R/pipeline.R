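# End-to-end orchestration: configuration with the pipeline's canonical
# default thresholds, the staged run, and its JSON/TSV reports.

#' Pipeline configuration
#'
#' Holds all tunable thresholds with their canonical defaults: DE filter
#' |log2FC| >= 2 and padj <= 0.01; operon chaining gap < 50 bp; promoter
#' window 300 bp upstream + 10 bp downstream of the start codon; RBH
#' coverage >= 0.70 and identity >= 0.35; scan p-value cutoff 1e-4; motif
#' width 22; domain-score cutoffs 35 (Autoind_bind), 20 (GerE-HTH),
#' 50 (Autoind_synth).
#'
#' @param de_table,regulon,genes,genome Input paths (DE TSV; one-id-per-line
#'   regulon list; gene TSV or GFF3; genome FASTA).
#' @param motif Optional MEME-format motif to scan with; when NULL a motif
#'   is discovered from the extracted promoters.
#' @param lfc_min,padj_max DE thresholds.
#' @param operon_max_gap Operon chaining bound (strict, bp).
#' @param promoter_up,promoter_down Promoter window extents (bp).
#' @param rbh_min_cov,rbh_min_id RBH thresholds.
#' @param scan_p_cut Scan p-value cutoff.
#' @param motif_width,restarts Motif discovery settings.
#' @param cut_bind,cut_hth,cut_synth Domain-score cutoffs.
#' @param seed Integer seed for all stochastic stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(de_table = NULL, regulon = NULL, genes = NULL,
                            genome = NULL, motif = NULL,
                            lfc_min = 2, padj_max = 0.01,
                            operon_max_gap = 50L,
                            promoter_up = 300L, promoter_down = 10L,
                            rbh_min_cov = 0.70, rbh_min_id = 0.35,
                            scan_p_cut = 1e-4, motif_width = 22L,
                            restarts = 20L,
                            cut_bind = 35, cut_hth = 20, cut_synth = 50,
                            seed = 1L) {
  cfg <- list(de_table = de_table, regulon = regulon, genes = genes,
              genome = genome, motif = motif, lfc_min = lfc_min,
              padj_max = padj_max, operon_max_gap = operon_max_gap,
              promoter_up = promoter_up, promoter_down = promoter_down,
              rbh_min_cov = rbh_min_cov, rbh_min_id = rbh_min_id,
              scan_p_cut = scan_p_cut, motif_width = motif_width,
              restarts = restarts, cut_bind = cut_bind, cut_hth = cut_hth,
              cut_synth = cut_synth, seed = seed)
  stopifnot(cfg$lfc_min >= 0, cfg$padj_max >= 0, cfg$padj_max <= 1,
            cfg$operon_max_gap >= 0, cfg$promoter_up >= 0,
            cfg$promoter_down >= 0, cfg$rbh_min_cov >= 0,
            cfg$rbh_min_cov <= 1, cfg$rbh_min_id >= 0, cfg$rbh_min_id <= 1,
            cfg$scan_p_cut > 0, cfg$scan_p_cut <= 1, cfg$motif_width >= 2)
  structure(cfg, class = "pipeline_config")
}

#' Run the binding-site discovery pipeline
#'
#' Stages: DE filter -> regulon subtraction -> operon collapsing -> promoter
#' extraction -> motif (loaded from `config$motif` or discovered by ZOOPS
#' EM) -> PWM scan with exact p-values -> palindromic-hit aggregation.
#' All inputs are checked before any stage runs; per-stage outputs, a JSON
#' summary and a log (with a byte-for-byte config echo) are written to
#' `outdir`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Stage-count summary list, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  needed <- c("de_table", "regulon", "genes", "genome")
  for (f in needed) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("missing input before any stage ran: ", f)
  }
  if (!is.null(config$motif) && !file.exists(config$motif))
    stop("missing input before any stage ran: motif")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                              append = TRUE)
  cat("pipeline run\n", file = logf)
  logmsg("config: %s", jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                        null = "null"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  de <- stage("read-inputs", read_de_table(config$de_table))
  regulon <- stage("read-inputs", readLines(config$regulon))
  regulon <- regulon[nzchar(trimws(regulon))]
  genes <- stage("read-inputs",
                 if (grepl("\\.gff3?$", config$genes, ignore.case = TRUE))
                   read_gff_genes(config$genes) else
                     read_gene_table(config$genes))
  genome <- stage("read-inputs", read_fasta(config$genome))

  de_genes <- stage("filter-de",
                    filter_de(de, config$lfc_min, config$padj_max))
  logmsg("filter-de: %d genes pass", length(de_genes))
  kept <- stage("subtract-regulon", subtract_regulon(de_genes, regulon))
  logmsg("subtract-regulon: removed %d, kept %d",
         attr(kept, "n_removed"), length(kept))

  gsub_df <- genes[genes$gene_id %in% kept, , drop = FALSE]
  operons <- stage("operons", call_operons(gsub_df, config$operon_max_gap))
  logmsg("operons: %d transcriptional units", nrow(operons))
  op_flat <- operons
  op_flat$gene_ids <- vapply(operons$gene_ids, paste, character(1),
                             collapse = ",")
  write.table(op_flat, file.path(outdir, "operons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  proms <- stage("promoters",
                 extract_promoters(genome, operons, genes,
                                   up = config$promoter_up,
                                   down = config$promoter_down))
  write_fasta(setNames(proms$seq, proms$region_id),
              file.path(outdir, "promoters.fasta"))
  write.table(proms[, c("contig", "start", "end", "region_id", "strand")],
              file.path(outdir, "promoters.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  logmsg("promoters: %d regions", nrow(proms))

  if (!is.null(config$motif)) {
    pwm <- stage("motif", read_meme(config$motif))
    model <- NULL
  } else {
    model <- stage("motif",
                   discover_motif(proms, w = config$motif_width,
                                  restarts = config$restarts,
                                  seed = config$seed))
    pwm <- model$pwm
    write_meme(model, file.path(outdir, "motif.meme"))
    logmsg("motif: consensus %s, occupancy %d/%d",
           as.character(model$consensus), model$occupancy[1],
           model$occupancy[2])
  }

  hits <- stage("scan", scan_region(pwm, proms, p_cut = config$scan_p_cut))
  agg <- stage("aggregate", aggregate_hits(hits))
  write.table(hits, file.path(outdir, "hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_hits_bed(hits, file.path(outdir, "hits.bed"), width = pwm$width)
  logmsg("scan: %d hits in %d regions", nrow(hits), nrow(agg$regions))

  summary <- list(
    n_de = length(de_genes),
    n_removed_by_regulon = attr(kept, "n_removed"),
    n_after_subtraction = length(kept),
    n_operons = nrow(operons),
    n_promoters = nrow(proms),
    motif = if (!is.null(model)) list(
      consensus = as.character(model$consensus),
      occupancy_found = unname(model$occupancy[1]),
      occupancy_total = unname(model$occupancy[2])) else
        list(consensus = as.character(consensus_from_pwm(pwm))),
    n_hits = nrow(hits),
    n_regions_with_hits = nrow(agg$regions),
    seed = config$seed,
    config = unclass(config))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(summary)
}

#' Read a species manifest for ortholog harvesting
#'
#' TSV with header `species`, `genome`, `annotation`, `proteome`; paths are
#' resolved relative to the manifest unless absolute.
#'
#' @param path Manifest path.
#' @return Named list of per-species bundles as consumed by
#'   [harvest_ortholog_promoters()].
#' @export
read_species_manifest <- function(path) {
  mf <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "genome", "annotation", "proteome")
  if (!all(need %in% names(mf)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  out <- lapply(seq_len(nrow(mf)), function(i) {
    list(genome = read_fasta(resolve(mf$genome[i])),
         genes = read_gene_table(resolve(mf$annotation[i])),
         proteome = read_fasta(resolve(mf$proteome[i]), alphabet = "protein"))
  })
  names(out) <- mf$species
  out
}
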