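#' @importFrom Biostrings readDNAStringSet
NULL

#' Run the full discovery and annotation pipeline on a file bundle
#'
#' Orchestrates every stage over a set of input files (for example the
#' bundle written by [generate_world()]): funnel filtering and
#' classification, breed-specificity, DE-table thresholding, cis/host/trans
#' target prediction, conservation summarization, synteny scanning, QTL
#' co-localization, network construction with module detection, and
#' over-representation analysis of module genes. All stage outputs are
#' written as TSV files under `out_dir` and returned.
#'
#' @param paths named list of input file paths, with the names used by
#'   [generate_world()]: `reference_gtf`, `assembled_gtf`, `fasta`,
#'   `repeats_bed`, `expression`, `groups`, `de_table`, `hits`, `domains`,
#'   `scores`, `qtl`, `ppi`, `gmt`, and per species
#'   `foreign_genes_<sp>`, `foreign_lincs_<sp>`, `orthologs_<sp>`;
#'   `cross_species_hits` optional.
#' @param out_dir output directory (created if absent).
#' @param params a [filter_params()].
#' @param r_min_targets,p_max trans-target thresholds (defaults 0.99 /
#'   5e-5).
#' @param r_min_network looser correlation threshold used when building the
#'   co-expression edges of the integrated network (default 0.95).
#' @param cis_window cis search window in bp (default 1e5).
#' @param qtl_trait optional trait substring for the QTL stage.
#' @param qtl_max_span optional QTL span ceiling in bp.
#' @param min_module_size,module_p_max,penalty module-detection parameters.
#' @param enrich_fdr enrichment FDR ceiling (default 0.05).
#' @return invisible list with every stage's result plus `log`, a
#'   data.frame of per-stage counts.
#' @export
run_pipeline <- function(paths, out_dir,
                         params = filter_params(),
                         r_min_targets = 0.99, p_max = 0.00005,
                         r_min_network = 0.95,
                         cis_window = 100000,
                         qtl_trait = NULL, qtl_max_span = NULL,
                         min_module_size = 6L, module_p_max = 0.01,
                         penalty = 2.0, enrich_fdr = 0.05) {
  need <- c("reference_gtf", "assembled_gtf", "fasta", "repeats_bed",
            "expression", "groups", "de_table", "hits", "domains",
            "scores", "qtl", "ppi", "gmt")
  for (nm in need) {
    if (is.null(paths[[nm]])) stop("missing input path: ", nm)
    if (!file.exists(paths[[nm]]))
      stop("input file does not exist: ", paths[[nm]], " (", nm, ")")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, fname) utils::write.table(
    df, file.path(out_dir, fname), sep = "\t", quote = FALSE,
    row.names = FALSE)
  log_rows <- list()
  note <- function(stage, count) log_rows[[length(log_rows) + 1L]] <<-
    data.frame(stage = stage, count = count, stringsAsFactors = FALSE)

  ref <- read_gtf(paths$reference_gtf)
  assembled <- read_gtf(paths$assembled_gtf)
  repeats <- if (file.size(paths$repeats_bed) > 0)
    read_repeat_bed(paths$repeats_bed) else GenomicRanges::GRanges()
  expr <- read_expression(paths$expression, paths$groups)
  seq_set <- Biostrings::readDNAStringSet(paths$fasta)
  sequences <- setNames(as.character(seq_set), names(seq_set))
  evidence <- list(
    hits = utils::read.delim(paths$hits, stringsAsFactors = FALSE),
    domains = utils::read.delim(paths$domains, stringsAsFactors = FALSE),
    scores = utils::read.delim(paths$scores, stringsAsFactors = FALSE))

  # funnel --------------------------------------------------------------
  funnel <- run_funnel(assembled, ref, repeats, expr, evidence, sequences,
                       params)
  cands <- funnel$candidates
  note("candidates", nrow(cands))
  wtsv(funnel$report, "funnel_report.tsv")
  wtsv(funnel$rejected, "rejected_transcripts.tsv")
  wtsv(cands, "candidates.tsv")
  cat_attr <- setNames(sprintf('category "%s";', cands$category),
                       cands$transcript_id)
  keep_ex <- assembled$exons[
    S4Vectors::mcols(assembled$exons)$transcript_id %in%
      cands$transcript_id]
  if (length(keep_ex)) {
    sub <- genome_annotation(data.frame(
      chrom = as.character(GenomicRanges::seqnames(keep_ex)),
      start = GenomicRanges::start(keep_ex),
      end = GenomicRanges::end(keep_ex),
      strand = as.character(GenomicRanges::strand(keep_ex)),
      transcript_id = S4Vectors::mcols(keep_ex)$transcript_id,
      gene_id = S4Vectors::mcols(keep_ex)$gene_id,
      stringsAsFactors = FALSE))
    write_gtf(sub, file.path(out_dir, "candidates.gtf"),
              extra_attrs = cat_attr)
  }

  # breed-specificity -----------------------------------------------------
  cand_expr_ids <- intersect(cands$transcript_id, rownames(expr$values))
  bs <- vapply(cand_expr_ids, breed_specific, character(1), expr = expr)
  bs_tbl <- data.frame(transcript_id = cand_expr_ids,
                       breed = unname(bs), stringsAsFactors = FALSE)
  bs_tbl <- bs_tbl[!is.na(bs_tbl$breed), , drop = FALSE]
  note("breed_specific", nrow(bs_tbl))
  wtsv(bs_tbl, "breed_specific.tsv")

  # differential expression (consumed table) ------------------------------
  de <- classify_de(utils::read.delim(paths$de_table,
                                      stringsAsFactors = FALSE))
  de_cand <- de[de$id %in% cands$transcript_id, , drop = FALSE]
  note("de_lncRNAs", nrow(de_cand))
  wtsv(de_cand, "de_lncRNAs.tsv")

  # targets ----------------------------------------------------------------
  mrna_ids <- unique(ref$transcripts$gene_id[
    ref$transcripts$biotype == "protein_coding"])
  lnc_expr <- expr$values[intersect(cands$transcript_id,
                                    rownames(expr$values)), , drop = FALSE]
  mrna_expr <- expr$values[intersect(mrna_ids, rownames(expr$values)), ,
                           drop = FALSE]
  cand_in <- cands
  names(cand_in)[names(cand_in) == "transcript_id"] <- "lnc_id"
  targets <- predict_targets(cand_in, ref, lnc_expr, mrna_expr,
                             window = cis_window, r_min = r_min_targets,
                             p_max = p_max)
  note("target_assignments", nrow(targets))
  wtsv(targets, "targets.tsv")

  # conservation ------------------------------------------------------------
  conservation <- NULL
  if (!is.null(paths$cross_species_hits) &&
      file.exists(paths$cross_species_hits)) {
    xs <- utils::read.delim(paths$cross_species_hits,
                            stringsAsFactors = FALSE)
    tg <- setNames(cands$locus_id, cands$transcript_id)
    conservation <- conservation_summary(xs, tg)
    wtsv(conservation$per_species, "conservation.tsv")
    note("conserved_species", nrow(conservation$per_species))
  }

  # synteny -----------------------------------------------------------------
  sp_names <- sub("^foreign_lincs_", "",
                  grep("^foreign_lincs_", names(paths), value = TRUE))
  synteny <- NULL
  if (length(sp_names)) {
    foreign <- lapply(sp_names, function(sp) list(
      lincs = utils::read.delim(paths[[paste0("foreign_lincs_", sp)]],
                                stringsAsFactors = FALSE),
      genes = utils::read.delim(paths[[paste0("foreign_genes_", sp)]],
                                stringsAsFactors = FALSE),
      orthologs = utils::read.delim(paths[[paste0("orthologs_", sp)]],
                                    stringsAsFactors = FALSE)))
    names(foreign) <- sp_names
    sheep_genes <- data.frame(
      gene_id = S4Vectors::mcols(ref$genes)$gene_id,
      chrom = as.character(GenomicRanges::seqnames(ref$genes)),
      start = GenomicRanges::start(ref$genes),
      end = GenomicRanges::end(ref$genes),
      stringsAsFactors = FALSE)
    sheep_genes <- sheep_genes[
      S4Vectors::mcols(ref$genes)$biotype == "protein_coding", ]
    lincs <- cand_in[cand_in$category == "lincRNA", , drop = FALSE]
    synteny <- synteny_scan(lincs, sheep_genes, foreign)
    note("syntenic_records", sum(synteny$conserved_synteny))
    wtsv(synteny, "synteny.tsv")
  }

  # QTL ---------------------------------------------------------------------
  qtls <- read_qtl(paths$qtl)
  loci <- cand_in[, c("lnc_id", "chrom", "start", "end", "category")]
  qtl_hits <- qtl_annotate(loci, qtls, trait_filter = qtl_trait,
                           max_qtl_span = qtl_max_span)
  note("qtl_annotations", nrow(qtl_hits))
  wtsv(qtl_hits, "qtl_annotations.tsv")

  # network + modules ------------------------------------------------------
  coexp <- trans_targets(lnc_expr, mrna_expr, r_min = r_min_network,
                         p_max = p_max)
  ppi <- utils::read.delim(paths$ppi, stringsAsFactors = FALSE)
  net <- build_network(coexp, ppi)
  modules <- detect_modules(net, min_size = min_module_size,
                            p_max = module_p_max, penalty = penalty)
  note("modules", length(modules))
  wtsv(modules_table(modules), "modules.tsv")
  wtsv(net$edges, "network_edges.tsv")

  # enrichment of module genes ----------------------------------------------
  sets <- read_gmt(paths$gmt)
  background <- mrna_ids
  enrichment <- NULL
  if (length(modules)) {
    per_mod <- lapply(seq_along(modules), function(i) {
      genes <- intersect(modules[[i]]$members, background)
      if (!length(genes)) return(NULL)
      res <- ora(genes, sets, background, fdr_max = enrich_fdr)
      cbind(module = i, res)
    })
    enrichment <- do.call(rbind, per_mod)
    if (!is.null(enrichment)) {
      wtsv(enrichment, "enrichment.tsv")
      note("enriched_sets", sum(enrichment$significant))
    }
  }

  log_df <- do.call(rbind, log_rows)
  wtsv(log_df, "run_log.tsv")
  invisible(list(funnel = funnel, candidates = cands,
                 breed_specific = bs_tbl, de = de_cand, targets = targets,
                 conservation = conservation, synteny = synteny,
                 qtl = qtl_hits, network = net, modules = modules,
                 enrichment = enrichment, log = log_df))
}
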