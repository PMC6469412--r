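#' Read a BLAST tabular (outfmt-6-like) hit table
#'
#' Expects at least the columns query, subject, identity, length and evalue
#' in the standard 12-column order, or a headered TSV with those names.
#'
#' @param path TSV path.
#' @param species species label attached to every hit.
#' @param direction `"sheep_as_query"` or `"sheep_as_subject"`.
#' @return data.frame: `query_id`, `subject_id`, `species`, `evalue`,
#'   `alignment_length`, `direction`.
#' @export
read_blast_hits <- function(path, species,
                            direction = c("sheep_as_query",
                                          "sheep_as_subject")) {
  direction <- match.arg(direction)
  first <- readLines(path, n = 1)
  has_header <- grepl("query", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < 12) stop("unrecognized BLAST tabular layout: ", path)
    names(df)[c(1, 2, 3, 4, 11)] <-
      c("query_id", "subject_id", "identity", "length", "evalue")
  }
  data.frame(query_id = df$query_id, subject_id = df$subject_id,
             species = species, evalue = df$evalue,
             alignment_length = df$length, direction = direction,
             stringsAsFactors = FALSE)
}

#' Summarize sequence conservation from cross-species homology hits
#'
#' A candidate transcript is conserved in a species when any hit in either
#' query direction reaches `evalue <= emax`; a candidate gene is conserved
#' when any member transcript is. The mean alignment length is taken over
#' the best (lowest-E, then longest) hit per conserved transcript.
#'
#' @param hits data.frame as from [read_blast_hits()], sheep candidate ids in
#'   `query_id` for `sheep_as_query` rows and in `subject_id` otherwise.
#' @param transcript_gene named character vector mapping candidate
#'   transcript_id to gene/locus id.
#' @param emax E-value cutoff, inclusive (default 1e-5).
#' @return list with `per_species` data.frame (`species`,
#'   `conserved_transcripts`, `conserved_genes`, `mean_alignment_length`)
#'   and `conserved_ids`, a per-species list of conserved transcript ids.
#' @export
conservation_summary <- function(hits, transcript_gene, emax = 1e-5) {
  if (is.null(hits$alignment_length) && !is.null(hits$length))
    hits$alignment_length <- hits$length
  hits$candidate_id <- ifelse(hits$direction == "sheep_as_query",
                              hits$query_id, hits$subject_id)
  sig <- hits[hits$evalue <= emax, , drop = FALSE]
  species <- sort(unique(hits$species))
  conserved_ids <- lapply(species, function(s)
    sort(unique(sig$candidate_id[sig$species == s])))
  names(conserved_ids) <- species
  per_species <- do.call(rbind, lapply(species, function(s) {
    ids <- conserved_ids[[s]]
    best_len <- vapply(ids, function(id) {
      h <- sig[sig$species == s & sig$candidate_id == id, ]
      h <- h[order(h$evalue, -h$alignment_length), ]
      h$alignment_length[1]
    }, numeric(1))
    data.frame(species = s,
               conserved_transcripts = length(ids),
               conserved_genes = length(unique(transcript_gene[ids])),
               mean_alignment_length = if (length(ids)) mean(best_len)
                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_species = per_species, conserved_ids = conserved_ids)
}

# nearest flanking protein-coding genes left and right of an interval;
# NA on a side with no gene
flanking_pair <- function(chrom, start, end, genes_df) {
  g <- genes_df[genes_df$chrom == chrom, , drop = FALSE]
  left <- g[g$end < start, , drop = FALSE]
  right <- g[g$start > end, , drop = FALSE]
  list(left = if (nrow(left)) left$gene_id[which.max(left$end)]
         else NA_character_,
       right = if (nrow(right)) right$gene_id[which.min(right$start)]
         else NA_character_)
}

#' Synteny conservation of an intergenic lncRNA in one foreign species
#'
#' The sheep candidate's flanking pair (nearest protein-coding gene on each
#' side) is mapped through the ortholog table; the locus is syntenically
#' conserved when some foreign lincRNA's own nearest flanking pair equals
#' the mapped pair. Matching is unordered by default (orientation-blind);
#' `strict_order = TRUE` requires left/right to match exactly.
#'
#' @param lnc one row with `chrom`, `start`, `end` and an id column.
#' @param sheep_genes data.frame of sheep protein-coding genes: `gene_id`,
#'   `chrom`, `start`, `end`.
#' @param foreign_lincs data.frame of the species' lincRNA positions:
#'   `linc_id`, `chrom`, `start`, `end`.
#' @param foreign_genes data.frame of the species' protein-coding genes.
#' @param orthologs data.frame `sheep_gene`, `foreign_gene`.
#' @param species species label for the record.
#' @param strict_order require orientation-preserving flank match.
#' @return one-row data.frame: `lnc_id`, `species`, `left_gene`,
#'   `right_gene`, `matched_foreign_linc`, `conserved_synteny`, `flag`.
#' @export
synteny_conserved <- function(lnc, sheep_genes, foreign_lincs, foreign_genes,
                              orthologs, species, strict_order = FALSE) {
  lnc_id <- if (!is.null(lnc$lnc_id)) lnc$lnc_id[1] else lnc$transcript_id[1]
  fl <- flanking_pair(lnc$chrom[1], lnc$start[1], lnc$end[1], sheep_genes)
  rec <- data.frame(lnc_id = lnc_id, species = species,
                    left_gene = fl$left, right_gene = fl$right,
                    matched_foreign_linc = NA_character_,
                    conserved_synteny = FALSE, flag = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.na(fl$left) || is.na(fl$right)) {
    rec$flag <- "incomplete_flank"
    return(rec)
  }
  map <- setNames(orthologs$foreign_gene, orthologs$sheep_gene)
  ox <- map[fl$left]; oy <- map[fl$right]
  if (is.na(ox) || is.na(oy)) {
    rec$flag <- "missing_ortholog"
    return(rec)
  }
  want <- sort(c(unname(ox), unname(oy)))
  for (j in order(foreign_lincs$linc_id)) {
    ffl <- flanking_pair(foreign_lincs$chrom[j], foreign_lincs$start[j],
                         foreign_lincs$end[j], foreign_genes)
    if (is.na(ffl$left) || is.na(ffl$right)) next
    ok <- if (strict_order)
      identical(c(ffl$left, ffl$right), c(unname(ox), unname(oy)))
    else identical(sort(c(ffl$left, ffl$right)), want)
    if (ok) {
      rec$matched_foreign_linc <- foreign_lincs$linc_id[j]
      rec$conserved_synteny <- TRUE
      return(rec)
    }
  }
  rec
}

#' Synteny records for many candidates across many species
#'
#' @param lncs data.frame of candidates (`lnc_id` or `transcript_id`,
#'   `chrom`, `start`, `end`).
#' @param sheep_genes sheep protein-coding gene table.
#' @param foreign list per species: `lincs`, `genes`, `orthologs`.
#' @param strict_order see [synteny_conserved()].
#' @return data.frame of one record per (lnc, species).
#' @export
synteny_scan <- function(lncs, sheep_genes, foreign, strict_order = FALSE) {
  out <- list()
  for (i in seq_len(nrow(lncs))) {
    for (s in names(foreign)) {
      out[[length(out) + 1L]] <- synteny_conserved(
        lncs[i, ], sheep_genes, foreign[[s]]$lincs, foreign[[s]]$genes,
        foreign[[s]]$orthologs, s, strict_order)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Venn partition of synteny conservation across species
#'
#' @param records data.frame from [synteny_scan()].
#' @return list with `sets` (conserved lnc ids per species) and `partition`
#'   (data.frame `region` — a `+`-joined species combination — and `count`
#'   of lncs exactly in that combination).
#' @export
synteny_venn <- function(records) {
  species <- sort(unique(records$species))
  if (length(species) < 2L) stop("at least two species required")
  sets <- lapply(species, function(s)
    sort(unique(records$lnc_id[records$species == s &
                                 records$conserved_synteny])))
  names(sets) <- species
  all_ids <- sort(unique(unlist(sets)))
  combos <- unlist(lapply(seq_along(species), function(k)
    utils::combn(species, k, simplify = FALSE)), recursive = FALSE)
  partition <- do.call(rbind, lapply(combos, function(cmb) {
    inside <- Reduce(intersect, sets[cmb])
    outside <- unlist(sets[setdiff(species, cmb)])
    data.frame(region = paste(cmb, collapse = "+"),
               count = length(setdiff(inside, outside)),
               stringsAsFactors = FALSE)
  }))
  list(sets = sets, partition = partition, n_conserved_any = length(all_ids))
}
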