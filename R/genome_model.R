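#' @import methods
#' @importFrom GenomicRanges GRanges findOverlaps reduce strand seqnames start end width
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors mcols queryHits subjectHits split
#' @importFrom GenomeInfoDb seqlevels
NULL

#' Build a genome annotation from per-exon coordinates
#'
#' The central container of the package: an indexed annotation holding every
#' transcript as an ordered set of exons, together with derived gene spans
#' (the union hull of all transcripts of a gene) and per-transcript introns.
#' All coordinates are 1-based closed, the GenomicRanges convention; file
#' readers convert from each format's native convention at the boundary.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`, `gene_id` and optionally `biotype` (one exon per row,
#'   1-based closed coordinates).
#' @return An object of class `genome_annotation` with components:
#'   \describe{
#'     \item{transcripts}{data.frame, one row per transcript: `transcript_id`,
#'       `gene_id`, `chrom`, `strand`, `start`, `end` (hull), `n_exons`,
#'       `spliced_length`, `biotype`.}
#'     \item{exons}{`GRanges` of all exons with `transcript_id`, `gene_id`.}
#'     \item{genes}{`GRanges` of gene hulls with `gene_id`, `biotype`.}
#'     \item{introns}{`GRanges` of per-transcript introns (gaps between
#'       consecutive exons) with `transcript_id`, `gene_id`.}
#'   }
#' @export
genome_annotation <- function(exons) {
  stopifnot(is.data.frame(exons),
            all(c("chrom", "start", "end", "strand",
                  "transcript_id", "gene_id") %in% names(exons)))
  if (is.null(exons$biotype)) exons$biotype <- rep("novel", nrow(exons))
  if (nrow(exons) == 0L) {
    empty_gr <- GenomicRanges::GRanges()
    ann <- list(
      transcripts = data.frame(transcript_id = character(), gene_id = character(),
                               chrom = character(), strand = character(),
                               start = integer(), end = integer(),
                               n_exons = integer(), spliced_length = integer(),
                               biotype = character(), stringsAsFactors = FALSE),
      exons = empty_gr, genes = empty_gr, introns = empty_gr)
    class(ann) <- "genome_annotation"
    return(ann)
  }
  bad <- exons$start > exons$end
  if (any(bad))
    stop("exon with start > end for transcript ",
         exons$transcript_id[which(bad)[1]])
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]

  # per-transcript consistency: one chrom, one strand, non-overlapping exons
  tx_split <- split(seq_len(nrow(exons)), exons$transcript_id)
  tx <- do.call(rbind, lapply(tx_split, function(idx) {
    e <- exons[idx, , drop = FALSE]
    if (length(unique(e$chrom)) != 1L || length(unique(e$strand)) != 1L)
      stop("transcript ", e$transcript_id[1],
           " has exons on multiple chromosomes or strands")
    if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("transcript ", e$transcript_id[1], " has overlapping exons")
    data.frame(transcript_id = e$transcript_id[1], gene_id = e$gene_id[1],
               chrom = e$chrom[1], strand = e$strand[1],
               start = min(e$start), end = max(e$end),
               n_exons = nrow(e),
               spliced_length = sum(e$end - e$start + 1L),
               biotype = e$biotype[1], stringsAsFactors = FALSE)
  }))
  rownames(tx) <- NULL

  exon_gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand)
  S4Vectors::mcols(exon_gr)$transcript_id <- exons$transcript_id
  S4Vectors::mcols(exon_gr)$gene_id <- exons$gene_id

  # gene hulls: union span of all transcripts of the gene
  g_split <- split(seq_len(nrow(tx)), tx$gene_id)
  genes_df <- do.call(rbind, lapply(g_split, function(idx) {
    t <- tx[idx, , drop = FALSE]
    data.frame(gene_id = t$gene_id[1], chrom = t$chrom[1],
               strand = t$strand[1],
               start = min(t$start), end = max(t$end),
               biotype = t$biotype[1], stringsAsFactors = FALSE)
  }))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes_df$chrom,
    ranges = IRanges::IRanges(genes_df$start, genes_df$end),
    strand = genes_df$strand)
  S4Vectors::mcols(gene_gr)$gene_id <- genes_df$gene_id
  S4Vectors::mcols(gene_gr)$biotype <- genes_df$biotype

  # introns: gaps between consecutive exons of each transcript
  intron_rows <- lapply(tx_split, function(idx) {
    e <- exons[idx, , drop = FALSE]
    if (nrow(e) < 2L) return(NULL)
    data.frame(chrom = e$chrom[1], start = e$end[-nrow(e)] + 1L,
               end = e$start[-1] - 1L, strand = e$strand[1],
               transcript_id = e$transcript_id[1], gene_id = e$gene_id[1],
               stringsAsFactors = FALSE)
  })
  intron_df <- do.call(rbind, intron_rows)
  if (is.null(intron_df) || nrow(intron_df) == 0L) {
    intron_gr <- GenomicRanges::GRanges()
  } else {
    intron_gr <- GenomicRanges::GRanges(
      seqnames = intron_df$chrom,
      ranges = IRanges::IRanges(intron_df$start, intron_df$end),
      strand = intron_df$strand)
    S4Vectors::mcols(intron_gr)$transcript_id <- intron_df$transcript_id
    S4Vectors::mcols(intron_gr)$gene_id <- intron_df$gene_id
  }

  ann <- list(transcripts = tx, exons = exon_gr, genes = gene_gr,
              introns = intron_gr)
  class(ann) <- "genome_annotation"
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$transcripts), "transcripts,",
      length(x$genes), "genes\n")
  if (nrow(x$transcripts) > 0)
    print(table(x$transcripts$biotype))
  invisible(x)
}

#' Read a GTF file into a genome annotation
#'
#' Coordinates on disk are 1-based inclusive (the GTF convention) and are kept
#' as such internally. Transcript biotype is read from the `gene_biotype`
#' attribute when present; the value `"lncRNA"` is mapped to `known_lncRNA`
#' (annotated lncRNA genes), `"protein_coding"` stays `protein_coding`, a
#' missing attribute yields `novel`, anything else `other`.
#'
#' @param path path to a GTF file.
#' @return A [genome_annotation()] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in GTF: ", path)
  if (any(is.na(gr$transcript_id)))
    stop("GTF exon record without transcript_id in ", path)
  biotype <- if ("gene_biotype" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$gene_biotype) else rep(NA_character_, length(gr))
  biotype <- ifelse(is.na(biotype), "novel",
             ifelse(biotype == "lncRNA", "known_lncRNA",
             ifelse(biotype == "protein_coding", "protein_coding",
             ifelse(biotype %in% c("novel", "known_lncRNA"), biotype,
                    "other"))))
  genome_annotation(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    biotype = biotype,
    stringsAsFactors = FALSE))
}

#' Write a genome annotation to GTF
#'
#' Emits one `exon` feature line per exon with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes (`known_lncRNA` is written back as `lncRNA`, the
#' Ensembl vocabulary). Read/write round-trips preserve all coordinates.
#'
#' @param ann a [genome_annotation()].
#' @param path output file path.
#' @param source source field for column 2 (default `"lncfunnel"`).
#' @param extra_attrs optional named character vector keyed by transcript_id,
#'   appended verbatim as an extra attribute string (e.g. a category tag).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path, source = "lncfunnel", extra_attrs = NULL) {
  ex <- ann$exons
  tid <- S4Vectors::mcols(ex)$transcript_id
  gid <- S4Vectors::mcols(ex)$gene_id
  bt <- ann$transcripts$biotype[match(tid, ann$transcripts$transcript_id)]
  bt <- ifelse(bt == "known_lncRNA", "lncRNA", bt)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                   gid, tid, bt)
  if (!is.null(extra_attrs)) {
    extra <- extra_attrs[tid]
    attrs <- ifelse(is.na(extra), attrs, paste(attrs, extra))
  }
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(GenomicRanges::seqnames(ex)), source,
                   GenomicRanges::start(ex), GenomicRanges::end(ex),
                   as.character(GenomicRanges::strand(ex)), attrs)
  # order by transcript then coordinate for stable output
  o <- order(tid, GenomicRanges::start(ex))
  writeLines(lines[o], path)
  invisible(path)
}

#' Read a BED repeat track
#'
#' BED is 0-based half-open on disk; rtracklayer converts to 1-based closed.
#'
#' @param path path to a BED file.
#' @return `GRanges` of repeat intervals.
#' @export
read_repeat_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  rtracklayer::import(path, format = "bed")
}

#' Positional class code of a transcript against a reference annotation
#'
#' Assigns the reduced class-code vocabulary used by the discovery funnel:
#' \describe{
#'   \item{u}{intergenic: no exon of the query overlaps any gene span of a
#'     protein-coding or annotated-lncRNA gene (strand ignored).}
#'   \item{i}{intronic: the whole query span lies within a single intron of
#'     some protein-coding transcript (any isoform; strand ignored).}
#'   \item{overlap}{anything else, i.e. some exonic-span overlap.}
#' }
#' A query on a chromosome absent from the reference is intergenic.
#'
#' @param query a single-row subset of a `genome_annotation$transcripts`
#'   data.frame, or a list/row with `chrom`, `start`, `end`, `transcript_id`.
#' @param ann reference [genome_annotation()].
#' @param query_exons optional `GRanges` of the query's exons; when omitted
#'   they are looked up in `query$ann` or the span is used as one exon.
#' @return one of `"u"`, `"i"`, `"overlap"`.
#' @export
assign_class_code <- function(query, ann, query_exons = NULL) {
  chrom <- as.character(query$chrom[1])
  if (is.null(query_exons)) {
    query_exons <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(query$start[1], query$end[1]))
  }
  genes <- ann$genes[S4Vectors::mcols(ann$genes)$biotype %in%
                       c("protein_coding", "known_lncRNA")]
  if (!(chrom %in% as.character(GenomicRanges::seqnames(genes))))
    return("u")
  hit_gene <- IRanges::overlapsAny(query_exons, genes, ignore.strand = TRUE)
  if (!any(hit_gene)) return("u")
  # intronic: whole query span within one intron of a protein-coding isoform
  span <- range(query_exons, ignore.strand = TRUE)
  introns <- ann$introns
  if (length(introns) > 0L) {
    coding_tx <- ann$transcripts$transcript_id[
      ann$transcripts$biotype == "protein_coding"]
    introns <- introns[S4Vectors::mcols(introns)$transcript_id %in% coding_tx]
    if (length(introns) > 0L) {
      within <- IRanges::overlapsAny(span, introns, type = "within",
                                     ignore.strand = TRUE)
      if (any(within)) return("i")
    }
  }
  "overlap"
}

#' Class codes for every transcript of an assembled annotation
#'
#' @param assembled [genome_annotation()] of query transcripts.
#' @param ref reference [genome_annotation()].
#' @return named character vector, class code per transcript_id.
#' @export
classify_transcripts <- function(assembled, ref) {
  tx <- assembled$transcripts
  ex <- assembled$exons
  ex_tid <- S4Vectors::mcols(ex)$transcript_id
  codes <- vapply(seq_len(nrow(tx)), function(i) {
    assign_class_code(tx[i, ], ref, query_exons = ex[ex_tid == tx$transcript_id[i]])
  }, character(1))
  names(codes) <- tx$transcript_id
  codes
}

#' Cluster transcripts into gene loci by same-strand exonic overlap
#'
#' Two transcripts share a locus iff they are connected, transitively, by at
#' least 1 bp of same-strand exonic overlap. The locus id is the
#' lexicographically smallest member transcript id, which makes the clustering
#' deterministic and invariant to input order.
#'
#' @param ann [genome_annotation()] holding the transcripts to cluster (one
#'   category at a time, e.g. the lincRNA candidates).
#' @return named character vector mapping transcript_id to locus_id.
#' @export
cluster_loci <- function(ann) {
  tx_ids <- sort(ann$transcripts$transcript_id)
  if (length(tx_ids) == 0L) return(setNames(character(), character()))
  ex <- ann$exons
  hits <- GenomicRanges::findOverlaps(ex, ex, ignore.strand = FALSE,
                                      minoverlap = 1L)
  a <- S4Vectors::mcols(ex)$transcript_id[S4Vectors::queryHits(hits)]
  b <- S4Vectors::mcols(ex)$transcript_id[S4Vectors::subjectHits(hits)]
  keep <- a != b
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = tx_ids))
  comp <- igraph::components(g)$membership
  locus <- vapply(split(names(comp), comp), function(m) min(m), character(1))
  out <- locus[as.character(comp[tx_ids])]
  names(out) <- tx_ids
  out
}

#' Gap distance between two genomic intervals
#'
#' Distance is the number of bases strictly between the intervals: touching
#' intervals (no gap) are at distance 0, overlapping intervals return -1, and
#' intervals on different chromosomes return `Inf`.
#'
#' @param chrom_a,start_a,end_a first interval (1-based closed).
#' @param chrom_b,start_b,end_b second interval.
#' @return numeric scalar: gap in bp, `-1` for overlap, `Inf` across
#'   chromosomes.
#' @export
gene_distance <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  if (chrom_a != chrom_b) return(Inf)
  if (start_a <= end_b && start_b <= end_a) return(-1)
  max(start_a, start_b) - min(end_a, end_b) - 1
}
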