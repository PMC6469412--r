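#' Filtering funnel parameters
#'
#' Thresholds of the stepwise lncRNA discovery funnel. All comparisons follow
#' the stringent published convention: "longer than" and score cutoffs are
#' strict, the expression floor (FPKM >= 1) is inclusive.
#'
#' @param min_length_nt minimum spliced length; transcripts of length
#'   `<= min_length_nt` are rejected (default 200 nt).
#' @param max_monoexon_length_nt single-exon transcripts strictly longer than
#'   this are rejected (default 10000 nt).
#' @param min_fpkm expression floor counted as "expressed" (default 1.0).
#' @param min_expressed_samples minimum number of samples at or above
#'   `min_fpkm`, pooled across groups (default 2).
#' @param homology_evalue_max hits strictly below this E-value against any
#'   homology database cause rejection (default 1e-5).
#' @param coding_votes_to_reject minimum number of coding votes (of 5 tools)
#'   that marks a transcript protein-coding (default 3).
#' @param orf_reject_aa transcripts whose longest ORF is `>= orf_reject_aa`
#'   amino acids are rejected (default 300).
#' @param min_gene_distance_nt intergenic candidates strictly closer than
#'   this to a protein-coding gene are rejected (default 1000 bp).
#' @param domain_evalue_max optional E-value cutoff for protein-domain hits;
#'   `NULL` (default) rejects on any reported domain hit.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_length_nt = 200,
                          max_monoexon_length_nt = 10000,
                          min_fpkm = 1.0,
                          min_expressed_samples = 2L,
                          homology_evalue_max = 1e-5,
                          coding_votes_to_reject = 3L,
                          orf_reject_aa = 300L,
                          min_gene_distance_nt = 1000L,
                          domain_evalue_max = NULL) {
  p <- list(min_length_nt = min_length_nt,
            max_monoexon_length_nt = max_monoexon_length_nt,
            min_fpkm = min_fpkm,
            min_expressed_samples = as.integer(min_expressed_samples),
            homology_evalue_max = homology_evalue_max,
            coding_votes_to_reject = as.integer(coding_votes_to_reject),
            orf_reject_aa = as.integer(orf_reject_aa),
            min_gene_distance_nt = as.integer(min_gene_distance_nt),
            domain_evalue_max = domain_evalue_max)
  stopifnot(p$min_length_nt > 0, p$max_monoexon_length_nt > 0,
            p$min_fpkm > 0, p$min_expressed_samples > 0,
            p$homology_evalue_max > 0, p$coding_votes_to_reject <= 5)
  class(p) <- "filter_params"
  p
}

#' Structural filter: length, single-exon length, single-exon repeat overlap
#'
#' @param tx one row of `genome_annotation$transcripts`.
#' @param tx_exons `GRanges` of the transcript's exons.
#' @param repeats `GRanges` of simple-repeat intervals (may be empty).
#' @param p [filter_params()].
#' @return `"keep"` or a rejection reason: `"min_length"`,
#'   `"monoexon_too_long"`, `"monoexon_repeat"`.
#' @export
structural_filter <- function(tx, tx_exons, repeats, p = filter_params()) {
  len <- tx$spliced_length[1]
  if (len <= p$min_length_nt) return("min_length")
  if (tx$n_exons[1] == 1L) {
    if (len > p$max_monoexon_length_nt) return("monoexon_too_long")
    if (length(repeats) > 0L &&
        any(IRanges::overlapsAny(tx_exons, repeats, ignore.strand = TRUE)))
      return("monoexon_repeat")
  }
  "keep"
}

#' Expression filter: expressed (FPKM >= floor) in enough samples
#'
#' Samples are pooled across groups; a transcript absent from the matrix is
#' rejected with its own reason.
#'
#' @param t_id transcript id.
#' @param expr an [expression_matrix()].
#' @param p [filter_params()].
#' @return `"keep"`, `"low_expression"` or `"missing_expression"`.
#' @export
expression_filter <- function(t_id, expr, p = filter_params()) {
  if (!(t_id %in% rownames(expr$values))) return("missing_expression")
  n_expr <- sum(expr$values[t_id, ] >= p$min_fpkm)
  if (n_expr >= p$min_expressed_samples) "keep" else "low_expression"
}

#' Homology filter: significant hit in any noncoding/protein database
#'
#' Rejects on any hit with E-value strictly below the cutoff against any of
#' the searched databases (protein knowledgebase, miRNA and RNA-family
#' catalogs). Protein-domain hits are handled by [domain_filter()].
#'
#' @param hits data.frame of the transcript's hits with column `evalue`
#'   (zero rows = no hits).
#' @param p [filter_params()].
#' @return `"keep"` or `"homology_hit"`.
#' @export
homology_filter <- function(hits, p = filter_params()) {
  if (!is.null(hits) && nrow(hits) > 0L &&
      any(hits$evalue < p$homology_evalue_max)) "homology_hit" else "keep"
}

#' Protein-domain filter
#'
#' Rejects on any reported domain hit; an optional E-value cutoff restricts
#' which hits count (default: all reported hits count).
#'
#' @param domain_hits data.frame with column `evalue` (zero rows = none).
#' @param p [filter_params()].
#' @return `"keep"` or `"domain_hit"`.
#' @export
domain_filter <- function(domain_hits, p = filter_params()) {
  if (is.null(domain_hits) || nrow(domain_hits) == 0L) return("keep")
  if (!is.null(p$domain_evalue_max) &&
      !any(domain_hits$evalue < p$domain_evalue_max)) return("keep")
  "domain_hit"
}

#' Coding-potential majority vote over five tools
#'
#' Each tool casts a coding vote under its published decision rule: CPC2
#' score > 0.5, CNCI score > 0, CPAT score > 0.36, PLEK score > 0, and a
#' binary FEElnc label. All score thresholds are strict. A missing FEElnc
#' label counts as a noncoding vote. The verdict is `coding` when at least
#' `votes_to_reject` (default 3) tools vote coding.
#'
#' @param cpc2,cnci,cpat,plek numeric tool scores.
#' @param feelnc one of `"coding"`, `"noncoding"`, `"missing"`.
#' @param votes_to_reject majority threshold (default 3).
#' @return list with `votes` (integer 0-5) and `verdict`
#'   (`"coding"`/`"noncoding"`).
#' @export
coding_vote <- function(cpc2, cnci, cpat, plek, feelnc = "noncoding",
                        votes_to_reject = 3L) {
  stopifnot(is.numeric(cpc2), is.numeric(cnci), is.numeric(cpat),
            is.numeric(plek))
  if (!feelnc %in% c("coding", "noncoding", "missing"))
    stop("invalid FEElnc label: ", feelnc)
  votes <- sum(cpc2 > 0.5, cnci > 0, cpat > 0.36, plek > 0,
               feelnc == "coding")
  list(votes = as.integer(votes),
       verdict = if (votes >= votes_to_reject) "coding" else "noncoding")
}

#' Longest open reading frame on the sense strand
#'
#' Scans the three sense-strand frames. An ORF starts at ATG and runs to the
#' first in-frame stop codon (TAA/TAG/TGA), its length counted in codons from
#' the ATG up to but excluding the stop. An ATG with no downstream in-frame
#' stop also counts as a 3'-partial ORF running to the last complete codon.
#' Returns 0 when no ATG-initiated ORF exists.
#'
#' @param seq nucleotide string over `A`, `C`, `G`, `T`, `N` (case
#'   insensitive).
#' @return integer: longest ORF length in amino acids.
#' @export
find_longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) return(0L)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 1L) next
    pos <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seq, pos, pos + 2L)
    is_start <- codons == "ATG"
    if (!any(is_start)) next
    is_stop <- codons %in% stops
    # for each codon index, index of next stop at or after it
    next_stop <- rev(cummin(rev(ifelse(is_stop, seq_len(n_codons),
                                       n_codons + 1L))))
    starts <- which(is_start)
    lens <- ifelse(next_stop[starts] <= n_codons,
                   next_stop[starts] - starts,          # complete ORF
                   n_codons - starts + 1L)              # 3'-partial ORF
    best <- max(best, max(lens))
  }
  as.integer(best)
}

#' Proximity filter for intergenic candidates
#'
#' Rejects an intergenic candidate whose span lies strictly closer than the
#' cutoff (default 1 kb) to any protein-coding gene span on the same
#' chromosome.
#'
#' @param tx one row of `genome_annotation$transcripts` (class u candidate).
#' @param ref reference [genome_annotation()].
#' @param p [filter_params()].
#' @return `"keep"` or `"near_coding_gene"`.
#' @export
proximity_filter <- function(tx, ref, p = filter_params()) {
  genes <- ref$genes[S4Vectors::mcols(ref$genes)$biotype == "protein_coding"]
  genes <- genes[as.character(GenomicRanges::seqnames(genes)) == tx$chrom[1]]
  if (length(genes) == 0L) return("keep")
  d <- vapply(seq_along(genes), function(i)
    gene_distance(tx$chrom[1], tx$start[1], tx$end[1],
                  tx$chrom[1], GenomicRanges::start(genes)[i],
                  GenomicRanges::end(genes)[i]), numeric(1))
  if (any(d < p$min_gene_distance_nt)) "near_coding_gene" else "keep"
}

#' Run the complete lncRNA discovery funnel
#'
#' Applies, in order: positional class selection (keep intergenic `u` and
#' intronic `i` transcripts only), the structural filter, the expression
#' filter, the homology filter, the protein-domain filter, the
#' coding-potential majority vote, the ORF-length filter, and (for
#' intergenic candidates only) the gene-proximity filter. Survivors are
#' classified as lincRNA (class u) or ilncRNA (class i), and optionally
#' flagged when they overlap a previously reported lncRNA catalog by at
#' least 1 bp of exonic overlap.
#'
#' @param assembled [genome_annotation()] of assembled transcripts; known
#'   (annotated) transcripts may be present and are set aside by the class
#'   step.
#' @param ref reference [genome_annotation()].
#' @param repeats `GRanges` of simple repeats.
#' @param expr [expression_matrix()].
#' @param evidence list with data.frames `hits` (transcript_id, db, evalue),
#'   `domains` (transcript_id, domain_id, evalue), `scores` (transcript_id,
#'   cpc2, cnci, cpat, plek, feelnc); all keyed by transcript_id.
#' @param sequences named character vector of transcript sequences (used to
#'   compute ORF length); ids missing a sequence are an error.
#' @param p [filter_params()].
#' @param known_lnc_catalog optional `GRanges` of previously reported lncRNA
#'   exons; candidates with >= 1 bp exonic overlap are flagged.
#' @return list with components:
#'   \describe{
#'     \item{candidates}{data.frame: `transcript_id`, `gene_id`, `chrom`,
#'       `start`, `end`, `strand`, `category` (`lincRNA`/`ilncRNA`),
#'       `locus_id`, `previously_reported` (logical).}
#'     \item{report}{data.frame funnel report: `step`, `input_count`,
#'       `removed_count`, `surviving_count`.}
#'     \item{survivor_ids}{list of surviving transcript ids per step.}
#'     \item{rejected}{data.frame: `transcript_id`, `step`, `reason`.}
#'   }
#' @export
run_funnel <- function(assembled, ref, repeats, expr, evidence, sequences,
                       p = filter_params(), known_lnc_catalog = NULL) {
  tx <- assembled$transcripts
  rejected <- list()
  steps <- list()
  survivors <- sort(tx$transcript_id)

  note_step <- function(name, before, after, reasons) {
    steps[[length(steps) + 1L]] <<- list(step = name,
                                         input_count = length(before),
                                         removed_count = length(before) - length(after),
                                         surviving = after)
    dropped <- setdiff(before, after)
    if (length(dropped))
      rejected[[length(rejected) + 1L]] <<- data.frame(
        transcript_id = dropped, step = name,
        reason = reasons[dropped], stringsAsFactors = FALSE)
  }

  if (nrow(tx) == 0L) {
    report <- data.frame(step = character(), input_count = integer(),
                         removed_count = integer(),
                         surviving_count = integer(),
                         stringsAsFactors = FALSE)
    return(list(candidates = data.frame(), report = report,
                survivor_ids = list(),
                rejected = data.frame(transcript_id = character(),
                                      step = character(), reason = character(),
                                      stringsAsFactors = FALSE)))
  }

  # step 0: positional class selection -------------------------------------
  codes <- classify_transcripts(assembled, ref)
  keep <- survivors[codes[survivors] %in% c("u", "i")]
  reasons <- setNames(paste0("class_", codes[survivors]), survivors)
  note_step("class_selection", survivors, keep, reasons)
  survivors <- keep

  # step 1: structural ------------------------------------------------------
  ex_tid <- S4Vectors::mcols(assembled$exons)$transcript_id
  verdicts <- vapply(survivors, function(id) {
    structural_filter(tx[tx$transcript_id == id, ],
                      assembled$exons[ex_tid == id], repeats, p)
  }, character(1))
  keep <- survivors[verdicts == "keep"]
  note_step("structural", survivors, keep, verdicts)
  survivors <- keep

  # step 2: expression ------------------------------------------------------
  verdicts <- vapply(survivors, expression_filter, character(1),
                     expr = expr, p = p)
  keep <- survivors[verdicts == "keep"]
  note_step("expression", survivors, keep, verdicts)
  survivors <- keep

  # consistency of evidence tables
  ev_ids <- unique(evidence$scores$transcript_id)
  missing_ev <- setdiff(survivors, ev_ids)
  if (length(missing_ev))
    stop("transcripts without coding-potential scores: ",
         paste(utils::head(missing_ev, 5), collapse = ", "))

  # step 3: homology ---------------------------------------------------------
  verdicts <- vapply(survivors, function(id)
    homology_filter(evidence$hits[evidence$hits$transcript_id == id, ,
                                  drop = FALSE], p), character(1))
  keep <- survivors[verdicts == "keep"]
  note_step("homology", survivors, keep, verdicts)
  survivors <- keep

  # step 4: protein domains --------------------------------------------------
  verdicts <- vapply(survivors, function(id)
    domain_filter(evidence$domains[evidence$domains$transcript_id == id, ,
                                   drop = FALSE], p), character(1))
  keep <- survivors[verdicts == "keep"]
  note_step("domains", survivors, keep, verdicts)
  survivors <- keep

  # step 5: coding-potential vote --------------------------------------------
  sc <- evidence$scores
  verdicts <- vapply(survivors, function(id) {
    row <- sc[sc$transcript_id == id, ]
    v <- coding_vote(row$cpc2, row$cnci, row$cpat, row$plek, row$feelnc,
                     p$coding_votes_to_reject)
    if (v$verdict == "coding") "coding_vote" else "keep"
  }, character(1))
  keep <- survivors[verdicts == "keep"]
  note_step("coding_vote", survivors, keep, verdicts)
  survivors <- keep

  # step 6: ORF length ---------------------------------------------------------
  missing_seq <- setdiff(survivors, names(sequences))
  if (length(missing_seq))
    stop("transcripts without sequence: ",
         paste(utils::head(missing_seq, 5), collapse = ", "))
  verdicts <- vapply(survivors, function(id) {
    if (find_longest_orf(sequences[[id]]) >= p$orf_reject_aa)
      "long_orf" else "keep"
  }, character(1))
  keep <- survivors[verdicts == "keep"]
  note_step("orf", survivors, keep, verdicts)
  survivors <- keep

  # step 7: proximity (intergenic candidates only) -----------------------------
  verdicts <- vapply(survivors, function(id) {
    if (codes[id] != "u") return("keep")
    proximity_filter(tx[tx$transcript_id == id, ], ref, p)
  }, character(1))
  keep <- survivors[verdicts == "keep"]
  note_step("proximity", survivors, keep, verdicts)
  survivors <- keep

  # final classification -----------------------------------------------------
  cand_tx <- tx[match(survivors, tx$transcript_id), , drop = FALSE]
  category <- ifelse(codes[survivors] == "u", "lincRNA", "ilncRNA")

  prev <- rep(FALSE, length(survivors))
  if (!is.null(known_lnc_catalog) && length(known_lnc_catalog) > 0L &&
      length(survivors) > 0L) {
    prev <- vapply(survivors, function(id) {
      any(IRanges::overlapsAny(assembled$exons[ex_tid == id],
                               known_lnc_catalog, ignore.strand = TRUE))
    }, logical(1))
  }

  loci <- if (length(survivors) > 0L) {
    keep_ex <- assembled$exons[ex_tid %in% survivors]
    sub <- genome_annotation(data.frame(
      chrom = as.character(GenomicRanges::seqnames(keep_ex)),
      start = GenomicRanges::start(keep_ex),
      end = GenomicRanges::end(keep_ex),
      strand = as.character(GenomicRanges::strand(keep_ex)),
      transcript_id = S4Vectors::mcols(keep_ex)$transcript_id,
      gene_id = S4Vectors::mcols(keep_ex)$gene_id,
      stringsAsFactors = FALSE))
    cluster_loci(sub)
  } else setNames(character(), character())

  candidates <- data.frame(
    transcript_id = survivors,
    gene_id = cand_tx$gene_id,
    chrom = cand_tx$chrom, start = cand_tx$start, end = cand_tx$end,
    strand = cand_tx$strand,
    category = category,
    locus_id = unname(loci[survivors]),
    previously_reported = unname(prev),
    stringsAsFactors = FALSE)
  rownames(candidates) <- NULL

  report <- data.frame(
    step = vapply(steps, `[[`, character(1), "step"),
    input_count = vapply(steps, `[[`, integer(1), "input_count"),
    removed_count = vapply(steps, `[[`, integer(1), "removed_count"),
    surviving_count = vapply(steps, function(s) length(s$surviving),
                             integer(1)),
    stringsAsFactors = FALSE)

  rejected_df <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(transcript_id = character(), step = character(),
               reason = character(), stringsAsFactors = FALSE)
  rownames(rejected_df) <- NULL

  list(candidates = candidates, report = report,
       survivor_ids = setNames(lapply(steps, `[[`, "surviving"),
                               report$step),
       rejected = rejected_df)
}
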