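#' Cis targets: nearest protein-coding genes within a window
#'
#' Reports the nearest protein-coding gene strictly to the left and strictly
#' to the right of an intergenic lncRNA's span, each only when the gap is at
#' most `window` bp (default 100 kb). Equidistant genes on one side are all
#' reported.
#'
#' @param lnc one row of a candidate table with `chrom`, `start`, `end`,
#'   `transcript_id` (or `lnc_id`).
#' @param ref reference [genome_annotation()].
#' @param window maximum gap in bp (default 1e5).
#' @return data.frame of target assignments: `lnc_id`, `gene_id`, `mode`
#'   (`cis_left`/`cis_right`), `distance_bp` (zero rows when nothing is in
#'   range).
#' @export
cis_targets <- function(lnc, ref, window = 100000) {
  lnc_id <- if (!is.null(lnc$lnc_id)) lnc$lnc_id[1] else lnc$transcript_id[1]
  genes <- ref$genes[S4Vectors::mcols(ref$genes)$biotype == "protein_coding"]
  genes <- genes[as.character(GenomicRanges::seqnames(genes)) == lnc$chrom[1]]
  empty <- data.frame(lnc_id = character(), gene_id = character(),
                      mode = character(), distance_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (length(genes) == 0L) return(empty)
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  gid <- S4Vectors::mcols(genes)$gene_id
  out <- empty
  left <- which(ge < lnc$start[1])
  if (length(left)) {
    d <- lnc$start[1] - ge[left] - 1
    keep <- left[d == min(d)]
    if (min(d) <= window)
      out <- rbind(out, data.frame(lnc_id = lnc_id, gene_id = gid[keep],
                                   mode = "cis_left", distance_bp = min(d),
                                   stringsAsFactors = FALSE))
  }
  right <- which(gs > lnc$end[1])
  if (length(right)) {
    d <- gs[right] - lnc$end[1] - 1
    keep <- right[d == min(d)]
    if (min(d) <= window)
      out <- rbind(out, data.frame(lnc_id = lnc_id, gene_id = gid[keep],
                                   mode = "cis_right", distance_bp = min(d),
                                   stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Host gene of an intronic lncRNA
#'
#' The protein-coding gene one of whose transcripts' introns contains the
#' whole ilncRNA span. For an intronic candidate both flanks are the host
#' itself.
#'
#' @param ilnc one row with `chrom`, `start`, `end`, `transcript_id`.
#' @param ref reference [genome_annotation()].
#' @return data.frame with one row: `lnc_id`, `gene_id`, `mode = "host"`.
#' @export
host_gene <- function(ilnc, ref) {
  lnc_id <- if (!is.null(ilnc$lnc_id)) ilnc$lnc_id[1] else
    ilnc$transcript_id[1]
  introns <- ref$introns
  coding_tx <- ref$transcripts$transcript_id[
    ref$transcripts$biotype == "protein_coding"]
  introns <- introns[S4Vectors::mcols(introns)$transcript_id %in% coding_tx]
  hit <- as.character(GenomicRanges::seqnames(introns)) == ilnc$chrom[1] &
    GenomicRanges::start(introns) <= ilnc$start[1] &
    GenomicRanges::end(introns) >= ilnc$end[1]
  hosts <- unique(S4Vectors::mcols(introns)$gene_id[hit])
  if (length(hosts) == 0L)
    stop("no containing intron for intronic candidate ", lnc_id)
  data.frame(lnc_id = lnc_id, gene_id = hosts[1], mode = "host",
             stringsAsFactors = FALSE)
}

#' Trans targets by all-pairs Pearson correlation
#'
#' Tests every lncRNA-mRNA pair: a pair is a trans target when the absolute
#' Pearson correlation across samples strictly exceeds `r_min` and the
#' two-sided p-value from the exact t-distribution of
#' t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom is strictly below
#' `p_max`. Zero-variance profiles are skipped.
#'
#' @param lnc_expr numeric matrix, lncRNAs x samples.
#' @param mrna_expr numeric matrix, mRNA genes x samples (same columns).
#' @param r_min correlation magnitude threshold, strict (default 0.99).
#' @param p_max p-value threshold, strict (default 5e-5).
#' @return data.frame: `lnc_id`, `gene_id`, `mode = "trans"`, `r`, `p_value`.
#' @export
trans_targets <- function(lnc_expr, mrna_expr, r_min = 0.99,
                          p_max = 0.00005) {
  stopifnot(is.matrix(lnc_expr), is.matrix(mrna_expr))
  if (ncol(lnc_expr) != ncol(mrna_expr))
    stop("sample columns differ between matrices")
  n <- ncol(lnc_expr)
  if (n < 3L) stop("at least 3 paired samples required")
  var_l <- apply(lnc_expr, 1, stats::var)
  var_m <- apply(mrna_expr, 1, stats::var)
  lnc_expr <- lnc_expr[var_l > 0, , drop = FALSE]
  mrna_expr <- mrna_expr[var_m > 0, , drop = FALSE]
  empty <- data.frame(lnc_id = character(), gene_id = character(),
                      mode = character(), r = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(lnc_expr) == 0L || nrow(mrna_expr) == 0L) return(empty)
  r <- stats::cor(t(lnc_expr), t(mrna_expr))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  hit <- which(abs(r) > r_min & p < p_max, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  out <- data.frame(
    lnc_id = rownames(lnc_expr)[hit[, 1]],
    gene_id = rownames(mrna_expr)[hit[, 2]],
    mode = "trans",
    r = r[hit], p_value = p[hit],
    stringsAsFactors = FALSE)
  out <- out[order(out$lnc_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' All target assignments for a candidate table
#'
#' Runs [cis_targets()] for every lincRNA, [host_gene()] for every ilncRNA,
#' and [trans_targets()] over the expression matrices when supplied.
#'
#' @param candidates candidate data.frame from [run_funnel()].
#' @param ref reference [genome_annotation()].
#' @param lnc_expr,mrna_expr optional matrices for the trans step.
#' @param window cis window (default 1e5).
#' @param r_min,p_max trans thresholds.
#' @return data.frame with columns `lnc_id`, `gene_id`, `mode`,
#'   `distance_bp`, `r`, `p_value` (NA where not applicable).
#' @export
predict_targets <- function(candidates, ref, lnc_expr = NULL,
                            mrna_expr = NULL, window = 100000,
                            r_min = 0.99, p_max = 0.00005) {
  rows <- list()
  pad <- function(df) {
    for (col in c("distance_bp", "r", "p_value"))
      if (is.null(df[[col]])) df[[col]] <- NA_real_
    df[, c("lnc_id", "gene_id", "mode", "distance_bp", "r", "p_value")]
  }
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    if (cand$category == "lincRNA") {
      ct <- cis_targets(cand, ref, window)
      if (nrow(ct)) rows[[length(rows) + 1L]] <- pad(ct)
    } else {
      rows[[length(rows) + 1L]] <- pad(host_gene(cand, ref))
    }
  }
  if (!is.null(lnc_expr) && !is.null(mrna_expr)) {
    tt <- trans_targets(lnc_expr, mrna_expr, r_min, p_max)
    if (nrow(tt)) rows[[length(rows) + 1L]] <- pad(tt)
  }
  if (!length(rows))
    return(data.frame(lnc_id = character(), gene_id = character(),
                      mode = character(), distance_bp = numeric(),
                      r = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
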