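#' Bundled worked-example tables
#'
#' Two small tables transcribed from a published sheep fat-tail RNA-seq
#' comparison of a fat-tailed and a thin-tailed breed, used as worked
#' examples throughout the package:
#' \describe{
#'   \item{de}{the eight differentially expressed novel lncRNAs with their
#'     per-breed mean FPKM (`mean_a` = fat-tailed breed, `mean_b` =
#'     thin-tailed breed), FDR and flanking mRNAs.}
#'   \item{qtl}{the seven novel lncRNA loci reported inside
#'     "Tail fat deposition" QTL intervals, with both the lncRNA and the
#'     QTL coordinates (1-based inclusive).}
#' }
#'
#' @param which `"de"` or `"qtl"`.
#' @return a data.frame.
#' @export
example_table <- function(which = c("de", "qtl")) {
  which <- match.arg(which)
  fname <- switch(which, de = "sheep_de_lncRNAs.tsv",
                  qtl = "sheep_tail_fat_qtl.tsv")
  path <- system.file("extdata", fname, package = "lncfunnel",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(c("qtl_id", "chrom", "qtl_chrom"), names(df)))
    df[[col]] <- as.character(df[[col]])
  df
}
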