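#' Read a QTL table
#'
#' Accepts either a 5-column TSV (`qtl_id`, `trait`, `chrom`, `start`,
#' `end`) or a GFF-like dump whose attribute column carries `QTL_ID` and
#' `Name`/`trait`. Coordinates are 1-based inclusive, the convention of
#' animal QTL databases. Chromosome names are normalized by stripping a
#' leading `Chr.`/`chr` prefix.
#'
#' @param path file path.
#' @return data.frame `qtl_id`, `trait`, `chrom`, `start`, `end`, `span`.
#' @export
read_qtl <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\tQTL\t|gff-version", first) ||
      grepl("QTL_ID=", paste(readLines(path, n = 5), collapse = ""))) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t")
    df <- do.call(rbind, lapply(parts, function(p) {
      attr_get <- function(key) {
        m <- regmatches(p[9], regexec(paste0(key, "=([^;]+)"), p[9]))[[1]]
        if (length(m) == 2) m[2] else NA_character_
      }
      data.frame(qtl_id = attr_get("QTL_ID"),
                 trait = ifelse(is.na(attr_get("trait")), attr_get("Name"),
                                attr_get("trait")),
                 chrom = p[1], start = as.integer(p[4]),
                 end = as.integer(p[5]), stringsAsFactors = FALSE)
    }))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("qtl_id", "trait", "chrom", "start", "end") %in%
                    names(df)))
  }
  df$chrom <- sub("^[Cc]hr\\.?", "", df$chrom)
  df$qtl_id <- as.character(df$qtl_id)
  df$span <- df$end - df$start + 1L
  df
}

#' Containment of an lncRNA gene locus within a QTL interval
#'
#' True iff the locus and the QTL share a chromosome and both the locus
#' start and end fall within the QTL interval (1-based inclusive on both
#' sides). Partial overlap does not count.
#'
#' @param lnc_chrom,lnc_start,lnc_end locus coordinates.
#' @param qtl one row of a [read_qtl()] table.
#' @return logical.
#' @export
qtl_contains <- function(lnc_chrom, lnc_start, lnc_end, qtl) {
  as.character(lnc_chrom) == as.character(qtl$chrom[1]) &&
    lnc_start >= qtl$start[1] && lnc_end <= qtl$end[1]
}

#' Annotate lncRNA gene loci with containing QTL
#'
#' All (locus, QTL) containment pairs, optionally restricted to QTL whose
#' trait contains a substring and/or whose span is strictly below a
#' ceiling.
#'
#' @param lncs data.frame of loci: `lnc_id`, `chrom`, `start`, `end` and
#'   optionally `category`.
#' @param qtls data.frame from [read_qtl()].
#' @param trait_filter optional substring to match against `trait`.
#' @param max_qtl_span optional span ceiling in bp, strict (`span <
#'   max_qtl_span`).
#' @return data.frame `lnc_id`, `category`, `qtl_id`, `trait`, `qtl_span`.
#' @export
qtl_annotate <- function(lncs, qtls, trait_filter = NULL,
                         max_qtl_span = NULL) {
  if (!is.null(trait_filter))
    qtls <- qtls[grepl(trait_filter, qtls$trait, fixed = TRUE), ,
                 drop = FALSE]
  if (!is.null(max_qtl_span))
    qtls <- qtls[(qtls$end - qtls$start + 1L) < max_qtl_span, ,
                 drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(lncs))) {
    for (j in seq_len(nrow(qtls))) {
      if (qtl_contains(lncs$chrom[i], lncs$start[i], lncs$end[i],
                       qtls[j, ])) {
        out[[length(out) + 1L]] <- data.frame(
          lnc_id = lncs$lnc_id[i],
          category = if (!is.null(lncs$category)) lncs$category[i]
            else NA_character_,
          qtl_id = qtls$qtl_id[j], trait = qtls$trait[j],
          qtl_span = qtls$end[j] - qtls$start[j] + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(lnc_id = character(), category = character(),
                      qtl_id = character(), trait = character(),
                      qtl_span = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$lnc_id, res$qtl_id), ]
  rownames(res) <- NULL
  res
}
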