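#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set id, description, member genes).
#' @return named list of character vectors (members per set id).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (any(lengths(sets) == 0L)) stop("empty gene set in ", path)
  sets
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment.
#'
#' @param pvalues numeric vector in [0,1].
#' @return adjusted values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values outside [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis against gene-set collections
#'
#' For each set, the hypergeometric upper-tail probability of drawing at
#' least the observed overlap: population = background, successes = set
#' intersected with background, draws = query. Adjustment across all tested
#' sets by Benjamini-Hochberg; significant iff fdr < `fdr_max`.
#'
#' @param query character vector of query gene ids (must be a subset of
#'   `background`).
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param background character vector of background gene ids.
#' @param fdr_max significance ceiling, strict (default 0.05).
#' @return data.frame `set_id`, `set_size`, `overlap`, `p`, `fdr`,
#'   `significant`, sorted by p.
#' @export
ora <- function(query, sets, background, fdr_max = 0.05) {
  query <- unique(query)
  background <- unique(background)
  if (length(query) == 0L) stop("empty query gene set")
  stray <- setdiff(query, background)
  if (length(stray)) stop("query genes outside background: ",
                          paste(utils::head(stray, 5), collapse = ", "))
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], background)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$fdr < fdr_max
  out <- out[order(out$p, out$set_id), ]
  rownames(out) <- NULL
  out
}
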