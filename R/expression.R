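#' @importFrom stats setNames cor pt phyper wilcox.test p.adjust rnorm runif rbinom
NULL

#' Construct an expression matrix with a sample grouping
#'
#' @param values numeric matrix of FPKM values, features in rows, samples in
#'   columns; dimnames required; no negative values.
#' @param groups named character vector mapping sample id to group (breed)
#'   label; must cover every column.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("negative FPKM values")
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) stop("samples without group label: ",
                            paste(missing, collapse = ", "))
  obj <- list(values = values, groups = groups[colnames(values)])
  class(obj) <- "expression_matrix"
  obj
}

#' Read an expression TSV (feature x sample) plus a group map TSV
#'
#' @param path TSV with first column `feature_id`, remaining columns samples.
#' @param groups_path two-column TSV `sample`, `group`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, groups_path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  expression_matrix(m, setNames(g$group, g$sample))
}

#' Breed-specific expression call for one feature
#'
#' A feature is specific to breed X iff at least two samples of X are
#' expressed (FPKM at or above `expressed_min_fpkm`) and every sample of the
#' other breed is silent (FPKM strictly below `silent_max_fpkm`). The two
#' conditions cannot hold for both breeds simultaneously, so the call is
#' mutually exclusive by construction.
#'
#' @param feature feature id.
#' @param expr an [expression_matrix()] with exactly two groups.
#' @param expressed_min_fpkm expression floor (default 1.0).
#' @param silent_max_fpkm silence ceiling (default 1.0).
#' @param min_expressed_samples samples required at the floor (default 2).
#' @return the breed label, or `NA_character_` when not breed-specific.
#' @export
breed_specific <- function(feature, expr, expressed_min_fpkm = 1.0,
                           silent_max_fpkm = 1.0,
                           min_expressed_samples = 2L) {
  if (!(feature %in% rownames(expr$values)))
    stop("feature not in expression matrix: ", feature)
  breeds <- unique(expr$groups)
  if (length(breeds) != 2L) stop("breed-specificity requires two groups")
  v <- expr$values[feature, ]
  for (b in breeds) {
    other <- setdiff(breeds, b)
    if (sum(v[expr$groups == b] >= expressed_min_fpkm) >= min_expressed_samples &&
        all(v[expr$groups == other] < silent_max_fpkm))
      return(b)
  }
  NA_character_
}

#' Breed-specific calls for all features of a matrix
#'
#' @inheritParams breed_specific
#' @return named character vector (NA = not specific) per feature.
#' @export
breed_specific_all <- function(expr, expressed_min_fpkm = 1.0,
                               silent_max_fpkm = 1.0,
                               min_expressed_samples = 2L) {
  vapply(rownames(expr$values), breed_specific, character(1), expr = expr,
         expressed_min_fpkm = expressed_min_fpkm,
         silent_max_fpkm = silent_max_fpkm,
         min_expressed_samples = min_expressed_samples)
}

#' Threshold a differential-expression table and call directions
#'
#' Consumes a Cuffdiff-like table of per-feature group means and FDR values.
#' Features at `fdr <= fdr_max` are differentially expressed; the direction
#' is `up` when the first group's mean exceeds the second's. Rows where one
#' group mean is zero and the other positive are additionally flagged as
#' specifically expressed within the DE set.
#'
#' @param table data.frame with columns `id`, `mean_a`, `mean_b`, `fdr`.
#' @param fdr_max FDR ceiling, inclusive (default 0.1).
#' @return data.frame of DE records: `id`, `mean_a`, `mean_b`, `fdr`,
#'   `direction` (`up`/`down` relative to group A), `specific`
#'   (`"a"`, `"b"` or `NA`).
#' @export
classify_de <- function(table, fdr_max = 0.1) {
  stopifnot(all(c("id", "mean_a", "mean_b", "fdr") %in% names(table)))
  if (any(table$fdr < 0 | table$fdr > 1)) stop("FDR outside [0,1]")
  de <- table[table$fdr <= fdr_max, , drop = FALSE]
  de$direction <- ifelse(de$mean_a > de$mean_b, "up", "down")
  de$specific <- ifelse(de$mean_a == 0 & de$mean_b > 0, "b",
                 ifelse(de$mean_b == 0 & de$mean_a > 0, "a", NA_character_))
  rownames(de) <- NULL
  de
}

#' Relative expression by the comparative Ct method (2^-ddCt)
#'
#' Per sample, dCt = Ct(target) - Ct(reference housekeeping gene); ddCt is
#' the mean dCt of the test condition minus the mean dCt of the baseline;
#' the fold change is 2^-ddCt.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct_target`,
#'   `ct_reference`, `condition`.
#' @param baseline baseline condition label.
#' @return data.frame `gene`, `condition`, `fold_change` for every
#'   non-baseline condition.
#' @export
ddct_fold_change <- function(ct, baseline) {
  stopifnot(all(c("sample", "gene", "ct_target", "ct_reference",
                  "condition") %in% names(ct)))
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)))
    stop("non-finite Ct value")
  if (!baseline %in% ct$condition)
    stop("baseline condition absent: ", baseline)
  ct$dct <- ct$ct_target - ct$ct_reference
  out <- list()
  for (g in unique(ct$gene)) {
    sub <- ct[ct$gene == g, ]
    base_mean <- mean(sub$dct[sub$condition == baseline])
    for (cond in setdiff(unique(sub$condition), baseline)) {
      ddct <- mean(sub$dct[sub$condition == cond]) - base_mean
      out[[length(out) + 1L]] <- data.frame(
        gene = g, condition = cond, fold_change = 2^(-ddct),
        stringsAsFactors = FALSE)
    }
    # baseline vs itself is the identity, reported for completeness
    out[[length(out) + 1L]] <- data.frame(
      gene = g, condition = baseline, fold_change = 1.0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Descriptive feature statistics per transcript class
#'
#' Summaries used to compare novel candidates against annotated transcripts:
#' mean spliced length, mean exon count, GC fraction (Ns excluded), mean
#' FPKM over all samples, and the fraction of transcripts with at most two
#' exons.
#'
#' @param classes named character vector: class label per transcript_id.
#' @param ann [genome_annotation()] containing the transcripts.
#' @param sequences named character vector of transcript sequences.
#' @param expr optional [expression_matrix()] for mean FPKM.
#' @return data.frame, one row per class: `class`, `n`, `mean_length`,
#'   `mean_exons`, `gc`, `mean_fpkm`, `frac_le2_exons`.
#' @export
feature_stats <- function(classes, ann, sequences, expr = NULL) {
  tx <- ann$transcripts
  out <- lapply(sort(unique(classes)), function(cl) {
    ids <- names(classes)[classes == cl]
    t <- tx[tx$transcript_id %in% ids, , drop = FALSE]
    gc <- vapply(ids, function(id) {
      s <- toupper(sequences[[id]])
      counts <- table(strsplit(s, "")[[1]])
      acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
      if (acgt == 0) return(NA_real_)
      sum(counts[intersect(names(counts), c("G", "C"))]) / acgt
    }, numeric(1))
    fpkm <- if (!is.null(expr)) {
      present <- intersect(ids, rownames(expr$values))
      if (length(present)) mean(expr$values[present, , drop = FALSE])
      else NA_real_
    } else NA_real_
    data.frame(class = cl, n = nrow(t),
               mean_length = mean(t$spliced_length),
               mean_exons = mean(t$n_exons),
               gc = mean(gc, na.rm = TRUE),
               mean_fpkm = fpkm,
               frac_le2_exons = mean(t$n_exons <= 2L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
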