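# Independent brute-force oracles used against the implementation.

# longest ORF by walking every ATG codon by codon
orf_oracle <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- 0L
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(seq, i, i + 2) != "ATG") next
    len <- 0L
    j <- i
    while (j + 2 <= n) {
      codon <- substr(seq, j, j + 2)
      if (len > 0L && codon %in% c("TAA", "TAG", "TGA")) break
      len <- len + 1L
      j <- j + 3L
    }
    best <- max(best, len)
  }
  best
}

# interval overlap by explicit base enumeration (small coordinates only)
bases <- function(start, end) seq.int(start, end)
overlap_bases <- function(s1, e1, s2, e2)
  length(intersect(bases(s1, e1), bases(s2, e2)))

# gap distance by scanning integer positions strictly between two intervals
distance_oracle <- function(s1, e1, s2, e2) {
  if (overlap_bases(s1, e1, s2, e2) > 0) return(-1)
  sum(!(seq.int(min(s1, s2), max(e1, e2)) %in% c(bases(s1, e1),
                                                 bases(s2, e2))))
}

# class code by exhaustive pairwise overlap enumeration
class_code_oracle <- function(q_exons, gene_spans, introns) {
  any_gene <- FALSE
  for (i in seq_len(nrow(q_exons))) {
    for (j in seq_len(nrow(gene_spans))) {
      if (q_exons$chrom[i] == gene_spans$chrom[j] &&
          overlap_bases(q_exons$start[i], q_exons$end[i],
                        gene_spans$start[j], gene_spans$end[j]) > 0)
        any_gene <- TRUE
    }
  }
  if (!any_gene) return("u")
  qs <- min(q_exons$start); qe <- max(q_exons$end)
  for (j in seq_len(nrow(introns))) {
    if (q_exons$chrom[1] == introns$chrom[j] &&
        qs >= introns$start[j] && qe <= introns$end[j])
      return("i")
  }
  "overlap"
}

# connected components of the same-strand exonic-overlap graph by
# label propagation to a fixpoint
components_oracle <- function(exons) {
  ids <- sort(unique(exons$transcript_id))
  lab <- setNames(ids, ids)
  adj <- function(a, b) {
    ea <- exons[exons$transcript_id == a, ]
    eb <- exons[exons$transcript_id == b, ]
    for (i in seq_len(nrow(ea)))
      for (j in seq_len(nrow(eb)))
        if (ea$chrom[i] == eb$chrom[j] && ea$strand[i] == eb$strand[j] &&
            overlap_bases(ea$start[i], ea$end[i], eb$start[j],
                          eb$end[j]) > 0) return(TRUE)
    FALSE
  }
  repeat {
    changed <- FALSE
    for (a in ids) for (b in ids) {
      if (a != b && adj(a, b) && lab[b] < lab[a]) {
        lab[a] <- lab[b]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# BH step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# small random annotation: genes with introns, on a couple of chromosomes
random_ref <- function(n_genes = 6, chroms = c("c1", "c2")) {
  rows <- list()
  for (g in seq_len(n_genes)) {
    ch <- sample(chroms, 1)
    start <- sample(1000:50000, 1)
    n_ex <- sample(2:4, 1)
    cur <- start
    for (k in seq_len(n_ex)) {
      len <- sample(100:300, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = cur, end = cur + len - 1L, strand = "+",
        transcript_id = sprintf("rg%02d.t1", g),
        gene_id = sprintf("rg%02d", g), biotype = "protein_coding",
        stringsAsFactors = FALSE)
      cur <- cur + len + sample(500:2000, 1)
    }
  }
  genome_annotation(do.call(rbind, rows))
}

# tiny clique-based PPI frame
clique_edges <- function(members, score = 1) {
  p <- utils::combn(members, 2)
  data.frame(protein1 = p[1, ], protein2 = p[2, ], combined_score = score,
             stringsAsFactors = FALSE)
}
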