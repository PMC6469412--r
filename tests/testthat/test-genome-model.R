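test_that("GTF reading preserves coordinates and groups exons by transcript", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("c1\tsrc\texon\t101\t200\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "tA"; gene_biotype "protein_coding";'),
    paste0("c1\tsrc\texon\t301\t400\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "tA"; gene_biotype "protein_coding";'),
    paste0("c1\tsrc\texon\t1001\t1500\t.\t-\t.\t",
           'gene_id "gB"; transcript_id "tB"; gene_biotype "lncRNA";')),
    gtf)
  ann <- read_gtf(gtf)
  tx <- ann$transcripts
  expect_equal(nrow(tx), 2)
  a <- tx[tx$transcript_id == "tA", ]
  expect_equal(a$n_exons, 2)
  expect_equal(a$spliced_length, 200)  # two 100-bp exons
  expect_equal(c(a$start, a$end), c(101, 400))
  # lncRNA biotype mapped to the annotated-lncRNA class
  expect_equal(tx$biotype[tx$transcript_id == "tB"], "known_lncRNA")
  # intron derived as the gap between consecutive exons
  expect_equal(GenomicRanges::start(ann$introns), 201)
  expect_equal(GenomicRanges::end(ann$introns), 300)
})

test_that("GTF write/read round-trip preserves a generated 50-gene annotation", {
  set.seed(11)
  rows <- list()
  for (g in 1:50) {
    ch <- sample(c("c1", "c2", "c3"), 1)
    cur <- sample(1:1e6, 1)
    for (k in seq_len(sample(1:5, 1))) {
      len <- sample(50:400, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = cur, end = cur + len - 1L,
        strand = sample(c("+", "-"), 1),
        transcript_id = sprintf("t%02d", g), gene_id = sprintf("g%02d", g),
        biotype = sample(c("protein_coding", "known_lncRNA", "novel"), 1),
        stringsAsFactors = FALSE)
      cur <- cur + len + sample(100:5000, 1)
    }
  }
  # one chrom/strand per transcript
  df <- do.call(rbind, rows)
  df <- do.call(rbind, lapply(split(df, df$transcript_id), function(e) {
    e$chrom <- e$chrom[1]; e$strand <- e$strand[1]; e$biotype <- e$biotype[1]
    e
  }))
  ann1 <- genome_annotation(df)
  path <- tempfile(fileext = ".gtf")
  write_gtf(ann1, path)
  ann2 <- read_gtf(path)
  o1 <- ann1$transcripts[order(ann1$transcripts$transcript_id), ]
  o2 <- ann2$transcripts[order(ann2$transcripts$transcript_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
  expect_equal(sort(GenomicRanges::start(ann2$exons)),
               sort(GenomicRanges::start(ann1$exons)))
  expect_equal(sort(GenomicRanges::end(ann2$exons)),
               sort(GenomicRanges::end(ann1$exons)))
})

test_that("annotation construction rejects malformed transcripts", {
  bad <- data.frame(chrom = "c1", start = 200, end = 100, strand = "+",
                    transcript_id = "t1", gene_id = "g1")
  expect_error(genome_annotation(bad), "start > end")
  two_chrom <- data.frame(chrom = c("c1", "c2"), start = c(1, 50),
                          end = c(10, 80), strand = "+",
                          transcript_id = "t1", gene_id = "g1")
  expect_error(genome_annotation(two_chrom), "multiple chromosomes")
})

make_ref_for_codes <- function() {
  # gene gA exons [1000,1200] and [3000,3500]; gene gB at [9000,12000]
  genome_annotation(data.frame(
    chrom = "c1",
    start = c(1000, 3000, 9000),
    end = c(1200, 3500, 12000),
    strand = "+",
    transcript_id = c("tA", "tA", "tB"),
    gene_id = c("gA", "gA", "gB"),
    biotype = "protein_coding", stringsAsFactors = FALSE))
}

test_that("class codes: intergenic, intronic and overlapping queries", {
  ref <- make_ref_for_codes()
  q_u <- data.frame(chrom = "c1", start = 5001, end = 5600,
                    transcript_id = "q1")
  expect_equal(assign_class_code(q_u, ref), "u")
  # entirely inside the gap between gA's exons
  q_i <- data.frame(chrom = "c1", start = 1500, end = 2500,
                    transcript_id = "q2")
  expect_equal(assign_class_code(q_i, ref), "i")
  q_o <- data.frame(chrom = "c1", start = 1100, end = 1400,
                    transcript_id = "q3")
  expect_equal(assign_class_code(q_o, ref), "overlap")
  # absent chromosome is intergenic by definition
  q_chr <- data.frame(chrom = "c9", start = 1100, end = 1400,
                      transcript_id = "q4")
  expect_equal(assign_class_code(q_chr, ref), "u")
})

test_that("class codes match the brute-force overlap oracle on random queries", {
  set.seed(21)
  ref <- random_ref(n_genes = 6)
  gene_spans <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ref$genes)),
    start = GenomicRanges::start(ref$genes),
    end = GenomicRanges::end(ref$genes), stringsAsFactors = FALSE)
  introns <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ref$introns)),
    start = GenomicRanges::start(ref$introns),
    end = GenomicRanges::end(ref$introns), stringsAsFactors = FALSE)
  codes <- character(50)
  for (i in 1:50) {
    ch <- sample(c("c1", "c2"), 1)
    s <- sample(1:60000, 1)
    q <- data.frame(chrom = ch, start = s, end = s + sample(50:3000, 1),
                    transcript_id = "q")
    got <- assign_class_code(q, ref)
    want <- class_code_oracle(
      data.frame(chrom = ch, start = q$start, end = q$end), gene_spans,
      introns)
    expect_equal(got, want, info = sprintf("query %s:%d-%d", ch, q$start,
                                           q$end))
    codes[i] <- got
  }
  expect_true(all(codes %in% c("u", "i", "overlap")))
})

test_that("locus clustering equals brute-force connected components", {
  set.seed(31)
  for (rep in 1:4) {
    rows <- list()
    for (t in 1:30) {
      s <- sample(1:5000, 1)
      rows[[t]] <- data.frame(
        chrom = "c1", start = s, end = s + sample(50:400, 1),
        strand = sample(c("+", "-"), 1),
        transcript_id = sprintf("t%02d", t),
        gene_id = sprintf("t%02d", t), stringsAsFactors = FALSE)
    }
    exons <- do.call(rbind, rows)
    ann <- genome_annotation(exons)
    got <- cluster_loci(ann)
    want <- components_oracle(exons)
    expect_equal(got[names(want)], want)
    # order invariance
    perm <- exons[sample(nrow(exons)), ]
    got2 <- cluster_loci(genome_annotation(perm))
    expect_equal(got2[names(got)], got)
  }
})

test_that("locus clustering trivia: overlap joins, disjoint stay apart", {
  two_overlap <- genome_annotation(data.frame(
    chrom = "c1", start = c(100, 150), end = c(200, 260), strand = "+",
    transcript_id = c("ta", "tb"), gene_id = c("ta", "tb")))
  expect_equal(length(unique(cluster_loci(two_overlap))), 1)
  disjoint <- genome_annotation(data.frame(
    chrom = "c1", start = c(100, 500), end = c(200, 600), strand = "+",
    transcript_id = c("ta", "tb"), gene_id = c("ta", "tb")))
  expect_equal(length(unique(cluster_loci(disjoint))), 2)
  # opposite strands never cluster
  anti <- genome_annotation(data.frame(
    chrom = "c1", start = c(100, 150), end = c(200, 260),
    strand = c("+", "-"),
    transcript_id = c("ta", "tb"), gene_id = c("ta", "tb")))
  expect_equal(length(unique(cluster_loci(anti))), 2)
})

test_that("gene distance: touching, gapped, overlapping, cross-chromosome", {
  # touching intervals have no base between them
  expect_equal(gene_distance("c1", 101, 200, "c1", 201, 300), 0)
  expect_equal(gene_distance("c1", 101, 200, "c1", 1200, 1300), 999)
  expect_equal(gene_distance("c1", 101, 200, "c1", 150, 300), -1)
  expect_equal(gene_distance("c1", 101, 200, "c2", 201, 300), Inf)
  set.seed(41)
  for (i in 1:60) {
    s1 <- sample(1:400, 1); e1 <- s1 + sample(0:80, 1)
    s2 <- sample(1:400, 1); e2 <- s2 + sample(0:80, 1)
    expect_equal(gene_distance("c1", s1, e1, "c1", s2, e2),
                 distance_oracle(s1, e1, s2, e2))
  }
})
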