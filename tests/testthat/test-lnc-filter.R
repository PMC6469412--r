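mk_tx <- function(len, n_exons = 1, chrom = "c1", start = 10000) {
  ex_l <- rep(len %/% n_exons, n_exons)
  ex_l[n_exons] <- len - sum(ex_l[-n_exons])
  rows <- list(); cur <- start
  for (k in seq_len(n_exons)) {
    rows[[k]] <- data.frame(chrom = chrom, start = cur,
                            end = cur + ex_l[k] - 1L, strand = "+",
                            transcript_id = "t", gene_id = "t",
                            stringsAsFactors = FALSE)
    cur <- cur + ex_l[k] + 500L
  }
  ann <- genome_annotation(do.call(rbind, rows))
  list(tx = ann$transcripts, exons = ann$exons)
}

test_that("structural filter applies the length and single-exon rules strictly", {
  no_rep <- GenomicRanges::GRanges()
  t150 <- mk_tx(150)
  expect_equal(structural_filter(t150$tx, t150$exons, no_rep), "min_length")
  t200 <- mk_tx(200)
  expect_equal(structural_filter(t200$tx, t200$exons, no_rep), "min_length")
  t201 <- mk_tx(201)
  expect_equal(structural_filter(t201$tx, t201$exons, no_rep), "keep")
  # mono-exon boundary: 10000 kept, 10001 rejected
  t10k <- mk_tx(10000)
  expect_equal(structural_filter(t10k$tx, t10k$exons, no_rep), "keep")
  t10k1 <- mk_tx(10001)
  expect_equal(structural_filter(t10k1$tx, t10k1$exons, no_rep),
               "monoexon_too_long")
  # multi-exon transcripts are exempt from the mono-exon rules
  t12k2 <- mk_tx(12000, n_exons = 2)
  expect_equal(structural_filter(t12k2$tx, t12k2$exons, no_rep), "keep")
  # single exon on a simple repeat
  rep_iv <- GenomicRanges::GRanges("c1", IRanges::IRanges(10050, 10080))
  t500 <- mk_tx(500)
  expect_equal(structural_filter(t500$tx, t500$exons, rep_iv),
               "monoexon_repeat")
  t500b <- mk_tx(500, n_exons = 2)
  expect_equal(structural_filter(t500b$tx, t500b$exons, rep_iv), "keep")
})

test_that("expression filter counts samples at the inclusive FPKM floor", {
  m <- rbind(a = c(1.2, 0.5, 0, 0, 0, 0),
             b = c(1.0, 1.0, 0, 0, 0, 0),
             c = c(5, 3, 2, 1, 1, 1))
  colnames(m) <- paste0("s", 1:6)
  expr <- expression_matrix(m, setNames(rep(c("x", "y"), each = 3),
                                        colnames(m)))
  expect_equal(expression_filter("a", expr), "low_expression")
  expect_equal(expression_filter("b", expr), "keep")  # >= 1 inclusive
  expect_equal(expression_filter("c", expr), "keep")
  expect_equal(expression_filter("zz", expr), "missing_expression")
  set.seed(5)
  for (i in 1:40) {
    v <- round(stats::runif(6, 0, 2), 2)
    m2 <- matrix(v, 1, dimnames = list("f", paste0("s", 1:6)))
    e2 <- expression_matrix(m2, setNames(rep(c("x", "y"), each = 3),
                                         paste0("s", 1:6)))
    want <- if (sum(v >= 1) >= 2) "keep" else "low_expression"
    expect_equal(expression_filter("f", e2), want)
  }
})

test_that("homology filter rejects only strictly significant hits", {
  p <- filter_params()
  expect_equal(homology_filter(data.frame(evalue = 1e-6), p),
               "homology_hit")
  expect_equal(homology_filter(data.frame(evalue = 1e-5), p), "keep")
  expect_equal(homology_filter(data.frame(evalue = numeric()), p), "keep")
  expect_equal(homology_filter(NULL, p), "keep")
  # truth table over all 32 patterns of 5 hits straddling the cutoff
  for (mask in 0:31) {
    ev <- ifelse(bitwAnd(mask, 2^(0:4)) > 0, 1e-7, 1e-4)
    want <- if (any(ev < 1e-5)) "homology_hit" else "keep"
    expect_equal(homology_filter(data.frame(evalue = ev), p), want)
  }
})

test_that("domain filter rejects on any reported hit, optional cutoff", {
  expect_equal(domain_filter(data.frame(domain_id = "PF1", evalue = 1e-8)),
               "domain_hit")
  expect_equal(domain_filter(data.frame(domain_id = character(),
                                        evalue = numeric())), "keep")
  expect_equal(domain_filter(NULL), "keep")
  p_cut <- filter_params(domain_evalue_max = 1e-5)
  expect_equal(domain_filter(data.frame(domain_id = "PF1", evalue = 1e-3),
                             p_cut), "keep")
  expect_equal(domain_filter(data.frame(domain_id = "PF1", evalue = 1e-6),
                             p_cut), "domain_hit")
})

test_that("coding vote counts strict thresholds; verdict over all 32 patterns", {
  v <- coding_vote(0.6, 1.2, 0.40, -0.1, "noncoding")
  expect_equal(v$votes, 3)
  expect_equal(v$verdict, "coding")
  # every threshold is strict: exactly-at-threshold scores cast no vote
  v0 <- coding_vote(0.5, 0.0, 0.36, 0.0, "noncoding")
  expect_equal(v0$votes, 0)
  expect_equal(v0$verdict, "noncoding")
  expect_equal(coding_vote(0, 0, 0, 0, "missing")$votes, 0)
  for (mask in 0:31) {
    b <- bitwAnd(mask, 2^(0:4)) > 0
    v <- coding_vote(cpc2 = if (b[1]) 0.9 else 0.1,
                     cnci = if (b[2]) 0.5 else -0.5,
                     cpat = if (b[3]) 0.5 else 0.2,
                     plek = if (b[4]) 0.5 else -0.5,
                     feelnc = if (b[5]) "coding" else "noncoding")
    expect_equal(v$votes, sum(b))
    expect_equal(v$verdict, if (sum(b) >= 3) "coding" else "noncoding")
  }
  expect_error(coding_vote(0.1, 0, 0, 0, "maybe"), "FEElnc")
})

test_that("ORF finder handles canonical and degenerate inputs", {
  expect_equal(find_longest_orf("ATGTAA"), 1)
  expect_equal(find_longest_orf("CCCCCC"), 0)
  expect_equal(find_longest_orf(""), 0)
  expect_equal(find_longest_orf("AT"), 0)
  # 3'-partial ORF: ATG then run to sequence end without a stop
  expect_equal(find_longest_orf("ATGAAAAAA"), 3)
  # stop excluded from the length; second frame
  expect_equal(find_longest_orf("CATGAAATGA"), 2)
  expect_equal(find_longest_orf(tolower("ATGTAA")), 1)
})

test_that("ORF finder equals the brute-force scanner on 1000 random sequences", {
  set.seed(99)
  for (i in 1:1000) {
    s <- paste(sample(c("A", "C", "G", "T"), 900, replace = TRUE),
               collapse = "")
    got <- find_longest_orf(s)
    expect_identical(got, orf_oracle(s))
    expect_lte(got, 300)  # never exceeds floor(len/3)
  }
})

test_that("proximity filter uses a strict 1-kb distance to coding genes", {
  ref <- genome_annotation(data.frame(
    chrom = "c1", start = 1000, end = 2000, strand = "+",
    transcript_id = "g1.t1", gene_id = "g1", biotype = "protein_coding"))
  mk <- function(start) data.frame(chrom = "c1", start = start,
                                   end = start + 400, spliced_length = 401,
                                   n_exons = 1, transcript_id = "q")
  # gene ends at 2000: candidate starting at 3000 is 999 bp away
  expect_equal(proximity_filter(mk(3000), ref), "near_coding_gene")
  expect_equal(proximity_filter(mk(3001), ref), "keep")
  other_chrom <- data.frame(chrom = "c2", start = 2500, end = 2900,
                            transcript_id = "q")
  expect_equal(proximity_filter(other_chrom, ref), "keep")
})

test_that("funnel recovers exactly the planted candidates; decoys fail at their step", {
  w <- generate_world(world_config(seed = 123), out_dir = tempfile("w"))
  ref <- read_gtf(w$paths$reference_gtf)
  assembled <- read_gtf(w$paths$assembled_gtf)
  repeats <- read_repeat_bed(w$paths$repeats_bed)
  expr <- read_expression(w$paths$expression, w$paths$groups)
  evidence <- list(
    hits = read.delim(w$paths$hits, stringsAsFactors = FALSE),
    domains = read.delim(w$paths$domains, stringsAsFactors = FALSE),
    scores = read.delim(w$paths$scores, stringsAsFactors = FALSE))
  seqs <- Biostrings::readDNAStringSet(w$paths$fasta)
  sequences <- setNames(as.character(seqs), names(seqs))
  res <- run_funnel(assembled, ref, repeats, expr, evidence, sequences)

  truth <- w$truth$transcripts
  planted <- truth$transcript_id[truth$expected_step == "survive"]
  expect_setequal(res$candidates$transcript_id, planted)
  # each decoy removed at its designated step
  decoys <- truth[truth$expected_step != "survive", ]
  got_step <- setNames(res$rejected$step, res$rejected$transcript_id)
  expect_equal(unname(got_step[decoys$transcript_id]),
               decoys$expected_step)
  # categories follow the planted class
  expect_equal(
    sort(res$candidates$transcript_id[res$candidates$category == "ilncRNA"]),
    sort(truth$transcript_id[truth$role == "planted_ilnc"]))
  # funnel counts are monotone and survivors nest
  expect_true(all(diff(res$report$input_count) <= 0))
  expect_equal(res$report$input_count - res$report$removed_count,
               res$report$surviving_count)
  for (k in 2:length(res$survivor_ids))
    expect_true(all(res$survivor_ids[[k]] %in% res$survivor_ids[[k - 1]]))
  # previously-reported catalog flags
  catalog <- read.delim(w$paths$known_catalog, stringsAsFactors = FALSE)
  cat_gr <- GenomicRanges::GRanges(
    catalog$chrom, IRanges::IRanges(catalog$start, catalog$end))
  res2 <- run_funnel(assembled, ref, repeats, expr, evidence, sequences,
                     known_lnc_catalog = cat_gr)
  flagged <- res2$candidates$transcript_id[res2$candidates$previously_reported]
  expect_setequal(flagged, w$truth$previously_reported)
})

test_that("funnel on an empty assembled set yields empty outputs", {
  empty <- genome_annotation(data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), transcript_id = character(),
    gene_id = character()))
  ref <- random_ref(2)
  m <- matrix(1, 1, 2, dimnames = list("x", c("s1", "s2")))
  expr <- expression_matrix(m, setNames(c("a", "b"), c("s1", "s2")))
  res <- run_funnel(empty, ref, GenomicRanges::GRanges(), expr,
                    list(hits = NULL, domains = NULL,
                         scores = data.frame(transcript_id = character())),
                    character())
  expect_equal(nrow(res$candidates), 0)
  expect_equal(nrow(res$report), 0)
})
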