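test_that("conservation summary applies the inclusive E-value cutoff", {
  hits <- data.frame(
    query_id = c("t1", "t2", "t2", "x"),
    subject_id = c("b1", "b2", "b3", "t3"),
    species = c("bovine", "bovine", "bovine", "bovine"),
    evalue = c(1e-6, 1e-4, 1e-3, 1e-8),
    alignment_length = c(300, 100, 90, 250),
    direction = c("sheep_as_query", "sheep_as_query", "sheep_as_query",
                  "sheep_as_subject"),
    stringsAsFactors = FALSE)
  tg <- c(t1 = "g1", t2 = "g2", t3 = "g1")
  cs <- conservation_summary(hits, tg)
  # t2's hits are all weaker than 1e-5; t3 counts via the reverse direction
  expect_setequal(cs$conserved_ids$bovine, c("t1", "t3"))
  row <- cs$per_species[cs$per_species$species == "bovine", ]
  expect_equal(row$conserved_transcripts, 2)
  expect_equal(row$conserved_genes, 1)  # t1 and t3 share a gene
  expect_equal(row$mean_alignment_length, mean(c(300, 250)))
  # raising the cutoff never loses conserved transcripts
  cs2 <- conservation_summary(hits, tg, emax = 1e-3)
  expect_true(all(cs$conserved_ids$bovine %in% cs2$conserved_ids$bovine))
})

test_that("planted conserved transcripts and alignment lengths are recovered", {
  w <- generate_world(world_config(seed = 9), out_dir = tempfile("w"))
  hits <- read.delim(w$paths$cross_species_hits, stringsAsFactors = FALSE)
  tg <- setNames(w$truth$transcripts$transcript_id,
                 w$truth$transcripts$transcript_id)
  cs <- conservation_summary(hits, tg)
  for (sp in c("bovine", "human")) {
    expect_setequal(cs$conserved_ids[[sp]], w$truth$conserved[[sp]]$ids)
    row <- cs$per_species[cs$per_species$species == sp, ]
    expect_equal(row$mean_alignment_length,
                 w$truth$conserved[[sp]]$mean_len)
  }
  expect_equal(length(cs$conserved_ids[["chicken"]]), 0)
})

# a hand-built two-genome synteny scenario mirroring a locus flanked by
# ACACA-like and C17orf78-like genes in both genomes
mini_synteny <- function() {
  sheep_genes <- data.frame(
    gene_id = c("ACACA", "C17orf78", "FAR1"),
    chrom = "11", start = c(1000, 20000, 60000),
    end = c(5000, 24000, 64000), stringsAsFactors = FALSE)
  foreign_genes <- data.frame(
    gene_id = c("ACACA_hum", "C17orf78_hum", "FAR1_hum"),
    chrom = "17", start = c(500, 9000, 30000),
    end = c(3000, 12000, 33000), stringsAsFactors = FALSE)
  orthologs <- data.frame(
    sheep_gene = c("ACACA", "C17orf78", "FAR1"),
    foreign_gene = c("ACACA_hum", "C17orf78_hum", "FAR1_hum"),
    stringsAsFactors = FALSE)
  list(sheep_genes = sheep_genes, foreign_genes = foreign_genes,
       orthologs = orthologs)
}

test_that("synteny requires both flank orthologs around a foreign lincRNA", {
  sc <- mini_synteny()
  lnc <- data.frame(lnc_id = "linc1", chrom = "11", start = 8000,
                    end = 9000)
  # human lincRNA between the two orthologs
  f_lincs <- data.frame(linc_id = "hlinc1", chrom = "17", start = 5000,
                        end = 6000, stringsAsFactors = FALSE)
  rec <- synteny_conserved(lnc, sc$sheep_genes, f_lincs, sc$foreign_genes,
                           sc$orthologs, "human")
  expect_true(rec$conserved_synteny)
  expect_equal(rec$matched_foreign_linc, "hlinc1")
  expect_equal(c(rec$left_gene, rec$right_gene), c("ACACA", "C17orf78"))
  # foreign lincRNA with only one matching flank does not count
  f_wrong <- data.frame(linc_id = "hlinc2", chrom = "17", start = 15000,
                        end = 16000, stringsAsFactors = FALSE)
  rec2 <- synteny_conserved(lnc, sc$sheep_genes, f_wrong, sc$foreign_genes,
                            sc$orthologs, "human")
  expect_false(rec2$conserved_synteny)
  # missing ortholog for a flank means not conserved
  orth_partial <- sc$orthologs[sc$orthologs$sheep_gene != "C17orf78", ]
  rec3 <- synteny_conserved(lnc, sc$sheep_genes, f_lincs, sc$foreign_genes,
                            orth_partial, "human")
  expect_false(rec3$conserved_synteny)
  expect_equal(rec3$flag, "missing_ortholog")
  # candidate at a chromosome end lacks a flank
  edge <- data.frame(lnc_id = "linc2", chrom = "11", start = 100, end = 500)
  rec4 <- synteny_conserved(edge, sc$sheep_genes, f_lincs,
                            sc$foreign_genes, sc$orthologs, "human")
  expect_false(rec4$conserved_synteny)
  expect_equal(rec4$flag, "incomplete_flank")
})

test_that("planted syntenic loci are recovered across the species panel", {
  w <- generate_world(world_config(seed = 17), out_dir = tempfile("w"))
  ref <- read_gtf(w$paths$reference_gtf)
  assembled <- read_gtf(w$paths$assembled_gtf)
  planted <- w$truth$transcripts$transcript_id[
    w$truth$transcripts$role == "planted_linc"]
  lncs <- assembled$transcripts[
    assembled$transcripts$transcript_id %in% planted, ]
  names(lncs)[names(lncs) == "transcript_id"] <- "lnc_id"
  sheep_genes <- data.frame(
    gene_id = S4Vectors::mcols(ref$genes)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(ref$genes)),
    start = GenomicRanges::start(ref$genes),
    end = GenomicRanges::end(ref$genes), stringsAsFactors = FALSE)
  sheep_genes <- sheep_genes[
    S4Vectors::mcols(ref$genes)$biotype == "protein_coding", ]
  foreign <- lapply(c(bovine = "bovine", human = "human",
                      chicken = "chicken"), function(sp) list(
    lincs = read.delim(w$paths[[paste0("foreign_lincs_", sp)]],
                       stringsAsFactors = FALSE),
    genes = read.delim(w$paths[[paste0("foreign_genes_", sp)]],
                       stringsAsFactors = FALSE),
    orthologs = read.delim(w$paths[[paste0("orthologs_", sp)]],
                           stringsAsFactors = FALSE)))
  rec <- synteny_scan(lncs, sheep_genes, foreign)
  # per-species conserved sets equal the planted truth
  for (sp in names(foreign)) {
    want <- w$truth$syntenic$lnc_id[w$truth$syntenic$species == sp]
    got <- rec$lnc_id[rec$species == sp & rec$conserved_synteny]
    expect_setequal(got, want)
  }
  # the all-species intersection is exactly the fully planted loci
  v <- synteny_venn(rec)
  all_region <- v$partition$count[v$partition$region ==
                                    "bovine+chicken+human"]
  expect_equal(all_region, length(w$truth$syntenic_all_species))
  inter <- Reduce(intersect, v$sets)
  expect_setequal(inter, w$truth$syntenic_all_species)
  # every conserved record carries both flank orthologs
  ok <- rec[rec$conserved_synteny, ]
  expect_true(all(!is.na(ok$left_gene) & !is.na(ok$right_gene)))
})

test_that("Venn partition counts match brute-force membership enumeration", {
  mk_rec <- function(sets) {
    do.call(rbind, lapply(names(sets), function(sp) data.frame(
      lnc_id = sets[[sp]], species = sp, conserved_synteny = TRUE,
      stringsAsFactors = FALSE)))
  }
  # disjoint single-species sets: pairwise intersections empty
  v <- synteny_venn(mk_rec(list(a = c("x1", "x2"), b = c("y1"))))
  expect_equal(v$partition$count[v$partition$region == "a"], 2)
  expect_equal(v$partition$count[v$partition$region == "a+b"], 0)
  # a triple member is counted once, in the triple region only
  v3 <- synteny_venn(mk_rec(list(a = "z", b = "z", c = "z")))
  expect_equal(v3$partition$count[v3$partition$region == "a+b+c"], 1)
  expect_true(all(v3$partition$count[v3$partition$region != "a+b+c"] == 0))
  # random sets vs explicit enumeration
  set.seed(8)
  for (rep in 1:5) {
    ids <- sprintf("l%02d", 1:12)
    sets <- list(a = sample(ids, 5), b = sample(ids, 4),
                 c = sample(ids, 6))
    v <- synteny_venn(mk_rec(sets))
    for (i in seq_len(nrow(v$partition))) {
      cmb <- strsplit(v$partition$region[i], "+", fixed = TRUE)[[1]]
      want <- sum(vapply(ids, function(id) {
        inside <- vapply(names(sets), function(sp) id %in% sets[[sp]],
                         logical(1))
        setequal(names(sets)[inside], cmb)
      }, logical(1)))
      expect_equal(v$partition$count[i], want)
    }
  }
})
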