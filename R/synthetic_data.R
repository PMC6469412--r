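#' Configuration of the synthetic study world
#'
#' Defaults mirror the emulated study design: two breeds (one fat-tailed,
#' one thin-tailed) with three biological replicates each, a compact
#' multi-chromosome annotation, a planted set of clean lncRNA candidates,
#' and one decoy per filter rule per replicate so that every funnel step has
#' known casualties.
#'
#' @param seed integer seed; fixes every emitted byte.
#' @param n_chromosomes number of chromosomes (default 3).
#' @param n_coding_genes protein-coding genes in the reference (default 60).
#' @param n_known_lincRNAs annotated lncRNA genes in the reference
#'   (default 8).
#' @param n_planted_lincRNAs clean intergenic candidates (default 20).
#' @param n_planted_ilncRNAs clean intronic candidates (default 6).
#' @param n_decoys_per_filter decoys per filter rule, 9 rules (default 5).
#' @param samples_per_breed replicates per breed (default 3).
#' @param breeds two breed labels.
#' @param n_breed_specific planted breed-specific candidates per breed
#'   (named integer vector over `breeds`).
#' @param n_trans_pairs planted lncRNA-mRNA co-expression pairs with
#'   |r| > 0.999 (default 8, one of them negative).
#' @param n_conserved planted conserved candidate transcripts per species
#'   (named vector, default bovine 8 / human 5 / chicken 0).
#' @param n_syntenic_all planted loci syntenic in all species (default 9).
#' @param n_syntenic_one additional loci syntenic in exactly one species,
#'   per species (default 2).
#' @param n_qtl QTL records (default 10); planted containments use the
#'   trait `"Tail fat deposition"` and spans straddle 1 Mb.
#' @param clique_sizes sizes of planted PPI cliques (default 9, 10, 12).
#' @param gc_target GC fraction of emitted candidate sequences
#'   (default 0.48).
#' @param sigma_log standard deviation of log-normal expression noise
#'   (default 0.2).
#' @return a `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_chromosomes = 3L,
                         n_coding_genes = 60L,
                         n_known_lincRNAs = 8L,
                         n_planted_lincRNAs = 20L,
                         n_planted_ilncRNAs = 6L,
                         n_decoys_per_filter = 5L,
                         samples_per_breed = 3L,
                         breeds = c("Lori-Bakhtiari", "Zel"),
                         n_breed_specific = c(4L, 2L),
                         n_trans_pairs = 8L,
                         n_conserved = c(bovine = 8L, human = 5L,
                                         chicken = 0L),
                         n_syntenic_all = 9L,
                         n_syntenic_one = 2L,
                         n_qtl = 10L,
                         clique_sizes = c(9L, 10L, 12L),
                         gc_target = 0.48,
                         sigma_log = 0.2) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$breeds) == 2L,
            cfg$n_planted_lincRNAs >= sum(cfg$n_breed_specific),
            cfg$n_planted_lincRNAs >= cfg$n_syntenic_all +
              2L * cfg$n_syntenic_one,
            cfg$seed < 2^31)
  names(cfg$n_breed_specific) <- cfg$breeds
  class(cfg) <- "world_config"
  cfg
}

# random nucleotide string at a GC target
rand_seq <- function(len, gc) {
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# random sequence whose longest ORF stays below max_aa (rejection sampling)
seq_capped_orf <- function(len, gc, max_aa = 250L) {
  repeat {
    s <- rand_seq(len, gc)
    if (find_longest_orf(s) < max_aa) return(s)
  }
}

# sequence carrying an ORF of at least min_aa amino acids
seq_with_orf <- function(len, gc, min_aa = 320L) {
  need <- 3L * (min_aa + 2L)
  stopifnot(len >= need + 6L)
  non_stop <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                        c("A","C","G","T")), 1, paste,
                            collapse = ""),
                      c("TAA", "TAG", "TGA", "ATG"))
  orf <- paste0("ATG",
                paste(sample(non_stop, min_aa + 1L, replace = TRUE),
                      collapse = ""),
                "TAA")
  lead <- len - nchar(orf)
  pre <- lead %/% 2
  paste0(seq_capped_orf(pre, gc, 100L), orf,
         seq_capped_orf(lead - pre, gc, 100L))
}

# exon layout for a transcript starting at `start`: returns data.frame and
# total span
make_exons <- function(start, n_exons, exon_lens, intron_lens) {
  starts <- integer(n_exons); ends <- integer(n_exons)
  cur <- start
  for (k in seq_len(n_exons)) {
    starts[k] <- cur
    ends[k] <- cur + exon_lens[k] - 1L
    cur <- ends[k] + (if (k < n_exons) intron_lens[k] else 0L) + 1L
  }
  list(starts = starts, ends = ends, span_end = ends[n_exons])
}

#' Generate the complete synthetic study world
#'
#' Writes every input the pipeline consumes — reference and assembled GTF,
#' transcript FASTA, repeat BED, expression and group TSVs, a
#' Cuffdiff-like DE table, homology/domain/coding-score tables,
#' cross-species hit tables, foreign lincRNA/gene/ortholog tables, a QTL
#' table, a PPI edge list and a GMT collection — into `out_dir`, together
#' with a ground-truth object covering every planted element, and a
#' manifest of all emitted files.
#'
#' @param cfg a [world_config()].
#' @param out_dir output directory (created if absent).
#' @return invisible list with `paths` (named file paths), `truth` (named
#'   list of truth tables) and `config`.
#' @export
generate_world <- function(cfg = world_config(), out_dir = tempfile("world")) {
  stopifnot(inherits(cfg, "world_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  chroms <- as.character(seq_len(cfg$n_chromosomes))
  ref_rows <- list()    # reference GTF exon rows
  asm_rows <- list()    # assembled (novel) GTF exon rows
  gene_tbl <- list()    # coding gene spans
  repeat_rows <- list()
  sequences <- list()
  truth_tx <- list()

  ## ---- coding genes laid out per chromosome, intergenic units in gaps ----
  decoy_types <- c("min_length", "monoexon_too_long", "monoexon_repeat",
                   "low_expression", "homology_hit", "domain_hit",
                   "coding_vote", "long_orf", "near_coding_gene")
  # queues: proximity decoys must open a gap (they sit < 1 kb from the
  # preceding gene); at most one planted lincRNA per gap so every candidate
  # owns a unique flanking-gene pair (needed for clean synteny truth)
  prox_queue <- lapply(seq_len(cfg$n_decoys_per_filter), function(i)
    list(kind = "decoy_near_coding_gene",
         id = sprintf("decoy.near_coding_gene.%02d", i)))
  linc_queue <- lapply(seq_len(cfg$n_planted_lincRNAs), function(i)
    list(kind = "planted_linc", id = sprintf("lincRNA.%03d", i)))
  other_units <- c(
    unlist(lapply(setdiff(decoy_types, "near_coding_gene"), function(ty)
      lapply(seq_len(cfg$n_decoys_per_filter), function(i)
        list(kind = paste0("decoy_", ty),
             id = sprintf("decoy.%s.%02d", ty, i)))),
      recursive = FALSE),
    lapply(seq_len(cfg$n_known_lincRNAs), function(i)
      list(kind = "known_linc", id = sprintf("KNOWNLNC%02d", i))))
  other_queue <- other_units[sample.int(length(other_units))]

  genes_per_chrom <- table(rep(chroms, length.out = cfg$n_coding_genes))
  gene_no <- 0L
  neighbors <- list()   # per planted linc: left/right coding gene
  intron_pool <- list() # introns available for ilncRNA planting

  for (ch in chroms) {
    cursor <- 50000L
    last_gene <- NA_character_
    for (gi in seq_len(genes_per_chrom[[ch]])) {
      gene_no <- gene_no + 1L
      gid <- sprintf("G%04d", gene_no)
      n_ex <- sample(2:12, 1)
      ex_l <- sample(150:400, n_ex, replace = TRUE)
      in_l <- sample(2000:8000, n_ex - 1, replace = TRUE)
      lay <- make_exons(cursor, n_ex, ex_l, in_l)
      tid <- paste0(gid, ".t1")
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        chrom = ch, start = lay$starts, end = lay$ends, strand = "+",
        transcript_id = tid, gene_id = gid, biotype = "protein_coding",
        stringsAsFactors = FALSE)
      gene_tbl[[length(gene_tbl) + 1L]] <- data.frame(
        gene_id = gid, chrom = ch, start = cursor, end = lay$span_end,
        stringsAsFactors = FALSE)
      if (n_ex > 1L)
        intron_pool[[length(intron_pool) + 1L]] <- data.frame(
          gene_id = gid, transcript_id = tid, chrom = ch,
          start = lay$ends[-n_ex] + 1L, end = lay$starts[-1] - 1L,
          stringsAsFactors = FALSE)
      last_gene <- gid
      cursor <- lay$span_end + 1L

      # fill the following gap: an optional proximity decoy hugging this
      # gene, at most one planted lincRNA, plus other units
      gap_units <- list()
      if (gi < genes_per_chrom[[ch]]) {
        if (length(prox_queue)) {
          gap_units <- prox_queue[1L]; prox_queue[[1L]] <- NULL
        }
        if (length(linc_queue)) {
          gap_units <- c(gap_units, linc_queue[1L]); linc_queue[[1L]] <- NULL
        }
        while (length(gap_units) < 2L && length(other_queue)) {
          gap_units <- c(gap_units, other_queue[1L])
          other_queue[[1L]] <- NULL
        }
      }
      for (k in seq_along(gap_units)) {
        u <- gap_units[[k]]
        margin <- if (u$kind == "decoy_near_coding_gene")
          sample(300:900, 1) else sample(1500:25000, 1)
        res <- place_unit(u, ch, cursor + margin, cfg)
        if (u$kind == "known_linc") {
          ref_rows[[length(ref_rows) + 1L]] <- res$exons
        } else {
          asm_rows[[length(asm_rows) + 1L]] <- res$exons
          sequences[[u$id]] <- res$seq
          truth_tx[[length(truth_tx) + 1L]] <- data.frame(
            transcript_id = u$id, role = u$kind,
            expected_step = res$expected_step, class = "u",
            stringsAsFactors = FALSE)
          if (u$kind == "planted_linc")
            neighbors[[u$id]] <- list(chrom = ch, left = last_gene,
                                      start = cursor + margin,
                                      end = res$span_end)
          if (!is.null(res$repeat_iv))
            repeat_rows[[length(repeat_rows) + 1L]] <- res$repeat_iv
        }
        cursor <- res$span_end + 1L
      }
      # trailing gap before the next gene keeps >= 1.5 kb clearance
      cursor <- cursor + sample(2000:30000, 1)
    }
  }
  unplaced <- length(prox_queue) + length(linc_queue) + length(other_queue)
  if (unplaced)
    stop("layout infeasible: ", unplaced, " units unplaced; ",
         "increase n_coding_genes")
  genes_df <- do.call(rbind, gene_tbl)

  # record right-hand coding neighbor of each planted linc
  for (id in names(neighbors)) {
    nb <- neighbors[[id]]
    g <- genes_df[genes_df$chrom == nb$chrom & genes_df$start > nb$end, ]
    neighbors[[id]]$right <- if (nrow(g)) g$gene_id[which.min(g$start)]
      else NA_character_
  }

  ## ---- intronic candidates planted inside coding-gene introns -----------
  introns_df <- do.call(rbind, intron_pool)
  introns_df <- introns_df[introns_df$end - introns_df$start + 1L >= 2000L, ]
  pick <- sample(nrow(introns_df), cfg$n_planted_ilncRNAs)
  ilnc_host <- character()
  for (i in seq_len(cfg$n_planted_ilncRNAs)) {
    iv <- introns_df[pick[i], ]
    id <- sprintf("ilncRNA.%03d", i)
    len <- sample(300:min(1500, iv$end - iv$start - 200L), 1)
    s <- iv$start + sample(50:100, 1)
    asm_rows[[length(asm_rows) + 1L]] <- data.frame(
      chrom = iv$chrom, start = s, end = s + len - 1L, strand = "+",
      transcript_id = id, gene_id = id, biotype = "novel",
      stringsAsFactors = FALSE)
    sequences[[id]] <- seq_capped_orf(len, cfg$gc_target + 0.03)
    truth_tx[[length(truth_tx) + 1L]] <- data.frame(
      transcript_id = id, role = "planted_ilnc", expected_step = "survive",
      class = "i", stringsAsFactors = FALSE)
    ilnc_host[id] <- iv$gene_id
  }
  truth_tx <- do.call(rbind, truth_tx)

  planted_linc <- truth_tx$transcript_id[truth_tx$role == "planted_linc"]
  planted_ilnc <- truth_tx$transcript_id[truth_tx$role == "planted_ilnc"]
  planted_all <- c(planted_linc, planted_ilnc)
  novel_ids <- truth_tx$transcript_id

  ## ---- expression matrix -------------------------------------------------
  samples <- paste(rep(cfg$breeds, each = cfg$samples_per_breed),
                   seq_len(cfg$samples_per_breed), sep = "_")
  groups <- setNames(rep(cfg$breeds, each = cfg$samples_per_breed), samples)
  n_s <- length(samples)
  lognorm <- function(mu) exp(log(mu) + stats::rnorm(n_s, 0, cfg$sigma_log))

  expr <- matrix(0, 0, n_s, dimnames = list(NULL, samples))
  add_row <- function(id, v) {
    expr <<- rbind(expr, matrix(v, 1, n_s, dimnames = list(id, samples)))
  }

  # breed-specific planted lincRNAs (first rows of the planted set)
  bs_truth <- list()
  bs_ids <- list()
  idx <- 1L
  for (b in cfg$breeds) {
    ids <- planted_linc[idx:(idx + cfg$n_breed_specific[[b]] - 1L)]
    idx <- idx + cfg$n_breed_specific[[b]]
    bs_ids[[b]] <- ids
    for (id in ids) {
      v <- setNames(numeric(n_s), samples)
      v[groups == b] <- exp(log(8) + stats::rnorm(sum(groups == b), 0,
                                                  cfg$sigma_log))
      v[groups != b] <- stats::runif(sum(groups != b), 0, 0.5)
      add_row(id, v)
      bs_truth[[length(bs_truth) + 1L]] <- data.frame(
        transcript_id = id, breed = b, stringsAsFactors = FALSE)
    }
  }
  bs_used <- unlist(bs_ids)

  # trans-correlated pairs: shared latent profile, |r| > 0.999 enforced
  free_linc <- setdiff(planted_linc, bs_used)
  stopifnot(length(free_linc) >= cfg$n_trans_pairs)
  coding_ids <- genes_df$gene_id
  trans_genes <- sample(coding_ids, cfg$n_trans_pairs)
  trans_truth <- list()
  trans_expr_gene <- list()
  for (k in seq_len(cfg$n_trans_pairs)) {
    id <- free_linc[k]
    sign_k <- if (k == cfg$n_trans_pairs) -1 else 1   # one negative pair
    repeat {
      z <- stats::rnorm(n_s)
      lnc_v <- 10 + 4 * z + stats::rnorm(n_s, 0, 0.02)
      gene_v <- 20 + sign_k * 6 * z + stats::rnorm(n_s, 0, 0.02)
      lnc_v <- pmax(lnc_v, 1.1); gene_v <- pmax(gene_v, 1.1)
      if (abs(stats::cor(lnc_v, gene_v)) > 0.999) break
    }
    add_row(id, lnc_v)
    trans_expr_gene[[trans_genes[k]]] <- gene_v
    trans_truth[[length(trans_truth) + 1L]] <- data.frame(
      lnc_id = id, gene_id = trans_genes[k], sign = sign_k,
      stringsAsFactors = FALSE)
  }
  trans_truth <- do.call(rbind, trans_truth)

  # remaining planted candidates: expressed everywhere
  for (id in setdiff(planted_all, rownames(expr)))
    add_row(id, lognorm(stats::runif(1, 3, 40)))

  # decoys: expression decoys sparse, all others well expressed
  for (i in seq_len(nrow(truth_tx))) {
    id <- truth_tx$transcript_id[i]
    if (id %in% rownames(expr)) next
    if (truth_tx$role[i] == "decoy_low_expression") {
      v <- stats::runif(n_s, 0, 0.8)
      v[sample(n_s, 1)] <- stats::runif(1, 1.2, 3)  # exactly one qualifying
      add_row(id, v)
    } else add_row(id, lognorm(stats::runif(1, 3, 40)))
  }

  # coding genes (gene-level rows); trans partners use their latent profile
  for (g in coding_ids) {
    if (!is.null(trans_expr_gene[[g]])) add_row(g, trans_expr_gene[[g]])
    else add_row(g, lognorm(stats::runif(1, 2, 60)))
  }

  ## ---- DE table (Cuffdiff-like, consumed not recomputed) -----------------
  de_candidates <- sample(planted_all, 8)
  de_rows <- lapply(seq_along(de_candidates), function(i) {
    id <- de_candidates[i]
    a <- round(stats::runif(1, 2, 300), 2)
    b <- round(stats::runif(1, 2, 300), 2)
    if (i <= 2) { if (i == 1) a <- 0 else b <- 0 }  # zero-vs-nonzero rows
    data.frame(id = id, mean_a = a, mean_b = b,
               fdr = round(stats::runif(1, 0.001, 0.1), 3),
               stringsAsFactors = FALSE)
  })
  null_ids <- setdiff(novel_ids, de_candidates)
  de_rows <- c(de_rows, lapply(null_ids, function(id) data.frame(
    id = id, mean_a = round(stats::runif(1, 1, 50), 2),
    mean_b = round(stats::runif(1, 1, 50), 2),
    fdr = round(stats::runif(1, 0.2, 1), 3), stringsAsFactors = FALSE)))
  de_tbl <- do.call(rbind, de_rows)

  ## ---- evidence tables ----------------------------------------------------
  dbs <- c("UniProtKB", "miRBase", "Rfam")
  hit_rows <- list()
  for (i in seq_len(nrow(truth_tx))) {
    id <- truth_tx$transcript_id[i]
    if (truth_tx$role[i] == "decoy_homology_hit") {
      for (j in seq_len(sample(1:3, 1)))
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          transcript_id = id, db = sample(dbs, 1),
          evalue = 10^stats::runif(1, -20, -5.1), stringsAsFactors = FALSE)
    } else if (stats::runif(1) < 0.3) {
      # weak, non-significant hits on other transcripts
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        transcript_id = id, db = sample(dbs, 1),
        evalue = 10^stats::runif(1, -4.9, -1), stringsAsFactors = FALSE)
    }
  }
  hits_tbl <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(transcript_id = character(), db = character(),
               evalue = numeric(), stringsAsFactors = FALSE)

  domain_rows <- lapply(
    truth_tx$transcript_id[truth_tx$role == "decoy_domain_hit"],
    function(id) data.frame(
      transcript_id = id, domain_id = sprintf("PF%05d", sample(1e5, 1)),
      evalue = 10^stats::runif(1, -30, -6), stringsAsFactors = FALSE))
  domains_tbl <- if (length(domain_rows)) do.call(rbind, domain_rows) else
    data.frame(transcript_id = character(), domain_id = character(),
               evalue = numeric(), stringsAsFactors = FALSE)

  score_rows <- lapply(seq_len(nrow(truth_tx)), function(i) {
    id <- truth_tx$transcript_id[i]
    if (truth_tx$role[i] == "decoy_coding_vote") {
      n_votes <- sample(3:5, 1)
      voters <- sample(5, n_votes)
    } else {
      voters <- if (stats::runif(1) < 0.4) sample(5, sample(0:2, 1)) else
        integer()
    }
    data.frame(
      transcript_id = id,
      cpc2 = if (1 %in% voters) stats::runif(1, 0.51, 1) else
        stats::runif(1, 0, 0.5),
      cnci = if (2 %in% voters) stats::runif(1, 0.01, 2) else
        stats::runif(1, -2, 0),
      cpat = if (3 %in% voters) stats::runif(1, 0.37, 1) else
        stats::runif(1, 0, 0.36),
      plek = if (4 %in% voters) stats::runif(1, 0.01, 2) else
        stats::runif(1, -2, 0),
      feelnc = if (5 %in% voters) "coding" else
        sample(c("noncoding", "missing"), 1, prob = c(0.8, 0.2)),
      stringsAsFactors = FALSE)
  })
  scores_tbl <- do.call(rbind, score_rows)

  ## ---- cross-species conservation hits ------------------------------------
  cons_truth <- list(); xs_rows <- list()
  for (sp in names(cfg$n_conserved)) {
    n_c <- cfg$n_conserved[[sp]]
    ids <- if (n_c > 0) sample(planted_all, n_c) else character()
    best_lens <- integer()
    for (id in ids) {
      len <- sample(150:500, 1)
      dir <- sample(c("sheep_as_query", "sheep_as_subject"), 1)
      foreign_id <- paste0("NON", toupper(sp), sample(1e6, 1))
      xs_rows[[length(xs_rows) + 1L]] <- data.frame(
        query_id = if (dir == "sheep_as_query") id else foreign_id,
        subject_id = if (dir == "sheep_as_query") foreign_id else id,
        identity = round(stats::runif(1, 80, 99), 1), length = len,
        evalue = 10^stats::runif(1, -30, -6), species = sp,
        direction = dir, stringsAsFactors = FALSE)
      best_lens[id] <- len
    }
    # non-significant hits on a few other transcripts
    for (id in utils::head(setdiff(planted_all, ids), 3))
      xs_rows[[length(xs_rows) + 1L]] <- data.frame(
        query_id = id, subject_id = paste0("NON", toupper(sp),
                                           sample(1e6, 1)),
        identity = 75, length = sample(50:120, 1),
        evalue = 10^stats::runif(1, -4, -2), species = sp,
        direction = "sheep_as_query", stringsAsFactors = FALSE)
    cons_truth[[sp]] <- list(ids = sort(ids),
                             mean_len = if (length(best_lens))
                               mean(best_lens) else NA_real_)
  }
  xs_tbl <- do.call(rbind, xs_rows)

  ## ---- synteny: foreign genomes, lincRNAs, orthologs ----------------------
  species <- c("bovine", "human", "chicken")
  synt_all <- planted_linc[seq_len(cfg$n_syntenic_all)]
  remaining <- setdiff(planted_linc, synt_all)
  synt_one <- list()
  for (sp in species) {
    synt_one[[sp]] <- utils::head(remaining, cfg$n_syntenic_one)
    remaining <- setdiff(remaining, synt_one[[sp]])
  }
  foreign <- list(); synt_truth <- list()
  for (sp in species) {
    want <- union(synt_all, synt_one[[sp]])
    f_genes <- list(); f_lincs <- list()
    cursor <- 100000L
    li <- 0L
    for (id in planted_linc) {
      nb <- neighbors[[id]]
      if (is.na(nb$right)) next
      if (id %in% want) {
        # ortholog pair with a foreign lincRNA between them
        for (g in c(nb$left, nb$right)) {
          f_genes[[length(f_genes) + 1L]] <- data.frame(
            gene_id = paste0(g, "_", sp), chrom = "f1", start = cursor,
            end = cursor + 4999L, stringsAsFactors = FALSE)
          if (g == nb$left) {
            li <- li + 1L
            f_lincs[[length(f_lincs) + 1L]] <- data.frame(
              linc_id = sprintf("%s_linc%03d", sp, li), chrom = "f1",
              start = cursor + 7000L, end = cursor + 8000L,
              stringsAsFactors = FALSE)
            synt_truth[[length(synt_truth) + 1L]] <- data.frame(
              lnc_id = id, species = sp, stringsAsFactors = FALSE)
          }
          cursor <- cursor + 15000L
        }
        cursor <- cursor + 50000L
      } else {
        # orthologs exist but no foreign lincRNA between them
        for (g in c(nb$left, nb$right)) {
          f_genes[[length(f_genes) + 1L]] <- data.frame(
            gene_id = paste0(g, "_", sp), chrom = "f1", start = cursor,
            end = cursor + 4999L, stringsAsFactors = FALSE)
          cursor <- cursor + 15000L
        }
        cursor <- cursor + 50000L
      }
    }
    # decoy foreign lincRNA with unmatched flanks at the chromosome end
    f_lincs[[length(f_lincs) + 1L]] <- data.frame(
      linc_id = paste0(sp, "_linc999"), chrom = "f1",
      start = cursor + 200000L, end = cursor + 201000L,
      stringsAsFactors = FALSE)
    f_genes_df <- unique(do.call(rbind, f_genes))
    orth <- data.frame(
      sheep_gene = sub(paste0("_", sp, "$"), "", f_genes_df$gene_id),
      foreign_gene = f_genes_df$gene_id, stringsAsFactors = FALSE)
    foreign[[sp]] <- list(genes = f_genes_df,
                          lincs = do.call(rbind, f_lincs),
                          orthologs = unique(orth))
  }
  synt_truth <- do.call(rbind, synt_truth)

  ## ---- QTL table ----------------------------------------------------------
  qtl_rows <- list(); qtl_truth <- list()
  qtl_linc <- utils::head(synt_all, min(6L, length(synt_all)))
  qtl_ilnc <- utils::head(planted_ilnc, 1L)
  qid <- 126000L
  for (id in c(qtl_linc, qtl_ilnc)) {
    row <- asm_rows_span(asm_rows, id)
    qid <- qid + 1L
    # pads stay below the minimum inter-candidate spacing so each planted
    # QTL contains exactly its own locus
    pad_l <- sample(600:1400, 1); pad_r <- sample(600:1400, 1)
    qtl_rows[[length(qtl_rows) + 1L]] <- data.frame(
      qtl_id = as.character(qid), trait = "Tail fat deposition",
      chrom = row$chrom, start = max(1L, row$start - pad_l),
      end = row$end + pad_r, stringsAsFactors = FALSE)
    qtl_truth[[length(qtl_truth) + 1L]] <- data.frame(
      lnc_id = id, qtl_id = as.character(qid),
      category = if (id %in% qtl_ilnc) "ilncRNA" else "lincRNA",
      stringsAsFactors = FALSE)
  }
  # non-containing QTL with other traits, spans straddling 1 Mb
  while (length(qtl_rows) < cfg$n_qtl) {
    qid <- qid + 1L
    ch <- sample(chroms, 1)
    s <- sample(1:2000000, 1)
    span <- if (length(qtl_rows) %% 2 == 0) sample(1100000:3000000, 1) else
      sample(50000:900000, 1)
    qtl_rows[[length(qtl_rows) + 1L]] <- data.frame(
      qtl_id = as.character(qid),
      trait = sample(c("Fatty acid content", "Carcass fat percentage"), 1),
      chrom = ch, start = s, end = s + span - 1L, stringsAsFactors = FALSE)
  }
  qtl_tbl <- do.call(rbind, qtl_rows)
  qtl_truth <- do.call(rbind, qtl_truth)

  ## ---- PPI cliques and noise ----------------------------------------------
  non_trans <- setdiff(coding_ids, trans_genes)
  stopifnot(length(non_trans) >= sum(cfg$clique_sizes))
  pool <- sample(non_trans)
  ppi_rows <- list(); clique_truth <- list(); off <- 0L
  for (ci in seq_along(cfg$clique_sizes)) {
    mem <- sort(pool[(off + 1L):(off + cfg$clique_sizes[ci])])
    off <- off + cfg$clique_sizes[ci]
    prs <- utils::combn(mem, 2)
    ppi_rows[[length(ppi_rows) + 1L]] <- data.frame(
      protein1 = prs[1, ], protein2 = prs[2, ],
      combined_score = sample(800:950, ncol(prs), replace = TRUE),
      stringsAsFactors = FALSE)
    clique_truth[[ci]] <- mem
  }
  # sparse background noise among the remaining coding genes
  rest <- pool[(off + 1L):length(pool)]
  if (length(rest) >= 2L) {
    n_noise <- min(20L, choose(length(rest), 2))
    all_pairs <- utils::combn(rest, 2)
    sel <- sample(ncol(all_pairs), n_noise)
    ppi_rows[[length(ppi_rows) + 1L]] <- data.frame(
      protein1 = all_pairs[1, sel], protein2 = all_pairs[2, sel],
      combined_score = sample(150:400, n_noise, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  ppi_tbl <- do.call(rbind, ppi_rows)

  ## ---- GMT with one planted enriched set ----------------------------------
  enriched_members <- clique_truth[[1]]
  gmt <- list(PLANTED_SET = unique(c(enriched_members,
                                     sample(coding_ids, 3))))
  for (k in 2:8)
    gmt[[sprintf("RANDOM_SET_%d", k)]] <- sample(coding_ids,
                                                 sample(8:20, 1))

  ## ---- previously-reported lncRNA catalog ---------------------------------
  prev_ids <- utils::head(planted_linc, 3)
  prev_rows <- do.call(rbind, lapply(prev_ids, function(id) {
    row <- asm_rows_span(asm_rows, id)
    data.frame(chrom = row$chrom, start = row$start, end = row$end,
               name = paste0("known_", id), stringsAsFactors = FALSE)
  }))

  ## ---- write everything ---------------------------------------------------
  paths <- list()
  wp <- function(name, fname) {
    paths[[name]] <<- file.path(out_dir, fname)
    paths[[name]]
  }
  wtsv <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)

  ref_ann <- genome_annotation(do.call(rbind, ref_rows))
  write_gtf(ref_ann, wp("reference_gtf", "reference.gtf"), "synthetic")
  asm_ann <- genome_annotation(do.call(rbind, asm_rows))
  write_gtf(asm_ann, wp("assembled_gtf", "assembled.gtf"), "synthetic")

  fasta <- unlist(lapply(names(sequences), function(id)
    c(paste0(">", id), sequences[[id]])))
  writeLines(fasta, wp("fasta", "transcripts.fa"))

  if (length(repeat_rows)) {
    rp <- do.call(rbind, repeat_rows)
    writeLines(sprintf("%s\t%d\t%d\trepeat_%d", rp$chrom, rp$start - 1L,
                       rp$end, seq_len(nrow(rp))),
               wp("repeats_bed", "repeats.bed"))
  } else writeLines(character(), wp("repeats_bed", "repeats.bed"))

  expr_df <- data.frame(feature_id = rownames(expr), expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  wtsv(expr_df, wp("expression", "expression.tsv"))
  wtsv(data.frame(sample = samples, group = unname(groups)),
       wp("groups", "groups.tsv"))
  wtsv(de_tbl, wp("de_table", "de_table.tsv"))
  wtsv(hits_tbl, wp("hits", "homology_hits.tsv"))
  wtsv(domains_tbl, wp("domains", "domain_hits.tsv"))
  wtsv(scores_tbl, wp("scores", "coding_scores.tsv"))
  wtsv(xs_tbl, wp("cross_species_hits", "cross_species_hits.tsv"))
  for (sp in species) {
    wtsv(foreign[[sp]]$genes, wp(paste0("foreign_genes_", sp),
                                 sprintf("foreign_genes_%s.tsv", sp)))
    wtsv(foreign[[sp]]$lincs, wp(paste0("foreign_lincs_", sp),
                                 sprintf("foreign_lincs_%s.tsv", sp)))
    wtsv(foreign[[sp]]$orthologs, wp(paste0("orthologs_", sp),
                                     sprintf("orthologs_%s.tsv", sp)))
  }
  wtsv(qtl_tbl, wp("qtl", "qtl.tsv"))
  wtsv(ppi_tbl, wp("ppi", "ppi.tsv"))
  writeLines(vapply(names(gmt), function(nm)
    paste(c(nm, "synthetic gene set", gmt[[nm]]), collapse = "\t"),
    character(1)), wp("gmt", "gene_sets.gmt"))
  wtsv(prev_rows, wp("known_catalog", "known_lnc_catalog.tsv"))

  manifest <- data.frame(role = names(paths),
                         path = basename(unlist(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$manifest <- file.path(out_dir, "MANIFEST.tsv")

  truth <- list(
    transcripts = truth_tx,
    breed_specific = do.call(rbind, bs_truth),
    trans_pairs = trans_truth,
    de_ids = sort(de_candidates),
    conserved = cons_truth,
    syntenic = synt_truth,
    syntenic_all_species = sort(synt_all),
    qtl = qtl_truth,
    cliques = clique_truth,
    enriched_set = "PLANTED_SET",
    ilnc_host = ilnc_host,
    previously_reported = sort(prev_ids),
    neighbors = neighbors)

  invisible(list(paths = paths, truth = truth, config = cfg,
                 out_dir = out_dir))
}

# span (chrom, start, end) of a transcript id within accumulated exon rows
asm_rows_span <- function(asm_rows, id) {
  for (df in asm_rows) {
    if (df$transcript_id[1] == id)
      return(list(chrom = df$chrom[1], start = min(df$start),
                  end = max(df$end)))
  }
  stop("transcript not found: ", id)
}

# place one intergenic unit at `start`; returns exon rows, sequence, truth
place_unit <- function(u, ch, start, cfg) {
  gc <- cfg$gc_target
  res <- list(repeat_iv = NULL, seq = NULL, expected_step = "survive")
  if (u$kind == "known_linc") {
    n_ex <- sample(1:3, 1)
    lay <- make_exons(start, n_ex, sample(300:900, n_ex, replace = TRUE),
                      if (n_ex > 1) sample(500:2000, n_ex - 1,
                                           replace = TRUE) else integer())
    res$exons <- data.frame(chrom = ch, start = lay$starts, end = lay$ends,
                            strand = "+", transcript_id = paste0(u$id, ".t1"),
                            gene_id = u$id, biotype = "known_lncRNA",
                            stringsAsFactors = FALSE)
    res$span_end <- lay$span_end
    return(res)
  }
  spec <- switch(
    u$kind,
    planted_linc = list(n_ex = sample(1:4, 1), len = sample(300:1800, 1)),
    decoy_min_length = list(n_ex = 1L, len = sample(120:200, 1),
                            step = "structural"),
    decoy_monoexon_too_long = list(n_ex = 1L, len = sample(10500:12000, 1),
                                   step = "structural"),
    decoy_monoexon_repeat = list(n_ex = 1L, len = sample(500:2000, 1),
                                 step = "structural", repeat_hit = TRUE),
    decoy_low_expression = list(n_ex = sample(1:3, 1),
                                len = sample(300:1500, 1),
                                step = "expression"),
    decoy_homology_hit = list(n_ex = sample(1:3, 1),
                              len = sample(300:1500, 1), step = "homology"),
    decoy_domain_hit = list(n_ex = sample(1:3, 1),
                            len = sample(300:1500, 1), step = "domains"),
    decoy_coding_vote = list(n_ex = sample(1:3, 1),
                             len = sample(300:1500, 1),
                             step = "coding_vote"),
    decoy_long_orf = list(n_ex = 2L, len = sample(1100:1400, 1),
                          step = "orf", long_orf = TRUE),
    decoy_near_coding_gene = list(n_ex = sample(1:2, 1),
                                  len = sample(300:1000, 1),
                                  step = "proximity"),
    stop("unknown unit kind: ", u$kind))
  if (!is.null(spec$step)) res$expected_step <- spec$step
  n_ex <- spec$n_ex
  # split the spliced length over exons
  if (n_ex == 1L) ex_l <- spec$len else {
    cut <- sort(sample(seq_len(spec$len - 1L), n_ex - 1L))
    ex_l <- diff(c(0L, cut, spec$len))
    ex_l <- pmax(ex_l, 30L)
  }
  lay <- make_exons(start, n_ex, ex_l,
                    if (n_ex > 1) sample(300:1500, n_ex - 1, replace = TRUE)
                    else integer())
  res$exons <- data.frame(chrom = ch, start = lay$starts, end = lay$ends,
                          strand = "+", transcript_id = u$id, gene_id = u$id,
                          biotype = "novel", stringsAsFactors = FALSE)
  res$span_end <- lay$span_end
  total_len <- sum(lay$ends - lay$starts + 1L)
  res$seq <- if (isTRUE(spec$long_orf))
    seq_with_orf(total_len, gc, 320L) else seq_capped_orf(total_len, gc)
  if (isTRUE(spec$repeat_hit))
    res$repeat_iv <- data.frame(
      chrom = ch, start = lay$starts[1] + 10L,
      end = min(lay$ends[1], lay$starts[1] + 120L), stringsAsFactors = FALSE)
  res
}
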