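#' @importFrom igraph graph_from_data_frame components V vcount as_adjacency_matrix
NULL

#' Merge co-expression and PPI edges into one weighted network
#'
#' Co-expression edges are weighted by absolute correlation; PPI edges by
#' score, rescaled from the 0-1000 convention of STRING-style tables to
#' (0,1] when scores above 1 are detected. A pair present in both sources
#' keeps the maximum weight and a concatenated source tag. Self-loops are
#' dropped.
#'
#' @param coexp data.frame of trans assignments: `lnc_id`, `gene_id`, `r`
#'   (may have zero rows).
#' @param ppi data.frame `protein1`, `protein2`, `combined_score` (may have
#'   zero rows).
#' @param min_ppi_score drop PPI edges below this score, on the input scale
#'   (default 0).
#' @param node_kind optional named character vector id -> kind
#'   (`lncRNA`/`protein_coding`); lnc ids default to `lncRNA`, others to
#'   `protein_coding`.
#' @return a `weighted_network`: list with `edges` data.frame (`a`, `b`,
#'   `weight`, `source`) and `nodes` data.frame (`id`, `kind`).
#' @export
build_network <- function(coexp = NULL, ppi = NULL, min_ppi_score = 0,
                          node_kind = NULL) {
  edges <- list()
  lnc_ids <- character()
  if (!is.null(coexp) && nrow(coexp) > 0L) {
    lnc_ids <- unique(coexp$lnc_id)
    edges[[length(edges) + 1L]] <- data.frame(
      a = coexp$lnc_id, b = coexp$gene_id, weight = abs(coexp$r),
      source = "coexpression", stringsAsFactors = FALSE)
  }
  if (!is.null(ppi) && nrow(ppi) > 0L) {
    ppi <- ppi[ppi$combined_score >= min_ppi_score, , drop = FALSE]
    w <- ppi$combined_score
    if (any(w > 1)) w <- w / 1000
    edges[[length(edges) + 1L]] <- data.frame(
      a = ppi$protein1, b = ppi$protein2, weight = w, source = "ppi",
      stringsAsFactors = FALSE)
  }
  if (!length(edges))
    return(structure(list(edges = data.frame(a = character(), b = character(),
                                             weight = numeric(),
                                             source = character(),
                                             stringsAsFactors = FALSE),
                          nodes = data.frame(id = character(),
                                             kind = character(),
                                             stringsAsFactors = FALSE)),
                     class = "weighted_network"))
  e <- do.call(rbind, edges)
  e <- e[e$a != e$b, , drop = FALSE]
  # canonical pair ordering, then resolve duplicates by max weight
  swap <- e$a > e$b
  tmp <- e$a[swap]; e$a[swap] <- e$b[swap]; e$b[swap] <- tmp
  key <- paste(e$a, e$b, sep = "\r")
  merged <- do.call(rbind, lapply(split(seq_len(nrow(e)), key), function(idx) {
    sub <- e[idx, , drop = FALSE]
    data.frame(a = sub$a[1], b = sub$b[1], weight = max(sub$weight),
               source = paste(sort(unique(sub$source)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$a, merged$b), ]
  rownames(merged) <- NULL
  ids <- sort(unique(c(merged$a, merged$b)))
  kind <- if (!is.null(node_kind)) {
    k <- node_kind[ids]
    ifelse(is.na(k), "protein_coding", k)
  } else ifelse(ids %in% lnc_ids, "lncRNA", "protein_coding")
  structure(list(edges = merged,
                 nodes = data.frame(id = ids, kind = unname(kind),
                                    stringsAsFactors = FALSE)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("weighted_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

# dense weighted adjacency matrix of a weighted_network
adjacency <- function(net) {
  ids <- net$nodes$id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    ia <- match(net$edges$a, ids)
    ib <- match(net$edges$b, ids)
    A[cbind(ia, ib)] <- net$edges$weight
    A[cbind(ib, ia)] <- net$edges$weight
  }
  A
}

#' Cohesiveness of a node subset
#'
#' f(V) = w_in / (w_in + w_bound + penalty * |V|), where w_in is the total
#' weight of edges with both ends in V and w_bound the total weight of
#' edges crossing the boundary of V. The additive penalty models unobserved
#' edges and discourages loose growth.
#'
#' @param members character vector of node ids (non-empty).
#' @param net a `weighted_network`, or a precomputed adjacency matrix.
#' @param penalty per-node penalty (default 2.0).
#' @return numeric in [0, 1].
#' @export
cohesiveness <- function(members, net, penalty = 2.0) {
  if (length(members) == 0L) stop("empty node subset")
  A <- if (is.matrix(net)) net else adjacency(net)
  if (!all(members %in% rownames(A))) stop("unknown node in subset")
  inside <- rownames(A) %in% members
  w_in <- sum(A[inside, inside, drop = FALSE]) / 2
  w_bound <- sum(A[inside, !inside, drop = FALSE])
  denom <- w_in + w_bound + penalty * sum(inside)
  if (denom == 0) return(0)
  w_in / denom
}

#' Greedy cohesive module growth from a seed node
#'
#' Starts from the seed and repeatedly applies the single best add-a-
#' boundary-node or remove-a-member step, as long as it strictly increases
#' cohesiveness; stops at a local maximum. Ties are broken by node id, so
#' the procedure is deterministic.
#'
#' @param seed node id.
#' @param net `weighted_network` or adjacency matrix.
#' @param penalty see [cohesiveness()].
#' @return character vector of member node ids (sorted).
#' @export
grow_module <- function(seed, net, penalty = 2.0) {
  A <- if (is.matrix(net)) net else adjacency(net)
  ids <- rownames(A)
  if (!(seed %in% ids)) stop("seed not in network: ", seed)
  deg_w <- rowSums(A)
  members <- seed
  repeat {
    inside <- ids %in% members
    w_in <- sum(A[inside, inside, drop = FALSE]) / 2
    w_bound <- sum(A[inside, !inside, drop = FALSE])
    f0 <- {
      d <- w_in + w_bound + penalty * length(members)
      if (d == 0) 0 else w_in / d
    }
    # connectivity of each node to the current member set
    conn <- rowSums(A[, members, drop = FALSE])
    ops <- list()
    # additions: boundary nodes (positive connectivity, not members)
    for (v in ids[!inside & conn > 0]) {
      w_in2 <- w_in + conn[v]
      w_bound2 <- w_bound - conn[v] + (deg_w[v] - conn[v])
      ops[[length(ops) + 1L]] <- list(
        type = "add", node = v,
        f = w_in2 / (w_in2 + w_bound2 + penalty * (length(members) + 1L)))
    }
    # removals (keep at least one node)
    if (length(members) > 1L) {
      for (v in members) {
        w_in2 <- w_in - conn[v]
        w_bound2 <- w_bound + conn[v] - (deg_w[v] - conn[v])
        ops[[length(ops) + 1L]] <- list(
          type = "remove", node = v,
          f = w_in2 / (w_in2 + w_bound2 + penalty * (length(members) - 1L)))
      }
    }
    fs <- vapply(ops, `[[`, numeric(1), "f")
    improving <- which(fs > f0 + 1e-12)
    if (!length(improving)) break
    # best improvement; ties broken by node id for determinism
    best_f <- max(fs[improving])
    tied <- improving[fs[improving] >= best_f - 1e-12]
    tied <- tied[order(vapply(ops[tied], `[[`, character(1), "node"))]
    best_op <- ops[[tied[1]]]
    if (best_op$type == "add") members <- c(members, best_op$node)
    else members <- setdiff(members, best_op$node)
  }
  sort(members)
}

# one-sided rank test: are member nodes' in-module incident weights larger
# than their out-of-module incident weights?
module_pvalue <- function(members, A) {
  inside <- rownames(A) %in% members
  in_w <- rowSums(A[inside, inside, drop = FALSE])
  out_w <- rowSums(A[inside, !inside, drop = FALSE])
  if (all(in_w == out_w)) return(1)
  suppressWarnings(
    stats::wilcox.test(in_w, out_w, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value)
}

#' Detect cohesive, significance-filtered overlapping modules
#'
#' Grows a candidate module from every node not yet covered by an earlier
#' candidate (seeds visited in decreasing weighted-degree order, ties by
#' id), merges candidates whose overlap score
#' omega(A,B) = |A∩B|^2 / (|A|·|B|) reaches `overlap_merge`, discards
#' modules of size below `min_size`, scores each remaining module with a
#' one-sided rank test of member in-module versus out-of-module incident
#' weight, keeps p <= p_max and returns modules sorted by p-value.
#'
#' Candidates below a minimum internal density
#' 2 * w_in / (|V| * (|V| - 1)) are discarded before significance testing,
#' mirroring the published overlapping-neighborhood-expansion procedure;
#' the default follows that tool's auto rule (0.5 for unweighted graphs,
#' 0.3 when edge weights vary).
#'
#' @param net a `weighted_network`.
#' @param min_size minimum module size, inclusive (default 6, i.e. strictly
#'   more than 5 genes).
#' @param p_max significance ceiling, inclusive (default 0.01).
#' @param overlap_merge omega threshold for merging (default 0.8).
#' @param penalty growth penalty (default 2.0).
#' @param min_density minimum internal weighted density; `NULL` (default)
#'   selects 0.5 when every edge weight equals 1 and 0.3 otherwise.
#' @return list of modules, each a list with `members`, `size`,
#'   `cohesiveness`, `density`, `p_value`.
#' @export
detect_modules <- function(net, min_size = 6L, p_max = 0.01,
                           overlap_merge = 0.8, penalty = 2.0,
                           min_density = NULL) {
  if (is.null(min_density))
    min_density <- if (nrow(net$edges) && all(net$edges$weight == 1)) 0.5
      else 0.3
  A <- adjacency(net)
  if (nrow(A) == 0L) return(list())
  deg_w <- rowSums(A)
  seeds <- rownames(A)[order(-deg_w, rownames(A))]
  covered <- character()
  cands <- list()
  for (s in seeds) {
    if (s %in% covered) next
    m <- grow_module(s, A, penalty)
    covered <- union(covered, m)
    cands[[length(cands) + 1L]] <- m
  }
  # merge highly overlapping candidates (union), iterate to fixpoint
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < length(cands)) {
      j <- i + 1L
      while (j <= length(cands)) {
        ov <- length(intersect(cands[[i]], cands[[j]]))^2 /
          (length(cands[[i]]) * length(cands[[j]]))
        if (ov >= overlap_merge) {
          cands[[i]] <- sort(union(cands[[i]], cands[[j]]))
          cands[[j]] <- NULL
          merged_any <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  cands <- unique(cands)
  cands <- Filter(function(m) length(m) >= min_size, cands)
  cands <- Filter(function(m) {
    inside <- rownames(A) %in% m
    w_in <- sum(A[inside, inside, drop = FALSE]) / 2
    2 * w_in / (length(m) * (length(m) - 1)) >= min_density
  }, cands)
  mods <- lapply(cands, function(m) {
    inside <- rownames(A) %in% m
    w_in <- sum(A[inside, inside, drop = FALSE]) / 2
    list(members = m, size = length(m),
         cohesiveness = cohesiveness(m, A, penalty),
         density = 2 * w_in / (length(m) * (length(m) - 1)),
         p_value = module_pvalue(m, A))
  })
  mods <- Filter(function(x) x$p_value <= p_max, mods)
  mods[order(vapply(mods, `[[`, numeric(1), "p_value"),
             vapply(mods, function(m) m$members[1], character(1)))]
}

#' Export modules as a data.frame
#'
#' @param modules list from [detect_modules()].
#' @return data.frame `module`, `size`, `cohesiveness`, `p_value`,
#'   `members` (comma-joined).
#' @export
modules_table <- function(modules) {
  if (!length(modules))
    return(data.frame(module = integer(), size = integer(),
                      cohesiveness = numeric(), p_value = numeric(),
                      members = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    data.frame(module = i, size = m$size, cohesiveness = m$cohesiveness,
               p_value = m$p_value,
               members = paste(m$members, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
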