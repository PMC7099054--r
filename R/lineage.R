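#' Identify multi-compartmental clones
#'
#' A clone qualifies when its clonal cluster contains at least one sequence
#' from each of the paired compartments (blood and synovium) of a donor.
#'
#' @param cluster_set a [cluster_clones()] result over the paired samples
#'   (clustered jointly).
#' @return character vector of qualifying `clone_id`s.
#' @export
find_multicompartment_clones <- function(cluster_set) {
  rec <- cluster_set$records
  has_b <- rowsum(as.integer(rec$compartment == "blood"), rec$clone_id)
  has_s <- rowsum(as.integer(rec$compartment == "synovium"), rec$clone_id)
  rownames(has_b)[has_b[, 1L] > 0L & has_s[match(rownames(has_b),
                                                 rownames(has_s)), 1L] > 0L]
}

# ---------------------------------------------------------------------------
# maximum parsimony over clone member sequences (Fitch counting)
# ---------------------------------------------------------------------------

BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

seq_to_bits <- function(s) {
  b <- BASE_BITS[strsplit(s, "")[[1]]]
  b[is.na(b)] <- 15L  # ambiguous = any base
  unname(b)
}

# all unrooted binary tree topologies over taxa 1..m as edge matrices;
# internal nodes are numbered m+1, m+2, ... in insertion order
enumerate_topologies <- function(m) {
  if (m < 2L) stop("need >= 2 taxa")
  if (m == 2L) return(list(matrix(c(1L, 2L), ncol = 2L)))
  base <- matrix(c(1L, m + 1L, 2L, m + 1L, 3L, m + 1L), ncol = 2L,
                 byrow = TRUE)
  trees <- list(base)
  if (m == 3L) return(trees)
  for (t in 4L:m) {
    new_internal <- m + t - 2L
    out <- vector("list", 0L)
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        t2 <- tr[-e, , drop = FALSE]
        t2 <- rbind(t2,
                    c(tr[e, 1L], new_internal),
                    c(new_internal, tr[e, 2L]),
                    c(t, new_internal))
        out[[length(out) + 1L]] <- t2
      }
    }
    trees <- out
  }
  trees
}

# adjacency list from an edge matrix
tree_adjacency <- function(edges, n_nodes) {
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Fitch parsimony score of a topology rooted at taxon 1 (the germline).
# leaf_bits: list of integer vectors (bit-encoded bases) per taxon.
fitch_score <- function(edges, leaf_bits) {
  m <- length(leaf_bits)
  n_nodes <- max(edges)
  if (m == 2L) {
    return(sum(bitwAnd(leaf_bits[[1L]], leaf_bits[[2L]]) == 0L))
  }
  adj <- tree_adjacency(edges, n_nodes)
  # iterative postorder from the germline leaf
  root_top <- adj[[1L]][1L]
  order <- integer(0)
  parent <- integer(n_nodes)
  stack <- root_top
  parent[root_top] <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    for (u in adj[[v]]) {
      if (u != parent[v]) {
        parent[u] <- v
        stack <- c(stack, u)
      }
    }
  }
  L <- length(leaf_bits[[1L]])
  masks <- vector("list", n_nodes)
  for (v in seq_len(m)) masks[[v]] <- leaf_bits[[v]]
  score <- 0L
  for (v in rev(order)) {
    if (v <= m) next
    kids <- adj[[v]][adj[[v]] != parent[v]]
    mk <- masks[[kids[1L]]]
    for (k in kids[-1L]) {
      inter <- bitwAnd(mk, masks[[k]])
      un <- inter == 0L
      score <- score + sum(un)
      mk[un] <- bitwOr(mk[un], masks[[k]][un])
      mk[!un] <- inter[!un]
    }
    masks[[v]] <- mk
  }
  score + sum(bitwAnd(masks[[root_top]], leaf_bits[[1L]]) == 0L)
}

# assign ancestral states down from the germline root; returns a list of
# base-bit vectors per node (single bits for internals)
fitch_states <- function(edges, leaf_bits) {
  m <- length(leaf_bits)
  n_nodes <- max(edges)
  adj <- tree_adjacency(edges, n_nodes)
  if (m == 2L) {
    return(list(states = leaf_bits, parent = c(0L, 1L)))
  }
  root_top <- adj[[1L]][1L]
  parent <- integer(n_nodes); parent[root_top] <- 1L
  order <- integer(0)
  stack <- root_top
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (u in adj[[v]]) if (u != parent[v]) { parent[u] <- v; stack <- c(stack, u) }
  }
  masks <- vector("list", n_nodes)
  for (v in seq_len(m)) masks[[v]] <- leaf_bits[[v]]
  for (v in rev(order)) {
    if (v <= m) next
    kids <- adj[[v]][adj[[v]] != parent[v]]
    mk <- masks[[kids[1L]]]
    for (k in kids[-1L]) {
      inter <- bitwAnd(mk, masks[[k]])
      un <- inter == 0L
      mk[un] <- bitwOr(mk[un], masks[[k]][un])
      mk[!un] <- inter[!un]
    }
    masks[[v]] <- mk
  }
  lowest_bit <- function(x) bitwAnd(x, -x)
  states <- vector("list", n_nodes)
  states[[1L]] <- leaf_bits[[1L]]
  for (v in order) {
    ps <- states[[parent[v]]]
    mk <- masks[[v]]
    inherit <- bitwAnd(ps, mk) != 0L
    st <- integer(length(mk))
    st[inherit] <- ps[inherit]
    st[!inherit] <- lowest_bit(mk[!inherit])
    if (v <= m) st <- mk   # observed leaves keep their own sequence
    states[[v]] <- st
  }
  list(states = states, parent = parent)
}

bits_to_seq <- function(bits) {
  paste0(names(BASE_BITS)[match(bits, BASE_BITS)], collapse = "")
}

stepwise_topology <- function(leaf_bits) {
  m <- length(leaf_bits)
  edges <- matrix(c(1L, m + 1L, 2L, m + 1L, 3L, m + 1L), ncol = 2L,
                  byrow = TRUE)
  next_internal <- m + 2L
  for (t in 4L:m) {
    best <- NULL; best_score <- Inf
    for (e in seq_len(nrow(edges))) {
      t2 <- rbind(edges[-e, , drop = FALSE],
                  c(edges[e, 1L], next_internal),
                  c(next_internal, edges[e, 2L]),
                  c(t, next_internal))
      sc <- fitch_score(t2, leaf_bits[seq_len(t)])
      if (sc < best_score) { best_score <- sc; best <- t2 }
    }
    edges <- best
    next_internal <- next_internal + 1L
  }
  edges
}

nni_refine <- function(edges, leaf_bits, max_pass = 5L) {
  m <- length(leaf_bits)
  score <- fitch_score(edges, leaf_bits)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    internal <- which(edges[, 1L] > m & edges[, 2L] > m)
    for (e in internal) {
      a <- edges[e, 1L]; b <- edges[e, 2L]
      a_nb <- setdiff(c(edges[edges[, 1L] == a, 2L],
                        edges[edges[, 2L] == a, 1L]), b)
      b_nb <- setdiff(c(edges[edges[, 1L] == b, 2L],
                        edges[edges[, 2L] == b, 1L]), a)
      if (length(a_nb) < 2L || length(b_nb) < 2L) next
      for (sw in 1:2) {
        y <- a_nb[2L]; z <- b_nb[sw]
        t2 <- edges
        for (r in seq_len(nrow(t2))) {
          if (all(sort(t2[r, ]) == sort(c(a, y)))) t2[r, ] <- c(a, z)
          else if (all(sort(t2[r, ]) == sort(c(b, z)))) t2[r, ] <- c(b, y)
        }
        sc <- fitch_score(t2, leaf_bits)
        if (sc < score) {
          edges <- t2; score <- sc; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  edges
}

#' Build a maximum-parsimony lineage tree for one clone
#'
#' Infers a germline-rooted lineage over the clone's unique member
#' sequences by Fitch parsimony: exhaustive search over all unrooted binary
#' topologies for up to `exhaustive_max` unique sequences (10395 topologies
#' at 7), and stepwise addition with nearest-neighbor-interchange refinement
#' beyond. Ancestral sequences are reconstructed top-down (preferring the
#' parent state on ties); inferred nodes identical to an observed child are
#' collapsed into it, which is how observed sequences become internal nodes
#' of the lineage.
#'
#' @param records clone member records (equal-length `sequence`, `v_call`,
#'   `compartment`, `duplicate_count`, `sequence_id`, `v_mutation_count`).
#' @param germline_nt germline root sequence (same length as the members;
#'   see [clone_germline()]).
#' @param exhaustive_max leaf count up to which the search is exhaustive.
#' @return an `igraph` directed graph (class kept as igraph) with vertex
#'   attributes `name`, `tissue` (germline/blood/synovium/inferred),
#'   `mutation_count`, `duplicate_count`, and graph attribute
#'   `parsimony_score`; edges point away from the germline root.
#' @export
build_lineage <- function(records, germline_nt, exhaustive_max = 7L) {
  stopifnot(nrow(records) >= 1L)
  lens <- unique(nchar(c(records$sequence, germline_nt)))
  if (length(lens) != 1L) {
    stop("clone member sequences must share one length with the germline")
  }
  # unique sequences per compartment
  key <- paste(records$sequence, records$compartment, sep = "\r")
  dup <- rowsum(records$duplicate_count, key)
  first <- !duplicated(key)
  u <- records[first, , drop = FALSE]
  u$duplicate_count <- as.integer(dup[match(key[first], rownames(dup)), 1L])
  u <- u[order(u$v_mutation_count, u$sequence, u$compartment), , drop = FALSE]
  n <- nrow(u)

  if (n == 1L) {
    warning("single unique sequence; trivial lineage")
    g <- igraph::make_graph(c(1, 2), directed = TRUE)
    igraph::V(g)$name <- c("germline", u$sequence_id[1L])
    igraph::V(g)$tissue <- c("germline", u$compartment[1L])
    igraph::V(g)$mutation_count <- c(0, u$v_mutation_count[1L])
    igraph::V(g)$duplicate_count <- c(0, u$duplicate_count[1L])
    g <- igraph::set_graph_attr(g, "parsimony_score",
                                sum(seq_to_bits(germline_nt) !=
                                      seq_to_bits(u$sequence[1L])))
    return(g)
  }

  # restrict to variable columns for speed; score is unaffected elsewhere
  allseq <- c(germline_nt, u$sequence)
  mat <- do.call(rbind, lapply(allseq, seq_to_bits))
  varying <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
  leaf_bits <- lapply(seq_len(nrow(mat)), function(i) mat[i, varying])

  m <- n + 1L  # taxa = germline + unique sequences
  if (m <= 3L) {
    edges <- enumerate_topologies(m)[[1L]]
  } else if (n <= exhaustive_max) {
    tops <- enumerate_topologies(m)
    scores <- vapply(tops, fitch_score, 0L, leaf_bits = leaf_bits)
    edges <- tops[[which.min(scores)]]
  } else {
    edges <- stepwise_topology(leaf_bits)
    edges <- nni_refine(edges, leaf_bits)
  }
  score <- fitch_score(edges, leaf_bits)
  st <- fitch_states(edges, leaf_bits)
  n_nodes <- max(edges)

  # rebuild full-length sequences for internal nodes
  base_template <- mat[1L, ]
  node_seq <- character(n_nodes)
  node_seq[1L] <- germline_nt
  for (v in 2L:n_nodes) {
    bits <- base_template
    bits[varying] <- st$states[[v]]
    node_seq[v] <- if (v <= m) c(germline_nt, u$sequence)[v] else
      bits_to_seq(bits)
  }

  tissue <- c("germline", u$compartment,
              rep("inferred", max(0L, n_nodes - m)))
  vname <- c("germline", u$sequence_id,
             if (n_nodes > m) sprintf("inferred_%d", seq_len(n_nodes - m)))
  dupc <- c(0L, u$duplicate_count, rep(0L, max(0L, n_nodes - m)))

  # contract zero-length inferred->child edges (child inherits the parent's
  # other children); prefer the first identical child deterministically
  parent <- st$parent
  alive <- rep(TRUE, n_nodes)
  repr <- seq_len(n_nodes)  # representative after contraction
  for (v in seq_len(n_nodes)) {
    if (v <= m || !alive[v]) next
    kids <- which(parent == v & alive)
    same <- kids[node_seq[kids] == node_seq[v]]
    if (length(same)) {
      tgt <- same[1L]
      alive[v] <- FALSE
      repr[v] <- tgt
      parent[kids[kids != tgt]] <- tgt
      parent[tgt] <- parent[v]
    }
  }
  resolve <- function(v) { while (!alive[v]) v <- repr[v]; v }
  # inferred nodes identical to their (resolved) parent merge upward
  for (v in seq_len(n_nodes)) {
    if (v <= m || !alive[v]) next
    p <- if (parent[v] > 0L) resolve(parent[v]) else 0L
    if (p > 0L && p != v && node_seq[p] == node_seq[v]) {
      alive[v] <- FALSE
      repr[v] <- p
      parent[parent == v] <- p
    }
  }
  idx <- which(alive)
  remap <- match(seq_len(n_nodes), idx)
  el <- cbind(vapply(parent[idx[idx != 1L]], resolve, 0L), idx[idx != 1L])
  el <- el[el[, 1L] != 0L, , drop = FALSE]
  g <- igraph::graph_from_edgelist(matrix(remap[el], ncol = 2L),
                                   directed = TRUE)
  igraph::V(g)$name <- vname[idx]
  igraph::V(g)$tissue <- tissue[idx]
  mutc <- vapply(idx, function(v) {
    if (v == 1L) 0L
    else if (v <= m) as.integer(u$v_mutation_count[v - 1L])
    else sum(seq_to_bits(node_seq[v]) != seq_to_bits(germline_nt))
  }, 0L)
  igraph::V(g)$mutation_count <- mutc
  igraph::V(g)$duplicate_count <- dupc[idx]
  igraph::set_graph_attr(g, "parsimony_score", score)
}

#' Germline root sequence for a clone
#'
#' The clone's modal V allele germline followed by the modal observed
#' non-V tail (junction insert, J segment and constant stub are not
#' germline-encoded, so the tail is taken from the members).
#'
#' @param records clone member records.
#' @param ref germline reference.
#' @export
clone_germline <- function(records, ref) {
  v <- names(sort(-table(records$v_call)))[1L]
  vseq <- ref$alleles[[v]]$nt_sequence
  tails <- substr(records$sequence, nchar(vseq) + 1L,
                  nchar(records$sequence))
  tail <- names(sort(-table(rep(tails, records$duplicate_count))))[1L]
  paste0(vseq, tail)
}

#' Call synovium-to-periphery egression events on a lineage tree
#'
#' An egression event is a transition from a synovium-labeled node to a
#' blood-labeled node along a directed edge, or along a path whose
#' intermediate nodes are all inferred (tissue of inferred nodes is never
#' imputed).
#'
#' @param tree a [build_lineage()] igraph.
#' @return data frame of events (`from`, `to`), zero rows when none.
#' @export
call_egressions <- function(tree) {
  tis <- igraph::V(tree)$tissue
  nm <- igraph::V(tree)$name
  events <- list()
  syn <- which(tis == "synovium")
  for (s in syn) {
    # descend through inferred-only paths
    frontier <- as.integer(igraph::neighbors(tree, s, mode = "out"))
    while (length(frontier)) {
      v <- frontier[1L]; frontier <- frontier[-1L]
      if (tis[v] == "inferred") {
        frontier <- c(frontier,
                      as.integer(igraph::neighbors(tree, v, mode = "out")))
      } else if (tis[v] == "blood") {
        events[[length(events) + 1L]] <- data.frame(
          from = nm[s], to = nm[v], stringsAsFactors = FALSE)
      }
      # observed synovium nodes terminate the path (their own egressions
      # are found from their own traversal)
    }
  }
  if (length(events)) do.call(rbind, events) else
    data.frame(from = character(0), to = character(0))
}

#' Discard lineage trees containing suspect sequences
#'
#' Any tree containing a sequence flagged as suspected index misassignment
#' is removed entirely.
#'
#' @param trees list of lineage igraphs.
#' @param suspect_ids character vector of flagged sequence ids.
#' @return the filtered list; attribute `n_discarded` counts removals.
#' @export
discard_suspect_lineages <- function(trees, suspect_ids) {
  keep <- vapply(trees, function(g) {
    !any(igraph::V(g)$name %in% suspect_ids)
  }, TRUE)
  out <- trees[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Lineage trees for all multi-compartmental clones of a paired donor
#'
#' Clusters the two compartments jointly, applies the duplicate-count
#' filter, and builds one parsimony lineage per multi-compartmental clone
#' with at least two unique member sequences.
#'
#' @param blood_records,synovium_records collapsed records per compartment.
#' @param ref germline reference.
#' @param min_duplicates duplicate filter (default 2, the paired pathway).
#' @return named list of lineage igraphs keyed by clone id.
#' @export
lineage_trees <- function(blood_records, synovium_records, ref,
                          min_duplicates = 2L) {
  cols <- intersect(names(blood_records), names(synovium_records))
  rec <- rbind(blood_records[cols], synovium_records[cols])
  rec <- rec[rec$duplicate_count >= min_duplicates, , drop = FALSE]
  if (nrow(rec) == 0L) return(list())
  cs <- cluster_clones(rec)
  mc <- find_multicompartment_clones(cs)
  trees <- list()
  for (cid in mc) {
    cl <- cs$records[cs$records$clone_id == cid, , drop = FALSE]
    if (length(unique(cl$sequence)) < 2L) next
    germ <- clone_germline(cl, ref)
    if (any(nchar(cl$sequence) != nchar(germ))) next
    trees[[cid]] <- build_lineage(cl, germ)
  }
  trees
}

#' Export / import a lineage tree as GML
#'
#' @param tree a lineage igraph.
#' @param path output file.
#' @export
write_lineage_gml <- function(tree, path) {
  igraph::write_graph(tree, path, format = "gml")
  invisible(path)
}

#' @rdname write_lineage_gml
#' @export
read_lineage_gml <- function(path) {
  igraph::read_graph(path, format = "gml")
}
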