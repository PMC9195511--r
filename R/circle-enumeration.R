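# Enumeration of plausible circular paths: simple cycles, restricted to a
# single strongly connected component, that alternate between coverage-type
# edges (coverage, coverage+split) and junction-type edges (split, deletion,
# or coverage+split serving as junction). The two-node simplest circle uses
# the two directions of one coverage+split connection in the two roles.

.COV_ROLE <- c("coverage", "coverage+split")
.JUNC_ROLE <- c("split", "deletion", "coverage+split")

#' Strongly connected components of a breakpoint graph
#'
#' @param graph `breakpoint_graph`.
#' @return list of integer vectors of node indices, one per SCC, each sorted;
#'   components ordered by their smallest node.
#' @export
scc_partition <- function(graph) {
  n <- nrow(graph$nodes)
  if (n == 0) return(list())
  if (!nrow(graph$edges)) return(as.list(seq_len(n)))
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(ig, mode = "strong")
  out <- split(seq_len(n), comp$membership)
  out <- lapply(out, function(x) sort(unname(x)))
  unname(out[order(vapply(out, min, numeric(1)))])
}

#' Enumerate plausible circular paths
#'
#' Johnson-style depth-first search for simple cycles, restricted per SCC,
#' with the alternation constraint applied during the search. Nodes not
#' incident to both a coverage-capable and a junction-capable edge cannot lie
#' on a plausible cycle and are excluded up front.
#'
#' @param graph `breakpoint_graph` (pruned).
#' @param max_cycles abort the whole enumeration (with a truncation flag)
#'   after this many raw cycles (default 10000).
#' @param max_edges maximum cycle length in edges (default 64); search
#'   paths reaching this depth are pruned and the result is flagged
#'   truncated, but enumeration of shorter cycles continues.
#' @param require_split if TRUE (default) a candidate must contain at least
#'   one split-bearing junction edge; cycles whose junctions are all
#'   deletions are dropped.
#' @return list of `circle_candidate` objects (deduplicated, canonical,
#'   ids assigned in deterministic order) with attribute `truncated`.
#' @export
enumerate_plausible_cycles <- function(graph, max_cycles = 10000L,
                                       max_edges = 64L,
                                       require_split = TRUE) {
  edges <- graph$edges
  nodes <- graph$nodes
  truncated <- FALSE   # hard abort: max_cycles reached
  depth_hit <- FALSE   # soft truncation: some path pruned at max_edges
  found <- list()
  if (nrow(edges)) {
    cov_cap <- edges$type %in% .COV_ROLE
    junc_cap <- edges$type %in% .JUNC_ROLE
    allowed <- intersect(
      unique(c(edges$from[cov_cap], edges$to[cov_cap])),
      unique(c(edges$from[junc_cap], edges$to[junc_cap])))
    sccs <- scc_partition(graph)
    adj <- split(seq_len(nrow(edges)), edges$from)
    n_found <- 0L

    for (comp in sccs) {
      comp <- intersect(comp, allowed)
      if (length(comp) < 2) next
      compset <- logical(nrow(nodes)); compset[comp] <- TRUE

      for (s in comp) {
        if (truncated) break
        in_path <- logical(nrow(nodes))
        path_nodes <- integer(0)
        path_edges <- integer(0)
        path_roles <- character(0)

        dfs <- function(u, last_role, first_role) {
          if (truncated) return()
          out_e <- adj[[as.character(u)]]
          if (is.null(out_e)) return()
          for (e in out_e) {
            if (truncated) return()
            v <- edges$to[e]
            if (!compset[v] || v < s) next
            ty <- edges$type[e]
            roles <- c(if (ty %in% .COV_ROLE) "cov",
                       if (ty %in% .JUNC_ROLE) "junc")
            for (r in roles) {
              if (!is.na(last_role) && r == last_role) next
              if (v == s) {
                # closing edge: must also alternate against the first edge
                if (is.na(first_role) || r == first_role) next
                if (length(path_edges) + 1L < 2L) next
                n_found <<- n_found + 1L
                found[[n_found]] <<- list(
                  node_seq = c(s, path_nodes),
                  edge_seq = c(path_edges, e),
                  role_seq = c(path_roles, r))
                if (n_found >= max_cycles) truncated <<- TRUE
              } else if (!in_path[v]) {
                if (length(path_edges) + 1L >= max_edges) {
                  depth_hit <<- TRUE
                  next
                }
                in_path[v] <<- TRUE
                path_nodes <<- c(path_nodes, v)
                path_edges <<- c(path_edges, e)
                path_roles <<- c(path_roles, r)
                dfs(v, r, if (is.na(first_role)) r else first_role)
                in_path[v] <<- FALSE
                path_nodes <<- path_nodes[-length(path_nodes)]
                path_edges <<- path_edges[-length(path_edges)]
                path_roles <<- path_roles[-length(path_roles)]
              }
            }
          }
        }
        in_path[s] <- TRUE
        dfs(s, NA_character_, NA_character_)
      }
      if (truncated) break
    }
  }
  if (truncated || depth_hit) {
    warning("cycle enumeration truncated (max_cycles/max_edges reached); ",
            "candidate set may be incomplete")
  }
  # build, filter, canonicalize, deduplicate
  cands <- list()
  sigs <- character(0)
  for (cy in found) {
    cand <- .cycle_to_candidate(cy$node_seq, cy$edge_seq, cy$role_seq,
                                graph)
    if (is.null(cand)) next
    if (require_split && !any(cand$junctions$type == "split")) next
    if (!(cand$signature %in% sigs)) {
      sigs <- c(sigs, cand$signature)
      cands[[length(cands) + 1L]] <- cand
    }
  }
  if (length(cands)) {
    o <- order(vapply(cands, function(x) x$signature, character(1)))
    cands <- cands[o]
    for (i in seq_along(cands)) cands[[i]]$id <- paste0("circle_", i)
  }
  attr(cands, "truncated") <- truncated || depth_hit
  cands
}

# Build a circle_candidate from a node/edge/role sequence; returns NULL for
# degenerate cycles (should not occur from the constrained search).
.cycle_to_candidate <- function(node_seq, edge_seq, role_seq, graph) {
  k <- length(edge_seq)
  if (k < 2 || k %% 2 != 0) return(NULL)
  edges <- graph$edges
  nodes <- graph$nodes
  # canonical orientation before extracting structure
  cn <- .canonical_order(node_seq, edge_seq, role_seq, graph)
  node_seq <- cn$node_seq; edge_seq <- cn$edge_seq; role_seq <- cn$role_seq

  segs <- list(); juncs <- list()
  for (i in seq_len(k)) {
    u <- node_seq[i]
    v <- node_seq[if (i == k) 1L else i + 1L]
    e <- edge_seq[i]
    if (role_seq[i] == "cov") {
      if (nodes$contig[u] != nodes$contig[v]) return(NULL)
      segs[[length(segs) + 1L]] <- data.frame(
        contig = nodes$contig[u],
        start = min(nodes$pos[u], nodes$pos[v]),
        end = max(nodes$pos[u], nodes$pos[v]),
        mean_depth = edges$mean_depth[e], stringsAsFactors = FALSE)
    } else {
      # sides from the flanking coverage segments in traversal order
      iprev <- if (i == 1L) k else i - 1L
      inext <- if (i == k) 1L else i + 1L
      uprev <- node_seq[iprev]
      vnext <- node_seq[if (inext == k) 1L else inext + 1L]
      side_a <- if (nodes$pos[uprev] < nodes$pos[u]) "left" else "right"
      side_b <- if (nodes$pos[vnext] > nodes$pos[v]) "right" else "left"
      juncs[[length(juncs) + 1L]] <- data.frame(
        contig_a = nodes$contig[u], pos_a = nodes$pos[u], side_a = side_a,
        contig_b = nodes$contig[v], pos_b = nodes$pos[v], side_b = side_b,
        type = if (edges$type[e] == "deletion") "deletion" else "split",
        n_split = edges$n_split[e], link_ids = edges$link_ids[e],
        stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)
  junctions <- do.call(rbind, juncs)
  if (is.null(segments) || is.null(junctions)) return(NULL)
  jstr <- vapply(seq_len(nrow(junctions)), function(i) {
    ends <- sort(c(sprintf("%s:%d", junctions$contig_a[i], junctions$pos_a[i]),
                   sprintf("%s:%d", junctions$contig_b[i], junctions$pos_b[i])))
    sprintf("J:%s:%s", junctions$type[i], paste(ends, collapse = "|"))
  }, character(1))
  sig <- paste(
    paste(sort(sprintf("S:%s:%d-%d", segments$contig, segments$start,
                       segments$end)), collapse = ";"),
    paste(sort(jstr), collapse = ";"),
    sep = "||")
  structure(list(
    id = NA_character_,
    node_seq = data.frame(contig = nodes$contig[node_seq],
                          pos = nodes$pos[node_seq],
                          stringsAsFactors = FALSE),
    roles = role_seq,
    types = edges$type[edge_seq],
    segments = segments,
    junctions = junctions,
    length = sum(segments$end - segments$start),
    signature = sig
  ), class = "circle_candidate")
}

# Fix rotation (start at lexicographically smallest node) and direction
# (lexicographically smaller traversal string) of a cycle.
.canonical_order <- function(node_seq, edge_seq, role_seq, graph) {
  nodes <- graph$nodes
  k <- length(node_seq)
  keys <- sprintf("%s:%012d", nodes$contig[node_seq], nodes$pos[node_seq])
  start <- order(keys)[1]
  rot <- function(x, s) if (s == 1) x else c(x[s:length(x)], x[seq_len(s - 1)])
  fwd_nodes <- rot(node_seq, start)
  fwd_edges <- rot(edge_seq, start)
  fwd_roles <- rot(role_seq, start)
  # reverse traversal: nodes reversed keeping start first; edge i' of the
  # reverse between fwd nodes j and j-1 is the partner direction of the same
  # pair; roles travel with the edges
  rev_nodes <- c(fwd_nodes[1], rev(fwd_nodes[-1]))
  rev_edges <- rev(fwd_edges)
  rev_roles <- rev(fwd_roles)
  # map each edge to its opposite-direction row (same pair_id)
  edges <- graph$edges
  opp <- function(e) {
    cand <- which(edges$pair_id == edges$pair_id[e] & seq_len(nrow(edges)) != e)
    if (length(cand) == 1) cand else e
  }
  rev_edges <- vapply(rev_edges, opp, integer(1))
  strfor <- function(ns, rs) paste(sprintf("%s:%012d", nodes$contig[ns],
                                           nodes$pos[ns]), rs,
                                   collapse = ">")
  if (strfor(rev_nodes, rev_roles) < strfor(fwd_nodes, fwd_roles)) {
    list(node_seq = rev_nodes, edge_seq = rev_edges, role_seq = rev_roles)
  } else {
    list(node_seq = fwd_nodes, edge_seq = fwd_edges, role_seq = fwd_roles)
  }
}

#' Canonicalize an alternating cycle
#'
#' Fixes the rotation to start at the lexicographically smallest
#' (contig, position) node and maps a cycle and its reverse traversal to the
#' same canonical form. Rejects sequences violating the alternation rule.
#'
#' @param node_seq integer node indices along the cycle.
#' @param edge_seq integer edge row indices (`graph$edges`), one per step.
#' @param role_seq "cov"/"junc" role of each edge.
#' @param graph `breakpoint_graph`.
#' @return `circle_candidate`.
#' @export
canonicalize <- function(node_seq, edge_seq, role_seq, graph) {
  k <- length(edge_seq)
  if (k < 2 || k %% 2 != 0) stop("cycle must have an even number (>= 2) of edges")
  nxt <- c(role_seq[-1], role_seq[1])
  if (any(role_seq == nxt)) stop("cycle does not alternate roles")
  ty <- graph$edges$type[edge_seq]
  if (any(role_seq == "cov" & !(ty %in% .COV_ROLE)) ||
      any(role_seq == "junc" & !(ty %in% .JUNC_ROLE))) {
    stop("edge type incompatible with assigned role")
  }
  cand <- .cycle_to_candidate(node_seq, edge_seq, role_seq, graph)
  if (is.null(cand)) stop("degenerate cycle")
  cand
}

#' @export
print.circle_candidate <- function(x, ...) {
  cat("circle_candidate", x$id, "-", nrow(x$segments), "segment(s),",
      nrow(x$junctions), "junction(s),", x$length, "bp\n")
  for (i in seq_len(nrow(x$segments))) {
    cat(sprintf("  seg %s:%d-%d (%.1fx)\n", x$segments$contig[i],
                x$segments$start[i], x$segments$end[i],
                x$segments$mean_depth[i]))
  }
  for (i in seq_len(nrow(x$junctions))) {
    cat(sprintf("  junc [%s] %s:%d(%s) ~ %s:%d(%s) n_split=%d\n",
                x$junctions$type[i], x$junctions$contig_a[i],
                x$junctions$pos_a[i], x$junctions$side_a[i],
                x$junctions$contig_b[i], x$junctions$pos_b[i],
                x$junctions$side_b[i], x$junctions$n_split[i]))
  }
  invisible(x)
}
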