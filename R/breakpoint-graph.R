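# Breakpoint graph: nodes are genomic loci where the depth classification
# changes or where split reads start/end; edges are typed
# coverage/deletion/split/coverage+split connections. Neighbour edges
# (coverage, deletion) and split edges are stored as directed edge pairs
# sharing a pair_id, so a circle is traversable in either rotation.

#' Collect breakpoint-graph nodes
#'
#' Nodes are the union of (i) positions where the depth classification
#' changes (zero / sub-threshold / covered at `theta`) and (ii) split-link
#' endpoints. Endpoints within `merge_tol` bases on the same contig are
#' clustered to a single node at the (lower) median position; the mapping
#' from original positions to cluster representatives is attached as
#' attribute `posmap` and used to re-point split links during graph building.
#'
#' @param profile `depth_profile`.
#' @param links `nc_links`.
#' @param merge_tol cluster radius in bp (default 10).
#' @param theta coverage threshold (>= 1, default 1).
#' @param theta_zero deletion threshold: intervals with mean depth at or
#'   below it count as read-free (default 0, the strict no-covering-reads
#'   rule; raise it when a linear background is present).
#' @return data.frame(contig, pos) of class `nc_nodes`, sorted, with
#'   attribute `posmap`.
#' @export
collect_nodes <- function(profile, links, merge_tol = 10L, theta = 1L,
                          theta_zero = 0) {
  stopifnot(merge_tol >= 0, theta >= 1, theta_zero < theta)
  pts <- list()
  if (nrow(profile)) {
    cls <- .depth_class(profile$depth, theta, theta_zero)
    for (ctg in unique(profile$contig)) {
      i <- which(profile$contig == ctg)
      ci <- cls[i]
      # per-contig profiles are contiguous; boundaries are starts + last end,
      # with implicit zero class outside the profiled block
      bounds <- c(profile$start[i], profile$end[i][length(i)])
      ext <- c("zero", ci, "zero")
      pp <- bounds[ext[-length(ext)] != ext[-1]]
      if (length(pp)) {
        pts[[length(pts) + 1L]] <- data.frame(contig = ctg, pos = pp,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (nrow(links)) {
    pts[[length(pts) + 1L]] <- data.frame(
      contig = c(links$contig_a, links$contig_b),
      pos = c(links$pos_a, links$pos_b), stringsAsFactors = FALSE)
  }
  if (!length(pts)) {
    nodes <- data.frame(contig = character(0), pos = integer(0),
                        stringsAsFactors = FALSE)
    attr(nodes, "posmap") <- data.frame(contig = character(0),
                                        pos = integer(0),
                                        node_pos = integer(0))
    attr(nodes, "merge_tol") <- as.integer(merge_tol)
    class(nodes) <- c("nc_nodes", "data.frame")
    return(nodes)
  }
  all_pts <- unique(do.call(rbind, pts))
  all_pts <- all_pts[order(all_pts$contig, all_pts$pos), , drop = FALSE]
  # single-linkage clustering: break where the gap exceeds merge_tol
  maps <- lapply(split(all_pts, all_pts$contig), function(p) {
    gap <- c(Inf, diff(p$pos))
    newc <- gap > merge_tol | c(TRUE, p$contig[-1] != p$contig[-nrow(p)])
    cl <- cumsum(newc)
    rep_pos <- vapply(split(p$pos, cl), function(x) {
      sort(x)[ceiling(length(x) / 2)]  # lower median, integer position
    }, numeric(1))
    data.frame(contig = p$contig, pos = p$pos,
               node_pos = as.integer(rep_pos[cl]), stringsAsFactors = FALSE)
  })
  posmap <- do.call(rbind, maps)
  rownames(posmap) <- NULL
  nodes <- unique(posmap[, c("contig", "node_pos")])
  names(nodes) <- c("contig", "pos")
  nodes <- nodes[order(nodes$contig, nodes$pos), , drop = FALSE]
  rownames(nodes) <- NULL
  attr(nodes, "posmap") <- posmap
  attr(nodes, "merge_tol") <- as.integer(merge_tol)
  class(nodes) <- c("nc_nodes", "data.frame")
  nodes
}

.depth_class <- function(depth, theta, theta_zero = 0) {
  ifelse(depth <= theta_zero, "zero", ifelse(depth >= theta, "cov", "sub"))
}

# Snap split-link endpoints to node representatives using the posmap.
.snap_links <- function(links, posmap) {
  if (!nrow(links)) return(links)
  key <- function(ctg, pos) paste(ctg, pos, sep = ":")
  m <- stats::setNames(posmap$node_pos, key(posmap$contig, posmap$pos))
  links$pos_a <- unname(m[key(links$contig_a, links$pos_a)])
  links$pos_b <- unname(m[key(links$contig_b, links$pos_b)])
  if (anyNA(links$pos_a) || anyNA(links$pos_b)) {
    stop("split-link endpoint not present in node map")
  }
  # a link whose two endpoints collapse to the same node is uninformative
  links[!(links$contig_a == links$contig_b & links$pos_a == links$pos_b), ,
        drop = FALSE]
}

#' Build the typed breakpoint graph
#'
#' Adjacent same-contig node pairs receive a coverage edge (mean depth >=
#' `theta`), a deletion edge (no covering reads), or no neighbour edge
#' (sub-threshold). Split links add split edges between their (snapped)
#' endpoint nodes; a split connection coinciding with a coverage neighbour
#' pair becomes a single coverage+split edge. All connections are inserted
#' as directed edge pairs (both directions, one `pair_id`).
#'
#' @param nodes from [collect_nodes()] on the same inputs.
#' @param profile `depth_profile`.
#' @param links `nc_links`.
#' @param theta coverage threshold (>= 1).
#' @param theta_zero deletion threshold (see [collect_nodes()]).
#' @param max_del_len longest interval that may become a deletion edge
#'   (default Inf: no cap). Deletions inside a circle arise from library
#'   preparation and are bounded by the circle size; a cap prevents
#'   read-free intervals between unrelated covered loci from acting as
#'   junctions.
#' @return object of class `breakpoint_graph`: list(nodes, edges, profile,
#'   links, params).
#' @export
build_graph <- function(nodes, profile, links, theta = 1L, theta_zero = 0,
                        max_del_len = Inf) {
  if (theta < 1) stop("theta must be >= 1")
  if (theta_zero >= theta) stop("theta_zero must be < theta")
  posmap <- attr(nodes, "posmap")
  slinks <- .snap_links(links, posmap)
  edges <- .derive_edges(nodes, profile, slinks, theta, theta_zero,
                         max_del_len)
  g <- list(nodes = as.data.frame(nodes), edges = edges, profile = profile,
            links = slinks,
            params = list(theta = as.integer(theta),
                          theta_zero = theta_zero,
                          max_del_len = max_del_len,
                          merge_tol = attr(nodes, "merge_tol"),
                          mapq_min = attr(profile, "mapq_min")))
  class(g) <- "breakpoint_graph"
  g
}

# Shared by build_graph and prune_graph: derive all edges for a node set.
.derive_edges <- function(nodes, profile, slinks, theta, theta_zero = 0,
                          max_del_len = Inf) {
  nodes <- as.data.frame(nodes)
  nkey <- paste(nodes$contig, nodes$pos, sep = ":")
  nid <- stats::setNames(seq_len(nrow(nodes)), nkey)
  erows <- list()
  pair_id <- 0L
  add_pair <- function(u, v, type, mean_depth = NA_real_, n_split = 0L,
                       link_ids = "") {
    pair_id <<- pair_id + 1L
    erows[[length(erows) + 1L]] <<- data.frame(
      pair_id = pair_id, from = c(u, v), to = c(v, u), type = type,
      mean_depth = mean_depth, n_split = n_split, link_ids = link_ids,
      stringsAsFactors = FALSE)
  }
  # split connections grouped by unordered node pair
  split_pairs <- new.env(parent = emptyenv())
  if (nrow(slinks)) {
    ka <- paste(slinks$contig_a, slinks$pos_a, sep = ":")
    kb <- paste(slinks$contig_b, slinks$pos_b, sep = ":")
    ua <- nid[ka]; ub <- nid[kb]
    lo <- pmin(ua, ub); hi <- pmax(ua, ub)
    grp <- paste(lo, hi, sep = "-")
    for (gkey in unique(grp)) {
      ii <- which(grp == gkey)
      assign(gkey, ii, envir = split_pairs)
    }
  }
  used_split <- character(0)
  # neighbour edges per contig
  for (ctg in unique(nodes$contig)) {
    i <- which(nodes$contig == ctg)
    if (length(i) < 2) next
    pos <- nodes$pos[i]
    for (k in seq_len(length(i) - 1)) {
      u <- i[k]; v <- i[k + 1]
      a <- pos[k]; b <- pos[k + 1]
      integ <- .depth_integral(profile, ctg, a, b)
      md <- integ / (b - a)
      is_del <- md <= theta_zero && (b - a) <= max_del_len
      gkey <- paste(min(u, v), max(u, v), sep = "-")
      ii <- if (exists(gkey, envir = split_pairs)) get(gkey, envir = split_pairs) else integer(0)
      if (is_del) {
        add_pair(u, v, "deletion", mean_depth = md)
        if (length(ii)) {  # deletion and split kept as separate pairs
          add_pair(u, v, "split", n_split = length(ii),
                   link_ids = paste(ii, collapse = ","))
          used_split <- c(used_split, gkey)
        }
      } else if (md >= theta) {
        if (length(ii)) {
          add_pair(u, v, "coverage+split", mean_depth = md,
                   n_split = length(ii), link_ids = paste(ii, collapse = ","))
          used_split <- c(used_split, gkey)
        } else {
          add_pair(u, v, "coverage", mean_depth = md)
        }
      } else {
        # sub-threshold: no neighbour edge, but a split connection survives
        if (length(ii)) {
          add_pair(u, v, "split", n_split = length(ii),
                   link_ids = paste(ii, collapse = ","))
          used_split <- c(used_split, gkey)
        }
      }
    }
  }
  # remaining split pairs (non-neighbours / different contigs)
  for (gkey in ls(split_pairs)) {
    if (gkey %in% used_split) next
    ii <- get(gkey, envir = split_pairs)
    uv <- as.integer(strsplit(gkey, "-", fixed = TRUE)[[1]])
    add_pair(uv[1], uv[2], "split", n_split = length(ii),
             link_ids = paste(ii, collapse = ","))
  }
  edges <- if (length(erows)) do.call(rbind, erows) else
    data.frame(pair_id = integer(0), from = integer(0), to = integer(0),
               type = character(0), mean_depth = numeric(0),
               n_split = integer(0), link_ids = character(0),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  edges
}

#' Prune nodes that cannot lie on a plausible circular path
#'
#' Removes nodes with no incident coverage or coverage+split edge, then
#' re-derives neighbour edges among the survivors (so a deletion interval
#' interrupted by a pruned stray split endpoint is restored as a single
#' deletion edge). Iterates to a fixpoint; pruning is idempotent.
#'
#' @param graph `breakpoint_graph`.
#' @return pruned `breakpoint_graph`.
#' @export
prune_graph <- function(graph) {
  nodes <- graph$nodes
  slinks <- graph$links
  theta <- graph$params$theta
  theta_zero <- if (is.null(graph$params$theta_zero)) 0 else graph$params$theta_zero
  max_del_len <- if (is.null(graph$params$max_del_len)) Inf else graph$params$max_del_len
  repeat {
    edges <- .derive_edges(nodes, graph$profile, slinks, theta, theta_zero,
                           max_del_len)
    covered <- unique(c(edges$from[edges$type %in% c("coverage", "coverage+split")],
                        edges$to[edges$type %in% c("coverage", "coverage+split")]))
    if (length(covered) == nrow(nodes)) break
    keep <- sort(covered)
    if (!length(keep)) {
      nodes <- nodes[0, , drop = FALSE]
      edges <- edges[0, , drop = FALSE]
      break
    }
    newnodes <- nodes[keep, , drop = FALSE]
    rownames(newnodes) <- NULL
    # drop links touching removed nodes
    nkey <- paste(newnodes$contig, newnodes$pos, sep = ":")
    la <- paste(slinks$contig_a, slinks$pos_a, sep = ":")
    lb <- paste(slinks$contig_b, slinks$pos_b, sep = ":")
    slinks <- slinks[la %in% nkey & lb %in% nkey, , drop = FALSE]
    nodes <- newnodes
  }
  out <- graph
  out$nodes <- nodes
  out$edges <- edges
  out$links <- slinks
  class(out) <- "breakpoint_graph"
  out
}

#' @export
print.breakpoint_graph <- function(x, ...) {
  tt <- table(x$edges$type[!duplicated(x$edges$pair_id)])
  cat("breakpoint_graph:", nrow(x$nodes), "nodes,",
      length(unique(x$edges$pair_id)), "connections\n")
  if (length(tt)) {
    cat(paste0("  ", names(tt), ": ", as.integer(tt), collapse = "\n"), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Export / import

#' Convert a breakpoint graph to igraph
#' @param graph `breakpoint_graph`.
#' @return directed igraph with vertex attributes contig/pos and edge
#'   attributes type/mean_depth/n_split/pair_id.
#' @export
as_igraph <- function(graph) {
  vn <- paste(graph$nodes$contig, graph$nodes$pos, sep = ":")
  vdf <- data.frame(name = vn, contig = graph$nodes$contig,
                    pos = graph$nodes$pos, stringsAsFactors = FALSE)
  e <- graph$edges
  edf <- data.frame(from = vn[e$from], to = vn[e$to], type = e$type,
                    mean_depth = ifelse(is.na(e$mean_depth), -1, e$mean_depth),
                    n_split = e$n_split, pair_id = e$pair_id,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

.edge_colors <- c(coverage = "blue", deletion = "red", split = "orange",
                  `coverage+split` = "green")

#' Export a breakpoint graph as GraphML or DOT
#'
#' DOT output colors edges by type following the convention of the QC plots:
#' blue coverage, red deletion, orange split, green coverage+split.
#'
#' @param graph `breakpoint_graph`.
#' @param path output file.
#' @param format "graphml" or "dot".
#' @export
export_graph <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  } else {
    vn <- paste(graph$nodes$contig, graph$nodes$pos, sep = ":")
    e <- graph$edges
    lines <- c("digraph breakpoints {",
               sprintf('  "%s";', vn),
               sprintf('  "%s" -> "%s" [color=%s, label="%s"];',
                       vn[e$from], vn[e$to],
                       .edge_colors[e$type],
                       ifelse(e$type %in% c("coverage", "coverage+split"),
                              sprintf("%.1fx", e$mean_depth), e$type)),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Import a breakpoint graph from GraphML
#'
#' Restores nodes and typed edges (the depth profile and raw links are not
#' stored in GraphML; the result supports enumeration and export, not
#' re-pruning).
#'
#' @param path GraphML file written by [export_graph()].
#' @return `breakpoint_graph`.
#' @export
import_graph <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::vertex_attr(ig)
  nodes <- data.frame(contig = vat$contig, pos = as.integer(vat$pos),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(ig, names = FALSE)
  eat <- igraph::edge_attr(ig)
  edges <- data.frame(pair_id = as.integer(eat$pair_id), from = el[, 1],
                      to = el[, 2], type = eat$type,
                      mean_depth = ifelse(eat$mean_depth < 0, NA_real_,
                                          eat$mean_depth),
                      n_split = as.integer(eat$n_split),
                      link_ids = "", stringsAsFactors = FALSE)
    o <- order(edges$pair_id, edges$from)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  g <- list(nodes = nodes, edges = edges, profile = NULL,
            links = NULL, params = list(theta = NA_integer_))
  class(g) <- "breakpoint_graph"
  g
}
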