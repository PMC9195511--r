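# Deterministic fixtures: idealized read mappings for the three canonical
# circle topologies (single-contig circle; two-contig chimeric circle;
# circle with an internal uncovered deletion), and small graph builders.

# Simple circle on c1:[2000,5000): stacked full-length reads plus two
# junction-crossing split reads (end -> start).
fixture_simple_segments <- function() {
  sort_segments(rbind(
    aligned_segments(paste0("r", 1:5), "c1", 2000, 5000),
    aligned_segments("j1", "c1", 3500, 5000, qstart = 0),
    aligned_segments("j1", "c1", 2000, 3000, qstart = 1500,
                     is_supplementary = TRUE),
    aligned_segments("j2", "c1", 4000, 5000, qstart = 0),
    aligned_segments("j2", "c1", 2000, 2500, qstart = 1000,
                     is_supplementary = TRUE)))
}

# Chimeric circle: c1:[1000,3000) + c2:[500,2500), joined by two split-read
# families (end of each part to start of the other).
fixture_chimeric_segments <- function() {
  sort_segments(rbind(
    aligned_segments(paste0("a", 1:4), "c1", 1000, 3000),
    aligned_segments(paste0("b", 1:4), "c2", 500, 2500),
    # read crossing junction c1-end -> c2-start
    aligned_segments("j1", "c1", 2200, 3000, qstart = 0),
    aligned_segments("j1", "c2", 500, 1200, qstart = 800,
                     is_supplementary = TRUE),
    # read crossing junction c2-end -> c1-start
    aligned_segments("j2", "c2", 1800, 2500, qstart = 0),
    aligned_segments("j2", "c1", 1000, 1700, qstart = 700,
                     is_supplementary = TRUE)))
}

# Circle on c1:[2000,8000) with an uncovered deletion [4000,5000): reads
# stop at the deletion boundaries without linkage; split reads cross only
# the wrap junction 8000 -> 2000.
fixture_deletion_segments <- function() {
  sort_segments(rbind(
    aligned_segments(paste0("l", 1:4), "c1", 2000, 4000),
    aligned_segments(paste0("m", 1:4), "c1", 5000, 8000),
    aligned_segments("j1", "c1", 6500, 8000, qstart = 0),
    aligned_segments("j1", "c1", 2000, 3200, qstart = 1500,
                     is_supplementary = TRUE),
    aligned_segments("j2", "c1", 7000, 8000, qstart = 0),
    aligned_segments("j2", "c1", 2000, 2600, qstart = 1000,
                     is_supplementary = TRUE)))
}

fixture_graph <- function(segments, theta = 1L, merge_tol = 10L) {
  profile <- compute_depth_profile(segments)
  links <- extract_split_links(segments)
  nodes <- collect_nodes(profile, links, merge_tol = merge_tol,
                         theta = theta)
  build_graph(nodes, profile, links, theta = theta)
}

# Unordered typed connection table of a graph: one row per pair_id.
pair_table <- function(graph) {
  e <- graph$edges[!duplicated(graph$edges$pair_id), , drop = FALSE]
  key <- function(i) {
    u <- graph$nodes[e$from[i], ]
    v <- graph$nodes[e$to[i], ]
    ends <- data.frame(contig = c(u$contig, v$contig), pos = c(u$pos, v$pos))
    ends <- ends[order(ends$contig, ends$pos), ]
    paste(paste0(ends$contig, ":", ends$pos), collapse = "~")
  }
  data.frame(pair = vapply(seq_len(nrow(e)), key, character(1)),
             type = e$type, stringsAsFactors = FALSE)
}

# Hand-built breakpoint_graph from a node table and an unordered typed pair
# list; used for enumeration fuzzing against the brute-force oracle.
make_graph_obj <- function(nodes, pairs) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    data.frame(pair_id = i,
               from = c(pairs$u[i], pairs$v[i]),
               to = c(pairs$v[i], pairs$u[i]),
               type = pairs$type[i],
               mean_depth = ifelse(pairs$type[i] %in%
                                     c("coverage", "coverage+split"), 10, 0),
               n_split = ifelse(pairs$type[i] %in%
                                  c("split", "coverage+split"), 2L, 0L),
               link_ids = "", stringsAsFactors = FALSE)
  })
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = integer(0), from = integer(0), to = integer(0),
               type = character(0), mean_depth = numeric(0),
               n_split = integer(0), link_ids = character(0),
               stringsAsFactors = FALSE)
  g <- list(nodes = nodes, edges = edges, profile = NULL,
            links = NULL, params = list(theta = 1L))
  class(g) <- "breakpoint_graph"
  g
}

# Random typed graph on one contig (all node pairs eligible for any type).
random_graph <- function(n_nodes, p_edge = 0.4, seed = 1) {
  withr::with_seed(seed, {
    nodes <- data.frame(contig = "z", pos = 10L * seq_len(n_nodes),
                        stringsAsFactors = FALSE)
    cmb <- utils::combn(n_nodes, 2)
    keep <- stats::runif(ncol(cmb)) < p_edge
    cmb <- cmb[, keep, drop = FALSE]
    types <- sample(c("coverage", "deletion", "split", "coverage+split"),
                    ncol(cmb), replace = TRUE)
    pairs <- data.frame(u = cmb[1, ], v = cmb[2, ], type = types,
                        stringsAsFactors = FALSE)
    make_graph_obj(nodes, pairs)
  })
}

# Random read set (plus split links) for pipeline-level fuzzing.
random_segments <- function(seed, n_reads = 40, contig_len = 20000,
                            n_split = 3) {
  withr::with_seed(seed, {
    st <- sort(sample.int(contig_len - 600, n_reads, replace = TRUE))
    ln <- sample(200:2000, n_reads, replace = TRUE)
    seg <- aligned_segments(sprintf("r%03d", seq_len(n_reads)), "c1",
                            st, pmin(st + ln, contig_len))
    if (n_split > 0) {
      for (k in seq_len(n_split)) {
        a <- sort(sample.int(contig_len - 200, 2))
        seg <- rbind(seg,
          aligned_segments(sprintf("s%02d", k), "c1", a[2],
                           min(a[2] + 500, contig_len), qstart = 0),
          aligned_segments(sprintf("s%02d", k), "c1", a[1],
                           a[1] + 300, qstart = 500,
                           is_supplementary = TRUE))
      }
    }
    sort_segments(seg)
  })
}
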