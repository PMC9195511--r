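# SCC partitioning, plausible-cycle enumeration, canonicalization.

test_that("each canonical topology yields exactly one candidate matching truth", {
  # single-contig circle: one candidate, two edges
  r1 <- enumerate_plausible_cycles(prune_graph(fixture_graph(fixture_simple_segments())))
  expect_length(r1, 1)
  expect_length(r1[[1]]$roles, 2)
  expect_equal(r1[[1]]$segments[, c("contig", "start", "end")],
               data.frame(contig = "c1", start = 2000, end = 5000),
               ignore_attr = TRUE)
  expect_equal(r1[[1]]$junctions$type, "split")

  # chimeric circle: one candidate with both contigs
  r2 <- enumerate_plausible_cycles(prune_graph(fixture_graph(fixture_chimeric_segments())))
  expect_length(r2, 1)
  s2 <- r2[[1]]$segments[order(r2[[1]]$segments$contig), ]
  expect_equal(s2$contig, c("c1", "c2"))
  expect_equal(s2$start, c(1000, 500))
  expect_equal(s2$end, c(3000, 2500))
  expect_equal(sort(r2[[1]]$junctions$type), c("split", "split"))

  # deletion circle: one candidate, deletion + split junctions
  r3 <- enumerate_plausible_cycles(prune_graph(fixture_graph(fixture_deletion_segments())))
  expect_length(r3, 1)
  s3 <- r3[[1]]$segments[order(r3[[1]]$segments$start), ]
  expect_equal(s3$start, c(2000, 5000))
  expect_equal(s3$end, c(4000, 8000))
  expect_setequal(r3[[1]]$junctions$type, c("deletion", "split"))
})

test_that("SCC partition handles the canonical cases", {
  g1 <- fixture_graph(fixture_simple_segments())
  expect_equal(scc_partition(g1), list(c(1L, 2L)))
  # two disjoint circles: two SCCs
  seg <- sort_segments(rbind(fixture_simple_segments(), rbind(
    aligned_segments(c("q1", "q2"), "c9", 100, 900),
    aligned_segments("qj", "c9", 500, 900, qstart = 0),
    aligned_segments("qj", "c9", 100, 400, qstart = 400,
                     is_supplementary = TRUE))))
  g2 <- fixture_graph(seg)
  expect_length(scc_partition(g2), 2)
})

test_that("SCC partition equals the reachability-closure oracle on random digraphs", {
  for (seed in 1:40) {
    n <- withr::with_seed(seed, sample(2:12, 1))
    g <- random_graph(n, p_edge = 0.3, seed = seed)
    got <- scc_partition(g)
    exp <- scc_oracle(n, g$edges$from, g$edges$to)
    expect_equal(got, exp)
  }
})

test_that("enumeration equals the exhaustive cyclic-permutation oracle", {
  for (seed in 1:60) {
    n <- withr::with_seed(seed * 13L, sample(3:6, 1))
    g <- random_graph(n, p_edge = 0.5, seed = seed * 13L)
    cands <- enumerate_plausible_cycles(g, require_split = FALSE)
    got <- sort(vapply(cands, function(x) x$signature, character(1)))
    expect_equal(got, cycle_oracle(g, require_split = FALSE),
                 info = paste("seed", seed))
  }
})

test_that("every emitted candidate alternates and stays inside one SCC", {
  for (seed in c(101, 202, 303)) {
    g <- random_graph(7, p_edge = 0.5, seed = seed)
    sccs <- scc_partition(g)
    comp_of <- integer(nrow(g$nodes))
    for (i in seq_along(sccs)) comp_of[sccs[[i]]] <- i
    cands <- enumerate_plausible_cycles(g, require_split = FALSE)
    for (cand in cands) {
      k <- length(cand$roles)
      expect_true(k %% 2 == 0 && k >= 2)
      nxt <- c(cand$roles[-1], cand$roles[1])
      expect_true(all(cand$roles != nxt))
      # all nodes of the candidate share one SCC
      idx <- vapply(seq_len(nrow(cand$node_seq)), function(i) {
        which(g$nodes$contig == cand$node_seq$contig[i] &
                g$nodes$pos == cand$node_seq$pos[i])
      }, integer(1))
      expect_length(unique(comp_of[idx]), 1)
    }
  }
})

test_that("an SCC with a plasmid homologous to a chromosomal locus yields 3 paths", {
  # plasmid contig P (its own circle) sharing split links with a homologous
  # chromosomal locus: three plausible circular paths in one SCC
  nodes <- data.frame(contig = c("P", "P", "chr8", "chr8"),
                      pos = c(0L, 5000L, 100L, 5100L),
                      stringsAsFactors = FALSE)
  pairs <- data.frame(u = c(1L, 3L, 2L, 4L),
                      v = c(2L, 4L, 3L, 1L),
                      type = c("coverage+split", "coverage+split",
                               "split", "split"),
                      stringsAsFactors = FALSE)
  g <- make_graph_obj(nodes, pairs)
  expect_length(scc_partition(g), 1)
  cands <- enumerate_plausible_cycles(g)
  expect_length(cands, 3)
  nsegs <- sort(vapply(cands, function(x) nrow(x$segments), integer(1)))
  expect_equal(nsegs, c(1L, 1L, 2L))
})

test_that("candidates require split evidence unless disabled", {
  # coverage/deletion alternating square: a cycle with no split support
  nodes <- data.frame(contig = "z", pos = c(10L, 20L, 30L, 40L))
  pairs <- data.frame(u = c(1L, 2L, 3L, 4L), v = c(2L, 3L, 4L, 1L),
                      type = c("coverage", "deletion", "coverage",
                               "deletion"), stringsAsFactors = FALSE)
  g <- make_graph_obj(nodes, pairs)
  expect_length(enumerate_plausible_cycles(g, require_split = TRUE), 0)
  expect_length(enumerate_plausible_cycles(g, require_split = FALSE), 1)
})

test_that("enumeration truncates with a warning when caps are hit", {
  # dense coverage+split clique: combinatorially many alternating cycles
  n <- 8L
  nodes <- data.frame(contig = "z", pos = 10L * seq_len(n))
  cmb <- utils::combn(n, 2)
  pairs <- data.frame(u = cmb[1, ], v = cmb[2, ], type = "coverage+split",
                      stringsAsFactors = FALSE)
  g <- make_graph_obj(nodes, pairs)
  expect_warning(cands <- enumerate_plausible_cycles(g, max_cycles = 5),
                 "truncated")
  expect_true(attr(cands, "truncated"))
  expect_warning(c2 <- enumerate_plausible_cycles(g, max_edges = 4),
                 "truncated")
  expect_true(attr(c2, "truncated"))
  # cycles that were found are still valid
  expect_gt(length(c2), 0)
})

test_that("canonicalization is invariant to rotation and reversal", {
  nodes <- data.frame(contig = "z", pos = c(10L, 20L, 30L, 40L))
  pairs <- data.frame(u = c(1L, 2L, 3L, 4L), v = c(2L, 3L, 4L, 1L),
                      type = c("coverage", "split", "coverage", "split"),
                      stringsAsFactors = FALSE)
  g <- make_graph_obj(nodes, pairs)
  e <- g$edges
  erow <- function(u, v) which(e$from == u & e$to == v)
  fwd_nodes <- c(1L, 2L, 3L, 4L)
  fwd_edges <- c(erow(1, 2), erow(2, 3), erow(3, 4), erow(4, 1))
  roles <- c("cov", "junc", "cov", "junc")
  base <- canonicalize(fwd_nodes, fwd_edges, roles, g)
  # all rotations map to the same signature and start node
  for (s in 2:4) {
    rot <- function(x) c(x[s:4], x[seq_len(s - 1)])
    cand <- canonicalize(rot(fwd_nodes), rot(fwd_edges), rot(roles), g)
    expect_equal(cand$signature, base$signature)
    expect_equal(cand$node_seq$pos[1], 10)
  }
  # reverse traversal too
  rev_nodes <- c(1L, 4L, 3L, 2L)
  rev_edges <- c(erow(1, 4), erow(4, 3), erow(3, 2), erow(2, 1))
  rev_roles <- c("junc", "cov", "junc", "cov")
  expect_equal(canonicalize(rev_nodes, rev_edges, rev_roles, g)$signature,
               base$signature)
  # a structurally different cycle does not collide
  pairs2 <- pairs
  pairs2$type[2] <- "deletion"
  g2 <- make_graph_obj(nodes, pairs2)
  e2 <- g2$edges
  erow2 <- function(u, v) which(e2$from == u & e2$to == v)
  other <- canonicalize(fwd_nodes,
                        c(erow2(1, 2), erow2(2, 3), erow2(3, 4), erow2(4, 1)),
                        roles, g2)
  expect_false(other$signature == base$signature)
})

test_that("canonicalize rejects non-alternating or ill-typed cycles", {
  nodes <- data.frame(contig = "z", pos = c(10L, 20L, 30L, 40L))
  pairs <- data.frame(u = c(1L, 2L, 3L, 4L), v = c(2L, 3L, 4L, 1L),
                      type = c("coverage", "split", "coverage", "split"),
                      stringsAsFactors = FALSE)
  g <- make_graph_obj(nodes, pairs)
  e <- g$edges
  erow <- function(u, v) which(e$from == u & e$to == v)
  edges <- c(erow(1, 2), erow(2, 3), erow(3, 4), erow(4, 1))
  expect_error(canonicalize(1:4, edges, c("cov", "cov", "junc", "junc"), g),
               "alternate")
  expect_error(canonicalize(1:4, edges, c("junc", "cov", "junc", "cov"), g),
               "incompatible")
  expect_error(canonicalize(1:3, edges[1:3], c("cov", "junc", "cov"), g),
               "even")
})

test_that("random canonical forms collide exactly when cycles are equal", {
  # 200 random alternating cycles; shuffle rotations and check pairwise
  # signature equality against structural equality of the edge sets
  sigs <- character(0)
  keys <- character(0)
  for (seed in 1:50) {
    g <- random_graph(6, p_edge = 0.6, seed = seed + 7000)
    cands <- enumerate_plausible_cycles(g, require_split = FALSE)
    for (cand in cands) {
      sigs <- c(sigs, cand$signature)
      keys <- c(keys, paste(seed, cand$signature))
    }
  }
  # within one graph, signatures are unique (no two distinct cycles collide)
  expect_equal(anyDuplicated(keys), 0)
})
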