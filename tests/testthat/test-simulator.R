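# Synthetic-data generator and the recall/precision evaluator.

test_that("reference simulation is deterministic and GC-calibrated", {
  r1 <- simulate_reference(2, 5e4, gc = 0.5, seed = 8)
  r2 <- simulate_reference(2, 5e4, gc = 0.5, seed = 8)
  expect_identical(as.character(r1), as.character(r2))
  r3 <- simulate_reference(2, 5e4, gc = 0.5, seed = 9)
  expect_false(identical(as.character(r1), as.character(r3)))
  big <- simulate_reference(1, 1e6, gc = 0.5, seed = 8)
  gc <- sum(Biostrings::letterFrequency(big, c("G", "C"))) / 1e6
  expect_lt(abs(gc - 0.5), 0.01)
  # FASTA write is byte-identical across runs
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(r1, f1)
  Biostrings::writeXStringSet(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("truth simulation honours topology mix and placement rules", {
  ref <- simulate_reference(2, 4e5, seed = 10)
  cfg <- sim_config(seed = 10, n_circles = 3,
                    size_range = c(5000, 20000),
                    topology_mix = c(simple = 1, chimeric = 1,
                                     with_deletion = 1))
  # one circle per topology is representable
  for (topo in c("simple", "chimeric", "with_deletion")) {
    cfg1 <- cfg
    cfg1$topology_mix <- stats::setNames(1, topo)
    tr <- simulate_truth(ref, cfg1)
    expect_true(all(tr$topology == topo))
    expect_equal(nrow(tr), if (topo == "simple") 3 else 6)
    if (topo == "chimeric") {
      for (id in unique(tr$circle_id)) {
        expect_length(unique(tr$contig[tr$circle_id == id]), 2)
      }
    }
  }
  expect_equal(nrow(simulate_truth(ref, sim_config(seed = 1,
                                                   n_circles = 0))), 0)
})

test_that("random truth configurations satisfy the invariants", {
  ref <- simulate_reference(2, 5e5, seed = 3)
  for (seed in 1:30) {
    cfg <- sim_config(seed = seed,
                      n_circles = withr::with_seed(seed, sample(1:5, 1)),
                      size_range = c(3000, 30000))
    tr <- simulate_truth(ref, cfg)
    expect_true(all(tr$end > tr$start))
    # total covered length within the configured range
    for (id in unique(tr$circle_id)) {
      L <- sum((tr$end - tr$start)[tr$circle_id == id])
      expect_gte(L, 3000 - 1)
      expect_lte(L, 30000 + 1)
    }
    # circle footprints do not overlap
    for (ctg in unique(tr$contig)) {
      t <- tr[tr$contig == ctg, ]
      t <- t[order(t$start), ]
      if (nrow(t) > 1) expect_true(all(t$start[-1] >= t$end[-nrow(t)]))
    }
    # determinism
    expect_identical(tr, simulate_truth(ref, cfg))
  }
})

test_that("circle reads cover at the target depth with exact junctions", {
  cfg <- sim_config(seed = 14, n_circles = 1, size_range = c(3000, 3001),
                    topology_mix = c(simple = 1), background_coverage = 0)
  ref <- simulate_reference(1, 2e5, seed = 14)
  truth <- simulate_truth(ref, cfg)
  sim <- simulate_alignments(ref, truth, cfg)
  links <- extract_split_links(sim$segments)
  # zero jitter: all split links exactly end -> start
  expect_true(all(links$pos_a == truth$end[1]))
  expect_true(all(links$pos_b == truth$start[1]))
  prof <- compute_depth_profile(sim$segments)
  md <- mean_depth(prof, truth$contig[1], truth$start[1], truth$end[1])
  expect_lt(abs(md - 25) / 25, 0.15)
  # no reads outside the circle (background off)
  expect_equal(mean_depth(prof, truth$contig[1], 0, truth$start[1]),
               0, tolerance = 1e-12)
})

test_that("zero circle coverage leaves only background", {
  cfg <- sim_config(seed = 15, n_circles = 1, circle_coverage = 0,
                    size_range = c(3000, 4000),
                    topology_mix = c(simple = 1))
  ref <- simulate_reference(1, 1e5, seed = 15)
  truth <- simulate_truth(ref, cfg)
  sim <- simulate_alignments(ref, truth, cfg)
  expect_gt(nrow(sim$segments), 0)           # background reads exist
  expect_equal(nrow(extract_split_links(sim$segments)), 0)
})

test_that("the deletion gap of a with-deletion circle is read-free", {
  cfg <- sim_config(seed = 16, n_circles = 1, size_range = c(8000, 12000),
                    topology_mix = c(with_deletion = 1),
                    background_coverage = 0)
  ref <- simulate_reference(1, 2e5, seed = 16)
  truth <- simulate_truth(ref, cfg)
  gap <- c(truth$end[1], truth$start[2])
  sim <- simulate_alignments(ref, truth, cfg)
  prof <- compute_depth_profile(sim$segments)
  expect_equal(mean_depth(prof, truth$contig[1], gap[1], gap[2]), 0,
               tolerance = 1e-12)
  # and no split link crosses the gap
  links <- extract_split_links(sim$segments)
  expect_false(any(links$pos_a %in% gap & links$pos_b %in% gap))
})

test_that("alignment simulation is deterministic per seed", {
  cfg <- sim_config(seed = 17, n_circles = 2, size_range = c(3000, 9000))
  ref <- simulate_reference(2, 2e5, seed = 17)
  truth <- simulate_truth(ref, cfg)
  s1 <- simulate_alignments(ref, truth, cfg)
  s2 <- simulate_alignments(ref, truth, cfg)
  expect_identical(s1$segments, s2$segments)
})

test_that("subsampling keeps all fragments of a molecule together", {
  cfg <- sim_config(seed = 18, n_circles = 2, size_range = c(5000, 15000),
                    topology_mix = c(with_deletion = 1, chimeric = 1))
  ref <- simulate_reference(2, 3e5, seed = 18)
  truth <- simulate_truth(ref, cfg)
  sim <- simulate_alignments(ref, truth, cfg)
  sub <- subsample_reads(sim$segments, 0.4, seed = 5)
  expect_lt(nrow(sub), nrow(sim$segments))
  # molecules are kept or dropped wholesale
  per_mol <- table(sim$segments$molecule)
  kept <- table(sub$molecule)
  expect_true(all(per_mol[names(kept)] == kept))
  expect_identical(sub, subsample_reads(sim$segments, 0.4, seed = 5))
})

test_that("recall and precision follow the set-overlap formulas", {
  seg <- function(ctg, s, e) data.frame(contig = ctg, start = s, end = e,
                                        mean_depth = NA_real_)
  truth <- data.frame(circle_id = rep(sprintf("t%d", 1:4), each = 1),
                      topology = "simple", seg = 1L, contig = "c1",
                      start = c(1000L, 5000L, 9000L, 13000L),
                      end = c(2000L, 6000L, 10000L, 14000L))
  class(truth) <- c("true_circles", "data.frame")
  # C = T
  calls <- lapply(1:4, function(i)
    fake_call(paste0("c", i), seg("c1", truth$start[i], truth$end[i])))
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  # |T| = 4, |C| = 3, 2 matches
  calls2 <- list(
    fake_call("c1", seg("c1", 1000L, 2000L)),
    fake_call("c2", seg("c1", 5020L, 6020L)),      # within 50 bp: match
    fake_call("c3", seg("c1", 20000L, 21000L)))    # no match
  ev2 <- evaluate_calls(calls2, truth, match_tol = 50)
  expect_equal(ev2$recall, 0.5)
  expect_equal(ev2$precision, 2 / 3)
  # tolerance boundary: 51 bp off is not a match
  ev3 <- evaluate_calls(list(fake_call("x", seg("c1", 1051L, 2051L))),
                        truth, match_tol = 50)
  expect_equal(ev3$n_matched, 0)
  ev4 <- evaluate_calls(list(fake_call("x", seg("c1", 1050L, 2050L))),
                        truth, match_tol = 50)
  expect_equal(ev4$n_matched, 1)
  # segment-count mismatch is never a match
  two <- rbind(seg("c1", 1000L, 1500L), seg("c1", 1600L, 2000L))
  expect_equal(evaluate_calls(list(fake_call("x", two)), truth)$n_matched, 0)
  # 0/0 conventions
  ev0 <- evaluate_calls(list(), truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)
  empty_truth <- truth[0, ]
  class(empty_truth) <- c("true_circles", "data.frame")
  expect_equal(evaluate_calls(list(), empty_truth)$recall, 1)
})

test_that("matching is one-to-one even with ambiguous candidates", {
  # two calls both near one truth circle: only one can match
  truth <- data.frame(circle_id = "t1", topology = "simple", seg = 1L,
                      contig = "c1", start = 1000L, end = 2000L)
  class(truth) <- c("true_circles", "data.frame")
  seg <- function(s, e) data.frame(contig = "c1", start = s, end = e,
                                   mean_depth = NA_real_)
  calls <- list(fake_call("a", seg(1010L, 2010L)),
                fake_call("b", seg(990L, 1990L)))
  ev <- evaluate_calls(calls, truth, match_tol = 50)
  expect_equal(ev$n_matched, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 0.5)
})

test_that("FASTQ emission produces reads of the aligned lengths", {
  cfg <- sim_config(seed = 19, n_circles = 1, size_range = c(2000, 3000),
                    topology_mix = c(simple = 1), background_coverage = 0,
                    sub_rate = 0, ins_rate = 0, del_rate = 0)
  ref <- simulate_reference(1, 5e4, seed = 19)
  truth <- simulate_truth(ref, cfg)
  sim <- simulate_alignments(ref, truth, cfg)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim, ref, fq)
  lines <- readLines(fq)
  expect_equal(length(lines) %% 4, 0)
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  expect_setequal(ids, unique(sim$segments$read_id))
  # with zero error rates a junction read equals its reference pieces
  rid <- ids[1]
  sq <- lines[which(lines == paste0("@", rid)) + 1]
  ps <- sim$segments[sim$segments$read_id == rid, ]
  expect_equal(nchar(sq), sum(ps$end - ps$start))
})
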