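# Depth profiles, split links and QC counting.

test_that("depth profile reproduces single-read and overlap pileups", {
  seg <- sort_segments(aligned_segments("r1", "c1", 10, 20))
  prof <- compute_depth_profile(seg)
  expect_equal(as.data.frame(prof),
               data.frame(contig = "c1", start = 10, end = 20, depth = 1L),
               ignore_attr = TRUE)
  expect_equal(profile_depth_at(prof, "c1", 9), 0L)
  expect_equal(profile_depth_at(prof, "c1", 19), 1L)
  expect_equal(profile_depth_at(prof, "c1", 20), 0L)

  seg2 <- sort_segments(rbind(aligned_segments("r1", "c1", 10, 20),
                              aligned_segments("r2", "c1", 15, 25)))
  prof2 <- compute_depth_profile(seg2)
  expect_equal(profile_depth_at(prof2, "c1", 12), 1L)
  expect_equal(profile_depth_at(prof2, "c1", 17), 2L)
  expect_equal(profile_depth_at(prof2, "c1", 22), 1L)
})

test_that("depth profile equals the per-base pileup oracle on random reads", {
  for (seed in 1:5) {
    seg <- random_segments(seed, n_reads = 200, contig_len = 10000,
                           n_split = 0)
    prof <- compute_depth_profile(seg)
    oracle <- pileup_oracle(seg, "c1", 10000)
    got <- vapply(0:9999, function(p) profile_depth_at(prof, "c1", p),
                  integer(1))
    expect_identical(got, oracle)
    # profile closes at zero: total increments equal decrements
    expect_identical(profile_depth_at(prof, "c1", max(prof$end)), 0L)
  }
})

test_that("raising mapq_min never increases depth anywhere", {
  seg <- random_segments(7, n_reads = 100, contig_len = 5000, n_split = 0)
  seg$mapq <- withr::with_seed(7, sample(c(0L, 20L, 60L), nrow(seg),
                                         replace = TRUE))
  p0 <- compute_depth_profile(seg, mapq_min = 0)
  p30 <- compute_depth_profile(seg, mapq_min = 30)
  at <- seq(0, 4999, by = 7)
  d0 <- vapply(at, function(p) profile_depth_at(p0, "c1", p), integer(1))
  d30 <- vapply(at, function(p) profile_depth_at(p30, "c1", p), integer(1))
  expect_true(all(d30 <= d0))
})

test_that("unsorted input is rejected naming the offending record", {
  seg <- rbind(aligned_segments("r2", "c1", 500, 900),
               aligned_segments("r1", "c1", 10, 20))
  class(seg) <- c("nc_segments", "data.frame")
  expect_error(compute_depth_profile(seg), "not sorted.*r1")
})

test_that("mean depth is the length-weighted mean with zeros outside", {
  seg <- sort_segments(rbind(
    aligned_segments(c("a", "b"), "c1", 100, 200),
    aligned_segments(c("c", "d"), "c1", 100, 150)))
  prof <- compute_depth_profile(seg)
  expect_equal(mean_depth(prof, "c1", 100, 150), 4)
  expect_equal(mean_depth(prof, "c1", 100, 200), 3)   # 4 then 2, equal halves
  expect_equal(mean_depth(prof, "c1", 150, 250), 1)   # half 2x, half 0
  expect_equal(mean_depth(prof, "c1", 500, 600), 0)
  expect_error(mean_depth(prof, "c1", 100, 100))
})

test_that("mean depth matches per-base averaging on random profiles", {
  seg <- random_segments(11, n_reads = 150, contig_len = 8000, n_split = 0)
  prof <- compute_depth_profile(seg)
  oracle <- pileup_oracle(seg, "c1", 8000)
  for (iv in list(c(0, 8000), c(100, 250), c(4000, 4001), c(7000, 8000))) {
    expect_equal(mean_depth(prof, "c1", iv[1], iv[2]),
                 mean(oracle[(iv[1] + 1):iv[2]]), tolerance = 1e-10)
  }
})

test_that("split links follow query order and orientation", {
  seg <- sort_segments(rbind(
    aligned_segments("r", "c1", 100, 600, qstart = 0),
    aligned_segments("r", "c1", 5000, 5500, qstart = 500,
                     is_supplementary = TRUE)))
  links <- extract_split_links(seg)
  expect_equal(nrow(links), 1)
  expect_equal(links$pos_a, 600)
  expect_equal(links$side_a, "left")
  expect_equal(links$pos_b, 5000)
  expect_equal(links$side_b, "right")

  # single alignment, no supplementary: no links
  expect_equal(nrow(extract_split_links(
    sort_segments(aligned_segments("solo", "c1", 10, 500)))), 0)

  # circle junction: end of circle back to its start
  segc <- fixture_simple_segments()
  lc <- extract_split_links(segc)
  expect_true(all(lc$pos_a == 5000 & lc$pos_b == 2000))
})

test_that("a read with k segments yields exactly k-1 links", {
  for (k in 2:5) {
    seg <- do.call(rbind, lapply(seq_len(k), function(i) {
      aligned_segments("multi", "c1", 1000 * i, 1000 * i + 500,
                       qstart = (i - 1) * 500, is_supplementary = i > 1)
    }))
    links <- extract_split_links(sort_segments(seg))
    expect_equal(nrow(links), k - 1)
  }
})

test_that("links below the MAPQ threshold are dropped", {
  seg <- sort_segments(rbind(
    aligned_segments("r", "c1", 100, 600, qstart = 0, mapq = 60),
    aligned_segments("r", "c1", 5000, 5500, qstart = 500, mapq = 10,
                     is_supplementary = TRUE)))
  expect_equal(nrow(extract_split_links(seg, mapq_min = 0)), 1)
  expect_equal(nrow(extract_split_links(seg, mapq_min = 30)), 0)
})

test_that("SA tags parse, tolerate trailing separators and flag bad entries", {
  sa <- parse_sa_tag("c2,1001,+,500M,60,3;c3,52,-,100S400M,13,1;")
  expect_equal(sa$contig, c("c2", "c3"))
  expect_equal(sa$pos, c(1001L, 52L))
  expect_equal(sa$strand, c("+", "-"))
  expect_equal(sa$mapq, c(60L, 13L))
  expect_warning(bad <- parse_sa_tag("c2,notanumber,+,5M,60,0;c2,5,+,5M,60,0;"),
                 "malformed")
  expect_equal(nrow(bad), 1)
  expect_equal(attr(bad, "n_skipped"), 1L)
  expect_equal(nrow(parse_sa_tag(NA)), 0)
})

test_that("SAM round trip preserves spans, split structure and SA linkage", {
  seg <- fixture_chimeric_segments()
  contigs <- data.frame(name = c("c1", "c2"), length = c(10000, 10000))
  sam <- tempfile(fileext = ".sam")
  write_sam(seg, contigs, sam)
  back <- read_alignments(sam)
  expect_equal(nrow(back), nrow(seg))
  key <- function(x) paste(x$read_id, x$contig, x$start, x$end)
  expect_setequal(key(back), key(seg))
  # split links identical after the round trip
  l1 <- extract_split_links(seg)
  l2 <- extract_split_links(back)
  o <- function(x) x[order(x$read_id), c("read_id", "pos_a", "pos_b")]
  expect_equal(o(l2), o(l1), ignore_attr = TRUE)
})

test_that("QC bins classify split reads relative to circle breakpoints", {
  seg <- fixture_simple_segments()
  links <- extract_split_links(seg)
  res <- detect_circles(segments = seg)
  cand <- res$candidates[[1]]
  qc <- qc_bin_counts(seg, links, cand, window = 3, n_bins = 10)
  expect_equal(nrow(qc), 10)
  # perfect junction reads: everything split maps to the breakpoint class
  expect_true(all(qc$split_in == 0))
  expect_true(all(qc$split_out == 0))
  expect_true(sum(qc$split_at_bp) > 0)
  # depth roughly the stacked coverage (7 reads over most of the circle)
  expect_gt(mean(qc$depth), 5)

  # jittered endpoints with window 0 move reads out of the breakpoint class
  segj <- fixture_simple_segments()
  segj$end[segj$read_id == "j1" & segj$end == 5000] <- 4998
  linksj <- extract_split_links(segj)
  qcj <- qc_bin_counts(segj, linksj, cand, window = 0, n_bins = 10)
  expect_gt(sum(qcj$split_in), 0)
  qcw <- qc_bin_counts(segj, linksj, cand, window = 3, n_bins = 10)
  expect_equal(sum(qcw$split_in), 0)

  # a link leaving the circle counts as split-out
  sego <- rbind(seg,
                aligned_segments("out1", "c1", 4500, 5000, qstart = 0),
                aligned_segments("out1", "c1", 9000, 9400, qstart = 500,
                                 is_supplementary = TRUE))
  sego <- sort_segments(sego)
  linkso <- extract_split_links(sego)
  qco <- qc_bin_counts(sego, linkso, cand, window = 3, n_bins = 10)
  expect_gt(sum(qco$split_out), 0)
})

test_that("QC category counts match direct enumeration on simulated truth", {
  cfg <- sim_config(seed = 5, n_circles = 1, size_range = c(4000, 6000),
                    topology_mix = c(simple = 1), background_coverage = 0)
  ref <- simulate_reference(1, 2e5, seed = 5)
  truth <- simulate_truth(ref, cfg)
  sim <- simulate_alignments(ref, truth, cfg)
  res <- detect_circles(segments = sim$segments)
  cand <- res$filtered_candidates[[1]]
  links <- extract_split_links(sim$segments)
  qc <- qc_bin_counts(sim$segments, links, cand, window = 3, n_bins = 20)
  # all simulated split reads cross the junction exactly -> at-breakpoint
  split_reads <- unique(links$read_id)
  expect_gt(length(split_reads), 0)
  expect_equal(sum(qc$split_in), 0)
  expect_equal(sum(qc$split_out), 0)
  # at-breakpoint bases equal the total aligned bases of the split reads
  sp <- sim$segments[sim$segments$read_id %in% split_reads, ]
  expect_equal(sum(qc$split_at_bp), sum(sp$end - sp$start))
})
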