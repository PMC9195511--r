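# Per-bin QC over a circle's covered segments: alignment match/insertion/
# deletion base counts, split-read base categories relative to the circle's
# breakpoints, and read depth.

#' Per-bin QC counts for a circle candidate
#'
#' Bins the candidate's covered segments and tabulates, per bin and filtered
#' at a MAPQ threshold: matched/inserted/deleted bases from the CIGARs of
#' overlapping alignments, bases of split reads classified as
#' `split_at_bp` (a link endpoint within +/- `window` of a circle
#' breakpoint), `split_in` (split endpoints inside the circle's segments but
#' not at a breakpoint) or `split_out` (link leaving the circle's regions),
#' and mean read depth. Widening `window` shifts reads from `split_in` into
#' `split_at_bp`.
#'
#' @param segments `nc_segments`.
#' @param links `nc_links`.
#' @param candidate `circle_candidate`.
#' @param window breakpoint match window in bp (default 3).
#' @param n_bins total number of bins across the circle (default 40).
#' @param mapq_min alignments below this MAPQ are ignored (default 0).
#' @return data.frame: bin, contig, start, end, matches, insertions,
#'   deletions, split_at_bp, split_in, split_out, depth.
#' @export
qc_bin_counts <- function(segments, links, candidate, window = 3L,
                          n_bins = 40L, mapq_min = 0L) {
  stopifnot(window >= 0, n_bins >= 1)
  segs <- candidate$segments
  j <- candidate$junctions
  bps <- unique(data.frame(
    contig = c(j$contig_a, j$contig_b, segs$contig, segs$contig),
    pos = c(j$pos_a, j$pos_b, segs$start, segs$end),
    stringsAsFactors = FALSE))

  # bins proportional to segment length, at least one per segment
  total <- sum(segs$end - segs$start)
  bins <- list()
  for (si in seq_len(nrow(segs))) {
    w <- segs$end[si] - segs$start[si]
    nb <- max(1L, round(n_bins * w / total))
    edges <- unique(round(seq(segs$start[si], segs$end[si], length.out = nb + 1)))
    bins[[si]] <- data.frame(contig = segs$contig[si], start = edges[-length(edges)],
                             end = edges[-1], stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, bins)
  bins$bin <- seq_len(nrow(bins))

  aln <- segments[segments$mapq >= mapq_min, , drop = FALSE]
  lnk <- if (nrow(links)) links[links$mapq_min >= mapq_min, , drop = FALSE] else links

  in_segs <- function(ctg, pos) {
    any(segs$contig == ctg & pos >= segs$start & pos <= segs$end)
  }
  at_bp <- function(ctg, pos) {
    any(bps$contig == ctg & abs(bps$pos - pos) <= window)
  }
  # per split read: one category
  cat_of_read <- new.env(parent = emptyenv())
  for (rid in unique(lnk$read_id)) {
    ll <- lnk[lnk$read_id == rid, , drop = FALSE]
    ends_at_bp <- mapply(at_bp, c(ll$contig_a, ll$contig_b),
                         c(ll$pos_a, ll$pos_b))
    ends_in <- mapply(in_segs, c(ll$contig_a, ll$contig_b),
                      c(ll$pos_a, ll$pos_b))
    categ <- if (any(!ends_in)) "split_out"
    else if (any(matrix(ends_at_bp, ncol = 2)[, 1] &
                 matrix(ends_at_bp, ncol = 2)[, 2])) "split_at_bp"
    else "split_in"
    assign(rid, categ, envir = cat_of_read)
  }

  m <- matrix(0, nrow = nrow(bins),
              ncol = 6, dimnames = list(NULL, c("matches", "insertions",
                                                "deletions", "split_at_bp",
                                                "split_in", "split_out")))
  depth_bases <- numeric(nrow(bins))
  for (ai in seq_len(nrow(aln))) {
    a <- aln[ai, ]
    bi <- which(bins$contig == a$contig & bins$start < a$end &
                  bins$end > a$start)
    if (!length(bi)) next
    ops <- if (!is.na(a$cigar) && a$cigar != "*") {
      .cigar_ref_ops(a$cigar, a$start)
    } else {
      data.frame(op = "M", start = a$start, end = a$end, len = a$end - a$start)
    }
    categ <- if (exists(a$read_id, envir = cat_of_read))
      get(a$read_id, envir = cat_of_read) else NA_character_
    for (b in bi) {
      ov_all <- 0
      for (oi in seq_len(nrow(ops))) {
        op <- ops$op[oi]
        if (op %in% c("M", "=", "X", "D")) {
          ov <- min(ops$end[oi], bins$end[b]) - max(ops$start[oi], bins$start[b])
          if (ov <= 0) next
          col <- if (op == "D") "deletions" else "matches"
          m[b, col] <- m[b, col] + ov
          if (op != "D") ov_all <- ov_all + ov
        } else if (op == "I") {
          if (ops$start[oi] >= bins$start[b] && ops$start[oi] < bins$end[b]) {
            m[b, "insertions"] <- m[b, "insertions"] + ops$len[oi]
          }
        }
      }
      depth_bases[b] <- depth_bases[b] + ov_all
      if (!is.na(categ) && ov_all > 0) {
        m[b, categ] <- m[b, categ] + ov_all
      }
    }
  }
  cbind(bins[, c("bin", "contig", "start", "end")],
        as.data.frame(m),
        depth = depth_bases / (bins$end - bins$start))
}
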