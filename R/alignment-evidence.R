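# Evidence extraction from mapped long reads: read-depth step functions and
# split-read junction links. Internal coordinates are 0-based half-open;
# 1-based coordinates appear only at VCF/report boundaries.

#' Construct an aligned-segment table
#'
#' The canonical in-memory representation of mapped reads used throughout the
#' package: one row per aligned segment (a primary alignment or one
#' supplementary piece of a split read).
#'
#' @param read_id character; read (query) name.
#' @param contig character; reference contig.
#' @param start,end 0-based half-open reference span of the aligned segment
#'   (clipped bases excluded).
#' @param strand "+" or "-".
#' @param mapq integer mapping quality (0-255).
#' @param is_supplementary logical; TRUE for supplementary records.
#' @param qstart 0-based offset of the segment's first aligned base in the
#'   original read orientation; used to order the pieces of a split read
#'   along the query.
#' @param cigar CIGAR string, or "*" when unavailable.
#' @param molecule identifier of the originating molecule (defaults to
#'   `read_id`; the simulator uses it to group fragments for subsampling).
#' @return data.frame with class `nc_segments`.
#' @export
aligned_segments <- function(read_id, contig, start, end, strand = "+",
                             mapq = 60L, is_supplementary = FALSE,
                             qstart = 0L, cigar = "*", molecule = read_id) {
  n <- length(read_id)
  seg <- data.frame(
    read_id = as.character(read_id),
    contig = rep_len(as.character(contig), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    mapq = rep_len(as.integer(mapq), n),
    is_supplementary = rep_len(as.logical(is_supplementary), n),
    qstart = rep_len(as.integer(qstart), n),
    cigar = rep_len(as.character(cigar), n),
    molecule = rep_len(as.character(molecule), n),
    stringsAsFactors = FALSE
  )
  validate_segments(seg)
  class(seg) <- c("nc_segments", "data.frame")
  seg
}

validate_segments <- function(seg) {
  stopifnot(all(c("read_id", "contig", "start", "end", "strand", "mapq") %in%
                  names(seg)))
  if (nrow(seg)) {
    bad <- which(seg$start >= seg$end)
    if (length(bad)) {
      stop("aligned segment with start >= end (row ", bad[1], ": read ",
           seg$read_id[bad[1]], ")")
    }
    if (any(seg$mapq < 0L | seg$mapq > 255L)) {
      stop("MAPQ outside 0-255")
    }
    if (!all(seg$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'")
    }
  }
  invisible(seg)
}

sort_segments <- function(seg) {
  seg <- seg[order(seg$contig, seg$start, seg$end, seg$read_id), , drop = FALSE]
  rownames(seg) <- NULL
  class(seg) <- unique(c("nc_segments", class(seg)))
  seg
}

#' Parse an SA tag into its alignment entries
#'
#' The SA tag dialect is `contig,pos,strand,CIGAR,mapQ,NM;` repeated. Entries
#' that do not parse are skipped with a warning (the skip count is returned in
#' the `n_skipped` attribute).
#'
#' @param sa a single SA tag string (trailing ';' optional), or NA.
#' @return data.frame(contig, pos (1-based), strand, cigar, mapq) with
#'   attribute `n_skipped`.
#' @export
parse_sa_tag <- function(sa) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), cigar = character(0),
                      mapq = integer(0), stringsAsFactors = FALSE)
  if (is.null(sa) || length(sa) == 0 || is.na(sa) || !nzchar(sa)) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  entries <- strsplit(sa, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  rows <- vector("list", length(entries))
  n_skipped <- 0L
  for (i in seq_along(entries)) {
    f <- strsplit(entries[i], ",", fixed = TRUE)[[1]]
    ok <- length(f) >= 5 &&
      !is.na(suppressWarnings(as.integer(f[2]))) &&
      f[3] %in% c("+", "-") &&
      !is.na(suppressWarnings(as.integer(f[5])))
    if (!ok) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[i]] <- data.frame(contig = f[1], pos = as.integer(f[2]),
                            strand = f[3], cigar = f[4],
                            mapq = as.integer(f[5]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty
  if (n_skipped > 0) {
    warning(n_skipped, " malformed SA entr", if (n_skipped == 1) "y" else "ies",
            " skipped")
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read aligned segments from a SAM or BAM file
#'
#' Ingests a coordinate-sorted SAM/BAM (any long-read mapper upstream),
#' keeping primary and supplementary alignments and dropping unmapped and
#' secondary records. If a read's supplementary records are missing from the
#' file but announced in the primary's SA tag, segments are reconstructed
#' from the SA entries so that split reads remain linkable.
#'
#' @param path SAM or BAM file.
#' @return `nc_segments` data.frame sorted by (contig, start).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "SA",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  if (n == 0) {
    return(sort_segments(aligned_segments(character(0), character(0),
                                          integer(0), integer(0))[0, ]))
  }
  cigar <- res$cigar
  refw <- cigar_ref_width(cigar)
  strand <- ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+")
  supp <- bitwAnd(res$flag, 2048L) > 0L
  clips <- t(vapply(cigar, .cigar_clips, integer(2), USE.NAMES = FALSE))
  qstart <- ifelse(strand == "+", clips[, 1], clips[, 2])
  mapq <- res$mapq
  mapq[is.na(mapq)] <- 0L
  seg <- data.frame(
    read_id = res$qname,
    contig = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + refw,
    strand = strand,
    mapq = as.integer(mapq),
    is_supplementary = supp,
    qstart = as.integer(qstart),
    cigar = cigar,
    molecule = res$qname,
    stringsAsFactors = FALSE
  )
  sa <- if (!is.null(res$tag$SA)) res$tag$SA else rep(NA_character_, n)

  # Reconstruct supplementary segments announced in SA tags but absent as
  # records (some pipelines strip them).
  recon <- list()
  counts <- table(seg$read_id)
  for (i in which(!supp & !is.na(sa) & nzchar(sa))) {
    entries <- parse_sa_tag(sa[i])
    expected <- nrow(entries) + 1L
    have <- counts[[seg$read_id[i]]]
    if (have >= expected || nrow(entries) == 0) next
    known <- seg[seg$read_id == seg$read_id[i], , drop = FALSE]
    for (k in seq_len(nrow(entries))) {
      e <- entries[k, ]
      s0 <- e$pos - 1L
      e0 <- s0 + cigar_ref_width(e$cigar)
      if (any(known$contig == e$contig & known$start == s0)) next
      cl <- .cigar_clips(e$cigar)
      qs <- if (e$strand == "+") cl[["lead"]] else cl[["trail"]]
      recon[[length(recon) + 1L]] <- data.frame(
        read_id = seg$read_id[i], contig = e$contig, start = s0, end = e0,
        strand = e$strand, mapq = e$mapq, is_supplementary = TRUE,
        qstart = as.integer(qs), cigar = e$cigar,
        molecule = seg$read_id[i], stringsAsFactors = FALSE)
    }
  }
  if (length(recon)) seg <- rbind(seg, do.call(rbind, recon))
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  validate_segments(seg)
  sort_segments(seg)
}

# ---------------------------------------------------------------------------
# Depth profile

#' Compute a read-depth step function from aligned segments
#'
#' Counter-event estimator: each retained segment increments a counter at its
#' start and decrements one at its end; the cumulative sum yields the depth at
#' every reference position. Depth is counted over the full reference span of
#' each segment (no per-base CIGAR walking), and supplementary segments
#' contribute like primaries.
#'
#' @param segments `nc_segments` sorted by (contig, start).
#' @param mapq_min segments with MAPQ below this are excluded (default 0).
#' @return object of class `depth_profile`: data.frame(contig, start, end,
#'   depth) describing a right-open step function; bases outside all
#'   intervals have depth 0.
#' @export
compute_depth_profile <- function(segments, mapq_min = 0L) {
  validate_segments(segments)
  stopifnot(mapq_min >= 0)
  # enforce sortedness 
  if (nrow(segments) > 1) {
    o <- order(segments$contig)
    if (is.unsorted(o) && !identical(segments$contig, segments$contig[o])) {
      # contigs out of order handled below via per-row check
    }
    prev_contig <- c(NA_character_, segments$contig[-nrow(segments)])
    prev_start <- c(NA_integer_, segments$start[-nrow(segments)])
    same <- !is.na(prev_contig) & prev_contig == segments$contig
    bad <- which(same & segments$start < prev_start)
    badc <- which(!is.na(prev_contig) & segments$contig < prev_contig)
    bad <- sort(c(bad, badc))
    if (length(bad)) {
      stop("segments not sorted by (contig, start): offending record ",
           bad[1], " (read ", segments$read_id[bad[1]], " at ",
           segments$contig[bad[1]], ":", segments$start[bad[1]], ")")
    }
  }
  seg <- segments[segments$mapq >= mapq_min, , drop = FALSE]
  out <- list()
  for (ctg in unique(seg$contig)) {
    s <- seg[seg$contig == ctg, , drop = FALSE]
    ev <- c(s$start, s$end)
    dl <- c(rep(1L, nrow(s)), rep(-1L, nrow(s)))
    o <- order(ev)
    ev <- ev[o]
    dl <- dl[o]
    pos <- unique(ev)
    delta <- vapply(split(dl, match(ev, pos)), sum, integer(1))
    depth <- cumsum(delta)
    n <- length(pos)
    if (n < 2) next
    df <- data.frame(contig = ctg, start = pos[-n], end = pos[-1],
                     depth = as.integer(depth[-n]), stringsAsFactors = FALSE)
    # merge adjacent intervals with equal depth
    keep <- c(TRUE, df$depth[-1] != df$depth[-nrow(df)])
    idx <- cumsum(keep)
    df <- data.frame(contig = ctg,
                     start = tapply(df$start, idx, min),
                     end = tapply(df$end, idx, max),
                     depth = df$depth[keep],
                     stringsAsFactors = FALSE)
    if (any(df$depth < 0)) stop("negative depth: corrupt segment spans")
    out[[ctg]] <- df
  }
  prof <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               depth = integer(0), stringsAsFactors = FALSE)
  rownames(prof) <- NULL
  attr(prof, "mapq_min") <- mapq_min
  class(prof) <- c("depth_profile", "data.frame")
  prof
}

# Per-contig lookup tables for fast integral queries.
.profile_index <- function(profile) {
  idx <- attr(profile, "index")
  if (!is.null(idx)) return(idx)
  idx <- lapply(split(seq_len(nrow(profile)), profile$contig), function(i) {
    p <- profile[i, , drop = FALSE]
    # breakpoints of the step function including zero runs between blocks
    b <- sort(unique(c(p$start, p$end)))
    d <- numeric(length(b) - 1)
    ii <- findInterval(p$start, b)
    d[ii] <- p$depth
    # intervals not covered by profile rows are zero already unless profile
    # rows are contiguous; fill by matching midpoints
    mids <- (b[-length(b)] + b[-1]) / 2
    row <- findInterval(mids, p$start)
    inrow <- row >= 1 & mids < p$end[pmax(row, 1)]
    d[inrow] <- p$depth[row[inrow]]
    d[!inrow] <- 0
    area <- c(0, cumsum(d * diff(b)))
    list(b = b, d = d, area = area)
  })
  idx
}

# Integral of the depth step function over [start, end) on one contig.
.depth_integral <- function(profile, contig, start, end) {
  idx <- .profile_index(profile)[[contig]]
  if (is.null(idx)) return(0)
  Fx <- function(x) {
    x <- pmin(pmax(x, idx$b[1]), idx$b[length(idx$b)])
    i <- findInterval(x, idx$b)
    i <- pmin(i, length(idx$b) - 1)
    idx$area[i] + idx$d[i] * (x - idx$b[i])
  }
  Fx(end) - Fx(start)
}

#' Mean read depth over a genomic interval
#'
#' Length-weighted mean of the depth step function over `[start, end)`;
#' unprofiled bases count as depth 0.
#'
#' @param profile `depth_profile`.
#' @param contig,start,end interval (0-based half-open), start < end.
#' @return non-negative numeric.
#' @export
mean_depth <- function(profile, contig, start, end) {
  stopifnot(start < end)
  .depth_integral(profile, contig, start, end) / (end - start)
}

#' Write a depth profile as 4-column bedGraph-style TSV
#' @param profile `depth_profile`.
#' @param path output file.
#' @export
write_depth_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[, c("contig", "start", "end", "depth")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Split links

#' Extract split-read junction links
#'
#' One link per adjacent pair of aligned segments of the same read, ordered
#' along the query. Each endpoint records the reference-side boundary where
#' the alignment breaks and on which side of that boundary the aligned
#' segment lies (`"left"`: segment ends at the breakpoint, the read exits
#' rightward; `"right"`: segment starts there).
#'
#' @param segments `nc_segments`.
#' @param mapq_min links with either segment's MAPQ below this are dropped.
#' @return data.frame of class `nc_links`: read_id, contig_a, pos_a, side_a,
#'   contig_b, pos_b, side_b, mapq_min (min of the two segments).
#' @export
extract_split_links <- function(segments, mapq_min = 0L) {
  validate_segments(segments)
  empty <- data.frame(read_id = character(0), contig_a = character(0),
                      pos_a = integer(0), side_a = character(0),
                      contig_b = character(0), pos_b = integer(0),
                      side_b = character(0), mapq_min = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("nc_links", "data.frame")
  if (!nrow(segments)) return(empty)
  splitreads <- split(seq_len(nrow(segments)), segments$read_id)
  rows <- list()
  for (ii in splitreads) {
    if (length(ii) < 2) next
    s <- segments[ii, , drop = FALSE]
    s <- s[order(s$qstart), , drop = FALSE]
    for (k in seq_len(nrow(s) - 1)) {
      a <- s[k, ]
      b <- s[k + 1, ]
      # breakpoint on the earlier segment: where the read leaves it
      if (a$strand == "+") {
        pos_a <- a$end; side_a <- "left"
      } else {
        pos_a <- a$start; side_a <- "right"
      }
      # breakpoint on the later segment: where the read enters it
      if (b$strand == "+") {
        pos_b <- b$start; side_b <- "right"
      } else {
        pos_b <- b$end; side_b <- "left"
      }
      if (a$contig == b$contig && pos_a == pos_b && side_a == side_b) next
      if (min(a$mapq, b$mapq) < mapq_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = a$read_id, contig_a = a$contig, pos_a = pos_a,
        side_a = side_a, contig_b = b$contig, pos_b = pos_b, side_b = side_b,
        mapq_min = min(a$mapq, b$mapq), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  class(out) <- c("nc_links", "data.frame")
  out
}

#' Write split links as TSV
#' @param links `nc_links`.
#' @param path output file.
#' @export
write_links_tsv <- function(links, path) {
  utils::write.table(as.data.frame(links), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
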