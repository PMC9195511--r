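# Translation of circle candidates to chains of VCF breakend (BND) records
# and back. This is the only place where 0-based half-open coordinates are
# converted to the 1-based positions of VCF.
#
# Bracket convention: a breakend whose own segment lies LEFT of the
# breakpoint is written base-first ("N[...[" / "N]...]"), one whose segment
# lies RIGHT is written base-last. The bracket character points at the
# mate's side: "[" when the mate's segment extends rightward from the mate
# position, "]" when it extends leftward.

# 1-based VCF position of a junction endpoint: the last/first covered base.
.bnd_pos1 <- function(pos0, side) {
  if (side == "left") pos0 else pos0 + 1L
}

.bnd_alt <- function(ref_base, own_side, mate_contig, mate_pos1, mate_side) {
  br <- if (mate_side == "right") "[" else "]"
  mate <- paste0(br, mate_contig, ":", mate_pos1, br)
  if (own_side == "left") paste0(ref_base, mate) else paste0(mate, ref_base)
}

.ref_base_at <- function(reference, contig, pos1) {
  if (is.null(reference)) return("N")
  if (!(contig %in% names(reference))) return("N")
  len <- Biostrings::width(reference[contig])
  if (pos1 < 1 || pos1 > len) {
    stop("junction position ", contig, ":", pos1, " outside reference")
  }
  as.character(Biostrings::subseq(reference[[contig]], pos1, pos1))
}

#' Translate a circle candidate into VCF breakend records
#'
#' One reciprocal breakend pair per junction-type edge; all records of a
#' candidate share an EVENT id. Deletion junctions are emitted as breakends
#' too, with their type carried in INFO/JTYPE.
#'
#' @param candidate `circle_candidate`.
#' @param reference optional `DNAStringSet` for REF bases ("N" when absent).
#' @return data.frame of breakend records (one row per breakend), sorted by
#'   (contig, pos).
#' @export
cycle_to_breakends <- function(candidate, reference = NULL) {
  j <- candidate$junctions
  ev <- candidate$id
  rows <- list()
  for (i in seq_len(nrow(j))) {
    pa <- .bnd_pos1(j$pos_a[i], j$side_a[i])
    pb <- .bnd_pos1(j$pos_b[i], j$side_b[i])
    ra <- .ref_base_at(reference, j$contig_a[i], pa)
    rb <- .ref_base_at(reference, j$contig_b[i], pb)
    ida <- sprintf("%s_bnd_%03da", ev, i)
    idb <- sprintf("%s_bnd_%03db", ev, i)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = c(j$contig_a[i], j$contig_b[i]),
      pos = c(pa, pb),
      id = c(ida, idb),
      ref = c(ra, rb),
      alt = c(.bnd_alt(ra, j$side_a[i], j$contig_b[i], pb, j$side_b[i]),
              .bnd_alt(rb, j$side_b[i], j$contig_a[i], pa, j$side_a[i])),
      mate_id = c(idb, ida),
      event = ev,
      jtype = j$type[i],
      n_split = j$n_split[i],
      circle_len = candidate$length,
      segments = paste(sprintf("%s:%d-%d", candidate$segments$contig,
                               candidate$segments$start,
                               candidate$segments$end), collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$pos, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write breakend records to a VCF 4.2 file
#'
#' @param records data.frame from [cycle_to_breakends()] (possibly several
#'   candidates row-bound), optionally with a `prob` column (posterior
#'   probability, written as INFO/PROB).
#' @param path output file.
#' @param contigs data.frame(name, length) declared in the header.
#' @export
write_breakend_vcf <- function(records, path, contigs) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=nanocircle",
    sprintf("##contig=<ID=%s,length=%d>", contigs$name,
            as.integer(contigs$length)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"Circle candidate id grouping all breakends of one circular event\">",
    "##INFO=<ID=JTYPE,Number=1,Type=String,Description=\"Junction type: split or deletion\">",
    "##INFO=<ID=NSPLIT,Number=1,Type=Integer,Description=\"Number of supporting split reads\">",
    "##INFO=<ID=CIRCLELEN,Number=1,Type=Integer,Description=\"Total length of the circle's covered segments\">",
    "##INFO=<ID=SEGS,Number=1,Type=String,Description=\"Covered segments of the circle, 0-based half-open\">",
    "##INFO=<ID=PROB,Number=1,Type=Float,Description=\"Posterior probability that the circle is present\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- hdr
  if (!is.null(records) && nrow(records)) {
    records <- records[order(records$contig, records$pos, records$id), ,
                       drop = FALSE]
    info <- sprintf(
      "SVTYPE=BND;MATEID=%s;EVENT=%s;JTYPE=%s;NSPLIT=%d;CIRCLELEN=%d;SEGS=%s",
      records$mate_id, records$event, records$jtype,
      as.integer(records$n_split), as.integer(records$circle_len),
      records$segments)
    if (!is.null(records$prob)) {
      info <- paste0(info, sprintf(";PROB=%.6g", records$prob))
    }
    lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                              records$contig, records$pos, records$id,
                              records$ref, records$alt, info))
  }
  writeLines(lines, path)
  invisible(path)
}

.parse_bnd_alt <- function(alt, context = "") {
  m <- regmatches(alt, regexec(
    "^([ACGTN]*)(\\[|\\])([^:\\[\\]]+):([0-9]+)(\\[|\\])([ACGTN]*)$", alt,
    perl = TRUE))[[1]]
  if (length(m) == 0 || m[3] != m[6] || (nzchar(m[2]) == nzchar(m[7]))) {
    stop("malformed breakend ALT '", alt, "' ", context)
  }
  own_side <- if (nzchar(m[2])) "left" else "right"
  mate_side <- if (m[3] == "[") "right" else "left"
  list(own_side = own_side, mate_contig = m[4],
       mate_pos1 = as.integer(m[5]), mate_side = mate_side,
       ref = if (nzchar(m[2])) m[2] else m[7])
}

.info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

#' Read circle candidates back from a breakend VCF
#'
#' Parses the package's own VCF dialect: BND records grouped by EVENT, with
#' junction structure recovered from the bracket notation and covered
#' segments from INFO/SEGS.
#'
#' @param path VCF file written by [write_breakend_vcf()].
#' @return list of `circle_candidate`-like objects (id, segments, junctions,
#'   length, prob when present).
#' @export
read_breakend_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(list())
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, integer(1)) < 8)
  if (length(bad)) stop("malformed VCF record at line ", bad[1])
  rec <- data.frame(
    contig = vapply(f, `[`, "", 1), pos = as.integer(vapply(f, `[`, "", 2)),
    id = vapply(f, `[`, "", 3), ref = vapply(f, `[`, "", 4),
    alt = vapply(f, `[`, "", 5), info = vapply(f, `[`, "", 8),
    stringsAsFactors = FALSE)
  rec$event <- vapply(rec$info, .info_field, "", key = "EVENT",
                      USE.NAMES = FALSE)
  out <- list()
  for (ev in unique(rec$event)) {
    r <- rec[rec$event == ev, , drop = FALSE]
    # use the 'a' record of each reciprocal pair
    ra <- r[grepl("a$", r$id), , drop = FALSE]
    ra <- ra[order(ra$id), , drop = FALSE]
    juncs <- list()
    for (i in seq_len(nrow(ra))) {
      p <- .parse_bnd_alt(ra$alt[i], paste0("(record ", ra$id[i], ")"))
      pos_a0 <- if (p$own_side == "left") ra$pos[i] else ra$pos[i] - 1L
      pos_b0 <- if (p$mate_side == "left") p$mate_pos1 else p$mate_pos1 - 1L
      juncs[[i]] <- data.frame(
        contig_a = ra$contig[i], pos_a = pos_a0, side_a = p$own_side,
        contig_b = p$mate_contig, pos_b = pos_b0, side_b = p$mate_side,
        type = .info_field(ra$info[i], "JTYPE"),
        n_split = as.integer(.info_field(ra$info[i], "NSPLIT")),
        link_ids = "", stringsAsFactors = FALSE)
    }
    segstr <- .info_field(r$info[1], "SEGS")
    segs <- do.call(rbind, lapply(strsplit(segstr, ",", fixed = TRUE)[[1]],
      function(s) {
        m <- regmatches(s, regexec("^(.+):([0-9]+)-([0-9]+)$", s))[[1]]
        data.frame(contig = m[2], start = as.integer(m[3]),
                   end = as.integer(m[4]), mean_depth = NA_real_,
                   stringsAsFactors = FALSE)
      }))
    prob <- suppressWarnings(as.numeric(.info_field(r$info[1], "PROB")))
    cand <- structure(list(
      id = ev, node_seq = NULL, roles = NULL, types = NULL,
      segments = segs, junctions = do.call(rbind, juncs),
      length = as.integer(.info_field(r$info[1], "CIRCLELEN")),
      signature = NA_character_, prob = if (is.na(prob)) NULL else prob
    ), class = "circle_candidate")
    out[[length(out) + 1L]] <- cand
  }
  # deterministic order by id
  out[order(vapply(out, function(x) x$id, character(1)))]
}
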