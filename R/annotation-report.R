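# Final outputs: gene annotation of circle segments, junction sequences for
# primer design, and the TSV report.

#' Read gene intervals from BED or GFF3
#'
#' BED input is 0-based half-open, GFF3 1-based inclusive; both are returned
#' as a GRanges with a `gene_name` column (BED name column; GFF3
#' Name/gene_name/ID attribute, type `gene` records when present).
#'
#' @param path BED (.bed) or GFF3 (.gff/.gff3) file.
#' @return GRanges with metadata column `gene_name`.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md)) {
    if (any(md$type == "gene")) gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  nm <- NULL
  for (col in c("gene_name", "Name", "name", "ID")) {
    if (col %in% names(md) && !all(is.na(md[[col]]))) {
      nm <- as.character(md[[col]])
      break
    }
  }
  if (is.null(nm)) nm <- paste0("feature_", seq_along(gr))
  S4Vectors::mcols(gr)$gene_name <- nm
  gr
}

#' Genes overlapped by a circle's segments
#'
#' Half-open interval overlap of the candidate's covered segments against a
#' gene annotation.
#'
#' @param candidate `circle_candidate`.
#' @param genes GRanges with `gene_name` (see [read_gene_annotation()]).
#' @return sorted unique character vector of gene names.
#' @export
annotate_genes <- function(candidate, genes) {
  segs <- candidate$segments
  known <- unique(as.character(GenomicRanges::seqnames(genes)))
  unknown <- setdiff(unique(segs$contig), known)
  if (length(unknown) == length(unique(segs$contig))) {
    stop("no circle contig found in annotation; unknown contigs: ",
         paste(unknown, collapse = ", "))
  }
  segs <- segs[segs$contig %in% known, , drop = FALSE]
  qr <- GenomicRanges::GRanges(segs$contig,
                               IRanges::IRanges(start = segs$start + 1L,
                                                end = segs$end))
  hits <- GenomicRanges::findOverlaps(qr, genes)
  sort(unique(S4Vectors::mcols(genes)$gene_name[S4Vectors::subjectHits(hits)]))
}

#' Junction-spanning sequence for primer design
#'
#' For each junction, the sequence a junction-crossing amplicon would have:
#' `flank` bases approaching the breakpoint along the circle on the donor
#' side, followed by `flank` bases leaving it on the acceptor side. Flanks
#' are truncated (with a warning) at contig ends and to the adjoining
#' segment's length; segments on the "right" side of a breakpoint enter the
#' amplicon reverse-complemented so that the emitted sequence reads
#' continuously in circle orientation.
#'
#' @param candidate `circle_candidate`.
#' @param reference `DNAStringSet`.
#' @param flank flank length in bp (default 2000, the usual primer-design
#'   window).
#' @return character vector, one sequence per junction.
#' @export
junction_sequence <- function(candidate, reference, flank = 2000L) {
  j <- candidate$junctions
  segs <- candidate$segments
  seg_len_at <- function(ctg, pos, side) {
    sel <- segs$contig == ctg &
      (if (side == "left") segs$end == pos else segs$start == pos)
    if (any(sel)) max(segs$end[sel] - segs$start[sel]) else Inf
  }
  take <- function(ctg, pos0, side) {
    len <- Biostrings::width(reference[ctg])
    fl <- flank
    seg_l <- seg_len_at(ctg, pos0, side)
    if (fl > seg_l) {
      warning("flank ", flank, " exceeds segment length at ", ctg, ":", pos0,
              "; truncated to ", seg_l)
      fl <- seg_l
    }
    if (side == "left") {
      s1 <- max(1L, pos0 - fl + 1L)  # 1-based window [pos0-fl+1, pos0]
      if (s1 < pos0 - fl + 1L) warning("flank truncated at contig start")
      as.character(Biostrings::subseq(reference[[ctg]], s1, pos0))
    } else {
      e1 <- min(len, pos0 + fl)      # 1-based window [pos0+1, pos0+fl]
      if (e1 < pos0 + fl) warning("flank truncated at contig end")
      as.character(Biostrings::subseq(reference[[ctg]], pos0 + 1L, e1))
    }
  }
  vapply(seq_len(nrow(j)), function(i) {
    # donor half: sequence approaching the breakpoint along its segment
    donor <- if (j$side_a[i] == "left") {
      take(j$contig_a[i], j$pos_a[i], "left")
    } else {
      # segment right of breakpoint: approach = reverse complement
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        take(j$contig_a[i], j$pos_a[i], "right"))))
    }
    accept <- if (j$side_b[i] == "right") {
      take(j$contig_b[i], j$pos_b[i], "right")
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        take(j$contig_b[i], j$pos_b[i], "left"))))
    }
    paste0(donor, accept)
  }, character(1))
}

#' Assemble the per-circle call table
#'
#' @param candidates list of `circle_candidate`.
#' @param probs numeric posterior per candidate (NA allowed).
#' @param supports list of per-candidate support data.frames (optional).
#' @param genes optional GRanges annotation; when given, a `genes` column is
#'   added.
#' @return data.frame, one row per candidate: circle_id, n_segments,
#'   n_junctions, circle_length, prob, genes, segments and junctions in
#'   1-based display coordinates, support counts.
#' @export
call_table <- function(candidates, probs = NULL, supports = NULL,
                       genes = NULL) {
  rows <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    segs1 <- sprintf("%s:%d-%d", cand$segments$contig,
                     cand$segments$start + 1L, cand$segments$end)
    j <- cand$junctions
    juncs1 <- sprintf("%s:%d(%s)~%s:%d(%s)[%s,n=%d]",
                      j$contig_a, vapply(seq_len(nrow(j)), function(k)
                        .bnd_pos1(j$pos_a[k], j$side_a[k]), integer(1)),
                      j$side_a,
                      j$contig_b, vapply(seq_len(nrow(j)), function(k)
                        .bnd_pos1(j$pos_b[k], j$side_b[k]), integer(1)),
                      j$side_b, j$type, j$n_split)
    sup <- if (!is.null(supports)) supports[[i]] else NULL
    data.frame(
      circle_id = cand$id,
      n_segments = nrow(cand$segments),
      n_junctions = nrow(j),
      circle_length = cand$length,
      prob = if (!is.null(probs)) probs[i] else NA_real_,
      genes = if (!is.null(genes))
        paste(annotate_genes(cand, genes), collapse = ",") else "",
      segments = paste(segs1, collapse = ";"),
      junctions = paste(juncs1, collapse = ";"),
      n_support = if (!is.null(sup)) sum(sup$c_support) else NA_integer_,
      n_cover = if (!is.null(sup)) sum(sup$c_cover) else NA_integer_,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    circle_id = character(0), n_segments = integer(0),
    n_junctions = integer(0), circle_length = integer(0), prob = numeric(0),
    genes = character(0), segments = character(0), junctions = character(0),
    n_support = integer(0), n_cover = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write the circle call report as TSV
#' @param calls data.frame from [call_table()] (possibly filtered).
#' @param path output file.
#' @export
write_report <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a circle call report back
#' @param path TSV written by [write_report()].
#' @return data.frame with the same columns and types as [call_table()].
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(circle_id = "character",
                                         genes = "character",
                                         segments = "character",
                                         junctions = "character"))
  df$genes[is.na(df$genes)] <- ""
  df
}
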