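# End-to-end detection pipeline: evidence -> graph -> pruning -> cycle
# enumeration -> scoring -> annotation/report.

#' Detect circular DNA candidates from mapped reads
#'
#' Runs the full detection pipeline on aligned segments (in memory or from a
#' SAM/BAM file): depth profile and split links, breakpoint graph with
#' pruning, plausible-cycle enumeration per strongly connected component,
#' junction-support scoring, and (optionally) gene annotation.
#'
#' @param segments `nc_segments`, or NULL to read from `alignments`.
#' @param alignments path to a coordinate-sorted SAM/BAM file.
#' @param genes optional GRanges gene annotation (see
#'   [read_gene_annotation()]).
#' @param theta coverage-edge threshold (mean depth, default 1).
#' @param theta_zero deletion-edge threshold (default 0: strictly read-free
#'   intervals).
#' @param mapq_min MAPQ filter applied to depth and split links (default 0).
#' @param merge_tol breakpoint clustering tolerance in bp (default 10).
#' @param max_del_len deletion-edge length cap (default Inf; see
#'   [build_graph()]).
#' @param max_cycles,max_edges enumeration caps.
#' @param require_split require at least one split-bearing junction per
#'   candidate (default TRUE).
#' @param model `scoring_model`.
#' @param min_prob posterior threshold for the filtered call set (default
#'   0.95).
#' @param support_tol breakpoint tolerance for junction-support counting.
#' @return object of class `circle_detection`: graph, candidates, supports,
#'   probs, `calls` (all candidates) and `filtered` tables,
#'   `filtered_candidates`, params.
#' @export
detect_circles <- function(segments = NULL, alignments = NULL, genes = NULL,
                           theta = 1L, theta_zero = 0, max_del_len = Inf,
                           mapq_min = 0L,
                           merge_tol = 10L, max_cycles = 10000L,
                           max_edges = 64L, require_split = TRUE,
                           model = scoring_model(), min_prob = 0.95,
                           support_tol = 10L) {
  if (is.null(segments)) {
    if (is.null(alignments)) stop("provide `segments` or `alignments`")
    segments <- read_alignments(alignments)
  }
  segments <- sort_segments(segments)
  profile <- compute_depth_profile(segments, mapq_min = mapq_min)
  links <- extract_split_links(segments, mapq_min = mapq_min)
  nodes <- collect_nodes(profile, links, merge_tol = merge_tol,
                         theta = theta, theta_zero = theta_zero)
  graph <- build_graph(nodes, profile, links, theta = theta,
                       theta_zero = theta_zero, max_del_len = max_del_len)
  pruned <- prune_graph(graph)
  cands <- enumerate_plausible_cycles(pruned, max_cycles = max_cycles,
                                      max_edges = max_edges,
                                      require_split = require_split)
  supports <- lapply(cands, collect_junction_support,
                     segments = segments, links = pruned$links,
                     tolerance = support_tol)
  probs <- vapply(seq_along(cands), function(i)
    score_circle(cands[[i]], supports[[i]], model), numeric(1))
  calls <- call_table(cands, probs = probs, supports = supports,
                      genes = genes)
  filtered <- filter_calls(calls, min_prob = min_prob)
  fc <- cands[match(filtered$circle_id,
                    vapply(cands, function(x) x$id, character(1)))]
  out <- list(profile = profile, links = links, graph = pruned,
              candidates = cands, supports = supports, probs = probs,
              calls = calls, filtered = filtered, filtered_candidates = fc,
              truncated = isTRUE(attr(cands, "truncated")),
              params = list(theta = theta, theta_zero = theta_zero,
                            max_del_len = max_del_len,
                            mapq_min = mapq_min, merge_tol = merge_tol,
                            max_cycles = max_cycles, max_edges = max_edges,
                            require_split = require_split, model = model,
                            min_prob = min_prob, support_tol = support_tol))
  class(out) <- "circle_detection"
  out
}

#' @export
print.circle_detection <- function(x, ...) {
  cat("circle_detection:", length(x$candidates), "candidate(s),",
      nrow(x$filtered), "call(s) at min_prob", x$params$min_prob, "\n")
  if (nrow(x$filtered)) {
    print(utils::head(x$filtered[, c("circle_id", "n_segments",
                                     "circle_length", "prob")], 10))
  }
  invisible(x)
}

#' Run detection and write the full output bundle
#'
#' Produces the on-disk results of one detection run: depth profile TSV,
#' split-link TSV, graph exports (GraphML + DOT), candidate and scored VCFs,
#' the TSV report, and a JSON provenance record (tool version, parameters,
#' input checksums).
#'
#' @param alignments path to SAM/BAM, or NULL if `segments` given.
#' @param out_dir output directory (created if needed).
#' @param segments optional in-memory `nc_segments`.
#' @param reference optional `DNAStringSet` or FASTA path (REF bases and
#'   junction sequences).
#' @param genes_file optional BED/GFF3 gene annotation path.
#' @param flank junction-sequence flank length (default 2000).
#' @param ... passed to [detect_circles()].
#' @return the `circle_detection` object, invisibly.
#' @export
run_detect <- function(alignments = NULL, out_dir, segments = NULL,
                       reference = NULL, genes_file = NULL, flank = 2000L,
                       ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  genes <- if (!is.null(genes_file)) read_gene_annotation(genes_file) else NULL
  res <- detect_circles(segments = segments, alignments = alignments,
                        genes = genes, ...)
  write_depth_tsv(res$profile, file.path(out_dir, "depth.tsv"))
  write_links_tsv(res$links, file.path(out_dir, "split_links.tsv"))
  if (nrow(res$graph$nodes)) {
    export_graph(res$graph, file.path(out_dir, "graph.graphml"), "graphml")
    export_graph(res$graph, file.path(out_dir, "graph.dot"), "dot")
  }
  contigs <- .contig_table(res, reference, segments)
  bnd_all <- .records_for(res$candidates, reference, probs = res$probs)
  write_breakend_vcf(bnd_all, file.path(out_dir, "candidates.vcf"), contigs)
  keep <- res$filtered$circle_id
  bnd_f <- if (length(keep)) bnd_all[bnd_all$event %in% keep, , drop = FALSE]
           else NULL
  write_breakend_vcf(bnd_f, file.path(out_dir, "calls.vcf"), contigs)
  report <- res$filtered
  if (!is.null(reference) && nrow(report)) {
    report$junction_seq <- vapply(res$filtered_candidates, function(cand) {
      paste(junction_sequence(cand, reference, flank = flank),
            collapse = ";")
    }, character(1))
  }
  write_report(report, file.path(out_dir, "report.tsv"))
  prov <- list(
    tool = "nanocircle",
    version = as.character(utils::packageVersion("nanocircle")),
    params = res$params[setdiff(names(res$params), "model")],
    model = unclass(res$params$model),
    inputs = if (!is.null(alignments))
      list(path = alignments,
           md5 = unname(tools::md5sum(alignments))) else list(),
    n_candidates = length(res$candidates),
    n_calls = nrow(res$filtered))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

.contig_table <- function(res, reference, segments) {
  if (!is.null(reference)) {
    data.frame(name = names(reference),
               length = Biostrings::width(reference),
               stringsAsFactors = FALSE)
  } else if (nrow(res$profile)) {
    agg <- tapply(res$profile$end, res$profile$contig, max)
    data.frame(name = names(agg), length = as.integer(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(0), length = integer(0))
  }
}

.records_for <- function(cands, reference, probs = NULL) {
  if (!length(cands)) return(NULL)
  recs <- lapply(seq_along(cands), function(i) {
    r <- cycle_to_breakends(cands[[i]], reference)
    if (!is.null(probs)) r$prob <- probs[i]
    r
  })
  do.call(rbind, recs)
}

#' Simulate a full benchmark bundle to disk
#'
#' @param out_dir output directory.
#' @param config `sim_config`.
#' @param n_contigs,contig_length,gc reference parameters.
#' @param fastq also write simulated read sequences as FASTQ.
#' @return list(reference, truth, sim) invisibly; writes reference.fasta,
#'   truth.tsv, reads.sam (and reads.fastq when requested).
#' @export
run_simulate <- function(out_dir, config = sim_config(), n_contigs = 2L,
                         contig_length = 5e5, gc = 0.41, fastq = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(n_contigs, contig_length, gc, seed = config$seed)
  truth <- simulate_truth(ref, config)
  sim <- simulate_alignments(ref, truth, config)
  Biostrings::writeXStringSet(ref, file.path(out_dir, "reference.fasta"))
  utils::write.table(as.data.frame(truth), file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  contigs <- data.frame(name = names(ref), length = Biostrings::width(ref))
  write_sam(sim$segments, contigs, file.path(out_dir, "reads.sam"))
  if (fastq) write_fastq(sim, ref, file.path(out_dir, "reads.fastq"))
  invisible(list(reference = ref, truth = truth, sim = sim))
}

#' Read a truth table written by [run_simulate()]
#' @param path truth.tsv path.
#' @return `true_circles` data.frame.
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("true_circles", "data.frame")
  df
}

#' Evaluate a calls VCF against a truth table
#'
#' @param calls_vcf breakend VCF written by [run_detect()].
#' @param truth_tsv truth TSV written by [run_simulate()].
#' @param match_tol breakpoint tolerance in bp (default 50).
#' @return data.frame with recall, precision and counts.
#' @export
run_evaluate <- function(calls_vcf, truth_tsv, match_tol = 50L) {
  calls <- read_breakend_vcf(calls_vcf)
  truth <- read_truth_tsv(truth_tsv)
  ev <- evaluate_calls(calls, truth, match_tol)
  data.frame(recall = ev$recall, precision = ev$precision,
             n_true = ev$n_true, n_called = ev$n_called,
             n_matched = ev$n_matched)
}
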