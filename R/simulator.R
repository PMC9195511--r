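# Synthetic-data generator and evaluator for the detection benchmark:
# circle-derived reads (with split alignments across circle junctions) on
# top of linear whole-genome background reads, plus recall/precision
# evaluation and a coverage sweep with read subsampling.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  fn()
}

#' Simulation configuration
#'
#' Defaults mirror the benchmark design: circles sequenced at 25x with reads
#' crossing their junctions, on top of linear whole-genome background reads
#' at 1x; log-normal read lengths with an 8 kb median; nanopore-like error
#' rates (5% substitutions, 3% insertions, 4% deletions).
#'
#' @param seed RNG seed; all outputs are deterministic given the seed.
#' @param n_circles number of circles to simulate.
#' @param size_range circle size range in bp (covered length).
#' @param topology_mix named weights for `simple`, `chimeric`,
#'   `with_deletion` topologies.
#' @param circle_coverage mean read depth over circle segments (default 25).
#' @param background_coverage linear background depth (default 1).
#' @param read_length_meanlog,read_length_sdlog log-normal read-length
#'   parameters (defaults give a median of 8 kb).
#' @param min_read_length shortest simulated read (default 300 bp).
#' @param sub_rate,ins_rate,del_rate per-base error rates used when read
#'   sequences or CIGARs are emitted.
#' @param jitter junction-endpoint jitter in bp (uniform in +/- jitter,
#'   emulating mapper imprecision at breakpoints; default 0).
#' @param mapq mapping quality assigned to simulated alignments.
#' @param emit_cigar generate per-read CIGARs with indel errors (default
#'   FALSE: plain match CIGARs; alignment spans are unaffected).
#' @param deletion_frac fraction of a with-deletion circle's span removed
#'   from its middle (default 0.2).
#' @param margin minimum distance between circle footprints and to contig
#'   ends (default 20 kb).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_circles = 3L, size_range = c(2e3, 5e4),
                       topology_mix = c(simple = 1, chimeric = 1,
                                        with_deletion = 1),
                       circle_coverage = 25, background_coverage = 1,
                       read_length_meanlog = log(8000),
                       read_length_sdlog = 0.6,
                       min_read_length = 300L,
                       sub_rate = 0.05, ins_rate = 0.03, del_rate = 0.04,
                       jitter = 0L, mapq = 60L, emit_cigar = FALSE,
                       deletion_frac = 0.2, margin = 2e4) {
  stopifnot(circle_coverage >= 0, background_coverage >= 0,
            all(c(sub_rate, ins_rate, del_rate) >= 0),
            all(c(sub_rate, ins_rate, del_rate) <= 1),
            jitter >= 0, deletion_frac > 0, deletion_frac < 1)
  cfg <- list(seed = as.integer(seed), n_circles = as.integer(n_circles),
              size_range = size_range, topology_mix = topology_mix,
              circle_coverage = circle_coverage,
              background_coverage = background_coverage,
              read_length_meanlog = read_length_meanlog,
              read_length_sdlog = read_length_sdlog,
              min_read_length = as.integer(min_read_length),
              sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
              jitter = as.integer(jitter), mapq = as.integer(mapq),
              emit_cigar = emit_cigar, deletion_frac = deletion_frac,
              margin = margin)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a reference genome
#'
#' @param n_contigs number of contigs.
#' @param lengths contig lengths (recycled).
#' @param gc GC fraction (default 0.41, human-like).
#' @param seed RNG seed.
#' @return named `DNAStringSet` (contig1, contig2, ...).
#' @export
simulate_reference <- function(n_contigs = 2L, lengths = 5e5, gc = 0.41,
                               seed = 1L) {
  lengths <- rep_len(as.integer(lengths), n_contigs)
  .with_seed(seed, function() {
    seqs <- vapply(seq_len(n_contigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), lengths[i], replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
    ref <- Biostrings::DNAStringSet(seqs)
    names(ref) <- paste0("contig", seq_len(n_contigs))
    ref
  })
}

#' Simulate true circles
#'
#' Places non-overlapping circles of three topologies: `simple` (one covered
#' segment, one split junction), `chimeric` (two segments on different
#' contigs, two split junctions), `with_deletion` (two covered segments on
#' one contig separated by an uncovered gap: one deletion junction, one
#' split junction).
#'
#' @param reference `DNAStringSet`.
#' @param config `sim_config`.
#' @return data.frame of class `true_circles`: circle_id, topology, seg
#'   (order along the molecule), contig, start, end (0-based half-open
#'   covered segments).
#' @export
simulate_truth <- function(reference, config) {
  lens <- stats::setNames(Biostrings::width(reference), names(reference))
  .with_seed(config$seed + 1L, function() {
    mix <- config$topology_mix / sum(config$topology_mix)
    topos <- sample(names(mix), config$n_circles, replace = TRUE, prob = mix)
    if (length(lens) < 2) topos[topos == "chimeric"] <- "simple"
    occupied <- lapply(lens, function(x) cbind(start = numeric(0),
                                               end = numeric(0)))
    place <- function(ctg, size) {
      lo <- config$margin
      hi <- lens[[ctg]] - config$margin - size
      if (hi <= lo) return(NULL)
      for (try in 1:200) {
        s <- floor(stats::runif(1, lo, hi))
        occ <- occupied[[ctg]]
        if (!nrow(occ) || all(s + size + config$margin <= occ[, "start"] |
                                s - config$margin >= occ[, "end"])) {
          occupied[[ctg]] <<- rbind(occ, c(start = s, end = s + size))
          return(s)
        }
      }
      NULL
    }
    rows <- list()
    for (ci in seq_along(topos)) {
      size <- floor(stats::runif(1, config$size_range[1],
                                 config$size_range[2]))
      id <- sprintf("true_%02d", ci)
      topo <- topos[ci]
      if (topo == "simple") {
        ctg <- sample(names(lens), 1, prob = lens)
        s <- place(ctg, size)
        if (is.null(s)) stop("cannot place circle ", ci,
                             "; reduce n_circles or sizes")
        rows[[length(rows) + 1L]] <- data.frame(
          circle_id = id, topology = topo, seg = 1L, contig = ctg,
          start = s, end = s + size, stringsAsFactors = FALSE)
      } else if (topo == "chimeric") {
        ctgs <- sample(names(lens), 2, prob = lens)
        half <- floor(size / 2)
        s1 <- place(ctgs[1], half)
        s2 <- place(ctgs[2], size - half)
        if (is.null(s1) || is.null(s2)) stop("cannot place circle ", ci,
                                             "; reduce n_circles or sizes")
        rows[[length(rows) + 1L]] <- data.frame(
          circle_id = id, topology = topo, seg = 1:2,
          contig = ctgs, start = c(s1, s2),
          end = c(s1 + half, s2 + size - half), stringsAsFactors = FALSE)
      } else {  # with_deletion
        gap <- max(200L, floor(size * config$deletion_frac))
        span <- size + gap
        ctg <- sample(names(lens), 1, prob = lens)
        s <- place(ctg, span)
        if (is.null(s)) stop("cannot place circle ", ci,
                             "; reduce n_circles or sizes")
        a <- floor(size / 2)
        rows[[length(rows) + 1L]] <- data.frame(
          circle_id = id, topology = topo, seg = 1:2, contig = ctg,
          start = c(s, s + a + gap), end = c(s + a, s + a + gap + size - a),
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    if (is.null(truth)) {
      truth <- data.frame(circle_id = character(0), topology = character(0),
                          seg = integer(0), contig = character(0),
                          start = integer(0), end = integer(0),
                          stringsAsFactors = FALSE)
    }
    rownames(truth) <- NULL
    class(truth) <- c("true_circles", "data.frame")
    truth
  })
}

# Junction plan of a circle in molecule order: between arc i and i+1
# (cyclically); "split" junctions produce supplementary alignments, a
# "deletion" junction fragments the molecule (library-prep break).
.junction_plan <- function(topology, k) {
  if (topology == "with_deletion") c("deletion", "split")[seq_len(k)]
  else rep("split", k)
}

#' Simulate aligned reads for circles plus linear background
#'
#' Circle reads are sampled from random rotations of each circle molecule
#' and fragmented to the read-length distribution (capped at the circle
#' length, so a read crosses each junction at most once). A read crossing a
#' split junction is emitted as primary + supplementary alignments with the
#' configured endpoint jitter; a read crossing a deletion junction is broken
#' into unlinked fragments. Background reads are uniform over the reference
#' at `background_coverage`.
#'
#' @param reference `DNAStringSet`.
#' @param truth `true_circles`.
#' @param config `sim_config`.
#' @return list of class `sim_result`: `segments` (`nc_segments`, sorted),
#'   `truth`, `config`.
#' @export
simulate_alignments <- function(reference, truth, config) {
  lens <- stats::setNames(Biostrings::width(reference), names(reference))
  .with_seed(config$seed + 2L, function() {
    rows <- list()
    emit <- function(read_id, molecule, contig, start, end, supp, qstart) {
      w <- end - start
      cigar <- if (config$emit_cigar) .sim_cigar(w, config) else
        sprintf("%dM", w)
      rows[[length(rows) + 1L]] <<- data.frame(
        read_id = read_id, contig = contig, start = start, end = end,
        strand = "+", mapq = config$mapq, is_supplementary = supp,
        qstart = qstart, cigar = cigar, molecule = molecule,
        stringsAsFactors = FALSE)
    }
    jit <- function() if (config$jitter > 0)
      sample(seq(-config$jitter, config$jitter), 1) else 0L

    for (id in unique(truth$circle_id)) {
      arcs <- truth[truth$circle_id == id, , drop = FALSE]
      arcs <- arcs[order(arcs$seg), , drop = FALSE]
      k <- nrow(arcs)
      alen <- arcs$end - arcs$start
      L <- sum(alen)
      jplan <- .junction_plan(arcs$topology[1], k)
      offs <- cumsum(c(0, alen))[seq_len(k)]
      target <- config$circle_coverage * L
      got <- 0
      rix <- 0L
      while (got < target) {
        rix <- rix + 1L
        rl <- min(L, max(config$min_read_length,
                         round(stats::rlnorm(1, config$read_length_meanlog,
                                             config$read_length_sdlog))))
        got <- got + rl
        u <- floor(stats::runif(1, 0, L))
        # walk circle coords [u, u+rl), splitting at arc boundaries
        pieces <- list()   # (arc, from, to) in circle coords
        left <- rl
        cur <- u
        while (left > 0) {
          ai <- findInterval(cur %% L, offs)
          arc_end <- offs[ai] + alen[ai]
          take <- min(left, arc_end - (cur %% L))
          pieces[[length(pieces) + 1L]] <- c(ai, cur %% L, (cur %% L) + take)
          cur <- cur + take
          left <- left - take
        }
        # group into fragments at deletion junctions; junction after piece j
        # (between arcs ai and ai+1 cyclic) has type jplan[ai]
        frag <- 1L
        frags <- integer(length(pieces))
        frags[1] <- 1L
        if (length(pieces) > 1) {
          for (p in 2:length(pieces)) {
            prev_arc <- pieces[[p - 1]][1]
            if (jplan[prev_arc] == "deletion") frag <- frag + 1L
            frags[p] <- frag
          }
        }
        mol <- sprintf("%s_r%04d", id, rix)
        for (fr in unique(frags)) {
          pidx <- which(frags == fr)
          rid <- if (max(frags) == 1L) mol else sprintf("%s_f%d", mol, fr)
          qoff <- 0L
          for (pj in seq_along(pidx)) {
            p <- pieces[[pidx[pj]]]
            ai <- p[1]
            s_ref <- arcs$start[ai] + (p[2] - offs[ai])
            e_ref <- arcs$start[ai] + (p[3] - offs[ai])
            # jitter junction-adjacent endpoints (split junctions only)
            if (pj > 1) s_ref <- s_ref + jit()
            if (pj < length(pidx)) e_ref <- e_ref + jit()
            s_ref <- max(arcs$start[ai], min(s_ref, arcs$end[ai] - 1L))
            e_ref <- max(s_ref + 1L, min(e_ref, arcs$end[ai]))
            emit(rid, mol, arcs$contig[ai], as.integer(s_ref),
                 as.integer(e_ref), pj > 1L, as.integer(qoff))
            qoff <- qoff + (e_ref - s_ref)
          }
        }
      }
    }
    # background
    if (config$background_coverage > 0) {
      for (ctg in names(lens)) {
        len <- lens[[ctg]]
        mean_len <- exp(config$read_length_meanlog +
                          config$read_length_sdlog^2 / 2)
        n <- ceiling(config$background_coverage * len / mean_len)
        if (n <= 0) next
        rl <- pmax(config$min_read_length,
                   round(stats::rlnorm(n, config$read_length_meanlog,
                                       config$read_length_sdlog)))
        st <- floor(stats::runif(n, 0, len - 1))
        en <- pmin(st + rl, len)
        for (i in seq_len(n)) {
          emit(sprintf("bg_%s_%05d", ctg, i), sprintf("bg_%s_%05d", ctg, i),
               ctg, as.integer(st[i]), as.integer(en[i]), FALSE, 0L)
        }
      }
    }
    segments <- if (length(rows)) do.call(rbind, rows) else
      data.frame(read_id = character(0), contig = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 mapq = integer(0), is_supplementary = logical(0),
                 qstart = integer(0), cigar = character(0),
                 molecule = character(0), stringsAsFactors = FALSE)
    validate_segments(segments)
    out <- list(segments = sort_segments(segments), truth = truth,
                config = config)
    class(out) <- "sim_result"
    out
  })
}

# CIGAR with single-base indel errors scattered over a span of w reference
# bases (reference span preserved: nD deleted bases are still consumed).
.sim_cigar <- function(w, config) {
  nD <- stats::rbinom(1, w, config$del_rate)
  nI <- stats::rbinom(1, w, config$ins_rate)
  npos <- nD + nI
  if (npos == 0 || w < npos + 2) return(sprintf("%dM", w))
  at <- sort(sample(seq_len(w - 1), min(npos, w - 1)))
  op <- sample(c(rep("D", nD), rep("I", nI)))[seq_along(at)]
  parts <- character(0)
  prev <- 0L
  for (i in seq_along(at)) {
    m <- at[i] - prev
    if (m > 0) parts <- c(parts, sprintf("%dM", m))
    parts <- c(parts, paste0("1", op[i]))
    prev <- at[i] + as.integer(op[i] == "D")
  }
  if (w - prev > 0) parts <- c(parts, sprintf("%dM", w - prev))
  paste(parts, collapse = "")
}

#' Subsample reads to a lower coverage
#'
#' Thins uniformly per molecule (all alignment records and fragments of a
#' molecule are kept or dropped together), emulating subsampling a high-
#' coverage read set down to a target coverage.
#'
#' @param segments `nc_segments` with a `molecule` column.
#' @param fraction keep probability in \[0, 1\].
#' @param seed RNG seed.
#' @return thinned, sorted `nc_segments`.
#' @export
subsample_reads <- function(segments, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  .with_seed(seed, function() {
    mols <- unique(segments$molecule)
    keep <- mols[stats::runif(length(mols)) < fraction]
    sort_segments(segments[segments$molecule %in% keep, , drop = FALSE])
  })
}

# ---------------------------------------------------------------------------
# SAM / FASTQ emission

#' Write aligned segments as a SAM file
#'
#' Coordinate-sorted SAM with SA tags linking the pieces of split reads.
#' SEQ/QUAL are omitted ("*"); clipping in the CIGAR encodes each piece's
#' query offset.
#'
#' @param segments `nc_segments`.
#' @param contigs data.frame(name, length).
#' @param path output .sam path.
#' @export
write_sam <- function(segments, contigs, path) {
  seg <- sort_segments(segments)
  # query length per read for clip bookkeeping
  qw <- cigar_query_width(seg$cigar)
  qw[seg$cigar == "*"] <- seg$end[seg$cigar == "*"] - seg$start[seg$cigar == "*"]
  qlen <- tapply(seg$qstart + qw, seg$read_id, max)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs$name,
                   as.integer(contigs$length)))
  core <- function(i) {
    cg <- seg$cigar[i]
    w <- seg$end[i] - seg$start[i]
    if (cg == "*") cg <- sprintf("%dM", w)
    lead <- seg$qstart[i]
    trail <- qlen[[seg$read_id[i]]] - seg$qstart[i] - qw[i]
    paste0(if (lead > 0) sprintf("%dS", lead) else "",
           cg,
           if (trail > 0) sprintf("%dS", trail) else "")
  }
  cigars <- vapply(seq_len(nrow(seg)), core, character(1))
  sa_of <- function(i) {
    mates <- which(seg$read_id == seg$read_id[i])
    mates <- mates[mates != i]
    if (!length(mates)) return(NULL)
    paste0(paste(seg$contig[mates], seg$start[mates] + 1L,
                 seg$strand[mates], cigars[mates], seg$mapq[mates], 0,
                 sep = ","), collapse = ";")
  }
  lines <- vapply(seq_len(nrow(seg)), function(i) {
    flag <- 0L
    if (seg$strand[i] == "-") flag <- flag + 16L
    if (seg$is_supplementary[i]) flag <- flag + 2048L
    sa <- sa_of(i)
    paste(c(seg$read_id[i], flag, seg$contig[i], seg$start[i] + 1L,
            seg$mapq[i], cigars[i], "*", 0, 0, "*", "*",
            if (!is.null(sa)) paste0("SA:Z:", sa, ";")), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' Reconstructs each read's sequence from the reference along its aligned
#' pieces (in query order, across junctions) and applies the configured
#' substitution/indel error model. Suitable for end-to-end runs through a
#' real long-read mapper.
#'
#' @param sim `sim_result`.
#' @param reference `DNAStringSet`.
#' @param path output .fastq path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(sim, reference, path) {
  seg <- sim$segments
  cfg <- sim$config
  con <- file(path, "w")
  on.exit(close(con))
  .with_seed(cfg$seed + 3L, function() {
    for (rid in unique(seg$read_id)) {
      s <- seg[seg$read_id == rid, , drop = FALSE]
      s <- s[order(s$qstart), , drop = FALSE]
      parts <- vapply(seq_len(nrow(s)), function(i) {
        x <- Biostrings::subseq(reference[[s$contig[i]]], s$start[i] + 1L,
                                s$end[i])
        if (s$strand[i] == "-") x <- Biostrings::reverseComplement(x)
        as.character(x)
      }, character(1))
      sq <- .apply_errors(paste(parts, collapse = ""), cfg)
      writeLines(c(paste0("@", rid), sq, "+",
                   paste(rep("I", nchar(sq)), collapse = "")), con)
    }
  })
  invisible(path)
}

.apply_errors <- function(s, cfg) {
  if (cfg$sub_rate + cfg$ins_rate + cfg$del_rate == 0) return(s)
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  bases <- c("A", "C", "G", "T")
  subs <- which(stats::runif(n) < cfg$sub_rate)
  if (length(subs)) {
    v[subs] <- vapply(v[subs], function(b)
      sample(setdiff(bases, b), 1), character(1))
  }
  dels <- stats::runif(n) < cfg$del_rate
  ins <- which(stats::runif(n) < cfg$ins_rate)
  if (length(ins)) {
    v[ins] <- paste0(v[ins], sample(bases, length(ins), replace = TRUE))
  }
  paste(v[!dels], collapse = "")
}

# ---------------------------------------------------------------------------
# Evaluation

# Does one call match one true circle: same segment count and every
# breakpoint within tol.
.circle_matches <- function(call_segs, true_segs, tol) {
  if (nrow(call_segs) != nrow(true_segs)) return(FALSE)
  a <- call_segs[order(call_segs$contig, call_segs$start), , drop = FALSE]
  b <- true_segs[order(true_segs$contig, true_segs$start), , drop = FALSE]
  all(a$contig == b$contig) &&
    all(abs(a$start - b$start) <= tol) &&
    all(abs(a$end - b$end) <= tol)
}

#' Recall and precision of circle calls against simulated truth
#'
#' A call matches a true circle iff it has the same number of covered
#' segments and every breakpoint lies within `match_tol`. Matching is
#' one-to-one (maximum bipartite matching); recall = matched/|T|,
#' precision = matched/|C|, with 0/0 defined as 1.
#'
#' @param calls list of `circle_candidate` (e.g. filtered calls).
#' @param truth `true_circles`.
#' @param match_tol breakpoint tolerance in bp (default 50).
#' @return list: recall, precision, n_true, n_called, n_matched, pairs
#'   (data.frame call_id/true_id).
#' @export
evaluate_calls <- function(calls, truth, match_tol = 50L) {
  stopifnot(match_tol >= 0)
  true_ids <- unique(truth$circle_id)
  nT <- length(true_ids)
  nC <- length(calls)
  if (nT == 0 || nC == 0) {
    return(list(recall = if (nT == 0) 1 else 0,
                precision = if (nC == 0) 1 else nC * 0,
                n_true = nT, n_called = nC, n_matched = 0L,
                pairs = data.frame(call_id = character(0),
                                   true_id = character(0))))
  }
  adj <- matrix(FALSE, nC, nT)
  for (i in seq_len(nC)) {
    for (j in seq_len(nT)) {
      ts <- truth[truth$circle_id == true_ids[j], , drop = FALSE]
      adj[i, j] <- .circle_matches(calls[[i]]$segments, ts, match_tol)
    }
  }
  m <- .max_bipartite(adj)
  pairs <- data.frame(
    call_id = vapply(m$left, function(i) calls[[i]]$id, character(1)),
    true_id = true_ids[m$right], stringsAsFactors = FALSE)
  list(recall = nrow(pairs) / nT, precision = nrow(pairs) / nC,
       n_true = nT, n_called = nC, n_matched = nrow(pairs), pairs = pairs)
}

# Maximum bipartite matching (augmenting paths) on a logical adjacency
# matrix rows=left, cols=right; returns matched index pairs.
.max_bipartite <- function(adj) {
  nL <- nrow(adj)
  nR <- ncol(adj)
  match_r <- rep(NA_integer_, nR)
  try_kuhn <- function(u, seen) {
    for (v in which(adj[u, ])) {
      if (seen[v]) next
      seen[v] <- TRUE
      if (is.na(match_r[v]) || Recall(match_r[v], seen)) {
        match_r[v] <<- u
        return(TRUE)
      }
    }
    FALSE
  }
  for (u in seq_len(nL)) try_kuhn(u, rep(FALSE, nR))
  got <- which(!is.na(match_r))
  list(left = match_r[got], right = got)
}

#' Coverage sweep: recall and precision across subsampled coverages
#'
#' Simulates each replicate once at the configured (high) circle coverage,
#' thins the read set to each target coverage, runs detection and evaluates
#' against the truth.
#'
#' @param reference `DNAStringSet`.
#' @param truth `true_circles`.
#' @param config `sim_config` (its `circle_coverage` is the source
#'   coverage that subsampling thins from).
#' @param coverages target coverages (default c(5, 10, 15, 25)).
#' @param replicates number of simulation replicates (default 3).
#' @param match_tol breakpoint tolerance for evaluation.
#' @param ... passed to [detect_circles()] (theta, theta_zero, min_prob,
#'   ...).
#' @return data.frame: replicate, coverage, recall, precision, n_called.
#' @export
coverage_sweep <- function(reference, truth, config,
                           coverages = c(5, 10, 15, 25), replicates = 3L,
                           match_tol = 50L, ...) {
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * rep_i
    sim <- simulate_alignments(reference, truth, cfg)
    for (cov in coverages) {
      frac <- min(1, cov / config$circle_coverage)
      seg <- subsample_reads(sim$segments, frac, seed = cfg$seed + cov)
      res <- detect_circles(segments = seg, ...)
      ev <- evaluate_calls(res$filtered_candidates, truth, match_tol)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep_i, coverage = cov, recall = ev$recall,
        precision = ev$precision, n_called = ev$n_called)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
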