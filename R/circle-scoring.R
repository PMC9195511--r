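# Posterior scoring of circle candidates. The model is a deliberately simple
# generative stand-in for a full realignment-based caller: at each junction,
# reads near the breakpoints either support the junction (their alignment
# breaks at both breakends with compatible orientation) or span it
# contiguously. If the circle is real, a read near a junction supports it
# with probability rho (circle-enriched libraries make junction-crossing
# reads dominant); if it is not, apparent support arises only from
# mapping/chimera artifacts at rate epsilon. Junction Bayes factors combine
# by independence.

#' Scoring model parameters
#'
#' @param prior prior probability that a candidate is real (default 0.5).
#' @param epsilon per-read probability that a non-circle read presents as
#'   junction-supporting (artifact rate, default 0.01).
#' @param rho expected support fraction at a true junction (default 0.9).
#' @return object of class `scoring_model`.
#' @export
scoring_model <- function(prior = 0.5, epsilon = 0.01, rho = 0.9) {
  stopifnot(prior > 0, prior < 1, epsilon > 0, epsilon < 1,
            rho > 0, rho < 1, epsilon < rho)
  structure(list(prior = prior, epsilon = epsilon, rho = rho),
            class = "scoring_model")
}

# MAPQ-derived read weight: probability the mapping location is correct.
.mapq_weight <- function(mapq) 1 - 10^(-mapq / 10)

#' Collect per-junction read support for a candidate
#'
#' A read supports a junction when one of its split links matches both
#' breakends within `tolerance` and with compatible orientation. A read
#' covers a junction without supporting it when one of its segments extends
#' at least `tolerance + 1` bases on both sides of a breakend boundary.
#' Counts are MAPQ-weighted (weight 1 - 10^(-MAPQ/10)); integer counts are
#' kept alongside.
#'
#' @param candidate `circle_candidate`.
#' @param segments `nc_segments`.
#' @param links `nc_links`.
#' @param tolerance breakpoint match tolerance in bp (default 10).
#' @return data.frame: junction, n_support, n_cover (weighted), c_support,
#'   c_cover (integer read counts).
#' @export
collect_junction_support <- function(candidate, segments, links,
                                     tolerance = 10L) {
  stopifnot(tolerance >= 0)
  j <- candidate$junctions
  out <- vector("list", nrow(j))
  for (i in seq_len(nrow(j))) {
    # support: links matching both endpoints (either endpoint assignment)
    match_end <- function(lc, lp, ls, jc, jp, js) {
      lc == jc & abs(lp - jp) <= tolerance & ls == js
    }
    if (nrow(links)) {
      fwd <- match_end(links$contig_a, links$pos_a, links$side_a,
                       j$contig_a[i], j$pos_a[i], j$side_a[i]) &
             match_end(links$contig_b, links$pos_b, links$side_b,
                       j$contig_b[i], j$pos_b[i], j$side_b[i])
      rev <- match_end(links$contig_a, links$pos_a, links$side_a,
                       j$contig_b[i], j$pos_b[i], j$side_b[i]) &
             match_end(links$contig_b, links$pos_b, links$side_b,
                       j$contig_a[i], j$pos_a[i], j$side_a[i])
      sup <- links[fwd | rev, , drop = FALSE]
    } else {
      sup <- links
    }
    sup_reads <- unique(sup$read_id)
    w_sup <- sum(.mapq_weight(sup$mapq_min[!duplicated(sup$read_id)]))
    # coverage: segments spanning either breakend boundary
    margin <- tolerance + 1L
    spans <- function(jc, jp) {
      segments$contig == jc & segments$start <= jp - margin &
        segments$end >= jp + margin
    }
    sp <- spans(j$contig_a[i], j$pos_a[i]) | spans(j$contig_b[i], j$pos_b[i])
    cov <- segments[sp & !(segments$read_id %in% sup_reads), , drop = FALSE]
    if (nrow(cov)) {
      # one weight per read: its best spanning segment
      wr <- tapply(.mapq_weight(cov$mapq), cov$read_id, max)
      w_cov <- sum(wr)
      c_cov <- length(wr)
    } else {
      w_cov <- 0
      c_cov <- 0L
    }
    out[[i]] <- data.frame(junction = i, n_support = w_sup, n_cover = w_cov,
                           c_support = length(sup_reads), c_cover = c_cov)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(junction = integer(0), n_support = numeric(0),
                      n_cover = numeric(0), c_support = integer(0),
                      c_cover = integer(0))
  }
  res
}

#' Posterior probability that a candidate circle is present
#'
#' Per junction j with support k_j out of n_j = k_j + cover_j informative
#' reads, the Bayes factor of Bin(k_j | n_j, rho) against Bin(k_j | n_j,
#' epsilon) is computed (binomial coefficients cancel); junction factors
#' multiply under independence, and the posterior is
#' prior * BF / (prior * BF + 1 - prior). A junction with no informative
#' reads contributes a factor of 1 (uninformative); a candidate with no
#' informative reads anywhere therefore scores the prior.
#'
#' @param candidate `circle_candidate` (used only for reporting).
#' @param supports data.frame from [collect_junction_support()].
#' @param model `scoring_model`.
#' @return posterior probability in \[0, 1\].
#' @export
score_circle <- function(candidate, supports, model = scoring_model()) {
  stopifnot(inherits(model, "scoring_model"))
  k <- supports$n_support
  n <- supports$n_support + supports$n_cover
  log_bf <- ifelse(n == 0, 0,
                   k * (log(model$rho) - log(model$epsilon)) +
                     (n - k) * (log1p(-model$rho) - log1p(-model$epsilon)))
  stats::plogis(stats::qlogis(model$prior) + sum(log_bf))
}

#' Filter and order scored circle calls
#'
#' @param calls data.frame of calls with columns `prob` and `circle_length`.
#' @param min_prob minimum posterior probability (default 0.95).
#' @return calls with `prob >= min_prob`, sorted by probability then circle
#'   length, both descending.
#' @export
filter_calls <- function(calls, min_prob = 0.95) {
  stopifnot(min_prob >= 0, min_prob <= 1)
  keep <- calls[calls$prob >= min_prob, , drop = FALSE]
  keep <- keep[order(-keep$prob, -keep$circle_length), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
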