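# Minimal CIGAR arithmetic. All coordinates 0-based half-open unless noted.

.cigar_split <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    return(list(len = integer(0), op = character(0)))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) {
    stop("malformed CIGAR string: ", cigar)
  }
  list(len = lens, op = ops)
}

#' Reference-consumed width of a CIGAR string
#'
#' @param cigar character vector of CIGAR strings ("*" gives 0).
#' @return integer vector of reference widths (M/D/N/=/X operations).
#' @keywords internal
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    cc <- .cigar_split(cg)
    sum(cc$len[cc$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Query-consumed width of a CIGAR string (clips excluded)
#' @keywords internal
#' @noRd
cigar_query_width <- function(cigar) {
  vapply(cigar, function(cg) {
    cc <- .cigar_split(cg)
    sum(cc$len[cc$op %in% c("M", "I", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Leading/trailing clip lengths (S or H), in reference orientation.
.cigar_clips <- function(cigar) {
  cc <- .cigar_split(cigar)
  n <- length(cc$op)
  lead <- 0L
  trail <- 0L
  i <- 1L
  while (i <= n && cc$op[i] %in% c("S", "H")) {
    lead <- lead + cc$len[i]
    i <- i + 1L
  }
  j <- n
  while (j >= i && cc$op[j] %in% c("S", "H")) {
    trail <- trail + cc$len[j]
    j <- j - 1L
  }
  c(lead = lead, trail = trail)
}

# Per-operation reference intervals of a CIGAR anchored at `start` (0-based).
# Returns data.frame(op, start, end, len); insertions get a zero-width
# interval at their reference anchor.
.cigar_ref_ops <- function(cigar, start) {
  cc <- .cigar_split(cigar)
  keep <- !(cc$op %in% c("S", "H", "P"))
  op <- cc$op[keep]
  len <- cc$len[keep]
  consumes <- ifelse(op %in% c("M", "D", "N", "=", "X"), len, 0L)
  ends <- start + cumsum(consumes)
  starts <- ends - consumes
  data.frame(op = op, start = starts, end = ends, len = len,
             stringsAsFactors = FALSE)
}
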