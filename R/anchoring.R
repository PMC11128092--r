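# MUM anchoring.
#
# A MUM (maximal unique match) is an exact match present in every genome of
# the set, occurring exactly once in each genome counting both strands, and
# not extensible left or right in all genomes simultaneously.  MUMs anchor
# the core-genome alignment; uniqueness is counted over both strands because
# an inverted duplicate makes a match useless as an anchor.

#' Find maximal unique matches across a genome set
#'
#' Builds a generalized suffix array (linear-time SA-IS) over both strands of
#' every genome and scans the LCP array for windows of exactly one suffix per
#' genome.  Reference loci are always reported on the forward strand (the
#' reference is never flipped); query strands are relative to the reference.
#'
#' @param genomes a \code{\link{genome_set}}.
#' @param min_length minimum match length in bp (>= 8).
#' @return an object of class \code{mum_anchors}: a list with \code{length}
#'   (bp per anchor), \code{pos} (anchors x genomes matrix of 0-based
#'   forward-strand start positions, roster order), \code{fwd} (logical
#'   matrix, TRUE = '+') and \code{roster}.  Anchors are sorted by reference
#'   position and no two share a reference start.
#' @export
find_mums <- function(genomes, min_length = 15L) {
  if (!inherits(genomes, "genome_set")) stop("genomes must be a genome_set")
  if (genomes$n < 1L)
    stop("MUMs are undefined without at least one query genome")
  if (min_length < 8L) stop("min_length must be >= 8")
  res <- .find_mums_cpp(gs_seqs(genomes), as.integer(min_length))
  colnames(res$pos) <- colnames(res$fwd) <- genomes$roster
  structure(list(length = res$length, pos = res$pos, fwd = res$fwd,
                 roster = genomes$roster, min_length = as.integer(min_length)),
            class = "mum_anchors")
}

#' @export
print.mum_anchors <- function(x, ...) {
  cat("<mum_anchors>", length(x$length), "anchors over",
    length(x$roster), "genomes,", sum(x$length), "anchored reference bp\n")
  invisible(x)
}

anchors_subset <- function(anchors, idx) {
  structure(list(length = anchors$length[idx],
                 pos = anchors$pos[idx, , drop = FALSE],
                 fwd = anchors$fwd[idx, , drop = FALSE],
                 roster = anchors$roster, min_length = anchors$min_length),
            class = "mum_anchors")
}

#' Remove spurious anchors
#'
#' Keeps, per query genome, a maximum-total-length union of strand-consistent
#' monotone runs: the heaviest strictly monotone subsequence (increasing for
#' '+' anchors, decreasing for '-') is extracted repeatedly until the best
#' remaining run falls below \code{min_run} anchored bp; anchors outside the
#' kept runs in any query are dropped.  A single mislocated anchor interrupting
#' a long collinear run forms its own sub-threshold run and is removed, while
#' genuine inverted or translocated blocks survive as heavy runs of their own.
#'
#' @param anchors a \code{mum_anchors} object from \code{\link{find_mums}}.
#' @param genomes the genome set the anchors came from (unused, kept for
#'   symmetry with the other pipeline stages).
#' @param min_run minimum anchored bp for a run to be kept; defaults to three
#'   times the anchor minimum length.
#' @return the filtered \code{mum_anchors}; dropped anchor indices are
#'   recorded in attribute \code{"dropped"}.
#' @export
filter_spurious <- function(anchors, genomes = NULL, min_run = NULL) {
  M <- length(anchors$length)
  if (M == 0L) return(anchors)
  min_run <- min_run %||% (3L * anchors$min_length)
  G <- length(anchors$roster)
  keep <- rep(TRUE, M)
  w <- as.numeric(anchors$length)
  for (g in seq_len(G)[-1L]) {
    pos <- anchors$pos[, g]
    fwd <- anchors$fwd[, g]
    rem <- seq_len(M)
    kept_g <- logical(M)
    repeat {
      if (!length(rem)) break
      fi <- rem[fwd[rem]]
      ri <- rem[!fwd[rem]]
      best <- integer(0)
      bw <- -1
      if (length(fi)) {
        ch <- fi[.wis_cpp(pos[fi], w[fi], FALSE)]
        cw <- sum(w[ch])
        if (cw > bw) { bw <- cw; best <- ch }
      }
      if (length(ri)) {
        ch <- ri[.wis_cpp(pos[ri], w[ri], TRUE)]
        cw <- sum(w[ch])
        if (cw > bw) { bw <- cw; best <- ch }
      }
      if (bw < min_run) break
      kept_g[best] <- TRUE
      rem <- rem[!rem %in% best]
    }
    keep <- keep & kept_g
  }
  out <- anchors_subset(anchors, which(keep))
  attr(out, "dropped") <- which(!keep)
  out
}
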