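# Chaining of MUM anchors into locally collinear runs.
#
# A chain is a maximal run of anchors, in reference order, whose per-genome
# positions are strictly monotone (increasing on '+', decreasing on '-'),
# with consistent orientation per genome and every inter-anchor gap at most
# max_gap in every genome.  Breakpoint criteria: order inversion, strand
# flip, oversized gap, or a gap spanning a contig boundary.

#' Chain collinearity-filtered anchors into locally collinear runs
#'
#' Anchors overlapping on the reference are trimmed on their left side (the
#' trimmed prefix is covered by the previous anchor); anchors fully contained
#' in the previous reference interval are dropped.  Chains whose total
#' anchored length falls below \code{min_chain} are discarded.
#'
#' @param anchors filtered \code{mum_anchors}.
#' @param genomes the \code{\link{genome_set}}.
#' @param max_gap maximum allowed inter-anchor gap in any genome (bp).
#' @param min_chain minimum total anchored bp per chain (default 3x the
#'   anchor minimum length).
#' @return list of \code{anchor_chain} objects ordered by reference position.
#' @export
chain_anchors <- function(anchors, genomes, max_gap = 1000L,
                          min_chain = NULL) {
  min_chain <- min_chain %||% (3L * anchors$min_length)
  M <- length(anchors$length)
  if (M == 0L) return(list())
  len <- as.integer(anchors$length)
  pos <- anchors$pos
  fwd <- anchors$fwd
  G <- ncol(pos)

  # overlap trimming on the reference
  keep <- rep(TRUE, M)
  last <- 0L
  for (i in seq_len(M)) {
    if (last == 0L) { last <- i; next }
    o <- pos[last, 1L] + len[last] - pos[i, 1L]
    if (o >= len[i]) { keep[i] <- FALSE; next }
    if (o > 0L) {
      len[i] <- len[i] - o
      f <- fwd[i, ]
      pos[i, f] <- pos[i, f] + o
    }
    last <- i
  }
  idx <- which(keep)
  len <- len[idx]; pos <- pos[idx, , drop = FALSE]
  fwd <- fwd[idx, , drop = FALSE]
  M <- length(idx)
  if (M == 0L) return(list())

  bad <- rep(FALSE, M - 1L)
  if (M > 1L) {
    P1 <- pos[-M, , drop = FALSE]; P2 <- pos[-1L, , drop = FALSE]
    L1 <- len[-M]; L2 <- len[-1L]
    F1 <- fwd[-M, , drop = FALSE]; F2 <- fwd[-1L, , drop = FALSE]
    gapF <- P2 - (P1 + L1)
    gapR <- P1 - (P2 + L2)
    gap <- ifelse(F2, gapF, gapR)
    bad <- rowSums(F1 != F2) > 0L | rowSums(gap < 0L) > 0L |
      rowSums(gap > max_gap) > 0L
    # break chains whose gap would span a contig boundary or an N
    glist <- gs_genomes(genomes)
    for (g in seq_len(G)) {
      sp <- sentinel_positions(glist[[g]]$seq)
      if (!length(sp)) next
      lo <- ifelse(F2[, g], P1[, g] + L1[, g], P2[, g] + L2[, g])
      hi <- ifelse(F2[, g], P2[, g], P1[, g])
      hi <- pmax(hi, lo)
      bad <- bad | (findInterval(hi - 1L, sp) - findInterval(lo - 1L, sp)) > 0L
    }
  }

  grp <- cumsum(c(TRUE, bad))
  out <- lapply(split(seq_len(M), grp), function(ii) {
    structure(list(length = len[ii], pos = pos[ii, , drop = FALSE],
                   fwd = fwd[ii, , drop = FALSE],
                   orient = fwd[ii[1L], ],
                   roster = anchors$roster,
                   min_length = anchors$min_length),
              class = "anchor_chain")
  })
  names(out) <- NULL
  out[vapply(out, function(ch) sum(ch$length), integer(1)) >= min_chain]
}

#' @export
print.anchor_chain <- function(x, ...) {
  cat("<anchor_chain>", length(x$length), "anchors, reference",
      x$pos[1L, 1L], "-", x$pos[nrow(x$pos), 1L] +
        x$length[length(x$length)], "\n")
  invisible(x)
}

# per-genome gap interval (forward strand, 0-based half-open) between
# adjacent anchors i-1 and i of a chain
chain_gap <- function(chain, i) {
  o <- chain$orient
  L <- chain$length
  lo <- ifelse(o, chain$pos[i - 1L, ] + L[i - 1L], chain$pos[i, ] + L[i])
  hi <- ifelse(o, chain$pos[i, ], chain$pos[i - 1L, ])
  cbind(lo = lo, hi = hi)
}

#' Recursive MUM search inside oversized inter-anchor gaps
#'
#' For every inter-anchor gap whose span exceeds four times the previous
#' level's minimum length in any genome, MUM search is re-run restricted to
#' the gap's per-genome substrings (in alignment orientation) at the next
#' smaller minimum length; collinear hits are inserted into the chain.  The
#' default schedule uses two levels: the top-level minimum and 0.6x that.
#'
#' @param chain an \code{anchor_chain}.
#' @param genomes the \code{\link{genome_set}}.
#' @param level_min_lengths descending vector of per-level minimum MUM
#'   lengths; a single level disables recursion.
#' @param gap_cap gaps longer than this in any genome are left alone (they
#'   are split off later).
#' @return the augmented \code{anchor_chain}.
#' @export
recursive_anchor <- function(chain, genomes,
                             level_min_lengths = c(chain$min_length,
                                                   ceiling(chain$min_length *
                                                             0.6)),
                             gap_cap = 10000L) {
  if (length(level_min_lengths) < 2L) return(chain)
  seqs <- gs_seqs(genomes)
  G <- length(seqs)
  for (li in seq_along(level_min_lengths)[-1L]) {
    span_thresh <- 4L * level_min_lengths[li - 1L]
    M <- length(chain$length)
    if (M < 2L) break
    add_len <- integer(0)
    add_pos <- NULL
    for (i in 2:M) {
      gp <- chain_gap(chain, i)
      glen <- gp[, "hi"] - gp[, "lo"]
      if (max(glen) <= span_thresh || any(glen <= 0L) ||
          any(glen > gap_cap)) next
      gapstr <- vapply(seq_len(G), function(g) {
        s <- substr0(seqs[g], gp[g, "lo"], gp[g, "hi"])
        if (chain$orient[g]) s else revcomp(s)
      }, character(1))
      if (any(grepl("[!N]", gapstr))) next
      sub <- .find_mums_cpp(gapstr, as.integer(level_min_lengths[li]))
      if (!length(sub$length)) next
      ok <- rowSums(!sub$fwd) == 0L  # keep matches collinear with the chain
      if (!any(ok)) next
      o <- order(sub$pos[, 1L])
      o <- o[ok[o]]
      lastend <- rep(-1L, G)
      for (j in o) {
        p <- sub$pos[j, ]
        if (any(p < lastend)) next
        lastend <- p + sub$length[j]
        gpos <- ifelse(chain$orient, gp[, "lo"] + p,
                       gp[, "hi"] - p - sub$length[j])
        add_len <- c(add_len, sub$length[j])
        add_pos <- rbind(add_pos, gpos)
      }
    }
    if (length(add_len)) {
      len <- c(chain$length, add_len)
      pos <- rbind(chain$pos, add_pos)
      fwd <- rbind(chain$fwd,
                   matrix(chain$orient, nrow = length(add_len),
                          ncol = G, byrow = TRUE))
      o <- order(pos[, 1L])
      chain$length <- len[o]
      chain$pos <- pos[o, , drop = FALSE]
      chain$fwd <- fwd[o, , drop = FALSE]
      rownames(chain$pos) <- rownames(chain$fwd) <- NULL
    }
  }
  chain
}

# split a chain wherever any genome's inter-anchor gap exceeds the hard cap
split_large_gaps <- function(chain, gap_cap = 10000L) {
  M <- length(chain$length)
  if (M < 2L) return(list(chain))
  bad <- vapply(2:M, function(i) {
    gp <- chain_gap(chain, i)
    any(gp[, "hi"] - gp[, "lo"] > gap_cap)
  }, logical(1))
  if (!any(bad)) return(list(chain))
  grp <- cumsum(c(TRUE, bad))
  lapply(split(seq_len(M), grp), function(ii) {
    structure(list(length = chain$length[ii],
                   pos = chain$pos[ii, , drop = FALSE],
                   fwd = chain$fwd[ii, , drop = FALSE],
                   orient = chain$orient, roster = chain$roster,
                   min_length = chain$min_length),
              class = "anchor_chain")
  })
}
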