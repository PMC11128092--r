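# Reference-anchored per-query alignment maps.
#
# For every query genome the package computes, once, a global map assigning
# each query base either a reference position or "insertion".  The map is
# built from pairwise (reference, query) MUM chains whose inter-anchor gaps
# are closed by global Needleman-Wunsch alignment.  All multi-genome LCB
# rows are then read off these maps, so the base-to-reference-position
# assignment of a query is identical in every run that contains it --
# in particular, partitioned and nonpartitioned runs call SNP columns
# identically wherever both consider them core.

#' Compute reference-alignment maps for all query genomes
#'
#' @param genomes a \code{\link{genome_set}}.
#' @param min_length pairwise MUM minimum length.
#' @param max_gap maximum pairwise inter-anchor gap (bp) closed by dynamic
#'   programming; larger gaps break the pairwise chain.
#' @param scoring named vector with elements \code{match}, \code{mismatch},
#'   \code{gap} for the gap-closing aligner.
#' @param max_cells cap on the DP matrix size per gap; bigger gaps are left
#'   unaligned.
#' @return named list (by query genome id) of integer vectors, one entry per
#'   query base (0-based concatenated coordinates): the 0-based reference
#'   position the base is aligned to, or -1 for an unaligned/inserted base.
#' @export
reference_maps <- function(genomes, min_length = 15L, max_gap = 5000L,
                           scoring = c(match = 2, mismatch = -4, gap = -4),
                           max_cells = 2.5e7) {
  ref <- genomes$reference
  out <- lapply(genomes$queries, function(qry) {
    query_map(ref, qry, min_length, max_gap, scoring, max_cells)
  })
  names(out) <- vapply(genomes$queries, `[[`, character(1), "genome_id")
  out
}

query_map <- function(ref, qry, min_length, max_gap, scoring, max_cells) {
  mini <- genome_set(ref, list(qry))
  anch <- find_mums(mini, min_length)
  anch <- filter_spurious(anch)
  chains <- chain_anchors(anch, mini, max_gap = max_gap)
  map <- rep(-1L, qry$length)
  if (!length(chains)) return(map)
  # heaviest chains claim contested query bases first
  wts <- vapply(chains, function(ch) sum(ch$length), integer(1))
  refs <- qrys <- vector("list", 0L)
  meta <- vector("list", 0L)
  for (ch in chains[order(-wts)]) {
    len <- ch$length; pos <- ch$pos
    o <- ch$orient[2L]
    ax <- sequence(len, from = pos[, 2L])
    ar <- if (o) sequence(len, from = pos[, 1L]) else
      sequence(len, from = pos[, 1L] + len - 1L, by = -1L)
    free <- map[ax + 1L] == -1L
    map[ax[free] + 1L] <- ar[free]
    M <- length(len)
    if (M < 2L) next
    # per-gap substrings, vectorized over the chain
    rlo <- pos[-M, 1L] + len[-M]; rhi <- pos[-1L, 1L]
    if (o) { qlo <- pos[-M, 2L] + len[-M]; qhi <- pos[-1L, 2L] }
    else   { qlo <- pos[-1L, 2L] + len[-1L]; qhi <- pos[-M, 2L] }
    ok <- rhi > rlo & qhi > qlo & rhi - rlo <= max_gap &
      qhi - qlo <= max_gap
    if (!any(ok)) next
    rs <- substring(ref$seq, rlo[ok] + 1L, rhi[ok])
    qf <- substring(qry$seq, qlo[ok] + 1L, qhi[ok])
    if (!o) qf <- vapply(qf, revcomp, character(1), USE.NAMES = FALSE)
    clean <- !grepl("[!N]", rs) & !grepl("[!N]", qf)
    if (!any(clean)) next
    k <- length(refs)
    refs[[k + 1L]] <- rs[clean]
    qrys[[k + 1L]] <- qf[clean]
    meta[[k + 1L]] <- cbind(rlo[ok][clean], qlo[ok][clean], qhi[ok][clean],
                            as.integer(o))
  }
  refs <- unlist(refs)
  qrys <- unlist(qrys)
  meta_m <- do.call(rbind, meta)
  if (length(refs)) {
    maps <- .nw_map_many_cpp(refs, qrys, scoring[["match"]],
                             scoring[["mismatch"]], scoring[["gap"]],
                             max_cells)
    for (k in seq_along(maps)) {
      ml <- maps[[k]]
      hit <- which(ml >= 0L)
      if (!length(hit)) next
      rlo <- meta_m[k, 1L]; qlo <- meta_m[k, 2L]; qhi <- meta_m[k, 3L]
      o <- meta_m[k, 4L] == 1L
      x <- if (o) qlo + hit - 1L else qhi - hit
      free <- map[x + 1L] == -1L
      map[x[free] + 1L] <- rlo + ml[hit[free]]
    }
  }
  map
}
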