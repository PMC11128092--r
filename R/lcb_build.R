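# LCB construction.
#
# An anchor chain fixes, for every genome, an oriented interval and a set of
# exactly matching anchor columns.  The columns between anchors are read off
# the per-query reference-alignment maps: every query base either sits in
# the column of its assigned reference position or becomes part of an
# insertion block attached to the preceding reference position.  Insertions
# attached to the same reference position by different queries are merged
# with partial-order alignment, in roster order.

POA_SCORING <- c(match = 2, mismatch = -4, gap = -4)

#' Build one aligned LCB from an anchor chain
#'
#' The chain fixes the reference window and each genome's orientation; the
#' columns themselves are read off the per-query reference maps, so a
#' query's base-to-reference-position assignment does not depend on which
#' cohort it is aligned in.  Query bases the map leaves unassigned become
#' insertion blocks attached to the preceding reference position and are
#' merged across queries with POA.
#'
#' @param chain an \code{anchor_chain}.
#' @param genomes the \code{\link{genome_set}}.
#' @param maps per-query reference maps from \code{\link{reference_maps}}.
#' @param scoring POA scoring for insertion merging.
#' @param invmaps optional precomputed inverse maps (reference position ->
#'   query position); recomputed if NULL.
#' @param gap_cap edge pairs further than this many query bases from the
#'   rest of the block are discarded.
#' @return an \code{lcb}.
#' @export
build_lcb <- function(chain, genomes, maps, scoring = POA_SCORING,
                      invmaps = NULL, gap_cap = 10000L) {
  glist <- gs_genomes(genomes)
  roster <- chain$roster
  G <- length(roster)
  len <- chain$length
  pos <- chain$pos
  M <- length(len)
  a <- pos[1L, 1L]
  b <- pos[M, 1L] + len[M]
  width <- b - a
  invmaps <- invmaps %||% invert_maps(maps, glist[[1L]]$length)

  rowraw <- vector("list", G)
  rowraw[[1L]] <- charToRaw(substr0(glist[[1L]]$seq, a, b))
  starts <- ends <- integer(G)
  strands <- character(G)
  starts[1L] <- a; ends[1L] <- b; strands[1L] <- "+"
  ev_attach <- integer(0); ev_g <- integer(0); ev_str <- character(0)

  for (g in seq_len(G)[-1L]) {
    o <- chain$orient[g]
    xs_of_ref <- invmaps[[roster[g]]][(a + 1L):b]
    hasx <- !is.na(xs_of_ref)
    pr <- which(hasx) + a - 1L   # ref positions, ascending
    px <- xs_of_ref[hasx]        # the query base mapped to each
    if (length(px) >= 2L) {
      mono <- if (o) !is.unsorted(px, strictly = TRUE)
              else !is.unsorted(rev(px), strictly = TRUE)
      if (!mono) {
        ch <- .wis_cpp(px, rep(1, length(px)), !o)
        pr <- pr[ch]; px <- px[ch]
      }
      # discard stray edge pairs far from the body of the block
      repeat {
        k <- length(px)
        if (k >= 2L && abs(px[2L] - px[1L]) > gap_cap) {
          px <- px[-1L]; pr <- pr[-1L]
        } else if (k >= 2L && abs(px[k] - px[k - 1L]) > gap_cap) {
          px <- px[-k]; pr <- pr[-k]
        } else break
      }
    }
    strands[g] <- if (o) "+" else "-"
    if (!length(px)) {  # query absent over this window
      rowraw[[g]] <- rep(GAPBYTE, width)
      starts[g] <- ends[g] <- 0L
      next
    }
    c0 <- min(px); d0 <- max(px) + 1L
    starts[g] <- c0; ends[g] <- d0
    base <- charToRaw(substr0(glist[[g]]$seq, c0, d0))
    rr <- rep(GAPBYTE, width)
    rr[pr - a + 1L] <- if (o) base[px - c0 + 1L] else
      comp_raw(base[px - c0 + 1L])
    rowraw[[g]] <- rr
    # unassigned query bases between mapped neighbours become insertions
    matched <- logical(d0 - c0)
    matched[px - c0 + 1L] <- TRUE
    un <- which(!matched)
    if (length(un)) {
      sx <- sort(px)
      vr <- pr[order(px)]  # ref position per sorted query position
      pik <- findInterval(un + c0 - 1L, sx)
      att <- if (o) vr[pik] else vr[pmin(pik + 1L, length(sx))]
      ub <- base[un]
      if (!o) ub <- comp_raw(ub)
      runs <- split(seq_along(un),
                    cumsum(c(TRUE, diff(un) != 1L | diff(att) != 0L)))
      for (rn in runs) {
        ev_attach <- c(ev_attach, att[rn[1L]])
        ev_g <- c(ev_g, g)
        ev_str <- c(ev_str,
                    if (o) rawToChar(ub[rn]) else rawToChar(rev(ub[rn])))
      }
    }
  }

  rows <- splice_insertions(rowraw, a, width, ev_attach, ev_g, ev_str, G,
                            scoring)
  names(rows) <- roster
  names(starts) <- names(ends) <- names(strands) <- roster
  contig <- vapply(seq_len(G), function(g) {
    off <- glist[[g]]$offsets
    names(off)[findInterval(starts[g], off)]
  }, character(1))
  names(contig) <- roster
  new_lcb(rows, starts, ends, strands, contig)
}

# invert per-query maps: for each reference position, the query base (0-based
# position) assigned to it, or NA
invert_maps <- function(maps, ref_len) {
  lapply(maps, function(mp) {
    inv <- rep(NA_integer_, ref_len)
    hit <- which(mp >= 0L)
    inv[mp[hit] + 1L] <- hit - 1L
    inv
  })
}

# merge insertion events into the base rows; one POA per attachment site
splice_insertions <- function(rowraw, a, width, ev_attach, ev_g, ev_str, G,
                              scoring) {
  if (!length(ev_attach)) {
    return(vapply(rowraw, rawToChar, character(1)))
  }
  key <- paste(ev_g, ev_attach)
  if (anyDuplicated(key)) {  # coalesce multiple runs at one site
    agg <- vapply(split(ev_str, key), paste, character(1), collapse = "")
    first <- !duplicated(key)
    ev_str <- as.character(agg[key[first]])
    ev_g <- ev_g[first]; ev_attach <- ev_attach[first]
  }
  sites <- sort(unique(ev_attach))
  seqsets <- lapply(sites, function(s) {
    sel <- ev_attach == s
    g <- ev_g[sel]
    o <- order(g)
    setNames(ev_str[sel][o], g[o])
  })
  aligned <- .poa_align_many_cpp(lapply(seqsets, unname),
                                 scoring[["match"]], scoring[["mismatch"]],
                                 scoring[["gap"]])
  widths <- vapply(aligned, function(x) nchar(x[1L]), integer(1))
  cut <- sites - a + 1L
  vapply(seq_len(G), function(g) {
    segs <- list()
    prev <- 0L
    for (i in seq_along(sites)) {
      segs[[length(segs) + 1L]] <- rowraw[[g]][seq_len(cut[i] - prev) + prev]
      gi <- match(as.character(g), names(seqsets[[i]]))
      segs[[length(segs) + 1L]] <-
        if (is.na(gi)) rep(GAPBYTE, widths[i])
        else charToRaw(aligned[[i]][gi])
      prev <- cut[i]
    }
    if (prev < width)
      segs[[length(segs) + 1L]] <- rowraw[[g]][(prev + 1L):width]
    rawToChar(unlist(segs))
  }, character(1))
}

#' Align one cohort of genomes (single, nonpartitioned run)
#'
#' Runs the full anchoring pipeline on a genome set: MUM detection,
#' collinearity filtering, chaining, recursive re-anchoring of large gaps,
#' and LCB construction.
#'
#' @param genomes a \code{\link{genome_set}}.
#' @param maps reference maps (computed if NULL).
#' @param min_length minimum MUM length.
#' @param max_gap chaining gap limit (bp).
#' @param min_chain minimum anchored bp per chain.
#' @param levels recursive anchoring schedule (descending minimum lengths).
#' @param gap_cap hard cap on per-genome gaps; chains are split at larger
#'   gaps.
#' @return a \code{\link{core_alignment}}.
#' @export
align_cohort <- function(genomes, maps = NULL, min_length = 15L,
                         max_gap = 1000L, min_chain = 3L * min_length,
                         levels = c(min_length, ceiling(min_length * 0.6)),
                         gap_cap = 10000L) {
  maps <- maps %||% reference_maps(genomes, min_length = min_length)
  anch <- find_mums(genomes, min_length)
  anch <- filter_spurious(anch, genomes, min_run = min_chain)
  chains <- chain_anchors(anch, genomes, max_gap = max_gap,
                          min_chain = min_chain)
  chains <- lapply(chains, recursive_anchor, genomes = genomes,
                   level_min_lengths = levels, gap_cap = gap_cap)
  chains <- unlist(lapply(chains, split_large_gaps, gap_cap = gap_cap),
                   recursive = FALSE)
  invmaps <- invert_maps(maps, genomes$reference$length)
  lcbs <- lapply(chains, build_lcb, genomes = genomes, maps = maps,
                 invmaps = invmaps, gap_cap = gap_cap)
  core_alignment(genomes$roster, lcbs, ref_layout(genomes$reference))
}
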