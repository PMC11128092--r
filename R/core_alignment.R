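# Containers for aligned blocks.
#
# An LCB (locally collinear block) holds one gapped row per roster genome,
# all of equal length, in alignment orientation (reverse-strand rows are
# stored reverse-complemented so every row reads left to right along the
# reference).  Per-genome coordinates are 0-based half-open intervals on the
# forward strand of the concatenated genome; the strand flag preserves
# provenance.  A core_alignment is an ordered set of LCBs over a fixed
# roster (reference first) whose reference intervals are pairwise disjoint.

new_lcb <- function(rows, start, end, strand, contig) {
  ncols <- unique(nchar(rows))
  if (length(ncols) != 1L) stop("LCB rows have unequal lengths")
  structure(list(rows = rows, start = start, end = end, strand = strand,
                 contig = contig, ncol = ncols),
            class = "lcb")
}

#' @export
print.lcb <- function(x, ...) {
  cat("<lcb>", length(x$rows), "rows x", x$ncol, "columns, reference",
      x$start[1L], "-", x$end[1L], "\n")
  invisible(x)
}

#' Construct a core alignment
#'
#' @param roster character vector of genome ids, reference first.
#' @param lcbs list of LCBs, ordered by reference start, reference intervals
#'   pairwise disjoint.
#' @param ref_layout data frame describing the reference contig layout
#'   (columns contig_id, offset, length).
#' @return an object of class \code{core_alignment}.
#' @export
core_alignment <- function(roster, lcbs, ref_layout) {
  if (length(lcbs)) {
    rs <- vapply(lcbs, function(b) b$start[1L], integer(1))
    re <- vapply(lcbs, function(b) b$end[1L], integer(1))
    o <- order(rs)
    lcbs <- lcbs[o]
    rs <- rs[o]; re <- re[o]
    if (any(rs[-1L] < re[-length(re)]))
      stop("reference intervals of LCBs overlap")
    for (b in lcbs)
      if (!identical(names(b$rows), roster))
        stop("LCB roster mismatch")
  }
  structure(list(roster = roster, lcbs = lcbs, ref_layout = ref_layout),
            class = "core_alignment")
}

#' @export
print.core_alignment <- function(x, ...) {
  tot <- sum(vapply(x$lcbs, function(b) b$end[1L] - b$start[1L], integer(1)))
  cat("<core_alignment>", length(x$roster), "genomes,", length(x$lcbs),
      "LCB(s),", tot, "reference bp\n")
  invisible(x)
}

#' Reference intervals of a core alignment
#'
#' @param aln a \code{\link{core_alignment}}.
#' @return an \code{\link{interval_set}} of the per-LCB reference intervals
#'   (0-based half-open, concatenated reference coordinates).
#' @export
ref_intervals <- function(aln) {
  if (!length(aln$lcbs)) return(interval_set(integer(0), integer(0)))
  interval_set(vapply(aln$lcbs, function(b) b$start[1L], integer(1)),
               vapply(aln$lcbs, function(b) b$end[1L], integer(1)))
}

# ungapped sequence of one row (in alignment orientation)
lcb_ungap <- function(lcb, id) gsub("-", "", lcb$rows[[id]], fixed = TRUE)
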