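# Core-genome SNP extraction and summary statistics.

BASEBYTES <- charToRaw("ACGT")

#' Extract SNPs from a core alignment
#'
#' One record per alignment column where the reference is non-gap and at
#' least one query carries a different base.  A gap or N in a query is
#' recorded as missing (NA), never as an allele; columns whose only
#' deviations are gaps or Ns yield no record.
#'
#' @param aln a \code{\link{core_alignment}}.
#' @return data frame sorted by reference position: \code{contig_id},
#'   \code{pos} (0-based within contig), \code{gpos} (0-based concatenated),
#'   \code{ref}, then one character column per query genome.
#' @export
extract_snps <- function(aln) {
  roster <- aln$roster
  queries <- roster[-1L]
  recs <- lapply(aln$lcbs, function(b) {
    refraw <- charToRaw(b$rows[[1L]])
    mcol <- which(refraw != GAPBYTE)
    if (!length(mcol)) return(NULL)
    refm <- as.integer(refraw[mcol])
    qm <- vapply(queries,
                 function(q) as.integer(charToRaw(b$rows[[q]])[mcol]),
                 integer(length(mcol)))
    if (is.null(dim(qm))) qm <- matrix(qm, nrow = length(mcol))
    isbase <- matrix(qm %in% as.integer(BASEBYTES), nrow = nrow(qm))
    isdiff <- isbase & (qm != matrix(refm, nrow(qm), ncol(qm)))
    hit <- which(rowSums(isdiff) > 0L)
    if (!length(hit)) return(NULL)
    al <- matrix(NA_character_, length(hit), length(queries),
                 dimnames = list(NULL, queries))
    sub <- qm[hit, , drop = FALSE]
    subbase <- isbase[hit, , drop = FALSE]
    al[subbase] <- strsplit(rawToChar(as.raw(sub[subbase])), "")[[1L]]
    data.frame(gpos = b$start[1L] + hit - 1L,
               ref = strsplit(rawToChar(as.raw(refm[hit])), "")[[1L]],
               al, stringsAsFactors = FALSE, check.names = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    recs <- data.frame(gpos = integer(0), ref = character(0),
                       matrix(character(0), 0, length(queries),
                              dimnames = list(NULL, queries)),
                       stringsAsFactors = FALSE, check.names = FALSE)
  recs <- recs[order(recs$gpos), , drop = FALSE]
  loc <- layout_locate(aln$ref_layout, recs$gpos)
  out <- cbind(data.frame(contig_id = loc$contig_id, pos = loc$pos,
                          stringsAsFactors = FALSE), recs)
  rownames(out) <- NULL
  out
}

#' Weighted average reference divergence (\%)
#'
#' Per LCB, the average nucleotide identity (ANI) to the reference is the
#' mean over queries of matching columns over columns where both the
#' reference and the query have a base; N columns are excluded from both
#' numerator and denominator.  Each LCB is weighted by the total number of
#' nucleotides (non-gap characters, all rows) it contains; the statistic is
#' 100 * (1 - sum(w * ANI) / sum(w)).
#'
#' @param aln a \code{\link{core_alignment}} with at least one LCB.
#' @param weight_by \code{"nucleotides"} (default) or \code{"columns"}.
#' @return divergence percentage in [0, 100].
#' @export
weighted_reference_divergence <- function(aln,
                                          weight_by = c("nucleotides",
                                                        "columns")) {
  weight_by <- match.arg(weight_by)
  if (!length(aln$lcbs)) stop("divergence is undefined for an empty alignment")
  stats <- vapply(aln$lcbs, function(b) {
    refraw <- as.integer(charToRaw(b$rows[[1L]]))
    refok <- refraw %in% as.integer(BASEBYTES)
    ani <- vapply(b$rows[-1L], function(row) {
      q <- as.integer(charToRaw(row))
      comp <- refok & (q %in% as.integer(BASEBYTES))
      if (!any(comp)) return(NA_real_)
      sum(q[comp] == refraw[comp]) / sum(comp)
    }, numeric(1))
    w <- if (weight_by == "nucleotides")
      sum(vapply(b$rows, function(r) sum(charToRaw(r) != GAPBYTE),
                 integer(1)))
    else b$ncol
    c(ani = mean(ani, na.rm = TRUE), w = w)
  }, numeric(2))
  100 * (1 - sum(stats["ani", ] * stats["w", ]) / sum(stats["w", ]))
}

#' Average core length (bp per genome)
#'
#' Mean over roster genomes of the summed non-gap characters across all
#' LCBs: the average number of nucleotides each genome contributes to the
#' core alignment.
#'
#' @param aln a \code{\link{core_alignment}}.
#' @return average core length in bp (0 for an empty alignment).
#' @export
average_core_length <- function(aln) {
  if (!length(aln$lcbs)) return(0)
  per <- rowSums(vapply(aln$lcbs, function(b)
    vapply(b$rows, function(r) sum(charToRaw(r) != GAPBYTE), integer(1)),
    integer(length(aln$roster))))
  mean(per)
}

#' Remove LCBs containing large indels
#'
#' Drops every LCB in which any row contains a gap run strictly longer than
#' \code{max_indel} (large indels represent sequence absent from some input
#' genome, hence not core).
#'
#' @param aln a \code{\link{core_alignment}}.
#' @param max_indel maximum tolerated gap run (bp); the default removes
#'   LCBs with indels > 300 nucleotides.
#' @return the filtered alignment; the number of removed LCBs is recorded
#'   in attribute \code{"removed"}.
#' @export
filter_large_indel_lcbs <- function(aln, max_indel = 300L) {
  big <- vapply(aln$lcbs, function(b) {
    any(vapply(b$rows, function(r) {
      rl <- rle(charToRaw(r) == GAPBYTE)
      m <- rl$lengths[rl$values]
      if (length(m)) max(m) else 0L
    }, integer(1)) > max_indel)
  }, logical(1))
  out <- core_alignment(aln$roster, aln$lcbs[!big], aln$ref_layout)
  attr(out, "removed") <- sum(big)
  out
}

#' Core-genome summary statistics
#'
#' @param aln a \code{\link{core_alignment}}.
#' @return list with \code{weighted_ref_divergence} (percent),
#'   \code{avg_core_length} (bp) and \code{lcb_count}.
#' @export
core_stats <- function(aln) {
  list(weighted_ref_divergence = if (length(aln$lcbs))
         weighted_reference_divergence(aln) else NA_real_,
       avg_core_length = average_core_length(aln),
       lcb_count = length(aln$lcbs))
}
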