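# Partial-order alignment (POA) public surface.
#
# Sequences are aligned one after another against a growing DAG of bases
# (global, end-to-end), so the result depends on input order; the pipeline
# always presents sequences in roster order for determinism.  The default
# scoring is match +2, mismatch -4, gap -4 with a linear (non-affine) gap
# penalty; affine penalties are a configuration hook only.

#' Partial-order multiple alignment
#'
#' @param seqs named character vector of sequences (possibly empty strings,
#'   which become all-gap rows).
#' @param scoring named vector with \code{match}, \code{mismatch},
#'   \code{gap}.
#' @param affine unimplemented; anything but FALSE is an error.
#' @return named character vector of equal-length gapped rows, one per
#'   input, in input order; per-sequence alignment scores (the score of
#'   aligning each sequence against the graph built from its predecessors)
#'   in attribute \code{"scores"}.
#' @export
poa_align <- function(seqs, scoring = POA_SCORING, affine = FALSE) {
  if (!identical(affine, FALSE))
    stop("affine gap penalties are not implemented")
  if (!length(seqs)) stop("need at least one sequence")
  res <- .poa_align_cpp(unname(as.character(seqs)), scoring[["match"]],
                        scoring[["mismatch"]], scoring[["gap"]])
  rows <- res$rows
  names(rows) <- names(seqs)
  attr(rows, "scores") <- res$scores
  rows
}

#' Heaviest-path POA consensus
#'
#' Builds the POA graph of the input sequences and returns the source-to-sink
#' path maximizing total edge support, ties broken towards smaller node ids
#' (i.e. earlier-added sequence material).
#'
#' @inheritParams poa_align
#' @return consensus sequence (character scalar).
#' @export
poa_consensus <- function(seqs, scoring = POA_SCORING) {
  if (!length(seqs)) stop("need at least one sequence")
  as.character(.poa_consensus_cpp(unname(as.character(seqs)),
                                  scoring[["match"]], scoring[["mismatch"]],
                                  scoring[["gap"]]))
}
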