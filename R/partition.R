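# Divide-and-conquer partitioning: split the queries into groups of equal
# size sharing the reference, align each group, intersect the per-partition
# reference interval sets (R_i) into the final core intervals (R*), trim
# every partition alignment to R*, and stitch the trimmed alignments into a
# single core-genome alignment.

#' Interval set on reference coordinates
#'
#' @param begin,end integer vectors of 0-based half-open intervals.
#' @return an \code{interval_set}; intervals sorted, disjointness enforced.
#' @export
interval_set <- function(begin, end) {
  begin <- as.integer(begin); end <- as.integer(end)
  if (length(begin) != length(end)) stop("begin/end length mismatch")
  if (any(end <= begin)) stop("empty or inverted interval")
  o <- order(begin)
  begin <- begin[o]; end <- end[o]
  if (length(begin) > 1L && any(begin[-1L] < end[-length(end)]))
    stop("intervals overlap")
  structure(list(begin = begin, end = end), class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat("<interval_set>", length(x$begin), "interval(s),",
      sum(x$end - x$begin), "bp\n")
  invisible(x)
}

iset_to_iranges <- function(x) IRanges::IRanges(start = x$begin + 1L,
                                               end = x$end)
iranges_to_iset <- function(r) {
  r <- IRanges::reduce(r)
  interval_set(IRanges::start(r) - 1L, IRanges::end(r))
}

# total bases covered
iset_width <- function(x) sum(x$end - x$begin)

#' Intersect interval sets
#'
#' Exact set-theoretic intersection of one or more interval sets; zero-length
#' results are discarded.
#'
#' @param sets a list of \code{\link{interval_set}} objects (>= 1).
#' @return the intersection as an \code{interval_set}.
#' @export
intersect_interval_sets <- function(sets) {
  if (!length(sets)) stop("need at least one interval set")
  r <- Reduce(IRanges::intersect, lapply(sets, iset_to_iranges))
  if (length(r) == 0L) return(interval_set(integer(0), integer(0)))
  # IRanges normalizes away touching pieces; re-split the intersection at
  # every source-interval boundary so each result interval lies inside a
  # single interval of every input set (the trimming precondition)
  begin <- IRanges::start(r) - 1L
  end <- IRanges::end(r)
  bnd <- sort(unique(unlist(lapply(sets, function(s) c(s$begin, s$end)))))
  rb <- re <- vector("list", length(begin))
  for (i in seq_along(begin)) {
    cuts <- bnd[bnd > begin[i] & bnd < end[i]]
    rb[[i]] <- c(begin[i], cuts)
    re[[i]] <- c(cuts, end[i])
  }
  interval_set(unlist(rb), unlist(re))
}

#' Partition the query genomes into groups of equal size
#'
#' Queries are assigned contiguously in roster order to q = ceiling(n/p)
#' partitions whose sizes differ by at most one; the reference is shared by
#' every partition.
#'
#' @param genomes a \code{\link{genome_set}} with n queries.
#' @param p genomes per partition (1 <= p <= n); p = n disables partitioning.
#' @return a \code{partition_scheme}: list with \code{n}, \code{p}, \code{q}
#'   and \code{assignment} (partition index per query).
#' @export
make_partitions <- function(genomes, p) {
  n <- genomes$n
  if (p < 1L) stop("partition size p must be >= 1")
  p <- min(p, n)
  q <- as.integer(ceiling(n / p))
  base <- n %/% q
  extra <- n %% q
  sizes <- rep(base, q) + c(rep(1L, extra), rep(0L, q - extra))
  assignment <- rep(seq_len(q), times = sizes)
  structure(list(n = n, p = as.integer(p), q = q, sizes = sizes,
                 assignment = assignment),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("<partition_scheme>", x$n, "queries, p =", x$p, "-> q =", x$q,
      "partition(s) of sizes", paste(x$sizes, collapse = ","), "\n")
  invisible(x)
}

#' Trim a core alignment to a set of core intervals
#'
#' Each core interval must be contained in exactly one LCB's reference
#' interval.  The output has one LCB per core interval, keeping the columns
#' whose reference attachment position falls inside the interval: a match
#' column attaches to its own reference position, an insertion column to the
#' preceding reference position (so insertions at an interval's left
#' boundary are excluded).
#'
#' @param aln a \code{\link{core_alignment}}.
#' @param core a \code{\link{interval_set}} of core intervals.
#' @return the trimmed \code{\link{core_alignment}} with one LCB per core
#'   interval.
#' @export
trim_to_intervals <- function(aln, core) {
  if (!length(core$begin))
    return(core_alignment(aln$roster, list(), aln$ref_layout))
  starts <- vapply(aln$lcbs, function(b) b$start[1L], integer(1))
  ends <- vapply(aln$lcbs, function(b) b$end[1L], integer(1))
  src <- findInterval(core$begin, starts)
  bad <- src == 0L | core$end > ends[pmax(src, 1L)] |
    core$begin < starts[pmax(src, 1L)]
  if (any(bad))
    stop("core interval [", core$begin[which(bad)[1L]], ",",
         core$end[which(bad)[1L]], ") is not contained in any LCB")
  out <- vector("list", length(core$begin))
  cache_idx <- -1L
  cache <- NULL
  for (k in seq_along(core$begin)) {
    if (src[k] != cache_idx) {
      cache <- lcb_trim_cache(aln$lcbs[[src[k]]])
      cache_idx <- src[k]
    }
    out[[k]] <- lcb_trim(aln$lcbs[[src[k]]], cache, core$begin[k],
                         core$end[k])
  }
  core_alignment(aln$roster, out, aln$ref_layout)
}

# per-LCB precomputation reused across trims: column attachment positions
# and per-row non-gap prefix counts
lcb_trim_cache <- function(lcb) {
  a <- lcb$start[1L]
  refraw <- charToRaw(lcb$rows[[1L]])
  attach <- a - 1L + cumsum(refraw != GAPBYTE)
  ng <- lapply(lcb$rows, function(r) cumsum(charToRaw(r) != GAPBYTE))
  list(attach = attach, ng = ng)
}

lcb_trim <- function(lcb, cache, b2, e2) {
  if (b2 == lcb$start[1L] && e2 == lcb$end[1L]) return(lcb)
  keepcols <- which(cache$attach >= b2 & cache$attach < e2)
  c1 <- keepcols[1L]; c2 <- keepcols[length(keepcols)]
  rows <- vapply(lcb$rows, substr, character(1), c1, c2)
  G <- length(rows)
  start <- end <- integer(G)
  for (g in seq_len(G)) {
    ng <- cache$ng[[g]]
    c_left <- if (c1 > 1L) ng[c1 - 1L] else 0L
    c_right <- ng[length(ng)] - ng[c2]
    if (lcb$strand[g] == "+" || g == 1L) {
      start[g] <- lcb$start[g] + c_left
      end[g] <- lcb$end[g] - c_right
    } else {
      start[g] <- lcb$start[g] + c_right
      end[g] <- lcb$end[g] - c_left
    }
  }
  names(start) <- names(end) <- names(rows)
  new_lcb(rows, start, end, lcb$strand, lcb$contig)
}

#' Stitch trimmed partition alignments into one combined alignment
#'
#' All inputs must have identical reference interval lists (one LCB per core
#' interval) and reference rows that ungap to identical sequences.  Columns
#' anchored at the same reference position are merged across partitions;
#' where any partition carries insertion columns after a reference position,
#' the inserted query substrings from all partitions are re-aligned together
#' with POA and spliced in, with all-gap rows for queries without an
#' insertion there.
#'
#' @param trimmed list of trimmed \code{\link{core_alignment}}s, one per
#'   partition.
#' @param scheme the \code{partition_scheme} that produced them.
#' @param scoring POA scoring used for insertion merging.
#' @return the combined \code{\link{core_alignment}} over the full roster.
#' @export
stitch_partitions <- function(trimmed, scheme, scoring = POA_SCORING) {
  if (length(trimmed) == 1L) return(trimmed[[1L]])
  nlcb <- vapply(trimmed, function(a) length(a$lcbs), integer(1))
  if (length(unique(nlcb)) != 1L)
    stop("partitions have differing LCB counts")
  roster <- c(trimmed[[1L]]$roster[1L],
              unlist(lapply(trimmed, function(a) a$roster[-1L])))
  lcbs <- lapply(seq_len(nlcb[1L]), function(k) {
    stitch_block(lapply(trimmed, function(a) a$lcbs[[k]]), roster, scoring)
  })
  core_alignment(roster, lcbs, trimmed[[1L]]$ref_layout)
}

stitch_block <- function(blocks, roster, scoring) {
  refung <- vapply(blocks, lcb_ungap, character(1), 1L)
  if (length(unique(refung)) != 1L)
    stop("reference rows disagree between partitions at LCB starting ",
         blocks[[1L]]$start[1L])
  a <- blocks[[1L]]$start[1L]
  b <- blocks[[1L]]$end[1L]
  width <- b - a
  rowraw <- list()
  ev_attach <- integer(0); ev_g <- integer(0); ev_str <- character(0)
  start <- end <- integer(0)
  strand <- contig <- character(0)
  rowraw[[1L]] <- charToRaw(refung[1L])
  start[1L] <- a; end[1L] <- b; strand[1L] <- "+"
  contig[1L] <- blocks[[1L]]$contig[1L]
  gi <- 1L
  for (blk in blocks) {
    refraw <- charToRaw(blk$rows[[1L]])
    isref <- refraw != GAPBYTE
    attach <- a - 1L + cumsum(isref)
    for (g in seq_along(blk$rows)[-1L]) {
      gi <- gi + 1L
      rr <- charToRaw(blk$rows[[g]])
      rowraw[[gi]] <- rr[isref]
      start[gi] <- blk$start[g]; end[gi] <- blk$end[g]
      strand[gi] <- blk$strand[g]; contig[gi] <- blk$contig[g]
      ins <- which(!isref & rr != GAPBYTE)
      if (length(ins)) {
        at <- attach[ins]
        runs <- split(seq_along(ins),
                      cumsum(c(TRUE, diff(ins) != 1L | diff(at) != 0L)))
        for (rn in runs) {
          if (at[rn[1L]] < a) next  # boundary insertions were trimmed away
          ev_attach <- c(ev_attach, at[rn[1L]])
          ev_g <- c(ev_g, gi)
          ev_str <- c(ev_str, rawToChar(rr[ins[rn]]))
        }
      }
    }
  }
  rows <- splice_insertions(rowraw, a, width, ev_attach, ev_g, ev_str,
                            length(roster), scoring)
  names(rows) <- names(start) <- names(end) <- names(strand) <-
    names(contig) <- roster
  new_lcb(rows, start, end, strand, contig)
}

#' Run the partitioned core-genome alignment workflow
#'
#' Composes \code{\link{make_partitions}}, per-partition alignment,
#' reference-interval intersection, trimming and stitching.  Partitions are
#' independent work units: the result is identical regardless of the order
#' in which they are processed.  With p = n (a single partition) the output
#' is exactly the single-run pipeline's.
#'
#' @param genomes a \code{\link{genome_set}}.
#' @param p genomes per partition; default 50 when n > 100, else n.
#' @param maps precomputed \code{\link{reference_maps}} (computed if NULL);
#'   sharing maps across runs with different p saves the dominant cost.
#' @param ... passed to \code{\link{align_cohort}}.
#' @return a \code{\link{core_alignment}}; attributes \code{scheme},
#'   \code{partition_intervals} (the R_i) and \code{core_intervals} (R*)
#'   record the partition bookkeeping.
#' @export
run_partitioned <- function(genomes, p = NULL, maps = NULL, ...) {
  n <- genomes$n
  p <- p %||% (if (n > 100L) 50L else n)
  scheme <- make_partitions(genomes, p)
  maps <- maps %||% reference_maps(genomes,
                                   min_length = list(...)$min_length %||% 15L)
  if (scheme$q == 1L) {
    aln <- align_cohort(genomes, maps = maps, ...)
    attr(aln, "scheme") <- scheme
    attr(aln, "partition_intervals") <- list(ref_intervals(aln))
    attr(aln, "core_intervals") <- ref_intervals(aln)
    return(aln)
  }
  parts <- lapply(seq_len(scheme$q), function(i) {
    sub <- genome_set(genomes$reference,
                      genomes$queries[scheme$assignment == i])
    align_cohort(sub, maps = maps[sub$roster[-1L]], ...)
  })
  ri <- lapply(parts, ref_intervals)
  rstar <- intersect_interval_sets(ri)
  if (!length(rstar$begin)) {
    warning("empty core after interval intersection")
    aln <- core_alignment(genomes$roster, list(),
                          ref_layout(genomes$reference))
  } else {
    trimmed <- lapply(parts, trim_to_intervals, core = rstar)
    aln <- stitch_partitions(trimmed, scheme)
  }
  attr(aln, "scheme") <- scheme
  attr(aln, "partition_intervals") <- ri
  attr(aln, "core_intervals") <- rstar
  aln
}
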