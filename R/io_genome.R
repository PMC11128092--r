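#' Construct a genome from contig sequences
#'
#' A genome is an ordered set of contigs over the alphabet \{A,C,G,T,N\}.
#' Internally the contigs are concatenated with a sentinel character so that
#' exact-match search can treat the genome as a single string; matches can
#' never span the sentinel.  All internal coordinates are 0-based half-open
#' positions on this concatenated forward strand.
#'
#' @param genome_id short unique label for the genome.
#' @param contigs named character vector of uppercase contig sequences.
#' @return an object of class \code{genome} with fields \code{genome_id},
#'   \code{contigs}, \code{seq} (concatenated sequence), \code{offsets}
#'   (0-based start of each contig in \code{seq}) and \code{length}.
#' @export
genome <- function(genome_id, contigs) {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must have unique names")
  if (any(nchar(contigs) == 0L))
    stop("zero-length contig in genome '", genome_id, "': ",
         names(contigs)[nchar(contigs) == 0L][1L])
  contigs <- toupper(contigs)
  bad <- vapply(contigs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) stop("contig contains characters outside {A,C,G,T,N}")
  seq <- paste(contigs, collapse = SENTINEL)
  offsets <- cumsum(c(0L, head(nchar(contigs) + 1L, -1L)))
  names(offsets) <- names(contigs)
  structure(list(genome_id = genome_id, contigs = contigs, seq = seq,
                 offsets = offsets, total_length = sum(nchar(contigs)),
                 length = nchar(seq)),
            class = "genome")
}

#' Read a genome from a FASTA file
#'
#' Lowercase bases are normalized to uppercase; IUPAC ambiguity codes and any
#' other character outside \{A,C,G,T,N\} are mapped to N, with a warning
#' giving the number of substituted characters.
#'
#' @param path path to a FASTA file with at least one record.
#' @param genome_id label for the genome; defaults to the file base name.
#' @return a \code{\link{genome}}.
#' @export
read_genome <- function(path, genome_id = NULL) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("FASTA file has no records: ", path)
  ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate contig id in ", path, ": ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(recs))
  zero <- nchar(seqs) == 0L
  if (any(zero)) stop("zero-length record in ", path, ": ", ids[zero][1L])
  nbad <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (nbad > 0L) {
    warning(nbad, " non-ACGTN character(s) mapped to N in ", path)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  names(seqs) <- ids
  genome(genome_id %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                            basename(path)), seqs)
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$genome_id, "-", length(x$contigs), "contig(s),",
      x$total_length, "bp\n")
  invisible(x)
}

#' Assemble a genome set
#'
#' @param reference the reference \code{\link{genome}}.
#' @param queries list of query genomes (n >= 1).
#' @return an object of class \code{genome_set} with the roster ordered
#'   reference first.
#' @export
genome_set <- function(reference, queries) {
  if (length(queries) < 1L) stop("need at least one query genome")
  ids <- c(reference$genome_id, vapply(queries, `[[`, character(1),
                                       "genome_id"))
  if (anyDuplicated(ids)) stop("duplicate genome_id in genome set")
  structure(list(reference = reference, queries = queries, roster = ids,
                 n = length(queries)),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("<genome_set> reference", x$reference$genome_id, "+", x$n,
      "query genome(s)\n")
  invisible(x)
}

# all genomes of a set as a list, reference first
gs_genomes <- function(gs) c(list(gs$reference), gs$queries)

# concatenated sequences in roster order
gs_seqs <- function(gs) vapply(gs_genomes(gs), `[[`, character(1), "seq")

# reference contig layout (used for VCF output and XMFA round-trips)
ref_layout <- function(ref) {
  data.frame(contig_id = names(ref$contigs),
             offset = as.integer(ref$offsets),
             length = nchar(ref$contigs), row.names = NULL,
             stringsAsFactors = FALSE)
}

# map 0-based concatenated reference positions to (contig_id, local 0-based)
layout_locate <- function(layout, gpos) {
  i <- findInterval(gpos, layout$offset)
  data.frame(contig_id = layout$contig_id[i],
             pos = gpos - layout$offset[i], stringsAsFactors = FALSE)
}

# positions (0-based) of sentinel characters in a concatenated sequence
sentinel_positions <- function(seq) {
  r <- charToRaw(seq)
  which(r == charToRaw(SENTINEL) | r == charToRaw("N")) - 1L
}
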