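# XMFA input/output.
#
# XMFA ("extended multi-FASTA") represents a multiple genome alignment as a
# series of "="-terminated blocks, one per LCB.  There is no single upstream
# standard for the header fields, so this package writes a self-describing
# dialect and guarantees bit-exact round-trips of its own output:
#
#   #corealn-xmfa 1
#   #Roster <id> <id> ...            genome ids, reference first
#   #RefContig <contig_id> <offset> <length>   (one line per reference contig)
#   > <index>:<start>-<end> <strand> <genome_id>:<contig_id>
#   <sequence, wrapped at 80 columns>
#   =
#
# Coordinates are 1-based inclusive on the forward strand of the genome's
# concatenated sequence; an empty row (a genome absent over the interval) is
# written as start = end + 1.  Reverse-strand rows are stored
# reverse-complemented (alignment orientation); the strand column records
# the original orientation.

#' Write a core alignment as XMFA
#'
#' @param aln a \code{\link{core_alignment}}.
#' @param path output file path.
#' @param width column width for wrapped sequence lines.
#' @return \code{path}, invisibly.
#' @export
write_xmfa <- function(aln, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#corealn-xmfa 1",
               paste(c("#Roster", aln$roster), collapse = " ")), con)
  if (!is.null(aln$ref_layout))
    writeLines(sprintf("#RefContig %s %d %d", aln$ref_layout$contig_id,
                       aln$ref_layout$offset, aln$ref_layout$length), con)
  for (b in aln$lcbs) {
    for (i in seq_along(aln$roster)) {
      id <- aln$roster[i]
      writeLines(sprintf("> %d:%d-%d %s %s:%s", i, b$start[[id]] + 1L,
                         b$end[[id]], b$strand[[id]], id, b$contig[[id]]), con)
      row <- b$rows[[id]]
      starts <- seq.int(1L, max(nchar(row), 1L), by = width)
      writeLines(substring(row, starts, pmin(starts + width - 1L,
                                             nchar(row))), con)
    }
    writeLines("=", con)
  }
  invisible(path)
}

#' Read an XMFA alignment written by \code{\link{write_xmfa}}
#'
#' @param path path to an XMFA file in this package's dialect.
#' @return a \code{\link{core_alignment}}.
#' @export
read_xmfa <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  roster_line <- lines[grepl("^#Roster ", lines)]
  if (length(roster_line) != 1L) stop("XMFA: missing #Roster header")
  roster <- strsplit(roster_line, " ")[[1]][-1L]
  lay <- lines[grepl("^#RefContig ", lines)]
  ref_layout <- NULL
  if (length(lay)) {
    parts <- do.call(rbind, strsplit(lay, " "))
    ref_layout <- data.frame(contig_id = parts[, 2L],
                             offset = as.integer(parts[, 3L]),
                             length = as.integer(parts[, 4L]),
                             stringsAsFactors = FALSE)
  }
  body <- lines[!hdr & nzchar(lines)]
  lcbs <- list()
  cur_hdr <- character(0)
  cur_seq <- list()
  seq_buf <- character(0)
  flush_seq <- function() {
    if (length(cur_hdr)) cur_seq[[length(cur_seq) + 1L]] <<-
        paste(seq_buf, collapse = "")
    seq_buf <<- character(0)
  }
  for (ln in body) {
    if (startsWith(ln, ">")) {
      flush_seq()
      cur_hdr <- c(cur_hdr, ln)
    } else if (ln == "=") {
      flush_seq()
      lcbs[[length(lcbs) + 1L]] <- parse_xmfa_block(cur_hdr, cur_seq, roster,
                                                    length(lcbs) + 1L)
      cur_hdr <- character(0)
      cur_seq <- list()
    } else {
      seq_buf <- c(seq_buf, ln)
    }
  }
  core_alignment(roster, lcbs, ref_layout)
}

parse_xmfa_block <- function(hdrs, seqs, roster, block_idx) {
  if (length(hdrs) != length(roster))
    stop("XMFA block ", block_idx, ": expected ", length(roster),
         " rows, found ", length(hdrs))
  m <- regmatches(hdrs, regexec(
    "^> (\\d+):(\\d+)-(-?\\d+) ([+-]) ([^:]+):(.+)$", hdrs))
  rows <- start <- end <- strand <- contig <- NULL
  rows <- character(length(roster))
  start <- end <- integer(length(roster))
  strand <- contig <- character(length(roster))
  for (i in seq_along(hdrs)) {
    p <- m[[i]]
    if (length(p) != 7L) stop("XMFA block ", block_idx, ": bad header: ",
                              hdrs[i])
    idx <- as.integer(p[2L])
    rows[idx] <- seqs[[i]]
    start[idx] <- as.integer(p[3L]) - 1L
    end[idx] <- as.integer(p[4L])
    strand[idx] <- p[5L]
    contig[idx] <- p[7L]
  }
  names(rows) <- names(start) <- names(end) <- names(strand) <-
    names(contig) <- roster
  ng <- vapply(rows, function(r) sum(charToRaw(r) != GAPBYTE), integer(1))
  if (any(ng != end - start))
    stop("XMFA block ", block_idx, ": non-gap count does not match the ",
         "coordinate span for row ", roster[which(ng != end - start)[1L]])
  if (length(unique(nchar(rows))) != 1L)
    stop("XMFA block ", block_idx, ": ragged rows")
  new_lcb(rows, start, end, strand, contig)
}
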