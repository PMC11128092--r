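# Minimal VCF 4.2 output for core-genome SNPs (GT fields only) and a parser
# for the same dialect, used for round-tripping the pipeline's own output.

#' Write SNP records as VCF 4.2
#'
#' One sample column per non-reference genome; genotype (GT) fields only.
#' Multi-allelic sites emit comma-separated ALT alleles in order of first
#' appearance across the query columns; a query whose state is missing (gap
#' or N in the alignment) gets genotype ".".
#'
#' @param snps SNP data frame from \code{\link{extract_snps}}: columns
#'   \code{contig_id}, \code{pos} (0-based), \code{ref}, then one allele
#'   column per query genome.
#' @param roster genome ids, reference first; sample columns follow this
#'   order (reference excluded).
#' @param path output file path.
#' @param ref_layout optional reference contig layout for ##contig headers.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(snps, roster, path, ref_layout = NULL) {
  samples <- setdiff(roster, roster[1L])
  if (nrow(snps)) {
    o <- order(match(snps$contig_id, unique(snps$contig_id)), snps$pos)
    if (any(o != seq_len(nrow(snps))))
      stop("SNP records must be sorted by reference contig then position")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=corealn",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  if (!is.null(ref_layout))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ref_layout$contig_id,
                       ref_layout$length), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  if (nrow(snps)) {
    amat <- as.matrix(snps[, samples, drop = FALSE])
    lines <- vapply(seq_len(nrow(snps)), function(i) {
      al <- amat[i, ]
      alts <- unique(al[!is.na(al) & al != snps$ref[i]])
      gt <- ifelse(is.na(al), ".",
                   ifelse(al == snps$ref[i], "0",
                          match(al, alts)))
      paste(c(snps$contig_id[i], snps$pos[i] + 1L, ".", snps$ref[i],
              paste(alts, collapse = ","), ".", "PASS", ".", "GT", gt),
            collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a VCF written by \code{\link{write_vcf}}
#'
#' @param path path to a VCF 4.2 file with GT-only genotype fields.
#' @return a SNP data frame with columns \code{contig_id}, \code{pos}
#'   (0-based), \code{ref} and one allele column per sample (NA = missing).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  meta <- grepl("^##", lines)
  hdr <- lines[grepl("^#CHROM", lines)]
  if (length(hdr) != 1L) stop("VCF: missing #CHROM header line")
  cols <- strsplit(hdr, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!meta & !grepl("^#", lines)]
  body <- body[nzchar(body)]
  out <- data.frame(contig_id = character(0), pos = integer(0),
                    ref = character(0), stringsAsFactors = FALSE)
  for (s in samples) out[[s]] <- character(0)
  if (!length(body)) return(out)
  f <- strsplit(body, "\t")
  rows <- lapply(f, function(p) {
    alleles <- c(p[4L], strsplit(p[5L], ",")[[1]])
    gts <- p[-(1:9)]
    idx <- suppressWarnings(as.integer(gts))
    al <- ifelse(is.na(idx), NA_character_, alleles[idx + 1L])
    c(list(contig_id = p[1L], pos = as.integer(p[2L]) - 1L, ref = p[4L]),
      as.list(setNames(al, samples)))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}
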