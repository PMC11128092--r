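# Internal low-level sequence helpers.  Sequences are plain uppercase
# character strings over {A,C,G,T,N}; multi-contig genomes are concatenated
# with the sentinel '!', which can never take part in a match.

SENTINEL <- "!"
GAPBYTE <- charToRaw("-")

.comp_tab <- {
  tab <- as.raw(0:255)
  from <- charToRaw("ACGTN!")
  to <- charToRaw("TGCAN!")
  tab[as.integer(from) + 1L] <- to
  tab
}

# reverse complement of a plain character string
revcomp <- function(x) {
  r <- charToRaw(x)
  rawToChar(rev(.comp_tab[as.integer(r) + 1L]))
}

# complement (no reversal) of a raw vector
comp_raw <- function(r) .comp_tab[as.integer(r) + 1L]

# 0-based half-open substring of a plain string
substr0 <- function(x, start0, end0) {
  if (end0 <= start0) return("")
  substr(x, start0 + 1L, end0)
}

# number of non-gap bytes in a raw vector
nongap <- function(r) sum(r != GAPBYTE)

`%||%` <- function(a, b) if (is.null(a)) b else a
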