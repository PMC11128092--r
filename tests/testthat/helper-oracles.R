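# Independent oracles and fixture generators, built in code at test time.

rc <- function(x) corealn:::revcomp(x)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# mutated clones of a common ancestor: guarantees shared substrings so that
# MUM sets are non-trivial
random_genome_strings <- function(n_genomes, len, subst = 0.03) {
  anc <- strsplit(random_dna(len), "")[[1]]
  vapply(seq_len(n_genomes), function(g) {
    s <- anc
    hits <- which(runif(len) < subst)
    if (length(hits))
      s[hits] <- sample(c("A", "C", "G", "T"), length(hits), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
}

string_genome_set <- function(seqs) {
  gens <- lapply(seq_along(seqs), function(i)
    genome(sprintf("g%02d", i), setNames(seqs[i], "c1")))
  genome_set(gens[[1L]], gens[-1L])
}

# Brute-force MUM oracle: enumerates all reference substrings per length,
# counts occurrences in every genome over both strands via k-mer tables, and
# applies uniqueness and maximality literally.
oracle_mums <- function(seqs, min_len) {
  G <- length(seqs)
  rcs <- vapply(seqs, rc, character(1), USE.NAMES = FALSE)
  L1 <- nchar(seqs[1L])
  pres <- uniq <- list()
  for (l in min_len:L1) {
    ns <- L1 - l + 1L
    if (ns < 1L) break
    subs <- substring(seqs[1L], 1:ns, l:L1)
    p <- u <- rep(TRUE, ns)
    for (g in seq_len(G)) {
      cnt <- rep(0L, ns)
      for (txt in c(seqs[g], rcs[g])) {
        ng <- nchar(txt) - l + 1L
        if (ng < 1L) next
        tb <- table(substring(txt, 1:ng, l:nchar(txt)))
        hitn <- as.integer(tb[subs])
        cnt <- cnt + ifelse(is.na(hitn), 0L, hitn)
      }
      p <- p & cnt >= 1L
      u <- u & cnt == 1L
    }
    pres[[l]] <- p
    uniq[[l]] <- u
    if (!any(p)) break
  }
  get_pres <- function(l, i) {
    l <= length(pres) && !is.null(pres[[l]]) && i <= length(pres[[l]]) &&
      pres[[l]][i]
  }
  out <- list()
  for (i in seq_len(L1 - min_len + 1L)) {
    if (!get_pres(min_len, i)) next
    lstar <- min_len
    while (get_pres(lstar + 1L, i)) lstar <- lstar + 1L
    if (!uniq[[lstar]][i]) next
    if (i > 1L && get_pres(lstar + 1L, i - 1L)) next  # left-extensible
    s <- substr(seqs[1L], i, i + lstar - 1L)
    pos <- integer(G); fwd <- logical(G)
    for (g in seq_len(G)) {
      hit <- regexpr(s, seqs[g], fixed = TRUE)
      if (hit > 0L) { pos[g] <- hit - 1L; fwd[g] <- TRUE }
      else {
        hit <- regexpr(s, rcs[g], fixed = TRUE)
        pos[g] <- nchar(seqs[g]) - (hit - 1L) - lstar
        fwd[g] <- FALSE
      }
    }
    out[[length(out) + 1L]] <- list(len = lstar, pos = pos, fwd = fwd)
  }
  list(length = vapply(out, `[[`, integer(1), "len"),
       pos = do.call(rbind, c(lapply(out, `[[`, "pos"), list(matrix(0L, 0,
                                                                    G)))),
       fwd = do.call(rbind, c(lapply(out, `[[`, "fwd"),
                              list(matrix(TRUE, 0, G)))))
}

# quadratic global-alignment DP oracle (score only, linear gap penalty)
nw_score_oracle <- function(a, b, match = 2, mismatch = -4, gap = -4) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  prev <- gap * (0:m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- gap * i
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(prev[j] + if (av[i] == bv[j]) match else mismatch,
                         prev[j + 1L] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1L]
}

# random valid core_alignment for round-trip and stats tests
random_alignment <- function(n_genomes = 4L, n_lcbs = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  roster <- sprintf("g%02d", seq_len(n_genomes))
  refpos <- 0L
  lcbs <- lapply(seq_len(n_lcbs), function(k) {
    ncol <- sample(20:60, 1L)
    rows <- vapply(seq_len(n_genomes), function(g) {
      r <- sample(c("A", "C", "G", "T", "-"), ncol, replace = TRUE,
                  prob = c(.23, .23, .23, .23, .08))
      paste(r, collapse = "")
    }, character(1))
    # reference must carry at least one base
    if (!grepl("[ACGT]", rows[1L]))
      rows[1L] <- paste0("A", substr(rows[1L], 2L, ncol))
    names(rows) <- roster
    ng <- vapply(rows, function(r) sum(charToRaw(r) != charToRaw("-")),
                 integer(1))
    start <- c(refpos, sample.int(1000L, n_genomes - 1L))
    names(start) <- roster
    end <- start + ng
    refpos <<- end[1L] + sample.int(10L, 1L)
    strand <- c("+", sample(c("+", "-"), n_genomes - 1L, replace = TRUE))
    names(strand) <- roster
    contig <- setNames(rep("c1", n_genomes), roster)
    corealn:::new_lcb(rows, start, end, strand, contig)
  })
  layout <- data.frame(contig_id = "c1", offset = 0L,
                       length = refpos + 100L, stringsAsFactors = FALSE)
  core_alignment(roster, lcbs, layout)
}

# strip attributes that legitimately differ (run bookkeeping, row names)
aln_equal <- function(a, b) {
  attributes(a) <- attributes(a)[c("names", "class")]
  attributes(b) <- attributes(b)[c("names", "class")]
  rownames(a$ref_layout) <- rownames(b$ref_layout) <- NULL
  isTRUE(all.equal(a, b, check.attributes = TRUE))
}

# shared heavyweight fixtures, built once per test run
.fixtures <- new.env()

fixture_sim <- function(key, ...) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- evolve(sim_config(...))
  .fixtures[[key]]
}
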