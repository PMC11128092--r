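# MUM detection and spurious-anchor filtering.

test_that("find_mums handles identity, disjoint, and reverse-duplicate cases", {
  # two identical genomes whose k-mers are distinct: one full-length anchor
  s <- "ACGTACGGTCCATTGA"
  gs <- string_genome_set(c(s, s))
  a <- find_mums(gs, 8L)
  expect_equal(length(a$length), 1L)
  expect_equal(a$length[1L], nchar(s))
  expect_equal(unname(a$pos[1L, ]), c(0L, 0L))
  expect_true(all(a$fwd))

  # disjoint alphabets on both strands: no shared substring at all
  gs2 <- string_genome_set(c(strrep("A", 20L), strrep("C", 20L)))
  expect_equal(length(find_mums(gs2, 8L)$length), 0L)

  # an inverted duplicate destroys uniqueness: the shared 10-mer appears
  # once forward and once reverse-complemented in the first genome
  core <- "ACGGTTCAAG"
  g1 <- paste0(core, "CCCCCCCC", rc(core))
  g2 <- paste0("TTTTTTTT", core)
  expect_equal(length(find_mums(string_genome_set(c(g1, g2)), 10L)$length),
               0L)
})

test_that("query matches on the reverse strand are reported with '-' and forward coordinates", {
  s <- "ACGTACGGTCCATTGA"
  gs <- string_genome_set(c(s, rc(s)))
  a <- find_mums(gs, 8L)
  expect_equal(length(a$length), 1L)
  expect_equal(a$length[1L], nchar(s))
  expect_true(a$fwd[1L, 1L])
  expect_false(a$fwd[1L, 2L])
  expect_equal(unname(a$pos[1L, ]), c(0L, 0L))
})

test_that("find_mums validates its inputs", {
  gs <- string_genome_set(c("ACGTACGT", "ACGTACGT"))
  expect_error(find_mums(gs, 7L), ">= 8")
  expect_error(genome_set(gs$reference, list()), "at least one query")
})

test_that("find_mums agrees with the brute-force substring oracle", {
  set.seed(99)
  for (rep in 1:12) {
    G <- sample(3:6, 1L)
    len <- sample(50:300, 1L)
    seqs <- random_genome_strings(G, len)
    got <- corealn:::.find_mums_cpp(seqs, 10L)
    want <- oracle_mums(seqs, 10L)
    expect_equal(got$length, want$length, info = paste("rep", rep))
    expect_equal(unname(got$pos), unname(want$pos), info = paste("rep", rep))
    expect_equal(unname(got$fwd), unname(want$fwd), info = paste("rep", rep))
  }
})

test_that("every returned anchor verifies by direct string comparison", {
  set.seed(7)
  seqs <- random_genome_strings(4L, 200L)
  a <- corealn:::.find_mums_cpp(seqs, 10L)
  for (i in seq_along(a$length)) {
    subs <- vapply(seq_along(seqs), function(g) {
      s <- substr(seqs[g], a$pos[i, g] + 1L, a$pos[i, g] + a$length[i])
      if (a$fwd[i, g]) s else rc(s)
    }, character(1))
    expect_equal(length(unique(subs)), 1L)
    # exactly one occurrence per genome over both strands
    for (g in seq_along(seqs)) {
      both <- paste0(seqs[g], "!", rc(seqs[g]))
      expect_equal(lengths(regmatches(both, gregexpr(subs[1L], both,
                                                     fixed = TRUE))), 1L)
    }
  }
})

test_that("raising min_length never adds an anchor", {
  set.seed(13)
  seqs <- random_genome_strings(4L, 250L)
  lo <- corealn:::.find_mums_cpp(seqs, 9L)
  hi <- corealn:::.find_mums_cpp(seqs, 14L)
  keylo <- paste(lo$pos[, 1L], lo$length)
  keyhi <- paste(hi$pos[, 1L], hi$length)
  expect_true(all(keyhi %in% keylo))
  expect_true(all(hi$length >= 14L))
})

test_that("filter_spurious keeps collinear anchors and drops a run-breaking anchor", {
  s <- "ACGTACGGTCCATTGA"
  gs <- string_genome_set(c(s, s))
  a <- find_mums(gs, 8L)
  # already collinear: a no-op (run threshold below the anchor weight)
  expect_equal(filter_spurious(a, min_run = 10L)$length, a$length)

  # construct an anchor set by hand: a long collinear run plus one short
  # anchor whose query position jumps far out of order
  fake <- structure(list(
    length = c(100L, 15L, 100L, 100L),
    pos = cbind(c(0L, 150L, 300L, 450L), c(0L, 5000L, 300L, 450L)),
    fwd = matrix(TRUE, 4, 2),
    roster = c("r", "q"), min_length = 15L), class = "mum_anchors")
  filt <- filter_spurious(fake)
  expect_equal(filt$length, c(100L, 100L, 100L))
  expect_equal(attr(filt, "dropped"), 2L)

  empty <- corealn:::anchors_subset(fake, integer(0))
  expect_equal(length(filter_spurious(empty)$length), 0L)
})

test_that("filter_spurious preserves heavy inverted blocks", {
  fake <- structure(list(
    length = c(100L, 80L, 100L),
    pos = cbind(c(0L, 150L, 300L), c(0L, 170L, 300L)),
    fwd = cbind(c(TRUE, TRUE, TRUE), c(TRUE, FALSE, TRUE)),
    roster = c("r", "q"), min_length = 15L), class = "mum_anchors")
  filt <- filter_spurious(fake)
  expect_equal(length(filt$length), 3L)  # the '-' block outweighs min_run
})
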