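# Anchor chaining, recursive re-anchoring, and LCB construction.

fake_anchors <- function(len, pos, fwd, roster = c("r", "q1", "q2")) {
  structure(list(length = len, pos = pos, fwd = fwd, roster = roster,
                 min_length = 15L), class = "mum_anchors")
}

test_that("collinear anchors chain together; an inverted anchor splits the run", {
  gs <- string_genome_set(random_genome_strings(3L, 4000L, subst = 0))
  len <- rep(50L, 5L)
  pos <- cbind(seq(0L, 2000L, by = 500L), seq(0L, 2000L, by = 500L),
               seq(0L, 2000L, by = 500L))
  fwd <- matrix(TRUE, 5L, 3L)
  ch <- chain_anchors(fake_anchors(len, pos, fwd), gs, max_gap = 1000L)
  expect_equal(length(ch), 1L)
  expect_equal(length(ch[[1L]]$length), 5L)

  fwd2 <- fwd; fwd2[3L, 3L] <- FALSE  # strand flip in query 2
  ch2 <- chain_anchors(fake_anchors(len, pos, fwd2), gs, max_gap = 1000L)
  expect_equal(vapply(ch2, function(c) length(c$length), integer(1)),
               c(2L, 1L, 2L))
  # the singleton is dropped when min_chain exceeds its length
  ch3 <- chain_anchors(fake_anchors(len, pos, fwd2), gs, max_gap = 1000L,
                       min_chain = 60L)
  expect_equal(length(ch3), 2L)

  expect_equal(length(chain_anchors(fake_anchors(integer(0),
                                                 matrix(0L, 0, 3),
                                                 matrix(TRUE, 0, 3)), gs)),
               0L)
})

test_that("oversized gaps and out-of-order query positions break chains", {
  gs <- string_genome_set(random_genome_strings(3L, 9000L, subst = 0))
  len <- rep(50L, 3L)
  pos <- cbind(c(0L, 500L, 5000L), c(0L, 500L, 5000L), c(0L, 500L, 5000L))
  ch <- chain_anchors(fake_anchors(len, pos, matrix(TRUE, 3, 3)), gs,
                      max_gap = 1000L)
  expect_equal(vapply(ch, function(c) length(c$length), integer(1)),
               c(2L, 1L))

  pos2 <- cbind(c(0L, 500L, 1000L), c(0L, 500L, 1000L), c(0L, 1000L, 500L))
  ch2 <- chain_anchors(fake_anchors(len, pos2, matrix(TRUE, 3, 3)), gs,
                       max_gap = 1000L)
  # order violation in query 2 between anchors 2 and 3
  expect_equal(vapply(ch2, function(c) length(c$length), integer(1)),
               c(2L, 1L))
})

test_that("recursive anchoring finds a unique seed inside a large gap and is a no-op otherwise", {
  set.seed(5)
  left <- random_dna(60)
  right <- random_dna(60)
  mid_shared <- random_dna(10)
  gaps <- vapply(1:3, function(i)
    paste0(random_dna(40), mid_shared, random_dna(40)), character(1))
  seqs <- paste0(left, gaps, right)
  gs <- string_genome_set(seqs)
  a <- find_mums(gs, 15L)
  chains <- chain_anchors(a, gs, max_gap = 1000L)
  expect_equal(length(chains), 1L)
  n0 <- length(chains[[1L]]$length)
  aug <- recursive_anchor(chains[[1L]], gs, level_min_lengths = c(15L, 10L))
  expect_gt(length(aug$length), n0)
  # the inserted anchor covers the shared 10-mer
  new_idx <- which(aug$length == 10L)
  expect_true(any(vapply(new_idx, function(i)
    substr(seqs[1L], aug$pos[i, 1L] + 1L,
           aug$pos[i, 1L] + 10L) == mid_shared, logical(1))))
  # single-level schedule: no recursion
  expect_equal(length(recursive_anchor(chains[[1L]], gs,
                                       level_min_lengths = 15L)$length), n0)
  # all gaps below the span threshold: unchanged
  small <- recursive_anchor(aug, gs, level_min_lengths = c(10L, 9L))
  expect_equal(length(small$length), length(aug$length))
})

test_that("build_lcb reproduces genome substrings and places insertion columns", {
  # identical gap sequences: gapless LCB equal to the concatenated region
  set.seed(31)
  s <- random_dna(300)
  gs <- string_genome_set(c(s, s, s))
  maps <- reference_maps(gs)
  aln <- align_cohort(gs, maps = maps)
  expect_equal(length(aln$lcbs), 1L)
  b <- aln$lcbs[[1L]]
  expect_false(grepl("-", b$rows[[1L]], fixed = TRUE))
  expect_equal(unname(b$rows[[1L]]),
               substr(s, b$start[[1L]] + 1L, b$end[[1L]]))

  # one query carries an insertion: a single gap column in the other rows
  ins <- paste0(substr(s, 1, 150), "GG", substr(s, 151, 300))
  gs2 <- string_genome_set(c(s, ins, s))
  aln2 <- align_cohort(gs2, maps = reference_maps(gs2))
  b2 <- aln2$lcbs[[1L]]
  expect_equal(b2$ncol, (b2$end[[1L]] - b2$start[[1L]]) + 2L)
  expect_equal(vapply(c("g01", "g03"), function(id)
    lengths(regmatches(b2$rows[[id]], gregexpr("--", b2$rows[[id]]))),
    integer(1), USE.NAMES = FALSE), c(1L, 1L))
})

test_that("LCB rows ungap to exact genome substrings on simulated data (strand-aware)", {
  sim <- fixture_sim("n6", n_genomes = 6L, root_length = 20000L,
                     target_divergence = 0.01, inversion_rate = 2,
                     seed = 42L)
  aln <- align_cohort(sim$genomes)
  glist <- corealn:::gs_genomes(sim$genomes)
  names(glist) <- sim$genomes$roster
  strands <- character(0)
  for (b in aln$lcbs) for (id in aln$roster) {
    ung <- corealn:::lcb_ungap(b, id)
    sub <- corealn:::substr0(glist[[id]]$seq, b$start[[id]], b$end[[id]])
    if (b$strand[[id]] == "-") sub <- rc(sub)
    expect_identical(ung, sub)
    strands <- c(strands, b$strand[[id]])
  }
  expect_true(any(strands == "-"))  # inversions actually exercised
  # reference intervals disjoint and sorted
  iv <- ref_intervals(aln)
  expect_true(all(diff(iv$begin) > 0))
  expect_true(all(iv$begin[-1L] >= iv$end[-length(iv$end)]))
})
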