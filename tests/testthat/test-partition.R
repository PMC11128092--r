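# Partition scheme, interval intersection, trimming, stitching.

test_that("make_partitions balances contiguous groups", {
  gs100 <- structure(list(n = 100L), class = "genome_set")
  s <- make_partitions(gs100, 50L)
  expect_equal(s$q, 2L)
  expect_equal(s$sizes, c(50L, 50L))

  gs101 <- structure(list(n = 101L), class = "genome_set")
  s2 <- make_partitions(gs101, 50L)
  expect_equal(s2$q, 3L)
  expect_equal(s2$sizes, c(34L, 34L, 33L))
  expect_equal(s2$assignment, rep(1:3, times = s2$sizes))

  s3 <- make_partitions(gs100, 100L)
  expect_equal(s3$q, 1L)
  expect_error(make_partitions(gs100, 0L), ">= 1")
})

test_that("interval intersection matches examples and a membership oracle", {
  one <- interval_set(c(0L, 20L), c(10L, 30L))
  expect_equal(intersect_interval_sets(list(one)), one)
  expect_equal(corealn:::iset_width(intersect_interval_sets(
    list(interval_set(0L, 10L), interval_set(10L, 20L)))), 0L)
  got <- intersect_interval_sets(list(one, interval_set(5L, 25L)))
  expect_equal(got$begin, c(5L, 20L))
  expect_equal(got$end, c(10L, 25L))

  # membership oracle on random sets over positions 0..500
  set.seed(41)
  member <- function(is) {
    v <- rep(FALSE, 501L)
    for (k in seq_along(is$begin))
      if (is$end[k] > is$begin[k])
        v[(is$begin[k] + 1L):is$end[k]] <- TRUE
    v
  }
  rand_set <- function() {
    b <- sort(sample(0:480, sample(1:8, 1L)))
    e <- pmin(b + sample(1:40, length(b), replace = TRUE), 500L)
    keep <- c(TRUE, b[-1L] >= cummax(e[-length(e)])[seq_len(length(b) - 1L)])
    # rebuild a valid disjoint set greedily
    bb <- ee <- integer(0)
    last <- -1L
    for (i in seq_along(b)) {
      if (b[i] >= last && e[i] > b[i]) { bb <- c(bb, b[i]); ee <- c(ee, e[i])
        last <- e[i] }
    }
    interval_set(bb, ee)
  }
  for (rep in 1:25) {
    sets <- lapply(seq_len(sample(2:4, 1L)), function(i) rand_set())
    got <- intersect_interval_sets(sets)
    want <- Reduce(`&`, lapply(sets, member))
    expect_equal(member(got), want, info = paste("rep", rep))
  }
})

test_that("trimming to the alignment's own intervals is the identity", {
  sim <- fixture_sim("n6", n_genomes = 6L, root_length = 20000L,
                     target_divergence = 0.01, inversion_rate = 2,
                     seed = 42L)
  aln <- align_cohort(sim$genomes)
  expect_true(aln_equal(trim_to_intervals(aln, ref_intervals(aln)), aln))
})

test_that("trimming slices gapless blocks and keeps interior insertion columns", {
  roster <- c("r", "q")
  ref <- "ACGTACGTAC"
  rows <- setNames(c(ref, "ACGTACGTAC"), roster)
  b <- corealn:::new_lcb(rows, setNames(c(0L, 0L), roster),
                         setNames(c(10L, 10L), roster),
                         setNames(c("+", "+"), roster),
                         setNames(c("c1", "c1"), roster))
  lay <- data.frame(contig_id = "c1", offset = 0L, length = 50L)
  aln <- core_alignment(roster, list(b), lay)
  tr <- trim_to_intervals(aln, interval_set(3L, 7L))
  expect_equal(tr$lcbs[[1L]]$ncol, 4L)
  expect_equal(unname(tr$lcbs[[1L]]$rows[[1L]]), substr(ref, 4L, 7L))
  expect_equal(unname(tr$lcbs[[1L]]$start), c(3L, 3L))

  # insertion column between reference positions 4 and 5 (0-based), i.e.
  # attached to interior position 4: kept when trimming to [3, 7)
  rows2 <- setNames(c("ACGTA-CGTAC", "ACGTAGCGTAC"), roster)
  b2 <- corealn:::new_lcb(rows2, setNames(c(0L, 0L), roster),
                          setNames(c(10L, 11L), roster),
                          setNames(c("+", "+"), roster),
                          setNames(c("c1", "c1"), roster))
  aln2 <- core_alignment(roster, list(b2), lay)
  tr2 <- trim_to_intervals(aln2, interval_set(3L, 7L))
  expect_equal(tr2$lcbs[[1L]]$ncol, 5L)
  expect_equal(unname(tr2$lcbs[[1L]]$rows[[1L]]), "TA-CG")
  expect_equal(unname(tr2$lcbs[[1L]]$rows[[2L]]), "TAGCG")
  # the same insertion (attached to position 4) is excluded when it falls
  # at the left boundary of the trimming interval
  tr3 <- trim_to_intervals(aln2, interval_set(5L, 9L))
  expect_equal(tr3$lcbs[[1L]]$ncol, 4L)
  expect_equal(unname(tr3$lcbs[[1L]]$rows[[2L]]), "CGTA")
  # intervals not contained in any LCB violate the contract
  expect_error(trim_to_intervals(aln2, interval_set(3L, 12L)),
               "not contained")
})

test_that("stitching merges match columns and POA-aligns insertions across partitions", {
  lay <- data.frame(contig_id = "c1", offset = 0L, length = 50L)
  mk <- function(qid, qrow, qlen) {
    roster <- c("r", qid)
    rows <- setNames(c("ACGTACGT--AC", qrow), roster)
    rows[1L] <- substr(rows[1L], 1L, nchar(qrow))
    corealn:::new_lcb(rows, setNames(c(0L, 0L), roster),
                      setNames(c(10L, qlen), roster),
                      setNames(c("+", "+"), roster),
                      setNames(c("c1", "c1"), roster))
  }
  # partition A: query a1 has insertion "GG" after reference position 7;
  # partition B: query b1 has "G" there
  ba <- mk("a1", "ACGTACGTGGAC", 12L)
  bb0 <- corealn:::new_lcb(
    setNames(c("ACGTACGT-AC", "ACGTACGTGAC"), c("r", "b1")),
    setNames(c(0L, 0L), c("r", "b1")), setNames(c(10L, 11L), c("r", "b1")),
    setNames(c("+", "+"), c("r", "b1")),
    setNames(c("c1", "c1"), c("r", "b1")))
  pa <- core_alignment(c("r", "a1"), list(ba), lay)
  pb <- core_alignment(c("r", "b1"), list(bb0), lay)
  scheme <- structure(list(n = 2L, p = 1L, q = 2L, sizes = c(1L, 1L),
                           assignment = 1:2), class = "partition_scheme")
  st <- stitch_partitions(list(pa, pb), scheme)
  expect_equal(st$roster, c("r", "a1", "b1"))
  b <- st$lcbs[[1L]]
  expect_equal(b$ncol, 12L)
  expect_equal(unname(b$rows[["r"]]), "ACGTACGT--AC")
  expect_equal(unname(b$rows[["a1"]]), "ACGTACGTGGAC")
  expect_true(unname(b$rows[["b1"]]) %in% c("ACGTACGTG-AC", "ACGTACGT-GAC"))
  expect_equal(unname(gsub("-", "", b$rows[["b1"]])), "ACGTACGTGAC")

  # q = 1 returns the input unchanged
  expect_true(aln_equal(stitch_partitions(list(pa),
                                          make_partitions(structure(list(
                                            n = 1L), class = "genome_set"),
                                            1L)), pa))
})

test_that("partitioned and nonpartitioned runs are consistent on simulated data", {
  sim <- fixture_sim("n12c5", n_genomes = 12L, root_length = 30000L,
                     target_divergence = 0.01, seed = 7L)
  gs <- sim$genomes
  maps <- reference_maps(gs)
  alnN <- run_partitioned(gs, p = gs$n, maps = maps)
  aln4 <- run_partitioned(gs, p = 4L, maps = maps)

  # p = n equals the single-run pipeline exactly
  expect_true(aln_equal(alnN, align_cohort(gs, maps = maps)))

  # subset property: R* within every partition's interval set
  ri <- attr(aln4, "partition_intervals")
  rstar <- attr(aln4, "core_intervals")
  member <- function(is, n) {
    v <- rep(FALSE, n)
    for (k in seq_along(is$begin)) v[(is$begin[k] + 1L):is$end[k]] <- TRUE
    v
  }
  n <- gs$reference$length
  ms <- member(rstar, n)
  for (i in seq_along(ri))
    expect_true(all(!ms | member(ri[[i]], n)))

  # SNP concordance inside the shared core
  s4 <- extract_snps(aln4)
  sN <- extract_snps(alnN)
  both <- member(ref_intervals(alnN), n) & ms
  in4 <- both[s4$gpos + 1L]
  inN <- both[sN$gpos + 1L]
  expect_equal(`rownames<-`(s4[in4, ], NULL), `rownames<-`(sN[inN, ], NULL))
})

test_that("repeated runs and permuted partition processing give byte-identical XMFA", {
  sim <- fixture_sim("n12c5", n_genomes = 12L, root_length = 30000L,
                     target_divergence = 0.01, seed = 7L)
  gs <- sim$genomes
  maps <- reference_maps(gs)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_xmfa(run_partitioned(gs, p = 4L, maps = maps), f1)
  write_xmfa(run_partitioned(gs, p = 4L, maps = maps), f2)
  expect_identical(readLines(f1), readLines(f2))

  # partitions aligned in reverse order, then merged in scheme order
  scheme <- make_partitions(gs, 4L)
  parts <- lapply(rev(seq_len(scheme$q)), function(i) {
    sub <- genome_set(gs$reference, gs$queries[scheme$assignment == i])
    align_cohort(sub, maps = maps[sub$roster[-1L]])
  })[scheme$q:1L]
  rstar <- intersect_interval_sets(lapply(parts, ref_intervals))
  st <- stitch_partitions(lapply(parts, trim_to_intervals, core = rstar),
                          scheme)
  f3 <- withr::local_tempfile()
  write_xmfa(st, f3)
  expect_identical(readLines(f1), readLines(f3))
})
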