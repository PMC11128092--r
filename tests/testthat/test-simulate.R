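# Synthetic genome evolution and ground truth bookkeeping.

test_that("sample_tree is deterministic and scaled to the target divergence", {
  t1 <- sample_tree(8L, seed = 4L, target_divergence = 0.03)
  t2 <- sample_tree(8L, seed = 4L, target_divergence = 0.03)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  for (seed in 1:5) {
    tr <- sample_tree(10L, seed = seed, target_divergence = 0.02)
    depths <- ape::node.depth.edgelength(tr)[1:10]
    expect_equal(mean(depths), 0.02, tolerance = 1e-12)
  }
  t3 <- sample_tree(2L, seed = 1L, target_divergence = 0.05)
  expect_equal(ape::Ntip(t3), 2L)
  expect_equal(mean(ape::node.depth.edgelength(t3)[1:2]), 0.05)
})

test_that("the null model (all rates zero) reproduces the root everywhere", {
  cfg <- sim_config(n_genomes = 4L, root_length = 5000L,
                    target_divergence = 0, indel_rate = 0,
                    inversion_rate = 0, translocation_rate = 0,
                    loss_rate = 0, hgt_rate = 0, seed = 11L)
  sim <- evolve(cfg)
  seqs <- vapply(corealn:::gs_genomes(sim$genomes), `[[`, character(1),
                 "seq")
  expect_equal(length(unique(seqs)), 1L)
  expect_equal(sim$truth$true_core$begin, 0L)
  expect_equal(sim$truth$true_core$end, 5000L)
})

test_that("evolution is deterministic under a fixed seed", {
  cfg <- sim_config(n_genomes = 5L, root_length = 5000L, seed = 13L)
  s1 <- evolve(cfg)
  s2 <- evolve(cfg)
  expect_identical(vapply(corealn:::gs_genomes(s1$genomes), `[[`,
                          character(1), "seq"),
                   vapply(corealn:::gs_genomes(s2$genomes), `[[`,
                          character(1), "seq"))
  expect_equal(s1$truth$true_core, s2$truth$true_core)
})

test_that("coordinate maps carry every surviving base without drift", {
  # substitutions (effectively) off: every mapped base must equal the root
  # base, or its complement on inverted segments, across indels and
  # rearrangements.  Event clocks are driven relative to the substitution
  # rate, so a tiny divergence with large relative rates keeps events on.
  cfg <- sim_config(n_genomes = 6L, root_length = 20000L,
                    target_divergence = 1e-9, indel_rate = 1e7,
                    mean_indel_length = 4, inversion_rate = 2,
                    translocation_rate = 2, loss_rate = 2, hgt_rate = 2,
                    seed = 17L)
  sim <- evolve(cfg, keep_maps = TRUE)
  root_seq <- sim$truth$root_seq
  comp <- c(4L, 3L, 2L, 1L)
  glist <- corealn:::gs_genomes(sim$genomes)
  ids <- vapply(glist, `[[`, character(1), "genome_id")
  base_of <- function(g) match(strsplit(g$seq, "")[[1L]],
                               c("A", "C", "G", "T"))
  n_events <- sum(sim$truth$event_log$type != "substitution")
  expect_gt(n_events, 10L)
  for (i in seq_along(glist)) {
    m <- sim$truth$maps[[match(ids[i], sprintf("g%03d", 1:6))]]
    b <- base_of(glist[[i]])
    mapped <- m != 0L
    fwd <- m > 0L
    expect_true(all(b[mapped & fwd] == root_seq[m[mapped & fwd]]))
    inv <- mapped & !fwd
    expect_true(all(b[inv] == comp[root_seq[-m[inv]]]))
    # no root position is carried twice
    expect_false(anyDuplicated(abs(m[mapped])) > 0L)
  }
})

test_that("positions lost on any lineage are excluded from the true core", {
  seq <- seq_len(1000L)
  st <- corealn:::apply_indels(seq, seq, ip = 100L, il = 50L, isdel = TRUE)
  expect_equal(length(st$seq), 950L)
  expect_false(any(st$map %in% 100:149))
  expect_true(all(diff(st$map) %in% c(1L, 51L)))  # one jump over [100,150)
})

test_that("observed core SNP divergence matches the Jukes-Cantor expectation", {
  cfg <- sim_config(n_genomes = 12L, root_length = 100000L,
                    target_divergence = 0.01, seed = 7L)
  sim <- evolve(cfg, keep_maps = TRUE)
  # column alignment of true-core root positions across leaves
  tc <- sim$truth$true_core
  refmap <- sim$truth$maps[[1L]]
  # core root positions: those reached from reference core intervals
  ref_core_pos <- unlist(Map(seq, tc$begin + 1L, tc$end))
  core_root <- abs(refmap[ref_core_pos])
  glist <- corealn:::gs_genomes(sim$genomes)
  cols <- vapply(seq_along(glist), function(i) {
    m <- sim$truth$maps[[i]]
    b <- strsplit(glist[[i]]$seq, "")[[1L]]
    o <- order(abs(m))
    sel <- o[abs(m)[o] %in% core_root]
    bb <- b[sel]
    flip <- m[sel] < 0L
    bb[flip] <- chartr("ACGT", "TGCA", bb[flip])
    bb[order(abs(m)[sel])]
    }, character(length(core_root)))
  D <- ape::cophenetic.phylo(sim$truth$true_tree)
  ids <- vapply(glist, `[[`, character(1), "genome_id")
  obs <- exp_ <- numeric(0)
  for (i in 1:11) for (j in (i + 1):12) {
    obs <- c(obs, mean(cols[, i] != cols[, j]))
    exp_ <- c(exp_, 0.75 * (1 - exp(-4 / 3 * D[ids[i], ids[j]])))
  }
  ratio <- mean(obs) / mean(exp_)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("score_core_recovery computes base-level precision and recall", {
  truth <- interval_set(c(0L, 100L), c(50L, 150L))
  expect_equal(score_core_recovery(truth, truth),
               c(precision = 1, recall = 1))
  half <- interval_set(0L, 50L)
  expect_equal(score_core_recovery(half, truth),
               c(precision = 1, recall = 0.5))
  expect_equal(score_core_recovery(interval_set(200L, 250L), truth),
               c(precision = 0, recall = 0))
  expect_error(score_core_recovery(half, interval_set(integer(0),
                                                      integer(0))),
               "empty truth")
})
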