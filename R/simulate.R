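# Synthetic genome evolution with ground truth.
#
# Genomes are evolved along a random coalescent tree scaled to a target
# average root-to-tip divergence.  Substitutions follow a Jukes-Cantor
# kernel with gamma-distributed site rates; small indels, inversions,
# translocations, segment loss and HGT-like segment insertion are applied
# per branch.  Every base carries a signed root-coordinate label, so the
# true core (root positions surviving in every leaf, expressed in reference
# coordinates) is exact.

#' Simulation configuration
#'
#' Event rates: \code{indel_rate} is expressed per site relative to the
#' substitution rate (0.05 means one indel event per twenty substitutions);
#' the genome-level rates (\code{inversion_rate}, \code{translocation_rate},
#' \code{loss_rate}, \code{hgt_rate}) are expected event counts per
#' root-to-tip lineage.  Segment lengths are geometric with the given means.
#'
#' @param n_genomes number of leaf genomes (>= 2).
#' @param root_length root genome length in bp (>= 1000).
#' @param target_divergence expected substitutions per site from root to a
#'   leaf tip (0.01 = 1\%).
#' @param indel_rate small-indel rate relative to the substitution rate.
#' @param mean_indel_length mean small-indel length (bp, geometric).
#' @param inversion_rate,translocation_rate,loss_rate,hgt_rate expected
#'   events per lineage.
#' @param mean_segment_length mean length of genome-level event segments.
#' @param rate_variability gamma shape for site-rate variation (0 = uniform
#'   rates).
#' @param seed RNG seed.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_genomes = 12L, root_length = 500000L,
                       target_divergence = 0.01, indel_rate = 0.05,
                       mean_indel_length = 3, inversion_rate = 0.3,
                       translocation_rate = 0.2, loss_rate = 0.3,
                       mean_segment_length = 500, hgt_rate = 0.3,
                       rate_variability = 1, seed = 1L) {
  stopifnot(n_genomes >= 2L, root_length >= 1000L, target_divergence >= 0,
            indel_rate >= 0, inversion_rate >= 0, translocation_rate >= 0,
            loss_rate >= 0, hgt_rate >= 0, rate_variability >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Sample a species tree
#'
#' Random coalescent topology with branch lengths rescaled so that the mean
#' root-to-tip path length equals \code{target_divergence} exactly.
#'
#' @param n number of leaves (>= 2).
#' @param seed RNG seed (NULL = use the current RNG state).
#' @param target_divergence mean root-to-tip path length after scaling.
#' @return a rooted \code{phylo} tree with tip labels \code{g001, g002, ...}
#' @export
sample_tree <- function(n, seed = NULL, target_divergence = 0.01) {
  if (n < 2L) stop("need at least 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rcoal(n)
  tr$tip.label <- sprintf("g%03d", seq_len(n))  # label tips by index
  depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
  tr$edge.length <- tr$edge.length * target_divergence / mean(depths)
  tr
}

#' Evolve a genome set along a species tree
#'
#' @param config a \code{\link{sim_config}}.
#' @param keep_maps keep each leaf's signed root-coordinate map in the truth
#'   object (memory-heavy; used by bookkeeping tests).
#' @return list with \code{genomes} (a \code{\link{genome_set}}, first leaf
#'   as reference) and \code{truth} (class \code{sim_truth}: \code{true_tree},
#'   \code{true_core} as an \code{\link{interval_set}} on reference
#'   coordinates, \code{event_log}, and optionally \code{maps}).
#' @export
evolve <- function(config, keep_maps = FALSE) {
  set.seed(config$seed)
  n <- config$n_genomes
  L0 <- config$root_length
  tree <- sample_tree(n, seed = NULL,
                      target_divergence = config$target_divergence)
  site_rate <- if (config$rate_variability > 0)
    rgamma(L0, shape = config$rate_variability,
           rate = config$rate_variability) else rep(1, L0)
  root_seq <- sample.int(4L, L0, replace = TRUE)
  root_map <- seq_len(L0)

  ntip <- n
  root <- ntip + 1L
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  edge_len <- setNames(tree$edge.length,
                       paste(tree$edge[, 1L], tree$edge[, 2L]))
  leaves <- vector("list", ntip)
  log_env <- new.env()
  log_env$rows <- list()
  note <- function(branch, type, len, start = NA_integer_) {
    log_env$rows[[length(log_env$rows) + 1L]] <-
      data.frame(branch = branch, type = type, length = len,
                 start = start, stringsAsFactors = FALSE)
  }

  walk <- function(node, seq, map) {
    if (node <= ntip) { leaves[[node]] <<- list(seq = seq, map = map); return() }
    for (child in children[[as.character(node)]]) {
      b <- edge_len[[paste(node, child)]]
      st <- evolve_branch(seq, map, b, config, site_rate,
                          paste(node, child), note)
      walk(child, st$seq, st$map)
    }
  }
  walk(root, root_seq, root_map)

  # truth: root positions surviving in every leaf, in reference coordinates
  alive <- integer(L0)
  for (lf in leaves) {
    m <- abs(lf$map)
    m <- m[m > 0L]
    alive[m] <- alive[m] + 1L
  }
  core_root <- alive == ntip
  refmap <- abs(leaves[[1L]]$map)
  ref_core <- refmap > 0L & core_root[pmax(refmap, 1L)]
  rl <- rle(ref_core)
  ends <- cumsum(rl$lengths)
  begins <- ends - rl$lengths
  true_core <- interval_set(begins[rl$values], ends[rl$values])

  ids <- sprintf("g%03d", seq_len(ntip))
  gens <- lapply(seq_len(ntip), function(i)
    genome(ids[i], setNames(rawToChar(as.raw(c(65L, 67L, 71L, 84L)
                                             [leaves[[i]]$seq])), "chr")))
  gs <- genome_set(gens[[1L]], gens[-1L])
  ev <- if (length(log_env$rows)) do.call(rbind, log_env$rows)
        else data.frame(branch = character(0), type = character(0),
                        length = numeric(0), start = integer(0),
                        stringsAsFactors = FALSE)
  truth <- structure(list(true_tree = tree, true_core = true_core,
                          event_log = ev,
                          maps = if (keep_maps) lapply(leaves, `[[`, "map"),
                          root_seq = if (keep_maps) root_seq,
                          root_length = L0),
                     class = "sim_truth")
  list(genomes = gs, truth = truth)
}

# one branch: substitutions, small indels, then genome-level events
evolve_branch <- function(seq, map, b, config, site_rate, branch, note) {
  L <- length(seq)
  rate <- ifelse(map == 0L, 1, site_rate[pmax(abs(map), 1L)])
  psub <- 0.75 * (1 - exp(-4 / 3 * b * rate))
  hits <- which(runif(L) < psub)
  if (length(hits)) {
    seq[hits] <- ((seq[hits] - 1L +
                     sample.int(3L, length(hits), replace = TRUE)) %% 4L) + 1L
    note(branch, "substitution", length(hits))
  }

  n_indel <- rpois(1L, config$indel_rate * b * L)
  if (n_indel > 0L) {
    ip <- sample.int(L, n_indel)
    il <- 1L + stats::rgeom(n_indel, 1 / config$mean_indel_length)
    isdel <- runif(n_indel) < 0.5
    st <- apply_indels(seq, map, ip, il, isdel)
    seq <- st$seq; map <- st$map
    note(branch, "indel", sum(il), ip[1L])
  }

  for (type in c("inversion", "translocation", "loss", "hgt")) {
    rate_ev <- config[[paste0(type, "_rate")]]
    k <- rpois(1L, rate_ev * b / max(config$target_divergence, 1e-9))
    for (i in seq_len(k)) {
      L <- length(seq)
      len <- min(1L + stats::rgeom(1L, 1 / config$mean_segment_length),
                 max(L %/% 2L, 1L))
      p <- sample.int(max(L - len, 1L), 1L)
      idx <- p:(p + len - 1L)
      if (type == "inversion") {
        seq[idx] <- 5L - rev(seq[idx])
        map[idx] <- -rev(map[idx])
      } else if (type == "translocation") {
        rest_seq <- seq[-idx]; rest_map <- map[-idx]
        q <- sample.int(length(rest_seq) + 1L, 1L) - 1L
        seq <- append(rest_seq, seq[idx], after = q)
        map <- append(rest_map, map[idx], after = q)
      } else if (type == "loss") {
        seq <- seq[-idx]; map <- map[-idx]
      } else {  # hgt: novel segment insertion
        q <- sample.int(L + 1L, 1L) - 1L
        seq <- append(seq, sample.int(4L, len, replace = TRUE), after = q)
        map <- append(map, rep(0L, len), after = q)
      }
      note(branch, type, len, p)
    }
  }
  list(seq = seq, map = map)
}

# batch-apply small indels (positions/lengths drawn on the incoming
# coordinates; overlapping deletions simply merge)
apply_indels <- function(seq, map, ip, il, isdel) {
  L <- length(seq)
  keep <- rep(TRUE, L)
  di <- which(isdel)
  for (j in di) keep[ip[j]:min(ip[j] + il[j] - 1L, L)] <- FALSE
  ii <- which(!isdel)
  if (length(ii)) {
    o <- order(ip[ii])
    ins_pos <- ip[ii][o]           # insert after this original position
    ins_len <- il[ii][o]
    kidx <- which(keep)
    grp <- findInterval(kidx - 0.5, ins_pos)  # insertions before each base
    kept_pieces <- split(kidx, factor(grp, levels = 0:length(ins_pos)))
    pieces_seq <- pieces_map <- vector("list", 2L * length(ins_pos) + 1L)
    for (j in seq_along(ins_pos)) {
      seg <- kept_pieces[[j]]
      pieces_seq[[2L * j - 1L]] <- seq[seg]
      pieces_map[[2L * j - 1L]] <- map[seg]
      pieces_seq[[2L * j]] <- sample.int(4L, ins_len[j], replace = TRUE)
      pieces_map[[2L * j]] <- rep(0L, ins_len[j])
    }
    seg <- kept_pieces[[length(kept_pieces)]]
    pieces_seq[[length(pieces_seq)]] <- seq[seg]
    pieces_map[[length(pieces_map)]] <- map[seg]
    seq <- unlist(pieces_seq); map <- unlist(pieces_map)
  } else {
    seq <- seq[keep]; map <- map[keep]
  }
  list(seq = seq, map = map)
}

#' Base-level precision and recall of predicted core intervals
#'
#' @param predicted an \code{\link{interval_set}} on reference coordinates.
#' @param truth a \code{sim_truth} (or an \code{interval_set}).
#' @return named numeric vector \code{c(precision, recall)}.
#' @export
score_core_recovery <- function(predicted, truth) {
  tc <- if (inherits(truth, "sim_truth")) truth$true_core else truth
  if (!length(tc$begin)) stop("empty truth core")
  pr <- iset_to_iranges(predicted)
  tr <- iset_to_iranges(tc)
  inter <- sum(IRanges::width(IRanges::intersect(pr, tr)))
  pw <- sum(IRanges::width(pr))
  c(precision = if (pw == 0) 0 else inter / pw,
    recall = inter / sum(IRanges::width(tr)))
}
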