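#' Search configuration
#'
#' @param pop_size population size (number of candidate SNP combinations
#'   kept alive); typical range 50-200.
#' @param max_gen number of candidate combinations generated and
#'   evaluated; one candidate per loop pass.
#' @param order maximum interaction order `mo`, or `-1` to estimate it
#'   from the sample sizes with [estimate_max_order()].
#' @param n_groups number of discussion groups the population is
#'   clustered into.
#' @param gen_probs probabilities of the three generation methods, in the
#'   order idea fusion / inspiration sparking / free association; must
#'   sum to 1.
#' @param sig_threshold G-test p-value threshold below which a pruned
#'   interaction is reported; `NULL` (default) resolves at run time to
#'   `0.05 / choose(N, 2)`, a Bonferroni bound over SNP pairs.
#' @param seed integer seed; all randomness in a run flows from it.
#' @param dof degrees-of-freedom rule for [g_test()].
#' @param verbose print progress (generation, best K2, pool size).
#' @return Object of class `gpbso_config`.
#' @export
gpbso_config <- function(pop_size = 100L, max_gen = 10000L, order = -1L,
                         n_groups = 5L, gen_probs = c(0.4, 0.3, 0.3),
                         sig_threshold = NULL, seed = 0L,
                         dof = c("observed", "full"), verbose = FALSE) {
  pop_size <- as.integer(pop_size)
  n_groups <- as.integer(n_groups)
  if (pop_size < n_groups || n_groups < 1L)
    stop("need pop_size >= n_groups >= 1")
  if (length(gen_probs) != 3L || any(gen_probs < 0) ||
      abs(sum(gen_probs) - 1) > 1e-8)
    stop("gen_probs must be 3 non-negative values summing to 1")
  order <- as.integer(order)
  if (order != -1L && order < 2L)
    stop("order must be -1 (auto) or >= 2")
  structure(
    list(pop_size = pop_size, max_gen = as.integer(max_gen), order = order,
         n_groups = n_groups, gen_probs = as.numeric(gen_probs),
         sig_threshold = sig_threshold, seed = as.integer(seed),
         dof = match.arg(dof), verbose = isTRUE(verbose)),
    class = "gpbso_config"
  )
}

## ---- generation methods (combination-level mechanics) -----------------
## Group and member selection live in the search loop; these operate on
## explicit SNP-index vectors so the contracts are directly testable.

# sample n elements of x (never interprets a length-1 x as 1:x)
sample_vec <- function(x, n, prob = NULL) x[sample.int(length(x), n, prob = prob)]

# draw `need` indices distinct from `taken` and from each other,
# preferring the gene pool and falling back to all remaining loci
fill_distinct <- function(taken, need, pool, n_loci) {
  if (need == 0L) return(integer(0))
  avail <- setdiff(pool, taken)
  if (length(avail) >= need) return(sample_vec(avail, need))
  rest <- setdiff(seq_len(n_loci), c(taken, avail))
  c(avail, sample_vec(rest, need - length(avail)))
}

#' Idea fusion: combine two parent combinations half-and-half
#'
#' Takes the first `ceiling(mo/2)` SNPs of `p1` and the last
#' `mo - ceiling(mo/2)` of `p2`; duplicate indices are replaced by draws
#' from the gene pool (or from all loci if the pool is exhausted).
#'
#' @param p1,p2 sorted parent SNP-index vectors of equal length `mo`.
#' @param pool integer vector of gene-pool indices.
#' @param n_loci total number of loci.
#' @return Sorted vector of `mo` distinct indices.
#' @export
idea_fusion <- function(p1, p2, pool, n_loci) {
  mo <- length(p1)
  stopifnot(length(p2) == mo, mo >= 2L)
  h <- ceiling(mo / 2)
  head_part <- p1[seq_len(h)]
  tail_part <- p2[seq.int(h + 1L, mo)]
  child <- c(head_part, tail_part[!(tail_part %in% head_part)])
  sort(c(child, fill_distinct(child, mo - length(child), pool, n_loci)))
}

#' Inspiration sparking: renew the second half of a combination
#'
#' Keeps the first `ceiling(mo/2)` SNPs of the parent and replaces the
#' remainder with distinct draws from the gene pool (fallback: loci not
#' already in the child).
#'
#' @inheritParams idea_fusion
#' @param parent sorted SNP-index vector.
#' @return Sorted vector of `length(parent)` distinct indices.
#' @export
inspiration_sparking <- function(parent, pool, n_loci) {
  mo <- length(parent)
  h <- ceiling(mo / 2)
  kept <- parent[seq_len(h)]
  sort(c(kept, fill_distinct(kept, mo - h, pool, n_loci)))
}

#' Free association: a wholly new combination from the gene pool
#'
#' @inheritParams idea_fusion
#' @param mo combination size.
#' @return Sorted vector of `mo` distinct indices drawn uniformly from
#'   the pool (shortfall drawn from the remaining loci).
#' @export
free_association <- function(pool, mo, n_loci) {
  if (length(pool) >= mo) return(sort(sample_vec(pool, mo)))
  sort(c(pool, fill_distinct(pool, mo - length(pool), integer(0), n_loci)))
}

## ---- k-means++ on binary membership vectors ---------------------------
## An individual is embedded as the 0/1 indicator of its SNP set; squared
## Euclidean distance (= twice the set Hamming distance at equal sizes)
## drives both seeding and Lloyd iterations.

membership_matrix <- function(pop_snps, n_loci) {
  x <- matrix(0, length(pop_snps), n_loci)
  for (i in seq_along(pop_snps)) x[i, pop_snps[[i]]] <- 1
  x
}

kmeanspp <- function(x, k, max_iter = 20L) {
  n <- nrow(x)
  if (k >= n) return(seq_len(n))        # degenerate: singleton groups
  sq <- rowSums(x^2)
  d2_to <- function(center) pmax(sq - 2 * drop(x %*% center) + sum(center^2), 0)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- d2_to(centers[1L, ])
  for (j in seq_len(k - 1L)) {
    pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
    centers[j + 1L, ] <- x[pick, ]
    d2 <- pmin(d2, d2_to(centers[j + 1L, ]))
  }
  assign_nearest <- function() {
    d <- outer(sq, rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
    max.col(-d, ties.method = "first")
  }
  cl <- assign_nearest()
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      idx <- which(cl == j)
      if (length(idx) == 0L) {           # revive empty cluster on the
        far <- which.max(sq)             # point farthest from the origin
        centers[j, ] <- x[far, ]
      } else {
        centers[j, ] <- colMeans(x[idx, , drop = FALSE])
      }
    }
    new_cl <- assign_nearest()
    if (all(new_cl == cl)) break
    cl <- new_cl
  }
  cl
}

## ---- population state -------------------------------------------------
## Mutable search state held in an environment: SNP sets and fitness of
## the population, group membership + centroids, and the gene pool
## (tracked through per-SNP use counts so eviction returns a SNP to the
## pool only when no survivor carries it).

new_state <- function(ds, cfg, mo) {
  st <- new.env(parent = emptyenv())
  st$ds <- ds
  st$cfg <- cfg
  st$mo <- mo
  st$n_loci <- ds$n_snps
  n <- ds$n_snps
  p <- cfg$pop_size
  if (p * mo > n)
    warning("pop_size * mo (", p * mo, ") exceeds the number of SNPs (",
            n, "); individuals will share SNPs and the pool may start empty")
  # disjoint initial coverage while the SNP supply lasts
  perm <- sample.int(n)
  pop <- vector("list", p)
  used <- 0L
  for (i in seq_len(p)) {
    if (used + mo <= n) {
      pop[[i]] <- sort(perm[(used + 1L):(used + mo)])
      used <- used + mo
    } else {
      pop[[i]] <- sort(sample_vec(seq_len(n), mo))
    }
  }
  st$pop_snps <- pop
  st$pop_fit <- vapply(pop, function(s) k2_score(ds, s), numeric(1))
  st$use_count <- tabulate(unlist(pop), nbins = n)
  st$in_pool <- st$use_count == 0L
  recluster(st)
  st
}

recluster <- function(st) {
  x <- membership_matrix(st$pop_snps, st$n_loci)
  st$group_id <- kmeanspp(x, st$cfg$n_groups)
  k <- max(st$cfg$n_groups, st$group_id)
  cent <- matrix(0, k, st$n_loci)
  for (j in seq_len(k)) {
    idx <- which(st$group_id == j)
    if (length(idx)) cent[j, ] <- colMeans(x[idx, , drop = FALSE])
  }
  st$centroids <- cent
  st$cent_sq <- rowSums(cent^2)
  invisible(st)
}

nearest_group <- function(st, snps) {
  s <- if (length(snps) == 1L) st$centroids[, snps] else
    rowSums(st$centroids[, snps, drop = FALSE])
  d <- length(snps) - 2 * s + st$cent_sq
  grp <- which.min(d)
  # never target an empty group
  while (!any(st$group_id == grp)) {
    d[grp] <- Inf
    grp <- which.min(d)
  }
  grp
}

# steady-state replacement: candidate vs the worst member of its nearest
# group; on eviction, SNPs return to the pool iff no survivor carries them.
# A candidate identical to a live individual is rejected outright - clones
# would erode the diversity the discussion groups exist to maintain.
update_population <- function(st, cand_snps, cand_fit) {
  grp <- nearest_group(st, cand_snps)
  members <- which(st$group_id == grp)
  worst <- members[which.max(st$pop_fit[members])]
  if (cand_fit >= st$pop_fit[worst]) return(FALSE)
  for (s in st$pop_snps)
    if (identical(s, cand_snps)) return(FALSE)
  old <- st$pop_snps[[worst]]
  st$use_count[old] <- st$use_count[old] - 1L
  st$in_pool[old[st$use_count[old] == 0L]] <- TRUE
  st$use_count[cand_snps] <- st$use_count[cand_snps] + 1L
  st$in_pool[cand_snps] <- FALSE
  st$pop_snps[[worst]] <- cand_snps
  st$pop_fit[worst] <- cand_fit
  # incremental centroid update for the affected group
  size <- length(members)
  cent <- st$centroids
  touched <- union(old, cand_snps)
  before <- cent[grp, touched]
  cent[grp, old] <- cent[grp, old] - 1 / size
  cent[grp, cand_snps] <- cent[grp, cand_snps] + 1 / size
  st$cent_sq[grp] <- st$cent_sq[grp] - sum(before^2) + sum(cent[grp, touched]^2)
  st$centroids <- cent
  TRUE
}

## ---- member / group selection -----------------------------------------

# rank-weighted choice of `n` distinct members among the best half of a
# group (lower K2 = better); returns population indices
pick_members <- function(st, members, n) {
  ord <- members[order(st$pop_fit[members])]
  h <- ceiling(length(ord) / 2)
  top <- ord[seq_len(h)]
  if (n > length(top)) return(NULL)
  sample_vec(top, n, prob = rev(seq_len(h)))
}

top_group <- function(st) {
  best <- tapply(st$pop_fit, st$group_id, min)
  as.integer(names(best)[which.min(best)])
}

random_group <- function(st) sample_vec(unique(st$group_id), 1L)

generate_candidate <- function(st) {
  pool <- which(st$in_pool)
  method <- sample.int(3L, 1L, prob = st$cfg$gen_probs)
  if (method == 1L) {
    grp <- top_group(st)
    members <- which(st$group_id == grp)
    if (length(members) >= 2L) {
      parents <- pick_members(st, members, 2L)
      if (!is.null(parents))
        return(idea_fusion(st$pop_snps[[parents[1L]]],
                           st$pop_snps[[parents[2L]]], pool, st$n_loci))
    }
    method <- 2L                        # group too small: fall back
  }
  if (method == 2L) {
    grp <- random_group(st)
    members <- which(st$group_id == grp)
    parent <- pick_members(st, members, 1L)
    return(inspiration_sparking(st$pop_snps[[parent]], pool, st$n_loci))
  }
  free_association(pool, st$mo, st$n_loci)
}

## ---- main search loop -------------------------------------------------

#' Detect epistatic interactions with gene-pool Brain Storm Optimization
#'
#' Runs the full search: resolves the maximum order, initializes a
#' population of SNP combinations clustered into discussion groups by
#' k-means++, then for `max_gen` iterations generates one candidate by
#' idea fusion / inspiration sparking / free association, scores it with
#' the K2 criterion, prunes it to a locally minimal set, G-tests new
#' pruned sets, and applies steady-state replacement with dynamic
#' gene-pool bookkeeping.  Fully deterministic given `cfg$seed`.
#'
#' @param ds a [genotype_dataset()].
#' @param cfg a [gpbso_config()].
#' @return `data.frame` of significant interactions sorted by p-value
#'   ascending: columns `p_value`, `g_stat`, `dof`, `k2`, `order`,
#'   `snps` (comma-joined identifiers) and list column `snp_idx`.
#' @export
gpbso <- function(ds, cfg = gpbso_config()) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(cfg, "gpbso_config"))
  set.seed(cfg$seed)
  mo <- if (cfg$order == -1L) estimate_max_order(ds$n_controls, ds$n_cases)
        else cfg$order
  if (mo > ds$n_snps) stop("order ", mo, " exceeds the number of SNPs")
  threshold <- if (is.null(cfg$sig_threshold))
    0.05 / choose(ds$n_snps, 2) else cfg$sig_threshold
  st <- new_state(ds, cfg, mo)
  recluster_every <- cfg$pop_size * 10L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  res <- list()
  ctrl <- ds$control_masks; cases <- ds$case_masks; lnfact <- ds$lnfact
  interrupted <- FALSE
  tryCatch({
    for (gen in seq_len(cfg$max_gen)) {
      cand <- generate_candidate(st)
      pr <- prune_k2_cpp(ctrl, cases, lnfact, cand - 1L)
      if (length(pr$snps) >= 2L) {
        key <- paste(sort(pr$snps), collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          snps <- sort(pr$snps + 1L)
          g <- g_test(contingency_table(ds, snps), dof = cfg$dof)
          if (g$p_value < threshold) {
            res[[length(res) + 1L]] <- list(
              p_value = g$p_value, g_stat = g$g_stat, dof = g$dof,
              k2 = pr$k2, order = length(snps), snp_idx = snps)
          }
        }
      }
      update_population(st, cand, pr$k2_initial)
      if (gen %% recluster_every == 0L) recluster(st)
      if (cfg$verbose && gen %% max(1L, cfg$max_gen %/% 20L) == 0L)
        message(sprintf("gen %d | best k2 %.3f | pool %d | hits %d",
                        gen, min(st$pop_fit), sum(st$in_pool), length(res)))
    }
  }, interrupt = function(e) {
    interrupted <<- TRUE
  })
  if (interrupted)
    warning("search interrupted; returning partial results")
  out <- results_frame(res, ds$snp_names)
  attr(out, "mo") <- mo
  attr(out, "sig_threshold") <- threshold
  out
}

results_frame <- function(res, snp_names) {
  if (length(res) == 0L) {
    out <- data.frame(p_value = numeric(0), g_stat = numeric(0),
                      dof = integer(0), k2 = numeric(0), order = integer(0),
                      snps = character(0), stringsAsFactors = FALSE)
    out$snp_idx <- list()
    return(out)
  }
  out <- data.frame(
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    g_stat = vapply(res, `[[`, numeric(1), "g_stat"),
    dof = vapply(res, `[[`, integer(1), "dof"),
    k2 = vapply(res, `[[`, numeric(1), "k2"),
    order = vapply(res, `[[`, integer(1), "order"),
    snps = vapply(res, function(r)
      paste(snp_names[r$snp_idx], collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  out$snp_idx <- lapply(res, `[[`, "snp_idx")
  ord <- order(out$p_value, out$k2)
  out[ord, , drop = FALSE]
}
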