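make_state <- function(n_snps = 100L, pop_size = 10L, mo = 2L,
                       n_groups = 3L, seed = 1L) {
  set.seed(seed)
  d <- random_geno(40L, n_snps)
  ds <- genotype_dataset(d$geno, d$pheno)
  cfg <- gpbso_config(pop_size = pop_size, n_groups = n_groups, order = mo)
  gpbso:::new_state(ds, cfg, mo)
}

pool_is_disjoint <- function(st) {
  pool <- which(st$in_pool)
  used <- unique(unlist(st$pop_snps))
  length(intersect(pool, used)) == 0L &&
    all(sort(unique(c(pool, used))) %in% seq_len(st$n_loci))
}

test_that("configuration validation catches inconsistent settings", {
  expect_error(gpbso_config(pop_size = 2, n_groups = 5), "pop_size >= n_groups")
  expect_error(gpbso_config(gen_probs = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(gpbso_config(order = 1), "-1 \\(auto\\) or >= 2")
})

test_that("initialization covers disjoint SNPs and leaves the rest pooled", {
  st <- make_state(n_snps = 100L, pop_size = 10L, mo = 2L)
  expect_equal(sum(st$in_pool), 80L)          # 100 - 10 x 2
  expect_true(pool_is_disjoint(st))
  expect_true(all(vapply(st$pop_snps, function(s)
    length(s) == 2L && !anyDuplicated(s), logical(1))))
})

test_that("initialization is deterministic and groups partition the population", {
  a <- make_state(seed = 9L)
  b <- make_state(seed = 9L)
  expect_identical(a$pop_snps, b$pop_snps)
  expect_identical(a$group_id, b$group_id)
  expect_identical(which(a$in_pool), which(b$in_pool))
  for (r in 1:10) {
    k <- sample(2:5, 1L)
    st <- make_state(pop_size = sample(6:20, 1L), n_groups = k,
                     seed = 100L + r)
    expect_length(st$group_id, length(st$pop_snps))
    expect_setequal(unique(st$group_id), seq_len(k))
  }
})

test_that("idea fusion joins parent halves and repairs duplicates", {
  set.seed(21)
  expect_identical(idea_fusion(c(1L, 2L, 3L, 4L), c(5L, 6L, 7L, 8L),
                               pool = 50:60, n_loci = 100L),
                   c(1L, 2L, 7L, 8L))
  for (r in 1:200) {
    child <- idea_fusion(c(1L, 2L), c(2L, 9L), pool = 40:49, n_loci = 100L)
    expect_length(child, 2L)
    expect_true(1L %in% child)
    expect_false(anyDuplicated(child) > 0L)
  }
  # property sweep: children always have mo distinct indices
  for (r in 1:500) {
    mo <- sample(2:5, 1L)
    p1 <- sort(sample(100L, mo)); p2 <- sort(sample(100L, mo))
    pool <- sample(100L, 20L)
    child <- idea_fusion(p1, p2, pool, 100L)
    expect_length(unique(child), mo)
  }
})

test_that("inspiration sparking keeps the first half and renews the rest", {
  set.seed(22)
  for (r in 1:200) {
    child <- inspiration_sparking(c(1L, 2L, 3L, 4L), pool = c(50L, 60L, 70L),
                                  n_loci = 100L)
    expect_identical(child[child <= 4L], c(1L, 2L))   # kept half
    expect_true(all(setdiff(child, c(1L, 2L)) %in% c(50L, 60L, 70L)))
    expect_length(unique(child), 4L)
  }
  # mo = 2: one kept, one replaced
  child <- inspiration_sparking(c(3L, 7L), pool = 90:95, n_loci = 100L)
  expect_true(3L %in% child)
  expect_true(any(child %in% 90:95))
})

test_that("free association draws uniformly from the gene pool", {
  set.seed(23)
  expect_identical(free_association(pool = c(4L, 9L, 31L), mo = 3L,
                                    n_loci = 100L), c(4L, 9L, 31L))
  pool <- 11:40
  draws <- replicate(5000, free_association(pool, 3L, 100L))
  expect_true(all(draws %in% pool))
  counts <- tabulate(factor(draws, levels = pool))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
  # shortfall falls back to the remaining loci, still distinct
  child <- free_association(pool = c(2L, 5L), mo = 4L, n_loci = 10L)
  expect_length(unique(child), 4L)
  expect_true(all(c(2L, 5L) %in% child))
})

test_that("steady-state replacement keeps the gene pool disjoint", {
  set.seed(24)
  st <- make_state(n_snps = 60L, pop_size = 12L, mo = 3L, n_groups = 3L)
  # a candidate worse than everything is rejected without side effects
  before <- list(st$pop_snps, which(st$in_pool))
  accepted <- gpbso:::update_population(st, sort(sample(60L, 3L)),
                                        max(st$pop_fit) + 100)
  expect_false(accepted)
  expect_identical(list(st$pop_snps, which(st$in_pool)), before)
  # a SNP shared with a survivor must not return to the pool
  st2 <- make_state(n_snps = 30L, pop_size = 4L, mo = 2L, n_groups = 1L,
                    seed = 77L)
  victim <- which.max(st2$pop_fit)
  shared <- st2$pop_snps[[victim]][1L]
  other <- setdiff(seq_len(4L), victim)[1L]
  st2$pop_snps[[other]] <- sort(c(shared, st2$pop_snps[[other]][1L]))
  st2$use_count <- tabulate(unlist(st2$pop_snps), nbins = 30L)
  st2$in_pool <- st2$use_count == 0L
  cand <- sort(sample(which(st2$in_pool), 2L))
  accepted <- gpbso:::update_population(st2, cand, min(st2$pop_fit) - 100)
  expect_true(accepted)
  expect_false(st2$in_pool[shared])
  expect_true(pool_is_disjoint(st2))
  # randomized sweep: invariant and monotone best fitness
  best <- min(st$pop_fit)
  for (r in 1:500) {
    cand <- sort(sample(60L, 3L))
    gpbso:::update_population(st, cand, stats::runif(1, 0, 200))
    expect_lte(min(st$pop_fit), best + 1e-12)
    best <- min(st$pop_fit)
  }
  expect_true(pool_is_disjoint(st))
})

test_that("the full search is deterministic and deduplicated", {
  spec <- penetrance_spec("xor", 2, baseline = 0.05, effect = 0.9,
                          mafs = 0.5)
  sim <- simulate_epistasis(150, 150, 30, spec, seed = 3)
  cfg <- gpbso_config(pop_size = 10, max_gen = 10000, seed = 5)
  r1 <- suppressWarnings(gpbso(sim$dataset, cfg))
  r2 <- suppressWarnings(gpbso(sim$dataset, cfg))
  expect_identical(r1, r2)
  expect_false(any(duplicated(vapply(r1$snp_idx, paste, character(1),
                                     collapse = ","))))
  expect_false(is.unsorted(r1$p_value))
  # the planted pair dominates this easy instance
  expect_identical(r1$snp_idx[[1L]], sim$truth)
  # a zero threshold reports nothing
  r0 <- suppressWarnings(
    gpbso(sim$dataset, gpbso_config(pop_size = 10, max_gen = 300,
                                    order = 2, seed = 5,
                                    sig_threshold = 0)))
  expect_identical(nrow(r0), 0L)
})

test_that("auto order resolution feeds the search", {
  set.seed(26)
  spec <- penetrance_spec("joint_recessive", 2, baseline = 0.2,
                          effect = 0.7, mafs = 0.4)
  sim <- simulate_epistasis(60, 60, 25, spec, seed = 8)
  res <- suppressWarnings(
    gpbso(sim$dataset, gpbso_config(pop_size = 10, max_gen = 200, seed = 1)))
  expect_identical(attr(res, "mo"), estimate_max_order(60, 60))
})
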