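# Independent oracles used by the tests; each deliberately avoids the
# code path it checks.

# nested-loop contingency count over raw genotype rows; emits cells in
# the same order as contingency_table (first combo SNP fastest)
naive_contingency <- function(geno, pheno, combo) {
  L <- length(combo)
  cells <- matrix(0L, 3^L, 2L)
  radix <- 3^(seq_len(L) - 1L)
  for (s in seq_len(nrow(geno))) {
    idx <- 1L + sum(geno[s, combo] * radix)
    j <- pheno[s] + 1L
    cells[idx, j] <- cells[idx, j] + 1L
  }
  cells
}

# ln(n!) by direct summation of logs of integers (no gamma function)
lnfact_direct <- function(n) if (n <= 1) 0 else sum(log(seq_len(n)))

# K2 score from first principles: -ln prod_c m_c0! m_c1! / (m_c*+1)!
k2_direct <- function(cells) {
  s <- 0
  for (r in seq_len(nrow(cells))) {
    m0 <- cells[r, 1L]; m1 <- cells[r, 2L]
    s <- s + lnfact_direct(m0 + m1 + 1L) - lnfact_direct(m0) -
      lnfact_direct(m1)
  }
  s
}

# likelihood-ratio G as 2 * sum O * ln(O/E) over the 3^L x 2 table
g_direct <- function(cells) {
  m0t <- sum(cells[, 1L]); m1t <- sum(cells[, 2L]); m <- m0t + m1t
  g <- 0
  for (r in seq_len(nrow(cells))) {
    mc <- sum(cells[r, ])
    for (j in 1:2) {
      o <- cells[r, j]
      e <- mc * c(m0t, m1t)[j] / m
      if (o > 0) g <- g + o * log(o / e)
    }
  }
  2 * g
}

# chi-squared upper tail by numerical integration of the density
# (independent of pchisq)
chisq_sf_direct <- function(x, df) {
  if (x <= 0) return(1)
  if (x > 1500) return(0)  # far tail: both routes are 0 to 1e-8
  stats::integrate(stats::dchisq, x, Inf, df = df,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# random case-control genotype matrix with at least one sample per class
random_geno <- function(n_samples, n_snps) {
  geno <- matrix(sample(0:2, n_samples * n_snps, replace = TRUE),
                 n_samples, n_snps)
  pheno <- c(0L, 1L, sample(0:1, n_samples - 2L, replace = TRUE))
  list(geno = geno, pheno = pheno)
}

# deterministic dataset where SNPs (1, 2) jointly determine the
# phenotype through the XOR-of-homozygous-minor pattern and the
# remaining SNPs are random noise
xor_pair_dataset <- function(reps = 4L, n_noise = 1L) {
  grid <- as.matrix(expand.grid(g1 = 0:2, g2 = 0:2))
  geno <- grid[rep(seq_len(nrow(grid)), each = reps), , drop = FALSE]
  pheno <- as.integer(xor(geno[, 1L] == 2L, geno[, 2L] == 2L))
  if (n_noise > 0L)
    geno <- cbind(geno, matrix(sample(0:2, nrow(geno) * n_noise,
                                      replace = TRUE),
                               nrow(geno), n_noise))
  genotype_dataset(geno, pheno)
}

# independent re-implementation of the greedy first-improvement deletion
# loop, built entirely on the naive counting and direct-factorial oracles
prune_direct <- function(geno, pheno, combo) {
  x <- combo
  k2x <- k2_direct(naive_contingency(geno, pheno, x))
  while (length(x) > 1L) {
    found <- FALSE
    for (i in seq_along(x)) {
      xx <- x[-i]
      k2xx <- k2_direct(naive_contingency(geno, pheno, xx))
      if (k2xx < k2x) {
        x <- xx
        k2x <- k2xx
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  list(snps = x, k2 = k2x)
}

# wrap an explicit cell matrix as a contingency_table (for closed-form
# score checks on hand-built tables)
fake_table <- function(cells) {
  cells <- matrix(as.integer(cells), ncol = 2L)
  structure(list(order = round(log(nrow(cells)) / log(3)), cells = cells,
                 m = sum(cells), m_star0 = sum(cells[, 1L]),
                 m_star1 = sum(cells[, 2L]), snps = NULL),
            class = "contingency_table")
}

write_tiny_dataset <- function(path, n0 = 8L, n1 = 8L, n_snps = 3L) {
  geno <- matrix(sample(0:2, (n0 + n1) * n_snps, replace = TRUE),
                 n0 + n1, n_snps)
  pheno <- rep(c(0L, 1L), c(n0, n1))
  df <- as.data.frame(geno)
  names(df) <- paste0("rs", seq_len(n_snps))
  df$Class <- pheno
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(geno = geno, pheno = pheno)
}
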