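#' Contingency table for a SNP combination
#'
#' Counts control and case samples in each of the `3^L` genotype
#' configurations of an `L`-SNP combination, using the bit-encoded masks
#' (one AND chain + popcount per cell).
#'
#' @param ds a [genotype_dataset()].
#' @param combo integer vector of 1-based locus indices (distinct).
#' @return Object of class `contingency_table`: list with `order`,
#'   `cells` (a `3^L` x 2 integer matrix, columns `m0` controls / `m1`
#'   cases; the first SNP's genotype varies fastest, as in
#'   `expand.grid(0:2, ...)`), and totals `m`, `m_star0`, `m_star1`.
#' @export
contingency_table <- function(ds, combo) {
  stopifnot(inherits(ds, "genotype_dataset"))
  combo <- as.integer(combo)
  check_combo(ds, combo)
  cells <- contingency_counts(ds$control_masks, ds$case_masks, combo - 1L)
  colnames(cells) <- c("m0", "m1")
  structure(
    list(order = length(combo), cells = cells,
         m = ds$n_controls + ds$n_cases,
         m_star0 = ds$n_controls, m_star1 = ds$n_cases,
         snps = ds$snp_names[combo]),
    class = "contingency_table"
  )
}

check_combo <- function(ds, combo, min_order = 1L) {
  if (length(combo) < min_order)
    stop("combination must contain at least ", min_order, " SNP(s)")
  if (anyNA(combo) || any(combo < 1L) || any(combo > ds$n_snps))
    stop("locus index out of range 1..", ds$n_snps)
  if (anyDuplicated(combo))
    stop("duplicate locus index in combination")
  max_cells <- getOption("gpbso.max_cells", 3^12)
  if (3^length(combo) > max_cells)
    stop("order ", length(combo), " gives 3^", length(combo),
         " contingency cells, above the configured budget (",
         max_cells, "); use a lower order")
  invisible(combo)
}

#' K2 Bayesian-network association score
#'
#' Negative-log form of the K2 marginal likelihood of the phenotype node
#' given a SNP-set parent configuration:
#' `sum_c [ ln((m_c0 + m_c1 + 1)!) - ln(m_c0!) - ln(m_c1!) ]`,
#' evaluated with log-gamma so arbitrary counts cannot overflow.
#' Lower values indicate a stronger phenotype association.
#'
#' @param x a `contingency_table`, or a [genotype_dataset()] when `combo`
#'   is given.
#' @param combo optional 1-based locus indices scored directly from the
#'   bit masks (faster: no table materialized).
#' @return Non-negative numeric score.
#' @export
k2_score <- function(x, combo = NULL) {
  if (inherits(x, "genotype_dataset")) {
    combo <- as.integer(combo)
    check_combo(x, combo)
    return(k2_from_masks(x$control_masks, x$case_masks, x$lnfact, combo - 1L))
  }
  stopifnot(inherits(x, "contingency_table"))
  m0 <- x$cells[, 1L]
  m1 <- x$cells[, 2L]
  sum(lgamma(m0 + m1 + 2) - lgamma(m0 + 1) - lgamma(m1 + 1))
}

#' Likelihood-ratio G-test on a contingency table
#'
#' `G = 2 * sum_c sum_j m_cj * ln( m_cj * m / (m_c* * m_*j) )` with
#' zero-count terms contributing 0; the statistic is referred to a
#' chi-squared null.  Degrees of freedom count, by default, only genotype
#' configurations actually observed (`m_c* > 0`) minus one - sparse
#' high-order tables otherwise inflate the dof - with the naive
#' `3^L - 1` available via `dof = "full"`.
#'
#' @param t a `contingency_table`.
#' @param dof `"observed"` (default) or `"full"`.
#' @return Object of class `g_test`: list with `g_stat`, `dof`, `p_value`.
#' @export
g_test <- function(t, dof = c("observed", "full")) {
  stopifnot(inherits(t, "contingency_table"))
  dof <- match.arg(dof)
  m0 <- t$cells[, 1L]
  m1 <- t$cells[, 2L]
  mc <- m0 + m1
  if (t$m_star0 <= 0L || t$m_star1 <= 0L)
    stop("G-test undefined: a phenotype class has no samples")
  term <- function(obs, class_total) {
    e <- mc * class_total / t$m
    ifelse(obs > 0, obs * log(obs / e), 0)
  }
  g <- 2 * sum(term(m0, t$m_star0) + term(m1, t$m_star1))
  g <- max(g, 0)                          # guard tiny negative rounding
  k <- if (dof == "observed") sum(mc > 0L) else nrow(t$cells)
  df <- max(1L, k - 1L)
  structure(
    list(g_stat = g, dof = df,
         p_value = stats::pchisq(g, df = df, lower.tail = FALSE)),
    class = "g_test"
  )
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G-test: G = %.4f, df = %d, p = %.4g\n",
              x$g_stat, x$dof, x$p_value))
  invisible(x)
}

#' Prune a SNP combination to a locally minimal epistatic set
#'
#' Greedy backward deletion on the K2 score: scan deletion candidates in
#' index order and accept the first whose removal strictly lowers the
#' score, restarting after each accepted deletion; stop when no single
#' deletion improves.  The surviving set is reported iff it still has at
#' least two SNPs; it is then locally minimal (every single-SNP deletion
#' strictly increases K2) and its score never exceeds the input's.
#'
#' @param ds a [genotype_dataset()].
#' @param combo integer vector of >= 2 distinct 1-based locus indices.
#' @param sig_threshold significance level applied to the G-test p-value.
#' @param dof passed to [g_test()].
#' @return An `epistasis_result` (fields `snps` — indices, `snp_names`,
#'   `k2`, `g` — a `g_test`, `significant`), or `NULL` if pruning reduced
#'   the combination to a single SNP.
#' @export
prune_combination <- function(ds, combo, sig_threshold = 0.05,
                              dof = c("observed", "full")) {
  stopifnot(inherits(ds, "genotype_dataset"))
  combo <- as.integer(combo)
  check_combo(ds, combo, min_order = 2L)
  pr <- prune_k2_cpp(ds$control_masks, ds$case_masks, ds$lnfact, combo - 1L)
  snps <- pr$snps + 1L
  if (length(snps) < 2L) return(NULL)
  g <- g_test(contingency_table(ds, snps), dof = match.arg(dof))
  structure(
    list(snps = sort(snps), snp_names = ds$snp_names[sort(snps)],
         k2 = pr$k2, g = g,
         significant = g$p_value < sig_threshold),
    class = "epistasis_result"
  )
}

#' @export
print.epistasis_result <- function(x, ...) {
  cat(sprintf("%s: k2 = %.3f, G p = %.3g%s\n",
              paste(x$snp_names, collapse = " x "), x$k2, x$g$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Write detected interactions as a tab-separated table
#'
#' One row per interaction, sorted by G-test p-value ascending: column
#' `g` (the p-value) followed by `snp1..snpK` identifier columns, padded
#' with empty strings for lower-order rows.
#'
#' @param results data frame as returned by [gpbso()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (nrow(results) == 0L) {
    writeLines("g\tsnp1\tsnp2", path)
    return(invisible(path))
  }
  kmax <- max(results$order)
  pad <- function(s) {
    v <- strsplit(s, ",", fixed = TRUE)[[1L]]
    c(v, rep("", kmax - length(v)))
  }
  snp_cols <- t(vapply(results$snps, pad, character(kmax)))
  colnames(snp_cols) <- paste0("snp", seq_len(kmax))
  df <- data.frame(g = sprintf("%.15g", results$p_value),
                   snp_cols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
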