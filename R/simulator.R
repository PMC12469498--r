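## Penetrance-model simulator: Hardy-Weinberg genotype sampling with a
## planted interaction following one of five two-locus penetrance
## indicator models (plus explicit order-3 extensions), additive effect
## parameterization P(disease | g) = alpha + beta * I(g).

# Two-locus 0/1 indicator matrices, indexed [g1 + 1, g2 + 1] where g1/g2
# are minor-allele counts at SNP1/SNP2 (0 = major homozygote).
indicator2 <- function(model) {
  m <- switch(model,
    joint_dominant = rbind(c(0, 0, 0),   # g2 = 0 row, g1 = 0..2 cols
                           c(0, 0, 1),
                           c(0, 1, 1)),
    joint_recessive = rbind(c(0, 0, 0),
                            c(0, 0, 0),
                            c(0, 0, 1)),
    modular = rbind(c(0, 0, 0),
                    c(0, 0, 1),
                    c(1, 1, 1)),
    diagonal = diag(3),
    xor = rbind(c(0, 0, 1),
                c(0, 0, 1),
                c(1, 1, 0)),
    stop("unknown penetrance model: ", model)
  )
  t(m)                                   # printed rows are SNP2 -> transpose
}

# Order-3 extensions of the same logical rules (explicit conventions;
# user-overridable through a custom table).
indicator3 <- function(model) {
  f <- switch(model,
    joint_dominant = function(g) all(g >= 1),
    joint_recessive = function(g) all(g == 2),
    modular = function(g) any(g == 2) || all(g >= 1),
    diagonal = function(g) length(unique(g)) == 1L,
    xor = function(g) sum(g >= 1) %% 2L == 1L,
    stop("unknown penetrance model: ", model)
  )
  grid <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  array(apply(grid, 1L, function(g) as.numeric(f(g))), dim = c(3, 3, 3))
}

#' Specify a planted epistatic interaction
#'
#' Disease probability is `alpha + beta * I(g)` where `I` is the model's
#' 0/1 genotype indicator, `alpha` the baseline penetrance and `beta`
#' the interaction effect.
#'
#' @param model one of `"joint_dominant"`, `"joint_recessive"`,
#'   `"modular"`, `"diagonal"`, `"xor"`, or `"custom"` with `table`.
#' @param order interaction order, 2 or 3 (ignored for `"custom"`).
#' @param baseline alpha in `[0, 1)`.
#' @param effect beta, with `alpha + beta` in `[0, 1]`.
#' @param mafs per-causal-locus minor allele frequencies in
#'   `[0.05, 0.5]`; recycled to `order`.
#' @param table for `model = "custom"`: an array with `dim = rep(3, order)`
#'   of disease probabilities (overrides `baseline`/`effect`).
#' @return Object of class `penetrance_spec`.
#' @export
penetrance_spec <- function(model, order = 2L, baseline = 0.1, effect = 0.5,
                            mafs = 0.25, table = NULL) {
  order <- as.integer(order)
  if (identical(model, "custom")) {
    if (is.null(table)) stop("model = 'custom' requires a penetrance table")
    table <- as.array(table)
    order <- length(dim(table))
    if (!all(dim(table) == 3L)) stop("custom table must be 3 x 3 (x 3 ...)")
    if (any(table < 0 | table > 1)) stop("penetrances must lie in [0, 1]")
  } else {
    if (!model %in% c("joint_dominant", "joint_recessive", "modular",
                      "diagonal", "xor"))
      stop("unknown penetrance model: ", model)
    if (!order %in% c(2L, 3L)) stop("order must be 2 or 3 for named models")
    if (baseline < 0 || baseline >= 1) stop("baseline must be in [0, 1)")
    if (baseline + effect > 1 || baseline + effect < 0)
      stop("baseline + effect must lie in [0, 1]")
  }
  mafs <- rep_len(as.numeric(mafs), order)
  if (any(mafs < 0.05 | mafs > 0.5))
    stop("minor allele frequencies must lie in [0.05, 0.5]")
  structure(list(model = model, order = order, baseline = baseline,
                 effect = effect, mafs = mafs, table = table),
            class = "penetrance_spec")
}

#' Penetrance table of a specification
#'
#' @param spec a [penetrance_spec()].
#' @return Array with `dim = rep(3, order)`: disease probability for each
#'   genotype configuration (indices = minor-allele count + 1; first
#'   causal SNP on the first dimension).
#' @export
penetrance_table <- function(spec) {
  stopifnot(inherits(spec, "penetrance_spec"))
  if (identical(spec$model, "custom")) return(spec$table)
  ind <- if (spec$order == 2L) indicator2(spec$model) else
    indicator3(spec$model)
  spec$baseline + spec$effect * ind
}

#' Simulate a case-control dataset with a planted interaction
#'
#' Every locus is sampled under Hardy-Weinberg equilibrium (genotype
#' probabilities `(1-p)^2, 2p(1-p), p^2` for minor allele frequency `p`);
#' noise-locus MAFs are drawn uniformly from `maf_range`.  Disease status
#' is Bernoulli in the penetrance of the causal genotype configuration,
#' and sampling is rejected until exactly the requested case and control
#' counts are collected.  Noise genotypes are independent of phenotype,
#' so they are drawn after case-control acceptance (distributionally
#' identical, far cheaper).
#'
#' @param n_cases,n_controls exact class sizes to collect.
#' @param n_snps total loci; `n_snps - spec$order` of them are noise.
#' @param spec a [penetrance_spec()].
#' @param maf_range range the noise-locus MAFs are drawn from, inside
#'   `[0.05, 0.5]`.
#' @param seed optional integer seed (sets the RNG).
#' @param max_draws rejection-sampling budget; exceeding it (a penetrance
#'   configuration that makes one class unreachable) is an error.
#' @return Object of class `simulated_dataset`: `dataset` (a
#'   [genotype_dataset()], controls first), `truth` (sorted causal locus
#'   indices), `spec`, `n_noise`, `noise_mafs`.
#' @export
simulate_epistasis <- function(n_cases, n_controls, n_snps, spec,
                               maf_range = c(0.05, 0.5), seed = NULL,
                               max_draws = 2000L * (n_cases + n_controls)) {
  stopifnot(inherits(spec, "penetrance_spec"),
            n_cases >= 1, n_controls >= 1, n_snps >= spec$order)
  if (maf_range[1] < 0.05 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be within [0.05, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  n_cases <- as.integer(n_cases)
  n_controls <- as.integer(n_controls)
  n_snps <- as.integer(n_snps)
  k <- spec$order
  n_noise <- n_snps - k
  noise_mafs <- stats::runif(n_noise, maf_range[1], maf_range[2])
  truth <- sort(sample_vec(seq_len(n_snps), k))
  ptab <- penetrance_table(spec)

  need_case <- n_cases
  need_ctrl <- n_controls
  case_g <- matrix(0L, 0L, k)
  ctrl_g <- matrix(0L, 0L, k)
  drawn <- 0L
  batch <- max(1024L, n_cases + n_controls)
  while (need_case > 0L || need_ctrl > 0L) {
    if (drawn >= max_draws)
      stop("rejection budget exhausted after ", drawn, " draws: the ",
           "penetrance configuration makes the remaining class ",
           "practically unreachable")
    b <- min(batch, max_draws - drawn)
    drawn <- drawn + b
    g <- vapply(spec$mafs,
                function(p) stats::rbinom(b, 2L, p), integer(b))
    if (b == 1L) g <- matrix(g, 1L, k)
    pen <- ptab[matrix(g + 1L, ncol = k)]  # one probability per sample
    y <- stats::rbinom(b, 1L, pen)
    if (need_case > 0L) {
      idx <- which(y == 1L)[seq_len(min(need_case, sum(y == 1L)))]
      case_g <- rbind(case_g, g[idx, , drop = FALSE])
      need_case <- need_case - length(idx)
    }
    if (need_ctrl > 0L) {
      idx <- which(y == 0L)[seq_len(min(need_ctrl, sum(y == 0L)))]
      ctrl_g <- rbind(ctrl_g, g[idx, , drop = FALSE])
      need_ctrl <- need_ctrl - length(idx)
    }
  }

  n <- n_cases + n_controls
  geno <- matrix(0L, n, n_snps)
  noise_cols <- setdiff(seq_len(n_snps), truth)
  if (n_noise > 0L)
    geno[, noise_cols] <- vapply(noise_mafs,
                                 function(p) stats::rbinom(n, 2L, p),
                                 integer(n))
  geno[, truth] <- rbind(ctrl_g, case_g)  # controls first
  pheno <- rep(c(0L, 1L), c(n_controls, n_cases))
  colnames(geno) <- paste0("SNP", seq_len(n_snps))
  structure(
    list(dataset = genotype_dataset(geno, pheno),
         truth = truth, spec = spec, n_noise = n_noise,
         noise_mafs = noise_mafs),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated case-control dataset: model ", x$spec$model,
      ", order ", x$spec$order, "\n", sep = "")
  cat("  planted loci: ", paste(x$dataset$snp_names[x$truth],
                                collapse = ", "), "\n", sep = "")
  print(x$dataset)
  invisible(x)
}
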