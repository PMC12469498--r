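#' Score reported interactions against the planted truth
#'
#' A reported SNP set is a true positive iff it matches the planted set:
#' exactly under `match = "exact"` (the default, strictest reading — a
#' superset containing the truth counts as a false positive), or by
#' containment under `match = "contains"`.  With a single planted
#' interaction, recall is 1 if any report matches and 0 otherwise;
#' precision is the matching fraction of reports; the F-measure is their
#' harmonic mean with the 0/0 -> 0 convention.
#'
#' @param reported list of SNP sets (integer indices or identifier
#'   vectors); an empty list means nothing was reported.
#' @param truth the planted SNP set (same identifier space).
#' @param match `"exact"` or `"contains"`.
#' @return list with `precision`, `recall`, `f_measure`, `detected`.
#' @export
score_detection <- function(reported, truth, match = c("exact", "contains")) {
  match <- match.arg(match)
  truth <- sort(unique(truth))
  stopifnot(length(truth) > 0L)
  hit <- vapply(reported, function(s) {
    s <- sort(unique(s))
    if (match == "exact") identical(s, truth) else all(truth %in% s)
  }, logical(1))
  tp <- sum(hit)
  precision <- if (length(reported) == 0L) 0 else tp / length(reported)
  recall <- as.numeric(tp > 0L)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f_measure = f,
       detected = tp > 0L)
}

#' Detection power over a dataset collection
#'
#' @param detected logical vector of per-dataset detection flags.
#' @return Fraction of datasets in which the planted interaction was
#'   identified.
#' @export
power_over <- function(detected) {
  stopifnot(length(detected) >= 1L)
  mean(as.logical(detected))
}

#' Simulate-detect-evaluate benchmark
#'
#' Generates replicate datasets per penetrance model, runs the detector
#' on each, and scores F-measure and power against the planted truth.
#'
#' @param models character vector of penetrance model names.
#' @param n_reps replicate datasets per model.
#' @param n_cases,n_controls,n_snps simulation dimensions.
#' @param order interaction order planted (2 or 3).
#' @param baseline,effect penetrance parameters (alpha, beta).
#' @param mafs causal-locus minor allele frequencies.
#' @param cfg a [gpbso_config()]; its seed seeds replicate `r` of model
#'   `m` as `seed + 1000*(m-1) + r - 1` for both simulation and search.
#' @param match matching rule passed to [score_detection()].
#' @return list with `per_dataset` (one row per model x replicate:
#'   precision, recall, F-measure, detected, reported count) and
#'   `summary` (per model: power, mean F-measure).
#' @export
gpbso_benchmark <- function(models = c("joint_dominant", "joint_recessive",
                                       "modular", "diagonal", "xor"),
                            n_reps = 10L, n_cases = 1000L, n_controls = 1000L,
                            n_snps = 100L, order = 2L, baseline = 0.05,
                            effect = 0.9, mafs = 0.5,
                            cfg = gpbso_config(), match = "exact") {
  rows <- list()
  for (mi in seq_along(models)) {
    spec <- penetrance_spec(models[mi], order = order, baseline = baseline,
                            effect = effect, mafs = mafs)
    for (r in seq_len(n_reps)) {
      seed <- cfg$seed + 1000L * (mi - 1L) + (r - 1L)
      sim <- simulate_epistasis(n_cases, n_controls, n_snps, spec,
                                seed = seed)
      run_cfg <- cfg
      run_cfg$seed <- seed
      res <- gpbso(sim$dataset, run_cfg)
      sc <- score_detection(res$snp_idx, sim$truth, match = match)
      rows[[length(rows) + 1L]] <- data.frame(
        model = models[mi], rep = r, seed = seed,
        precision = sc$precision, recall = sc$recall,
        f_measure = sc$f_measure, detected = sc$detected,
        n_reported = nrow(res), stringsAsFactors = FALSE)
    }
  }
  per_dataset <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_dataset, per_dataset$model),
    function(d) data.frame(model = d$model[1L],
                           power = power_over(d$detected),
                           mean_f_measure = mean(d$f_measure),
                           stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(per_dataset = per_dataset, summary = summary)
}
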