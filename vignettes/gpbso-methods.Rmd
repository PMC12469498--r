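---
title: "Methods: gene-pool Brain Storm Optimization for epistasis detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-pool Brain Storm Optimization for epistasis detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpbso)
```

This vignette describes the statistical model, the search procedure, the
tunable parameters, and the design choices behind `gpbso`, in the spirit
of a methods section: everything a user needs to judge what the package
computes and what its tests do and do not establish.

## Data model and storage

Input is a case–control genotype matrix: one row per sample, one column
per biallelic SNP coded 0/1/2 as the number of minor-allele copies, and a
final 0/1 class column (0 = control, 1 = case). Internally each locus is
held as three packed bit-vectors per phenotype class — bit *s* of vector
*g* is set iff sample *s* carries genotype *g* — so the count of samples
with a given multi-locus genotype configuration is a word-wise AND chain
followed by a popcount. For an *L*-SNP combination the full
3^*L*-cell contingency table costs O(S·L·3^L) bit operations, which is
what makes score evaluation inside a stochastic search affordable.

Missing genotypes are rejected rather than imputed: the representation's
core invariant — each sample contributes exactly one set bit across the
three genotype masks of a locus — cannot be maintained under missingness,
and silent imputation would bias the downstream counts. Input files with
missing cells fail loudly with the offending row and column named.

## Association score and significance

A SNP set $S$ is scored against the phenotype $Y$ with the K2
Bayesian-network marginal-likelihood criterion in negative-log form,

$$k2(Y,S) \;=\; \sum_{c\,\in\, C}\Big[\ln\big((m_{c,*}+1)!\big)
 - \ln\big(m_{c,0}!\big) - \ln\big(m_{c,1}!\big)\Big],$$

where $C$ is the set of genotype configurations of $S$, and $m_{c,0}$,
$m_{c,1}$, $m_{c,*}$ are the control, case, and total counts in cell
$c$. Lower values indicate stronger association. The raw product form of
this criterion under- or overflows at realistic sample sizes, so all
evaluation is in log space through the log-gamma function; the two
routes agree to better than $10^{-9}$ relative error on the table sizes
the tests exercise.

Each candidate is greedily pruned: deletion candidates are scanned in
index order and the **first** single-SNP deletion that **strictly**
lowers $k2$ is accepted, after which the scan restarts; pruning stops at
a local minimum or when one SNP remains. The surviving set is reported
only if it still has at least two SNPs. Consequences guaranteed by
construction and verified by tests: the pruned score never exceeds the
input score, and no further single deletion strictly improves it. Exact
score ties are *not* accepted as deletions, so on degenerate inputs
(e.g. duplicated columns) a deletion that would leave the score unchanged
keeps the larger set.

Significance of a pruned set uses the likelihood-ratio G-test,
$G = 2\sum_c\sum_j m_{c,j}\ln\!\big(m_{c,j}m/(m_{c,*}m_{*,j})\big)$ with
zero-count terms contributing 0, referred to a chi-squared distribution.
Degrees of freedom count only genotype configurations actually observed,
minus one: high-order tables are mostly empty cells, and the naive
$3^L-1$ rule would badly inflate the dof and destroy power; the naive
rule remains available via `g_test(..., dof = "full")` for comparison.
Under a zero-effect simulation the empirical rejection rate at
$\alpha \in \{0.01, 0.05\}$ stays within binomial sampling error of
$\alpha$ (the suite checks this at 2000 replicates of 200 samples). The
default reporting threshold is $0.05/\binom{N}{2}$, a Bonferroni bound
over SNP pairs — deliberately conservative, and user-overridable since
the appropriate correction depends on how many candidates a run
effectively examines.

## The search

The maximum interaction order is estimated from the smaller class size
$n$ as $\lfloor \ln n - 0.5\rfloor$, capped at the largest $k$ with
$3^k \le n/3$ (about three samples per cell of a full table) and floored
at 2. At $n = 1000$ this gives order 5.

The population of `pop_size` SNP sets is initialized by sampling disjoint
SNP sets while the supply lasts (maximizing initial coverage), then
clustered into `n_groups` discussion groups with k-means++ seeding and at
most 20 Lloyd iterations. Individuals are embedded as binary membership
vectors over the $N$ loci; squared Euclidean distance on this embedding
is twice the set Hamming distance for equal-size sets. This embedding was
an open design point: the SNP set is the only representation an
individual has, so its indicator vector is the natural feature space.

Per generation, one candidate is produced by one of three mechanisms
(default probabilities 0.4/0.3/0.3, a user-settable choice; the method
description fixes the mechanisms but not their mixture):

- **idea fusion** — in the group whose best member has the lowest $k2$,
  two distinct members are drawn rank-weighted from the better half, and
  the first $\lceil mo/2\rceil$ SNPs of one are joined with the last
  $mo - \lceil mo/2\rceil$ of the other; duplicate indices are repaired
  from the gene pool;
- **inspiration sparking** — a rank-weighted member of a random group
  keeps its first $\lceil mo/2\rceil$ SNPs and redraws the rest from the
  pool;
- **free association** — $mo$ distinct SNPs drawn uniformly from the
  pool (shortfall from the remaining loci).

"First half" refers to the sorted SNP list, the canonical form
individuals are kept in. The candidate is scored, pruned and G-tested;
every *new* pruned set (deduplicated by its sorted SNP tuple) that
passes the threshold is accumulated into the result set. Accumulating
from every evaluated candidate, rather than only from the final
population, was an open choice; it maximizes recall and costs only the
dedup lookup.

Replacement is steady-state: the candidate competes with the worst
member of the group nearest to it (same distance as the clustering) and
replaces it only on strict improvement. One guard supplements this rule:
a candidate identical to a live individual is rejected outright. Without
it, the best group drifts toward clones of its best member, and fusing
two identical parents regenerates the same set forever — at small $N$
this measurably starves exploration (a strongly planted pair could stay
unreachable for $10^4$ generations). Clone suppression preserves exactly
the diversity the discussion-group structure is meant to provide. On
eviction, each SNP of the removed individual returns to the gene pool iff
no surviving individual carries it; the pool is therefore disjoint from
the population at every step, an invariant the tests hammer with $10^4$
randomized updates. Groups are re-clustered every `pop_size * 10`
generations — re-clustering every generation would dominate runtime at
GWAS scale for no observed benefit at test scale.

All randomness flows from a single integer seed; two runs with the same
seed and input produce byte-identical output files.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `pop_size` | 100 | live candidate sets; 50–200 is the sensible range |
| `max_gen` | 10000 | candidates generated; $10^6$–$8\times10^7$ for real GWAS panels, $10^4$–$10^5$ at benchmark scale |
| `order` | −1 | maximum order; −1 estimates it from the sample sizes |
| `n_groups` | 5 | discussion groups |
| `gen_probs` | 0.4, 0.3, 0.3 | fusion / sparking / free-association mixture |
| `sig_threshold` | $0.05/\binom{N}{2}$ | G-test reporting threshold |
| `seed` | 0 | master seed |

## The simulator

`simulate_epistasis()` plants one interacting SNP set in a panel of
otherwise independent noise loci. Every locus is sampled under
Hardy–Weinberg equilibrium (minor-allele count $\sim$ Binomial(2, MAF));
noise MAFs are drawn uniformly from [0.05, 0.5]. Disease status is
Bernoulli with probability $\alpha + \beta\, I(g)$, where $I$ is the 0/1
indicator of the chosen two-locus model (joint-dominant,
joint-recessive, modular, diagonal, XOR — the XOR here is the XOR of
homozygous-minor status) and $\alpha,\beta$ are the baseline and effect
penetrances. Sampling is rejected until exactly the requested case and
control counts are collected; because noise loci are independent of
phenotype, they are drawn after acceptance, which is distributionally
identical and much cheaper. Third-order versions of the five models are
explicit conventions documented in `?penetrance_spec` (e.g.
joint-recessive = homozygous minor at every locus; XOR = odd number of
carrier loci); a custom penetrance table can be supplied for anything
else.

What the simulator deliberately does **not** model: linkage
disequilibrium, haplotype block structure, departures from
Hardy–Weinberg equilibrium, covariates, and missing genotypes. Passing
tests on these synthetic data therefore demonstrate correctness of the
counting, scoring and search machinery and calibration under
independence — not robustness to the correlation structure of real
genotype panels, where nearby proxies of a causal SNP can dilute
exact-set detection metrics.

## Evaluation

`score_detection()` uses exact-set matching by default: a reported set is
a true positive iff it equals the planted set; a strict superset counts
as a false positive. This is the strictest reading and makes the
F-measure penalize over-reporting; `match = "contains"` relaxes it.
F-measure is computed per dataset and `power_over()` aggregates detection
flags across datasets, matching a boxplot-style presentation of
per-dataset scores rather than pooling counts.

## Numerical and degenerate-input choices

- Scores are compared with strict `<` everywhere (pruning, replacement);
  ties preserve the incumbent, making runs deterministic given the seed.
- `g_stat` is clamped at 0 to absorb $-10^{-14}$-scale rounding on
  homogeneous tables; a table with a single occupied configuration gets
  $G = 0$, dof 1, p = 1.
- Contingency-table order is budgeted (`options(gpbso.max_cells = 3^12)`
  by default); larger requests error with advice rather than exhausting
  memory.
- Empty gene pool is legal (it happens whenever `pop_size * mo` exceeds
  `N`, warned about at initialization): pool draws fall back to uniform
  draws over the unused loci.
- The rejection sampler errors after a bounded budget when a penetrance
  configuration makes one class practically unreachable (e.g. all-zero
  penetrance), rather than looping forever.

## Scale of the shipped experiments

The test suite and `scripts/acceptance.R` run the full pipeline at a
deliberately desk-sized version of the simulated study design: 100 SNPs,
1000 cases + 1000 controls, strong-effect XOR interactions, 10 replicate
datasets at order 2 (and 5 at order 3), `pop_size = 100`,
`max_gen = 10^5`. These sizes exercise every code path, including the
automatic order estimate of 5, while keeping a complete run in minutes;
power at weaker effect sizes or on 10^4+-SNP panels is a function of
`max_gen` and is not characterized by the shipped experiments.

## Known limitations

- The search is stochastic: absence of a reported interaction is not
  evidence of absence, particularly at small `max_gen`.
- Reported p-values are selected by a search that favors low-$k2$ (hence
  low-p) sets; they are meaningful as ranking scores and against the
  conservative default threshold, but are not post-selection-corrected.
- Exact-set matching means a reported superset of the truth counts
  against precision even though it contains the signal; use
  `match = "contains"` when that is the question.
- No support for PLINK/VCF input, genotype QC, LD-aware analysis, or
  covariate adjustment; the canonical table format is the interface.
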