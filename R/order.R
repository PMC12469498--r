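#' Estimate the maximum interaction order from the sample size
#'
#' The search does not require a preset interaction order.  Let `n` be the
#' smaller of the control and case counts.  The raw estimate is
#' `floor(ln(n) - 0.5)`; it is then capped so that a full contingency
#' table at the returned order keeps roughly three samples per cell
#' (largest `k` with `3^k <= n/3`), and never drops below 2.
#'
#' @param n_controls,n_cases class sample counts (>= 1).
#' @return Integer maximum order `mo >= 2`.
#' @export
estimate_max_order <- function(n_controls, n_cases) {
  stopifnot(n_controls >= 1, n_cases >= 1)
  n <- min(n_controls, n_cases)
  if (n < 27) {
    warning("smaller class has ", n, " samples (< 27): cannot support ",
            "order 2 at ~3 samples per cell; forcing mo = 2")
    return(2L)
  }
  raw <- as.integer(floor(log(n) - 0.5))
  cap <- 0L
  while (3^(cap + 1L) <= n / 3) cap <- cap + 1L
  max(2L, min(raw, cap))
}
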