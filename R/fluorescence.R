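#' Simulate a reporter-fluorescence population
#'
#' Generates per-cell reporter intensities as a two-component log-normal
#' mixture: a minority high mode (reporter-high altruists) and a majority
#' low mode. Mirrors the promoter-reporter populations that are
#' FACS-sorted at top/bottom intensity thresholds.
#'
#' @param n_cells Number of cells.
#' @param high_weight Mixture weight of the high mode, in `(0, 0.5)`.
#' @param meanlog_low,meanlog_high Log-scale means of the two modes
#'   (arbitrary fluorescence units; defaults give a ~10-fold separation).
#' @param sdlog Common log-scale standard deviation of both modes.
#' @param seed Integer RNG seed.
#' @return A tibble of class `coop_fluorescence` with columns `cell`,
#'   `intensity` and `mode` (`"high"`/`"low"`, the generating component).
#' @export
simulate_fluorescence <- function(n_cells, high_weight = 0.1,
                                  meanlog_low = log(100),
                                  meanlog_high = log(1000),
                                  sdlog = 0.4, seed = NULL) {
  if (n_cells < 1) abort("`n_cells` must be >= 1.", class = "coopcell_error_param")
  if (high_weight <= 0 || high_weight >= 0.5) {
    abort("`high_weight` must be in (0, 0.5).", class = "coopcell_error_param")
  }
  check_positive(sdlog, "sdlog", strict = FALSE)
  with_seed(seed, {
    mode <- ifelse(runif(n_cells) < high_weight, "high", "low")
    intensity <- rlnorm(n_cells,
                        meanlog = ifelse(mode == "high", meanlog_high, meanlog_low),
                        sdlog = sdlog)
  })
  out <- tibble(cell = seq_len(n_cells), intensity = intensity, mode = mode)
  class(out) <- c("coop_fluorescence", class(out))
  out
}

#' Sort a fluorescence population at top/bottom quantile thresholds
#'
#' Splits a population into its brightest and dimmest fractions using
#' maximum and minimum intensity thresholds at quantile `q` (default 10\%),
#' as in reporter-based FACS sorting. The two subsets are disjoint and each
#' contains `round(q * n)` cells.
#'
#' @param pop A `coop_fluorescence` tibble (or any tibble with an
#'   `intensity` column).
#' @param q Sorting quantile, in `(0, 0.5)`.
#' @return A list with tibbles `high` and `low`.
#' @export
sort_fractions <- function(pop, q = 0.10) {
  if (q <= 0 || q >= 0.5) abort("`q` must be in (0, 0.5).", class = "coopcell_error_param")
  n <- nrow(pop)
  n_take <- round(q * n)
  if (n < 1 / q || n_take < 1) {
    abort("Population too small to form top/bottom fractions at this `q`.",
          class = "coopcell_error_degenerate")
  }
  if (length(unique(pop$intensity)) == 1) {
    abort("Degenerate population: all intensities identical; quantile gates undefined.",
          class = "coopcell_error_degenerate")
  }
  ord <- order(pop$intensity)
  list(high = pop[ord[seq(n - n_take + 1, n)], , drop = FALSE],
       low = pop[ord[seq_len(n_take)], , drop = FALSE])
}
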