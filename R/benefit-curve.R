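#' Percentage benefit attained at each altruist percentage
#'
#' Rescales bulk viability readouts of an altruist-titration series onto a
#' 0–100 benefit scale anchored at the 0\% and 50\% altruist wells:
#' \deqn{PB(x) = 100 \times \frac{R(x) - R(0)}{R(50) - R(0)}}
#' so that `PB(0) = 0` and `PB(50) = 100` identically.
#'
#' @param readouts A data frame with columns `percent` (altruist percentage
#'   of the well) and `viability` (e.g. an MTS reading); replicate rows per
#'   percent are averaged first unless `per_replicate = TRUE`. A
#'   `coop_benefit_series` tibble works directly.
#' @param per_replicate When `TRUE` and a `replicate` column is present,
#'   the benefit is computed within each replicate against that
#'   replicate's own anchors, yielding one curve per replicate (useful for
#'   curve fitting with realistic degrees of freedom).
#' @return A tibble with columns `percent`, `viability` and
#'   `percentage_benefit` (plus `replicate` in per-replicate mode).
#' @examples
#' pb <- percentage_benefit(
#'   data.frame(percent = c(0, 10, 50), viability = c(0.40, 0.75, 0.90)))
#' pb$percentage_benefit  # 0, 70, 100
#' @export
percentage_benefit <- function(readouts, per_replicate = FALSE) {
  stopifnot(all(c("percent", "viability") %in% names(readouts)))
  if (per_replicate && "replicate" %in% names(readouts)) {
    out <- readouts %>%
      as_tibble() %>%
      dplyr::group_split(.data$replicate) %>%
      purrr::map(function(g) {
        pb <- percentage_benefit(select(g, "percent", "viability"))
        pb$replicate <- g$replicate[1]
        pb
      }) %>%
      bind_rows()
    return(out)
  }
  means <- readouts %>%
    group_by(.data$percent) %>%
    summarise(viability = mean(.data$viability), .groups = "drop") %>%
    arrange(.data$percent)
  if (!all(c(0, 50) %in% means$percent)) {
    abort("Readouts must include the 0% and 50% anchor wells.",
          class = "coopcell_error_param")
  }
  r0 <- means$viability[means$percent == 0]
  r50 <- means$viability[means$percent == 50]
  if (r50 == r0) {
    abort("Degenerate anchors: readout at 50% equals readout at 0%.",
          class = "coopcell_error_degenerate")
  }
  mutate(means, percentage_benefit = 100 * (.data$viability - r0) / (r50 - r0))
}

#' Marginal benefit per percentage-point of altruists
#'
#' Rate of change of the percentage benefit between consecutive studied
#' altruist percentages `x` and `y`:
#' \deqn{MB = \frac{PB(y) - PB(x)}{(y - x) + 1}}
#' (the extra 1 in the denominator is part of the definition), reported at
#' the category value `(x + y) / 2`. A strictly decreasing marginal-benefit
#' sequence is the signature of a saturating benefit curve.
#'
#' @param pb A data frame with columns `percent` and `percentage_benefit`
#'   (as returned by [percentage_benefit()]), at least two rows.
#' @return A tibble with `category` (`(x + y) / 2`), `from`, `to` and
#'   `marginal_benefit`, ordered by category value.
#' @examples
#' marginal_benefit(data.frame(percent = c(0, 1), percentage_benefit = c(0, 30)))
#' @export
marginal_benefit <- function(pb) {
  stopifnot(all(c("percent", "percentage_benefit") %in% names(pb)))
  pb <- arrange(pb, .data$percent)
  if (anyDuplicated(pb$percent)) {
    abort("Duplicate altruist percentages.", class = "coopcell_error_param")
  }
  if (nrow(pb) < 2) abort("At least two points required.", class = "coopcell_error_param")
  x <- pb$percent[-nrow(pb)]
  y <- pb$percent[-1]
  pbx <- pb$percentage_benefit[-nrow(pb)]
  pby <- pb$percentage_benefit[-1]
  tibble(category = (x + y) / 2, from = x, to = y,
         marginal_benefit = (pby - pbx) / ((y - x) + 1))
}

#' Fit linear and quadratic models to a percentage-benefit curve
#'
#' Ordinary least-squares fits of the percentage benefit against the
#' altruist percentage for degree-1 and degree-2 polynomials, with the
#' best-fit shape selected by the nested-model F-test at level `alpha`. A
#' preferred quadratic with negative curvature indicates a saturating
#' benefit.
#'
#' @param pb A data frame with columns `percent` and `percentage_benefit`;
#'   at least 4 points for the quadratic fit.
#' @param alpha Significance level of the nested-model F-test.
#' @return An object of class `coop_benefit_fit`: a list with elements
#'   `linear`, `quadratic` (both `lm` fits), `best_fit`
#'   (`"linear"`/`"quadratic"`), `f_p_value`, `curvature` (the quadratic
#'   coefficient) and `data`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
fit_benefit_curve <- function(pb, alpha = 0.05) {
  stopifnot(all(c("percent", "percentage_benefit") %in% names(pb)))
  pb <- arrange(as_tibble(pb), .data$percent)
  if (nrow(pb) < 4) abort("At least 4 points required for the quadratic fit.",
                          class = "coopcell_error_param")
  if (length(unique(pb$percent)) < 3) {
    abort("Rank-deficient design: need at least 3 distinct percentages.",
          class = "coopcell_error_param")
  }
  lin <- lm(percentage_benefit ~ percent, data = pb)
  quad <- lm(percentage_benefit ~ percent + I(percent^2), data = pb)
  cmp <- anova(lin, quad)
  p <- cmp$`Pr(>F)`[2]
  best <- if (!is.na(p) && p < alpha) "quadratic" else "linear"
  structure(list(linear = lin, quadratic = quad, best_fit = best,
                 f_p_value = p, curvature = unname(coef(quad)[3]),
                 alpha = alpha, data = pb),
            class = "coop_benefit_fit")
}

#' @export
print.coop_benefit_fit <- function(x, ...) {
  cat("Percentage-benefit curve fit\n")
  cat(sprintf("  best fit: %s (nested-model F-test p = %.4g)\n", x$best_fit, x$f_p_value))
  cat(sprintf("  quadratic curvature: %.4g (%s)\n", x$curvature,
              if (is.na(x$curvature)) "NA" else if (x$curvature < 0) "saturating" else "accelerating"))
  invisible(x)
}

#' @rdname fit_benefit_curve
#' @param x A `coop_benefit_fit` object.
#' @param ... Unused.
#' @export
tidy.coop_benefit_fit <- function(x, ...) {
  bind_rows(
    tibble(model = "linear", term = names(coef(x$linear)),
           estimate = unname(coef(x$linear))),
    tibble(model = "quadratic", term = names(coef(x$quadratic)),
           estimate = unname(coef(x$quadratic))))
}

#' @rdname fit_benefit_curve
#' @export
glance.coop_benefit_fit <- function(x, ...) {
  tibble(best_fit = x$best_fit, f_p_value = x$f_p_value,
         curvature = x$curvature,
         rss_linear = sum(stats::residuals(x$linear)^2),
         rss_quadratic = sum(stats::residuals(x$quadratic)^2))
}

#' @rdname fit_benefit_curve
#' @param object A `coop_benefit_fit` object.
#' @export
autoplot.coop_benefit_fit <- function(object, ...) {
  grid <- tibble(percent = seq(min(object$data$percent), max(object$data$percent),
                               length.out = 200))
  grid$linear <- stats::predict(object$linear, grid)
  grid$quadratic <- stats::predict(object$quadratic, grid)
  long <- tidyr::pivot_longer(grid, c("linear", "quadratic"),
                              names_to = "model", values_to = "fit")
  ggplot(object$data, aes(x = .data$percent, y = .data$percentage_benefit)) +
    geom_point() +
    geom_line(data = long, aes(y = .data$fit, colour = .data$model)) +
    labs(x = "Altruist percentage", y = "Percentage benefit",
         colour = "Model",
         subtitle = sprintf("best fit: %s", object$best_fit)) +
    theme_minimal()
}
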