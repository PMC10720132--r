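# Secrete-and-sense lateral inhibition on a lattice: cells with high
# altruist-promoter activity secrete a diffusible inhibitory signal that
# lowers the activity of *other* cells (the secreting cell is insensitive
# to its own product), producing salt-and-pepper alternation at contact
# range and sparse spacing at longer range.

#' Rules of the lateral-inhibition patterning model
#'
#' @param d Signalling range in cell diameters: `1` = contact-only (the 4
#'   von Neumann neighbours, as in juxtacrine Notch-Delta signalling);
#'   `> 1` = uniform disc kernel of radius `d` (diffusible factors acting
#'   equally on all cells within range). The kernel is normalized and its
#'   self-weight is zero — a cell does not sense its own secretion.
#' @param theta Inhibition half-point: sensed signal at which the target
#'   activity is 1/2 (`> 0`). Larger `theta` = weaker inhibition. The
#'   default (0.01) makes a single secreting cell sufficient to suppress
#'   every cell in its range, which yields singleton high-fate cells spaced
#'   by roughly `d`.
#' @param m Hill coefficient of the inhibition function (`>= 1`); must be
#'   steep enough to destabilise the uniform state (default 12).
#' @param r Relaxation rate per step, in `(0, 1]`.
#' @param secretion Secretion function of activity; any nondecreasing
#'   function mapping `[0, 1]` to `[0, Inf)` (default identity).
#' @param antibody_mode When `TRUE`, the diffusible signal is neutralized
#'   beyond the cell-cell interface: the effective kernel is truncated to
#'   the contact kernel regardless of `d` (emulating neutralizing
#'   antibodies that cannot access tight interfaces).
#' @return A list of class `coop_inhibition_rules`.
#' @export
inhibition_rules <- function(d = 1, theta = 0.01, m = 12, r = 0.2,
                             secretion = identity, antibody_mode = FALSE) {
  check_positive(d, "d"); check_positive(theta, "theta")
  if (m < 1) abort("`m` must be >= 1.", class = "coopcell_error_param")
  if (r <= 0 || r > 1) abort("`r` must be in (0, 1].", class = "coopcell_error_param")
  stopifnot(is.function(secretion))
  structure(list(d = d, theta = theta, m = m, r = r, secretion = secretion,
                 antibody_mode = isTRUE(antibody_mode)),
            class = "coop_inhibition_rules")
}

# Contact (d = 1) or uniform-disc (d > 1) kernel with zero self-weight,
# normalized. `L` drops offsets that wrap onto the cell itself on small
# toruses, preserving self-insensitivity.
inhibition_kernel <- function(rules, L = Inf) {
  d_eff <- if (rules$antibody_mode) 1 else rules$d
  if (d_eff <= 1) {
    ker <- list(di = c(1, -1, 0, 0), dj = c(0, 0, 1, -1), w = rep(1 / 4, 4))
  } else {
    r <- floor(d_eff)
    grid <- expand.grid(di = -r:r, dj = -r:r)
    dist <- sqrt(grid$di^2 + grid$dj^2)
    keep <- dist > 0 & dist <= d_eff               # self-weight zero
    if (!any(keep)) abort("Kernel not normalizable.", class = "coopcell_error_param")
    grid <- grid[keep, ]
    ker <- list(di = grid$di, dj = grid$dj,
                w = rep(1 / nrow(grid), nrow(grid)))
  }
  if (is.finite(L)) {
    keep <- !(ker$di %% L == 0 & ker$dj %% L == 0)
    ker <- list(di = ker$di[keep], dj = ker$dj[keep], w = ker$w[keep])
    if (length(ker$w) > 0) ker$w <- ker$w / sum(ker$w)
  }
  ker
}

#' Simulate lateral-inhibition pattern formation
#'
#' Iterates the discrete-time relaxation
#' \deqn{s_i = \sum_j K_d(i, j)\, \mathrm{secretion}(a_j), \qquad
#'       a_i \leftarrow (1 - r) a_i + r\, f(s_i)}
#' with \eqn{f(s) = 1 / (1 + (s/\theta)^m)} on an `L x L` torus, starting
#' from activity `0.5` plus uniform noise, until `steps` are exhausted or
#' the update converges (`max |delta a| < 1e-6`). The binary social fate is
#' `a > 0.5` (high fate = altruist-promoter high).
#'
#' @param L Lattice side length.
#' @param rules An [inhibition_rules()] object.
#' @param init_noise Amplitude of the uniform initial perturbation.
#' @param steps Maximum number of update steps.
#' @param seed Integer RNG seed (determines the initial noise).
#' @return An object of class `coop_fate_field`: list with matrices
#'   `activity` and `signal`, logical matrix `fate` (`TRUE` = high), the
#'   number of `steps_run`, convergence info, and the rules.
#' @export
simulate_pattern <- function(L = 50, rules = inhibition_rules(),
                             init_noise = 0.05, steps = 800, seed = NULL) {
  stopifnot(inherits(rules, "coop_inhibition_rules"), steps >= 1)
  ker <- inhibition_kernel(rules, L = L)
  with_seed(seed, {
    a <- matrix(0.5 + runif(L * L, -init_noise, init_noise), L, L)
  })
  a <- pmin(pmax(a, 0), 1)
  s <- matrix(0, L, L)
  delta <- Inf
  used <- 0
  deltas <- numeric(steps)
  for (t in seq_len(steps)) {
    sec <- rules$secretion(a)
    s <- matrix(0, L, L)
    for (i in seq_along(ker$w)) {
      s <- s + ker$w[i] * mat_shift(sec, ker$di[i], ker$dj[i])
    }
    target <- 1 / (1 + (s / rules$theta)^rules$m)
    a_new <- (1 - rules$r) * a + rules$r * target
    delta <- max(abs(a_new - a))
    a <- a_new
    used <- t
    deltas[t] <- delta
    if (delta < 1e-6) break
  }
  structure(list(activity = a, signal = s, fate = a > 0.5,
                 steps_run = used, converged = delta < 1e-6,
                 delta_history = deltas[seq_len(used)], rules = rules),
            class = "coop_fate_field")
}

#' Pattern statistics of a binary fate field
#'
#' Quantifies a lateral-inhibition pattern: the high-fate fraction; the
#' lag-1 join-count autocorrelation (Pearson correlation of the fate
#' indicator over all 4-neighbour pairs, periodic wrap) — negative values
#' diagnose salt-and-pepper alternation; and the mean toroidal
#' nearest-neighbour distance among high-fate cells — large values diagnose
#' sparse spacing.
#'
#' @param field A `coop_fate_field`, or a logical/0-1 matrix of fates.
#' @return A tibble with `high_fraction`, `lag1_autocorr` (`NA` sentinel
#'   when the fates have zero variance) and `mean_nn_distance` (`NA`
#'   sentinel when fewer than two high-fate cells exist).
#' @examples
#' cb <- outer(1:10, 1:10, function(i, j) (i + j) %% 2 == 1)
#' pattern_stats(cb)  # high_fraction 0.5, lag1 -1, nn sqrt(2)
#' @export
pattern_stats <- function(field) {
  fate <- if (inherits(field, "coop_fate_field")) field$fate else field
  fate <- matrix(as.numeric(fate), nrow(fate), ncol(fate))
  if (length(fate) == 0) abort("Empty grid.", class = "coopcell_error_param")
  hf <- mean(fate)
  # all horizontal and vertical neighbour pairs with periodic wrap
  pairs_a <- c(fate, fate)
  pairs_b <- c(mat_shift(fate, 1, 0), mat_shift(fate, 0, 1))
  lag1 <- if (stats::sd(pairs_a) == 0 || stats::sd(pairs_b) == 0) {
    NA_real_
  } else {
    stats::cor(pairs_a, pairs_b)
  }
  idx <- which(fate == 1, arr.ind = TRUE)
  nn <- if (nrow(idx) < 2) NA_real_ else {
    L1 <- nrow(fate); L2 <- ncol(fate)
    di <- abs(outer(idx[, 1], idx[, 1], "-"))
    dj <- abs(outer(idx[, 2], idx[, 2], "-"))
    di <- pmin(di, L1 - di)
    dj <- pmin(dj, L2 - dj)
    dist <- sqrt(di^2 + dj^2)
    diag(dist) <- Inf
    mean(apply(dist, 1, min))
  }
  tibble(high_fraction = hf, lag1_autocorr = lag1, mean_nn_distance = nn)
}

#' Antibody-truncation scenario
#'
#' Simulates a long-range (`d > 1`) lateral-inhibition pattern with and
#' without neutralizing antibodies that restrict the secreted signal to the
#' cell-cell contact interface. Truncation restores the contact-range
#' salt-and-pepper signature (negative lag-1 autocorrelation) and raises
#' the high-fate fraction relative to the untruncated long-range run.
#'
#' @param rules Base [inhibition_rules()] with `d > 1`.
#' @param L,init_noise,steps,seed Passed to [simulate_pattern()].
#' @return A list with fields `untreated` and `antibody` (both
#'   `coop_fate_field`) and a `stats` tibble comparing the two.
#' @export
antibody_scenario <- function(rules, L = 50, init_noise = 0.05, steps = 800,
                              seed = NULL) {
  stopifnot(inherits(rules, "coop_inhibition_rules"))
  if (rules$d <= 1) {
    abort("Antibody scenario requires a base range d > 1.", class = "coopcell_error_param")
  }
  ab_rules <- rules
  ab_rules$antibody_mode <- TRUE
  untreated <- simulate_pattern(L, rules, init_noise, steps, seed)
  antibody <- simulate_pattern(L, ab_rules, init_noise, steps, seed)
  stats <- bind_rows(
    mutate(pattern_stats(untreated), condition = "untreated"),
    mutate(pattern_stats(antibody), condition = "antibody"))
  list(untreated = untreated, antibody = antibody, stats = stats)
}

#' @rdname simulate_pattern
#' @param object A `coop_fate_field`.
#' @param ... Unused.
#' @export
autoplot.coop_fate_field <- function(object, ...) {
  df <- tidyr::expand_grid(col = seq_len(ncol(object$fate)),
                           row = seq_len(nrow(object$fate)))
  df$fate <- as.vector(object$fate)  # column-major: row varies fastest
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$fate)) +
    geom_raster() +
    scale_fill_manual(values = c("FALSE" = "grey90", "TRUE" = "steelblue"),
                      labels = c("low", "high"), name = "Fate") +
    coord_equal() +
    labs(x = NULL, y = NULL) +
    theme_void()
}
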