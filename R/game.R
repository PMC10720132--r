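#' Well-mixed nonlinear public-goods game
#'
#' Defines the two-strategy evolutionary game between altruistic producers
#' of a diffusible survival factor and non-producing defectors in a
#' well-mixed population under therapy. Producer fitness is
#' \eqn{W_A = s_A(\tau) (1 - c)}: intrinsic drug tolerance discounted by the
#' per-division production cost, independent of the population composition
#' (the good is others-only). Defector fitness is
#' \eqn{W_D(x) = \sigma_0(\tau) + (1 - \sigma_0(\tau)) V(x)}: the bare
#' survival baseline under therapy intensity \eqn{\tau} plus the rescued
#' fraction supplied by the saturating benefit [hill_benefit()] at producer
#' frequency `x`. Because V is concave, defector fitness is frequency
#' dependent — defectors do worse the rarer the producers are — which under
#' therapy creates a stable interior equilibrium with producers at a
#' minority frequency.
#'
#' @param B,k,h Benefit parameters, see [hill_benefit()]. Concavity is
#'   required (asserted) when `h <= 1`.
#' @param c Producer cost in `[0, 1)`.
#' @param tau Therapy intensity in `[0, 1]`.
#' @param s_A Producer intrinsic survival under therapy. Defaults to
#'   `s_A_default(tau)`.
#' @param sigma0 Defector baseline survival under therapy, strictly
#'   decreasing in `tau`. Defaults to `sigma0_default(tau)`.
#' @param n Group size for the group-sampled variant (`n >= 2`), or `Inf`
#'   (default) for the mean-field game, in which each defector experiences
#'   the population producer frequency directly.
#' @return An object of class `coop_game`.
#' @examples
#' g <- public_goods_game(tau = 1)
#' find_equilibria(g)
#' @export
public_goods_game <- function(B = 0.9, k = 0.05, h = 1, c = 0.2, tau = 1,
                              s_A = s_A_default(tau),
                              sigma0 = sigma0_default(tau), n = Inf) {
  check_prob(B, "B"); check_prob(tau, "tau"); check_prob(s_A, "s_A")
  check_prob(sigma0, "sigma0")
  if (c < 0 || c >= 1) abort("`c` must be in [0, 1).", class = "coopcell_error_param")
  if (!is.infinite(n) && n < 2) abort("`n` must be >= 2 or Inf.", class = "coopcell_error_param")
  if (h <= 1 && !is_concave_benefit(B, k, h)) {
    abort("Benefit function must be concave for h <= 1.", class = "coopcell_error_param")
  }
  structure(list(B = B, k = k, h = h, c = c, tau = tau, s_A = s_A,
                 sigma0 = sigma0, n = n),
            class = "coop_game")
}

#' Default therapy-response curves of the two strategies
#'
#' `sigma0_default(tau) = 1 - 0.9 tau`: defector baseline survival falls
#' steeply with therapy intensity. `s_A_default(tau) = 1 - 0.05 tau`:
#' producers are relatively drug tolerant, declining far more slowly. At
#' `tau = 0` both equal 1 (no drug), so costly producers are always
#' disfavoured without therapy.
#'
#' @param tau Therapy intensity in `[0, 1]` (vectorised).
#' @return Survival probability.
#' @export
sigma0_default <- function(tau) 1 - 0.9 * tau

#' @rdname sigma0_default
#' @export
s_A_default <- function(tau) 1 - 0.05 * tau

#' Strategy fitness functions of a public-goods game
#'
#' Producer fitness `W_A` (constant in `x`) and defector fitness `W_D(x)`.
#' In the group-sampled variant (`n < Inf`) a defector samples `n - 1`
#' partners binomially at producer frequency `x` and experiences
#' `E[V(j / (n - 1))]`; as `n` grows this converges to the mean-field
#' `V(x)`.
#'
#' @param game A [public_goods_game()].
#' @param x Producer frequency, in `[0, 1]` (vectorised).
#' @return A tibble with columns `x`, `W_A`, `W_D`.
#' @export
fitness_functions <- function(game, x) {
  stopifnot(inherits(game, "coop_game"))
  if (any(x < 0 | x > 1)) abort("`x` must be in [0, 1].", class = "coopcell_error_param")
  W_A <- game$s_A * (1 - game$c)
  v <- if (is.infinite(game$n)) {
    hill_benefit(x, game$B, game$k, game$h)
  } else {
    m <- game$n - 1
    vapply(x, function(xi) {
      j <- 0:m
      sum(dbinom(j, m, xi) * hill_benefit(j / m, game$B, game$k, game$h))
    }, numeric(1))
  }
  tibble(x = x, W_A = W_A, W_D = game$sigma0 + (1 - game$sigma0) * v)
}

#' Gain function of the game
#'
#' `G(x) = W_A - W_D(x)`: positive where producers are favoured. Interior
#' zeros of `G` are the polymorphic equilibria of the replicator dynamics.
#'
#' @inheritParams fitness_functions
#' @return Numeric vector `G(x)`.
#' @export
gain_function <- function(game, x) {
  w <- fitness_functions(game, x)
  w$W_A - w$W_D
}

#' Find and classify the equilibria of a public-goods game
#'
#' Locates interior roots of the gain function by sign-change bracketing on
#' a uniform grid followed by bisection, and classifies their stability: an
#' interior root is stable iff `G > 0` on its left and `G < 0` on its right
#' (producers invade when rare, defectors when common). The boundary `x = 0`
#' is stable iff `G(0) < 0`, and `x = 1` iff `G(1) > 0`.
#'
#' @param game A [public_goods_game()].
#' @param grid_n Number of grid points for bracketing (default 1e4).
#' @param tol Bisection tolerance (default 1e-10).
#' @return An object of class `coop_equilibria`: list with tibble
#'   `interior` (columns `x_star`, `stable`), tibble `boundary`, and the
#'   game. `tidy()` returns the combined table.
#' @export
find_equilibria <- function(game, grid_n = 1e4, tol = 1e-10) {
  stopifnot(inherits(game, "coop_game"))
  check_positive(tol, "tol")
  xs <- seq(0, 1, length.out = grid_n)
  g <- gain_function(game, xs)
  if (any(!is.finite(g))) abort("Non-finite gain function.", class = "coopcell_error_param")
  roots <- numeric(0)
  for (i in seq_len(grid_n - 1)) {
    g1 <- g[i]; g2 <- g[i + 1]
    if (g1 == 0 && xs[i] > 0) {
      roots <- c(roots, xs[i])
    } else if (g1 * g2 < 0) {
      r <- uniroot(function(z) gain_function(game, z), c(xs[i], xs[i + 1]),
                   tol = tol)$root
      roots <- c(roots, r)
    }
  }
  roots <- sort(unique(roots[roots > tol & roots < 1 - tol]))
  eps <- max(tol * 10, 1e-8)
  stable <- vapply(roots, function(r) {
    gl <- gain_function(game, max(r - eps, 0))
    gr <- gain_function(game, min(r + eps, 1))
    gl > 0 && gr < 0
  }, logical(1))
  g0 <- gain_function(game, 0)
  g1 <- gain_function(game, 1)
  structure(list(
    interior = tibble(x_star = roots, stable = stable),
    boundary = tibble(x = c(0, 1), stable = c(g0 < 0, g1 > 0), gain = c(g0, g1)),
    game = game), class = "coop_equilibria")
}

#' @export
print.coop_equilibria <- function(x, ...) {
  cat("Public-goods game equilibria\n")
  if (nrow(x$interior) == 0) {
    cat("  no interior equilibrium\n")
  } else {
    for (i in seq_len(nrow(x$interior))) {
      cat(sprintf("  x* = %.6f (%s)\n", x$interior$x_star[i],
                  if (x$interior$stable[i]) "stable" else "unstable"))
    }
  }
  cat(sprintf("  boundaries: x=0 %s, x=1 %s\n",
              if (x$boundary$stable[1]) "stable" else "unstable",
              if (x$boundary$stable[2]) "stable" else "unstable"))
  invisible(x)
}

#' @rdname find_equilibria
#' @param x A `coop_equilibria` object.
#' @param ... Unused.
#' @export
tidy.coop_equilibria <- function(x, ...) {
  bind_rows(
    mutate(x$interior, type = "interior") %>% rename(x = "x_star"),
    mutate(select(x$boundary, -"gain"), type = "boundary"))
}

#' Integrate the replicator dynamics of the game
#'
#' Integrates \eqn{dx/dt = x (1 - x) G(x)} with a fixed-step classical
#' fourth-order Runge-Kutta scheme. The boundaries `x = 0` and `x = 1` are
#' exact fixed points; the trajectory is clipped to `[0, 1]` within
#' integrator tolerance.
#'
#' @param game A [public_goods_game()].
#' @param x0 Initial producer frequency in `[0, 1]`.
#' @param t_end Final time.
#' @param dt Step size (> 0).
#' @return A tibble of class `coop_trajectory` with columns `time`, `x`;
#'   attributes `game`, `dt`.
#' @export
integrate_replicator <- function(game, x0, t_end = 200, dt = 0.1) {
  stopifnot(inherits(game, "coop_game"))
  if (x0 < 0 || x0 > 1) abort("`x0` must be in [0, 1].", class = "coopcell_error_param")
  check_positive(dt, "dt"); check_positive(t_end, "t_end")
  f <- function(x) x * (1 - x) * gain_function(game, x)
  n_steps <- ceiling(t_end / dt)
  xs <- numeric(n_steps + 1)
  xs[1] <- x0
  x <- x0
  for (i in seq_len(n_steps)) {
    k1 <- f(x)
    k2 <- f(min(max(x + dt / 2 * k1, 0), 1))
    k3 <- f(min(max(x + dt / 2 * k2, 0), 1))
    k4 <- f(min(max(x + dt * k3, 0), 1))
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    x <- min(max(x, 0), 1)
    xs[i + 1] <- x
  }
  out <- tibble(time = seq(0, by = dt, length.out = n_steps + 1), x = xs)
  attr(out, "game") <- game
  attr(out, "dt") <- dt
  class(out) <- c("coop_trajectory", class(out))
  out
}

#' @rdname integrate_replicator
#' @param object A `coop_trajectory` tibble.
#' @param ... Unused.
#' @export
autoplot.coop_trajectory <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$x)) +
    geom_line() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Time", y = "Producer frequency x") +
    theme_minimal()
}

#' Stable producer frequency across a therapy sweep
#'
#' For each therapy intensity on the grid, builds the game with the given
#' therapy-response curves and reports the stable interior equilibrium (or
#' 0 when none exists). Under the stated preconditions — `sigma0_fun`
#' strictly decreasing and `s_A_fun` nonincreasing no faster than
#' `sigma0_fun` — the curve is nondecreasing: more therapy supports more
#' altruistic cooperation.
#'
#' @param tau_grid Therapy intensities in `[0, 1]`.
#' @param B,k,h,c,n Game parameters, see [public_goods_game()].
#' @param sigma0_fun,s_A_fun Therapy-response curves (functions of `tau`).
#' @param grid_n,tol Passed to [find_equilibria()].
#' @return A tibble of class `coop_sweep` with columns `tau`, `x_star`,
#'   `interior` (logical: interior equilibrium found).
#' @export
therapy_sweep <- function(tau_grid = seq(0, 1, length.out = 50),
                          B = 0.9, k = 0.05, h = 1, c = 0.2, n = Inf,
                          sigma0_fun = sigma0_default, s_A_fun = s_A_default,
                          grid_n = 1e4, tol = 1e-10) {
  if (any(tau_grid < 0 | tau_grid > 1)) {
    abort("`tau_grid` must lie in [0, 1].", class = "coopcell_error_param")
  }
  tau_grid <- sort(tau_grid)
  s0 <- sigma0_fun(tau_grid)
  sa <- s_A_fun(tau_grid)
  if (length(tau_grid) > 1) {
    d_s0 <- diff(s0); d_sa <- diff(sa)
    if (any(d_s0 >= 0)) {
      abort("`sigma0_fun` must be strictly decreasing in tau.",
            class = "coopcell_error_param")
    }
    if (any(d_sa > 0) || any(d_sa < d_s0)) {
      abort("`s_A_fun` must be nonincreasing, and no faster than `sigma0_fun`.",
            class = "coopcell_error_param")
    }
  }
  rows <- purrr::map2(tau_grid, seq_along(tau_grid), function(tau, i) {
    game <- public_goods_game(B = B, k = k, h = h, c = c, tau = tau,
                              s_A = sa[i], sigma0 = s0[i], n = n)
    eq <- find_equilibria(game, grid_n = grid_n, tol = tol)
    stable <- filter(eq$interior, .data$stable)
    if (nrow(stable) > 0) {
      tibble(tau = tau, x_star = stable$x_star[1], interior = TRUE)
    } else {
      # no interior equilibrium: population fixes at a stable boundary
      x_fix <- if (eq$boundary$stable[2]) 1 else 0
      tibble(tau = tau, x_star = x_fix, interior = FALSE)
    }
  })
  out <- bind_rows(rows)
  class(out) <- c("coop_sweep", class(out))
  out
}

#' @rdname therapy_sweep
#' @param object A `coop_sweep` tibble.
#' @param ... Unused.
#' @export
autoplot.coop_sweep <- function(object, ...) {
  ggplot(object, aes(x = .data$tau, y = .data$x_star)) +
    geom_line() +
    geom_point(aes(shape = .data$interior)) +
    labs(x = expression(paste("Therapy intensity ", tau)),
         y = "Stable producer frequency x*") +
    theme_minimal()
}
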