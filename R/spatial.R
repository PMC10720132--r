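# Lattice agent-based model of producers and defectors sharing a
# diffusible public good. Site codes: 0 = empty, 1 = producer, 2 = defector.

#' Rules of the lattice tumor model
#'
#' Parameterises the spatial agent-based model. Producers secrete the
#' public good at rate `secretion` per step; the field diffuses with range
#' `d` and decays by factor `lambda` per step. Survival mirrors the
#' well-mixed game: producers survive a step with probability
#' `1 - death_scale * (1 - (sigma0 + (1 - sigma0) * s_A))`, defectors with
#' `1 - death_scale * (1 - (sigma0 + (1 - sigma0) * V(g)))` where
#' `V(g) = B g / (k_field + g)` is the local benefit of the good. Empty
#' sites left by deaths are filled by a fitness-weighted draw among
#' occupied von Neumann neighbours, producers weighted `1 - c`. Offspring
#' inherit the parental type (`inheritance = "genetic"`) or re-evaluate
#' their fate from the local good (`"epigenetic"`): a new cell becomes a
#' producer with probability \eqn{\pi(g) = 1 / (1 + (g/\theta)^{m})},
#' i.e. preferentially where the good is scarce (best-response
#' regeneration). In epigenetic mode surviving cells also interconvert
#' slowly: defector to producer with probability `switch_rate * pi(g)` per
#' step, producer to defector with `switch_rate * (1 - pi(g))`.
#'
#' @param secretion Good secreted per producer per step.
#' @param d Diffusion range in lattice units (`1` = contact kernel over the
#'   site and its 4 neighbours; `> 1` = truncated Gaussian of sd `d`).
#' @param lambda Decay fraction per step, in `[0, 1]`.
#' @param tau Therapy intensity recorded with the rules (informational).
#' @param sigma0,s_A Per-step survival parameters, in the same roles as in
#'   [public_goods_game()] but on the chronic per-step scale of the
#'   lattice: defaults place fully protected defectors slightly above
#'   producers in survival, so that the producers' growth cost — not raw
#'   drug kill — decides the competition.
#' @param B,k_field Local benefit parameters (`k_field` in concentration
#'   units).
#' @param c Producer birth-weight cost in `[0, 1)`.
#' @param death_scale Per-step mortality scale in `(0, 1]`.
#' @param inheritance `"genetic"` or `"epigenetic"`.
#' @param theta Good concentration at which the producer-fate probability
#'   is 1/2 (`> 0`), epigenetic mode.
#' @param switch_m Steepness of the fate-switch curve.
#' @param switch_rate Per-step interconversion rate of established cells,
#'   epigenetic mode.
#' @param boundary `"periodic"` or `"reflecting"`.
#' @return A list of class `coop_spatial_rules`.
#' @export
spatial_rules <- function(secretion = 1, d = 1, lambda = 0.15, tau = 1,
                          sigma0 = 0.3, s_A = 0.8,
                          B = 0.9, k_field = 0.3, c = 0.5, death_scale = 0.4,
                          inheritance = c("genetic", "epigenetic"),
                          theta = 1, switch_m = 2, switch_rate = 0.02,
                          boundary = c("periodic", "reflecting")) {
  inheritance <- match.arg(inheritance)
  boundary <- match.arg(boundary)
  check_positive(secretion, "secretion", strict = FALSE)
  check_positive(d, "d")
  check_prob(lambda, "lambda"); check_prob(sigma0, "sigma0")
  check_prob(s_A, "s_A"); check_prob(B, "B")
  check_positive(k_field, "k_field"); check_positive(theta, "theta")
  if (c < 0 || c >= 1) abort("`c` must be in [0, 1).", class = "coopcell_error_param")
  if (death_scale <= 0 || death_scale > 1) {
    abort("`death_scale` must be in (0, 1].", class = "coopcell_error_param")
  }
  check_prob(switch_rate, "switch_rate")
  structure(list(secretion = secretion, d = d, lambda = lambda, tau = tau,
                 sigma0 = sigma0, s_A = s_A, B = B, k_field = k_field, c = c,
                 death_scale = death_scale, inheritance = inheritance,
                 theta = theta, switch_m = switch_m, switch_rate = switch_rate,
                 boundary = boundary),
            class = "coop_spatial_rules")
}

#' Initialise a lattice state
#'
#' @param L Lattice side length.
#' @param occupancy Fraction of sites initially occupied.
#' @param producer_fraction Producer fraction among occupied sites, in
#'   `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A list of class `coop_lattice` with matrices `type`
#'   (0 empty / 1 producer / 2 defector) and `field`, and a `step` counter.
#' @export
lattice_init <- function(L = 50, occupancy = 0.7, producer_fraction = 0.5,
                         seed = NULL) {
  check_prob(occupancy, "occupancy"); check_prob(producer_fraction, "producer_fraction")
  with_seed(seed, {
    occ <- runif(L * L) < occupancy
    prod <- runif(L * L) < producer_fraction
  })
  type <- matrix(0L, L, L)
  type[occ] <- ifelse(prod[occ], 1L, 2L)
  structure(list(type = type, field = matrix(0, L, L), step = 0L),
            class = "coop_lattice")
}

# Diffusion kernel as a list of (di, dj, weight) offsets.
diffusion_kernel <- function(d) {
  if (d <= 1) {
    offs <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    return(list(di = offs[, 1], dj = offs[, 2], w = rep(1 / 5, 5)))
  }
  r <- ceiling(2 * d)
  grid <- expand.grid(di = -r:r, dj = -r:r)
  w <- exp(-(grid$di^2 + grid$dj^2) / (2 * d^2))
  list(di = grid$di, dj = grid$dj, w = w / sum(w))
}

mat_shift_boundary <- function(m, di, dj, boundary) {
  if (boundary == "periodic") return(mat_shift(m, di, dj))
  n1 <- nrow(m); n2 <- ncol(m)
  reflect <- function(idx, n) {
    idx <- ((idx - 1) %% (2 * n))
    ifelse(idx < n, idx + 1, 2 * n - idx)
  }
  i <- reflect(seq_len(n1) - di, n1)
  j <- reflect(seq_len(n2) - dj, n2)
  m[i, j, drop = FALSE]
}

#' One diffusion-decay step of the public-good field
#'
#' Convolves the field with a normalized kernel of range `d` (`d = 1`:
#' uniform over the site and its 4 contact neighbours; `d > 1`: truncated
#' Gaussian of sd `d`), then multiplies by `1 - lambda`. With `lambda = 0`
#' and periodic boundaries, total field mass is conserved.
#'
#' @param field Non-negative numeric matrix.
#' @param d Diffusion range.
#' @param lambda Decay fraction per step.
#' @param boundary `"periodic"` or `"reflecting"`.
#' @return The updated field matrix.
#' @export
diffuse_decay <- function(field, d = 1, lambda = 0, boundary = "periodic") {
  if (any(field < 0)) abort("Field values must be >= 0.", class = "coopcell_error_param")
  check_prob(lambda, "lambda")
  ker <- diffusion_kernel(d)
  out <- matrix(0, nrow(field), ncol(field))
  for (i in seq_along(ker$w)) {
    out <- out + ker$w[i] * mat_shift_boundary(field, ker$di[i], ker$dj[i], boundary)
  }
  out * (1 - lambda)
}

# producer-fate probability from the local good concentration
producer_fate_prob <- function(g, rules) {
  1 / (1 + (g / rules$theta)^rules$switch_m)
}

#' Advance the lattice model by one step
#'
#' Order of sub-steps: producers secrete; the field diffuses and decays
#' (synchronous); each occupied site survives with its type- and
#' benefit-dependent probability; in epigenetic mode surviving cells may
#' switch fate; empty sites are filled by a fitness-weighted draw among
#' occupied neighbours, the offspring's fate copied (genetic) or
#' re-evaluated from the local good (epigenetic).
#'
#' @param state A `coop_lattice`.
#' @param rules A [spatial_rules()] object.
#' @return The updated `coop_lattice`.
#' @export
spatial_step <- function(state, rules) {
  stopifnot(inherits(state, "coop_lattice"), inherits(rules, "coop_spatial_rules"))
  type <- state$type
  g <- state$field + rules$secretion * (type == 1L)
  g <- diffuse_decay(g, rules$d, rules$lambda, rules$boundary)

  # survival
  v <- rules$B * g / (rules$k_field + g)
  surv_p <- rules$sigma0 + (1 - rules$sigma0) * rules$s_A
  surv_d <- rules$sigma0 + (1 - rules$sigma0) * v
  death_prob <- matrix(0, nrow(type), ncol(type))
  death_prob[type == 1L] <- rules$death_scale * (1 - surv_p)
  death_prob[type == 2L] <- rules$death_scale * (1 - surv_d[type == 2L])
  died <- matrix(runif(length(type)), nrow(type)) < death_prob
  type[died] <- 0L

  # slow epigenetic interconversion of established cells
  if (rules$inheritance == "epigenetic" && rules$switch_rate > 0) {
    pp <- producer_fate_prob(g, rules)
    u <- matrix(runif(length(type)), nrow(type))
    to_prod <- type == 2L & u < rules$switch_rate * pp
    to_def <- type == 1L & u < rules$switch_rate * (1 - pp)
    type[to_prod] <- 1L
    type[to_def] <- 2L
  }

  # births into empty sites: fitness-weighted draw among the 4 neighbours
  empty <- type == 0L
  if (any(empty)) {
    wmat <- matrix(0, nrow(type), ncol(type))
    wmat[type == 1L] <- 1 - rules$c
    wmat[type == 2L] <- 1
    nb <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    w_nb <- lapply(nb, function(o) mat_shift_boundary(wmat, o[1], o[2], rules$boundary))
    t_nb <- lapply(nb, function(o) mat_shift_boundary(type, o[1], o[2], rules$boundary))
    w_tot <- Reduce(`+`, w_nb)
    fillable <- empty & w_tot > 0
    if (any(fillable)) {
      u <- matrix(runif(length(type)), nrow(type)) * w_tot
      cum <- matrix(0, nrow(type), ncol(type))
      parent_type <- matrix(0L, nrow(type), ncol(type))
      chosen <- matrix(FALSE, nrow(type), ncol(type))
      for (i in seq_along(nb)) {
        cum <- cum + w_nb[[i]]
        take <- fillable & !chosen & u < cum
        parent_type[take] <- t_nb[[i]][take]
        chosen <- chosen | take
      }
      if (rules$inheritance == "epigenetic") {
        pp <- producer_fate_prob(g, rules)
        fate <- ifelse(matrix(runif(length(type)), nrow(type)) < pp, 1L, 2L)
        type[fillable & chosen] <- fate[fillable & chosen]
      } else {
        type[fillable & chosen] <- parent_type[fillable & chosen]
      }
    }
  }

  state$type <- type
  state$field <- g
  state$step <- state$step + 1L
  state
}

#' Run the lattice tumor model
#'
#' @param initial A `coop_lattice` (see [lattice_init()]).
#' @param rules A [spatial_rules()] object.
#' @param steps Number of steps.
#' @param seed Integer RNG seed (trajectories are reproducible given seed).
#' @param record_every Record the producer fraction every this many steps.
#' @return A list of class `coop_spatial_run`: tibble `series` (`step`,
#'   `producer_fraction`, `occupied_fraction`), the `final` lattice state,
#'   and the rules.
#' @export
run_spatial <- function(initial, rules, steps = 1000, seed = NULL,
                        record_every = 1) {
  stopifnot(steps >= 1)
  state <- initial
  rec_steps <- seq(0, steps, by = record_every)
  frac <- function(s) {
    occ <- sum(s$type != 0L)
    tibble(step = s$step,
           producer_fraction = if (occ > 0) sum(s$type == 1L) / occ else 0,
           occupied_fraction = occ / length(s$type))
  }
  rows <- vector("list", length(rec_steps))
  k <- 1
  rows[[k]] <- frac(state)
  with_seed(seed, {
    for (i in seq_len(steps)) {
      state <- spatial_step(state, rules)
      if (i %in% rec_steps) {
        k <- k + 1
        rows[[k]] <- frac(state)
      }
    }
  })
  structure(list(series = bind_rows(rows), final = state, rules = rules),
            class = "coop_spatial_run")
}

#' @rdname run_spatial
#' @param object A `coop_spatial_run`.
#' @param ... Unused.
#' @export
autoplot.coop_spatial_run <- function(object, ...) {
  ggplot(object$series, aes(x = .data$step, y = .data$producer_fraction)) +
    geom_line() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Step", y = "Producer fraction",
         subtitle = paste0(object$rules$inheritance, " inheritance")) +
    theme_minimal()
}

#' Re-equilibration from sorted all-producer / all-defector starts
#'
#' Runs the epigenetic lattice model from 0\% and 100\% producer initial
#' compositions (emulating regrowth of FACS-sorted reporter-low and
#' reporter-high fractions) and compares the long-run producer fractions
#' with each other and with a mixed start. Under best-response epigenetic
#' regeneration all three converge to the same minority band; genetic mode
#' is rejected (no regeneration pathway from a pure-defector start).
#'
#' @param rules Epigenetic [spatial_rules()].
#' @param L,occupancy Lattice geometry, see [lattice_init()].
#' @param steps Steps per run.
#' @param seeds Integer vector of seeds (one run per seed and start).
#' @param window Number of final recorded steps averaged as the long-run
#'   fraction.
#' @return A tibble of class `coop_reequilibration` with one row per
#'   (start, seed): columns `start`, `seed`, `long_run_fraction`.
#' @export
reequilibrate <- function(rules, L = 50, occupancy = 0.7, steps = 1000,
                          seeds = 1:5, window = 200) {
  stopifnot(inherits(rules, "coop_spatial_rules"))
  if (rules$inheritance != "epigenetic") {
    abort("Re-equilibration requires epigenetic inheritance (genetic mode has no regeneration pathway).",
          class = "coopcell_error_param")
  }
  starts <- c(all_defector = 0, mixed = 0.5, all_producer = 1)
  rows <- purrr::imap(starts, function(pf, name) {
    purrr::map(seeds, function(s) {
      init <- lattice_init(L, occupancy, pf, seed = s + 10000L)
      run <- run_spatial(init, rules, steps = steps, seed = s)
      tail_vals <- utils::tail(run$series$producer_fraction, window)
      tibble(start = name, seed = s, long_run_fraction = mean(tail_vals))
    }) %>% bind_rows()
  }) %>% bind_rows()
  class(rows) <- c("coop_reequilibration", class(rows))
  rows
}

#' Export a lattice snapshot as an integer-coded CSV grid
#'
#' @param state A `coop_lattice`.
#' @param path Output CSV path (rows = lattice rows; 0 empty, 1 producer,
#'   2 defector).
#' @return `path`, invisibly.
#' @export
write_lattice_csv <- function(state, path) {
  utils::write.table(state$type, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
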