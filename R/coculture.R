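#' Co-culture experimental design
#'
#' Describes a tagged 1:1 co-culture competition experiment: a "homogeneous"
#' mixture (fluorescence-tagged control cells mixed with untagged control
#' cells) and a "heterogeneous" mixture (control cells mixed with altruist
#' cells, one of the two fractions carrying the tag). Both mixtures are
#' seeded, exposed to a drug dose series, counted by flow cytometry four
#' days after treatment, and allowed to regrow to confluency.
#'
#' @param n_seed_per_fraction Cells seeded per fraction (default 5000, i.e.
#'   10,000 cells total per well).
#' @param doses Drug concentrations in nM (vehicle = 0). The experimental
#'   range is 0.8–20 nM docetaxel.
#' @param replicates Wells per mixture x dose combination.
#' @param tag_assignment Which fraction carries the fluorescent tag in the
#'   heterogeneous mixture: `"tag_control"` or `"tag_altruist"` (reciprocal
#'   tagging control).
#' @param altruist_fraction Altruist fraction at seeding in the heterogeneous
#'   mixture (default 0.5 for a 1:1 mix).
#' @param confluency_target Total cell number at regrown confluency
#'   (default 1e5).
#' @return A list of class `coop_design`.
#' @seealso [simulate_coculture()]
#' @export
coculture_design <- function(n_seed_per_fraction = 5000,
                             doses = c(0, 2),
                             replicates = 3,
                             tag_assignment = c("tag_control", "tag_altruist"),
                             altruist_fraction = 0.5,
                             confluency_target = 1e5) {
  tag_assignment <- match.arg(tag_assignment)
  check_positive(n_seed_per_fraction, "n_seed_per_fraction")
  check_positive(doses, "doses", strict = FALSE)
  if (replicates < 1) abort("`replicates` must be >= 1.", class = "coopcell_error_param")
  if (is.na(altruist_fraction) || altruist_fraction <= 0 || altruist_fraction >= 1) {
    abort("`altruist_fraction` for the heterogeneous mixture must be in (0, 1).",
          class = "coopcell_error_param")
  }
  check_positive(confluency_target, "confluency_target")
  structure(
    list(n_seed_per_fraction = n_seed_per_fraction, doses = doses,
         replicates = as.integer(replicates), tag_assignment = tag_assignment,
         altruist_fraction = altruist_fraction,
         confluency_target = confluency_target),
    class = "coop_design")
}

#' Ground-truth parameters of the synthetic co-culture generator
#'
#' Parameterises the generative survival model behind the synthetic
#' co-culture data. Altruists (producers) secrete a diffusible good whose
#' benefit to *other* cells follows the saturating curve
#' [hill_benefit()]; the producers themselves receive none of it
#' (others-only benefit), but evade a fraction `s_A` of the drug kill
#' through intrinsic tolerance and pay a per-division growth cost `c`
#' during regrowth. Non-producers survive at the dose-dependent baseline
#' `sigma0(dose)` plus the rescued fraction `(1 - sigma0) * V(x)` where `x`
#' is the altruist fraction in the well.
#'
#' `sigma0(dose) = 2^(-dose / dose_half)` by default, an exponential
#' dose-kill curve with half-kill dose `dose_half` nM.
#'
#' @param B,k,h Benefit-curve parameters, see [hill_benefit()]. Concavity
#'   over the altruist-fraction range is asserted numerically when `h <= 1`.
#' @param c Producer per-division growth cost in `[0, 1)`.
#' @param s_A Producer intrinsic drug tolerance in `[0, 1]`: the fraction of
#'   the drug-induced kill that producers evade. `0` makes producers
#'   indistinguishable from non-producers when `B = 0` and `c = 0`.
#' @param dose_half Half-kill drug dose (nM) of the baseline survival curve.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise applied to counts and viability readouts.
#' @return A list of class `coop_truth`.
#' @export
truth_params <- function(B = 0.5, k = 0.05, h = 1, c = 0.3, s_A = 0.9,
                         dose_half = 0.9, noise_cv = 0.05) {
  check_prob(B, "B"); check_prob(s_A, "s_A")
  if (c < 0 || c >= 1) abort("`c` must be in [0, 1).", class = "coopcell_error_param")
  check_positive(dose_half, "dose_half")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.", class = "coopcell_error_param")
  if (h <= 1 && !is_concave_benefit(B, k, h)) {
    abort("Benefit function is not concave for the given (B, k, h).",
          class = "coopcell_error_param")
  }
  structure(list(B = B, k = k, h = h, c = c, s_A = s_A,
                 dose_half = dose_half, noise_cv = noise_cv),
            class = "coop_truth")
}

#' Null (no-altruism) truth parameters
#'
#' Preset with no benefit (`B = 0`), no growth cost (`c = 0`) and no
#' intrinsic producer tolerance (`s_A = 0`): both fractions behave
#' identically at every dose, so relative survival and relative fitness are
#' centred on 1. Used as the symmetric null fixture.
#'
#' @param noise_cv Measurement noise CV (default 0.05).
#' @inheritParams truth_params
#' @return A `coop_truth` object.
#' @export
truth_null <- function(noise_cv = 0.05, dose_half = 0.9) {
  truth_params(B = 0, k = 0.05, h = 1, c = 0, s_A = 0,
               dose_half = dose_half, noise_cv = noise_cv)
}

# Baseline non-producer survival at a drug dose.
sigma0_dose <- function(dose, truth) 2^(-dose / truth$dose_half)

# Type-specific survival probabilities at altruist fraction x and dose D.
survival_probs <- function(x, dose, truth) {
  s0 <- sigma0_dose(dose, truth)
  v <- hill_benefit(x, truth$B, truth$k, truth$h)
  list(
    producer = s0 + (1 - s0) * truth$s_A,      # others-only good: no V(x) term
    defector = s0 + (1 - s0) * v
  )
}

# Deterministic regrowth to confluency. Survivor lineages expand
# geometrically, defectors doubling per round and producers growing by
# 2^(1 - c) per round; the (continuous) round count is solved so the well
# total equals the confluency target exactly.
regrow_to_confluency <- function(surv_defector, surv_producer, c, target) {
  total0 <- surv_defector + surv_producer
  if (total0 <= 0) return(list(defector = 0, producer = 0))
  if (total0 >= target) {
    scale <- target / total0
    return(list(defector = surv_defector * scale, producer = surv_producer * scale))
  }
  f <- function(t) surv_defector * 2^t + surv_producer * 2^(t * (1 - c)) - target
  t_max <- log2(target / total0) / max(1 - c, 1e-8) + 1
  t_star <- uniroot(f, c(0, t_max), tol = 1e-12)$root
  d <- surv_defector * 2^t_star
  p <- surv_producer * 2^(t_star * (1 - c))
  scale <- target / (d + p)                    # exact conservation
  list(defector = d * scale, producer = p * scale)
}

#' Simulate a tagged co-culture competition experiment
#'
#' Generates flow-cytometry-style count tables for the homogeneous and
#' heterogeneous mixtures of a tagged co-culture design, at two timepoints:
#' `post_treatment_day4` (survivor counts four days after drug exposure) and
#' `regrown_confluent` (composition of the population regrown to
#' confluency). Survival of each cell depends on its type and on the well's
#' altruist fraction; regrowth compounds the producers' per-division growth
#' cost until the well reaches its confluency target. Multiplicative
#' log-normal measurement noise with CV `truth$noise_cv` is applied to each
#' reported count. Fully reproducible from `seed`.
#'
#' @param design A [coculture_design()].
#' @param truth A [truth_params()] object.
#' @param seed Integer RNG seed (or `NULL` to use the current RNG state).
#' @return A tibble of class `coop_coculture` with columns `mixture`,
#'   `dose_nM`, `replicate`, `timepoint`, `tag`, `fraction_identity`
#'   (`"control_m"` or `"mir125b_m"`) and `count`. The design and truth are
#'   attached as attributes `design` and `truth`.
#' @examples
#' counts <- simulate_coculture(coculture_design(doses = c(0, 2)),
#'                              truth_params(noise_cv = 0), seed = 1)
#' dplyr::count(counts, mixture, timepoint)
#' @export
simulate_coculture <- function(design = coculture_design(),
                               truth = truth_params(),
                               seed = NULL) {
  stopifnot(inherits(design, "coop_design"), inherits(truth, "coop_truth"))
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      mixture = c("homogeneous", "heterogeneous"),
      dose_nM = design$doses,
      replicate = seq_len(design$replicates))
    rows <- purrr::pmap(grid, function(mixture, dose_nM, replicate) {
      simulate_well(mixture, dose_nM, replicate, design, truth)
    })
    out <- bind_rows(rows)
  })
  out <- as_tibble(out)
  attr(out, "design") <- design
  attr(out, "truth") <- truth
  class(out) <- c("coop_coculture", class(out))
  out
}

simulate_well <- function(mixture, dose_nM, replicate, design, truth) {
  n <- design$n_seed_per_fraction
  if (mixture == "heterogeneous") {
    x <- design$altruist_fraction
    ident <- if (design$tag_assignment == "tag_control") {
      c(tagged = "control_m", untagged = "mir125b_m")
    } else {
      c(tagged = "mir125b_m", untagged = "control_m")
    }
    # seeded numbers follow identity: altruists get fraction x of the well
    n_seed <- c(
      tagged   = 2 * n * if (ident[["tagged"]] == "mir125b_m") x else 1 - x,
      untagged = 2 * n * if (ident[["untagged"]] == "mir125b_m") x else 1 - x)
  } else {
    x <- 0
    ident <- c(tagged = "control_m", untagged = "control_m")
    n_seed <- c(tagged = n, untagged = n)
  }
  sp <- survival_probs(x, dose_nM, truth)
  surv_prob <- vapply(ident, function(id)
    if (id == "mir125b_m") sp$producer else sp$defector, numeric(1))
  survivors <- n_seed * surv_prob

  s_prod <- sum(survivors[ident == "mir125b_m"])
  s_def <- sum(survivors[ident != "mir125b_m"])
  reg <- regrow_to_confluency(s_def, s_prod, truth$c, design$confluency_target)
  regrown <- vapply(seq_along(ident), function(i) {
    if (ident[[i]] == "mir125b_m") {
      if (s_prod > 0) reg$producer * survivors[[i]] / s_prod else 0
    } else {
      if (s_def > 0) reg$defector * survivors[[i]] / s_def else 0
    }
  }, numeric(1))

  tibble(
    mixture = mixture, dose_nM = dose_nM, replicate = replicate,
    timepoint = rep(c("post_treatment_day4", "regrown_confluent"), each = 2),
    tag = rep(c("tagged", "untagged"), 2),
    fraction_identity = rep(unname(ident), 2),
    count = unname(c(survivors * lognormal_noise(2, truth$noise_cv),
                     regrown * lognormal_noise(2, truth$noise_cv))))
}

#' Simulate an altruist-fraction titration viability series
#'
#' Emulates the mixing experiment in which altruist cells are titrated into
#' a control population at fixed fractions (default 0, 1, 10, 30 and 50\%
#' of the well), treated with drug, and read out by a bulk viability (MTS)
#' assay. The readout is the population-mean survival under the generative
#' truth model plus multiplicative log-normal noise; its expectation is
#' nondecreasing in the altruist fraction whenever `s_A >= B`.
#'
#' @param fractions Altruist fractions in `[0, 1]`
#'   (default `c(0, 0.01, 0.10, 0.30, 0.50)`).
#' @param truth A [truth_params()] object.
#' @param dose_nM Drug dose applied to every well (default 2 nM).
#' @param replicates Readouts per fraction.
#' @param seed Integer RNG seed.
#' @return A tibble of class `coop_benefit_series` with columns `fraction`,
#'   `percent`, `replicate`, `viability`.
#' @export
simulate_benefit_series <- function(fractions = c(0, 0.01, 0.10, 0.30, 0.50),
                                    truth = truth_params(),
                                    dose_nM = 2, replicates = 3, seed = NULL) {
  stopifnot(inherits(truth, "coop_truth"))
  if (any(fractions < 0 | fractions > 1)) {
    abort("`fractions` must lie in [0, 1].", class = "coopcell_error_param")
  }
  check_positive(dose_nM, "dose_nM", strict = FALSE)
  with_seed(seed, {
    out <- tidyr::expand_grid(fraction = fractions,
                              replicate = seq_len(replicates)) %>%
      mutate(viability = purrr::map_dbl(.data$fraction, function(x) {
        sp <- survival_probs(x, dose_nM, truth)
        x * sp$producer + (1 - x) * sp$defector
      }) * lognormal_noise(dplyr::n(), truth$noise_cv),
      percent = 100 * .data$fraction) %>%
      select("fraction", "percent", "replicate", "viability")
  })
  attr(out, "truth") <- truth
  attr(out, "dose_nM") <- dose_nM
  class(out) <- c("coop_benefit_series", class(out))
  out
}

#' Expected viability of a mixed well under the generative truth model
#'
#' Noise-free population-mean survival for a well with altruist fraction
#' `x` at dose `dose_nM`; the closed-form oracle for
#' [simulate_benefit_series()].
#'
#' @inheritParams simulate_benefit_series
#' @param x Altruist fraction(s) in `[0, 1]`.
#' @return Numeric vector of expected viabilities.
#' @export
expected_viability <- function(x, truth = truth_params(), dose_nM = 2) {
  vapply(x, function(xi) {
    sp <- survival_probs(xi, dose_nM, truth)
    xi * sp$producer + (1 - xi) * sp$defector
  }, numeric(1))
}

#' Write a co-culture count table and its truth sidecar to disk
#'
#' Exports the count table as CSV (columns `mixture`, `dose_nM`,
#' `replicate`, `timepoint`, `tag`, `fraction_identity`, `count`) plus a
#' JSON sidecar recording the generator truth parameters and seed, so a run
#' is fully reconstructible.
#'
#' @param counts A `coop_coculture` tibble.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @param seed Seed to record in the sidecar (optional).
#' @return `path`, invisibly.
#' @export
write_coculture_csv <- function(counts, path, seed = NULL) {
  write.csv(as.data.frame(counts), path, row.names = FALSE)
  truth <- attr(counts, "truth")
  design <- attr(counts, "design")
  sidecar <- list(truth = unclass(truth), design = unclass(design), seed = seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a co-culture count table written by [write_coculture_csv()]
#'
#' @param path CSV path. If a `<path>.json` sidecar exists, the recorded
#'   truth and design are re-attached as attributes.
#' @return A `coop_coculture` tibble.
#' @export
read_coculture_csv <- function(path) {
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$truth)) attr(out, "truth") <- structure(meta$truth, class = "coop_truth")
    if (!is.null(meta$design)) attr(out, "design") <- structure(meta$design, class = "coop_design")
  }
  class(out) <- c("coop_coculture", class(out))
  out
}
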