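#' Relative survival from tagged co-culture counts
#'
#' Computes the relative-survival statistics from day-4 post-treatment
#' counts. For each dose x replicate, the tagged:untagged ratio of the
#' homogeneous well is normalized to 1:1 and the same normalization factor
#' is applied to the matched heterogeneous well. `rs_alpha` is then the
#' normalized number of surviving control cells in the heterogeneous well
#' divided by the normalized same-channel count in the homogeneous well;
#' `rs_alpha > 1` means control cells survived better beside altruists than
#' beside other control cells. `rs_beta` mirrors the computation for the
#' altruist fraction, referenced against the same channel of the
#' homogeneous well. NOTE: the altruist-side reference is a convention of
#' this package (an altruist-only homogeneous well is not part of the
#' design); interpret `rs_beta` accordingly.
#'
#' Relative survival is invariant to which fraction carries the tag
#' (reciprocal tagging) on noiseless data, and to rescaling all counts of a
#' treatment group by a common factor.
#'
#' @param counts A `coop_coculture` tibble (see [simulate_coculture()] for
#'   the schema).
#' @return A tibble with one row per dose x replicate: `dose_nM`,
#'   `replicate`, `normalization_factor`, `rs_alpha`, `rs_beta` (`NA` for a
#'   homogeneous-only design).
#' @examples
#' counts <- simulate_coculture(truth = truth_params(noise_cv = 0), seed = 1)
#' relative_survival(counts)
#' @export
relative_survival <- function(counts) {
  day4 <- filter(counts, .data$timepoint == "post_treatment_day4")
  compute_rs_rf(day4, ratio_name = "rs")
}

#' Relative fitness from regrown co-culture counts
#'
#' Computes relative fitness from the regrown-to-confluency composition.
#' The tagged:untagged ratio of the regrown homogeneous well is normalized
#' to 1:1 and the same factor applied to the heterogeneous well; `rf_alpha`
#' is the normalized number of control-derived cells divided by the number
#' of altruist-derived cells in the regrown heterogeneous population. A
#' value of 1 means equal progeny from the two fractions; `> 1` means the
#' control fraction out-reproduced the altruists (the altruists paid a
#' fitness cost). Zero altruist-derived counts yield an `Inf` sentinel with
#' a warning rather than an error, since high drug doses can legitimately
#' extinguish a fraction.
#'
#' @inheritParams relative_survival
#' @return A tibble with one row per dose x replicate: `dose_nM`,
#'   `replicate`, `normalization_factor`, `rf_alpha`.
#' @export
relative_fitness <- function(counts) {
  reg <- filter(counts, .data$timepoint == "regrown_confluent")
  out <- compute_rs_rf(reg, ratio_name = "rf")
  rename(out, rf_alpha = "rs_alpha") %>% select(-dplyr::any_of("rs_beta"))
}

# Shared normalization logic for RS (day-4) and RF (regrown) statistics.
compute_rs_rf <- function(tbl, ratio_name) {
  wide <- tbl %>%
    tidyr::pivot_wider(id_cols = c("mixture", "dose_nM", "replicate"),
                       names_from = "tag",
                       values_from = c("count", "fraction_identity"))
  groups <- wide %>% dplyr::distinct(.data$dose_nM, .data$replicate)
  rows <- purrr::pmap(groups, function(dose_nM, replicate) {
    g <- filter(wide, .data$dose_nM == !!dose_nM, .data$replicate == !!replicate)
    hom <- filter(g, .data$mixture == "homogeneous")
    het <- filter(g, .data$mixture == "heterogeneous")
    if (nrow(hom) != 1 || nrow(het) != 1) {
      abort(sprintf("No matched homogeneous/heterogeneous well pair for dose %s, replicate %s.",
                    dose_nM, replicate), class = "coopcell_error_pairing")
    }
    if (any(c(hom$count_tagged, hom$count_untagged) <= 0)) {
      abort("Zero count in a homogeneous normalization denominator.",
            class = "coopcell_error_degenerate")
    }
    f <- hom$count_untagged / hom$count_tagged   # tagged * f : untagged = 1:1
    norm_het <- c(tagged = het$count_tagged * f, untagged = het$count_untagged)
    norm_hom <- c(tagged = hom$count_tagged * f, untagged = hom$count_untagged)
    ident <- c(tagged = het$fraction_identity_tagged,
               untagged = het$fraction_identity_untagged)
    ctrl_chan <- names(ident)[ident == "control_m"]
    alt_chan <- names(ident)[ident == "mir125b_m"]
    if (ratio_name == "rs") {
      if (length(ctrl_chan) == 0) {
        abort("Heterogeneous well lacks a control_m fraction.", class = "coopcell_error_pairing")
      }
      rs_a <- unname(norm_het[ctrl_chan[1]] / norm_hom[ctrl_chan[1]])
      rs_b <- if (length(alt_chan)) {
        unname(norm_het[alt_chan[1]] / norm_hom[alt_chan[1]])
      } else NA_real_
      tibble(dose_nM = dose_nM, replicate = replicate,
             normalization_factor = f, rs_alpha = rs_a, rs_beta = rs_b)
    } else {
      if (length(ctrl_chan) == 0 || length(alt_chan) == 0) {
        abort("Heterogeneous well must contain both fractions for relative fitness.",
              class = "coopcell_error_pairing")
      }
      num <- unname(norm_het[ctrl_chan[1]])
      den <- unname(norm_het[alt_chan[1]])
      if (den == 0) {
        warn("Zero altruist-derived count: relative fitness reported as Inf sentinel.")
        rf <- Inf
      } else {
        rf <- num / den
      }
      tibble(dose_nM = dose_nM, replicate = replicate,
             normalization_factor = f, rs_alpha = rf)
    }
  })
  bind_rows(rows) %>% arrange(.data$dose_nM, .data$replicate)
}

#' Xenograft relative survival from FACS proportions and photon counts
#'
#' Closed-form relative survival for the xenograft design, where the number
#' of control cells per tumor is estimated as (FACS proportion of control
#' cells) x (photon count two days post-treatment):
#' `rs_alpha = (prop_het * photons_het) / (prop_homo * photons_homo)`.
#'
#' @param prop_het,prop_homo FACS proportion of control cells in the
#'   heterogeneous and homogeneous tumors.
#' @param photons_het,photons_homo Post-treatment photon counts of the two
#'   tumors.
#' @return `rs_alpha` (vectorised).
#' @examples
#' rs_alpha_xenograft(0.7, 2e8, 0.5, 2e8)  # 1.4
#' @export
rs_alpha_xenograft <- function(prop_het, photons_het, prop_homo, photons_homo) {
  check_positive(prop_homo, "prop_homo")
  check_positive(photons_homo, "photons_homo")
  (prop_het * photons_het) / (prop_homo * photons_homo)
}

#' Classify social behaviour from relative survival and relative fitness
#'
#' Maps the (RS, RF) pair onto the Hamilton-style social-behaviour matrix.
#' The effect on the recipient is the sign of `rs_alpha - 1` (partners
#' survive better or worse beside the focal fraction) and the effect on the
#' actor is the sign of `1 - rf_alpha` (`rf_alpha > 1` means the actor paid
#' a fitness cost). The four sign combinations give: benefit to both =
#' `mutual_benefit`; benefit to actor, cost to recipient = `selfishness`;
#' cost to actor, benefit to recipient = `altruism`; cost to both =
#' `spite`. Ratios within the tolerance band of 1 are `neutral`; when
#' per-replicate values are supplied, a one-sample two-sided t-test against
#' 1 at `alpha` is used instead of the fixed band.
#'
#' @param rs_alpha,rf_alpha Ratio point estimates (or replicate vectors when
#'   `method = "t_test"`).
#' @param tol Half-width of the neutral band on the ratio scale
#'   (default 0.05), used when `method = "band"`.
#' @param method `"band"` (default) or `"t_test"`.
#' @param alpha Significance level for the t-test mode.
#' @return A tibble with `label`, `actor_effect`, `recipient_effect`.
#' @examples
#' classify_social_behavior(1.4, 1.6)   # altruism
#' classify_social_behavior(1.4, 0.7)   # mutual_benefit
#' @export
classify_social_behavior <- function(rs_alpha, rf_alpha, tol = 0.05,
                                     method = c("band", "t_test"),
                                     alpha = 0.05) {
  method <- match.arg(method)
  if (any(rs_alpha <= 0) || any(rf_alpha[is.finite(rf_alpha)] <= 0)) {
    abort("Ratios must be positive.", class = "coopcell_error_param")
  }
  if (tol < 0) abort("`tol` must be >= 0.", class = "coopcell_error_param")
  effect_sign <- function(vals, mu) {
    if (method == "band") {
      m <- mean(vals[is.finite(vals)])
      if (any(is.infinite(vals))) m <- Inf
      if (abs(m - mu) <= tol && is.finite(m)) 0 else sign(m - mu)
    } else {
      ht <- one_sample_t(vals[is.finite(vals)], mu)
      if (is.na(ht$p_value) || ht$p_value > alpha) 0 else sign(ht$estimate - mu)
    }
  }
  recipient <- effect_sign(rs_alpha, 1)            # RS > 1: recipient gains
  actor <- -effect_sign(rf_alpha, 1)               # RF > 1: actor pays a cost
  label <- if (actor == 0 && recipient == 0) {
    "neutral"
  } else {
    # outside the joint band, classify by quadrant; an axis sitting exactly
    # in its band falls back to its raw sign (0 only at exact equality)
    a <- if (actor != 0) actor else -sign(mean(rf_alpha[is.finite(rf_alpha)]) - 1)
    r <- if (recipient != 0) recipient else sign(mean(rs_alpha) - 1)
    if (a >= 0 && r >= 0) "mutual_benefit"
    else if (a >= 0 && r < 0) "selfishness"
    else if (a < 0 && r >= 0) "altruism"
    else "spite"
  }
  tibble(label = label, actor_effect = actor, recipient_effect = recipient)
}

# One-sample two-sided t-test that tolerates zero-variance input (t = 0
# when the mean equals the reference, +/-Inf otherwise).
one_sample_t <- function(x, mu) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (n < 2 || is.na(s)) return(list(estimate = m, t = NA_real_, df = n - 1, p_value = NA_real_))
  if (s == 0) {
    t_stat <- if (abs(m - mu) <= 1e-12 * (abs(mu) + 1)) 0 else sign(m - mu) * Inf
  } else {
    t_stat <- (m - mu) / (s / sqrt(n))
  }
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  list(estimate = m, t = t_stat, df = n - 1, p_value = p)
}

#' Percentage rescue of a fitness disadvantage
#'
#' Fraction of the altruists' fitness disadvantage removed by knocking down
#' a candidate gene in the altruist fraction:
#' `(RF_het_controlKD - RF_het_geneKD) /
#'  (RF_het_controlKD - RF_homo_controlKD) * 100`.
#'
#' @param rf_het_control_kd Relative fitness of the heterogeneous mixture
#'   with control knockdown.
#' @param rf_het_gene_kd Relative fitness of the heterogeneous mixture with
#'   the gene knocked down.
#' @param rf_homo_control_kd Relative fitness of the homogeneous mixture
#'   with control knockdown.
#' @return Percentage rescue (vectorised). 0 when the knockdown changes
#'   nothing; 100 when it restores the homogeneous baseline.
#' @export
percent_rescue <- function(rf_het_control_kd, rf_het_gene_kd, rf_homo_control_kd) {
  den <- rf_het_control_kd - rf_homo_control_kd
  if (any(den == 0)) {
    abort("Degenerate rescue denominator: RF_het_controlKD equals RF_homo_controlKD.",
          class = "coopcell_error_degenerate")
  }
  (rf_het_control_kd - rf_het_gene_kd) / den * 100
}

#' Percentage change in cell viability between two lines under drug
#'
#' Drug-screen effect size: the relative viability change of the
#' altruist-mimicking line minus that of the control line, x100:
#' `[(mir_with - mir_without)/mir_without -
#'   (ctrl_with - ctrl_without)/ctrl_without] * 100`.
#'
#' @param mir_with,mir_without Viability readings of the altruist-mimicking
#'   line with and without the drug.
#' @param ctrl_with,ctrl_without Same for the control line.
#' @return Signed percentage (vectorised).
#' @export
percent_change_viability <- function(mir_with, mir_without, ctrl_with, ctrl_without) {
  if (any(mir_without <= 0) || any(ctrl_without <= 0)) {
    abort("No-drug baseline readings must be > 0.", class = "coopcell_error_degenerate")
  }
  ((mir_with - mir_without) / mir_without -
     (ctrl_with - ctrl_without) / ctrl_without) * 100
}

#' Percentage reduction in reporter activity induced by a knockdown
#'
#' For an NF-kB (or similar) transcriptional reporter elevated in the
#' altruist-mimicking cells: the share of the elevation removed by a gene
#' knockdown, `(read_mir_ctrlKD - read_mir_geneKD) /
#' (read_mir_ctrlKD - read_ctrl_ctrlKD) * 100`.
#'
#' @param read_mir_ctrl_kd Reporter reading, altruist-mimicking cells with
#'   control knockdown.
#' @param read_mir_gene_kd Same cells with the gene knocked down.
#' @param read_ctrl_ctrl_kd Control cells with control knockdown.
#' @return Percentage reduction (vectorised).
#' @export
percent_reduction_nfkb <- function(read_mir_ctrl_kd, read_mir_gene_kd, read_ctrl_ctrl_kd) {
  den <- read_mir_ctrl_kd - read_ctrl_ctrl_kd
  if (any(den == 0)) {
    abort("Degenerate denominator: reporter reading with control knockdown equals the control-cell baseline.",
          class = "coopcell_error_degenerate")
  }
  (read_mir_ctrl_kd - read_mir_gene_kd) / den * 100
}

#' Percentage effect of a CRISPRi perturbation on viability
#'
#' `(viability with site-targeting CRISPRi - viability with control CRISPRi)
#'  / viability with control CRISPRi * 100`.
#'
#' @param viab_kbs1 Viability with the site-targeting CRISPRi construct.
#' @param viab_control Viability with the control construct (> 0).
#' @return Signed percentage (vectorised).
#' @export
percent_effect_crispri <- function(viab_kbs1, viab_control) {
  if (any(viab_control <= 0)) {
    abort("Control viability must be > 0.", class = "coopcell_error_degenerate")
  }
  (viab_kbs1 - viab_control) / viab_control * 100
}

#' Linear-mixing expectation for a mixed culture, with one-sample test
#'
#' Computes the null expectation that a mixed culture's viability is the
#' fraction-weighted mean of the pure cultures' viabilities, and (when
#' replicate observations of the mixture are supplied) a one-sample
#' two-tailed t-test of the observed mixture against that expectation. An
#' observed mean significantly above the expectation under drug indicates a
#' cooperative, better-than-additive survival effect of the minority
#' fraction.
#'
#' @param pure_viabilities Viabilities of the pure cultures (one per fate).
#' @param fractions Mixing fractions; must sum to 1 (tolerance 1e-9).
#' @param observed Optional replicate readouts of the mixed culture.
#' @return A tibble with `expectation` and, when `observed` is given,
#'   `observed_mean`, `t`, `df`, `p_value` and `direction`
#'   (`"above"`/`"below"`/`"equal"`).
#' @examples
#' expected_mixture_viability(c(0.4, 0.8), c(0.1, 0.9))
#' @export
expected_mixture_viability <- function(pure_viabilities, fractions, observed = NULL) {
  if (length(pure_viabilities) != length(fractions)) {
    abort("`pure_viabilities` and `fractions` must have the same length.",
          class = "coopcell_error_param")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must sum to 1.", class = "coopcell_error_param")
  }
  expectation <- sum(fractions * pure_viabilities)
  if (is.null(observed)) return(tibble(expectation = expectation))
  ht <- one_sample_t(observed, expectation)
  tibble(expectation = expectation, observed_mean = ht$estimate,
         t = ht$t, df = ht$df, p_value = ht$p_value,
         direction = if (ht$estimate > expectation) "above"
         else if (ht$estimate < expectation) "below" else "equal")
}

#' Full social-fitness report for a co-culture count table
#'
#' Convenience wrapper chaining [relative_survival()],
#' [relative_fitness()] and [classify_social_behavior()]: one row per dose
#' with replicate means, standard deviations, and the social-behaviour
#' label.
#'
#' @inheritParams relative_survival
#' @param tol Neutral-band half-width passed to
#'   [classify_social_behavior()].
#' @return A tibble of class `coop_social_fitness` with per-dose summaries
#'   and labels; per-replicate values are attached as attribute
#'   `replicates`.
#' @export
social_fitness <- function(counts, tol = 0.05) {
  rs <- relative_survival(counts)
  rf <- relative_fitness(counts)
  per_rep <- left_join(rs, select(rf, "dose_nM", "replicate", "rf_alpha"),
                       by = c("dose_nM", "replicate"))
  out <- per_rep %>%
    group_by(.data$dose_nM) %>%
    summarise(
      rs_alpha_sd = stats::sd(.data$rs_alpha),
      rf_alpha_sd = stats::sd(.data$rf_alpha[is.finite(.data$rf_alpha)]),
      rs_alpha = mean(.data$rs_alpha),
      rs_beta = mean(.data$rs_beta),
      rf_alpha = mean(.data$rf_alpha[is.finite(.data$rf_alpha)]),
      n_replicates = dplyr::n(), .groups = "drop") %>%
    select("dose_nM", "rs_alpha", "rs_alpha_sd", "rs_beta",
           "rf_alpha", "rf_alpha_sd", "n_replicates") %>%
    mutate(label = purrr::map2_chr(.data$rs_alpha, .data$rf_alpha, function(a, b) {
      classify_social_behavior(a, b, tol = tol)$label
    }))
  attr(out, "replicates") <- per_rep
  class(out) <- c("coop_social_fitness", class(out))
  out
}
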