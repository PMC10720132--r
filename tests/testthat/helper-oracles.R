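# Hand-coded arithmetic oracles, written independently of the package
# implementations. Each mirrors a formula definition directly, with no
# shared code path.

oracle_rs_alpha <- function(hom_tagged, hom_untagged, het_control, het_other,
                            control_tagged = TRUE) {
  f <- hom_untagged / hom_tagged
  if (control_tagged) (het_control * f) / (hom_tagged * f)
  else het_control / hom_untagged
}

oracle_rf_alpha <- function(hom_tagged, hom_untagged, het_tagged, het_untagged,
                            control_tagged = TRUE) {
  f <- hom_untagged / hom_tagged
  if (control_tagged) (het_tagged * f) / het_untagged
  else het_untagged / (het_tagged * f)
}

oracle_percentage_benefit <- function(reading_x, reading_0, reading_50) {
  100 * (reading_x - reading_0) / (reading_50 - reading_0)
}

oracle_marginal_benefit <- function(pb_x, pb_y, x, y) {
  (pb_y - pb_x) / ((y - x) + 1)
}

oracle_percent_rescue <- function(het_ctrl, het_gene, homo_ctrl) {
  (het_ctrl - het_gene) / (het_ctrl - homo_ctrl) * 100
}

oracle_percent_change_viability <- function(mw, mo, cw, co) {
  ((mw - mo) / mo - (cw - co) / co) * 100
}

oracle_percent_reduction_nfkb <- function(mc, mg, cc) {
  (mc - mg) / (mc - cc) * 100
}

oracle_percent_effect_crispri <- function(v_kbs, v_ctrl) {
  (v_kbs - v_ctrl) / v_ctrl * 100
}

# Minimal one-pair count table in the generator's schema.
counts_from <- function(hom_tagged, hom_untagged, het_tagged, het_untagged,
                        timepoint = "post_treatment_day4") {
  out <- tibble::tibble(
    mixture = rep(c("homogeneous", "heterogeneous"), each = 2),
    dose_nM = 2, replicate = 1L, timepoint = timepoint,
    tag = rep(c("tagged", "untagged"), 2),
    fraction_identity = c("control_m", "control_m", "control_m", "mir125b_m"),
    count = c(hom_tagged, hom_untagged, het_tagged, het_untagged))
  class(out) <- c("coop_coculture", class(out))
  out
}

# Noise-free expected day-4 survival and regrown composition of the
# generative co-culture model, written directly from its definition.
oracle_coculture_expectation <- function(truth, design, dose) {
  s0 <- 2^(-dose / truth$dose_half)
  v <- function(x) truth$B * x^truth$h / (truth$k^truth$h + x^truth$h)
  surv_p <- s0 + (1 - s0) * truth$s_A
  surv_d <- function(x) s0 + (1 - s0) * v(x)
  n <- design$n_seed_per_fraction
  x <- design$altruist_fraction
  het_def <- 2 * n * (1 - x) * surv_d(x)
  het_prod <- 2 * n * x * surv_p
  hom_def <- n * surv_d(0)
  regrow <- function(sd, sp) {
    tot <- sd + sp
    K <- design$confluency_target
    if (tot >= K) return(c(def = sd * K / tot, prod = sp * K / tot))
    t_star <- uniroot(function(t) sd * 2^t + sp * 2^(t * (1 - truth$c)) - K,
                      c(0, 100), tol = 1e-13)$root
    d <- sd * 2^t_star; p <- sp * 2^(t_star * (1 - truth$c))
    c(def = d * K / (d + p), prod = p * K / (d + p))
  }
  list(
    hom_day4 = c(tagged = hom_def, untagged = hom_def),
    het_day4 = c(def = het_def, prod = het_prod),
    hom_regrown = regrow(2 * hom_def, 0),
    het_regrown = regrow(het_def, het_prod))
}

# Expected relative survival / fitness ratios from the noise-free model:
# RS_alpha compares control survival beside altruists vs beside controls;
# RF_alpha compares control- vs altruist-derived progeny after regrowth
# with the homogeneous regrown well normalized 1:1 (symmetric, factor 1).
oracle_rs_rf_from_truth <- function(truth, design, dose) {
  e <- oracle_coculture_expectation(truth, design, dose)
  n <- design$n_seed_per_fraction
  x <- design$altruist_fraction
  rs_alpha <- unname((e$het_day4[["def"]] / (2 * n * (1 - x))) /
                       (e$hom_day4[["tagged"]] / n))
  rf_alpha <- unname(e$het_regrown[["def"]] / e$het_regrown[["prod"]])
  c(rs_alpha = rs_alpha, rf_alpha = rf_alpha)
}
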