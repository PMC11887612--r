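# Shared fixtures, built in code.

# A small, fully explicit eight-cell table.
toy_cells <- function(outcome = "cesarean") {
  cell_counts(x = rep(1:2, each = 4),
              m1 = rep(c(1, 1, 2, 2), 2),
              m2 = rep(c(1, 2, 1, 2), 2),
              r = c(10, 20, 30, 40, 15, 25, 35, 45),
              n = rep(1000, 8), outcome = outcome)
}

# Calibrated cell-level simulation and fit, the recovery workhorse:
# baseline rate for every non-Black cell, a target total effect, optional CDE
# targets, reference mediator prevalences, configurable race totals.
recovery_fit <- function(te_target, cde_targets = NULL, baseline,
                         n_per_race = c(14e6, 3e6), seed = 1L, S = 10000,
                         outcome = "outcome") {
  prev <- reference_prevalence()
  probs <- calibrate_cell_probs(prev, te_target = te_target,
                                cde_targets = cde_targets, baseline = baseline)
  cfg <- generator_config(n_per_race, prev,
                          stats::setNames(list(probs), outcome),
                          seed = seed, level = "cell")
  cells <- simulate_cell_counts(cfg)
  po_mediate(cells, S = S, seed = seed)
}

# Monte-Carlo standard error of a sample quantile q from S draws of a
# distribution with density f at the quantile.
quantile_mc_se <- function(q, S, dens) sqrt(q * (1 - q) / S) / dens

# Write a 12-row record fixture with one row missing an outcome flag and one
# row missing height.
write_record_fixture <- function(path) {
  set.seed(99)
  df <- data.frame(race_class = rep(1:2, 6),
                   height = round(runif(12, 150, 180), 1),
                   prepreg_weight = round(runif(12, 50, 90), 1),
                   delivery_weight = NA, gestation_weeks = round(runif(12, 37, 42), 1),
                   gest_htn = rbinom(12, 1, 0.1), htn_eclampsia = 0,
                   induction = rbinom(12, 1, 0.2), cesarean = rbinom(12, 1, 0.3),
                   icu = 0)
  df$delivery_weight <- df$prepreg_weight + round(runif(12, 5, 20), 1)
  df$icu[3] <- NA        # deleted at the missing-outcome stage
  df$height[7] <- NA     # deleted at the missing-anthropometrics stage
  write.csv(df, path, row.names = FALSE, na = "")
  path
}
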