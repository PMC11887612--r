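test_that("total effect is centred where the pooled rates differ", {
  cc <- cell_counts(x = rep(1:2, each = 4), m1 = rep(c(1, 1, 2, 2), 2),
                    m2 = rep(c(1, 2, 1, 2), 2),
                    r = c(rep(250, 4), rep(500, 4)), n = rep(250000, 8))
  # pooled: non-Black (1000, 1e6), Black (2000, 1e6)
  te <- total_effect(cc, S = 10000, seed = 3)
  sd_te <- sqrt(0.001 * 0.999 / 1e6 + 0.002 * 0.998 / 1e6)
  expect_lt(abs(median(te$values) - 0.001), 3 * 1.253 * sd_te / sqrt(10000))
  expect_true(all(abs(te$values) <= 1))
})

test_that("identical race counts give a null, non-significant total effect", {
  cc <- cell_counts(x = rep(1:2, each = 4), m1 = rep(c(1, 1, 2, 2), 2),
                    m2 = rep(c(1, 2, 1, 2), 2),
                    r = rep(c(10, 20, 30, 40), 2), n = rep(1000, 8))
  te <- total_effect(cc, S = 1000, seed = 5)
  est <- summarize_draws(te)
  expect_equal(est$median, 0)
  expect_false(est$significant)
})

test_that("swapping race labels negates total-effect draws exactly", {
  cc <- toy_cells()
  swapped <- cell_counts(3 - cc$x, cc$m1, cc$m2, cc$r, cc$n)
  te <- total_effect(cc, S = 2000, seed = 11)
  te_swap <- total_effect(swapped, S = 2000, seed = 11)
  expect_identical(te$values, -te_swap$values)
})

test_that("controlled direct effects fix mediators at optimal and collapse the rest", {
  # only the (x, 1, 1) cells populated: the joint CDE is the total effect of
  # those cells alone
  cc <- cell_counts(x = c(1, 2), m1 = c(1, 1), m2 = c(1, 1),
                    r = c(50, 120), n = c(1000, 1000))
  cde <- controlled_direct_effect(cc, "M1M2", S = 20000, seed = 6)
  te <- total_effect(cc, S = 20000, seed = 6)
  for (q in c(0.1, 0.5, 0.9))
    expect_equal(unname(quantile(cde$values, q)), unname(quantile(te$values, q)),
                 tolerance = 0.02)

  # all cells at a common rate: every CDE is null
  cc0 <- cell_counts(x = rep(1:2, each = 4), m1 = rep(c(1, 1, 2, 2), 2),
                     m2 = rep(c(1, 2, 1, 2), 2),
                     r = rep(30, 8), n = rep(1000, 8))
  for (m in c("M1", "M2", "M1M2")) {
    d <- controlled_direct_effect(cc0, m, S = 1000, seed = 2)
    expect_equal(median(d$values), 0)
  }
})

test_that("CDE margins recover their calibration targets within MC error", {
  fit <- recovery_fit(te_target = 0.03,
                      cde_targets = list(M1 = 0.02, M2 = 0.015, M1M2 = 0.01),
                      baseline = 0.2, n_per_race = c(2e6, 1e6), seed = 23)
  o <- fit$outcomes[[1]]
  truth <- c(TE = 0.03, M1 = 0.02, M2 = 0.015, M1M2 = 0.01)
  draws <- c(list(TE = fit$outcomes[[1]]$te), o$cde)
  for (nm in names(truth)) {
    d <- draws[[nm]]$values
    expect_lt(abs(median(d) - truth[[nm]]), 4 * sd(d))
  }
})

test_that("percent attributable follows the draw-wise formula and sign convention", {
  te <- posterior_draws(rep(0.0105, 200))
  cde <- posterior_draws(rep(0.0125, 200))
  pa <- percent_attributable(te, cde)
  expect_equal(unique(pa$values), 100 * (0.0105 - 0.0125) / 0.0105) # -19.0476...
  expect_lt(unique(pa$values), 0)   # mediator optimization increases disparity

  expect_equal(unique(percent_attributable(te, posterior_draws(rep(0, 200)))$values), 100)
  expect_equal(unique(percent_attributable(te, te)$values), 0)
})

test_that("zero-TE draws are excluded with a count, never clamped", {
  te <- posterior_draws(c(0, 0.01, 0.02, rep(0.01, 197)))
  cde <- posterior_draws(rep(0.005, 200))
  pa <- percent_attributable(te, cde)
  expect_equal(attr(pa, "n_undefined"), 1)
  expect_equal(sum(is.na(pa$values)), 1)
  est <- summarize_draws(pa, "percent")
  expect_equal(est$n_undefined, 1)

  all_zero <- posterior_draws(rep(0, 200))
  expect_error(percent_attributable(all_zero, cde), "undefined")
})

test_that("PA requires paired draws", {
  te <- posterior_draws(runif(200), master = 1)
  expect_error(percent_attributable(te, posterior_draws(runif(100), master = 1)),
               "same number of draws")
  expect_error(percent_attributable(te, posterior_draws(runif(200), master = 2)),
               "master seeds")
})

test_that("draw-wise PA differs from the ratio of summarized medians", {
  # a skewed joint distribution where medians do not commute with the ratio
  set.seed(77)
  te <- posterior_draws(rlnorm(10000, log(0.01), 0.8))
  cde <- posterior_draws(0.5 * te$values + rlnorm(10000, log(0.005), 0.8))
  pa_drawwise <- summarize_draws(percent_attributable(te, cde), "percent")
  pa_of_medians <- 100 * (median(te$values) - median(cde$values)) / median(te$values)
  expect_gt(abs(pa_drawwise$median - pa_of_medians), 1)
  # and the draw-wise form is what summarize reports
  expect_equal(pa_drawwise$median,
               median(100 * (te$values - cde$values) / te$values))
})

test_that("summaries use equal-tailed percentiles and the zero-exclusion rule", {
  const <- posterior_draws(rep(0.4, 500))
  est <- summarize_draws(const)
  expect_equal(c(est$ci_low, est$median, est$ci_high), rep(0.4, 3))
  expect_true(est$significant)
  expect_false(summarize_draws(posterior_draws(rep(0, 500)))$significant)

  sym <- posterior_draws(c(seq(-1, 1, length.out = 501)))
  expect_false(summarize_draws(sym)$significant)

  set.seed(8)
  u <- posterior_draws(runif(10000))
  est_u <- summarize_draws(u)
  expect_lt(abs(est_u$median - 0.5), 3 * quantile_mc_se(0.5, 10000, 1))
  expect_lt(abs(est_u$ci_low - 0.025), 3 * quantile_mc_se(0.025, 10000, 1))
  expect_lt(abs(est_u$ci_high - 0.975), 3 * quantile_mc_se(0.975, 10000, 1))

  scaled <- summarize_draws(posterior_draws(rep(0.0105, 500)), "per1000")
  expect_equal(scaled$median, 10.5)
  expect_error(summarize_draws(posterior_draws(rep(0.1, 50))), "at least 100")
})

test_that("ordering of ci_low <= median <= ci_high always holds", {
  set.seed(12)
  for (k in 1:20) {
    est <- summarize_draws(posterior_draws(rnorm(500, sd = runif(1, 0.1, 2))))
    expect_true(est$ci_low <= est$median && est$median <= est$ci_high)
    expect_equal(est$significant, !(est$ci_low <= 0 && est$ci_high >= 0))
  }
})

test_that("the fit object exposes the model through the standard methods", {
  fit <- recovery_fit(te_target = 0.03, cde_targets = list(M1M2 = 0.015),
                      baseline = 0.2, n_per_race = c(5e5, 2e5), seed = 9,
                      S = 2000, outcome = "cesarean")
  expect_s3_class(fit, "po_mediation")
  expect_output(print(fit), "outcomes: cesarean")
  sm <- summary(fit)
  expect_setequal(sm$estimate_type, c("TE", "PA_M1", "PA_M2", "PA_M1M2"))
  expect_true(all(sm$ci_low <= sm$median & sm$median <= sm$ci_high))
  cf <- coef(fit)
  expect_equal(dim(cf), c(1, 4))
  expect_equal(cf["cesarean", "TE"], sm$median[sm$estimate_type == "TE"])
  ci <- confint(fit)
  expect_equal(ncol(ci), 2)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims$cesarean, 3)
  expect_true(all(vapply(sims$cesarean, inherits, logical(1), "cell_counts")))
  expect_equal(sims$cesarean[[1]]$n, fit$outcomes$cesarean$cells$n)
})

test_that("identical outcomes under one master seed give identical report rows", {
  cc <- toy_cells("gest_htn")
  cc2 <- cell_counts(cc$x, cc$m1, cc$m2, cc$r, cc$n, outcome = "icu")
  fit <- po_mediate(list(gest_htn = cc, icu = cc2), S = 1000, seed = 4)
  sm <- summary(fit)
  a <- sm[sm$outcome == "gest_htn", -1]
  b <- sm[sm$outcome == "icu", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("conjugate and iterative engines agree on the summaries", {
  cc <- toy_cells()
  fit_c <- po_mediate(cc, S = 4000, seed = 15, engine = "conjugate")
  fit_g <- po_mediate(cc, S = 4000, seed = 15, engine = "gibbs",
                      burn_in = 100, chains = 2)
  sc <- summary(fit_c); sg <- summary(fit_g)
  te_sd <- sd(fit_c$outcomes[[1]]$te$values) * 1000
  expect_lt(abs(sc$median[sc$estimate_type == "TE"] -
                  sg$median[sg$estimate_type == "TE"]), 4 * 1.253 * te_sd / sqrt(4000))
})

test_that("credible intervals cover the generating truth at the nominal rate", {
  prev <- reference_prevalence()
  te_true <- 0.02
  probs <- calibrate_cell_probs(prev, te_target = te_true, baseline = 0.1)
  n_rep <- 200
  covered <- 0
  for (k in seq_len(n_rep)) {
    cfg <- generator_config(c(1e5, 1e5), prev, list(y = probs),
                            seed = 1000 + k, level = "cell")
    cells <- simulate_cell_counts(cfg)
    te <- total_effect(cells[[1]], S = 1000, seed = 1000 + k)
    ci <- quantile(te$values, c(0.025, 0.975))
    if (ci[1] <= te_true && te_true <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.91)
  expect_lte(covered / n_rep, 0.99)
})
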