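test_that("BMI derivation matches hand arithmetic and flags bad input as NA", {
  expect_equal(derive_bmi(160, 64), 25.0)
  expect_equal(derive_bmi(180, 59.94), 18.5)
  expect_equal(derive_bmi(165, 70), 70 / 1.65^2)  # 25.711...
  expect_true(is.na(derive_bmi(NA, 70)))
  expect_true(is.na(derive_bmi(160, NA)))
  expect_true(is.na(derive_bmi(0, 70)))
  expect_true(is.na(derive_bmi(160, -5)))
  expect_equal(derive_bmi(c(160, 180), c(64, 59.94)), c(25, 18.5))
})

test_that("GWG is corrected to 40 weeks by proportional scaling", {
  expect_equal(adjust_gwg(60, 74, 40), 14)
  expect_equal(adjust_gwg(60, 74, 35), 16)
  expect_equal(adjust_gwg(55, 67.5, 38), 12.5 * 40 / 38)  # 13.157...
  expect_true(is.na(adjust_gwg(NA, 74, 40)))
  expect_true(is.na(adjust_gwg(60, 74, 0)))
  expect_true(is.na(adjust_gwg(60, 74, -1)))
  # weight loss is preserved, not dropped
  expect_equal(adjust_gwg(70, 65, 40), -5)
})

test_that("mediator classification applies the documented boundary conventions", {
  expect_equal(classify_mediators(22, 12), list(m1 = 1L, m2 = 1L))
  expect_equal(classify_mediators(25, 16), list(m1 = 2L, m2 = 1L))   # BMI 25 excluded
  expect_equal(classify_mediators(18.5, 11.5), list(m1 = 1L, m2 = 1L))
  expect_equal(classify_mediators(17, 20)$m1, 2L)
  expect_equal(classify_mediators(22, 16.0001)$m2, 2L)
  # conventions are configurable
  expect_equal(classify_mediators(25, 16, bmi_upper_inclusive = TRUE)$m1, 1L)
  expect_equal(classify_mediators(22, 16, gwg_upper_inclusive = FALSE)$m2, 2L)
  # negative adjusted GWG is allowed and non-optimal
  expect_equal(classify_mediators(22, -3)$m2, 2L)
})

make_complete_record <- function(n = 1) {
  one <- data.frame(race_class = 1, height = 160, prepreg_weight = 55,
                    delivery_weight = 68, gestation_weeks = 40,
                    gest_htn = 0, htn_eclampsia = 0, induction = 0,
                    cesarean = 0, icu = 0)
  one[rep(1L, n), , drop = FALSE]
}

test_that("filtering deletes missing-outcome records first, then missing anthropometrics", {
  df <- make_complete_record(4)
  df$icu[2] <- NA                       # outcome missing
  df$height[3] <- NA                    # anthropometrics missing
  df$icu[4] <- NA; df$height[4] <- NA   # both: counted at the outcome stage
  prep <- filter_records(df)
  expect_s3_class(prep, "prepared_records")
  expect_equal(prep$log$input, 4)
  expect_equal(prep$log$missing_outcome, 2)
  expect_equal(prep$log$missing_anthro, 1)
  expect_equal(prep$log$retained, 1)
  expect_equal(prep$log$input,
               prep$log$retained + prep$log$missing_outcome + prep$log$missing_anthro)
  # survivor carries derived classes: BMI 55/1.6^2 = 21.5 optimal, GWG 13 optimal
  expect_equal(prep$records$m1, 1L)
  expect_equal(prep$records$m2, 1L)
})

test_that("aggregation zero-fills, partitions retained records and counts cases", {
  empty <- filter_records(make_complete_record(0))
  cc0 <- aggregate_cells(empty, "cesarean")
  expect_equal(nrow(cc0), 8)
  expect_true(all(cc0$r == 0 & cc0$n == 0))

  # one record per Black cell, all cases
  df <- data.frame(race_class = 2, height = 160, prepreg_weight = c(55, 55, 80, 80),
                   delivery_weight = c(68, 75, 93, 100), gestation_weeks = 40,
                   gest_htn = 0, htn_eclampsia = 0, induction = 0, cesarean = 1, icu = 0)
  prep <- filter_records(df)
  expect_equal(sort(paste(prep$records$m1, prep$records$m2)),
               c("1 1", "1 2", "2 1", "2 2"))
  cc <- aggregate_cells(prep, "cesarean")
  expect_true(all(cc$r[cc$x == 2] == 1 & cc$n[cc$x == 2] == 1))
  expect_true(all(cc$r[cc$x == 1] == 0 & cc$n[cc$x == 1] == 0))
  expect_equal(sum(cc$n), prep$log$retained)
})

test_that("cell rates from aggregated simulated records match the generating truth", {
  prev <- reference_prevalence()
  probs <- cell_probs(seq(0.05, 0.40, length.out = 8))
  cfg <- generator_config(5e4, prev, probs, seed = 21, level = "record")
  prep <- filter_records(simulate_records(cfg))
  expect_equal(prep$log$retained, prep$log$input)  # no missingness configured
  cc <- aggregate_cells(prep, "cesarean")
  expect_equal(sum(cc$n), 1e5)
  p_true <- probs[cbind(cc$x, cc$m1, cc$m2)]
  se <- sqrt(p_true * (1 - p_true) / cc$n)
  expect_true(all(abs(cc$r / cc$n - p_true) < 4 * se))
})

test_that("prevalence table normalizes within race and rejects empty races", {
  cc <- toy_cells()
  prev <- prevalence_table(cc)
  expect_equal(rowSums(unclass(prev)), c(non_black = 100, black = 100))
  expect_equal(as.numeric(prev[1, ]), rep(25, 4))  # equal n in all cells

  one_race <- cell_counts(rep(1, 4), c(1, 1, 2, 2), c(1, 2, 1, 2),
                          r = rep(0, 4), n = rep(10, 4))
  expect_error(prevalence_table(one_race), "zero births")
})

test_that("prevalence constructor rescales printed percentages and rejects bad rows", {
  # a published column summing to 99.9 is rescaled to exactly 100
  prev <- prevalence_table(rbind(c(15.1, 14.0, 29.2, 41.7),
                                 c(9.7, 14.7, 24.2, 51.3)))
  expect_equal(rowSums(unclass(prev)), c(non_black = 100, black = 100))
  expect_equal(prev[2, 4], 51.3 / 99.9 * 100, tolerance = 1e-12)
  expect_error(prevalence_table(rbind(c(50, 30, 10, 5), c(25, 25, 25, 25))),
               "sum to 100")
})

test_that("record reader maps columns, converts units and honours sentinels", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  df <- make_complete_record(2)
  names(df)[2] <- "MHTR"
  df$MHTR <- c(63, 999)  # inches; second row a sentinel unknown
  df$prepreg_weight <- c(121, 130)  # pounds
  df$delivery_weight <- c(150, 160)
  write.csv(df, tmp, row.names = FALSE, na = "")
  rec <- read_birth_records(tmp, col_map = c(height = "MHTR"), units = "imperial")
  expect_equal(rec$height[1], 63 * 2.54)
  expect_true(is.na(rec$height[2]))
  expect_equal(rec$prepreg_weight[1], 121 * 0.45359237)

  # unparsable rows are an error naming the row
  writeLines(c("race_class,height,prepreg_weight,delivery_weight,gestation_weeks,gest_htn,htn_eclampsia,induction,cesarean,icu",
               "1,160,55,68,forty,0,0,0,0,0"), tmp)
  expect_error(read_birth_records(tmp), "row 1")
})
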