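test_that("generation is deterministic and has the right cardinalities", {
  cfg <- cohort_config(n = 50, seed = 101)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$complications, b$complications)
  expect_identical(a$followup, b$followup)
  expect_identical(nrow(a$patients), 50L)
  expect_identical(nrow(a$followup), 50L)
  expect_identical(nrow(a$truth), 50L)
  # skipping complication records leaves everything else untouched
  c <- generate_cohort(cfg, complications = FALSE)
  expect_identical(a$patients, c$patients)
  expect_identical(a$followup, c$followup)
  expect_null(c$complications)
})

test_that("marginal category frequencies converge to the configuration", {
  co <- generate_cohort(cohort_config(n = 100000, seed = 102),
                        complications = FALSE)
  sm <- prop.table(table(factor(co$truth$points_smb, levels = 1:4)))
  expect_true(all(abs(as.numeric(sm) - c(0.24, 0.36, 0.14, 0.26)) < 0.01))
  iga <- prop.table(table(factor(co$truth$points_iga, levels = c(1, 2, 4))))
  expect_true(all(abs(as.numeric(iga) - c(0.26, 0.24, 0.50)) < 0.01))
  expect_lt(abs(mean(co$truth$points_igm == 4) - 0.06), 0.01)
  cd4 <- prop.table(table(factor(co$truth$points_cd4, levels = 1:4)))
  expect_true(all(abs(as.numeric(cd4) - c(0.44, 0.12, 0.32, 0.12)) < 0.01))
  ab <- prop.table(table(factor(co$truth$points_ab, levels = c(1, 2, 4))))
  expect_lt(abs(ab[["4"]] - 0.58), 0.01)   # both responses altered
  expect_lt(abs(ab[["2"]] - 0.42), 0.01)   # exactly one altered
})

test_that("diagnosis ages respect the configured bounded distribution", {
  co <- generate_cohort(cohort_config(n = 20000, seed = 103),
                        complications = FALSE)
  age <- co$patients$age_at_diagnosis_years
  expect_true(all(age > 4 & age < 70))
  expect_lt(abs(stats::median(age) - 32), 1)
})

test_that("generated labs re-categorize to the drawn categories", {
  co <- generate_cohort(cohort_config(n = 500, seed = 104))
  chk <- roundtrip_check(co)
  expect_true(chk$ok)
  expect_identical(chk$n_mismatch, 0L)
})

test_that("a corrupted interval configuration is caught by the roundtrip", {
  ints <- visualcvid:::default_intervals()
  ints$smb$`2` <- c(7, 12)  # draws category-2 values in category-1 range
  co <- generate_cohort(cohort_config(n = 200, seed = 105,
                                      intervals = ints))
  chk <- roundtrip_check(co)
  expect_false(chk$ok)
  expect_gt(chk$n_mismatch, 0)
  expect_true(all(chk$mismatches$analyte == "points_smb"))
})

test_that("severity totals and complication records are cluster-consistent", {
  co <- generate_cohort(cohort_config(n = 80, seed = 106))
  amer <- severity_catalog("ameratunga")
  grim <- severity_catalog("grimbacher")
  sa <- score_severity(co$complications, amer,
                       patients = co$truth$patient_id)
  sg <- score_severity(co$complications, grim,
                       patients = co$truth$patient_id)
  # decomposed records reproduce the drawn totals exactly
  expect_identical(as.integer(sa$total), co$truth$ameratunga_total)
  expect_identical(as.integer(sg$total), co$truth$grimbacher_total)
  # and therefore the drawn cluster proportions, exactly
  expect_identical(as.character(sa$cluster), as.character(co$truth$cluster))
  expect_identical(as.character(sg$cluster), as.character(co$truth$cluster))
  expect_true(all(sa$total[sa$cluster == "B"] >= 14))
  expect_true(all(sa$total[sa$cluster == "A"] <= 13))
  expect_true(all(sg$total[sg$cluster == "B"] >= 5))
})

test_that("the severity link is calibrated near the target prevalence", {
  co <- generate_cohort(cohort_config(n = 50000, seed = 107),
                        complications = FALSE)
  expect_lt(abs(mean(co$truth$cluster == "B") - 0.56), 0.03)
})

test_that("stronger association raises the mean AUC monotonically", {
  mean_auc <- function(beta) {
    aucs <- vapply(1:10, function(s) {
      co <- generate_cohort(cohort_config(n = 200, seed = 700 + s,
                                          beta = beta),
                            complications = FALSE)
      if (length(unique(co$truth$cluster)) < 2) return(NA_real_)
      roc_auc(co$truth$visual_total, co$truth$cluster)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  a0 <- mean_auc(0)
  a1 <- mean_auc(log(1.3))
  a2 <- mean_auc(log(2))
  expect_lt(a0, a1)
  expect_lt(a1, a2)
})

test_that("empty or invalid generator configurations error", {
  expect_error(cohort_config(n = 50), "seed")
  expect_error(cohort_config(n = 1, seed = 1), "at least 2")
  expect_error(cohort_config(n = 10, seed = 1,
                             smb_probs = c(`1` = 0.5, `2` = 0.2,
                                           `3` = 0.2, `4` = 0.2)),
               "sum to 1")
  expect_error(cohort_config(n = 10, seed = 1, beta = Inf), "finite")
})

test_that("cohorts round-trip through CSV files", {
  co <- generate_cohort(cohort_config(n = 20, seed = 108))
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  back <- readr::read_csv(file.path(dir, "patients.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), 20)
  expect_equal(back$smb_pct, co$patients$smb_pct, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "generator_config.yaml")))
})
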