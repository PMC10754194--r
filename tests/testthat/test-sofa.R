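test_that("PF ratio is the exact quotient with guarded domains", {
  expect_equal(pf_ratio(100, 0.21), 476.2, tolerance = 0.1 / 476.2)
  expect_equal(pf_ratio(60, 1.0), 60)
  expect_equal(pf_ratio(80, 0.40), 200)
  expect_error(pf_ratio(0, 0.5), "positive")
  expect_error(pf_ratio(100, 0.1), "fio2")
})

test_that("PF-based respiratory score transcribes the classic table", {
  expect_equal(resp_sofa_from_pf(350, FALSE), 1L)
  expect_equal(resp_sofa_from_pf(150, TRUE), 3L)
  expect_equal(resp_sofa_from_pf(90, TRUE), 4L)
  expect_equal(resp_sofa_from_pf(150, FALSE), 2L)  # support cap
  expect_equal(resp_sofa_from_pf(450, FALSE), 0L)
  # boundaries: thresholds are strict "less than"
  expect_equal(resp_sofa_from_pf(c(400, 300, 200, 100), TRUE),
               c(0L, 1L, 2L, 3L))
  expect_equal(resp_sofa_from_pf(c(399.9, 299.9, 199.9, 99.9), TRUE),
               c(1L, 2L, 3L, 4L))
})

test_that("SpO2-threshold respiratory score follows the printed cutoffs", {
  expect_equal(resp_sofa_spo2_thresholds(93, FALSE), 1L)
  expect_equal(resp_sofa_spo2_thresholds(96, TRUE), 1L)
  expect_equal(resp_sofa_spo2_thresholds(84, TRUE), 4L)
  expect_equal(resp_sofa_spo2_thresholds(85, FALSE), 3L)
  # boundary values sit in the lower band (inclusive upper limits)
  expect_equal(resp_sofa_spo2_thresholds(c(95, 94, 91, 90, 86, 85), FALSE),
               c(0L, 1L, 1L, 2L, 2L, 3L))
  # the support bonus never decreases the score and caps at 4
  grid <- seq(50, 100, by = 0.5)
  expect_true(all(resp_sofa_spo2_thresholds(grid, TRUE) >=
                    resp_sofa_spo2_thresholds(grid, FALSE)))
  expect_true(all(resp_sofa_spo2_thresholds(grid, TRUE) <= 4))
})

test_that("method dispatch composes estimators, PF and support correctly", {
  rec <- make_record(spo2_pct = 98)  # pao2 missing, room air
  expect_equal(respiratory_sofa(rec, "CONV"), 0L)
  rec2 <- make_record(spo2_pct = 90, pao2_mmhg = 70)
  expect_equal(respiratory_sofa(rec2, "A"), 2L)  # 60/0.21 = 285.7
  expect_equal(respiratory_sofa(rec2, "B"), 1L)  # 70/0.21 = 333.3
  expect_equal(respiratory_sofa(rec2, "C"),
               resp_sofa_from_pf(estimate_pao2_hill(90) / 0.21, FALSE))
  expect_equal(respiratory_sofa(rec2, "D"), 1L)
  expect_equal(respiratory_sofa(rec2, "E"), 2L)
  expect_equal(respiratory_sofa(rec2, "F"), 1L)
  expect_error(respiratory_sofa(rec2, "G"))
})

test_that("conventional imputation modes differ only for missing PaO2", {
  on_o2 <- make_record(spo2_pct = 93, device = "SIMPLE_MASK", flow_lpm = 6)
  # imputed 100 mmHg at FiO2 0.40 -> PF 250 -> 2; score-zero mode gives 0
  expect_equal(respiratory_sofa(on_o2, "CONV"), 2L)
  expect_equal(respiratory_sofa(on_o2, "CONV", conv_mode = "score_zero"), 0L)
  measured <- make_record(spo2_pct = 93, pao2_mmhg = 65,
                          device = "SIMPLE_MASK", flow_lpm = 6)
  expect_equal(respiratory_sofa(measured, "CONV"),
               respiratory_sofa(measured, "CONV", conv_mode = "score_zero"))
})

test_that("all-records methods ignore measured PaO2; fill-in methods match the conventional branch", {
  cohort <- generate_cohort(default_config(n = 400, seed = 5))$records
  perturbed <- cohort
  keep <- !is.na(perturbed$pao2_mmhg)
  perturbed$pao2_mmhg[keep] <- perturbed$pao2_mmhg[keep] + 17
  for (m in c("A", "C", "E")) {
    expect_identical(respiratory_sofa(cohort, m),
                     respiratory_sofa(perturbed, m))
  }
  conv <- respiratory_sofa(cohort, "CONV")
  for (m in c("B", "D", "F")) {
    est <- respiratory_sofa(cohort, m)
    expect_identical(est[keep], conv[keep])
  }
})

test_that("respiratory score is weakly decreasing in oxygenation", {
  spo2_grid <- seq(55, 100, by = 1)
  for (m in c("A", "C", "E")) {
    sc <- vapply(spo2_grid, function(s) {
      respiratory_sofa(make_record(spo2_pct = s), m)
    }, integer(1))
    expect_true(all(diff(sc) <= 0))
  }
  pao2_grid <- seq(40, 120, by = 2)
  for (m in c("CONV", "B", "D", "F")) {
    sc <- vapply(pao2_grid, function(p) {
      respiratory_sofa(make_record(spo2_pct = 95, pao2_mmhg = p), m)
    }, integer(1))
    expect_true(all(diff(sc) <= 0))
  }
})

test_that("non-respiratory organ scores transcribe the classic thresholds", {
  healthy <- make_record()
  expect_equal(unlist(nonrespiratory_sofa(healthy)),
               c(coagulation = 0L, liver = 0L, cardiovascular = 0L,
                 cns = 0L, renal = 0L))
  expect_equal(nonrespiratory_sofa(make_record(platelets_k_ul = 45))$coagulation, 3L)
  expect_equal(nonrespiratory_sofa(make_record(map_mmhg = 65))$cardiovascular, 1L)
  expect_equal(
    nonrespiratory_sofa(make_record(platelets_k_ul = c(160, 149, 99, 49, 19)))$coagulation,
    c(0L, 1L, 2L, 3L, 4L))
  expect_equal(
    nonrespiratory_sofa(make_record(bilirubin_mg_dl = c(1.1, 1.2, 2, 6, 12)))$liver,
    c(0L, 1L, 2L, 3L, 4L))
  expect_equal(
    nonrespiratory_sofa(make_record(vasopressor_cat = vasopressor_categories,
                                    map_mmhg = 60))$cardiovascular,
    c(1L, 2L, 3L, 4L))
  expect_equal(
    nonrespiratory_sofa(make_record(gcs = c(15L, 14L, 13L, 12L, 10L, 9L, 6L, 5L, 3L)))$cns,
    c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(
    nonrespiratory_sofa(make_record(creatinine_mg_dl = c(1.1, 1.2, 2, 3.5, 5)))$renal,
    c(0L, 1L, 2L, 3L, 4L))
  expect_error(nonrespiratory_sofa(make_record(gcs = 16L)), "gcs")
  expect_error(nonrespiratory_sofa(make_record(vasopressor_cat = "ADRENALINE")),
               "vasopressor")
})

test_that("total SOFA is the sum of the six sub-scores, 0 to 24", {
  healthy <- make_record()
  for (m in sofa_methods) {
    expect_equal(total_sofa(healthy, m)$total, 0L)
  }
  worst <- make_record(spo2_pct = 70, pao2_mmhg = 40,
                       device = "MECHANICAL_VENT", set_fio2 = 1.0,
                       platelets_k_ul = 10, bilirubin_mg_dl = 15,
                       map_mmhg = 40, vasopressor_cat = "DOPA_GT15_OR_EPI_GT01",
                       gcs = 3L, creatinine_mg_dl = 6)
  expect_equal(total_sofa(worst, "CONV")$total, 24L)
  # additivity over a large generated cohort, every method
  cohort <- generate_cohort(default_config(n = 10000, seed = 99))$records
  for (m in sofa_methods) {
    br <- total_sofa(cohort, m)
    expect_true(all(br$total == br$respiratory + br$coagulation + br$liver +
                      br$cardiovascular + br$cns + br$renal))
    expect_true(all(br$total >= 0 & br$total <= 24))
    sub <- br[, c("respiratory", "coagulation", "liver", "cardiovascular",
                  "cns", "renal")]
    expect_true(all(as.matrix(sub) %in% 0:4))
  }
  # records differing only in respiratory inputs differ only there
  a <- total_sofa(make_record(spo2_pct = 85), "E")
  b <- total_sofa(make_record(spo2_pct = 98), "E")
  expect_equal(a$total - b$total, a$respiratory - b$respiratory)
})

test_that("score_cohort stacks one block per method", {
  cohort <- generate_cohort(default_config(n = 50, seed = 3))$records
  long <- score_cohort(cohort, methods = c("CONV", "E"))
  expect_equal(nrow(long), 100)
  expect_equal(unique(long$method), c("CONV", "E"))
})
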