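test_that("cmax/tmax pick the observed maximum with earliest-time ties", {
  expect_equal(find_cmax_tmax(1, 2.0), tibble::tibble(cmax = 2.0, tmax = 1))
  tie <- find_cmax_tmax(c(1, 2, 3), c(1, 2, 2))
  expect_equal(tie$tmax, 2)
  expect_error(find_cmax_tmax(c(1, 2), c(0, 0)), "quantifiable")
})

test_that("profile cleaning anchors (0,0) and drops BLQ records", {
  p <- nca_profile(c(0, 1, 2, 3), c(NA, 1, NA, 0.5),
                   blq = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(p$time_h, c(0, 1, 3))
  expect_equal(p$conc_ng_ml, c(0, 1, 0.5))
  expect_true(p$anchor[1])
  expect_error(nca_profile(c(1, 1, 2), c(1, 2, 3)), "strictly increasing")
})

test_that("lambda-z is exact on mono-exponential data", {
  t <- c(48, 72, 96)
  lz <- fit_lambda_z(t, exp(-0.02 * t))
  expect_equal(lz$lambda_z, 0.02, tolerance = 1e-10)
  expect_equal(lz$r2_adj, 1)
  expect_equal(lz$n_lambda_points, 3L)
})

test_that("lambda-z on the sampling schedule approximates the model ke", {
  prof <- typical_profile()
  lz <- fit_lambda_z(prof$time_h, prof$conc_ng_ml)
  expect_equal(lz$lambda_z, typical_ke(), tolerance = 0.02)
})

test_that("rising or too-short terminal phases are rejected", {
  t <- 1:5
  expect_error(fit_lambda_z(t, c(1, 0.2, 0.3, 0.45, 0.7)), "terminal phase")
  expect_error(fit_lambda_z(c(1, 2, 3), c(1, 2, 0.5)), "fewer than 3")
})

test_that("linear-up/log-down integrator matches hand-computed examples", {
  expect_equal(auc_linuplogdown(c(0, 1, 2), c(0, 1, 1)), 1.5)
  expect_equal(auc_linuplogdown(c(0, 1, 2), c(0, 4, 2)), 2 + 2 / log(2))
})

test_that("dense integration of the model profile matches the closed-form AUC", {
  tt <- seq(0, 1200, by = 0.1)
  prof <- typical_profile(tt)
  auc <- auc_linuplogdown(prof$time_h, prof$conc_ng_ml)
  expect_equal(auc, 59.31, tolerance = 5e-3)
})

test_that("AUC extrapolation follows clast/lambda_z", {
  ext <- extrapolate_auc(50, 0.2, 0.02)
  expect_equal(ext$auc_inf, 60)
  expect_equal(ext$pct_extrap, 100 / 6, tolerance = 1e-10)
  expect_equal(extrapolate_auc(50, 0, 0.02)$pct_extrap, 0)
})

test_that("NCA on dense noise-free profiles recovers the generating model", {
  tt <- sort(unique(c(seq(0.05, 12, by = 0.05), seq(12, 1200, by = 1))))
  prof <- typical_profile(tt)
  res <- run_nca(tibble::tibble(subject_id = "T", time_h = prof$time_h,
                                conc_ng_ml = prof$conc_ng_ml))
  sec <- derive_secondary(typical_params(), std_dose())
  expect_equal(res$lambda_z, sec$ke, tolerance = 0.01)
  expect_equal(res$t_half, sec$t_half, tolerance = 0.01)
  expect_equal(res$auc_inf, sec$auc_inf_model, tolerance = 0.01)
})

test_that("trailing BLQ records do not change auc_last", {
  prof <- typical_profile()
  base <- tibble::tibble(subject_id = "A", time_h = prof$time_h,
                         conc_ng_ml = prof$conc_ng_ml, blq = FALSE)
  extra <- dplyr::bind_rows(base, tibble::tibble(
    subject_id = "A", time_h = c(340, 360), conc_ng_ml = NA_real_, blq = TRUE))
  expect_equal(run_nca(extra)$auc_last, run_nca(base)$auc_last)
})

test_that("extrapolated fraction shrinks as sampling extends", {
  lasts <- c(120, 240, 480)
  pcts <- vapply(lasts, function(tl) {
    tt <- c(plasma_schedule()[plasma_schedule() <= tl], tl)
    prof <- typical_profile(sort(unique(tt)))
    run_nca(tibble::tibble(subject_id = "A", time_h = prof$time_h,
                           conc_ng_ml = prof$conc_ng_ml))$pct_extrap
  }, numeric(1))
  expect_true(all(diff(pcts) < 0))
})

test_that("predicted-clast toggle changes only the extrapolated tail", {
  cfg <- study_config(seed = 4)
  pl <- gen_plasma(cfg)
  obs <- run_nca(pl, clast = "observed")
  prd <- run_nca(pl, clast = "predicted")
  expect_equal(obs$auc_last, prd$auc_last)
  expect_false(isTRUE(all.equal(obs$auc_inf, prd$auc_inf)))
})

test_that("cohort summary reports mean, SD, median and range per parameter", {
  res <- tibble::tibble(subject_id = c("a", "b", "c"), cmax = c(1, 2, 3))
  s <- nca_cohort_summary(res)
  row <- s[s$parameter == "cmax", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sd, 1)
  expect_equal(row$median, 2)
  expect_equal(c(row$min, row$max), c(1, 3))
  one <- nca_cohort_summary(tibble::tibble(subject_id = "a", cmax = 5))
  expect_equal(one$sd[one$parameter == "cmax"], 0)
  expect_equal(one$n[one$parameter == "cmax"], 1)
})
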