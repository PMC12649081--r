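test_that("fractional excretion matches hand-computed examples", {
  expect_equal(fractional_excretion(50, 4, 100, 2), 25)
  # identical analyte and creatinine ratios give exactly 100%
  expect_equal(fractional_excretion(12, 3, 8, 2), 100)
  # halving urine creatinine doubles FE
  expect_equal(fractional_excretion(50, 4, 50, 2),
               2 * fractional_excretion(50, 4, 100, 2))
  expect_error(fractional_excretion(0, 4, 100, 2), "> 0")
  expect_error(fractional_excretion(50, 4, -1, 2), "> 0")
})

test_that("fractional excretion is invariant to unit rescaling", {
  base <- fractional_excretion(50, 4, 100, 2)
  # mmol/L -> mg/dL style common rescaling of the analyte pair
  expect_equal(fractional_excretion(50 * 18, 4 * 18, 100, 2), base)
  # and of the creatinine pair
  expect_equal(fractional_excretion(50, 4, 100 * 88.4, 2 * 88.4), base)
})

test_that("censored summaries report quantifiable-only means and counts", {
  d <- tibble::tibble(time_h = 24, conc_ng_ml = c(0.2, 0.04, 0.03))
  s <- censored_summary(d, loq = 0.05)
  expect_equal(s$mean, 0.2)
  expect_equal(s$n_above_loq, 1L)
  expect_equal(s$n_total, 3L)
  expect_false(s$nd)
  all_blq <- censored_summary(
    tibble::tibble(time_h = 360, conc_ng_ml = c(0.01, 0.02)), loq = 0.05)
  expect_true(all_blq$nd)
  expect_equal(all_blq$n_above_loq, 0L)
  expect_true(is.na(all_blq$mean))
  clean <- censored_summary(
    tibble::tibble(time_h = 1, conc_ng_ml = c(1, 2, 3)), loq = 0.05)
  expect_equal(clean$mean, 2)
  expect_equal(clean$sd, 1)
})

test_that("constant data produce a guarded zero F and no significant times", {
  d <- tidyr::expand_grid(subject_id = letters[1:4], time_h = c(0, 24, 48)) |>
    dplyr::mutate(value = 5)
  res <- rm_anova_baseline(d)
  expect_equal(res$anova$statistic[res$anova$term == "time"], 0)
  expect_equal(res$anova$p.value[res$anova$term == "time"], 1)
  expect_false(any(res$comparisons$significant))
})

test_that("two-subject knife-edge case is not significant after adjustment", {
  d <- tibble::tibble(subject_id = rep(c("a", "b"), each = 2),
                      time_h = rep(c(0, 24), 2),
                      value = c(0, 1, 0, -1))
  res <- rm_anova_baseline(d)
  expect_gt(res$comparisons$p_adj, 0.05)
  expect_false(res$comparisons$significant)
})

test_that("F statistic and p-value agree with the aov() error-stratum fit", {
  set.seed(42)
  d <- tidyr::expand_grid(subject_id = sprintf("h%02d", 1:8),
                          time_h = c(0, 2, 8, 24, 72)) |>
    dplyr::mutate(value = 10 + stats::rnorm(dplyr::n()) +
                    rep(stats::rnorm(8), each = 5) - 0.05 * time_h)
  res <- rm_anova_baseline(d)
  ref <- summary(stats::aov(value ~ factor(time_h) + Error(factor(subject_id)),
                            data = d))
  ref_tab <- ref[["Error: Within"]][[1]]
  i <- res$anova$term == "time"
  expect_equal(res$anova$statistic[i], ref_tab[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$anova$p.value[i], ref_tab[["Pr(>F)"]][1], tolerance = 1e-10)
  # post hoc agrees with t.test(paired = TRUE)
  cmp <- res$comparisons[res$comparisons$time_h == 24, ]
  w <- tidyr::pivot_wider(d, names_from = time_h, values_from = value)
  tt <- stats::t.test(w[["24"]], w[["0"]], paired = TRUE)
  expect_equal(cmp$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(cmp$p_adj, min(1, tt$p.value * 4), tolerance = 1e-10)
})

test_that("Bonferroni-adjusted p-values dominate raw p-values", {
  set.seed(7)
  for (rep in 1:5) {
    d <- tidyr::expand_grid(subject_id = letters[1:6],
                            time_h = c(0, 1, 2, 4, 8, 24)) |>
      dplyr::mutate(value = stats::rnorm(dplyr::n()))
    res <- rm_anova_baseline(d)
    expect_true(all(res$comparisons$p_adj >= res$comparisons$p_raw - 1e-12))
    expect_true(all(res$comparisons$significant <=
                      (res$comparisons$p_raw < 0.05)))
  }
})

test_that("subjects without baseline are dropped with a warning", {
  d <- tidyr::expand_grid(subject_id = letters[1:4], time_h = c(0, 24)) |>
    dplyr::mutate(value = stats::rnorm(8))
  d <- d[!(d$subject_id == "d" & d$time_h == 0), ]
  expect_warning(res <- rm_anova_baseline(d), "without baseline")
  expect_equal(res$comparisons$n, 3L)
})

test_that("unbalanced data fall back to pairwise-complete post hoc", {
  d <- tidyr::expand_grid(subject_id = letters[1:5], time_h = c(0, 12, 24)) |>
    dplyr::mutate(value = stats::rnorm(15))
  d <- d[!(d$subject_id == "e" & d$time_h == 12), ]
  res <- rm_anova_baseline(d)
  expect_equal(res$comparisons$n[res$comparisons$time_h == 12], 4L)
  expect_equal(res$comparisons$n[res$comparisons$time_h == 24], 5L)
})

test_that("electrolyte pre/post comparison reduces to a paired test", {
  cfg <- study_config(seed = 6)
  el <- gen_electrolytes(cfg)
  k <- el |>
    dplyr::filter(analyte == "potassium") |>
    dplyr::transmute(subject_id,
                     time_h = ifelse(phase == "pre", 0, 72),
                     value = plasma_value)
  res <- rm_anova_baseline(k)
  expect_equal(nrow(res$comparisons), 1L)
  expect_true(res$comparisons$significant) # 3.8 -> 2.7 mmol/L shift, n = 12
  expect_lt(res$comparisons$mean_diff, 0)
})
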