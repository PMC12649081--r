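#' Urinary fractional excretion
#'
#' Fractional excretion of an analyte relative to creatinine clearance,
#' \deqn{FE = \frac{U_x / P_x}{U_{cr} / P_{cr}} \times 100,}
#' in percent. Units cancel within each ratio, so any common rescaling of
#' the analyte pair or of the creatinine pair leaves FE unchanged;
#' vectorised over samples.
#'
#' @param urine_x,plasma_x Analyte concentration in urine and plasma (same
#'   units as each other).
#' @param urine_creatinine,plasma_creatinine Creatinine concentration in
#'   urine and plasma (same units as each other).
#' @return Fractional excretion, percent.
#' @examples
#' fractional_excretion(50, 4, 100, 2) # 25
#' @export
fractional_excretion <- function(urine_x, plasma_x, urine_creatinine,
                                 plasma_creatinine) {
  args <- list(urine_x, plasma_x, urine_creatinine, plasma_creatinine)
  if (any(vapply(args, function(a) any(!is.finite(a)) || any(a <= 0), TRUE))) {
    stop("all concentrations must be finite and > 0", call. = FALSE)
  }
  (urine_x / plasma_x) / (urine_creatinine / plasma_creatinine) * 100
}

#' Summarise censored concentrations per time point
#'
#' For each time point, reports the mean and sample SD over quantifiable
#' values only, together with the count of subjects at or above the limit
#' of quantitation. Time points where every subject is below the LOQ are
#' reported as not detected (`nd = TRUE`, `NA` mean/SD).
#'
#' @param data Data frame with columns `time_h` and `conc_ng_ml` (and
#'   optionally logical `blq`; `NA` concentrations are treated as BLQ).
#' @param loq Limit of quantitation in the units of `conc_ng_ml`.
#' @return A tibble with `time_h`, `mean`, `sd`, `n_above_loq`, `n_total`,
#'   `nd`.
#' @export
censored_summary <- function(data, loq) {
  stopifnot(all(c("time_h", "conc_ng_ml") %in% names(data)), loq > 0)
  if (!"blq" %in% names(data)) data$blq <- FALSE
  data |>
    dplyr::mutate(
      quant = !(.data$blq | is.na(.data$conc_ng_ml)) & .data$conc_ng_ml >= loq
    ) |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      mean = if (any(.data$quant)) mean(.data$conc_ng_ml[.data$quant]) else NA_real_,
      sd = if (sum(.data$quant) > 1L) stats::sd(.data$conc_ng_ml[.data$quant]) else NA_real_,
      n_above_loq = sum(.data$quant),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(nd = .data$n_above_loq == 0L)
}

# Core repeated-measures machinery on a complete subjects x times matrix.
# Returns the ANOVA partition and vectorised baseline-vs-time paired tests.
.rm_anova_core <- function(m, times, alpha, n_pairwise = NULL, d_list = NULL) {
  n <- nrow(m); t_lev <- ncol(m)
  grand <- mean(m)
  ss_subj <- t_lev * sum((rowMeans(m) - grand)^2)
  ss_time <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_res <- ss_tot - ss_subj - ss_time
  df_time <- t_lev - 1L
  df_res <- (n - 1L) * (t_lev - 1L)
  ms_time <- ss_time / df_time
  ms_res <- ss_res / df_res
  f <- if (ms_res <= 0) {
    if (ms_time <= 0) 0 else Inf
  } else ms_time / ms_res
  p_f <- if (is.finite(f)) stats::pf(f, df_time, df_res, lower.tail = FALSE) else 0
  if (f == 0) p_f <- 1
  anova_tbl <- tibble::tibble(
    term = c("subject", "time", "residual"),
    df = c(n - 1L, df_time, df_res),
    sumsq = c(ss_subj, ss_time, ss_res),
    meansq = c(ss_subj / (n - 1L), ms_time, ms_res),
    statistic = c(NA, f, NA),
    p.value = c(NA, p_f, NA)
  )
  # paired t of each post-baseline column vs baseline (column 1)
  if (is.null(d_list)) {
    d_list <- lapply(2:t_lev, function(j) m[, j] - m[, 1])
  }
  m_comp <- length(d_list)
  comp <- purrr::map2_dfr(d_list, times[-1], function(d, tm) {
    d <- d[is.finite(d)]
    nd <- length(d)
    md <- mean(d)
    sdd <- stats::sd(d)
    tt <- if (nd < 2L || sdd == 0) {
      if (nd >= 2L && md == 0) 0 else NA_real_
    } else md / (sdd / sqrt(nd))
    p <- if (is.na(tt)) NA_real_ else 2 * stats::pt(-abs(tt), nd - 1L)
    if (!is.na(tt) && tt == 0) p <- 1
    tibble::tibble(time_h = tm, n = nd, mean_diff = md, statistic = tt,
                   p_raw = p)
  })
  comp$p_adj <- pmin(comp$p_raw * m_comp, 1)
  comp$significant <- !is.na(comp$p_adj) & comp$p_adj < alpha
  list(anova = anova_tbl, comparisons = comp)
}

#' Baseline-versus-time repeated-measures comparison with Bonferroni post hoc
#'
#' Implements the classical balanced one-within-factor repeated-measures
#' ANOVA (subject + time + residual sum-of-squares partition;
#' `F = MS_time / MS_residual` on `(t - 1, (n - 1)(t - 1))` df, exactly the
#' random-intercept mixed model for balanced data), followed by paired
#' t-tests of each post-baseline time against baseline on within-subject
#' differences, Bonferroni-adjusted by the number of post-baseline
#' comparisons and capped at 1.
#'
#' Subjects missing the baseline record are dropped with a warning. If the
#' remaining data are unbalanced, the ANOVA is computed on the subjects with
#' complete series and the post hoc tests use pairwise-complete subjects
#' with the per-comparison n reported.
#'
#' @param data Data frame with columns `subject_id`, `time_h`, `value`
#'   (one record per subject and time).
#' @param alpha Family significance level (default 0.05).
#' @param baseline_time Time coding the baseline record (default 0).
#'
#' @return An object of class `baseline_anova` with elements `anova`
#'   (tibble) and `comparisons` (tibble: `time_h`, `n`, `mean_diff`,
#'   `statistic`, `p_raw`, `p_adj`, `significant`).
#' @examples
#' cfg <- study_config(seed = 1)
#' res <- rm_anova_baseline(gen_cortisol(cfg))
#' tidy(res)
#' @export
rm_anova_baseline <- function(data, alpha = 0.05, baseline_time = 0) {
  stopifnot(all(c("subject_id", "time_h", "value") %in% names(data)))
  times <- sort(unique(data$time_h))
  if (!baseline_time %in% times) stop("no baseline records present", call. = FALSE)
  if (length(times) < 2L) stop("need at least 2 time points", call. = FALSE)
  times <- c(baseline_time, setdiff(times, baseline_time))
  has_base <- unique(data$subject_id[data$time_h == baseline_time])
  dropped <- setdiff(unique(data$subject_id), has_base)
  if (length(dropped) > 0L) {
    warning("dropping subject(s) without baseline: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    data <- dplyr::filter(data, .data$subject_id %in% has_base)
  }
  if (length(has_base) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (anyDuplicated(data[, c("subject_id", "time_h")])) {
    stop("one value per subject and time is required", call. = FALSE)
  }
  # subjects x times matrix (NA for missing cells)
  subj <- sort(unique(data$subject_id))
  m <- matrix(NA_real_, length(subj), length(times),
              dimnames = list(subj, times))
  m[cbind(match(data$subject_id, subj), match(data$time_h, times))] <- data$value
  complete <- stats::complete.cases(m)
  if (all(complete)) {
    res <- .rm_anova_core(m, times, alpha)
  } else {
    d_list <- lapply(2:ncol(m), function(j) (m[, j] - m[, 1]))
    if (sum(complete) >= 2L) {
      res <- .rm_anova_core(m[complete, , drop = FALSE], times, alpha,
                            d_list = d_list)
    } else {
      stop("fewer than 2 subjects with complete series; cannot form the ANOVA",
           call. = FALSE)
    }
  }
  structure(c(res, list(alpha = alpha, baseline_time = baseline_time)),
            class = "baseline_anova")
}

#' @export
print.baseline_anova <- function(x, ...) {
  cat("<baseline_anova>  F(time) =",
      signif(x$anova$statistic[x$anova$term == "time"], 4),
      " p =", format.pval(x$anova$p.value[x$anova$term == "time"]), "\n  ",
      sum(x$comparisons$significant), "of", nrow(x$comparisons),
      "post-baseline times significant at Bonferroni-adjusted alpha =",
      x$alpha, "\n")
  invisible(x)
}

#' Tidy the post hoc comparisons of a baseline ANOVA
#'
#' @param x A `baseline_anova`.
#' @param ... Unused.
#' @return The per-time comparison tibble.
#' @method tidy baseline_anova
#' @export
tidy.baseline_anova <- function(x, ...) x$comparisons

#' One-row summary of a baseline ANOVA
#'
#' @param x A `baseline_anova`.
#' @param ... Unused.
#' @return A one-row tibble with the time-effect F statistic, its df and
#'   p-value, and the significant-comparison count.
#' @method glance baseline_anova
#' @export
glance.baseline_anova <- function(x, ...) {
  i <- which(x$anova$term == "time")
  tibble::tibble(
    statistic = x$anova$statistic[i],
    df_time = x$anova$df[i],
    df_residual = x$anova$df[x$anova$term == "residual"],
    p.value = x$anova$p.value[i],
    n_significant = sum(x$comparisons$significant),
    n_comparisons = nrow(x$comparisons)
  )
}
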