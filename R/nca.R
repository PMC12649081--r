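#' Clean a single-subject concentration profile for NCA
#'
#' Applies the package's censoring conventions: a leading below-LOQ (BLQ)
#' record at time zero — or an absent time-zero record — anchors the profile
#' at (0, 0) as expected for an extravascular dose; embedded and trailing
#' BLQ records are dropped from both terminal-slope regression and
#' integration. Times must be strictly increasing.
#'
#' @param time_h Sampling times, hours.
#' @param conc_ng_ml Concentrations, ng/mL (`NA` allowed for BLQ records).
#' @param blq Logical BLQ flags (default: all quantifiable).
#'
#' @return A tibble with columns `time_h`, `conc_ng_ml` and `anchor`
#'   (`TRUE` only for a synthetic (0, 0) record).
#' @export
nca_profile <- function(time_h, conc_ng_ml, blq = rep(FALSE, length(time_h))) {
  stopifnot(length(time_h) == length(conc_ng_ml), length(blq) == length(time_h))
  if (any(!is.finite(time_h)) || any(time_h < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  blq <- blq | is.na(conc_ng_ml)
  if (any(conc_ng_ml[!blq] < 0)) stop("concentrations must be >= 0", call. = FALSE)
  keep <- !blq
  out <- tibble::tibble(time_h = time_h[keep], conc_ng_ml = conc_ng_ml[keep],
                        anchor = FALSE)
  if (nrow(out) == 0L) stop("no quantifiable concentrations", call. = FALSE)
  if (out$time_h[1] > 0) {
    out <- dplyr::bind_rows(
      tibble::tibble(time_h = 0, conc_ng_ml = 0, anchor = TRUE), out)
  }
  out
}

#' Observed peak concentration and its time
#'
#' @param time_h,conc_ng_ml Quantifiable profile vectors (see [nca_profile()]).
#' @return A one-row tibble with `cmax` (ng/mL) and `tmax` (h); ties in the
#'   maximum are broken toward the earliest time.
#' @export
find_cmax_tmax <- function(time_h, conc_ng_ml) {
  quant <- conc_ng_ml > 0
  if (!any(quant)) stop("no quantifiable concentrations", call. = FALSE)
  i <- which(conc_ng_ml == max(conc_ng_ml[quant]))[1]
  tibble::tibble(cmax = conc_ng_ml[i], tmax = time_h[i])
}

#' Terminal slope (lambda-z) by best-fit suffix regression
#'
#' Fits ordinary least squares of `ln(conc)` against time over every suffix
#' of the quantifiable post-peak points (the peak itself excluded) with at
#' least three points, and keeps the window with the highest adjusted R².
#' Windows whose adjusted R² is within 1e-4 of the best are resolved in
#' favour of more points. The chosen slope must be negative;
#' `lambda_z = -slope`. When the peak is the first quantifiable sample —
#' the profile is already in decline, so no absorption phase is visible —
#' the whole profile is terminal and the peak is eligible for the window.
#'
#' @inheritParams find_cmax_tmax
#' @return A one-row tibble with `lambda_z` (1/h), `n_lambda_points`,
#'   `r2_adj`, and `intercept` (on the log scale).
#' @export
fit_lambda_z <- function(time_h, conc_ng_ml) {
  quant <- conc_ng_ml > 0
  tq <- time_h[quant]
  cq <- conc_ng_ml[quant]
  i_max <- which(cq == max(cq))[1]
  if (i_max > 1L) {
    tq <- tq[-seq_len(i_max)]
    cq <- cq[-seq_len(i_max)]
  }
  n <- length(tq)
  if (n < 3L) stop("terminal phase not estimable: fewer than 3 post-peak points",
                   call. = FALSE)
  y <- log(cq)
  best <- NULL
  for (start in seq_len(n - 2L)) {
    idx <- start:n
    fit <- stats::lm.fit(cbind(1, tq[idx]), y[idx])
    slope <- fit$coefficients[2]
    k <- length(idx)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y[idx] - mean(y[idx]))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    r2a <- 1 - (1 - r2) * (k - 1) / (k - 2)
    cand <- list(slope = slope, n = k, r2a = r2a, icpt = fit$coefficients[1])
    if (is.null(best) || r2a > best$r2a + 1e-4 ||
        (abs(r2a - best$r2a) <= 1e-4 && k > best$n)) {
      best <- cand
    }
  }
  if (!is.finite(best$slope) || best$slope >= -1e-12) {
    stop("terminal phase not estimable: non-negative terminal slope", call. = FALSE)
  }
  tibble::tibble(lambda_z = unname(-best$slope), n_lambda_points = best$n,
                 r2_adj = unname(best$r2a), intercept = unname(best$icpt))
}

#' Linear-up/log-down trapezoidal AUC to the last quantifiable point
#'
#' Each interval contributes the linear trapezoid
#' \eqn{(C_1 + C_2)\Delta t / 2} when the concentration is rising
#' (\eqn{C_2 \ge C_1}) or either endpoint is zero, and the logarithmic
#' trapezoid \eqn{(C_1 - C_2)\Delta t / \ln(C_1/C_2)} when it is falling
#' with both endpoints positive.
#'
#' @inheritParams find_cmax_tmax
#' @return `auc_last` in ng·h/mL.
#' @export
auc_linuplogdown <- function(time_h, conc_ng_ml) {
  n <- length(time_h)
  if (n < 2L) return(0)
  c1 <- conc_ng_ml[-n]; c2 <- conc_ng_ml[-1]
  dt <- diff(time_h)
  lin <- c2 >= c1 | c1 == 0 | c2 == 0
  seg <- ifelse(lin, (c1 + c2) / 2 * dt, (c1 - c2) * dt / log(c1 / c2))
  sum(seg)
}

#' Extrapolate AUC to infinity
#'
#' `auc_inf = auc_last + clast / lambda_z`; the percentage extrapolated is
#' `100 * (auc_inf - auc_last) / auc_inf`.
#'
#' @param auc_last AUC to the last quantifiable point, ng·h/mL.
#' @param clast_observed Last observed quantifiable concentration, ng/mL.
#' @param lambda_z Terminal slope, 1/h.
#' @return A one-row tibble with `auc_inf` and `pct_extrap`.
#' @export
extrapolate_auc <- function(auc_last, clast_observed, lambda_z) {
  stopifnot(auc_last >= 0, clast_observed >= 0, lambda_z > 0)
  auc_inf <- auc_last + clast_observed / lambda_z
  pct <- if (auc_inf == 0) 0 else 100 * (auc_inf - auc_last) / auc_inf
  tibble::tibble(auc_inf = auc_inf, pct_extrap = pct)
}

#' Non-compartmental analysis of a multi-subject concentration table
#'
#' Runs the full per-subject NCA (peak, terminal slope, linear-up/log-down
#' AUC, extrapolation to infinity) on a long-format concentration table.
#'
#' @param data A data frame with columns `subject_id`, `time_h`,
#'   `conc_ng_ml` and (optionally) logical `blq`.
#' @param clast Which concentration anchors the extrapolation: the observed
#'   last quantifiable value (default) or the lambda-z regression prediction
#'   at that time.
#'
#' @return A tibble, one row per subject: `cmax`, `tmax`, `lambda_z`,
#'   `t_half`, `auc_last`, `auc_inf`, `pct_extrap`, `n_lambda_points`,
#'   `r2_adj`.
#' @examples
#' cfg <- study_config(seed = 1)
#' run_nca(gen_plasma(cfg))
#' @export
run_nca <- function(data, clast = c("observed", "predicted")) {
  clast <- match.arg(clast)
  req <- c("subject_id", "time_h", "conc_ng_ml")
  if (!all(req %in% names(data))) {
    stop("`data` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0L) stop("`data` is empty", call. = FALSE)
  if (!"blq" %in% names(data)) data$blq <- FALSE
  data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      p <- nca_profile(d$time_h, d$conc_ng_ml, d$blq)
      pk <- find_cmax_tmax(p$time_h, p$conc_ng_ml)
      lz <- fit_lambda_z(p$time_h, p$conc_ng_ml)
      auc <- auc_linuplogdown(p$time_h, p$conc_ng_ml)
      i_last <- nrow(p)
      cl_obs <- if (clast == "observed") {
        p$conc_ng_ml[i_last]
      } else {
        exp(lz$intercept - lz$lambda_z * p$time_h[i_last])
      }
      ext <- extrapolate_auc(auc, cl_obs, lz$lambda_z)
      tibble::tibble(
        cmax = pk$cmax, tmax = pk$tmax,
        lambda_z = lz$lambda_z, t_half = log(2) / lz$lambda_z,
        auc_last = auc, auc_inf = ext$auc_inf, pct_extrap = ext$pct_extrap,
        n_lambda_points = lz$n_lambda_points, r2_adj = lz$r2_adj
      )
    }) |>
    dplyr::ungroup()
}

#' Cohort summary of NCA results
#'
#' Arithmetic mean, sample SD (n - 1 denominator), median and range for each
#' NCA parameter across subjects, in the layout conventional for PK summary
#' tables. With a single subject the SD is reported as 0 and flagged.
#'
#' @param results A tibble from [run_nca()].
#' @return A tibble with one row per parameter: `parameter`, `mean`, `sd`,
#'   `median`, `min`, `max`, `n`.
#' @export
nca_cohort_summary <- function(results) {
  num <- results |> dplyr::select(dplyr::where(is.numeric))
  num |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1L) stats::sd(.data$value) else 0,
      median = stats::median(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = names(num))) |>
    dplyr::arrange(.data$parameter) |>
    dplyr::mutate(parameter = as.character(.data$parameter))
}
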