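#' Starting values for an individual one-compartment fit
#'
#' Heuristic initial estimates from the data: `ke0` from the terminal slope
#' ([fit_lambda_z()]); `v0 = (dose/BW)/cmax * 1000` L/kg, bounded to
#' \[1, 500\]; `ka0 = max(5 * ke0, 5/tmax)` capped at 50/h (for rapid
#' absorption `tmax` is roughly `ln(ka/ke)/ka` and `ln(ka/ke)` sits near 5
#' for this compound class, so `5/tmax` lands within a small factor of the
#' true `ka`); `cl0 = ke0 * v0` converted back to mL/min/kg. A profile too
#' degenerate for a terminal fit (flat, rising) returns a bounded fallback
#' with a warning.
#'
#' @param time_h,conc_ng_ml Quantifiable profile vectors.
#' @param dose A [dose_event()].
#' @return A [pk_params()] initial estimate.
#' @export
default_init <- function(time_h, conc_ng_ml, dose) {
  pk <- find_cmax_tmax(time_h, conc_ng_ml)
  ke0 <- tryCatch(fit_lambda_z(time_h, conc_ng_ml)$lambda_z,
                  error = function(e) {
                    warning("terminal slope not estimable; using fallback init",
                            call. = FALSE)
                    0.05
                  })
  v0 <- min(max((dose$dose_mg / dose$bw_kg) / pk$cmax * 1000, 1), 500)
  ka0 <- min(max(5 * ke0, 5 / max(pk$tmax, 0.1)), 50)
  pk_params(ka = ka0, cl_f = ke0 * v0 / 0.06, v_f = v0)
}

# log-scale sum-of-squares objective for an individual profile
.fit_obj <- function(logpar, time_h, logc, dose_per_kg) {
  ka <- exp(logpar[1]); cl <- exp(logpar[2]); v <- exp(logpar[3])
  ke <- cl * 0.06 / v
  pred <- .conc_1cmt(time_h, ka, ke, dose_per_kg / v * 1000)
  if (any(pred <= 0)) return(1e10)
  sum((logc - log(pred))^2)
}

#' Fit the one-compartment model to one subject by log-scale least squares
#'
#' Minimises the sum of squared log-scale residuals
#' \eqn{\sum_j (\ln C_{obs,j} - \ln C_{pred,j})^2} over `(ka, cl_f, v_f)`,
#' the least-squares criterion matched to a multiplicative error model. The
#' parameters are optimised on the log scale to enforce positivity, with
#' repeated quasi-Newton passes until the relative parameter change is below
#' 1e-8 and a three-start jittered fallback on non-convergence. BLQ points
#' and the time-zero record are excluded.
#'
#' @param time_h,conc_ng_ml Profile vectors; `blq` logical flags.
#' @param dose A [dose_event()].
#' @param init Optional [pk_params()] start; default [default_init()].
#' @param blq Logical BLQ flags.
#' @param max_restarts Cap on polish restarts per start.
#'
#' @return An object of class `pk_fit`: list with `params` ([pk_params()]),
#'   `ssr` (log-scale residual sum of squares), `n_obs`, `aic`
#'   (`n log(SSR/n) + 2k`, k = 3), `converged`, `n_starts_used`.
#' @export
fit_pk_individual <- function(time_h, conc_ng_ml, dose, init = NULL,
                              blq = rep(FALSE, length(time_h)),
                              max_restarts = 8L) {
  blq <- blq | is.na(conc_ng_ml)
  keep <- !blq & time_h > 0 & conc_ng_ml > 0
  t_q <- time_h[keep]; c_q <- conc_ng_ml[keep]
  if (length(t_q) < 4L) {
    stop("at least 4 quantifiable post-dose points are required", call. = FALSE)
  }
  if (is.null(init)) init <- default_init(t_q, c_q, dose)
  logc <- log(c_q)
  dpk <- dose$dose_mg / dose$bw_kg
  run_start <- function(logpar0) {
    par <- logpar0
    converged <- FALSE
    for (i in seq_len(max_restarts)) {
      opt <- stats::optim(par, .fit_obj, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14),
                          time_h = t_q, logc = logc, dose_per_kg = dpk)
      step <- max(abs(opt$par - par) / pmax(abs(par), 1e-8))
      par <- opt$par
      if (step < 1e-8) { converged <- TRUE; break }
    }
    list(par = par, value = opt$value, converged = converged)
  }
  logpar0 <- log(c(init$ka, init$cl_f, init$v_f))
  best <- run_start(logpar0)
  n_starts <- 1L
  if (!best$converged) {
    set.seed(sum(utils::head(t_q, 4)) * 1e3 %% 2^31) # deterministic jitter
    for (s in 1:3) {
      cand <- run_start(logpar0 + stats::rnorm(3, 0, 0.5))
      n_starts <- n_starts + 1L
      if (cand$value < best$value || (cand$converged && !best$converged)) {
        best <- cand
      }
      if (best$converged) break
    }
  }
  n <- length(t_q)
  ssr <- best$value
  structure(
    list(
      params = pk_params(ka = exp(best$par[1]), cl_f = exp(best$par[2]),
                         v_f = exp(best$par[3])),
      ssr = ssr, n_obs = n,
      aic = n * log(max(ssr, 1e-300) / n) + 2 * 3,
      converged = best$converged, n_starts_used = n_starts
    ),
    class = "pk_fit"
  )
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> ka =", signif(x$params$ka, 4), " CL/F =",
      signif(x$params$cl_f, 4), " V/F =", signif(x$params$v_f, 4),
      "| SSR =", signif(x$ssr, 4), " AIC =", signif(x$aic, 4),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' Fit every subject in a long-format concentration table
#'
#' @param data Data frame with columns `subject_id`, `time_h`, `conc_ng_ml`
#'   and optionally `blq`.
#' @param dose A [dose_event()] shared by all subjects.
#' @return A tibble, one row per subject, with columns `subject_id`, `ka`,
#'   `cl_f`, `v_f`, `ssr`, `n_obs`, `aic`, `converged`, and a list-column
#'   `fit` holding each `pk_fit`.
#' @examples
#' cfg <- study_config(seed = 1)
#' fits <- fit_pk_cohort(gen_plasma(cfg), dose_event(20, 556.5))
#' @export
fit_pk_cohort <- function(data, dose) {
  if (!"blq" %in% names(data)) data$blq <- FALSE
  data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_pk_individual(d$time_h, d$conc_ng_ml, dose, blq = d$blq)
      tibble::tibble(ka = f$params$ka, cl_f = f$params$cl_f, v_f = f$params$v_f,
                     ssr = f$ssr, n_obs = f$n_obs, aic = f$aic,
                     converged = f$converged, fit = list(f))
    }) |>
    dplyr::ungroup()
}

#' Two-stage population estimate from individual fits
#'
#' Stage two of the two-stage estimator this package uses in place of a full
#' nonlinear mixed-effects fit: typical values are the geometric means of
#' the individual estimates, between-subject variances are the sample
#' variances (n - 1) of the log estimates, the residual proportional SD is
#' the square root of the pooled mean squared log residual, and the CV% of
#' each typical value is `100 * sd(ln p) / sqrt(n)` (delta method on the log
#' scale).
#'
#' @param fits A tibble from [fit_pk_cohort()] (or a list of `pk_fit`).
#' @return An object of class `pk_pop_fit` with elements `tv_hat`
#'   ([pk_params()]), `omega2_hat`, `stdev0_hat`, `cv_pct`, `n_subjects`.
#' @export
two_stage_population <- function(fits) {
  if (!is.data.frame(fits)) {
    fits <- tibble::tibble(
      subject_id = seq_along(fits),
      ka = vapply(fits, function(f) f$params$ka, 1),
      cl_f = vapply(fits, function(f) f$params$cl_f, 1),
      v_f = vapply(fits, function(f) f$params$v_f, 1),
      ssr = vapply(fits, function(f) f$ssr, 1),
      n_obs = vapply(fits, function(f) f$n_obs, 1),
      converged = vapply(fits, function(f) f$converged, TRUE)
    )
  }
  fits <- dplyr::filter(fits, .data$converged)
  n <- nrow(fits)
  if (n < 2L) stop("need at least 2 converged individual fits", call. = FALSE)
  lp <- log(as.matrix(fits[, c("ka", "v_f", "cl_f")]))
  mu <- colMeans(lp)
  v <- apply(lp, 2, stats::var)
  structure(
    list(
      tv_hat = pk_params(ka = exp(mu[["ka"]]), cl_f = exp(mu[["cl_f"]]),
                         v_f = exp(mu[["v_f"]])),
      omega2_hat = v[c("ka", "v_f", "cl_f")],
      stdev0_hat = sqrt(sum(fits$ssr) / sum(fits$n_obs)),
      cv_pct = 100 * sqrt(v[c("ka", "v_f", "cl_f")]) / sqrt(n),
      n_subjects = n
    ),
    class = "pk_pop_fit"
  )
}

#' @export
print.pk_pop_fit <- function(x, ...) {
  cat("<pk_pop_fit> from", x$n_subjects, "subjects\n")
  print(x$tv_hat)
  cat("  omega^2_hat:",
      paste(names(x$omega2_hat), signif(x$omega2_hat, 4), sep = " = ",
            collapse = ", "),
      "\n  stdev0_hat:", signif(x$stdev0_hat, 4), "\n")
  invisible(x)
}

#' Tidy a two-stage population fit
#'
#' @param x A `pk_pop_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `parameter`, `estimate`
#'   (typical value), `cv_pct`, `omega2`.
#' @method tidy pk_pop_fit
#' @export
tidy.pk_pop_fit <- function(x, ...) {
  tibble::tibble(
    parameter = c("ka", "v_f", "cl_f"),
    estimate = c(x$tv_hat$ka, x$tv_hat$v_f, x$tv_hat$cl_f),
    cv_pct = unname(x$cv_pct[c("ka", "v_f", "cl_f")]),
    omega2 = unname(x$omega2_hat[c("ka", "v_f", "cl_f")])
  )
}

#' One-row summary of a two-stage population fit
#'
#' @param x A `pk_pop_fit`.
#' @param ... Unused.
#' @return A one-row tibble: typical values, omega-squared estimates,
#'   residual SD and subject count.
#' @method glance pk_pop_fit
#' @export
glance.pk_pop_fit <- function(x, ...) {
  tibble::tibble(
    tv_ka = x$tv_hat$ka, tv_v_f = x$tv_hat$v_f, tv_cl_f = x$tv_hat$cl_f,
    omega2_ka = unname(x$omega2_hat[["ka"]]),
    omega2_v_f = unname(x$omega2_hat[["v_f"]]),
    omega2_cl_f = unname(x$omega2_hat[["cl_f"]]),
    stdev0 = x$stdev0_hat, n_subjects = x$n_subjects
  )
}

#' Convert a population fit into a simulation-ready population model
#'
#' @param x A `pk_pop_fit`.
#' @return A [population_model()] with the estimated typical values,
#'   variances and residual SD.
#' @export
as_population_model <- function(x) {
  stopifnot(inherits(x, "pk_pop_fit"))
  population_model(tv = x$tv_hat, omega2 = x$omega2_hat, stdev0 = x$stdev0_hat)
}

#' Fit a mono-exponential (no absorption phase) candidate to one subject
#'
#' Reduced candidate model `C(t) = A exp(-ke t)` fitted by log-scale least
#' squares (closed form: ordinary least squares on `ln C` vs `t`), provided
#' as a comparison candidate for [compare_pk_models()]. `aic` uses k = 2.
#'
#' @inheritParams fit_pk_individual
#' @return A list with `coef` (A, ke), `ssr`, `n_obs`, `aic`, `converged`.
#' @export
fit_monoexp_individual <- function(time_h, conc_ng_ml, dose = NULL,
                                   blq = rep(FALSE, length(time_h))) {
  keep <- !(blq | is.na(conc_ng_ml)) & time_h > 0 & conc_ng_ml > 0
  t_q <- time_h[keep]; y <- log(conc_ng_ml[keep])
  if (length(t_q) < 3L) stop("at least 3 quantifiable points required", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, t_q), y)
  n <- length(t_q)
  ssr <- sum(fit$residuals^2)
  list(coef = c(A = exp(fit$coefficients[1]), ke = -fit$coefficients[2]),
       ssr = ssr, n_obs = n, aic = n * log(max(ssr, 1e-300) / n) + 2 * 2,
       converged = TRUE)
}

#' Rank candidate structural models by total AIC
#'
#' Sums each candidate's per-subject AIC and ranks candidates from lowest
#' (best) to highest. Exact ties are flagged, not broken.
#'
#' @param fits_by_candidate Named list; each element is a list of fits (any
#'   objects carrying `aic`) or a tibble with an `aic` column.
#' @return A tibble with `candidate`, `total_aic`, `n_subjects`, `rank`,
#'   `tied`.
#' @export
compare_pk_models <- function(fits_by_candidate) {
  stopifnot(length(fits_by_candidate) >= 1L, !is.null(names(fits_by_candidate)))
  rows <- purrr::imap(fits_by_candidate, function(fits, nm) {
    aics <- if (is.data.frame(fits)) fits$aic else vapply(fits, `[[`, 1, "aic")
    tibble::tibble(candidate = nm, total_aic = sum(aics),
                   n_subjects = length(aics))
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$total_aic)
  out$rank <- rank(out$total_aic, ties.method = "min")
  out$tied <- duplicated(out$total_aic) | duplicated(out$total_aic, fromLast = TRUE)
  out
}
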