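#' One-compartment extravascular parameter set
#'
#' Bundles the three primary parameters of the one-compartment model with
#' first-order absorption, in the units used throughout the package:
#' absorption rate constant `ka` (1/h), apparent clearance `cl_f`
#' (mL/min/kg) and apparent volume of distribution `v_f` (L/kg). Because the
#' dose is extravascular, clearance and volume are apparent quantities
#' (CL/F, V/F): bioavailability is absorbed into both.
#'
#' @param ka Absorption rate constant, 1/h. Must be > 0.
#' @param cl_f Apparent clearance CL/F, mL/min/kg. Must be > 0.
#' @param v_f Apparent volume V/F, L/kg. Must be > 0.
#'
#' @return An object of class `pk_params` (a named list).
#' @examples
#' pk_params(ka = 8.34, cl_f = 10.1, v_f = 27.9)
#' @export
pk_params <- function(ka, cl_f, v_f) {
  for (nm in c("ka", "cl_f", "v_f")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("`", nm, "` must be a single finite number > 0", call. = FALSE)
    }
  }
  structure(list(ka = unname(ka), cl_f = unname(cl_f), v_f = unname(v_f)),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params>  ka =", x$ka, "1/h   CL/F =", x$cl_f,
      "mL/min/kg   V/F =", x$v_f, "L/kg\n")
  invisible(x)
}

#' Dosing event
#'
#' A single extravascular (intramuscular) bolus dose.
#'
#' @param dose_mg Administered dose, mg. Must be > 0.
#' @param bw_kg Body weight, kg. Must be > 0.
#' @param route Route label; only extravascular bolus dosing is supported.
#'
#' @return An object of class `dose_event`.
#' @examples
#' dose_event(20, 556.5)
#' @export
dose_event <- function(dose_mg, bw_kg, route = "im") {
  if (!is.numeric(dose_mg) || length(dose_mg) != 1L || !is.finite(dose_mg) || dose_mg <= 0) {
    stop("`dose_mg` must be a single finite number > 0", call. = FALSE)
  }
  if (!is.numeric(bw_kg) || length(bw_kg) != 1L || !is.finite(bw_kg) || bw_kg <= 0) {
    stop("`bw_kg` must be a single finite number > 0", call. = FALSE)
  }
  structure(list(dose_mg = dose_mg, bw_kg = bw_kg, route = route),
            class = "dose_event")
}

#' Convert clearance from mL/min/kg to L/h/kg
#'
#' Clearance is reported in mL/min/kg at the interface (the convention of the
#' population-model output this package mirrors) but used internally in
#' L/h/kg, where `ke = cl / v` comes out directly in 1/h. The conversion
#' factor is 60 min/h / 1000 mL/L = 0.06.
#'
#' @param cl_ml_min_kg Clearance in mL/min/kg; must be > 0 (vectorised).
#' @return Clearance in L/h/kg.
#' @examples
#' convert_clearance(10.1) # 0.606 L/h/kg
#' @export
convert_clearance <- function(cl_ml_min_kg) {
  if (!is.numeric(cl_ml_min_kg) || length(cl_ml_min_kg) < 1L ||
      any(!is.finite(cl_ml_min_kg)) || any(cl_ml_min_kg <= 0)) {
    stop("clearance must be finite and > 0", call. = FALSE)
  }
  cl_ml_min_kg * 0.06
}

# relative ka/ke gap below which the degenerate (ka == ke) limit is used
.flipflop_tol <- 1e-6

# Closed-form kernel, vectorised over parallel vectors ka, ke, scale at a
# single time or over times for scalar parameters. `scale` is
# (dose_mg/bw_kg)/v_f * 1000, i.e. the ng/mL prefactor.
.conc_1cmt <- function(t, ka, ke, scale) {
  n <- max(length(t), length(ka), length(ke), length(scale))
  t <- rep_len(t, n); ka <- rep_len(ka, n)
  ke <- rep_len(ke, n); scale <- rep_len(scale, n)
  degen <- abs(ka - ke) / ke < .flipflop_tol
  out <- numeric(n)
  if (any(degen)) {
    d <- degen
    out[d] <- scale[d] * ka[d] * t[d] * exp(-ka[d] * t[d])
  }
  if (any(!degen)) {
    g <- !degen
    out[g] <- scale[g] * ka[g] / (ka[g] - ke[g]) *
      (exp(-ke[g] * t[g]) - exp(-ka[g] * t[g]))
  }
  pmax(out, 0)
}

.ke_of <- function(params) convert_clearance(params$cl_f) / params$v_f

.scale_of <- function(params, dose) {
  (dose$dose_mg / dose$bw_kg) / params$v_f * 1000
}

#' Predict a concentration-time profile
#'
#' Evaluates the closed-form one-compartment extravascular model
#' \deqn{C(t) = \frac{D/BW}{V/F}\,\frac{k_a}{k_a - k_e}
#'   \left(e^{-k_e t} - e^{-k_a t}\right)}
#' in ng/mL, with \eqn{k_e = (CL/F)/(V/F)}. When \eqn{k_a} and \eqn{k_e}
#' coincide to within 1e-6 relative, the degenerate limit
#' \eqn{C(t) = \frac{D/BW}{V/F} k_a t e^{-k_a t}} is used. Flip-flop
#' parameter sets (`ka < ke`) are valid input: the same formula applies and
#' the terminal slope is then `ka`.
#'
#' @param params A [pk_params()] object.
#' @param dose A [dose_event()] object.
#' @param times Sampling times in hours; non-negative, sorted ascending.
#'
#' @return A tibble with columns `time_h` and `conc_ng_ml`.
#' @examples
#' predict_concentration(pk_params(8.34, 10.1, 27.9), dose_event(20, 556.5),
#'                       times = c(0, 1, 3, 24, 120))
#' @export
predict_concentration <- function(params, dose, times) {
  stopifnot(inherits(params, "pk_params"), inherits(dose, "dose_event"))
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times))) {
    stop("`times` must be finite numbers", call. = FALSE)
  }
  if (any(times < 0) || is.unsorted(times)) {
    stop("`times` must be non-negative and sorted ascending", call. = FALSE)
  }
  ke <- .ke_of(params)
  tibble::tibble(
    time_h = times,
    conc_ng_ml = .conc_1cmt(times, params$ka, ke, .scale_of(params, dose))
  )
}

#' Secondary parameters of the one-compartment model
#'
#' Derives the elimination rate constant, elimination half-life,
#' model-predicted time and value of the concentration peak, and the
#' model-predicted AUC to infinity, all from the primary parameters and the
#' dose:
#' `ke = (CL/F in L/h/kg)/(V/F)`, `t_half = ln 2 / ke`,
#' `tmax = ln(ka/ke)/(ka - ke)` (limit `1/ka` when `ka == ke`),
#' `auc_inf = (dose/BW)/(CL/F in L/h/kg) * 1000` ng·h/mL.
#'
#' @inheritParams predict_concentration
#' @return A one-row tibble with columns `ke`, `t_half`, `tmax_model`,
#'   `cmax_model`, `auc_inf_model`.
#' @examples
#' derive_secondary(pk_params(8.34, 10.1, 27.9), dose_event(20, 556.5))
#' @export
derive_secondary <- function(params, dose) {
  stopifnot(inherits(params, "pk_params"), inherits(dose, "dose_event"))
  ke <- .ke_of(params)
  ka <- params$ka
  tmax <- if (abs(ka - ke) / ke < .flipflop_tol) 1 / ka else log(ka / ke) / (ka - ke)
  cmax <- .conc_1cmt(tmax, ka, ke, .scale_of(params, dose))
  tibble::tibble(
    ke = ke,
    t_half = log(2) / ke,
    tmax_model = tmax,
    cmax_model = cmax,
    auc_inf_model = (dose$dose_mg / dose$bw_kg) / convert_clearance(params$cl_f) * 1000
  )
}
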