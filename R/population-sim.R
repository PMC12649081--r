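#' Population pharmacokinetic model with log-normal variability
#'
#' Typical one-compartment parameters plus diagonal between-subject
#' variability on the log scale and a proportional residual SD. The
#' defaults are the fitted population values for a 20 mg intramuscular dose
#' of isoflupredone acetate in horses: tvKa 8.34/h, tvV/F 27.9 L/kg,
#' tvCl/F 10.1 mL/min/kg; between-subject variances (of the log-scale random
#' effects) 0.5969 (ka), 0.1233 (v_f), 0.0492 (cl_f); residual proportional
#' SD 0.187. The variability entries are interpreted as variances
#' (omega-squared), the reporting convention of population PK software, and
#' random effects are independent (no correlations are modelled).
#'
#' @param tv A [pk_params()] object of typical values.
#' @param omega2 Named numeric vector of log-scale variances for `ka`, `v_f`,
#'   `cl_f`; entries must be >= 0.
#' @param stdev0 Proportional residual SD (unitless fraction); >= 0.
#'
#' @return An object of class `population_model`.
#' @examples
#' population_model() # the packaged defaults
#' @export
population_model <- function(tv = pk_params(ka = 8.34, cl_f = 10.1, v_f = 27.9),
                             omega2 = c(ka = 0.5969, v_f = 0.1233, cl_f = 0.0492),
                             stdev0 = 0.187) {
  stopifnot(inherits(tv, "pk_params"))
  if (!all(c("ka", "v_f", "cl_f") %in% names(omega2))) {
    stop("`omega2` must be named with ka, v_f, cl_f", call. = FALSE)
  }
  if (any(omega2 < 0) || stdev0 < 0) {
    stop("`omega2` entries and `stdev0` must be >= 0", call. = FALSE)
  }
  structure(list(tv = tv, omega2 = omega2[c("ka", "v_f", "cl_f")],
                 stdev0 = stdev0),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model>\n  typical:  ka =", x$tv$ka, "1/h, CL/F =", x$tv$cl_f,
      "mL/min/kg, V/F =", x$tv$v_f, "L/kg\n  omega^2: ",
      paste(names(x$omega2), round(x$omega2, 4), sep = " = ", collapse = ", "),
      "\n  residual proportional SD:", x$stdev0, "\n")
  invisible(x)
}

#' Sample individual parameter sets from a population model
#'
#' Each individual parameter is `tv * exp(eta)` with
#' `eta ~ Normal(0, omega2)`, drawn independently per parameter and
#' individual. Draws are parameter-major (all `ka`, then all `v_f`, then all
#' `cl_f`), so results are reproducible for a fixed `(seed, n)`.
#'
#' @param pop A [population_model()].
#' @param n Number of individuals, >= 1.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#'
#' @return A tibble with columns `id`, `ka`, `v_f`, `cl_f`.
#' @examples
#' sample_individuals(population_model(), n = 5, seed = 1)
#' @export
sample_individuals <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  tv <- pop$tv
  om <- pop$omega2
  tibble::tibble(
    id = seq_len(n),
    ka = tv$ka * exp(stats::rnorm(n, 0, sqrt(om[["ka"]]))),
    v_f = tv$v_f * exp(stats::rnorm(n, 0, sqrt(om[["v_f"]]))),
    cl_f = tv$cl_f * exp(stats::rnorm(n, 0, sqrt(om[["cl_f"]])))
  )
}

#' Simulate a cohort concentration matrix
#'
#' Samples `n` individuals from `pop` and evaluates the one-compartment
#' model on a shared time grid. Optionally applies multiplicative residual
#' error: each value is multiplied by `1 + eps`, `eps ~ Normal(0, stdev0^2)`
#' truncated below at -1 so concentrations stay non-negative. Residual error
#' is off by default: for detection-time work the regulatory quantity is the
#' individual's true concentration, not a noisy measurement of it.
#'
#' @param pop A [population_model()].
#' @param dose A [dose_event()].
#' @param grid Simulation times in hours, sorted ascending.
#' @param n Number of individuals.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param with_residual Apply multiplicative residual error? Default `FALSE`.
#'
#' @return An object of class `sim_cohort`: list with `grid`, `conc`
#'   (n x length(grid) matrix, ng/mL), `params` (tibble), `seed`,
#'   `residual_applied`.
#' @examples
#' sc <- simulate_cohort(population_model(), dose_event(20, 556.5),
#'                       grid = seq(0, 408, by = 3), n = 100, seed = 1)
#' dim(sc$conc)
#' @export
simulate_cohort <- function(pop, dose, grid, n, seed = NULL,
                            with_residual = FALSE) {
  stopifnot(inherits(pop, "population_model"), inherits(dose, "dose_event"))
  if (length(grid) == 0L) stop("empty simulation grid", call. = FALSE)
  if (any(grid < 0) || is.unsorted(grid)) {
    stop("`grid` must be non-negative and sorted ascending", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ind <- sample_individuals(pop, n)
  ke <- convert_clearance(ind$cl_f) / ind$v_f
  scale <- (dose$dose_mg / dose$bw_kg) / ind$v_f * 1000
  conc <- vapply(grid, function(t) .conc_1cmt(t, ind$ka, ke, scale),
                 numeric(n))
  conc <- matrix(conc, nrow = n)
  if (with_residual) {
    eps <- pmax(stats::rnorm(length(conc), 0, pop$stdev0), -1)
    conc <- conc * (1 + eps)
  }
  structure(
    list(grid = grid, conc = conc, params = ind, seed = seed,
         residual_applied = with_residual),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", nrow(x$conc), "individuals x", length(x$grid),
      "times;", if (x$residual_applied) "with" else "no", "residual error\n")
  invisible(x)
}

#' Tidy a simulated cohort into long format
#'
#' @param x A `sim_cohort`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `time_h`, `conc_ng_ml`.
#' @method tidy sim_cohort
#' @export
tidy.sim_cohort <- function(x, ...) {
  tibble::tibble(
    id = rep(x$params$id, times = length(x$grid)),
    time_h = rep(x$grid, each = nrow(x$conc)),
    conc_ng_ml = as.vector(x$conc)
  ) |>
    dplyr::arrange(.data$id, .data$time_h)
}
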