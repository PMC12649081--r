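#' Synthetic-study configuration
#'
#' Describes the simulated study that the generators in this package emit:
#' 12 horses given 20 mg intramuscularly, the rich plasma sampling schedule
#' (5 min to 312 h), urine collections from 24 h to 360 h, assay limits of
#' quantitation of 0.01 ng/mL (plasma) and 0.05 ng/mL (urine), baseline
#' cortisol 52.0 +/- 10.3 ng/mL with the nadir of suppression at 36 h, and
#' the packaged population PK model. Body weight is fixed at its cohort mean
#' by default; set `sample_bw = TRUE` to draw per-horse weights from
#' Normal(556.5, 58.4^2) kg.
#'
#' @param n_horses Number of horses.
#' @param dose_mg Intramuscular dose, mg.
#' @param bw_mean_kg,bw_sd_kg Body-weight mean and SD, kg.
#' @param sample_bw Draw per-horse body weights? Default fixed at the mean.
#' @param pop A [population_model()].
#' @param plasma_schedule_h Plasma sampling times, hours.
#' @param urine_schedule_h Urine sampling times, hours.
#' @param plasma_loq,urine_loq Assay limits of quantitation, ng/mL.
#' @param cortisol_baseline_mean,cortisol_baseline_sd Baseline cortisol
#'   distribution, ng/mL.
#' @param cortisol_nadir_time_h Time of maximal cortisol suppression, h.
#' @param seed Integer seed used by [gen_study()] (generator-specific
#'   offsets are added per output file).
#'
#' @return An object of class `study_config` (a named list).
#' @examples
#' study_config(seed = 1)
#' @export
study_config <- function(n_horses = 12,
                         dose_mg = 20,
                         bw_mean_kg = 556.5,
                         bw_sd_kg = 58.4,
                         sample_bw = FALSE,
                         pop = population_model(),
                         plasma_schedule_h = c(5 / 60, 10 / 60, 15 / 60, 0.5,
                                               0.75, 1, 2, 3, 4, 5, 6, 8, 12,
                                               18, 24, 30, 36, 48, 60, 72, 96,
                                               120, 168, 192, 216, 240, 312),
                         urine_schedule_h = c(24, 48, 72, 96, 120, 168, 192,
                                              216, 240, 312, 336, 360),
                         plasma_loq = 0.01,
                         urine_loq = 0.05,
                         cortisol_baseline_mean = 52.0,
                         cortisol_baseline_sd = 10.3,
                         cortisol_nadir_time_h = 36,
                         seed = 2026L) {
  stopifnot(n_horses >= 1, dose_mg > 0, bw_mean_kg > 0, bw_sd_kg >= 0,
            inherits(pop, "population_model"),
            !is.unsorted(plasma_schedule_h, strictly = TRUE),
            !is.unsorted(urine_schedule_h, strictly = TRUE),
            all(plasma_schedule_h > 0), all(urine_schedule_h > 0),
            plasma_loq > 0, urine_loq > 0,
            cortisol_baseline_mean > 0, cortisol_baseline_sd >= 0,
            cortisol_nadir_time_h > 0)
  structure(
    list(n_horses = as.integer(n_horses), dose_mg = dose_mg,
         bw_mean_kg = bw_mean_kg, bw_sd_kg = bw_sd_kg, sample_bw = sample_bw,
         pop = pop, plasma_schedule_h = plasma_schedule_h,
         urine_schedule_h = urine_schedule_h, plasma_loq = plasma_loq,
         urine_loq = urine_loq,
         cortisol_baseline_mean = cortisol_baseline_mean,
         cortisol_baseline_sd = cortisol_baseline_sd,
         cortisol_nadir_time_h = cortisol_nadir_time_h,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

.subject_ids <- function(n) sprintf("H%02d", seq_len(n))

#' Generate a synthetic plasma concentration dataset
#'
#' Per horse: sample individual PK parameters from the population model,
#' evaluate the one-compartment profile on the plasma schedule, apply
#' multiplicative residual error (`stdev0`, truncated below at -1), and
#' censor at the plasma LOQ. Censored records carry `blq = TRUE` and an
#' `NA` concentration, never a zero.
#'
#' @param config A [study_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A tibble with `subject_id`, `time_h`, `conc_ng_ml`, `blq`; the
#'   sampled individual parameters (and body weights) are attached as the
#'   `"params"` attribute for round-trip testing.
#' @export
gen_plasma <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "study_config"))
  set.seed(seed)
  n <- config$n_horses
  ind <- sample_individuals(config$pop, n)
  bw <- if (config$sample_bw) {
    stats::rnorm(n, config$bw_mean_kg, config$bw_sd_kg)
  } else {
    rep(config$bw_mean_kg, n)
  }
  tt <- config$plasma_schedule_h
  ke <- convert_clearance(ind$cl_f) / ind$v_f
  scale <- (config$dose_mg / bw) / ind$v_f * 1000
  conc <- vapply(tt, function(t) .conc_1cmt(t, ind$ka, ke, scale), numeric(n))
  conc <- matrix(conc, nrow = n)
  eps <- pmax(stats::rnorm(length(conc), 0, config$pop$stdev0), -1)
  conc <- conc * (1 + eps)
  ids <- .subject_ids(n)
  out <- tibble::tibble(
    subject_id = rep(ids, times = length(tt)),
    time_h = rep(tt, each = n),
    conc_ng_ml = as.vector(conc)
  ) |>
    dplyr::arrange(.data$subject_id, .data$time_h) |>
    dplyr::mutate(
      blq = .data$conc_ng_ml < config$plasma_loq,
      conc_ng_ml = ifelse(.data$blq, NA_real_, .data$conc_ng_ml)
    )
  attr(out, "params") <- dplyr::mutate(ind, subject_id = ids, bw_kg = bw)
  out
}

#' Generate a synthetic urine concentration dataset
#'
#' Urine concentrations are emulated (not mechanistically modelled) as
#' mono-exponential declines from the first collection:
#' `U(t) = U24 * exp(-kz (t - 24))` with `ln U24 ~ Normal(ln 13, 0.5^2)`,
#' `kz ~ Normal(0.012, 0.002^2)` per hour, multiplicative log-normal noise
#' (`sdlog` 0.2), and censoring at the urine LOQ. The defaults track the
#' observed cohort means and drive the above-LOQ count to ~0 by 360 h.
#'
#' @param config A [study_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @param u24_meanlog,u24_sdlog Log-scale location/SD of the 24 h level.
#' @param kz_mean,kz_sd Decline rate distribution, 1/h.
#' @param noise_sdlog Log-scale SD of the multiplicative noise (0 = exact
#'   exponential decline per horse).
#' @return A tibble with `subject_id`, `time_h`, `conc_ng_ml`, `blq`.
#' @export
gen_urine <- function(config, seed = config$seed,
                      u24_meanlog = log(13), u24_sdlog = 0.5,
                      kz_mean = 0.012, kz_sd = 0.002, noise_sdlog = 0.2) {
  stopifnot(inherits(config, "study_config"))
  set.seed(seed)
  n <- config$n_horses
  u24 <- exp(stats::rnorm(n, u24_meanlog, u24_sdlog))
  kz <- pmax(stats::rnorm(n, kz_mean, kz_sd), 1e-4)
  tt <- config$urine_schedule_h
  base <- outer(seq_len(n), seq_along(tt),
                function(i, j) u24[i] * exp(-kz[i] * (tt[j] - 24)))
  noise <- if (noise_sdlog > 0) {
    matrix(exp(stats::rnorm(n * length(tt), 0, noise_sdlog)), nrow = n)
  } else {
    1
  }
  conc <- base * noise
  ids <- .subject_ids(n)
  tibble::tibble(
    subject_id = rep(ids, times = length(tt)),
    time_h = rep(tt, each = n),
    conc_ng_ml = as.vector(conc)
  ) |>
    dplyr::arrange(.data$subject_id, .data$time_h) |>
    dplyr::mutate(
      blq = .data$conc_ng_ml < config$urine_loq,
      conc_ng_ml = ifelse(.data$blq, NA_real_, .data$conc_ng_ml)
    )
}

# Cortisol suppression template: fraction suppressed at time t. Fast onset
# to a plateau, a Gaussian deepening to the full `smax` at the nadir (so the
# nadir is identifiable above proportional noise), and a slow recovery.
.cortisol_suppression <- function(t, smax, onset_rate, recovery_rate, nadir,
                                  plateau_frac = 0.867, nadir_width = 20) {
  smax * (1 - exp(-onset_rate * t)) *
    (plateau_frac + (1 - plateau_frac) * exp(-((t - nadir) / nadir_width)^2)) *
    exp(-recovery_rate * pmax(0, t - nadir))
}

#' Generate a synthetic cortisol time series
#'
#' A shape template, not a mechanistic model: per horse the baseline is
#' drawn from Normal(52.0, 10.3^2) ng/mL and the value at time t is
#' `B * (1 - S(t)) * (1 + eps)` with proportional noise (SD 10%). The
#' suppression template rises within the first hour to a plateau
#' (`plateau_frac` of the maximum), deepens along a Gaussian bump of width
#' `nadir_width_h` to its full maximum (default 0.9) at the 36 h nadir, and
#' recovers slowly enough that suppression stays above 60% from 30 min
#' through 312 h. Sampling starts at 30 min with a baseline record at time
#' 0. `suppression_max = 0` gives the null generator (no time effect,
#' exchangeable noise) used for significance-level calibration.
#'
#' @param config A [study_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @param suppression_max Peak suppressed fraction in \[0, 1).
#' @param onset_rate Rise rate of suppression, 1/h.
#' @param recovery_rate Recovery rate after the nadir, 1/h.
#' @param plateau_frac Plateau suppression as a fraction of the maximum.
#' @param nadir_width_h Width of the nadir deepening, h.
#' @param noise_sd Proportional noise SD.
#' @return A tibble with `subject_id`, `time_h`, `value` (ng/mL), `analyte`.
#' @export
gen_cortisol <- function(config, seed = config$seed,
                         suppression_max = 0.9, onset_rate = 3,
                         recovery_rate = 0.0008, plateau_frac = 0.867,
                         nadir_width_h = 20, noise_sd = 0.10) {
  stopifnot(inherits(config, "study_config"),
            suppression_max >= 0, suppression_max < 1)
  set.seed(seed)
  n <- config$n_horses
  tt <- c(0, config$plasma_schedule_h[config$plasma_schedule_h >= 0.5])
  b <- stats::rnorm(n, config$cortisol_baseline_mean, config$cortisol_baseline_sd)
  s <- .cortisol_suppression(tt, suppression_max, onset_rate, recovery_rate,
                             config$cortisol_nadir_time_h,
                             plateau_frac, nadir_width_h)
  mu <- outer(b, 1 - s)
  val <- mu * (1 + matrix(stats::rnorm(n * length(tt), 0, noise_sd), nrow = n))
  val <- pmax(val, 0.01)
  ids <- .subject_ids(n)
  tibble::tibble(
    subject_id = rep(ids, times = length(tt)),
    time_h = rep(tt, each = n),
    value = as.vector(val),
    analyte = "cortisol"
  ) |>
    dplyr::arrange(.data$subject_id, .data$time_h)
}

# Distribution targets for the pre/post electrolyte generator. Plasma
# columns are mean/SD (SD for median-and-range entries taken as range/4);
# fractional excretion is log-normal around the reported medians with
# log-scale SD log(hi/lo)/4.
.electrolyte_targets <- tibble::tribble(
  ~analyte,     ~units,   ~pre_mean, ~pre_sd, ~post_mean, ~post_sd,
  ~fe_pre_med,  ~fe_pre_lo, ~fe_pre_hi, ~fe_post_med, ~fe_post_lo, ~fe_post_hi,
  "potassium",  "mmol/L", 3.8,  0.71, 2.7,  0.67, 39,   20,   61,   69,   27,    73,
  "sodium",     "mmol/L", 137,  1.0,  140,  1.0,  2.3,  1.47, 3.72, 1.61, 0.51,  3.03,
  "chloride",   "mmol/L", 100.1, 1.25, 99.9, 0.5, 3.7,  1.4,  20,   2.2,  1.4,   3.2,
  "calcium",    "mg/dL",  11.6, 0.25, 11.8, 0.25, 4.7,  0.7,  21,   12.1, 1.2,   45,
  "phosphorus", "mg/dL",  3.3,  0.66, 3.3,  0.71, 0.02, 0.01, 0.04, 0.02, 0.008, 0.03
)

#' Generate a synthetic pre/post electrolyte dataset
#'
#' Per horse and analyte, draws pre- and post-administration plasma values
#' from Normal distributions matching the reported cohort summaries
#' (potassium 3.8 -> 2.7 mmol/L, sodium 137 -> 140 mmol/L, etc.), plasma
#' and urine creatinine from plausible equine distributions, and a target
#' fractional excretion from a log-normal centred on the reported medians
#' (potassium 39% pre, 69% post); the urine analyte concentration is then
#' back-calculated so that [fractional_excretion()] of the emitted record
#' equals the drawn target. With `effect = FALSE` the post phase is drawn
#' from the pre distributions (a null mode for calibration).
#'
#' @param config A [study_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @param effect Apply the post-administration shifts? Default `TRUE`.
#' @return A tibble with `subject_id`, `phase` (`"pre"`/`"post"`),
#'   `analyte`, `units`, `plasma_value`, `urine_value`,
#'   `plasma_creatinine`, `urine_creatinine` (creatinine in mg/dL).
#' @export
gen_electrolytes <- function(config, seed = config$seed, effect = TRUE) {
  stopifnot(inherits(config, "study_config"))
  set.seed(seed)
  n <- config$n_horses
  ids <- .subject_ids(n)
  tg <- .electrolyte_targets
  rows <- purrr::map_dfr(seq_len(nrow(tg)), function(i) {
    r <- tg[i, ]
    purrr::map_dfr(c("pre", "post"), function(ph) {
      use_post <- effect && ph == "post"
      pm <- if (use_post) r$post_mean else r$pre_mean
      ps <- if (use_post) r$post_sd else r$pre_sd
      fe_med <- if (use_post) r$fe_post_med else r$fe_pre_med
      fe_sdlog <- if (use_post) {
        log(r$fe_post_hi / r$fe_post_lo) / 4
      } else {
        log(r$fe_pre_hi / r$fe_pre_lo) / 4
      }
      plasma <- pmax(stats::rnorm(n, pm, ps), 0.01 * pm)
      p_cr <- pmax(stats::rnorm(n, 1.5, 0.15), 0.5)
      u_cr <- pmax(stats::rnorm(n, 150, 30), 20)
      fe <- exp(stats::rnorm(n, log(fe_med), fe_sdlog))
      tibble::tibble(
        subject_id = ids, phase = ph, analyte = r$analyte, units = r$units,
        plasma_value = plasma,
        urine_value = fe / 100 * plasma * u_cr / p_cr,
        plasma_creatinine = p_cr, urine_creatinine = u_cr
      )
    })
  })
  dplyr::arrange(rows, .data$analyte, .data$phase, .data$subject_id)
}

#' Generate the complete synthetic study
#'
#' Runs all four generators with per-file seed offsets derived from
#' `config$seed` and, if `out_dir` is given, writes `plasma.csv`,
#' `urine.csv`, `biomarkers.csv`, `electrolytes.csv` and a JSON
#' `manifest.json` recording the configuration, seed and file digests.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A named list of the four tibbles plus the manifest (invisibly
#'   written when `out_dir` is given).
#' @export
gen_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  datasets <- list(
    plasma = gen_plasma(config, seed = config$seed),
    urine = gen_urine(config, seed = config$seed + 1L),
    biomarkers = gen_cortisol(config, seed = config$seed + 2L),
    electrolytes = gen_electrolytes(config, seed = config$seed + 3L)
  )
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(plasma = file.path(out_dir, "plasma.csv"),
               urine = file.path(out_dir, "urine.csv"),
               biomarkers = file.path(out_dir, "biomarkers.csv"),
               electrolytes = file.path(out_dir, "electrolytes.csv"))
    write_conc_csv(datasets$plasma, paths[["plasma"]])
    write_conc_csv(datasets$urine, paths[["urine"]])
    readr::write_csv(datasets$biomarkers, paths[["biomarkers"]])
    readr::write_csv(datasets$electrolytes, paths[["electrolytes"]])
    manifest <- run_manifest("simulate", config = config, seed = config$seed,
                             outputs = paths)
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  c(datasets, list(manifest = manifest))
}
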