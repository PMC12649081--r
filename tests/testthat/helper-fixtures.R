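# Shared fixtures: the typical horse, the standard dose, and the rich
# plasma sampling schedule used throughout.

typical_params <- function() pk_params(ka = 8.34, cl_f = 10.1, v_f = 27.9)

std_dose <- function() dose_event(dose_mg = 20, bw_kg = 556.5)

plasma_schedule <- function() study_config()$plasma_schedule_h

typical_ke <- function() 10.1 * 0.06 / 27.9

# noise-free typical profile on a given time vector
typical_profile <- function(times = plasma_schedule()) {
  predict_concentration(typical_params(), std_dose(), times)
}
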