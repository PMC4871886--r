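#' Fit an AMC fluorescence calibration curve
#'
#' Ordinary least-squares line through standard AMC solutions:
#' fluorescence = slope * concentration + intercept.
#'
#' @param concentration standard concentrations, nM
#' @param fluorescence measured fluorescence units
#' @return object of class `calibration_curve` with `slope` (FU per nM),
#'   `intercept` (FU), `r_squared` and `n_standards`
#' @export
fit_calibration <- function(concentration, fluorescence) {
  if (length(concentration) != length(fluorescence)) stopf("paired standards required")
  if (length(unique(concentration)) < 2) stopf("need >= 2 distinct standard concentrations")
  fit <- stats::lm(fluorescence ~ concentration)
  ss_tot <- sum((fluorescence - mean(fluorescence))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  res <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = r2,
              n_standards = length(concentration))
  class(res) <- "calibration_curve"
  res
}

#' Leucine-aminopeptidase hydrolysis rate from AMC fluorescence
#'
#' Blank-corrected fluorescence increase converted to AMC concentration via
#' the calibration slope, per hour of incubation. A negative corrected
#' increase is floored at 0 with a warning (expected at low signal).
#'
#' @param f_start,f_end sample fluorescence at start/end of the incubation
#' @param blank_start,blank_end blank (no-substrate) fluorescence
#' @param incubation incubation time, hours (> 0)
#' @param calib a [fit_calibration()] result
#' @return hydrolysis rate, nM AMC per hour
#' @export
aminopeptidase_rate <- function(f_start, f_end, blank_start = 0, blank_end = 0,
                                incubation = 1, calib) {
  if (calib$slope <= 0) stopf("calibration slope must be > 0")
  if (incubation <= 0) stopf("incubation must be > 0")
  df <- (f_end - f_start) - (blank_end - blank_start)
  if (df < 0) {
    mg_warn("assays", "negative blank-corrected fluorescence increase; rate floored at 0")
    df <- 0
  }
  df / calib$slope / incubation
}

#' Aminopeptidase activity of the predator-associated consortium
#'
#' A live ephyra is incubated in diluted seawater; its associated hydrolysis
#' is the vial rate scaled back by the dilution, minus the rate of the
#' ephyra-free seawater, per individual. Negative results floor at 0 with a
#' warning.
#'
#' @param vial_rate measured rate in the diluted vial, nM per hour
#' @param dilution dilution factor (>= 1; 10 in the study design)
#' @param seawater_rate bulk-seawater rate, nM per hour
#' @param n_individuals predators per vial (>= 1)
#' @return rate in nM per hour per individual
#' @export
ephyra_associated_rate <- function(vial_rate, dilution = 10, seawater_rate = 0,
                                   n_individuals = 1) {
  if (dilution < 1) stopf("dilution must be >= 1")
  if (n_individuals < 1) stopf("n_individuals must be >= 1")
  r <- (vial_rate * dilution - seawater_rate) / n_individuals
  if (any(r < 0)) {
    mg_warn("assays", "negative consortium rate floored at 0")
    r[r < 0] <- 0
  }
  r
}

#' Leucine incorporation rate from scintillation counts
#'
#' Net DPM (mean of sample replicates minus the killed control, floored at
#' 0) is converted to moles of leucine via the tracer specific activity
#' (1 Ci = 2.22e12 DPM) and scaled to nmol per litre per hour.
#'
#' @param dpm_samples DPM of the live replicates
#' @param dpm_killed DPM of the killed control
#' @param sample_volume incubated volume, mL
#' @param incubation incubation time, hours
#' @param specific_activity tracer specific activity, Ci per mmol
#' @param dpm_per_ci disintegrations per minute per Ci
#' @return leucine incorporation, nmol Leu per litre per hour
#' @export
leucine_incorporation <- function(dpm_samples, dpm_killed = 0,
                                  sample_volume = 1.7, incubation = 1,
                                  specific_activity = 52.9,
                                  dpm_per_ci = 2.22e12) {
  if (any(dpm_samples < 0) || dpm_killed < 0) stopf("DPM must be >= 0")
  if (incubation <= 0 || sample_volume <= 0) stopf("volume and incubation must be > 0")
  if (specific_activity <= 0) stopf("specific activity must be > 0")
  net <- max(mean(dpm_samples) - dpm_killed, 0)
  mmol <- net / (dpm_per_ci * specific_activity)
  nmol <- mmol * 1e6
  nmol / (sample_volume / 1000) / incubation
}

#' Heterotrophic carbon production from leucine incorporation
#'
#' `HCP = leucine rate * 1.55 kg C per mol Leu * isotope dilution` (default
#' twofold); 1.55 kg C per mol is 1.55 ug C per nmol, so the result is in
#' ug C per litre per hour.
#'
#' @param leu_rate leucine incorporation, nmol per litre per hour (>= 0)
#' @param conversion leucine-to-carbon factor, kg C per mol Leu
#' @param isotope_dilution intracellular isotope dilution factor
#' @return HCP, ug C per litre per hour
#' @export
heterotrophic_carbon_production <- function(leu_rate, conversion = 1.55,
                                            isotope_dilution = 2) {
  if (any(leu_rate < 0)) stopf("leucine rate must be >= 0")
  leu_rate * conversion * isotope_dilution
}
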