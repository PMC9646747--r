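#' Published reference designs for BK-channel BC5 pharmacology
#'
#' Experimental designs and fitted parameter values from published
#' patch-clamp characterization of the BK (Slo1) channel modulator BC5,
#' used throughout as ground truth for synthetic-data generation and
#' parameter-recovery benchmarks:
#'
#' * `activation`: BC5 dose dependence of the GV shift in the wild-type
#'   channel (EC50 2.5 uM, Hill n = 1), at the eleven BC5 concentrations
#'   of the published dose-response with the per-point patch counts of
#'   that dataset. The maximal shift is taken as -60 mV (leftward), a
#'   magnitude comparable to activation by ~1 uM intracellular Ca2+.
#' * `inhibition`: BC5 dose dependence of fractional outward-current
#'   block (IC50 1.1 uM, n = 1, full block at saturation).
#' * `e219r_gv` / `t245w_gv`: Boltzmann GV parameters of the two
#'   coupling-pathway mutants at zero Ca2+ and zero BC5
#'   (E219R: V1/2 263.7 mV, b 30.4 mV, n = 5 patches;
#'   T245W: V1/2 260.9 mV, b 21.1 mV, n = 6 patches), over the
#'   -30..300 mV, 20 mV-step voltage protocol.
#'
#' `noise_sd` values are per-replicate Gaussian noise scales chosen so
#' that the resulting per-point SEMs match the error-bar scale of such
#' recordings: 4 mV for GV-shift responses, 0.05 for fractional
#' inhibition, 0.1 normalized-conductance units for single GV curves.
#'
#' @return named list of design lists; each has the generator arguments
#'   for [make_dose_response()] or [make_gv_dataset()] plus the true
#'   parameter values under `truth`.
#' @export
bk_reference_designs <- function() {
  list(
    activation = list(
      concentrations = c(0.01, 0.03, 0.1, 0.3, 1, 2, 5, 10, 30, 100, 300),
      n_reps = c(3L, 3L, 10L, 4L, 4L, 5L, 6L, 3L, 5L, 5L, 4L),
      ec50 = 2.5, max_response = -60, hill_n = 1, noise_sd = 4,
      truth = c(ec50 = 2.5)),
    inhibition = list(
      concentrations = c(0.01, 0.1, 0.3, 1, 2, 5, 10, 30, 100, 300),
      n_reps = c(4L, 4L, 4L, 5L, 5L, 4L, 3L, 5L, 5L, 4L),
      ec50 = 1.1, max_response = 1, hill_n = 1, noise_sd = 0.05,
      truth = c(ic50 = 1.1)),
    e219r_gv = list(
      voltages = seq(-30, 300, by = 20),
      v_half = 263.7, slope = 30.4, n_reps = 5L, noise_sd = 0.1,
      truth = c(v_half = 263.7, slope = 30.4)),
    t245w_gv = list(
      voltages = seq(-30, 300, by = 20),
      v_half = 260.9, slope = 21.1, n_reps = 6L, noise_sd = 0.1,
      truth = c(v_half = 260.9, slope = 21.1))
  )
}
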