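#' Passive membrane specification
#'
#' Specific capacitance, maximal conductances and reversal potentials of the
#' model membrane.  The leak reversal potential is solved so that, with all
#' gates at their steady state, the net membrane current at `v_rest` is zero,
#' guaranteeing a stable resting potential.
#'
#' Reversal potentials for Na and K default to standard values (+50 / -80 mV);
#' they are tunable configuration fields.
#'
#' @param c_m specific capacitance (uF/cm2).
#' @param v_rest resting potential (mV).
#' @param g_na,g_k,g_leak maximal specific conductances (S/cm2), all > 0.
#' @param e_na,e_k reversal potentials (mV).
#' @param kinetics gate kinetics (list with `m`, `h`, `n`), used to balance
#'   the leak reversal; see [axon_kinetics()].
#' @return Object of class `membrane_spec` including the solved `e_leak`.
#' @export
membrane_spec <- function(c_m = 1, v_rest = -60,
                          g_na = 0.48, g_k = 1.088, g_leak = 0.0016,
                          e_na = 50, e_k = -80,
                          kinetics = axon_kinetics()) {
  stopifnot(c_m > 0, g_na > 0, g_k > 0, g_leak > 0)
  m0 <- gate_inf(v_rest, kinetics$m)
  h0 <- gate_inf(v_rest, kinetics$h)
  n0 <- gate_inf(v_rest, kinetics$n)
  i_na <- g_na * m0^kinetics$m$exponent * h0^kinetics$h$exponent * (v_rest - e_na)
  i_k <- g_k * n0^kinetics$n$exponent * (v_rest - e_k)
  e_leak <- v_rest + (i_na + i_k) / g_leak
  structure(list(c_m = c_m, v_rest = v_rest,
                 g_na = g_na, g_k = g_k, g_leak = g_leak,
                 e_na = e_na, e_k = e_k, e_leak = e_leak,
                 kinetics = kinetics),
            class = "membrane_spec")
}

#' Axon geometry specification
#'
#' Cable geometry and measurement layout.  The stimulated end of the axon is a
#' short temperature-insensitive segment so that temperature never alters
#' action-potential initiation; velocity is measured between two recording
#' sites placed away from both the stimulus and the sealed distal end.
#'
#' @param diameter_um axon diameter (um).
#' @param total_length_cm total cable length (cm).
#' @param dx_um compartment length (um).
#' @param r_a axial resistivity (Ohm cm).
#' @param stim_region_cm length of the temperature-insensitive stimulated
#'   segment (cm).
#' @param rec1_offset_cm distance of the first recording site from the end of
#'   the stimulated segment (cm).
#' @param rec2_offset_cm distance of the second recording site from the distal
#'   end (cm).
#' @param functional_distance_cm axon length over which arrival times are
#'   extrapolated for timing analyses (cm).
#' @return Object of class `axon_spec`, with derived compartment counts and
#'   recording indices.
#' @export
axon_spec <- function(diameter_um = 3, total_length_cm = 4.075, dx_um = 50,
                      r_a = 28, stim_region_cm = 0.075,
                      rec1_offset_cm = 0.5, rec2_offset_cm = 1.5,
                      functional_distance_cm = 4) {
  stopifnot(diameter_um > 0, total_length_cm > 0, dx_um > 0, r_a > 0,
            stim_region_cm >= 0, rec1_offset_cm > 0, rec2_offset_cm > 0)
  dx_cm <- dx_um * 1e-4
  n_comp <- round(total_length_cm / dx_cm)
  n_insens <- round(stim_region_cm / dx_cm)
  rec1_pos <- stim_region_cm + rec1_offset_cm
  rec2_pos <- total_length_cm - rec2_offset_cm
  if (rec1_pos >= rec2_pos)
    stop("first recording site must be proximal to the second")
  rec1 <- round(rec1_pos / dx_cm)
  rec2 <- round(rec2_pos / dx_cm)
  structure(list(diameter_um = diameter_um, total_length_cm = total_length_cm,
                 dx_um = dx_um, dx_cm = dx_cm, r_a = r_a,
                 stim_region_cm = stim_region_cm,
                 rec1_offset_cm = rec1_offset_cm,
                 rec2_offset_cm = rec2_offset_cm,
                 functional_distance_cm = functional_distance_cm,
                 n_comp = n_comp, n_insens = n_insens,
                 rec1 = rec1, rec2 = rec2,
                 span_cm = (rec2 - rec1) * dx_cm),
            class = "axon_spec")
}

#' Per-property Q10 set
#'
#' The six temperature sensitivities attached to one model variant: maximal
#' conductances of the Na, K and leak channels and the gate time constants of
#' Na activation (tau_m), Na inactivation (tau_h) and K activation (tau_n).
#' A value of 1 makes the property temperature-insensitive.
#'
#' @param g_na,g_k,g_leak,tau_m,tau_h,tau_n dimensionless Q10 values (> 0).
#' @return Object of class `q10_set`.
#' @export
q10_set <- function(g_na = 1, g_k = 1, g_leak = 1,
                    tau_m = 1, tau_h = 1, tau_n = 1) {
  vals <- c(g_na = g_na, g_k = g_k, g_leak = g_leak,
            tau_m = tau_m, tau_h = tau_h, tau_n = tau_n)
  if (any(vals <= 0)) stop("Q10 values must be positive")
  structure(as.list(vals), class = "q10_set")
}

#' Stimulus pulse specification
#'
#' A square current pulse injected into the first compartment.  When
#' `amplitude_na` is `NULL` the simulator uses twice the propagation threshold
#' found by bisection at the baseline temperature.
#'
#' @param amplitude_na pulse amplitude (nA) or `NULL` for 2x threshold.
#' @param duration_ms pulse duration (ms).
#' @export
stim_pulse <- function(amplitude_na = NULL, duration_ms = 1) {
  stopifnot(duration_ms > 0)
  if (!is.null(amplitude_na) && amplitude_na <= 0)
    stop("stimulus amplitude must be positive")
  structure(list(amplitude_na = amplitude_na, duration_ms = duration_ms),
            class = "stim_pulse")
}

q10_as_rfac <- function(q10, temp_c) {
  c(temperature_factor(q10$g_na, temp_c),
    temperature_factor(q10$g_k, temp_c),
    temperature_factor(q10$g_leak, temp_c),
    temperature_factor(q10$tau_m, temp_c),
    temperature_factor(q10$tau_h, temp_c),
    temperature_factor(q10$tau_n, temp_c))
}

kinetics_matrix <- function(kinetics) {
  rbind(
    unlist(kinetics$m[c("k_inf", "v_half_inf", "a_tau", "k_tau", "v_half_tau")]),
    unlist(kinetics$h[c("k_inf", "v_half_inf", "a_tau", "k_tau", "v_half_tau")]),
    unlist(kinetics$n[c("k_inf", "v_half_inf", "a_tau", "k_tau", "v_half_tau")])
  )
}

tau_form_vec <- function(kinetics) {
  as.integer(vapply(kinetics[c("m", "h", "n")],
                    function(g) identical(g$tau_form, "logistic"), logical(1)))
}
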