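# Shared fixtures.  Simulations for unit tests run on a shortened cable
# (1.575 cm, same compartment size and stimulated segment) to keep the suite
# fast; tests of the calibrated velocities use the full-length geometry.

default_membrane <- local({
  mem <- NULL
  function() {
    if (is.null(mem)) mem <<- membrane_spec()
    mem
  }
})

short_axon <- function(diameter_um = 3) {
  axon_spec(diameter_um = diameter_um, total_length_cm = 1.575,
            stim_region_cm = 0.075, rec1_offset_cm = 0.25,
            rec2_offset_cm = 0.25, functional_distance_cm = 4)
}

# stimulus amplitudes found once per geometry (2x threshold)
.fixture_env <- new.env(parent = emptyenv())

short_amp <- function(diameter_um = 3) {
  key <- paste0("amp_short_", diameter_um)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- 2 * find_stim_threshold(short_axon(diameter_um),
                                                   default_membrane())
  }
  .fixture_env[[key]]
}

full_amp <- function(diameter_um = 3) {
  key <- paste0("amp_full_", diameter_um)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- 2 * find_stim_threshold(axon_spec(diameter_um),
                                                   default_membrane())
  }
  .fixture_env[[key]]
}

short_sim <- function(q10 = q10_set(), temp_c = 10, diameter_um = 3, ...) {
  simulate_propagation(short_axon(diameter_um), default_membrane(), q10,
                       temp_c, stim_pulse(short_amp(diameter_um)),
                       t_max = 80, ...)
}

# The full sweep used by the acceptance tests, computed once per session.
full_sweep <- function() {
  if (is.null(.fixture_env$sweep)) {
    grid <- sweep_grid(temperatures_c = c(5, 10, 15, 20, 30))
    .fixture_env$sweep <- run_sweep(grid)
  }
  .fixture_env$sweep
}

# Hand-built velocity tables for the timing statistics (no simulation).
# `vel` is a function(q_row, diameter, temp) -> velocity in m/s.
synthetic_table <- function(vel, q10_values = c(1.5, 2, 3, 4),
                            diameters_um = c(3, 6),
                            temperatures_c = c(10, 20),
                            failed_fun = NULL) {
  grid <- sweep_grid(q10_values = q10_values, diameters_um = diameters_um,
                     temperatures_c = unique(c(10, temperatures_c)))
  sets <- enumerate_q10_sets(grid)
  rows <- list()
  for (d in diameters_um) for (tc in unique(c(10, temperatures_c))) {
    chunk <- data.frame(sets, diameter_um = d, temp_c = tc,
                        velocity_m_per_s = vapply(seq_len(nrow(sets)),
                          function(i) vel(sets[i, ], d, tc), numeric(1)),
                        failed = FALSE, unstable = FALSE)
    if (!is.null(failed_fun)) {
      chunk$failed <- vapply(seq_len(nrow(sets)),
                             function(i) failed_fun(sets[i, ], d, tc),
                             logical(1))
      chunk$velocity_m_per_s[chunk$failed] <- NA_real_
    }
    rows[[length(rows) + 1L]] <- chunk
  }
  out <- do.call(rbind, rows)
  attr(out, "grid") <- grid
  class(out) <- c("velocity_table", "data.frame")
  out
}
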