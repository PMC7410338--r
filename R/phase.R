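#' Sigmoid temperature-response fit
#'
#' Saturating response of (log-scaled) conduction velocity to temperature:
#' \deqn{f(T) = offset + amplitude / (1 + e^{-(T - T_{half})/scale}}
#'
#' @param offset lower asymptote.
#' @param amplitude rise between the asymptotes (> 0).
#' @param t_half_c temperature of half-rise (degrees C).
#' @param scale_c steepness scale (degrees C, > 0).
#' @return Object of class `sigmoid_fit`.
#' @export
sigmoid_fit <- function(offset, amplitude, t_half_c, scale_c) {
  stopifnot(amplitude >= 0, scale_c > 0)
  structure(list(offset = offset, amplitude = amplitude,
                 t_half_c = t_half_c, scale_c = scale_c),
            class = "sigmoid_fit")
}

#' Evaluate a sigmoid temperature-response fit
#'
#' @param temp_c temperature (degrees C); vectorized.
#' @param fit a [sigmoid_fit()].
#' @return `offset` as T goes to -Inf, `offset + amplitude` as T goes to
#'   +Inf, the midpoint at `t_half_c`.
#' @export
sigmoid_velocity <- function(temp_c, fit) {
  fit$offset + fit$amplitude / (1 + exp(-(temp_c - fit$t_half_c) / fit$scale_c))
}

#' Temperature-response fits of the three pyloric axon types
#'
#' Sigmoid parameters for the pyloric dilator (PD), pyloric constrictor (PY)
#' and lateral pyloric (LP) axons.  On the log10(velocity in m/s) scale these
#' give positive velocities ordered LP > PD > PY at 10 C (about 0.90, 0.75
#' and 0.59 m/s) with endpoint Q10s near 1.5, matching the reported axonal
#' temperature sensitivities; see [generate_velocity_dataset()].
#'
#' @return Named list of [sigmoid_fit()] objects (`PD`, `PY`, `LP`).
#' @export
pyloric_sigmoid_fits <- function() {
  list(
    PD = sigmoid_fit(-0.260, 0.417, 13.172, 4.186),
    PY = sigmoid_fit(-0.355, 0.370, 12.519, 3.963),
    LP = sigmoid_fit(-0.189, 0.401, 12.561, 4.371)
  )
}

#' Generate a synthetic per-animal velocity dataset
#'
#' Stands in for multi-animal recordings of conduction velocity against
#' temperature.  Each neuron type follows its sigmoid temperature response;
#' each animal adds multiplicative Gaussian noise, rectified to keep
#' velocities positive.  The generator emulates the shapes of the measured
#' responses, not their animal-to-animal statistics.
#'
#' @param fits named list of [sigmoid_fit()] per neuron type.
#' @param n_animals number of simulated animals.
#' @param temps_c recording temperatures (degrees C).
#' @param noise_sd multiplicative noise standard deviation (fraction).
#' @param seed mandatory integer seed; the dataset records it, and
#'   regeneration with the same arguments is identical.
#' @param scale `"log10"` (default): the sigmoid describes log10(velocity in
#'   m/s), the self-consistent reading of the printed fits, which are
#'   negative at low temperature on a linear scale.  `"normalized"`: the
#'   sigmoid is a normalized velocity multiplied by `baseline_m_per_s`.
#' @param baseline_m_per_s named per-neuron baseline speeds for the
#'   normalized scale.
#' @return Data frame (`animal_id`, `neuron`, `temp_c`, `velocity_m_per_s`)
#'   with generator provenance (seed, parameters) in attributes.
#' @export
generate_velocity_dataset <- function(fits = pyloric_sigmoid_fits(),
                                      n_animals = 5,
                                      temps_c = seq(5, 25, by = 2.5),
                                      noise_sd = 0.05, seed,
                                      scale = c("log10", "normalized"),
                                      baseline_m_per_s = NULL) {
  if (missing(seed)) stop("a seed is mandatory for the synthetic generator")
  scale <- match.arg(scale)
  if (any(temps_c < 5 - 1e-9) || any(temps_c > 25 + 1e-9))
    stop("temperatures must lie within the recorded range [5, 25] C")
  set.seed(seed)
  rows <- list()
  for (a in seq_len(n_animals)) {
    for (nm in names(fits)) {
      s <- sigmoid_velocity(temps_c, fits[[nm]])
      v <- if (scale == "log10") 10^s else {
        if (is.null(baseline_m_per_s) || is.null(baseline_m_per_s[[nm]]))
          stop("normalized scale needs baseline_m_per_s for neuron ", nm)
        baseline_m_per_s[[nm]] * s
      }
      v <- v * (1 + rnorm(length(v), 0, noise_sd))
      v <- pmax(v, 1e-6)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = a, neuron = nm, temp_c = temps_c, velocity_m_per_s = v)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- list(seed = seed, n_animals = n_animals,
                                  temps_c = temps_c, noise_sd = noise_sd,
                                  scale = scale,
                                  fits = lapply(fits, unclass))
  out
}

#' Deviation of terminal arrival time from its value at a reference
#' temperature
#'
#' Arrival time is `distance / velocity`; the deviation is relative to the
#' reference temperature, negative when the action potential arrives earlier
#' than at the reference.
#'
#' @param temps_c temperatures (degrees C).
#' @param velocities velocities (m/s), same length.
#' @param distance_cm travel distance (cm).
#' @param t_ref_c reference temperature; must be among `temps_c`.
#' @return Data frame `temp_c`, `deviation_ms`.
#' @export
arrival_deviation <- function(temps_c, velocities, distance_cm = 4,
                              t_ref_c = 10) {
  i <- which(abs(temps_c - t_ref_c) < 1e-9)
  if (!length(i)) stop("reference temperature not present in temps_c")
  t_ms <- 10 * distance_cm / velocities
  data.frame(temp_c = temps_c, deviation_ms = t_ms - t_ms[i[1]])
}

#' Cycle-period model for the pyloric rhythm
#'
#' Synthetic stand-in for measured cycle periods: period at a reference
#' temperature plus a Q10 describing how the rhythm *frequency* accelerates
#' with warming (so the period shrinks).  The phase pipeline equally accepts
#' a measured period table.
#'
#' @param period_ref_s cycle period at the reference temperature (s).
#' @param q10 frequency Q10 (> 0); 2 is typical for the pyloric rhythm.
#' @param t_ref_c reference temperature (degrees C).
#' @return Object of class `cycle_period_model`.
#' @export
cycle_period_model <- function(period_ref_s = 1, q10 = 2, t_ref_c = 10) {
  stopifnot(period_ref_s > 0, q10 > 0)
  structure(list(period_ref_s = period_ref_s, q10 = q10, t_ref_c = t_ref_c),
            class = "cycle_period_model")
}

#' Cycle period at temperature
#'
#' @param model a [cycle_period_model()] or a data frame with `temp_c` and
#'   `period_s` columns (measured periods; matched exactly).
#' @param temp_c temperature (degrees C); vectorized.
#' @return Period in seconds.
#' @export
cycle_period <- function(model, temp_c) {
  if (inherits(model, "cycle_period_model")) {
    model$period_ref_s * model$q10^(-(temp_c - model$t_ref_c) / 10)
  } else {
    idx <- match(round(temp_c, 6), round(model$temp_c, 6))
    if (anyNA(idx)) stop("period table lacks some requested temperatures")
    model$period_s[idx]
  }
}

#' Phase deviation of follower neurons from phase constancy
#'
#' Converts per-neuron velocities into arrival times at the functional
#' distance, takes the arrival-time difference of each follower to the
#' reference (pacemaker) neuron, expresses it as a fraction of the cycle
#' period at that temperature, and reports the change relative to the
#' reference temperature, in percent of cycle.  Perfect phase constancy gives
#' zero at every temperature; the reference neuron is identically zero by
#' construction.
#'
#' @param velocities data frame with `neuron`, `temp_c`, `velocity_m_per_s`
#'   (one value per neuron and temperature; average across animals first if
#'   needed).
#' @param periods a [cycle_period_model()] or period table (see
#'   [cycle_period()]).
#' @param reference reference neuron name (default `"PD"`).
#' @param distance_cm functional distance (cm).
#' @param t_ref_c reference temperature (degrees C).
#' @return Data frame `neuron`, `temp_c`, `phase_deviation_pct`.
#' @export
phase_deviation <- function(velocities, periods = cycle_period_model(),
                            reference = "PD", distance_cm = 4, t_ref_c = 10) {
  if (!reference %in% velocities$neuron)
    stop("reference neuron '", reference, "' not present in the data")
  temps <- sort(unique(velocities$temp_c))
  if (!any(abs(temps - t_ref_c) < 1e-9))
    stop("reference temperature not present in the data")
  arrival <- function(nm, tc) {
    v <- velocities$velocity_m_per_s[velocities$neuron == nm &
                                       abs(velocities$temp_c - tc) < 1e-9]
    if (length(v) != 1) stop("need exactly one velocity per neuron and ",
                             "temperature (got ", length(v), " for ", nm,
                             " at ", tc, " C)")
    10 * distance_cm / v  # ms
  }
  followers <- setdiff(unique(velocities$neuron), reference)
  rows <- list()
  for (nm in followers) {
    dev <- vapply(temps, function(tc) {
      dt_t <- arrival(nm, tc) - arrival(reference, tc)
      dt_0 <- arrival(nm, t_ref_c) - arrival(reference, t_ref_c)
      p_t <- 1000 * cycle_period(periods, tc)   # ms
      p_0 <- 1000 * cycle_period(periods, t_ref_c)
      100 * (dt_t / p_t - dt_0 / p_0)
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(neuron = nm, temp_c = temps, phase_deviation_pct = dev)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
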