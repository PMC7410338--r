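test_that("solver agrees with an independent stiff-ODE integration", {
  skip_if_not_installed("deSolve")
  mem <- default_membrane()
  n <- 120; dx <- 50e-4; d <- 3
  alpha <- 1000 * (0.5 * d * 1e-4) / (2 * 28 * dx^2)
  kin <- mem$kinetics
  stim_dens <- 3.4e-3 / (pi * d * 1e-4 * dx)
  rhs <- function(t, y, p) {
    V <- y[1:n]; m <- y[n + 1:n]; h <- y[2 * n + 1:n]; nn <- y[3 * n + 1:n]
    gna <- 480 * m^3 * h; gk <- 1088 * nn^4
    iion <- gna * (V - mem$e_na) + gk * (V - mem$e_k) +
      1.6 * (V - mem$e_leak)
    lap <- c(V[2] - V[1],
             V[1:(n - 2)] - 2 * V[2:(n - 1)] + V[3:n],
             V[n - 1] - V[n])
    istim <- numeric(n)
    if (t < 1) istim[1] <- stim_dens
    list(c(alpha * lap - iion + istim,
           (gate_inf(V, kin$m) - m) / gate_tau(V, kin$m),
           (gate_inf(V, kin$h) - h) / gate_tau(V, kin$h),
           (gate_inf(V, kin$n) - nn) / gate_tau(V, kin$n)))
  }
  v0 <- rep(-60, n)
  y0 <- c(v0, gate_inf(v0, kin$m), gate_inf(v0, kin$h), gate_inf(v0, kin$n))
  times <- seq(0, 22, by = 0.01)
  sol <- deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-7, atol = 1e-7)
  cross <- function(i0) {   # 0-based compartment index
    v <- sol[, 2 + i0]
    i <- which(v[-1] >= 0 & v[-length(v)] < 0)[1]
    times[i] + 0.01 * (0 - v[i]) / (v[i + 1] - v[i])
  }
  r1 <- 40L; r2 <- 100L
  v_oracle <- (r2 - r1) * dx * 10 / (cross(r2) - cross(r1))
  ax <- axon_spec(3, total_length_cm = n * dx, stim_region_cm = 0,
                  rec1_offset_cm = r1 * dx, rec2_offset_cm = (n - r2) * dx)
  expect_equal(c(ax$rec1, ax$rec2), c(r1, r2))
  r <- simulate_propagation(ax, mem, stim = stim_pulse(3.4), t_max = 22,
                            velocity_distance = "span")
  expect_equal(r$velocity_m_per_s, v_oracle, tolerance = 0.005)
})

test_that("baseline conduction velocities reproduce the calibration", {
  mem <- default_membrane()
  v <- vapply(c(3, 6, 12), function(d) {
    simulate_propagation(axon_spec(d), mem, stim = stim_pulse(full_amp(d)),
                         t_max = 200)$velocity_m_per_s
  }, numeric(1))
  expect_equal(v[1], 1.28, tolerance = 0.05)
  expect_equal(v[2], 1.80, tolerance = 0.05)
  # the cable equation forces velocity ~ sqrt(diameter) (within 15%)
  expect_equal(v[2] / v[1], sqrt(2), tolerance = 0.15)
  expect_equal(v[3] / v[1], 2, tolerance = 0.15)
  expect_true(all(diff(v) > 0))
})

test_that("arrival times are ordered and the velocity conventions differ by
           the span-to-functional ratio", {
  r <- short_sim()
  expect_false(r$failed); expect_false(r$unstable)
  expect_gt(r$arrival_rec2_ms, r$arrival_rec1_ms)
  ax <- short_axon()
  expect_equal(measure_velocity(r, ax, "span") * ax$functional_distance_cm /
                 ax$span_cm, measure_velocity(r, ax, "functional"))
  # arithmetic example: 2 cm span crossed in 10 ms is 2 m/s
  fake <- structure(list(arrival_rec1_ms = 10, arrival_rec2_ms = 20,
                         failed = FALSE, unstable = FALSE),
                    class = "simulation_result")
  expect_equal(measure_velocity(fake, axon_spec(), "span"), 2)
  expect_error(measure_velocity(structure(list(failed = TRUE,
                                               unstable = FALSE),
                                          class = "simulation_result"),
                                axon_spec()), "failed")
})

test_that("velocity is insensitive to stimulus amplitude above threshold", {
  a <- short_amp()
  v1 <- short_sim()$velocity_m_per_s
  v2 <- simulate_propagation(short_axon(), default_membrane(),
                             stim = stim_pulse(2 * a),
                             t_max = 80)$velocity_m_per_s
  expect_equal(v2, v1, tolerance = 0.005)
})

test_that("velocity is numerically converged in dt and dx", {
  mem <- default_membrane()
  ax <- axon_spec(3)
  amp <- full_amp(3)
  v <- simulate_propagation(ax, mem, stim = stim_pulse(amp),
                            t_max = 80)$velocity_m_per_s
  v_dt <- simulate_propagation(ax, mem, stim = stim_pulse(amp), dt = 0.00625,
                               t_max = 80)$velocity_m_per_s
  ax2 <- axon_spec(3, dx_um = 25)
  v_dx <- simulate_propagation(ax2, mem, stim = stim_pulse(amp),
                               t_max = 80)$velocity_m_per_s
  expect_equal(v_dt, v, tolerance = 0.005)
  expect_equal(v_dx, v, tolerance = 0.01)
})

test_that("membrane rests stably at every tested temperature", {
  mem <- default_membrane()
  ax <- short_axon()
  q <- q10_set(g_na = 4, g_k = 4, g_leak = 4, tau_m = 4, tau_h = 4, tau_n = 4)
  for (tc in c(5, 10, 20, 30)) {
    expect_lt(resting_excursion(ax, mem, q, tc, t_max = 100), 0.1)
  }
})

test_that("at the baseline temperature every Q10 set gives one velocity", {
  sets <- list(q10_set(), q10_set(g_na = 4, tau_m = 4),
               q10_set(g_leak = 4, tau_h = 4),
               q10_set(g_na = 2, g_k = 3, g_leak = 4, tau_m = 1.5,
                       tau_h = 3, tau_n = 2))
  v <- vapply(sets, function(q) short_sim(q, 10)$velocity_m_per_s, numeric(1))
  expect_equal(max(v) - min(v), 0)
})

test_that("single-property temperature effects have the expected signs", {
  v_ref <- short_sim(q10_set(), 20)$velocity_m_per_s
  one <- function(...) short_sim(q10_set(...), 20)$velocity_m_per_s
  expect_gt(one(tau_m = 4), v_ref)      # faster activation speeds the wave
  expect_gt(one(g_na = 4), v_ref)       # more Na current speeds the wave
  expect_lt(one(g_leak = 4), v_ref)     # leak shunt slows it
  expect_lt(one(tau_h = 4), v_ref)      # faster inactivation slows it
  # Potassium properties have < 2% influence
  expect_equal(one(g_k = 4), v_ref, tolerance = 0.02)
  expect_equal(one(tau_n = 4), v_ref, tolerance = 0.02)
})

test_that("fast Na inactivation with strong leak causes propagation failure
           at high temperature, reported separately from instability", {
  r <- short_sim(q10_set(g_leak = 4, tau_h = 4), 35)
  expect_true(r$failed)
  expect_false(r$unstable)
  expect_true(is.na(r$velocity_m_per_s))
  expect_error(measure_velocity(r, short_axon()), "failed")
})

test_that("threshold search brackets the propagation threshold", {
  a <- short_amp()    # 2x threshold
  thr <- a / 2
  below <- simulate_propagation(short_axon(), default_membrane(),
                                stim = stim_pulse(0.5 * thr), t_max = 80)
  expect_true(below$failed)
  above <- simulate_propagation(short_axon(), default_membrane(),
                                stim = stim_pulse(1.05 * thr), t_max = 80)
  expect_false(above$failed)
})
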