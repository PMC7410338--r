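#' Full run configuration
#'
#' Bundles every tunable of the pipeline -- membrane and geometry parameters,
#' solver settings, sweep grid, robustness criterion and synthetic-data
#' parameters -- into one serializable object.  A run is reproducible from
#' its configuration and the package version alone.
#'
#' @param ... named overrides of the defaults, e.g. `dt = 0.00625` or
#'   `grid = sweep_grid(...)`.
#' @return Object of class `axon_config`.
#' @export
axon_config <- function(...) {
  cfg <- list(
    membrane = list(c_m = 1, v_rest = -60, g_na = 0.48, g_k = 1.088,
                    g_leak = 0.0016, e_na = 50, e_k = -80),
    kinetics = list(exp_m = 3L, exp_h = 1L, exp_n = 4L,
                    tau_form = "logistic"),
    axon = list(total_length_cm = 4.075, dx_um = 50, r_a = 28,
                stim_region_cm = 0.075, rec1_offset_cm = 0.5,
                rec2_offset_cm = 1.5, functional_distance_cm = 4),
    solver = list(dt = 0.0125, detect_mv = 0, fail_mv = -20,
                  velocity_distance = "functional"),
    grid = sweep_grid(),
    robustness = list(mode = "pair_mean_baseline_fraction", fraction = 0.05),
    ratio_interval = c(0.375, 4 / 3),
    synthetic = list(n_animals = 5, noise_sd = 0.05,
                     period_ref_s = 1, period_q10 = 2),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration field(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = "axon_config")
}

#' Validate a run configuration
#'
#' Checks every invariant of every field and returns all violations at once.
#'
#' @param cfg an [axon_config()].
#' @return Character vector of error messages; empty when the configuration
#'   is valid.
#' @export
validate_config <- function(cfg) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  m <- cfg$membrane
  for (f in c("c_m", "g_na", "g_k", "g_leak"))
    if (!is.numeric(m[[f]]) || m[[f]] <= 0) add(paste0("membrane$", f, " must be > 0"))
  if (!is.numeric(m$v_rest) || m$v_rest >= 0) add("membrane$v_rest must be negative (mV)")
  k <- cfg$kinetics
  for (f in c("exp_m", "exp_h", "exp_n"))
    if (is.null(k[[f]]) || k[[f]] < 1) add(paste0("kinetics$", f, " must be >= 1"))
  if (!k$tau_form %in% c("logistic", "exponential"))
    add("kinetics$tau_form must be 'logistic' or 'exponential'")
  a <- cfg$axon
  for (f in c("total_length_cm", "dx_um", "r_a", "functional_distance_cm"))
    if (!is.numeric(a[[f]]) || a[[f]] <= 0) add(paste0("axon$", f, " must be > 0"))
  s <- cfg$solver
  if (!is.numeric(s$dt) || s$dt <= 0) add("solver$dt must be > 0")
  if (!s$velocity_distance %in% c("functional", "span"))
    add("solver$velocity_distance must be 'functional' or 'span'")
  if (!inherits(cfg$grid, "sweep_grid")) {
    g <- try(do.call(sweep_grid, cfg$grid), silent = TRUE)
    if (inherits(g, "try-error"))
      add(paste("grid:", conditionMessage(attr(g, "condition"))))
    else if (!length(g$q10_values)) add("grid has no Q10 values")
  } else if (!length(cfg$grid$q10_values)) add("grid has no Q10 values")
  r <- cfg$robustness
  if (!r$mode %in% c("pair_mean_baseline_fraction", "per_temperature_absolute"))
    add("robustness$mode unknown")
  if (r$mode == "pair_mean_baseline_fraction" &&
      (!is.numeric(r$fraction) || r$fraction <= 0))
    add("robustness$fraction must be > 0")
  if (length(cfg$ratio_interval) != 2 ||
      cfg$ratio_interval[1] > cfg$ratio_interval[2])
    add("ratio_interval must be c(lo, hi) with lo <= hi")
  sy <- cfg$synthetic
  if (sy$n_animals < 1) add("synthetic$n_animals must be >= 1")
  if (sy$noise_sd < 0) add("synthetic$noise_sd must be >= 0")
  if (sy$period_ref_s <= 0 || sy$period_q10 <= 0)
    add("synthetic period parameters must be > 0")
  errs
}

#' Write / read a configuration as YAML
#'
#' @param cfg an [axon_config()].
#' @param path YAML file path.
#' @return `read_config()` returns the configuration; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$grid <- unclass(x$grid)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$grid <- do.call(sweep_grid, x$grid)
  x$ratio_interval <- as.numeric(unlist(x$ratio_interval))
  cfg <- do.call(axon_config, x)
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  cfg
}

config_membrane <- function(cfg) {
  k <- cfg$kinetics
  m <- cfg$membrane
  membrane_spec(c_m = m$c_m, v_rest = m$v_rest, g_na = m$g_na, g_k = m$g_k,
                g_leak = m$g_leak, e_na = m$e_na, e_k = m$e_k,
                kinetics = axon_kinetics(k$exp_m, k$exp_h, k$exp_n,
                                         tau_form = k$tau_form))
}

config_axon <- function(cfg, diameter_um = 3) {
  a <- cfg$axon
  axon_spec(diameter_um = diameter_um, total_length_cm = a$total_length_cm,
            dx_um = a$dx_um, r_a = a$r_a, stim_region_cm = a$stim_region_cm,
            rec1_offset_cm = a$rec1_offset_cm,
            rec2_offset_cm = a$rec2_offset_cm,
            functional_distance_cm = a$functional_distance_cm)
}

#' Run the complete analysis pipeline
#'
#' Baseline calibration at every grid diameter, the exhaustive Q10 sweep,
#' velocity-Q10 distribution, pairwise delay matrices, robustness counts,
#' ratio regressions, necessity/sufficiency tests and the synthetic phase
#' pipeline.  Outputs (velocity table CSV, summary JSON) are written to
#' `out_dir` when given.
#'
#' @param cfg an [axon_config()].
#' @param out_dir optional output directory.
#' @param cache_dir optional sweep cache directory (see [run_sweep()]).
#' @param quiet suppress progress messages.
#' @return List of results: `baselines`, `sweep` (the velocity table),
#'   `velocity_q10_range`, per-pair robustness counts and percentages, and
#'   the synthetic phase analysis.
#' @export
run_reproduction <- function(cfg = axon_config(), out_dir = NULL,
                             cache_dir = NULL, quiet = TRUE) {
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  membrane <- config_membrane(cfg)
  axon <- config_axon(cfg)
  grid <- cfg$grid
  vd <- cfg$solver$velocity_distance

  # baselines per diameter
  baselines <- vapply(grid$diameters_um, function(d) {
    ax <- config_axon(cfg, d)
    thr <- find_stim_threshold(ax, membrane, dt = cfg$solver$dt)
    simulate_propagation(ax, membrane, stim = stim_pulse(2 * thr),
                         dt = cfg$solver$dt, t_max = 500,
                         velocity_distance = vd)$velocity_m_per_s
  }, numeric(1))
  names(baselines) <- paste0("d", grid$diameters_um)

  tab <- run_sweep(grid, axon, membrane, dt = cfg$solver$dt,
                   cache_dir = cache_dir, velocity_distance = vd,
                   quiet = quiet)

  d_small <- min(grid$diameters_um)
  s5 <- slice_velocity_table(tab, d_small, 5)
  s15 <- slice_velocity_table(tab, d_small, 15)
  vq10 <- velocity_q10_endpoint(s5$velocity_m_per_s, s15$velocity_m_per_s)

  crit <- robustness_criterion(cfg$robustness$mode, cfg$robustness$fraction,
                               cfg$robustness$absolute_thresholds_ms)
  iv <- cfg$ratio_interval
  pairs <- list()
  for (d_large in setdiff(grid$diameters_um, d_small)) {
    per_t <- list()
    for (tc in setdiff(grid$temperatures_c, 10)) {
      dm <- compute_delay_matrix(tab, d_small, d_large, tc,
                                 cfg$axon$functional_distance_cm)
      cls <- classify_robust(dm, crit)
      per_t[[as.character(tc)]] <- list(
        temp_c = tc, n_robust = cls$n_robust, n_failed = cls$n_failed,
        threshold_ms = cls$threshold_ms,
        necessity_tau_m = necessity_test(dm, cls$robust, iv, "tau_m"),
        sufficiency_tau_m = sufficiency_test(dm, cls$robust, iv, "tau_m"),
        necessity_tau_m_g_na = necessity_test(dm, cls$robust, iv,
                                              "tau_m", "g_na"),
        sufficiency_tau_m_g_na = sufficiency_test(dm, cls$robust, iv,
                                                  "tau_m", "g_na"),
        both_constrained_pct = if (cls$n_robust > 0)
          robust_constraint_fraction(dm, cls$robust, list(
            list(prop_large = "tau_m", prop_small = "tau_m", interval = iv),
            list(prop_large = "tau_m", prop_small = "g_na", interval = iv)))
          else NA_real_)
    }
    pairs[[sprintf("%gv%g", d_small, d_large)]] <- per_t
  }

  synth <- generate_velocity_dataset(n_animals = cfg$synthetic$n_animals,
                                     noise_sd = cfg$synthetic$noise_sd,
                                     seed = cfg$seed)
  mean_v <- stats::aggregate(velocity_m_per_s ~ neuron + temp_c, synth, mean)
  phase <- phase_deviation(mean_v,
                           cycle_period_model(cfg$synthetic$period_ref_s,
                                              cfg$synthetic$period_q10))

  out <- list(baselines = baselines, sweep = tab,
              velocity_q10_range = range(vq10, na.rm = TRUE),
              velocity_q10 = vq10, pairs = pairs,
              phase = phase, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_velocity_table(tab, file.path(out_dir, "velocity_table.csv"))
    summary <- out[c("baselines", "velocity_q10_range", "pairs")]
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
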