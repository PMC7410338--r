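#' Q10 sweep grid
#'
#' Defines the exhaustive sweep over per-property Q10 combinations.  Four
#' properties are varied over the value set (default 1.5, 2, 3, 4) while the
#' two Potassium properties stay fixed at 1.5, since they have essentially no
#' influence on velocity.  The nesting order fixes the model indexing: the
#' first varied property is outermost (slowest-changing), the last innermost.
#'
#' @param q10_values ordered Q10 values each varied property takes.
#' @param varied ordered property names, outermost first.  Allowed names:
#'   `g_na`, `g_k`, `g_leak`, `tau_m`, `tau_h`, `tau_n`.
#' @param fixed named vector of Q10s for the properties held constant.
#' @param diameters_um axon diameters to sweep (um).
#' @param temperatures_c temperatures to sweep (degrees C); must include the
#'   10 C baseline.
#' @return Object of class `sweep_grid`.
#' @export
sweep_grid <- function(q10_values = c(1.5, 2, 3, 4),
                       varied = c("g_na", "tau_m", "g_leak", "tau_h"),
                       fixed = c(g_k = 1.5, tau_n = 1.5),
                       diameters_um = c(3, 6, 12),
                       temperatures_c = c(5, 10, 15, 20, 25, 30)) {
  all_props <- c("g_na", "g_k", "g_leak", "tau_m", "tau_h", "tau_n")
  if (anyDuplicated(varied)) stop("duplicate property names in `varied`")
  bad <- setdiff(c(varied, names(fixed)), all_props)
  if (length(bad))
    stop("unknown channel properties: ", paste(bad, collapse = ", "),
         "; allowed: ", paste(all_props, collapse = ", "))
  if (length(intersect(varied, names(fixed))))
    stop("properties cannot be both varied and fixed")
  if (!length(q10_values) || any(q10_values <= 0))
    stop("q10_values must be positive")
  if (!10 %in% temperatures_c)
    stop("temperature grid must include the 10 C baseline")
  structure(list(q10_values = q10_values, varied = varied, fixed = fixed,
                 diameters_um = diameters_um, temperatures_c = temperatures_c),
            class = "sweep_grid")
}

#' Enumerate all Q10 combinations of a sweep grid
#'
#' Deterministic mixed-radix enumeration with the first varied property
#' outermost.  `model_index` 0 has every varied property at the smallest grid
#' value; the last index has every property at the largest.
#'
#' @param grid a [sweep_grid()].
#' @return Data frame with `model_index` (0-based) and one Q10 column per
#'   property (varied and fixed).
#' @export
enumerate_q10_sets <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  nv <- length(grid$q10_values)
  k <- length(grid$varied)
  n <- nv^k
  # innermost (last varied) cycles fastest
  cols <- lapply(seq_len(k), function(j) {
    each <- nv^(k - j)
    grid$q10_values[rep(rep(seq_len(nv), each = each), length.out = n)]
  })
  names(cols) <- grid$varied
  out <- data.frame(model_index = seq_len(n) - 1L, cols)
  for (p in names(grid$fixed)) out[[p]] <- grid$fixed[[p]]
  out
}

row_to_q10 <- function(row) {
  q10_set(g_na = row$g_na, g_k = row$g_k, g_leak = row$g_leak,
          tau_m = row$tau_m, tau_h = row$tau_h, tau_n = row$tau_n)
}

#' Run the Q10 sweep and build the velocity table
#'
#' Simulates every enumerated Q10 combination at every grid diameter and
#' temperature.  Per diameter, the stimulus threshold is found once by
#' bisection (the pulse is twice threshold) and the 10 C baseline -- identical
#' for every Q10 combination since all temperature factors are 1 -- is
#' simulated once and broadcast to all model indices.  Failures are recorded,
#' never dropped; numerically unstable runs are flagged separately.
#'
#' When `cache_dir` is given, per-(diameter, temperature) chunks are written
#' as CSV keyed by a hash of the full configuration, and re-runs load them
#' instead of resimulating.
#'
#' @param grid a [sweep_grid()].
#' @param axon geometry template ([axon_spec()]); its diameter is replaced by
#'   each grid diameter.
#' @param membrane a [membrane_spec()].
#' @param dt solver time step (ms).
#' @param cache_dir optional directory for resumable caching.
#' @param velocity_distance see [simulate_propagation()].
#' @param quiet suppress progress messages.
#' @return A velocity table: data frame with columns `model_index`, the Q10
#'   columns, `diameter_um`, `temp_c`, `velocity_m_per_s`, `failed`,
#'   `unstable`, carrying the grid and solver settings as attributes.
#' @export
run_sweep <- function(grid = sweep_grid(), axon = axon_spec(),
                      membrane = membrane_spec(), dt = 0.0125,
                      cache_dir = NULL,
                      velocity_distance = c("functional", "span"),
                      quiet = TRUE) {
  stopifnot(inherits(grid, "sweep_grid"))
  velocity_distance <- match.arg(velocity_distance)
  sets <- enumerate_q10_sets(grid)
  cfg_hash <- config_hash(list(grid = unclass(grid),
                               axon = unclass(axon),
                               membrane = membrane_signature(membrane),
                               dt = dt, velocity_distance = velocity_distance))
  chunks <- list()
  for (d in grid$diameters_um) {
    ax <- axon_spec(diameter_um = d, total_length_cm = axon$total_length_cm,
                    dx_um = axon$dx_um, r_a = axon$r_a,
                    stim_region_cm = axon$stim_region_cm,
                    rec1_offset_cm = axon$rec1_offset_cm,
                    rec2_offset_cm = axon$rec2_offset_cm,
                    functional_distance_cm = axon$functional_distance_cm)
    thr <- find_stim_threshold(ax, membrane, dt = dt)
    stim <- stim_pulse(2 * thr)
    base <- simulate_propagation(ax, membrane, q10_set(), 10, stim, dt,
                                 t_max = 500,
                                 velocity_distance = velocity_distance)
    if (base$failed || base$unstable)
      stop("baseline run failed at diameter ", d, " um; sweep aborted")
    t_window <- 3 * base$arrival_rec2_ms
    for (tc in grid$temperatures_c) {
      cache_file <- if (!is.null(cache_dir))
        file.path(cache_dir, sprintf("sweep_%s_d%g_T%g.csv", cfg_hash, d, tc))
      if (!is.null(cache_dir) && file.exists(cache_file)) {
        chunks[[length(chunks) + 1L]] <- read.csv(cache_file)
        next
      }
      if (!quiet)
        message(sprintf("sweep: %g um at %g C (%d models)", d, tc, nrow(sets)))
      if (tc == 10) {
        chunk <- data.frame(sets,
                            diameter_um = d, temp_c = tc,
                            velocity_m_per_s = base$velocity_m_per_s,
                            failed = FALSE, unstable = FALSE)
      } else {
        vel <- rep(NA_real_, nrow(sets))
        fail <- uns <- logical(nrow(sets))
        for (i in seq_len(nrow(sets))) {
          r <- simulate_propagation(ax, membrane, row_to_q10(sets[i, ]), tc,
                                    stim, dt, t_max = t_window,
                                    velocity_distance = velocity_distance)
          vel[i] <- r$velocity_m_per_s
          fail[i] <- r$failed
          uns[i] <- r$unstable
        }
        chunk <- data.frame(sets, diameter_um = d, temp_c = tc,
                            velocity_m_per_s = vel, failed = fail,
                            unstable = uns)
      }
      if (!is.null(cache_dir)) {
        dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
        write.csv(chunk, cache_file, row.names = FALSE)
      }
      chunks[[length(chunks) + 1L]] <- chunk
    }
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  attr(out, "dt") <- dt
  attr(out, "velocity_distance") <- velocity_distance
  attr(out, "config_hash") <- cfg_hash
  class(out) <- c("velocity_table", "data.frame")
  out
}

velocity_table_columns <- c("model_index", "g_na", "tau_m", "g_leak", "tau_h",
                            "g_k", "tau_n", "diameter_um", "temp_c",
                            "velocity_m_per_s", "failed", "unstable")

#' Persist a velocity table to CSV with a JSON sidecar
#'
#' The CSV holds the full-precision numeric data; the `<path>.json` sidecar
#' records the sweep grid, solver settings and configuration hash so a loaded
#' table is traceable to the run that made it.  The round trip is lossless
#' and, for a fixed configuration, byte-identical between runs.
#'
#' @param table a velocity table from [run_sweep()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_velocity_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  grid <- attr(table, "grid")
  sidecar <- list(grid = unclass(grid), dt = attr(table, "dt"),
                  velocity_distance = attr(table, "velocity_distance"),
                  config_hash = attr(table, "config_hash"),
                  n_rows = nrow(table),
                  package_version = as.character(utils::packageVersion("thermaxon")))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a velocity table written by [write_velocity_table()]
#'
#' @param path CSV file path.
#' @return A `velocity_table` data frame; errors if the schema does not match,
#'   naming the missing columns.
#' @export
read_velocity_table <- function(path) {
  df <- read.csv(path)
  missing <- setdiff(velocity_table_columns, names(df))
  if (length(missing))
    stop("velocity table at ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    g <- sc$grid
    attr(df, "grid") <- sweep_grid(g$q10_values, g$varied, unlist(g$fixed),
                                   g$diameters_um, g$temperatures_c)
    attr(df, "dt") <- sc$dt
    attr(df, "velocity_distance") <- sc$velocity_distance
    attr(df, "config_hash") <- sc$config_hash
  }
  class(df) <- c("velocity_table", "data.frame")
  df
}

membrane_signature <- function(membrane) {
  k <- membrane$kinetics
  list(c_m = membrane$c_m, v_rest = membrane$v_rest,
       g_na = membrane$g_na, g_k = membrane$g_k, g_leak = membrane$g_leak,
       e_na = membrane$e_na, e_k = membrane$e_k, e_leak = membrane$e_leak,
       kinetics = lapply(k, unclass))
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
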