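#' Velocity Q10 from two endpoint temperatures
#'
#' \deqn{Q_{10} = (v_2/v_1)^{10/(T_2-T_1)}}
#' With the study's endpoints 5 and 15 C this reduces to v(15)/v(5).
#'
#' @param v1,v2 velocities (m/s) at `t1_c` and `t2_c`; vectorized.
#' @param t1_c,t2_c the two temperatures (degrees C).
#' @return Dimensionless velocity Q10; `NA` where either velocity is missing
#'   (failed models are excluded, not zeroed).
#' @export
velocity_q10_endpoint <- function(v1, v2, t1_c = 5, t2_c = 15) {
  if (any(t1_c == t2_c)) stop("endpoint temperatures must differ")
  out <- (v2 / v1)^(10 / (t2_c - t1_c))
  out[!is.finite(out) | v1 <= 0 | v2 <= 0] <- NA_real_
  out
}

#' Velocity Q10 from a semilog regression
#'
#' Fits a linear regression of log10(velocity) on temperature and converts
#' the slope: \deqn{Q_{10} = 10^{10\,slope}.}  On perfectly exponential data
#' this equals the endpoint formula exactly.
#'
#' @param temps_c temperatures (degrees C), length >= 3.
#' @param velocities velocities (m/s), positive, same length.
#' @return Dimensionless Q10.
#' @export
velocity_q10_regression <- function(temps_c, velocities) {
  keep <- is.finite(temps_c) & is.finite(velocities) & velocities > 0
  temps_c <- temps_c[keep]; velocities <- velocities[keep]
  if (length(temps_c) < 3)
    stop("need at least 3 positive velocity points for the regression Q10")
  fit <- lm(log10(velocities) ~ temps_c)
  unname(10^(10 * coef(fit)[2]))
}

#' Windowed velocity Q10s over temperature increments
#'
#' One Q10 per successive temperature increment (default 5 C spacing), from
#' the pairwise slopes on the semilog scale.  On an exponential curve every
#' window gives the same Q10; on a saturating (sigmoid-like) curve the
#' windowed Q10s decrease with temperature.
#'
#' @param temps_c increasing temperatures (degrees C).
#' @param velocities matching positive velocities (m/s).
#' @return Data frame with window bounds and `q10` per increment.
#' @export
windowed_q10 <- function(temps_c, velocities) {
  ord <- order(temps_c)
  temps_c <- temps_c[ord]; velocities <- velocities[ord]
  if (length(temps_c) < 2) stop("need at least two temperatures")
  i <- seq_len(length(temps_c) - 1)
  data.frame(
    t_lo = temps_c[i], t_hi = temps_c[i + 1],
    q10 = velocity_q10_endpoint(velocities[i], velocities[i + 1],
                                temps_c[i], temps_c[i + 1]))
}

slice_velocity_table <- function(table, diameter_um, temp_c) {
  s <- table[table$diameter_um == diameter_um & table$temp_c == temp_c, ]
  if (!nrow(s)) stop("no rows for ", diameter_um, " um at ", temp_c, " C")
  s[order(s$model_index), ]
}

#' Inter-axon delay matrix at one temperature
#'
#' For every pairing of a small-diameter model i and a large-diameter model j,
#' the change relative to baseline (10 C) of the difference in arrival times
#' at the functional distance:
#' \deqn{delay_{ij}(T) = [t_i(T) - t_i(10)] - [t_j(T) - t_j(10)]}
#' with \eqn{t = L / v}, L the functional distance.  Positive delay means the
#' action potential of the smaller (slower) axon arrives late relative to
#' baseline timing.  Pairs where either model failed (at T or at baseline)
#' carry `NA` delay and are flagged.
#'
#' @param table a velocity table from [run_sweep()] containing both diameters
#'   at `temp_c` and at the 10 C baseline.
#' @param small_um,large_um the two axon diameters (um).
#' @param temp_c comparison temperature (degrees C).
#' @param distance_cm functional distance (cm).
#' @return Object of class `delay_matrix`: `delay` (rows = small-axon model
#'   index, columns = large-axon model index, ms), `pair_failed`, the per-axon
#'   Q10 tables, baseline arrival times, and metadata.
#' @export
compute_delay_matrix <- function(table, small_um, large_um, temp_c,
                                 distance_cm = 4) {
  s_t <- slice_velocity_table(table, small_um, temp_c)
  s_b <- slice_velocity_table(table, small_um, 10)
  l_t <- slice_velocity_table(table, large_um, temp_c)
  l_b <- slice_velocity_table(table, large_um, 10)
  if (!identical(s_t$model_index, l_t$model_index))
    stop("small- and large-axon slices enumerate different models")
  t_of <- function(v) 10 * distance_cm / v  # ms over distance_cm, v in m/s
  dt_small <- t_of(s_t$velocity_m_per_s) - t_of(s_b$velocity_m_per_s)
  dt_large <- t_of(l_t$velocity_m_per_s) - t_of(l_b$velocity_m_per_s)
  delay <- outer(dt_small, rep(1, length(dt_large))) -
    outer(rep(1, length(dt_small)), dt_large)
  bad_s <- s_t$failed | s_t$unstable | is.na(s_t$velocity_m_per_s)
  bad_l <- l_t$failed | l_t$unstable | is.na(l_t$velocity_m_per_s)
  pair_failed <- outer(bad_s, rep(TRUE, length(bad_l))) |
    outer(rep(TRUE, length(bad_s)), bad_l)
  delay[pair_failed] <- NA_real_
  q_cols <- c("g_na", "g_k", "g_leak", "tau_m", "tau_h", "tau_n")
  structure(list(
    delay = delay, pair_failed = pair_failed,
    q_small = s_t[, c("model_index", q_cols)],
    q_large = l_t[, c("model_index", q_cols)],
    baseline_arrival_ms = c(small = t_of(s_b$velocity_m_per_s[1]),
                            large = t_of(l_b$velocity_m_per_s[1])),
    small_um = small_um, large_um = large_um, temp_c = temp_c,
    distance_cm = distance_cm),
    class = "delay_matrix")
}

#' Robustness criterion for inter-axon timing
#'
#' "Temperature-robust" means the delay deviates from control by less than a
#' threshold.  The default mode derives the threshold as a fraction (5%) of
#' the mean of the two axons' baseline (10 C) arrival times over the
#' functional distance -- about 1.3 ms for the studied pairs.  The absolute
#' mode supplies explicit per-temperature thresholds in ms instead.
#'
#' @param mode `"pair_mean_baseline_fraction"` or `"per_temperature_absolute"`.
#' @param fraction fractional deviation bound (default 0.05).
#' @param absolute_thresholds_ms named vector, names = temperatures, for the
#'   absolute mode.
#' @export
robustness_criterion <- function(mode = c("pair_mean_baseline_fraction",
                                          "per_temperature_absolute"),
                                 fraction = 0.05,
                                 absolute_thresholds_ms = NULL) {
  mode <- match.arg(mode)
  if (mode == "pair_mean_baseline_fraction") {
    if (fraction <= 0) stop("fraction must be positive")
  } else if (is.null(absolute_thresholds_ms) ||
             any(absolute_thresholds_ms <= 0)) {
    stop("per_temperature_absolute mode needs positive thresholds")
  }
  structure(list(mode = mode, fraction = fraction,
                 absolute_thresholds_ms = absolute_thresholds_ms),
            class = "robustness_criterion")
}

resolve_threshold_ms <- function(dm, crit) {
  if (crit$mode == "pair_mean_baseline_fraction") {
    crit$fraction * mean(dm$baseline_arrival_ms)
  } else {
    key <- as.character(dm$temp_c)
    if (!key %in% names(crit$absolute_thresholds_ms))
      stop("no absolute threshold given for ", dm$temp_c, " C")
    unname(crit$absolute_thresholds_ms[key])
  }
}

#' Classify temperature-robust axon pairs
#'
#' A pair is robust when `|delay| < threshold`; pairs with propagation
#' failure are never robust but stay in the denominator.
#'
#' @param dm a [compute_delay_matrix()] result.
#' @param criterion a [robustness_criterion()].
#' @return List with the logical `robust` matrix, the resolved `threshold_ms`,
#'   `n_robust`, `n_failed` and `n_total`.
#' @export
classify_robust <- function(dm, criterion = robustness_criterion()) {
  stopifnot(inherits(dm, "delay_matrix"))
  thr <- resolve_threshold_ms(dm, criterion)
  robust <- !dm$pair_failed & abs(dm$delay) < thr
  robust[is.na(robust)] <- FALSE
  list(robust = robust, threshold_ms = thr,
       n_robust = sum(robust), n_failed = sum(dm$pair_failed),
       n_total = length(robust))
}

#' Ratio of a channel-property Q10 between two axons
#'
#' Convention: the larger axon's value over the smaller axon's value.
#'
#' @param large_value,small_value positive Q10 values; vectorized.
#' @return Dimensionless ratio.
#' @export
q10_ratio <- function(large_value, small_value) {
  if (any(large_value <= 0) || any(small_value <= 0))
    stop("Q10 values must be positive")
  large_value / small_value
}

#' Matrix of Q10 ratios aligned with a delay matrix
#'
#' `ratio[i, j]` = (large-axon model j's `prop_large` Q10) /
#' (small-axon model i's `prop_small` Q10), matching the `delay` layout.
#'
#' @param dm a [compute_delay_matrix()] result.
#' @param prop_large,prop_small property names (e.g. `"tau_m"`, `"g_na"`).
#' @return Numeric matrix.
#' @export
ratio_matrix <- function(dm, prop_large, prop_small = prop_large) {
  stopifnot(prop_large %in% names(dm$q_large),
            prop_small %in% names(dm$q_small))
  outer(1 / dm$q_small[[prop_small]], dm$q_large[[prop_large]])
}

#' Regress delay on a Q10 ratio
#'
#' Ordinary least squares of the pairwise delay against the (large/small)
#' Q10 ratio of one property pair, over non-failed pairs.  Steeper slopes
#' mark property ratios that better predict timing.
#'
#' @param dm a [compute_delay_matrix()] result.
#' @param prop_large,prop_small property names forming the ratio.
#' @return List with `slope` (ms per ratio unit), `intercept`, `r_squared`,
#'   `n` and the property pair.
#' @export
regress_delay_on_ratio <- function(dm, prop_large, prop_small = prop_large) {
  r <- ratio_matrix(dm, prop_large, prop_small)
  keep <- !dm$pair_failed
  fit <- lm(delay ~ ratio,
            data = data.frame(delay = dm$delay[keep], ratio = r[keep]))
  list(prop_large = prop_large, prop_small = prop_small,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = sum(keep))
}

#' Delay-vs-ratio regressions for every ordered property pair
#'
#' @param dm a [compute_delay_matrix()] result.
#' @param properties properties to cross (default the four varied ones).
#' @return Data frame of slopes and R-squared, sorted by |slope| descending.
#' @export
all_ratio_regressions <- function(dm, properties = c("g_na", "tau_m",
                                                     "g_leak", "tau_h")) {
  rows <- list()
  for (pl in properties) for (ps in properties) {
    f <- regress_delay_on_ratio(dm, pl, ps)
    rows[[length(rows) + 1L]] <-
      data.frame(prop_large = pl, prop_small = ps, slope = f$slope,
                 r_squared = f$r_squared, n = f$n)
  }
  out <- do.call(rbind, rows)
  out[order(-abs(out$slope)), ]
}

#' Observed range of a Q10 ratio among robust pairs
#'
#' @param dm a [compute_delay_matrix()] result.
#' @param robust logical matrix from [classify_robust()].
#' @param prop_large,prop_small property names forming the ratio.
#' @return Numeric `c(min, max)` of the ratio over robust pairs.
#' @export
observed_ratio_range <- function(dm, robust, prop_large,
                                 prop_small = prop_large) {
  r <- ratio_matrix(dm, prop_large, prop_small)
  vals <- r[robust]
  if (!length(vals)) stop("robust set is empty; ratio range undefined")
  range(vals)
}

ratio_in_interval <- function(ratio, interval, tol = 1e-9) {
  ratio >= interval[1] - tol & ratio <= interval[2] + tol
}

#' Necessity of a coordinated Q10 ratio for robust timing
#'
#' Among pairs whose ratio lies *outside* the coordinated interval, the
#' percentage that are not temperature-robust.  100% means the coordination
#' is strictly necessary.
#'
#' @param dm a [compute_delay_matrix()] result.
#' @param robust logical matrix from [classify_robust()].
#' @param interval closed ratio interval `c(lo, hi)`; grid ratios are
#'   compared with a 1e-9 tolerance so printed decimals like 1.33 match the
#'   exact grid ratio 4/3.
#' @param prop_large,prop_small property names forming the ratio.
#' @return Percentage (0-100); `NA` with a warning when no pair falls outside
#'   the interval (vacuous case).
#' @export
necessity_test <- function(dm, robust, interval, prop_large,
                           prop_small = prop_large) {
  r <- ratio_matrix(dm, prop_large, prop_small)
  outside <- !ratio_in_interval(r, interval)
  if (!any(outside)) {
    warning("no pairs outside the interval; necessity undefined")
    return(NA_real_)
  }
  100 * sum(outside & !robust) / sum(outside)
}

#' Sufficiency of a coordinated Q10 ratio for robust timing
#'
#' Among pairs whose ratio lies *inside* the coordinated interval, the
#' percentage that are temperature-robust.  100% means the coordination alone
#' guarantees robust timing.
#'
#' @inheritParams necessity_test
#' @return Percentage (0-100); `NA` with a warning when no pair lies inside.
#' @export
sufficiency_test <- function(dm, robust, interval, prop_large,
                             prop_small = prop_large) {
  r <- ratio_matrix(dm, prop_large, prop_small)
  inside <- ratio_in_interval(r, interval)
  if (!any(inside)) {
    warning("no pairs inside the interval; sufficiency undefined")
    return(NA_real_)
  }
  100 * sum(inside & robust) / sum(inside)
}

#' Fraction of robust pairs satisfying several ratio constraints at once
#'
#' @param dm a [compute_delay_matrix()] result.
#' @param robust logical matrix from [classify_robust()].
#' @param constraints list of lists with `prop_large`, `prop_small`,
#'   `interval`.
#' @return Percentage of robust pairs with every ratio in its interval.
#' @export
robust_constraint_fraction <- function(dm, robust, constraints) {
  if (!sum(robust)) stop("robust set is empty")
  ok <- matrix(TRUE, nrow(robust), ncol(robust))
  for (cs in constraints) {
    r <- ratio_matrix(dm, cs$prop_large,
                      if (is.null(cs$prop_small)) cs$prop_large else cs$prop_small)
    ok <- ok & ratio_in_interval(r, cs$interval)
  }
  100 * sum(robust & ok) / sum(robust)
}

#' High- versus low-Q10 composition of robust pairs per ratio bin
#'
#' For each ratio of `property` achievable by more than one (large, small)
#' Q10 combination, the combinations are ordered element-wise and the upper
#' half labelled "high" (e.g. ratio 0.75: 3:4 is high, 1.5:2 low; ratio 1.0:
#' 3:3 and 4:4 high, 1.5:1.5 and 2:2 low).  Reported is the percentage of
#' robust pairs in the bin that use a high combination.  Single-combination
#' ratios are excluded by definition.
#'
#' @param dm a [compute_delay_matrix()] result.
#' @param robust logical matrix from [classify_robust()].
#' @param property the property whose ratio defines the bins.
#' @param q10_values the grid values from which ratios can be formed.
#' @return Data frame: `ratio`, `n_combos`, `n_robust`, `pct_high`.
#' @export
high_low_proportion <- function(dm, robust, property = "tau_m",
                                q10_values = c(1.5, 2, 3, 4)) {
  combos <- expand.grid(large = q10_values, small = q10_values)
  combos$ratio <- round(combos$large / combos$small, 9)
  multi <- names(which(table(combos$ratio) > 1))
  rl <- dm$q_large[[property]]
  rs <- dm$q_small[[property]]
  out <- list()
  for (rv in sort(as.numeric(multi))) {
    cc <- combos[combos$ratio == rv, ]
    cc <- cc[order(cc$large), ]
    high <- cc[cc$large > stats::median(cc$large) |
                 (nrow(cc) == 2 & cc$large == max(cc$large)), ]
    # membership matrices for this bin
    in_bin <- high_ct <- 0
    for (k in seq_len(nrow(cc))) {
      sel <- outer(rs == cc$small[k], rl == cc$large[k]) & robust
      n_k <- sum(sel)
      in_bin <- in_bin + n_k
      if (cc$large[k] %in% high$large) high_ct <- high_ct + n_k
    }
    out[[length(out) + 1L]] <- data.frame(
      ratio = rv, n_combos = nrow(cc), n_robust = in_bin,
      pct_high = if (in_bin > 0) 100 * high_ct / in_bin else NA_real_)
  }
  do.call(rbind, out)
}

#' Coefficient-of-variation analysis of channel-property Q10s
#'
#' Within each ratio bin of the binning property (default the Na activation
#' time constant), the coefficient of variation of the *larger* axon's Q10
#' for `property` among robust pairs.  The chance baseline is the CV of the
#' uniform distribution over the grid values (0.3658 for 1.5, 2, 3, 4);
#' values clearly below baseline mark properties constrained by the
#' robustness requirement.
#'
#' @param dm a [compute_delay_matrix()] result.
#' @param robust logical matrix from [classify_robust()].
#' @param property property whose larger-axon Q10 variability is measured.
#' @param bin_property property whose ratio defines the bins.
#' @param q10_values grid values (for bins and the chance baseline).
#' @return List with data frame `bins` (`ratio`, `n`, `cv`) and
#'   `chance_cv`.
#' @export
cv_analysis <- function(dm, robust, property = "g_leak",
                        bin_property = "tau_m",
                        q10_values = c(1.5, 2, 3, 4)) {
  pop_cv <- function(x) {
    mu <- mean(x)
    sqrt(mean((x - mu)^2)) / mu
  }
  combos <- expand.grid(large = q10_values, small = q10_values)
  combos$ratio <- round(combos$large / combos$small, 9)
  bins <- sort(unique(combos$ratio))
  rmat <- round(ratio_matrix(dm, bin_property), 9)
  qlarge <- dm$q_large[[property]]
  rows <- list()
  for (rv in bins) {
    sel <- rmat == rv & robust
    vals <- qlarge[col(sel)[sel]]
    rows[[length(rows) + 1L]] <- data.frame(
      ratio = rv, n = length(vals),
      cv = if (length(vals)) pop_cv(vals) else NA_real_)
  }
  list(bins = do.call(rbind, rows), chance_cv = pop_cv(q10_values))
}
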