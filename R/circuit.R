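#' Reporter circuit parameters
#'
#' Parameters of the pyocyanin/Fcn(O)-driven reporter model. Synthesis is
#' Pyo-gated and Fcn(O)-amplified,
#' \deqn{s(f) = \frac{pyo}{K_{pyo}+pyo}\left(s_0 + s_{max}\frac{f}{K_{fcn}+f}\right),}
#' with `f` the oxidized mediator fraction; the reporter decays first-order
#' at `k_deg` (the ssrA-tag proteolysis rate). Defaults give a full-ON to
#' basal steady-state ratio of ~17x and a 25-min reporter half-life;
#' `K_fcn = 1` (half-saturation at full pool oxidation, i.e. 5 mM mediator)
#' keeps the charge response near-linear through a third of the pool, the
#' regime the device operates in.
#'
#' @param s0 basal Pyo-only synthesis rate, au/s
#' @param s_max maximal Fcn(O)-amplified synthesis rate, au/s
#' @param K_fcn half-saturation oxidized fraction (0, 1]
#' @param pyo pyocyanin concentration, uM
#' @param K_pyo pyocyanin half-saturation, uM
#' @param k_deg first-order degradation rate, 1/s
#' @param maturation_lag reporter maturation delay, s (phiLOV needs no
#'   oxygen-dependent maturation; default 0)
#' @return an object of class `circuit_params`
#' @export
circuit_params <- function(s0 = 0.05, s_max = 16 * 0.05 * 2, K_fcn = 1,
                           pyo = 5, K_pyo = 1, k_deg = log(2) / 1500,
                           maturation_lag = 0) {
  vals <- c(s0 = s0, s_max = s_max, pyo = pyo, K_pyo = K_pyo,
            k_deg = k_deg, maturation_lag = maturation_lag)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_invalid("all circuit rates/concentrations must be finite and >= 0")
  if (!is.finite(K_fcn) || K_fcn <= 0 || K_fcn > 1)
    stop_invalid("K_fcn must lie in (0, 1]")
  structure(as.list(c(vals, K_fcn = K_fcn)), class = "circuit_params")
}

#' Reporter fluorescence time series
#'
#' @param times seconds, strictly increasing
#' @param fluorescence arbitrary units, >= 0
#' @return an object of class `expression_trace`
#' @export
expression_trace <- function(times, fluorescence) {
  if (length(times) != length(fluorescence))
    stop_invalid("times and fluorescence must have equal length")
  if (any(diff(times) <= 0))
    stop_invalid("times must be strictly increasing")
  if (any(!is.finite(fluorescence)) || any(fluorescence < 0))
    stop_invalid("fluorescence must be finite and >= 0")
  structure(data.frame(time_s = as.numeric(times),
                       fluor_au = as.numeric(fluorescence)),
            class = c("expression_trace", "data.frame"))
}

#' Instantaneous reporter synthesis rate
#'
#' @param frac_ox oxidized mediator fraction in \[0, 1\]
#' @param params a [circuit_params]
#' @return synthesis rate, au/s; zero whenever `pyo = 0`
#' @export
synthesis_rate <- function(frac_ox, params = circuit_params()) {
  if (any(frac_ox < 0 | frac_ox > 1)) stop_invalid("frac_ox must be in [0, 1]")
  gate <- params$pyo / (params$K_pyo + params$pyo)
  if (params$pyo == 0) gate <- 0
  gate * (params$s0 + params$s_max * frac_ox / (params$K_fcn + frac_ox))
}

#' Simulate reporter expression under an applied-potential program
#'
#' Couples the bulk-electrolysis simulation to reporter dynamics
#' \deqn{dP/dt = s(f(t - lag)) - k_{deg} P,}
#' integrated with fixed-step RK4 on the electrolysis time grid. Also
#' accumulates the true cumulative synthesis \eqn{S(t) = \int_0^t s\,d\tau}
#' (trapezoid), the ground truth that [integrated_synthesis] recovers from
#' the fluorescence trace alone.
#'
#' @param schedule a [signal_schedule]
#' @param params a [circuit_params]
#' @param state an [electrolysis_state]
#' @param couple a [redox_couple]
#' @param k_e,k_cell,cell_density,dt passed to [simulate_bulk_electrolysis]
#' @param P0 initial fluorescence, au
#' @return list with `trace` (an [expression_trace]), `current`
#'   (a [current_trace]), `frac_ox`, `times`, and `S_true` (cumulative
#'   synthesis, au); class `expression_sim`
#' @export
simulate_expression <- function(schedule, params = circuit_params(),
                                state = electrolysis_state(),
                                couple = ferricyanide_couple(),
                                k_e = log(100) / 900, k_cell = 0,
                                cell_density = 0, dt = 1, P0 = 0) {
  stopifnot(inherits(params, "circuit_params"))
  if (P0 < 0) stop_invalid("P0 must be >= 0")
  sim <- simulate_bulk_electrolysis(state, schedule, couple,
                                    k_e = k_e, k_cell = k_cell,
                                    cell_density = cell_density, dt = dt)
  tt <- sim$times
  f_of <- stats::approxfun(tt, sim$frac_ox, rule = 2)
  lag <- params$maturation_lag
  s_of <- function(t) synthesis_rate(f_of(pmax(t - lag, 0)), params)

  n <- length(tt)
  h <- diff(tt)
  s_vals <- s_of(tt)
  s_mid <- s_of((utils::head(tt, -1L) + utils::tail(tt, -1L)) / 2)
  P <- numeric(n)
  P[1] <- P0
  k <- params$k_deg
  for (j in seq_len(n - 1L)) {
    hj <- h[j]
    k1 <- s_vals[j] - k * P[j]
    k2 <- s_mid[j] - k * (P[j] + hj / 2 * k1)
    k3 <- s_mid[j] - k * (P[j] + hj / 2 * k2)
    k4 <- s_vals[j + 1L] - k * (P[j] + hj * k3)
    P[j + 1L] <- max(P[j] + hj / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  structure(list(trace = expression_trace(tt, P), current = sim$trace,
                 frac_ox = sim$frac_ox, times = tt,
                 S_true = cumtrapz_(tt, s_vals), electrolysis = sim,
                 params = params),
            class = "expression_sim")
}

#' Cumulative synthesis deconvolved from a fluorescence trace
#'
#' Inverts the first-order degradation operator: if the reporter obeys
#' \eqn{dP/dt = s(t) - k P} then the cumulative degradation-free synthesis is
#' \deqn{S(t) = P(t) - P(0) + k \int_0^t P\,d\tau,}
#' evaluated with the trapezoid rule. `S` is nondecreasing whenever the
#' underlying synthesis rate is nonnegative; with `k_deg = 0` it reduces to
#' `P(t) - P(0)` exactly.
#'
#' @param trace an [expression_trace]
#' @param k_deg first-order degradation rate, 1/s
#' @param smooth_window odd integer; width of a centered running mean
#'   applied to the fluorescence before deconvolution (truncated at the
#'   ends). The default 1 applies no smoothing and makes the identity
#'   exact; a small window (e.g. 5) is the conventional variance-reduction
#'   step for measured traces, whose endpoint samples otherwise propagate
#'   their full measurement noise into S
#' @return numeric vector: cumulative synthesis S(t), au, same length as the
#'   trace
#' @export
integrated_synthesis <- function(trace, k_deg, smooth_window = 1L) {
  if (!inherits(trace, "expression_trace"))
    trace <- expression_trace(trace$time_s, trace$fluor_au)
  if (nrow(trace) < 2L) stop_invalid("integrated_synthesis needs >= 2 samples")
  if (k_deg < 0) stop_invalid("k_deg must be >= 0")
  if (smooth_window < 1 || smooth_window %% 2 == 0)
    stop_invalid("smooth_window must be a positive odd integer")
  P <- trace$fluor_au
  if (smooth_window > 1L) {
    hw <- (smooth_window - 1L) %/% 2L
    n <- length(P)
    P <- vapply(seq_len(n), function(i)
      mean(trace$fluor_au[max(1L, i - hw):min(n, i + hw)]), numeric(1))
  }
  P - P[1] + k_deg * cumtrapz_(trace$time_s, P)
}

# Total electrode charge delivered by an ON segment of given potential and
# duration (followed by nothing), for root finding.
.on_charge <- function(potential, duration, state, couple, k_e, dt) {
  sim <- simulate_bulk_electrolysis(state,
                                    signal_schedule(potential, duration),
                                    couple, k_e = k_e, dt = min(dt, duration / 2))
  utils::tail(integrate_charge(sim$trace), 1)
}

#' Charge versus integrated synthesis dose-response
#'
#' For each target charge, finds the oxidizing program delivering that charge
#' — either +0.5 V applied for a solved duration (`mode = "duration"`) or a
#' solved potential applied for a fixed 15-min pulse (`mode = "potential"`)
#' — then simulates expression to a fixed horizon (pulse followed by
#' open-circuit incubation) and reports the final deconvolved cumulative
#' synthesis. Equal charges delivered by either route give matching
#' synthesis, and over the low-conversion regime the relation is linear.
#'
#' @param charges target charges, coulombs (oxidation, so <= 0; magnitudes
#'   are used); at least 3 distinct values
#' @param params a [circuit_params]
#' @param state,couple,k_e,dt as in [simulate_expression]
#' @param horizon total simulated time, s
#' @param on_potential oxidizing potential for duration mode, V
#' @param pulse_duration fixed pulse length for potential mode, s
#' @param mode `"duration"` or `"potential"`
#' @return list with `data` (data frame: charge_C, duration_s or potential_V,
#'   synthesis_au) and `fit` (list: slope, intercept, r_squared) from an
#'   ordinary least-squares fit of synthesis on |charge|
#' @export
charge_synthesis_relation <- function(charges, params = circuit_params(),
                                      state = electrolysis_state(),
                                      couple = ferricyanide_couple(),
                                      k_e = log(100) / 900, dt = 1,
                                      horizon = 3 * 3600,
                                      on_potential = 0.5,
                                      pulse_duration = 900,
                                      mode = c("duration", "potential")) {
  mode <- match.arg(mode)
  q <- abs(as.numeric(charges))
  if (length(unique(q)) < 3L) stop_invalid("need >= 3 distinct charges")
  q_max_pool <- couple$n * .FARADAY * state$volume * state$total_conc *
    (nernst_fraction(on_potential, couple, state$temperature) - state$frac_ox)
  if (any(q > q_max_pool))
    stop_invalid("target charge %.3g C exceeds the Faraday maximum %.3g C of the pool",
                 max(q), q_max_pool)

  solve_one <- function(target) {
    if (target == 0) return(list(duration = 0, potential = NA_real_))
    if (mode == "duration") {
      g <- function(d) abs(.on_charge(on_potential, d, state, couple, k_e, dt)) - target
      d <- stats::uniroot(g, lower = 1e-3, upper = 50 / k_e, tol = 1e-6)$root
      list(duration = d, potential = on_potential)
    } else {
      g <- function(E) abs(.on_charge(E, pulse_duration, state, couple, k_e, dt)) - target
      E <- stats::uniroot(g, lower = couple$E0 - 1, upper = couple$E0 + 1,
                          tol = 1e-9)$root
      list(duration = pulse_duration, potential = E)
    }
  }

  syn <- numeric(length(q))
  dur <- numeric(length(q))
  pot <- numeric(length(q))
  for (i in seq_along(q)) {
    prog <- solve_one(q[i])
    dur[i] <- prog$duration
    pot[i] <- prog$potential
    sched <- if (prog$duration == 0 || q[i] == 0) {
      signal_schedule(NA, horizon)
    } else {
      signal_schedule(c(prog$potential, NA),
                      c(prog$duration, horizon - prog$duration))
    }
    sim <- simulate_expression(sched, params, state, couple,
                               k_e = k_e, dt = dt)
    syn[i] <- utils::tail(integrated_synthesis(sim$trace, params$k_deg), 1)
  }
  fit <- stats::lm(syn ~ q)
  list(data = data.frame(charge_C = -q, duration_s = dur, potential_V = pot,
                         synthesis_au = syn),
       fit = list(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]),
                  r_squared = summary(fit)$r.squared))
}

#' ON/OFF cycle-time sweep
#'
#' For each cycle time, applies the oxidizing potential for the first half
#' cycle and the reducing potential for the second, and records the
#' fluorescence at the half-cycle and end-of-cycle times (the Fig.-style
#' cycle experiment: half-cycle fluorescence grows with cycle time, and the
#' end-of-cycle decay becomes pronounced once the OFF half-cycle outlasts
#' mediator interconversion and reporter turnover).
#'
#' @param cycle_times full cycle times, seconds
#' @param params a [circuit_params]
#' @param state,couple,k_e,k_cell,cell_density,dt as in [simulate_expression]
#' @param on_potential,off_potential applied potentials, V
#' @return data frame with columns `cycle_time_s`, `half_cycle_fluor_au`,
#'   `end_cycle_fluor_au`
#' @export
cycle_experiment <- function(cycle_times, params = circuit_params(),
                             state = electrolysis_state(),
                             couple = ferricyanide_couple(),
                             k_e = log(100) / 900, k_cell = 0,
                             cell_density = 0, dt = 1,
                             on_potential = 0.5, off_potential = -0.3) {
  if (any(cycle_times <= 0)) stop_invalid("cycle times must be > 0")
  res <- lapply(cycle_times, function(ct) {
    sched <- signal_schedule(c(on_potential, off_potential), c(ct / 2, ct / 2))
    sim <- simulate_expression(sched, params, state, couple, k_e = k_e,
                               k_cell = k_cell, cell_density = cell_density,
                               dt = min(dt, ct / 4))
    P <- stats::approx(sim$times, sim$trace$fluor_au,
                       xout = c(ct / 2, ct))$y
    data.frame(cycle_time_s = ct, half_cycle_fluor_au = P[1],
               end_cycle_fluor_au = P[2])
  })
  do.call(rbind, res)
}

#' Fit the reporter degradation rate from an OFF-phase decay
#'
#' Log-linear least squares on the trace segment after `off_start`:
#' regressing log fluorescence on time gives the first-order decay rate as
#' minus the slope, with its standard error.
#'
#' @param trace an [expression_trace]
#' @param off_start start of the OFF (decay) window, seconds
#' @return list with `k_deg` (1/s), `stderr`, and `n` (samples used)
#' @export
fit_degradation_rate <- function(trace, off_start) {
  if (!inherits(trace, "expression_trace"))
    trace <- expression_trace(trace$time_s, trace$fluor_au)
  keep <- trace$time_s >= off_start
  if (sum(keep) < 4L) stop_invalid("need >= 4 samples after off_start")
  P <- trace$fluor_au[keep]
  if (any(P <= 0))
    stop_invalid("nonpositive fluorescence in the fit window")
  t <- trace$time_s[keep]
  fit <- stats::lm(log(P) ~ t)
  # a noiseless decay fits perfectly; the zero-residual warning is benign
  se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  list(k_deg = -unname(stats::coef(fit)[2]),
       stderr = unname(se), n = sum(keep))
}
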