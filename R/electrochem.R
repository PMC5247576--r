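#' Redox couple description
#'
#' A solution-phase redox couple characterised by its standard potential and
#' the number of electrons transferred per molecule. The package default is
#' the ferri/ferrocyanide couple Fcn(O)/Fcn(R), a one-electron couple with a
#' standard potential of about +0.2 V versus Ag/AgCl.
#'
#' @param name couple label
#' @param E0 standard potential, volts vs the reference electrode (Ag/AgCl)
#' @param n electrons transferred per molecule (integer >= 1)
#' @return an object of class `redox_couple`
#' @export
#' @examples
#' ferricyanide_couple()
redox_couple <- function(name = "Fcn(O/R)", E0 = 0.2, n = 1L) {
  if (!is.finite(E0)) stop_invalid("E0 must be finite")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_invalid("n must be an integer >= 1")
  structure(list(name = name, E0 = E0, n = n), class = "redox_couple")
}

#' @rdname redox_couple
#' @export
ferricyanide_couple <- function() redox_couple("Fcn(O/R)", E0 = 0.2, n = 1L)

#' Bulk electrolysis cell state
#'
#' The mediator pool in the working chamber: total moles are conserved, only
#' the oxidized fraction changes. Defaults mirror a 3 ml working volume of
#' 5 mM total Fcn(O)+Fcn(R) at 37 degrees C.
#'
#' @param volume litres
#' @param total_conc mol/L of oxidized + reduced species
#' @param frac_ox initial oxidized fraction in \[0, 1\]
#' @param temperature kelvin
#' @return an object of class `electrolysis_state`
#' @export
electrolysis_state <- function(volume = 3e-3, total_conc = 5e-3,
                               frac_ox = 0, temperature = 310.15) {
  if (!is.finite(volume) || volume <= 0) stop_invalid("volume must be > 0")
  if (!is.finite(total_conc) || total_conc <= 0)
    stop_invalid("total_conc must be > 0")
  if (!is.finite(frac_ox) || frac_ox < 0 || frac_ox > 1)
    stop_invalid("frac_ox must lie in [0, 1]")
  if (!is.finite(temperature) || temperature <= 0)
    stop_invalid("temperature must be > 0 K")
  structure(list(volume = volume, total_conc = total_conc,
                 frac_ox = frac_ox, temperature = temperature),
            class = "electrolysis_state")
}

#' Piecewise-constant applied-potential program
#'
#' Contiguous segments starting at t = 0. An `NA` potential denotes an
#' open-circuit segment: the electrode drive is off but solution-phase
#' processes (cell-mediated re-reduction) continue. The conventional signals
#' are +0.5 V for oxidation ("ON") and -0.3 V for reduction ("OFF").
#'
#' @param potential volts per segment (`NA` = open circuit)
#' @param duration seconds per segment, all > 0
#' @return an object of class `signal_schedule` (a data frame with columns
#'   `potential_V`, `duration_s`)
#' @export
#' @examples
#' signal_schedule(c(0.5, -0.3), c(900, 900))  # 15 min ON then 15 min OFF
signal_schedule <- function(potential, duration) {
  if (length(potential) != length(duration) || length(duration) == 0L)
    stop_invalid("potential and duration must be equal-length, non-empty")
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop_invalid("all durations must be positive and finite")
  if (any(!is.na(potential) & !is.finite(potential)))
    stop_invalid("potentials must be finite or NA (open circuit)")
  structure(data.frame(potential_V = as.numeric(potential),
                       duration_s = as.numeric(duration)),
            class = c("signal_schedule", "data.frame"))
}

#' Current trace
#'
#' Sampled current versus time. Sign convention: oxidation current is
#' negative, so oxidizing ("ON") signals accumulate negative charge.
#'
#' @param times seconds, strictly increasing, starting at >= 0
#' @param currents amperes
#' @return an object of class `current_trace`
#' @export
current_trace <- function(times, currents) {
  if (length(times) != length(currents))
    stop_invalid("times and currents must have equal length")
  if (length(times) && (times[1] < 0 || any(diff(times) <= 0)))
    stop_invalid("times must be strictly increasing and start at >= 0")
  if (any(!is.finite(currents)))
    stop_invalid("currents must be finite")
  structure(data.frame(time_s = as.numeric(times),
                       current_A = as.numeric(currents)),
            class = c("current_trace", "data.frame"))
}

#' Equilibrium oxidized fraction from the Nernst equation
#'
#' For an applied potential E the equilibrium oxidized fraction of a couple
#' is the logistic f = 1 / (1 + exp(-nF(E - E0)/(RT))). It equals 1/2 at
#' E = E0 and is monotone nondecreasing in E.
#'
#' @param E_applied applied potential, volts vs the couple's reference
#' @param couple a [redox_couple]
#' @param temperature kelvin
#' @return equilibrium oxidized fraction in \[0, 1\]
#' @export
#' @examples
#' nernst_fraction(0.5, ferricyanide_couple())  # ~1: strongly oxidizing
nernst_fraction <- function(E_applied, couple = ferricyanide_couple(),
                            temperature = 310.15) {
  if (any(!is.finite(E_applied))) stop_invalid("E_applied must be finite")
  if (!is.finite(temperature) || temperature <= 0)
    stop_invalid("temperature must be > 0 K")
  z <- couple$n * .FARADAY * (E_applied - couple$E0) / (.GAS_R * temperature)
  1 / (1 + exp(-z))
}

#' Faraday charge of a bulk conversion
#'
#' Q = n F (moles converted), signed by the trace convention: oxidation is
#' negative. Full oxidation of 3 ml of 5 mM one-electron mediator carries
#' |Q| of about 1.45 C; the device operates in the 0 to -2 C range.
#'
#' @param delta_moles moles converted (>= 0)
#' @param n electrons per molecule
#' @param direction `"oxidation"` (negative charge) or `"reduction"`
#' @return charge in coulombs
#' @export
faraday_charge <- function(delta_moles, n = 1L,
                           direction = c("oxidation", "reduction")) {
  direction <- match.arg(direction)
  if (any(!is.finite(delta_moles)) || any(delta_moles < 0))
    stop_invalid("delta_moles must be nonnegative")
  if (n < 1) stop_invalid("n must be >= 1")
  q <- n * .FARADAY * delta_moles
  if (direction == "oxidation") -q else q
}

#' Cumulative charge from a current trace
#'
#' Trapezoidal cumulative integral of current over time; the final element is
#' the total measured charge.
#'
#' @param trace a [current_trace]
#' @return numeric vector of cumulative charge (coulombs), same length as the
#'   trace, first element 0
#' @export
integrate_charge <- function(trace) {
  if (!inherits(trace, "current_trace")) trace <- current_trace(trace$time_s, trace$current_A)
  if (nrow(trace) < 2L) stop_invalid("integrate_charge needs >= 2 samples")
  cumtrapz_(trace$time_s, trace$current_A)
}

#' Simulate bulk electrolysis of the mediator pool
#'
#' Integrates the oxidized fraction under a piecewise-constant potential
#' program:
#' \deqn{df/dt = k_e (f_{eq}(E) - f) - k_{cell} \cdot \rho \cdot f}
#' where `f_eq` is the Nernst endpoint for the segment potential, `k_e` lumps
#' electrode kinetics and mass transport into a single relaxation rate, and
#' the second term is cell-mediated re-reduction of the oxidized mediator
#' proportional to cell density `rho` (OD units). In an open-circuit segment
#' (`NA` potential) the electrode term is dropped. The emitted current covers
#' the electrode term only, I(t) = -n F V C k_e (f_eq - f), so the integrated
#' charge matches the Faraday charge of net electrode-driven conversion.
#'
#' Fixed-step RK4; the default `k_e = ln(100)/900` gives 99% interconversion
#' in 15 min, the device's observed bulk-conversion time scale.
#'
#' @param state an [electrolysis_state]
#' @param schedule a [signal_schedule]
#' @param couple a [redox_couple]
#' @param k_e electrode relaxation rate, 1/s
#' @param k_cell cell-mediated reduction rate per OD unit, 1/s
#' @param cell_density cell density, OD600 units
#' @param dt integration step, seconds (must not exceed any segment duration)
#' @return list with `times`, `frac_ox` (same length), and `trace`
#'   (a [current_trace]); class `electrolysis_sim`
#' @export
#' @examples
#' sim <- simulate_bulk_electrolysis(electrolysis_state(),
#'                                   signal_schedule(0.5, 900))
#' tail(integrate_charge(sim$trace), 1)  # ~ -1.43 C
simulate_bulk_electrolysis <- function(state, schedule,
                                       couple = ferricyanide_couple(),
                                       k_e = log(100) / 900,
                                       k_cell = 0, cell_density = 0,
                                       dt = 1) {
  stopifnot(inherits(state, "electrolysis_state"),
            inherits(schedule, "signal_schedule"))
  if (!is.finite(dt) || dt <= 0) stop_invalid("dt must be > 0")
  if (k_e < 0 || k_cell < 0 || cell_density < 0)
    stop_invalid("rates and cell density must be >= 0")
  if (any(dt > schedule$duration_s))
    stop_invalid("dt (%g s) exceeds a segment duration", dt)

  kc <- k_cell * cell_density
  f <- state$frac_ox
  t_end <- 0
  times <- 0
  fracs <- f
  currents <- NULL
  cur_scale <- -couple$n * .FARADAY * state$volume * state$total_conc

  # One fixed RK4 step of the linear ODE f' = a - b f is the affine map
  # f <- R(bh) f + (1 - R(bh)) a/b with R the 4th-order Taylor polynomial of
  # exp(-bh); iterate it in closed form over the whole segment.
  rk4_seg <- function(f0, a, b, steps) {
    if (b == 0) return(f0 + a * cumsum(steps))
    fstar <- a / b
    R <- vapply(steps, function(h) {
      bh <- b * h
      1 - bh + bh^2 / 2 - bh^3 / 6 + bh^4 / 24
    }, numeric(1))
    fstar + (f0 - fstar) * cumprod(R)
  }

  for (i in seq_len(nrow(schedule))) {
    E <- schedule$potential_V[i]
    on <- !is.na(E)
    feq <- if (on) nernst_fraction(E, couple, state$temperature) else 0
    a <- if (on) k_e * feq else 0
    b <- (if (on) k_e else 0) + kc
    n_full <- floor(schedule$duration_s[i] / dt + 1e-9)
    steps <- rep(dt, n_full)
    rem <- schedule$duration_s[i] - n_full * dt
    if (rem > 1e-3) steps <- c(steps, rem)

    f_seg <- rk4_seg(f, a, b, steps)
    f_seg <- pmin(pmax(f_seg, 0), 1)  # FP guard; dynamics stay in [0,1]
    i_seg <- if (on) cur_scale * k_e * (feq - c(f, f_seg)) else
      numeric(length(steps) + 1L)

    if (is.null(currents)) {
      times <- c(times, t_end + cumsum(steps))
      fracs <- c(fracs, f_seg)
      currents <- i_seg
    } else {
      # the current jumps at a potential switch: represent the
      # discontinuity with a double sample 1 us apart so trapezoidal
      # charge integration stays exact across the boundary
      times <- c(times, t_end + 1e-6, t_end + cumsum(steps))
      fracs <- c(fracs, f, f_seg)
      currents <- c(currents, i_seg)
    }
    f <- f_seg[length(f_seg)]
    t_end <- t_end + sum(steps)
  }

  structure(list(times = times, frac_ox = fracs,
                 trace = current_trace(times, currents),
                 state = state, schedule = schedule, couple = couple,
                 k_e = k_e, k_cell = k_cell, cell_density = cell_density),
            class = "electrolysis_sim")
}
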