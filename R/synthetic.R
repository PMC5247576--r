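#' Synthetic reporter-expression trace with ground truth
#'
#' Integrates the reporter ODE \eqn{dP/dt = s(t) - k P} exactly (piecewise
#' closed form for a piecewise-constant synthesis profile), samples it at a
#' regular interval, adds measurement noise, and returns the noiseless
#' cumulative synthesis \eqn{S(t)=\int_0^t s\,d\tau} as ground truth for the
#' deconvolution machinery.
#'
#' @param s_rates synthesis rate per segment, au/s (>= 0)
#' @param s_durations segment durations, seconds
#' @param k_deg first-order degradation rate, 1/s
#' @param P0 initial fluorescence, au
#' @param noise_cv multiplicative noise coefficient of variation (default 0)
#' @param noise_sd additive Gaussian noise sd, au (default 0)
#' @param sampling_interval seconds between samples
#' @param seed RNG seed (generator is seed-deterministic)
#' @return list with `trace` (an [expression_trace], noisy), `truth`
#'   (data frame: time_s, P_true, S_true) and the scenario parameters
#' @export
gen_expression_trace <- function(s_rates, s_durations, k_deg,
                                 P0 = 0, noise_cv = 0, noise_sd = 0,
                                 sampling_interval = 60, seed = NULL) {
  if (length(s_rates) != length(s_durations) || length(s_rates) == 0L)
    stop_invalid("s_rates and s_durations must be equal-length, non-empty")
  if (any(s_rates < 0) || any(s_durations <= 0))
    stop_invalid("rates must be >= 0, durations > 0")
  if (k_deg < 0 || noise_cv < 0 || noise_sd < 0)
    stop_invalid("k_deg and noise parameters must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  t_total <- sum(s_durations)
  tt <- seq(0, t_total, by = sampling_interval)
  bounds <- c(0, cumsum(s_durations))
  seg_of <- pmin(findInterval(tt, bounds, rightmost.closed = TRUE),
                 length(s_rates))

  # exact P at segment boundaries, then within-segment closed form
  P_b <- numeric(length(bounds))
  P_b[1] <- P0
  for (i in seq_along(s_rates)) {
    s <- s_rates[i]
    d <- s_durations[i]
    P_b[i + 1L] <- if (k_deg == 0) P_b[i] + s * d else
      s / k_deg + (P_b[i] - s / k_deg) * exp(-k_deg * d)
  }
  S_b <- c(0, cumsum(s_rates * s_durations))

  tau <- tt - bounds[seg_of]
  s_here <- s_rates[seg_of]
  P_true <- if (k_deg == 0) P_b[seg_of] + s_here * tau else
    s_here / k_deg + (P_b[seg_of] - s_here / k_deg) * exp(-k_deg * tau)
  S_true <- S_b[seg_of] + s_here * tau

  P_obs <- P_true
  if (noise_cv > 0) P_obs <- P_obs * (1 + noise_cv * stats::rnorm(length(tt)))
  if (noise_sd > 0) P_obs <- P_obs + noise_sd * stats::rnorm(length(tt))
  P_obs <- pmax(P_obs, 0)

  list(trace = expression_trace(tt, P_obs),
       truth = data.frame(time_s = tt, P_true = P_true, S_true = S_true),
       k_deg = k_deg, P0 = P0, seed = seed)
}

# Render Gaussian blobs onto a background; positions in pixel coordinates.
.render_frame <- function(H, W, xs, ys, amps, psf_sigma, bg, noise_sd) {
  img <- matrix(bg, H, W)
  ext <- ceiling(3 * psf_sigma)
  for (i in seq_along(xs)) {
    cx <- xs[i]
    cy <- ys[i]
    c0 <- max(1L, floor(cx) - ext)
    c1 <- min(W, ceiling(cx) + ext)
    r0 <- max(1L, floor(cy) - ext)
    r1 <- min(H, ceiling(cy) + ext)
    if (c0 > c1 || r0 > r1) next
    gx <- exp(-((c0:c1) - cx)^2 / (2 * psf_sigma^2))
    gy <- exp(-((r0:r1) - cy)^2 / (2 * psf_sigma^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amps[i] * outer(gy, gx)
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
  matrix(as.integer(pmin(pmax(round(img), 0), 255)), H, W)
}

#' Synthetic run-and-tumble motility video with ground truth
#'
#' Simulates swimmers moving at constant speed with exponentially
#' distributed run lengths (tumble events redirect uniformly; evaluated at
#' frame boundaries), a `stuck_fraction` of immobile cells, and a uniform
#' background drift applied to every cell (stuck included, emulating bulk
#' flow across the slide). Cells are rendered as Gaussian blobs on a noisy
#' background. Motion reflects off the field edges. Ground-truth per-frame
#' positions, stuck labels and drift-free mean speeds are returned for
#' tracker validation.
#'
#' @param n_cells number of cells
#' @param swim_speed micrometres/second
#' @param tumble_rate tumbles per second (CheZ-induced smooth swimmers are
#'   low; CheZ-null cells high)
#' @param stuck_fraction fraction of immobile cells in \[0, 1\]
#' @param drift (dx, dy) micrometres/second applied to all cells
#' @param psf_sigma blob Gaussian sigma, pixels
#' @param noise_sd additive intensity noise sd (8-bit scale)
#' @param H,W frame size, pixels
#' @param fps frames per second
#' @param pixel_size micrometres per pixel
#' @param n_frames frames recorded (~100 matches typical acquisition)
#' @param amplitude mean blob peak intensity above background
#' @param bg background intensity
#' @param seed RNG seed
#' @param gate_radius tracker gate used only to warn when the scenario's
#'   per-frame displacement would violate it
#' @return list with `video` (a [video_stack]), `truth` (data frame:
#'   cell_id, frame, x_px, y_px, stuck), and `speeds` (data frame: cell_id,
#'   stuck, speed_um_s — drift-free ground-truth mean speed)
#' @export
gen_motility_video <- function(n_cells = 15, swim_speed = 20,
                               tumble_rate = 0.5, stuck_fraction = 0.1,
                               drift = c(0, 0), psf_sigma = 2,
                               noise_sd = 3, H = 320, W = 320, fps = 10,
                               pixel_size = 0.32, n_frames = 100,
                               amplitude = 140, bg = 30, seed = NULL,
                               gate_radius = 20) {
  if (n_frames < 2L) stop_invalid("n_frames must be >= 2")
  if (tumble_rate < 0 || swim_speed < 0) stop_invalid("rates must be >= 0")
  if (stuck_fraction < 0 || stuck_fraction > 1)
    stop_invalid("stuck_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / fps
  step_px <- (swim_speed + sqrt(sum(drift^2))) * dt / pixel_size
  if (step_px > gate_radius)
    warning(sprintf(
      "per-frame displacement %.1f px exceeds the %.1f px tracker gate",
      step_px, gate_radius), call. = FALSE)

  n_stuck <- round(n_cells * stuck_fraction)
  stuck <- c(rep(TRUE, n_stuck), rep(FALSE, n_cells - n_stuck))
  # seed cells upwind of any net drift so they stay in the field of view
  margin <- 6
  tot_dx <- drift[1] * (n_frames - 1) * dt / pixel_size
  tot_dy <- drift[2] * (n_frames - 1) * dt / pixel_size
  xr <- c(margin + max(0, -tot_dx), W - margin - max(0, tot_dx))
  yr <- c(margin + max(0, -tot_dy), H - margin - max(0, tot_dy))
  if (diff(xr) < 10 || diff(yr) < 10) {
    warning("drift traverses most of the field; cells may reach the border",
            call. = FALSE)
    xr <- c(margin, W - margin)
    yr <- c(margin, H - margin)
  }
  # rejection-sample starting positions so no two cells begin overlapped
  min_sep <- 8 * psf_sigma
  x <- numeric(n_cells)
  y <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    for (try in 1:200) {
      xi <- stats::runif(1, xr[1], xr[2])
      yi <- stats::runif(1, yr[1], yr[2])
      if (i == 1L || all(sqrt((x[seq_len(i - 1L)] - xi)^2 +
                              (y[seq_len(i - 1L)] - yi)^2) >= min_sep))
        break
    }
    x[i] <- xi
    y[i] <- yi
  }
  theta <- stats::runif(n_cells, 0, 2 * pi)
  amps <- amplitude * stats::runif(n_cells, 0.8, 1.2)

  step_um <- swim_speed * dt
  drift_px <- drift * dt / pixel_size
  p_tumble <- 1 - exp(-tumble_rate * dt)

  X <- matrix(NA_real_, n_frames, n_cells)
  Y <- matrix(NA_real_, n_frames, n_cells)
  X[1, ] <- x
  Y[1, ] <- y
  for (t in 2:n_frames) {
    tum <- stats::runif(n_cells) < p_tumble
    theta[tum] <- stats::runif(sum(tum), 0, 2 * pi)
    dx <- ifelse(stuck, 0, step_um * cos(theta) / pixel_size) + drift_px[1]
    dy <- ifelse(stuck, 0, step_um * sin(theta) / pixel_size) + drift_px[2]
    nx <- X[t - 1, ] + dx
    ny <- Y[t - 1, ] + dy
    # clamp at the borders and reverse heading so cells swim back inward
    refl_x <- nx < 2 | nx > W - 1
    refl_y <- ny < 2 | ny > H - 1
    nx[refl_x] <- pmin(pmax(nx[refl_x], 2), W - 1)
    ny[refl_y] <- pmin(pmax(ny[refl_y], 2), H - 1)
    theta[refl_x] <- pi - theta[refl_x]
    theta[refl_y] <- -theta[refl_y]
    X[t, ] <- nx
    Y[t, ] <- ny
  }

  frames <- lapply(seq_len(n_frames), function(t)
    .render_frame(H, W, X[t, ], Y[t, ], amps, psf_sigma, bg, noise_sd))

  truth <- data.frame(
    cell_id = rep(seq_len(n_cells), each = n_frames),
    frame = rep(seq_len(n_frames), n_cells),
    x_px = as.vector(X), y_px = as.vector(Y),
    stuck = rep(stuck, each = n_frames))
  # drift-free ground-truth speed per cell from true displacements
  sp <- vapply(seq_len(n_cells), function(i) {
    dxs <- diff(X[, i]) - drift_px[1]
    dys <- diff(Y[, i]) - drift_px[2]
    mean(sqrt(dxs^2 + dys^2)) * pixel_size * fps
  }, numeric(1))
  list(video = video_stack(frames, fps, pixel_size),
       truth = truth,
       speeds = data.frame(cell_id = seq_len(n_cells), stuck = stuck,
                           speed_um_s = sp))
}

#' Synthetic flow-cytometry event table with labels
#'
#' Draws labelled events from a mixture of populations: green fluorescence
#' is log-normal per population, scatter channels Gaussian. The default
#' two-population 1:1 design emulates a relay:receiver co-culture in which
#' only receivers light up.
#'
#' @param n_events number of events (50,000 matches typical acquisition)
#' @param populations list of population descriptors, each a list with
#'   `fraction`, `meanlog`, `sdlog` (natural-log parameters of green),
#'   `fsc_mean`, `fsc_sd`, `ssc_mean`, `ssc_sd`
#' @param seed RNG seed
#' @return list with `events` (an [event_table]) and `labels` (integer
#'   population index per event)
#' @export
gen_cytometry_events <- function(n_events = 50000,
                                 populations = list(
                                   list(fraction = 0.5, meanlog = log(300),
                                        sdlog = 0.5, fsc_mean = 500,
                                        fsc_sd = 80, ssc_mean = 300,
                                        ssc_sd = 60),
                                   list(fraction = 0.5, meanlog = log(3000),
                                        sdlog = 0.5, fsc_mean = 500,
                                        fsc_sd = 80, ssc_mean = 300,
                                        ssc_sd = 60)),
                                 seed = NULL) {
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop_invalid("population fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  labels <- sample.int(length(populations), n_events, replace = TRUE,
                       prob = fr)
  green <- numeric(n_events)
  fsc <- numeric(n_events)
  ssc <- numeric(n_events)
  for (p in seq_along(populations)) {
    k <- which(labels == p)
    pop <- populations[[p]]
    green[k] <- stats::rlnorm(length(k), pop$meanlog, pop$sdlog)
    fsc[k] <- stats::rnorm(length(k), pop$fsc_mean, pop$fsc_sd)
    ssc[k] <- stats::rnorm(length(k), pop$ssc_mean, pop$ssc_sd)
  }
  list(events = event_table(fsc, ssc, green), labels = labels)
}

#' Synthetic current trace with known total charge
#'
#' Runs the bulk-electrolysis simulation, adds Gaussian current noise, and
#' reports the noiseless total charge as ground truth.
#'
#' @param schedule a [signal_schedule]
#' @param state,couple,k_e,k_cell,cell_density,dt forwarded to
#'   [simulate_bulk_electrolysis]
#' @param noise_sd additive current noise sd, amperes
#' @param seed RNG seed
#' @return list with `trace` (noisy [current_trace]), `true_charge`
#'   (coulombs) and the noiseless simulation
#' @export
gen_current_trace <- function(schedule, state = electrolysis_state(),
                              couple = ferricyanide_couple(),
                              k_e = log(100) / 900, k_cell = 0,
                              cell_density = 0, dt = 1, noise_sd = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_bulk_electrolysis(state, schedule, couple, k_e = k_e,
                                    k_cell = k_cell,
                                    cell_density = cell_density, dt = dt)
  i_noisy <- sim$trace$current_A +
    if (noise_sd > 0) stats::rnorm(nrow(sim$trace), 0, noise_sd) else 0
  list(trace = current_trace(sim$trace$time_s, i_noisy),
       true_charge = utils::tail(integrate_charge(sim$trace), 1),
       sim = sim)
}
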