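#' Time-lapse video stack
#'
#' An ordered list of equally sized grayscale frames plus acquisition
#' metadata. Image convention: matrices are indexed `[row, col]`; a pixel at
#' row r, column c has coordinates (x = c, y = r), origin top-left, pixel
#' centres at integer coordinates.
#'
#' @param frames list of numeric/integer matrices, identical dimensions
#' @param fps frames per second
#' @param pixel_size micrometres per pixel
#' @return an object of class `video_stack`
#' @export
video_stack <- function(frames, fps, pixel_size) {
  if (!is.list(frames) || length(frames) < 2L)
    stop_invalid("a video needs at least 2 frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_invalid("all frames must share the same shape")
  if (fps <= 0 || pixel_size <= 0)
    stop_invalid("fps and pixel_size must be > 0")
  structure(list(frames = frames, fps = fps, pixel_size = pixel_size),
            class = "video_stack")
}

#' Otsu's threshold from an intensity histogram
#'
#' Exhaustively maximizes the between-class variance
#' \eqn{\sigma_b^2 = w_0 w_1 (\mu_0 - \mu_1)^2} over all split points. The
#' returned threshold T is the lowest intensity level of the foreground
#' class: pixels with intensity >= T are foreground. Ties are broken toward
#' the lower level.
#'
#' @param counts histogram counts per intensity level
#' @param levels intensity value of each bin (default `0:(length(counts)-1)`)
#' @return the threshold level
#' @export
otsu_threshold <- function(counts, levels = seq_along(counts) - 1) {
  if (length(counts) != length(levels))
    stop_invalid("counts and levels must have equal length")
  if (sum(counts > 0) < 2L)
    stop_invalid("degenerate histogram: fewer than 2 nonzero bins")
  n <- sum(counts)
  w0 <- cumsum(counts) / n
  mu <- cumsum(counts * levels) / n
  mu_tot <- mu[length(mu)]
  # split after bin i: class0 = bins 1..i, class1 = the rest
  i <- seq_len(length(counts) - 1L)
  w0i <- w0[i]
  valid <- w0i > 0 & w0i < 1
  sigma_b <- rep(-Inf, length(i))
  sigma_b[valid] <- (mu_tot * w0i[valid] - mu[i][valid])^2 /
    (w0i[valid] * (1 - w0i[valid]))
  best <- which.max(sigma_b)  # first maximum = lowest level on ties
  levels[best + 1L]
}

#' Segment one frame into cell detections
#'
#' Thresholds the frame (foreground = intensity >= threshold), labels
#' 8-connected components, drops components smaller than `min_area`, and
#' returns per-component centroids (unweighted pixel-coordinate means),
#' areas and mean intensities.
#'
#' @param frame numeric matrix
#' @param threshold intensity threshold (e.g. from [otsu_threshold])
#' @param min_area minimum component area in pixels
#' @param max_area maximum component area in pixels (guards against a
#'   flooded background or large debris)
#' @return data frame with columns `x`, `y`, `area`, `mean_intensity`
#' @export
segment_frame <- function(frame, threshold, min_area = 4,
                          max_area = Inf) {
  H <- nrow(frame)
  W <- ncol(frame)
  idx <- which(frame >= threshold)
  empty <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                      mean_intensity = numeric(0))
  if (length(idx) == 0L) return(empty)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  # 8-connectivity: half the neighbourhood suffices for an undirected graph
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  e_from <- integer(0)
  e_to <- integer(0)
  for (o in offs) {
    ok <- r + o[1] >= 1L & r + o[1] <= H & cc + o[2] >= 1L & cc + o[2] <= W
    nbr <- idx[ok] + o[1] + o[2] * H
    j <- match(nbr, idx)
    hit <- !is.na(j)
    e_from <- c(e_from, which(ok)[hit])
    e_to <- c(e_to, j[hit])
  }
  g <- igraph::make_graph(rbind(e_from, e_to), n = length(idx),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  ar <- tabulate(memb)
  keep <- which(ar >= min_area & ar <= max_area)
  if (length(keep) == 0L) return(empty)
  out <- do.call(rbind, lapply(keep, function(m) {
    px <- memb == m
    data.frame(x = mean(cc[px]), y = mean(r[px]), area = sum(px),
               mean_intensity = mean(frame[idx[px]]))
  }))
  rownames(out) <- NULL
  out
}

# Candidate pair costs between detection sets; gate may be per-row-of-a.
.pair_costs <- function(da, db, weights, gate) {
  na <- nrow(da)
  nb <- nrow(db)
  if (na == 0L || nb == 0L)
    return(data.frame(index_a = integer(0), index_b = integer(0),
                      cost = numeric(0), dist = numeric(0)))
  gate <- rep_len(gate, na)
  max_area <- max(da$area, db$area)
  max_int <- max(da$mean_intensity, db$mean_intensity)
  grid <- expand.grid(index_a = seq_len(na), index_b = seq_len(nb))
  d <- sqrt((da$x[grid$index_a] - db$x[grid$index_b])^2 +
            (da$y[grid$index_a] - db$y[grid$index_b])^2)
  g <- gate[grid$index_a]
  cost <- weights[1] * d / g +
    weights[2] * abs(da$area[grid$index_a] - db$area[grid$index_b]) /
      (if (max_area > 0) max_area else 1) +
    weights[3] * abs(da$mean_intensity[grid$index_a] -
                     db$mean_intensity[grid$index_b]) /
      (if (max_int > 0) max_int else 1)
  keep <- d <= g
  data.frame(index_a = grid$index_a[keep], index_b = grid$index_b[keep],
             cost = cost[keep], dist = d[keep])
}

# Greedy ascending-cost one-to-one assignment; ties broken by
# (lower index_a, lower index_b).
.greedy_assign <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  pairs <- pairs[order(pairs$cost, pairs$index_a, pairs$index_b), ]
  used_a <- logical(max(pairs$index_a))
  used_b <- logical(max(pairs$index_b))
  take <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$index_a[i]
    b <- pairs$index_b[i]
    if (!used_a[a] && !used_b[b]) {
      take[i] <- TRUE
      used_a[a] <- TRUE
      used_b[b] <- TRUE
    }
  }
  out <- pairs[take, ]
  rownames(out) <- NULL
  out
}

#' Link detections between two frames
#'
#' Nearest-neighbour linking on a combined cost of closeness, size
#' similarity and pixel intensity:
#' \deqn{cost = w_d d/gate + w_s |\Delta area|/max(area) + w_i |\Delta I|/max(I),}
#' with pairs farther apart than `gate_radius` forbidden. Assignment is
#' greedy in ascending cost, each detection used at most once; ties break
#' toward lower indices.
#'
#' @param dets_a,dets_b detection data frames (from [segment_frame])
#' @param weights nonnegative `(w_d, w_s, w_i)`, not all zero
#' @param gate_radius maximum linking distance, pixels
#' @return data frame with columns `index_a`, `index_b`, `cost`, `dist`
#' @export
link_detections <- function(dets_a, dets_b, weights = c(1, 0.5, 0.25),
                            gate_radius) {
  if (gate_radius <= 0) stop_invalid("gate_radius must be > 0")
  if (any(weights < 0) || all(weights == 0))
    stop_invalid("weights must be >= 0 and not all zero")
  .greedy_assign(.pair_costs(dets_a, dets_b, weights, gate_radius))
}

#' Build trajectories from a video
#'
#' Per-frame Otsu segmentation followed by frame-to-frame greedy linking.
#' Tracks missing from up to `max_gap` consecutive frames may be re-linked
#' (the gate grows linearly with the number of elapsed frames); tracks with
#' fewer than `min_length` detections are discarded.
#'
#' @param video a [video_stack]
#' @param threshold fixed intensity threshold, or `NULL` for per-frame Otsu
#' @param min_area minimum detection area, px
#' @param max_area maximum detection area, px
#' @param weights,gate_radius linking parameters (see [link_detections])
#' @param max_gap maximum missed frames inside a track
#' @param min_length minimum detections per reported track
#' @return list of trajectories (class `trajectory_set`); each trajectory is
#'   a list with `id` and `detections` (data frame: frame, x, y, area,
#'   mean_intensity)
#' @export
build_trajectories <- function(video, threshold = NULL, min_area = 4,
                               max_area = Inf,
                               weights = c(1, 0.5, 0.25), gate_radius = 20,
                               max_gap = 1, min_length = 10) {
  stopifnot(inherits(video, "video_stack"))
  dets <- lapply(seq_along(video$frames), function(t) {
    fr <- video$frames[[t]]
    thr <- threshold
    if (is.null(thr)) {
      h <- tabulate(pmin(pmax(as.integer(round(fr)), 0L), 255L) + 1L,
                    nbins = 256L)
      # a featureless frame (single grey level) has nothing to segment
      if (sum(h > 0) < 2L) return(data.frame(
        x = numeric(0), y = numeric(0), area = numeric(0),
        mean_intensity = numeric(0)))
      thr <- otsu_threshold(h, levels = 0:255)
    }
    d <- segment_frame(fr, thr, min_area, max_area)
    if (nrow(d)) d$frame <- t
    d
  })

  tracks <- list()        # each: list(rows, last_frame, open)
  new_track <- function(row) list(rows = row, last_frame = row$frame[1],
                                  open = TRUE)
  for (d in seq_len(nrow(dets[[1]]))) {
    tracks[[length(tracks) + 1L]] <- new_track(dets[[1]][d, ])
  }
  for (t in seq_along(video$frames)[-1]) {
    dt_now <- dets[[t]]
    open_ids <- which(vapply(tracks, function(tr)
      tr$open && (t - tr$last_frame) <= max_gap + 1L, logical(1)))
    if (length(open_ids) && nrow(dt_now)) {
      last_rows <- do.call(rbind, lapply(tracks[open_ids], function(tr)
        tr$rows[nrow(tr$rows), c("x", "y", "area", "mean_intensity")]))
      elapsed <- vapply(tracks[open_ids], function(tr) t - tr$last_frame,
                        numeric(1))
      pairs <- .pair_costs(last_rows, dt_now, weights,
                           gate = gate_radius * elapsed)
      asg <- .greedy_assign(pairs)
      matched_b <- rep(FALSE, nrow(dt_now))
      for (i in seq_len(nrow(asg))) {
        tid <- open_ids[asg$index_a[i]]
        tracks[[tid]]$rows <- rbind(tracks[[tid]]$rows,
                                    dt_now[asg$index_b[i], ])
        tracks[[tid]]$last_frame <- t
        matched_b[asg$index_b[i]] <- TRUE
      }
    } else {
      matched_b <- rep(FALSE, nrow(dt_now))
    }
    for (tid in seq_along(tracks)) {
      if (tracks[[tid]]$open && (t - tracks[[tid]]$last_frame) > max_gap + 1L)
        tracks[[tid]]$open <- FALSE
    }
    for (d in which(!matched_b)) {
      tracks[[length(tracks) + 1L]] <- new_track(dt_now[d, ])
    }
  }

  out <- Filter(function(tr) nrow(tr$rows) >= min_length, tracks)
  out <- lapply(seq_along(out), function(i) {
    rows <- out[[i]]$rows
    rownames(rows) <- NULL
    structure(list(id = i,
                   detections = rows[, c("frame", "x", "y", "area",
                                         "mean_intensity")]),
              class = "trajectory")
  })
  structure(out, class = "trajectory_set",
            n_frames = length(video$frames),
            fps = video$fps, pixel_size = video$pixel_size)
}

#' Estimate per-frame background drift
#'
#' The drift for each consecutive frame pair is the componentwise median
#' displacement over all linked detections in that pair — robust to the
#' swimming component, which is direction-random. Frame pairs with no links
#' get zero drift and are flagged.
#'
#' @param trajectories a `trajectory_set` (or list of trajectories)
#' @param n_frames number of frames (taken from the set's attribute if
#'   missing)
#' @return an `(n_frames - 1) x 2` matrix of (dx, dy) pixels/frame, with
#'   attribute `no_link_pairs` listing flagged pairs
#' @export
estimate_drift <- function(trajectories, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- attr(trajectories, "n_frames")
  if (is.null(n_frames)) stop_invalid("n_frames is required")
  dx <- vector("list", n_frames - 1L)
  dy <- vector("list", n_frames - 1L)
  for (tr in trajectories) {
    d <- tr$detections
    if (nrow(d) < 2L) next
    consec <- which(diff(d$frame) == 1L)
    for (i in consec) {
      p <- d$frame[i]
      dx[[p]] <- c(dx[[p]], d$x[i + 1L] - d$x[i])
      dy[[p]] <- c(dy[[p]], d$y[i + 1L] - d$y[i])
    }
  }
  drift <- cbind(
    vapply(dx, function(v) if (length(v)) stats::median(v) else 0, numeric(1)),
    vapply(dy, function(v) if (length(v)) stats::median(v) else 0, numeric(1)))
  colnames(drift) <- c("dx", "dy")
  no_link <- which(vapply(dx, length, integer(1)) == 0L)
  if (length(no_link))
    warning(sprintf("no links in %d frame pair(s); drift set to 0 there",
                    length(no_link)), call. = FALSE)
  attr(drift, "no_link_pairs") <- no_link
  drift
}

# Drift-corrected positions of a trajectory, micrometres.
.corrected_um <- function(traj, drift, pixel_size) {
  d <- traj$detections
  if (is.null(drift)) {
    cum <- cbind(rep(0, nrow(d)), rep(0, nrow(d)))
  } else {
    cdx <- c(0, cumsum(drift[, 1]))
    cdy <- c(0, cumsum(drift[, 2]))
    cum <- cbind(cdx[d$frame], cdy[d$frame])
  }
  cbind((d$x - cum[, 1]) * pixel_size, (d$y - cum[, 2]) * pixel_size)
}

#' Flag stuck cells
#'
#' A trajectory is stuck when its drift-corrected net displacement over the
#' whole track is below `net_disp_threshold`, or every sliding window of
#' `window` seconds is below it. Windows individually below the threshold
#' mark a partially stuck cell: the corresponding frame pairs are excluded
#' from velocity statistics and the track is flagged `partial`.
#'
#' @param traj a trajectory (from [build_trajectories])
#' @param fps,pixel_size acquisition metadata
#' @param drift per-frame drift matrix from [estimate_drift] (or `NULL`)
#' @param net_disp_threshold micrometres (default 2)
#' @param window seconds (default 1)
#' @return list with `stuck` (logical), `partial` (logical) and
#'   `moving_pairs` (logical per consecutive detection pair)
#' @export
filter_stuck <- function(traj, fps, pixel_size, drift = NULL,
                         net_disp_threshold = 2, window = 1) {
  d <- traj$detections
  if (nrow(d) < 2L) stop_invalid("trajectory needs >= 2 detections")
  pos <- .corrected_um(traj, drift, pixel_size)
  m <- nrow(pos)
  net_full <- sqrt(sum((pos[m, ] - pos[1, ])^2))
  w_frames <- max(1L, round(window * fps))
  pair_stuck <- rep(FALSE, m - 1L)
  for (i in seq_len(m - 1L)) {
    j <- max(which(d$frame - d$frame[i] <= w_frames))
    if (j <= i) next
    full_window <- (d$frame[j] - d$frame[i]) >= w_frames
    net <- sqrt(sum((pos[j, ] - pos[i, ])^2))
    if (full_window && net < net_disp_threshold)
      pair_stuck[i:(j - 1L)] <- TRUE
  }
  stuck <- net_full < net_disp_threshold || all(pair_stuck)
  partial <- !stuck && any(pair_stuck)
  list(stuck = stuck, partial = partial, moving_pairs = !pair_stuck)
}

#' Mean swimming speed of a trajectory
#'
#' Mean over consecutive detection pairs of the drift-corrected displacement
#' magnitude converted to micrometres per second; pairs spanning a gap use
#' the elapsed frame count in the denominator. Stuck trajectories are
#' excluded (error); partially stuck ones contribute only their moving
#' pairs via `moving_pairs`.
#'
#' @param traj a trajectory
#' @param fps,pixel_size acquisition metadata
#' @param drift per-frame drift matrix (or `NULL` for no correction)
#' @param moving_pairs logical mask from [filter_stuck] (or `NULL` for all)
#' @param stuck logical; pass the [filter_stuck] flag to enforce exclusion
#' @return mean speed, micrometres/second
#' @export
compute_velocity <- function(traj, fps, pixel_size, drift = NULL,
                             moving_pairs = NULL, stuck = FALSE) {
  if (isTRUE(stuck))
    stop_invalid("stuck trajectory excluded from velocity computation")
  d <- traj$detections
  if (nrow(d) < 2L) stop_invalid("trajectory needs >= 2 detections")
  pos <- .corrected_um(traj, drift, pixel_size)
  steps <- diff(d$frame)
  disp <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)
  speeds <- disp * fps / steps
  if (!is.null(moving_pairs)) speeds <- speeds[moving_pairs]
  if (length(speeds) == 0L)
    stop_invalid("no moving pairs left to compute a velocity")
  mean(speeds)
}

#' Origin-translated trajectory rose
#'
#' Truncates each trajectory to its first `ceiling(duration * fps)` points,
#' translates it so the first point sits at the origin, and converts to
#' micrometres — the conventional 3-second trajectory-rose display.
#'
#' @param trajectories a `trajectory_set` or list of trajectories
#' @param fps,pixel_size acquisition metadata (taken from the set's
#'   attributes when `NULL`)
#' @param duration seconds retained per track (default 3)
#' @param drift optional drift matrix for corrected roses
#' @return data frame with columns `track_id`, `time_s`, `x_um`, `y_um`
#' @export
trajectory_rose <- function(trajectories, fps = NULL, pixel_size = NULL,
                            duration = 3, drift = NULL) {
  if (duration <= 0) stop_invalid("duration must be > 0")
  if (is.null(fps)) fps <- attr(trajectories, "fps")
  if (is.null(pixel_size)) pixel_size <- attr(trajectories, "pixel_size")
  npts <- ceiling(duration * fps)
  out <- lapply(trajectories, function(tr) {
    d <- tr$detections
    if (nrow(d) < 2L) return(NULL)
    keep <- seq_len(min(nrow(d), npts))
    pos <- .corrected_um(tr, drift, pixel_size)[keep, , drop = FALSE]
    data.frame(track_id = tr$id,
               time_s = (d$frame[keep] - d$frame[1]) / fps,
               x_um = pos[, 1] - pos[1, 1],
               y_um = pos[, 2] - pos[1, 2])
  })
  do.call(rbind, out)
}

#' Velocity summary statistics and two-sample comparisons
#'
#' Per-condition mean and standard error of the mean, plus two-tailed
#' two-sample Student t-tests (pooled variance) between all condition pairs.
#' Identical groups give t = 0, p = 1.
#'
#' @param speeds named list of numeric speed vectors, one per condition
#'   (>= 2 samples each)
#' @return list with `summary` (condition, n, mean, sem) and `comparisons`
#'   (a, b, t, df, p) data frames
#' @export
velocity_statistics <- function(speeds) {
  if (!is.list(speeds) || is.null(names(speeds)))
    stop_invalid("speeds must be a named list of numeric vectors")
  if (any(vapply(speeds, length, integer(1)) < 2L))
    stop_invalid("each condition needs >= 2 samples")
  summ <- data.frame(
    condition = names(speeds),
    n = vapply(speeds, length, integer(1)),
    mean = vapply(speeds, mean, numeric(1)),
    sem = vapply(speeds, function(v) stats::sd(v) / sqrt(length(v)),
                 numeric(1)),
    row.names = NULL)
  cmp <- NULL
  nm <- names(speeds)
  if (length(speeds) >= 2L) {
    idx <- utils::combn(length(speeds), 2)
    cmp <- do.call(rbind, apply(idx, 2, function(ij) {
      a <- speeds[[ij[1]]]
      b <- speeds[[ij[2]]]
      n1 <- length(a)
      n2 <- length(b)
      df <- n1 + n2 - 2
      sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      diff_m <- mean(a) - mean(b)
      tval <- if (diff_m == 0) 0 else if (se == 0) sign(diff_m) * Inf
              else diff_m / se
      data.frame(a = nm[ij[1]], b = nm[ij[2]], t = tval, df = df,
                 p = 2 * stats::pt(-abs(tval), df))
    }))
    rownames(cmp) <- NULL
  }
  list(summary = summ, comparisons = cmp)
}

#' Track a video end to end
#'
#' Convenience wrapper chaining segmentation/linking ([build_trajectories]),
#' drift estimation, stuck-cell filtering and velocity computation — the
#' full video-analysis pass from frames to per-track speeds.
#'
#' @param video a [video_stack]
#' @param drift_correction estimate and subtract background drift
#' @param drift_smoothing `"temporal-median"` (default) replaces the
#'   per-frame-pair drift estimates by their componentwise median over all
#'   frame pairs — appropriate for background flow that is steady over the
#'   few-second acquisition, and much less noisy than the raw per-pair
#'   medians, whose swimming-direction component only cancels slowly with
#'   cell number. `"per-frame"` keeps the raw per-pair estimates.
#' @param net_disp_threshold,window stuck criterion (see [filter_stuck])
#' @param ... passed to [build_trajectories]
#' @return list with `trajectories` (a `trajectory_set`), `drift` (matrix or
#'   `NULL`), and `speeds` (data frame: track_id, n_detections, stuck,
#'   partial, mean_speed_um_s — `NA` speed for stuck tracks)
#' @export
track_video <- function(video, drift_correction = TRUE,
                        drift_smoothing = c("temporal-median", "per-frame"),
                        anchor_stuck = TRUE,
                        net_disp_threshold = 2, window = 1, ...) {
  drift_smoothing <- match.arg(drift_smoothing)
  trajs <- build_trajectories(video, ...)
  drift <- NULL
  if (drift_correction && length(trajs) > 0) {
    drift <- suppressWarnings(estimate_drift(trajs))
    if (drift_smoothing == "temporal-median") {
      drift[, 1] <- stats::median(drift[, 1])
      drift[, 2] <- stats::median(drift[, 2])
    }
    if (anchor_stuck) drift <- .anchor_drift(trajs, drift)
  }
  # nearest-neighbour distance between tracked detections in each frame:
  # when two cells come close their blob halos bias both centroids, so
  # those frames are excluded from speed statistics (as are frames whose
  # detection area is inconsistent with the track — a merged blob)
  all_det <- do.call(rbind, lapply(seq_along(trajs), function(k) {
    d <- trajs[[k]]$detections
    data.frame(k = k, i = seq_len(nrow(d)), frame = d$frame,
               x = d$x, y = d$y)
  }))
  nnd_ok <- vector("list", length(trajs))
  for (k in seq_along(trajs))
    nnd_ok[[k]] <- rep(TRUE, nrow(trajs[[k]]$detections))
  if (!is.null(all_det) && nrow(all_det) > 1L) {
    for (fd in split(all_det, all_det$frame)) {
      if (nrow(fd) < 2L) next
      dm <- as.matrix(stats::dist(fd[, c("x", "y")]))
      diag(dm) <- Inf
      close_ones <- which(apply(dm, 1, min) < 12)
      for (j in close_ones) nnd_ok[[fd$k[j]]][fd$i[j]] <- FALSE
    }
  }

  speeds <- do.call(rbind, lapply(seq_along(trajs), function(ki) {
    tr <- trajs[[ki]]
    fs <- filter_stuck(tr, video$fps, video$pixel_size, drift,
                       net_disp_threshold, window)
    a <- tr$detections$area
    det_ok <- a >= 0.6 * stats::median(a) & a <= 1.5 * stats::median(a) &
      nnd_ok[[ki]]
    pair_ok <- utils::head(det_ok, -1L) & utils::tail(det_ok, -1L)
    use <- fs$moving_pairs & pair_ok
    if (!any(use)) use <- fs$moving_pairs
    v <- if (fs$stuck) NA_real_ else
      compute_velocity(tr, video$fps, video$pixel_size, drift,
                       moving_pairs = use)
    data.frame(track_id = tr$id, n_detections = nrow(tr$detections),
               stuck = fs$stuck, partial = fs$partial,
               mean_speed_um_s = v)
  }))
  if (is.null(speeds))
    speeds <- data.frame(track_id = integer(0), n_detections = integer(0),
                         stuck = logical(0), partial = logical(0),
                         mean_speed_um_s = numeric(0))
  list(trajectories = trajs, drift = drift, speeds = speeds)
}

#' Compare tracker output against generator ground truth
#'
#' Matches each tracked detection to the nearest ground-truth cell in its
#' frame (within `match_radius`), assigns every trajectory to its majority
#' cell with a purity score, and scores (i) the fraction of ground-truth
#' consecutive-frame links recovered by the tracker, (ii) per-cell speed
#' agreement on high-purity tracks, and (iii) stuck-cell detection. A
#' ground-truth stuck cell counts as detected when its best-covering track
#' is flagged stuck or partially stuck — crossing events can splice a stuck
#' cell's track onto a swimmer's (an identity swap), in which case the
#' stuck portion is excluded by the windowed criterion and the track is
#' flagged partial.
#'
#' @param tracking result of [track_video]
#' @param truth ground-truth data frame from [gen_motility_video]
#'   (cell_id, frame, x_px, y_px, stuck)
#' @param true_speeds `speeds` data frame from [gen_motility_video]
#' @param match_radius pixels
#' @return list with `link_recovery` (fraction), `per_track` (one row per
#'   track: track_id, cell_id, purity, stuck_true, stuck_flag,
#'   partial_flag, true_speed, tracked_speed), `per_cell` (one row per
#'   ground-truth cell scored on its best-covering track, with `coverage`),
#'   `stuck_detection` (data frame per ground-truth stuck cell: cell_id,
#'   detected) and `n_truth_links`
#' @export
evaluate_tracking <- function(tracking, truth, true_speeds,
                              match_radius = 3) {
  trajs <- tracking$trajectories
  by_frame <- split(truth, truth$frame)
  match_det <- function(frame, x, y) {
    tf <- by_frame[[as.character(frame)]]
    d2 <- (tf$x_px - x)^2 + (tf$y_px - y)^2
    i <- which.min(d2)
    if (sqrt(d2[i]) <= match_radius) tf$cell_id[i] else NA_integer_
  }
  n_frames <- attr(trajs, "n_frames")
  n_cells <- length(unique(truth$cell_id))
  n_truth_links <- n_cells * (n_frames - 1L)

  recovered <- 0L
  traj_cell <- rep(NA_integer_, length(trajs))
  traj_purity <- rep(NA_real_, length(trajs))
  cover <- matrix(0L, nrow = max(1L, length(trajs)), ncol = n_cells)
  for (k in seq_along(trajs)) {
    d <- trajs[[k]]$detections
    ids <- mapply(match_det, d$frame, d$x, d$y)
    if (!all(is.na(ids))) {
      tab <- table(ids)
      traj_cell[k] <- as.integer(names(which.max(tab)))
      traj_purity[k] <- max(tab) / sum(tab)
      for (cid in as.integer(names(tab)))
        cover[k, cid] <- tab[[as.character(cid)]]
    }
    ok <- !is.na(ids)
    same <- diff(d$frame) == 1L & utils::head(ids, -1L) == utils::tail(ids, -1L) &
      utils::head(ok, -1L) & utils::tail(ok, -1L)
    recovered <- recovered + sum(same, na.rm = TRUE)
  }

  sp <- tracking$speeds
  per_track <- NULL
  if (length(trajs)) {
    per_track <- do.call(rbind, lapply(seq_along(trajs), function(k) {
      cid <- traj_cell[k]
      if (is.na(cid)) return(NULL)
      data.frame(track_id = k, cell_id = cid, purity = traj_purity[k],
                 stuck_true = true_speeds$stuck[true_speeds$cell_id == cid],
                 stuck_flag = sp$stuck[k], partial_flag = sp$partial[k],
                 true_speed = true_speeds$speed_um_s[true_speeds$cell_id == cid],
                 tracked_speed = sp$mean_speed_um_s[k])
    }))
  }

  per_cell <- do.call(rbind, lapply(seq_len(n_cells), function(cid) {
    if (length(trajs) == 0L || all(cover[, cid] == 0L)) return(NULL)
    best <- which.max(cover[, cid])
    data.frame(cell_id = cid, track_id = best,
               coverage = cover[best, cid] / n_frames,
               purity = traj_purity[best],
               stuck_true = true_speeds$stuck[true_speeds$cell_id == cid],
               stuck_flag = sp$stuck[best], partial_flag = sp$partial[best],
               true_speed = true_speeds$speed_um_s[true_speeds$cell_id == cid],
               tracked_speed = sp$mean_speed_um_s[best])
  }))

  stuck_ids <- true_speeds$cell_id[true_speeds$stuck]
  stuck_detection <- NULL
  if (length(stuck_ids)) {
    stuck_detection <- do.call(rbind, lapply(stuck_ids, function(cid) {
      if (length(trajs) == 0L || all(cover[, cid] == 0L))
        return(data.frame(cell_id = cid, detected = FALSE))
      best <- which.max(cover[, cid])
      data.frame(cell_id = cid,
                 detected = sp$stuck[best] || sp$partial[best])
    }))
  }
  list(link_recovery = recovered / n_truth_links,
       per_track = per_track, per_cell = per_cell,
       stuck_detection = stuck_detection, n_truth_links = n_truth_links)
}

# Refine a drift estimate by anchoring on coherently advected (stuck) cells.
#
# A swimmer's per-pair displacement always sits a full swim step away from
# the true drift, whereas a stuck cell is carried by the flow exactly, so a
# trajectory whose mean residual from the initial drift estimate is far
# below the typical residual marks a stuck cell; the flow is then re-read
# directly off those cells' displacements (accurate to centroid noise).
# With no such anchors the initial estimate is returned unchanged.
.anchor_drift <- function(trajs, drift0) {
  resid <- vapply(trajs, function(tr) {
    d <- tr$detections
    if (nrow(d) < 2L) return(NA_real_)
    consec <- which(diff(d$frame) == 1L)
    if (!length(consec)) return(NA_real_)
    p <- d$frame[consec]
    mean(sqrt((d$x[consec + 1L] - d$x[consec] - drift0[p, 1])^2 +
              (d$y[consec + 1L] - d$y[consec] - drift0[p, 2])^2))
  }, numeric(1))
  med <- stats::median(resid, na.rm = TRUE)
  if (!is.finite(med) || med < 1) return(drift0)  # no movers to set a scale
  # the absolute cap keeps a swimmer whose heading happens to sit near the
  # (noisy) initial estimate from being mistaken for an advected cell
  anchors <- which(!is.na(resid) & resid < pmin(0.5 * med, 2.5))
  if (!length(anchors)) return(drift0)
  dx <- vector("list", nrow(drift0))
  dy <- vector("list", nrow(drift0))
  for (k in anchors) {
    d <- trajs[[k]]$detections
    consec <- which(diff(d$frame) == 1L)
    for (i in consec) {
      p <- d$frame[i]
      ddx <- d$x[i + 1L] - d$x[i]
      ddy <- d$y[i + 1L] - d$y[i]
      # an anchor track spliced onto a swimmer contributes swim-sized
      # residuals on those pairs; gate each pair against the initial
      # estimate so only advection-consistent displacements count
      if (sqrt((ddx - drift0[p, 1])^2 + (ddy - drift0[p, 2])^2) >=
          0.5 * med) next
      dx[[p]] <- c(dx[[p]], ddx)
      dy[[p]] <- c(dy[[p]], ddy)
    }
  }
  out <- drift0
  for (p in seq_len(nrow(drift0))) {
    if (length(dx[[p]])) {
      out[p, 1] <- mean(dx[[p]])
      out[p, 2] <- mean(dy[[p]])
    }
  }
  out
}
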