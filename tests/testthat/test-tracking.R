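test_that("Otsu matches exhaustive search and honours the tie rule", {
  h <- rep(0, 256)
  h[51] <- 100   # level 50
  h[201] <- 100  # level 200
  expect_identical(otsu_threshold(h), 51)

  set.seed(403)
  for (i in 1:200) {
    counts <- rpois(256, lambda = sample(c(0.1, 2, 20), 1))
    if (sum(counts > 0) < 2) next
    expect_identical(otsu_threshold(counts), brute_otsu(counts))
  }

  single <- rep(0, 256)
  single[42] <- 10
  expect_error(otsu_threshold(single), "degenerate")
})

test_that("segmentation finds centroids, areas and filters small blobs", {
  fr <- matrix(0L, 40, 40)
  fr[20:24, 10:14] <- 200L   # rows = y 20..24, cols = x 10..14
  d <- segment_frame(fr, threshold = 100)
  expect_equal(nrow(d), 1)
  expect_equal(d$x, 12)
  expect_equal(d$y, 22)
  expect_equal(d$area, 25)
  expect_equal(d$mean_intensity, 200)

  fr[5:7, 30:32] <- 180L
  expect_equal(nrow(segment_frame(fr, 100)), 2)

  # area exactly min_area - 1 is discarded
  fr2 <- matrix(0L, 20, 20)
  fr2[3, 3:5] <- 150L
  expect_equal(nrow(segment_frame(fr2, 100, min_area = 4)), 0)
  expect_equal(nrow(segment_frame(fr2, 100, min_area = 3)), 1)

  # 8-connectivity: diagonal pixels belong to one component
  fr3 <- matrix(0L, 10, 10)
  fr3[cbind(c(2, 3, 4), c(2, 3, 4))] <- 150L
  expect_equal(nrow(segment_frame(fr3, 100, min_area = 1)), 1)
})

test_that("linking gates, separates by size, and matches the exhaustive matcher", {
  a <- make_dets(10, 10, 30, 120)
  b <- make_dets(13, 10, 30, 120)
  expect_equal(nrow(link_detections(a, b, gate_radius = 10)), 1)

  # two cells swap ends, but the size term keeps each in its class
  a2 <- make_dets(c(0, 10), c(0, 0), c(20, 60), c(120, 120))
  b2 <- make_dets(c(9, 1), c(0, 0), c(21, 58), c(120, 120))
  asg <- link_detections(a2, b2, gate_radius = 12)
  expect_equal(asg$index_b[asg$index_a == 1], 2)  # small links to small
  expect_equal(asg$index_b[asg$index_a == 2], 1)
  pc <- electrogenetics:::.pair_costs(a2, b2, c(1, 0.5, 0.25), 12)
  bf <- brute_assignment(pc, 2, 2)
  expect_true(same_assignment(asg, pc, bf))

  # displacement beyond the gate is forbidden
  b3 <- make_dets(21, 10, 30, 120)
  expect_equal(nrow(link_detections(a, b3, gate_radius = 10)), 0)

  set.seed(404)
  for (i in 1:100) {
    inst <- tracking_instance()
    g <- link_detections(inst$a, inst$b, gate_radius = inst$gate)
    pc <- electrogenetics:::.pair_costs(inst$a, inst$b, c(1, 0.5, 0.25),
                                        inst$gate)
    bf <- brute_assignment(pc, nrow(inst$a), nrow(inst$b))
    expect_true(same_assignment(g, pc, bf))
  }
  expect_error(link_detections(a, b, gate_radius = 0), "gate_radius")
  expect_error(link_detections(a, b, weights = c(0, 0, 0), gate_radius = 5),
               "weights")
})

test_that("trajectory building follows cells and splits at long gaps", {
  # single cell drifting right, visible in all frames
  frames <- lapply(1:20, function(t) blob_frame(40, 60, 10 + t, 20))
  v <- video_stack(frames, fps = 10, pixel_size = 0.32)
  trajs <- build_trajectories(v, gate_radius = 5, min_length = 10)
  expect_length(trajs, 1)
  expect_equal(nrow(trajs[[1]]$detections), 20)
  expect_equal(diff(trajs[[1]]$detections$x), rep(1, 19), tolerance = 0.2)

  # cell vanishing for 3 frames (> max_gap = 1) yields two tracks
  frames2 <- lapply(1:30, function(t) {
    if (t %in% 14:16) blob_frame(40, 60, numeric(0), numeric(0))
    else blob_frame(40, 60, 10 + t * 0.5, 20)
  })
  v2 <- video_stack(frames2, fps = 10, pixel_size = 0.32)
  trajs2 <- build_trajectories(v2, gate_radius = 5, max_gap = 1,
                               min_length = 10)
  expect_length(trajs2, 2)

  # the same video with a tolerant gap setting yields one track
  trajs3 <- build_trajectories(v2, gate_radius = 5, max_gap = 3,
                               min_length = 10)
  expect_length(trajs3, 1)
})

test_that("ten separated cells are recovered exactly from a clean video", {
  set.seed(405)
  xs <- seq(10, 100, by = 10)
  ys <- runif(10, 15, 35)
  # common heading: constant spacing, no crossings
  frames <- lapply(1:25, function(t)
    blob_frame(60, 110, xs + 0.3 * t, ys + 0.6 * t))
  v <- video_stack(frames, fps = 10, pixel_size = 0.32)
  trajs <- build_trajectories(v, gate_radius = 4, min_length = 10)
  expect_length(trajs, 10)
  expect_true(all(vapply(trajs, function(tr) nrow(tr$detections), numeric(1))
                  == 25))
})

test_that("drift is the per-pair median displacement", {
  mk_traj <- function(id, x0, y0, steps) {
    n <- nrow(steps) + 1
    structure(list(id = id, detections = data.frame(
      frame = 1:n, x = x0 + c(0, cumsum(steps[, 1])),
      y = y0 + c(0, cumsum(steps[, 2])), area = 30,
      mean_intensity = 120)), class = "trajectory")
  }
  # all cells translate by (2, 0) per frame
  trajs <- lapply(1:5, function(i)
    mk_traj(i, 10 * i, 10, cbind(rep(2, 9), rep(0, 9))))
  drift <- estimate_drift(trajs, n_frames = 10)
  expect_equal(unname(drift[, 1]), rep(2, 9))
  expect_equal(unname(drift[, 2]), rep(0, 9))

  # half stationary, half moving randomly: componentwise median oracle
  set.seed(406)
  mv <- lapply(1:4, function(i)
    mk_traj(i + 10, 50 + 5 * i, 30, cbind(rnorm(9), rnorm(9))))
  all_t <- c(trajs[1:4], mv)
  drift2 <- estimate_drift(all_t, n_frames = 10)
  for (p in 1:9) {
    dxs <- vapply(all_t, function(tr) tr$detections$x[p + 1] -
                    tr$detections$x[p], numeric(1))
    expect_equal(unname(drift2[p, 1]), median(dxs))
  }

  # no links at all: zero drift plus a warning
  lone <- list(mk_traj(1, 5, 5, cbind(1, 1)))
  expect_warning(d3 <- estimate_drift(lone, n_frames = 5), "no links")
  expect_equal(unname(d3[3, ]), c(0, 0))
})

test_that("stuck flags separate advected, swimming and composite cells", {
  fps <- 10
  px <- 0.32
  drift <- cbind(rep(1.5, 29), rep(0, 29))  # px/frame
  mk <- function(xs, ys) structure(list(id = 1, detections = data.frame(
    frame = seq_along(xs), x = xs, y = ys, area = 30, mean_intensity = 120)),
    class = "trajectory")

  # stationary cell carried by the flow: stuck after drift correction
  adv <- mk(10 + 1.5 * (0:29), rep(10, 30))
  fs <- filter_stuck(adv, fps, px, drift)
  expect_true(fs$stuck)

  # straight swimmer at 10 um/s on top of the same flow
  step <- 10 / fps / px
  swim <- mk(10 + (1.5 + step) * (0:29), rep(10, 30))
  fs2 <- filter_stuck(swim, fps, px, drift)
  expect_false(fs2$stuck)
  v <- compute_velocity(swim, fps, px, drift, moving_pairs = fs2$moving_pairs)
  expect_equal(v, 10, tolerance = 1e-9)

  # stuck first half, swimming second half: partial, only the swim counts
  xs <- c(10 + 1.5 * (0:14), 10 + 1.5 * 14 + (1.5 + step) * (1:15))
  comp <- mk(xs, rep(10, 30))
  fs3 <- filter_stuck(comp, fps, px, drift)
  expect_false(fs3$stuck)
  expect_true(fs3$partial)
  expect_false(any(fs3$moving_pairs[1:10]))
  v3 <- compute_velocity(comp, fps, px, drift,
                         moving_pairs = fs3$moving_pairs)
  expect_equal(v3, 10, tolerance = 0.05)
})

test_that("velocity arithmetic handles units, gaps and exclusions", {
  mk <- function(frames, xs) structure(list(id = 1, detections = data.frame(
    frame = frames, x = xs, y = 0, area = 30, mean_intensity = 120)),
    class = "trajectory")
  tr <- mk(1:10, 2 * (1:10))
  expect_equal(compute_velocity(tr, fps = 10, pixel_size = 0.32), 6.4)

  still <- mk(1:10, rep(5, 10))
  expect_equal(compute_velocity(still, 10, 0.32), 0)

  # a gap uses elapsed frames in the denominator
  gap <- mk(c(1, 2, 4), c(0, 2, 6))
  expect_equal(compute_velocity(gap, 10, 0.32), 6.4)

  expect_error(compute_velocity(tr, 10, 0.32, stuck = TRUE), "excluded")
})

test_that("trajectory roses start at the origin with the right length", {
  mk <- function(xs, ys) structure(list(id = 7, detections = data.frame(
    frame = seq_along(xs), x = xs, y = ys, area = 30, mean_intensity = 120)),
    class = "trajectory")
  tr <- mk(100 + 2 * (0:49), 50 + 0 * (0:49))
  rose <- trajectory_rose(list(tr), fps = 10, pixel_size = 0.32,
                          duration = 3)
  expect_equal(nrow(rose), 30)     # ceiling(3 s x 10 fps)
  expect_equal(rose$x_um[1], 0)
  expect_equal(rose$y_um[1], 0)
  # straight swimmer: path length = speed x duration (29 steps here)
  path <- sum(sqrt(diff(rose$x_um)^2 + diff(rose$y_um)^2))
  expect_equal(path, 2 * 0.32 * 29, tolerance = 1e-9)
  expect_error(trajectory_rose(list(tr), 10, 0.32, duration = 0), "duration")
})

test_that("velocity statistics agree with the reference t machinery", {
  a <- c(10, 11, 12, 13)
  vs <- velocity_statistics(list(x = a, y = a))
  expect_equal(vs$comparisons$t, 0)
  expect_equal(vs$comparisons$p, 1)

  # unequal group sizes as in the published comparison (n = 79 vs 117)
  set.seed(407)
  g1 <- rnorm(79, 20, 4)
  g2 <- rnorm(117, 16, 4)
  vs2 <- velocity_statistics(list(induced = g1, control = g2))
  ref <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(vs2$comparisons$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(vs2$comparisons$p, ref$p.value, tolerance = 1e-12)
  expect_equal(vs2$summary$sem[1], sd(g1) / sqrt(79))

  expect_error(velocity_statistics(list(a = 1, b = c(1, 2))), "2 samples")
})

test_that("uniform translation leaves drift-corrected speeds unchanged", {
  set.seed(408)
  g <- gen_motility_video(n_cells = 12, tumble_rate = 0.5,
                          stuck_fraction = 0.2, drift = c(0, 0),
                          n_frames = 40, seed = 408)
  res <- track_video(g$video, min_length = 8)
  speed_of <- function(trajs, drift) {
    vapply(seq_along(trajs), function(k) {
      fs <- filter_stuck(trajs[[k]], g$video$fps, g$video$pixel_size, drift)
      if (fs$stuck) return(NA_real_)
      compute_velocity(trajs[[k]], g$video$fps, g$video$pixel_size, drift,
                       moving_pairs = fs$moving_pairs)
    }, numeric(1))
  }
  base <- speed_of(res$trajectories, res$drift)

  shift <- c(1.0, -0.6)  # px/frame, applied to every detection
  trajs2 <- lapply(res$trajectories, function(tr) {
    tr$detections$x <- tr$detections$x + shift[1] * (tr$detections$frame - 1)
    tr$detections$y <- tr$detections$y + shift[2] * (tr$detections$frame - 1)
    tr
  })
  attributes(trajs2) <- attributes(res$trajectories)
  drift2 <- suppressWarnings(estimate_drift(trajs2))
  drift2[, 1] <- median(drift2[, 1])
  drift2[, 2] <- median(drift2[, 2])
  drift2 <- electrogenetics:::.anchor_drift(trajs2, drift2)
  shifted <- speed_of(trajs2, drift2)
  ok <- !is.na(base) & !is.na(shifted)
  expect_true(any(ok))
  expect_lt(max(abs(shifted[ok] - base[ok]) / base[ok]), 0.02)
})
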