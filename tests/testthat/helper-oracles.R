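# Independent oracles used across the suite.

# Exhaustive Otsu: try every split, compute class stats directly.
brute_otsu <- function(counts, levels = seq_along(counts) - 1) {
  best_t <- NA
  best_v <- -Inf
  n <- sum(counts)
  for (i in seq_len(length(counts) - 1L)) {
    c0 <- counts[1:i]
    c1 <- counts[(i + 1):length(counts)]
    w0 <- sum(c0) / n
    w1 <- sum(c1) / n
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(c0 * levels[1:i]) / sum(c0)
    mu1 <- sum(c1 * levels[(i + 1):length(counts)]) / sum(c1)
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- levels[i + 1L]
    }
  }
  best_t
}

# Exhaustive matching oracle: maximum cardinality, then minimum total cost,
# over all matchings of the gated candidate pairs.
brute_assignment <- function(pairs, na, nb) {
  best <- NULL
  n <- nrow(pairs)
  rec <- function(i, used_a, used_b, sel, cost) {
    if (i > n) {
      if (is.null(best) || length(sel) > length(best$sel) ||
          (length(sel) == length(best$sel) && cost < best$cost - 1e-12))
        best <<- list(sel = sel, cost = cost)
      return(invisible())
    }
    rec(i + 1L, used_a, used_b, sel, cost)
    a <- pairs$index_a[i]
    b <- pairs$index_b[i]
    if (!used_a[a] && !used_b[b]) {
      ua <- used_a
      ua[a] <- TRUE
      ub <- used_b
      ub[b] <- TRUE
      rec(i + 1L, ua, ub, c(sel, i), cost + pairs$cost[i])
    }
  }
  rec(1L, rep(FALSE, max(1, na)), rep(FALSE, max(1, nb)), integer(0), 0)
  best
}

make_dets <- function(x, y, area, intensity) {
  data.frame(x = x, y = y, area = area, mean_intensity = intensity)
}

# Random gate-respecting linking instance: separated cells, sub-gate steps.
tracking_instance <- function(gate = 10) {
  n <- sample(2:6, 1)
  repeat {
    x <- runif(n, 0, 100)
    y <- runif(n, 0, 100)
    if (n == 1 || min(dist(cbind(x, y))) > 1.2 * gate) break
  }
  ar <- runif(n, 20, 40)
  it <- runif(n, 100, 160)
  th <- runif(n, 0, 2 * pi)
  st <- runif(n, 0, 0.6 * gate)
  list(a = make_dets(x, y, ar, it),
       b = make_dets(x + st * cos(th), y + st * sin(th),
                     ar * runif(n, 0.9, 1.1), it * runif(n, 0.95, 1.05)),
       gate = gate)
}

# Same-assignment comparison, treating equal-cost solutions as equivalent.
same_assignment <- function(greedy, pairs, bf) {
  gset <- paste(sort(paste(greedy$index_a, greedy$index_b)), collapse = ";")
  bset <- paste(sort(paste(pairs$index_a[bf$sel], pairs$index_b[bf$sel])),
                collapse = ";")
  gset == bset ||
    (nrow(greedy) == length(bf$sel) &&
       abs(sum(greedy$cost) - bf$cost) < 1e-9)
}

# A tiny noiseless video with hand-placed blobs, for structural tests.
blob_frame <- function(H, W, xs, ys, amp = 150, bg = 20, sigma = 1.5) {
  img <- matrix(bg, H, W)
  for (i in seq_along(xs)) {
    gx <- exp(-((1:W) - xs[i])^2 / (2 * sigma^2))
    gy <- exp(-((1:H) - ys[i])^2 / (2 * sigma^2))
    img <- img + amp * outer(gy, gx)
  }
  matrix(as.integer(pmin(pmax(round(img), 0), 255)), H, W)
}
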