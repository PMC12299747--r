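# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the rectangle oracle is a dense angle sweep, the
# crossing oracle is a tiny-step explicit integrator of the friction ODE.

# Brute-force minimum-area rotated rectangle: sweep candidate orientations in
# 0.1 degree steps over the foreground pixel centers and keep the smallest
# (extent + 1)^2-style area. Independent of the convex-hull calipers.
sweep_min_rect <- function(mask, step_deg = 0.1) {
  idx <- which(unclass(mask) > 0, arr.ind = TRUE)
  x <- idx[, 2]; y <- idx[, 1]
  best <- Inf
  best_at <- NA
  for (ang in seq(0, 90 - step_deg, by = step_deg)) {
    t <- ang * pi / 180
    u <- x * cos(t) + y * sin(t)
    v <- -x * sin(t) + y * cos(t)
    area <- (diff(range(u)) + 1) * (diff(range(v)) + 1)
    if (area < best) {
      best <- area
      best_at <- ang
    }
  }
  list(area = best, angle = best_at)
}

# Random convex blob: pixels inside the convex hull of a handful of random
# points. Returns a binary matrix.
random_convex_blob <- function(size = 64, n_pts = 8) {
  px <- runif(n_pts, size * 0.15, size * 0.85)
  py <- runif(n_pts, size * 0.15, size * 0.85)
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h]
  X <- matrix(rep(seq_len(size), each = size), size, size)
  Y <- matrix(rep(seq_len(size), times = size), size, size)
  inside <- rep(TRUE, size * size)
  n <- length(hx)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    # chull returns clockwise order; interior is on one consistent side
    cross <- (hx[j] - hx[i]) * (Y - hy[i]) - (hy[j] - hy[i]) * (X - hx[i])
    inside <- inside & (as.vector(cross) <= 0)
  }
  matrix(as.integer(inside), size, size)
}

# Step-wise integrator of the post-blow crossing: decelerate at a = mu*g
# until the half belt width d is covered (or the item stops). Returns the
# exit speed, crossing time and downstream displacement.
integrate_crossing <- function(Vy1, mu, g, W, Vx, dt = 1e-5) {
  a <- mu * g
  d <- W / 2
  v <- Vy1
  s <- 0
  t <- 0
  while (s < d && v > 0) {
    v_new <- v - a * dt
    s <- s + (v + max(v_new, 0)) / 2 * dt
    v <- v_new
    t <- t + dt
    if (t > 60) break
  }
  list(Vy2 = max(v, 0), dt1 = t, X = t * Vx, stalled = s < d)
}

# A canonical intact mask used by several tests
demo_mask <- function(rotation_deg = 0, D1 = 60, H = 30, L = 40, D2 = 20) {
  render_mushroom(fixture_spec(
    D1 = D1, H = H, L = L, D2 = D2,
    rotation_deg = rotation_deg, canvas = c(192, 192)
  ))$mask
}
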