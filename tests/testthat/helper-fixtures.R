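# Fixtures built in code: digital discs and capsules, plus small random
# binary masks for metric property tests.

render_disc <- function(n, cy, cx, r) {
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  m <- matrix(0L, n, n)
  inside <- (ij$i - cy)^2 + (ij$j - cx)^2 <= r^2
  m[as.matrix(ij[inside, c("i", "j")])] <- 1L
  m
}

# Capsule: all pixels within half-width `w` of the segment of half-length
# `a` through (cy, cx) along `angle` (radians, (row, col) direction).
render_capsule <- function(n, cy, cx, w, a, angle = 0) {
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  u <- c(sin(angle), cos(angle))
  t <- (ij$i - cy) * u[1] + (ij$j - cx) * u[2]
  tc <- pmin(pmax(t, -a), a)
  d2 <- (ij$i - cy - tc * u[1])^2 + (ij$j - cx - tc * u[2])^2
  m <- matrix(0L, n, n)
  m[as.matrix(ij[d2 <= w^2, c("i", "j")])] <- 1L
  m
}

random_mask <- function(n, p = 0.5) {
  matrix(as.integer(stats::runif(n * n) < p), n, n)
}

# Brute-force pixel metrics by set arithmetic, the independent oracle for
# pixel_metrics(). Classes: background (0) and granule (1).
brute_pixel_metrics <- function(pred, truth) {
  p <- as.vector(pred) > 0
  t <- as.vector(truth) > 0
  accs <- ius <- c()
  correct <- 0
  for (cls in c(FALSE, TRUE)) {
    t_set <- which(t == cls)
    p_set <- which(p == cls)
    correct <- correct + length(intersect(t_set, p_set))
    if (length(t_set) == 0) next
    accs <- c(accs, length(intersect(t_set, p_set)) / length(t_set))
    ius <- c(ius, length(intersect(t_set, p_set)) /
               length(union(t_set, p_set)))
  }
  c(pixel_accuracy = correct / length(p),
    mean_accuracy = mean(accs),
    mean_iu = mean(ius))
}

# A fast tiny network spec for unit tests.
tiny_spec <- function() {
  network_spec(inception_kernels = c(3, 5), branch_factors = c(4, 8),
               base_channels = 4, channel_growth = 2)
}

quick_cfg <- function(...) {
  run_config(network = tiny_spec(), epochs = 2, ...)
}
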