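disc_map <- function(n, cy, cx, r) {
  structure(render_disc(n, cy, cx, r), class = "instance_map")
}

test_that("disc measurements match analytic values", {
  # Disc of radius 10 px at 10 nm/px: area ~ pi r^2, equivalent radius
  # 100 nm within discretization error, isoperimetric ratio ~ 1.
  imap <- disc_map(64, 32.3, 30.7, 10)
  img <- gray_image(matrix(37L, 64, 64), 10)
  rec <- measure_granules(imap, img)
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$equiv_radius_nm - 100), 2)
  expect_gt(rec$round_coefficient, 0.95)
  expect_lt(rec$round_coefficient, 1.05)
  expect_equal(rec$mean_gray, 37)
  expect_equal(rec$area_nm2, rec$area_px * 100)
  expect_equal(rec$equiv_radius_nm, sqrt(rec$area_nm2 / pi))
})

test_that("measure_granule extracts a single id and rejects missing ones", {
  m <- render_disc(64, 16, 16, 6) + 2L * render_disc(64, 48, 48, 8)
  imap <- structure(m, class = "instance_map")
  img <- gray_image(matrix(100L, 64, 64), 10)
  one <- measure_granule(imap, 2, img)
  expect_equal(one$id, 2L)
  expect_equal(one$centroid_row, 48, tolerance = 0.1)
  expect_error(measure_granule(imap, 9, img), "not found")
})

test_that("capsules have a lower round coefficient than equal-area discs", {
  img <- gray_image(matrix(0L, 96, 96), 10)
  for (r in c(5, 6, 8, 10, 12)) {
    # Capsule of aspect ~2 with approximately the disc's area.
    w <- r / sqrt(2)
    a <- (pi * r^2 - pi * w^2) / (4 * w)
    cap <- measure_granules(
      structure(render_capsule(96, 48, 48, w, a, pi / 7), class = "instance_map"),
      img)
    disc <- measure_granules(disc_map(96, 48, 48, r), img)
    expect_lt(cap$round_coefficient, disc$round_coefficient)
    # Analytic capsule isoperimetric ratio as oracle (within discretization).
    rc_true <- 4 * pi * (pi * w^2 + 4 * a * w) / (2 * pi * w + 4 * a)^2
    if (r >= 8) expect_equal(cap$round_coefficient, rc_true, tolerance = 0.08)
  }
})

test_that("dense-core radii attach to their parent granules", {
  gm <- render_disc(64, 32, 32, 12)
  cm <- render_disc(64, 32, 32, 6)
  rec <- measure_granules(structure(gm, class = "instance_map"),
                          gray_image(matrix(0L, 64, 64), 10),
                          cores = structure(cm, class = "instance_map"))
  expect_equal(rec$core_radius_nm, sqrt(sum(cm) * 100 / pi))
  expect_lt(abs(rec$core_radius_nm - 60), 2)
})

test_that("membrane distance matches the analytic fixture", {
  # Disc radius 10 px centred 30 px from a straight membrane, 10 nm/px:
  # edge-to-membrane distance 200 nm within half a pixel.
  imap <- disc_map(64, 32.3, 40.7, 10)
  img <- gray_image(matrix(0L, 64, 64), 10)
  membrane <- cbind(seq(1, 64, by = 0.5), 40.7 - 30)
  rec <- measure_granules(imap, img, membrane = membrane)
  expect_lt(abs(rec$membrane_distance_nm - 200), 5)
  # A granule touching the membrane has distance 0.
  b <- rec$boundary[[1]]
  through <- rbind(b[1, ], b[1, ] + c(0, 1))
  expect_equal(membrane_distance(rec, through, 10), 0)
})

test_that("membrane distance is invariant under rigid rotation", {
  imap <- disc_map(64, 32.3, 40.7, 10)
  img <- gray_image(matrix(0L, 64, 64), 10)
  membrane <- cbind(seq(1, 64, by = 0.5), 10.7)
  rec <- measure_granules(imap, img)
  d0 <- membrane_distance(rec, membrane, 10)
  th <- 0.53
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- function(P) t(R %*% t(P))
  d1 <- membrane_distance(rot(rec$boundary[[1]]), rot(membrane), 10)
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("granule density averages per cell with s.e.m. across cells", {
  # Two cells: 20 granules / 10 um^2 and 30 / 10 -> densities 2 and 3;
  # s.e.m. = sd({2, 3}) / sqrt(2) = 0.5.
  d <- granule_density(c(20, 30), c(10, 10))
  expect_equal(d$mean_density_per_um2, 2.5)
  expect_equal(d$sem, sd(c(2, 3)) / sqrt(2))
  expect_true(d$sem_defined)
  # One cell: flagged, s.e.m. reported as 0.
  d1 <- granule_density(10, 10)
  expect_equal(d1$mean_density_per_um2, 1)
  expect_equal(d1$sem, 0)
  expect_false(d1$sem_defined)
  expect_error(granule_density(c(1, 2), 10), "length")
  expect_error(granule_density(5, 0), "positive")
})

test_that("distance profiles bin and normalise correctly", {
  p <- distance_profile(c(10, 50, 90), 40, 120)
  expect_equal(p$count, c(1, 1, 1))
  expect_equal(sum(p$rel_freq), 1)
  expect_equal(p$bin_lo_nm, c(0, 40, 80))

  p0 <- distance_profile(c(0, 0, 0), 20, 100)
  expect_equal(p0$count[1], 3)
  expect_equal(sum(p0$count[-1]), 0)
  expect_equal(p0$rel_freq[1], 1)

  # Distances beyond max are excluded from counts and normalisation.
  p2 <- distance_profile(c(10, 500), 40, 120)
  expect_equal(sum(p2$count), 1)
  expect_equal(sum(p2$rel_freq), 1)
  # Conservation: total count equals granules within range.
  set.seed(1)
  d <- stats::runif(400, 0, 300)
  p3 <- distance_profile(d, 25, 200)
  expect_equal(sum(p3$count), sum(d <= 200))
})

test_that("group comparisons expose t and KS tests", {
  same <- c(1, 2, 3, 4)
  ks <- compare_groups(same, same, "distribution")
  expect_equal(ks$statistic, 0)
  expect_equal(ks$p_value, 1)
  ks2 <- compare_groups(c(0, 0, 0, 0), c(1, 1, 1, 1), "distribution")
  expect_equal(ks2$statistic, 1)
  # ECDF supremum by enumeration: a = {1,2,3}, b = {2,3,4} -> 1/3.
  ks3 <- compare_groups(c(1, 2, 3), c(2, 3, 4), "distribution")
  expect_equal(ks3$statistic, 1 / 3)
  tt <- compare_groups(rnorm(20), rnorm(20, 5), "mean")
  expect_lt(tt$p_value, 0.001)
  expect_error(compare_groups(1, c(1, 2), "mean"), "at least 2")
})

test_that("measured radii recover the generator's radius distribution", {
  scenes <- simulate_scenes(30, scene_spec(noise_sigma = 0), seed = 700)
  measured <- true_r <- c()
  for (sc in scenes) {
    if (nrow(sc$granule_params) == 0) next
    rec <- measure_granules(sc$granule_instances, sc$image)
    measured <- c(measured, rec$equiv_radius_nm)
    true_r <- c(true_r, sc$granule_params$radius_nm)
  }
  # Per-granule agreement (instance k of the truth map is granule k).
  expect_lt(stats::median(abs(measured - true_r) / true_r), 0.05)
  ks <- compare_groups(measured, true_r, "distribution")
  expect_gt(ks$p_value, 0.01)
})
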