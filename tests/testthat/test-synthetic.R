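test_that("scenes are bit-reproducible given the seed", {
  a <- generate_scene(scene_spec(seed = 3))
  b <- generate_scene(scene_spec(seed = 3))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(unclass(a$granule_instances), unclass(b$granule_instances))
  expect_identical(a$granule_params, b$granule_params)
  c <- generate_scene(scene_spec(seed = 4))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("zero density gives an empty scene with background structure only", {
  sc <- generate_scene(scene_spec(target_density_per_um2 = 0, seed = 5))
  expect_equal(nrow(sc$granule_params), 0)
  expect_true(all(unclass(sc$granule_instances) == 0L))
  expect_true(all(unclass(sc$core_instances) == 0L))
  expect_true(any(sc$cytoplasm_mask))
  pair <- scene_to_training_pair(sc)
  expect_true(all(pair$labels == 0L))
})

test_that("scene ground truth satisfies its structural invariants", {
  for (seed in c(11, 12, 13)) {
    sc <- generate_scene(scene_spec(seed = seed))
    gi <- unclass(sc$granule_instances)
    ci <- unclass(sc$core_instances)
    K <- nrow(sc$granule_params)
    # Labels consecutive 1..K.
    expect_identical(sort(unique(as.vector(gi[gi > 0]))),
                     if (K > 0) 1:K else integer(0))
    # Cores are a pixelwise subset of their granules.
    expect_true(all(gi[ci > 0] == ci[ci > 0]))
    # Every granule lies inside the cytoplasm (nucleus excluded).
    expect_true(all(sc$cytoplasm_mask[gi > 0]))
    # Radii respect the configured range.
    rr <- sc$spec$granule_radius_range_nm
    expect_true(all(sc$granule_params$radius_nm >= rr[1] &
                    sc$granule_params$radius_nm <= rr[2]))
  }
})

test_that("rendered intensities are ordered core < cytoplasm < halo", {
  sc <- generate_scene(scene_spec(seed = 21, noise_sigma = 0,
                                  illumination_gradient_amplitude = 0))
  gi <- unclass(sc$granule_instances)
  ci <- unclass(sc$core_instances)
  px <- sc$image$pixels
  halo <- gi > 0 & ci == 0
  cyt <- sc$cytoplasm_mask & gi == 0
  expect_lt(mean(px[ci > 0]), mean(px[cyt]))
  expect_lt(mean(px[cyt]), mean(px[halo]))
})

test_that("training pairs are the foreground indicator of the instances", {
  sc <- generate_scene(scene_spec(seed = 31))
  pair <- scene_to_training_pair(sc)
  gi <- unclass(sc$granule_instances)
  expect_identical(pair$labels == 1L, gi > 0L)
  expect_equal(sum(pair$labels), sum(tabulate(gi[gi > 0])))
  expect_identical(pair, scene_to_training_pair(sc))
})

test_that("realized granule counts are Poisson-consistent and density is recovered", {
  n <- 200
  target <- 2.3
  scenes <- simulate_scenes(n, scene_spec(target_density_per_um2 = target),
                            seed = 900)
  k <- vapply(scenes, function(s) nrow(s$granule_params), numeric(1))
  area <- vapply(scenes, function(s) {
    sum(s$cytoplasm_mask) * (s$spec$pixel_size_nm / 1000)^2
  }, numeric(1))
  dens <- granule_density(k, area)
  expect_lt(abs(dens$mean_density_per_um2 - target), 3 * dens$sem)
  # Dispersion (chi-square goodness-of-fit against per-scene Poisson means).
  lambda <- target * area
  x2 <- sum((k - lambda)^2 / lambda)
  p <- stats::pchisq(x2, df = n, lower.tail = FALSE)
  expect_gt(min(p, 1 - p), 0.005)
  # Rod-core fraction converges to its binomial target.
  rods <- sum(vapply(scenes, function(s) sum(s$granule_params$is_rod), numeric(1)))
  tot <- sum(k)
  expect_lt(abs(rods / tot - 0.2), 3 * sqrt(0.2 * 0.8 / tot))
})

test_that("infeasible densities are rejected rather than silently under-placed", {
  expect_error(
    scene_spec(target_density_per_um2 = 4, granule_radius_range_nm = c(350, 400)),
    "infeasible")
  # Feasible by expected area but geometrically impossible: granules of
  # radius ~400 nm cannot be packed at this density in a 64 px cell with
  # at most 20 % pairwise overlap, so rejection sampling gives up loudly.
  sp <- scene_spec(image_size_px = c(64, 64), target_density_per_um2 = 1.2,
                   granule_radius_range_nm = c(390, 400),
                   nucleus_present = FALSE, seed = 1)
  expect_error(generate_scene(sp), "infeasible|placed")
})

test_that("the nucleus distractor is dark, inside the cell, outside the cytoplasm", {
  sc <- generate_scene(scene_spec(seed = 41, noise_sigma = 0,
                                  illumination_gradient_amplitude = 0))
  expect_true(any(sc$nucleus_mask))
  expect_false(any(sc$nucleus_mask & sc$cytoplasm_mask))
  px <- sc$image$pixels
  expect_lt(mean(px[sc$nucleus_mask]),
            mean(px[sc$cytoplasm_mask]))
  off <- generate_scene(scene_spec(seed = 41, nucleus_present = FALSE))
  expect_false(any(off$nucleus_mask))
})
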