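test_that("identical masks score 1 on every pixel metric", {
  set.seed(1)
  m <- random_mask(16, 0.3)
  pm <- pixel_metrics(m, m)
  expect_equal(pm$pixel_accuracy, 1)
  expect_equal(pm$mean_accuracy, 1)
  expect_equal(pm$mean_iu, 1)
})

test_that("an all-background prediction hides behind pixel accuracy", {
  # 4 % foreground truth, empty prediction: pixel accuracy 0.96 but mean
  # accuracy 0.50 and mean IU 0.48 expose the failure.
  truth <- matrix(0L, 10, 10)
  truth[1:2, 1:2] <- 1L
  pred <- matrix(0L, 10, 10)
  pm <- pixel_metrics(pred, truth)
  expect_equal(pm$pixel_accuracy, 0.96)
  expect_equal(pm$mean_accuracy, 0.50)
  expect_equal(pm$mean_iu, 0.48)
})

test_that("the 3x3 toy case matches exhaustive set arithmetic", {
  truth <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0), 3, 3)
  pred <- matrix(c(1, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)
  pm <- pixel_metrics(pred, truth)
  # IoU_fg = |{2 hits}| / |{3 truth + 1 extra}| = 2/4; IoU_bg = 5/7.
  expect_equal(pm$mean_iu, (2 / 4 + 5 / 7) / 2)
  expect_equal(pm, tibble::as_tibble(as.list(brute_pixel_metrics(pred, truth))),
               tolerance = 1e-12)
})

test_that("metrics equal brute-force set arithmetic on random masks", {
  set.seed(99)
  for (i in 1:200) {
    pred <- random_mask(8, stats::runif(1, 0.1, 0.9))
    truth <- random_mask(8, stats::runif(1, 0.1, 0.9))
    pm <- pixel_metrics(pred, truth)
    bf <- brute_pixel_metrics(pred, truth)
    expect_equal(pm$pixel_accuracy, unname(bf["pixel_accuracy"]), tolerance = 1e-12)
    expect_equal(pm$mean_accuracy, unname(bf["mean_accuracy"]), tolerance = 1e-12)
    expect_equal(pm$mean_iu, unname(bf["mean_iu"]), tolerance = 1e-12)
    if (any(truth > 0) && any(truth == 0)) {
      expect_gte(pm$pixel_accuracy, pm$mean_iu)
    }
  }
})

test_that("single-class truths drop the absent class from the means", {
  truth <- matrix(1L, 8, 8)
  pred <- matrix(1L, 8, 8); pred[1, 1] <- 0L
  pm <- pixel_metrics(pred, truth)
  expect_equal(pm$mean_accuracy, 63 / 64)
  expect_equal(pm$mean_iu, 63 / 64)
  expect_error(pixel_metrics(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
})

test_that("instance matching is exact on identity and empty predictions", {
  sc <- generate_scene(scene_spec(seed = 77, noise_sigma = 0))
  K <- nrow(sc$granule_params)
  det <- glance(match_instances(sc$granule_instances, sc$granule_instances))
  expect_equal(det$tp, K)
  expect_equal(det$fp, 0)
  expect_equal(det$fn, 0)
  expect_equal(det$precision, 1)

  empty <- structure(matrix(0L, 128, 128), class = "instance_map")
  det0 <- glance(match_instances(empty, sc$granule_instances))
  expect_equal(det0$tp, 0)
  expect_equal(det0$fn, K)
  expect_equal(det0$precision, 0)
  expect_false(det0$precision_defined)
})

test_that("partial overlap plus a spurious blob scores tp 1, fp 1, fn 1", {
  truth <- matrix(0L, 40, 40)
  truth[5:14, 5:14] <- 1L          # 10x10 square
  truth[25:34, 25:34] <- 2L        # second granule, missed entirely
  pred <- matrix(0L, 40, 40)
  pred[5:14, 7:16] <- 1L           # shifted 2 cols: IoU = 80/120 = 2/3
  pred[20:23, 5:8] <- 2L           # spurious blob
  det <- match_instances(structure(pred, class = "instance_map"),
                         structure(truth, class = "instance_map"), 0.5)
  g <- glance(det)
  expect_equal(g$tp, 1)
  expect_equal(g$fp, 1)
  expect_equal(g$fn, 1)
  expect_equal(g$precision, 0.5)
  expect_equal(tidy(det)$iou, 2 / 3)
})

test_that("swapping prediction and truth swaps fp and fn, preserving tp", {
  for (seed in c(81, 82)) {
    sc <- generate_scene(scene_spec(seed = seed, noise_sigma = 0))
    ws <- watershed_instances(unclass(sc$granule_instances) > 0, 5, 1)
    a <- glance(match_instances(ws, sc$granule_instances))
    b <- glance(match_instances(sc$granule_instances, ws))
    expect_equal(a$tp, b$tp)
    expect_equal(a$fp, b$fn)
    expect_equal(a$fn, b$fp)
  }
})

test_that("raising the IoU threshold never increases true positives", {
  sc <- generate_scene(scene_spec(seed = 83, noise_sigma = 0))
  ws <- watershed_instances(unclass(sc$granule_instances) > 0, 5, 1)
  tps <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    glance(match_instances(ws, sc$granule_instances, th))$tp
  }, numeric(1))
  expect_true(all(diff(tps) <= 0))
})
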