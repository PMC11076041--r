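test_that("roundness follows the isoperimetric convention", {
  expect_equal(roundness(matrix(1, 1, 1)), 1)
  expect_gte(roundness(digital_disc(10)), 0.85)
  expect_lte(roundness(digital_disc(10)), 1)
  for (n in c(5, 8, 15)) {
    expect_lt(roundness(matrix(1, 1, n)), 0.7)
  }
  expect_lt(roundness(matrix(1, 3, 15)), 0.7)   # elongated bar
  expect_gt(roundness(digital_disc(4)), 0.7)    # compact disc passes
  expect_error(roundness(matrix(0, 3, 3)), "empty")
})

test_that("flat images yield an empty puncta table", {
  expect_equal(nrow(detect_puncta(matrix(0, 64, 64))), 0)
  expect_equal(nrow(detect_puncta(matrix(13.7, 64, 64))), 0)
  expect_error(detect_puncta(matrix(c(NA, 1:8), 3, 3)), "non-finite")
})

test_that("well-separated rendered boutons are each detected once, on target", {
  cfg <- random_scene(n_boutons = 10, image_shape = c(220, 220), sigma = 2,
                      amplitude = 150, min_separation = 15, seed = 21)
  sc <- render_scene(cfg)
  p <- detect_puncta(sc$image)
  expect_equal(nrow(p), 10)
  d <- sqrt(outer(p$x, sc$truth$x, "-")^2 + outer(p$y, sc$truth$y, "-")^2)
  expect_lte(max(apply(d, 2, min)), 1)
})

test_that("elongated bar is rejected while an equal-area disc is accepted", {
  img <- matrix(0, 64, 64)
  disc <- digital_disc(2)                       # area 13
  img <- stamp(img, disc, 10, 10, 100)
  img <- stamp(img, matrix(1, 1, 13), 40, 20, 100)  # 1 x 13 bar, area 13
  cfg <- detector_config(threshold_start = 90, threshold_floor = 10,
                         threshold_mode = "absolute", n_steps = 5,
                         smooth_sigma = 0, area_min = 4, area_max = 50)
  p <- detect_puncta(img, cfg)
  expect_equal(nrow(p), 1)
  # centroid at the disc, not the bar
  expect_lt(abs(p$x - (10 + 3)), 1.5)
  expect_lt(abs(p$y - (10 + 3)), 1.5)
  expect_gt(p$roundness, 0.7)
})

test_that("accepted puncta never share pixels and respect the filters", {
  for (s in c(4, 17)) {
    cfg <- random_scene(n_boutons = 15, image_shape = c(256, 256), sigma = 2,
                        amplitude = 150, offset = 20, noise_gaussian_sd = 30,
                        noise_poisson = TRUE, seed = s)
    sc <- render_scene(cfg)
    dc <- detector_config()
    p <- detect_puncta(sc$image, dc, keep_pixels = TRUE)
    expect_no_shared_pixels(p)
    expect_true(all(p$area >= dc$area_min & p$area <= dc$area_max))
    expect_true(all(p$roundness > dc$roundness_min))
  }
})

test_that("detection is invariant to a global multiplicative gain", {
  cfg <- random_scene(n_boutons = 12, image_shape = c(200, 200), sigma = 2,
                      amplitude = 150, offset = 20, noise_gaussian_sd = 25,
                      seed = 31)
  sc <- render_scene(cfg)
  p1 <- detect_puncta(sc$image)
  p2 <- detect_puncta(sc$image * 7.3)
  expect_equal(p1$x, p2$x, tolerance = 1e-9)
  expect_equal(p1$y, p2$y, tolerance = 1e-9)
  expect_equal(p1$area, p2$area)
  expect_equal(p2$peak_intensity, p1$peak_intensity * 7.3, tolerance = 1e-9)
})

test_that("peak intensity is the 2x2 block mean at the center of mass", {
  img <- matrix(5, 20, 20)
  expect_equal(peak_intensity(img, c(10.4, 7.9)), 5)
  img[8:9, 12:13] <- c(10, 30, 20, 40)   # column-major fill
  expect_equal(peak_intensity(img, c(12.2, 8.7)), 25)
  expect_error(peak_intensity(img, c(20, 10)), "border")
  expect_error(peak_intensity(img, c(0.4, 10)), "border")
})

test_that("rendered bouton peak matches the analytic 4-pixel integral mean", {
  cfg <- scene_config(image_shape = c(64, 64),
                      boutons = tibble::tibble(x = 30.5, y = 25.5, sigma = 2,
                                               amplitude = 100))
  sc <- render_scene(cfg)
  block <- expand.grid(i = 30:31, j = 25:26)   # pixels around the center
  vals <- mapply(function(i, j) {
    dx <- pnorm((i + 0.5 - 30.5) / 2) - pnorm((i - 0.5 - 30.5) / 2)
    dy <- pnorm((j + 0.5 - 25.5) / 2) - pnorm((j - 0.5 - 25.5) / 2)
    100 * 2 * pi * 4 * dx * dy
  }, block$i, block$j)
  expect_equal(peak_intensity(sc$image, c(30.5, 25.5)), mean(vals),
               tolerance = 0.02)
})

test_that("session normalization maps controls to 1 and cancels gain", {
  tbl <- tibble::tibble(
    session = c("s1", "s1", "s2", "s2"),
    condition = c("control", "treated", "control", "treated"),
    value = c(50, 25, 500, 250)
  )
  out <- normalize_sessions(tbl)
  expect_equal(out$value_norm[out$condition == "control"], c(1, 1))
  expect_equal(out$value_norm[out$condition == "treated"], c(0.5, 0.5))
  cs <- condition_summary(out)
  expect_equal(cs$mean_norm[cs$condition == "treated"], 0.5)

  tbl2 <- dplyr::bind_rows(tbl, tibble::tibble(session = "s3",
                                               condition = "treated",
                                               value = 10))
  expect_warning(out2 <- normalize_sessions(tbl2), "s3")
  expect_false("s3" %in% out2$session)
})
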