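test_that("GFP area quantification matches geometry oracles", {
  expect_equal(quantify_gfp_area(matrix(0, 50, 50), method = "fixed",
                                 threshold = 1), 0)

  # Disk of radius r: thresholded pixel count within 2% of pi r^2
  r <- 30
  grid <- expand.grid(x = 1:200, y = 1:200)
  disk <- matrix(as.numeric((grid$x - 60)^2 + (grid$y - 60)^2 <= r^2),
                 200, 200) * 100
  a1 <- quantify_gfp_area(disk, method = "fixed", threshold = 50)
  expect_lt(abs(a1 - pi * r^2) / (pi * r^2), 0.02)

  # Two disjoint disks: additivity
  disk2 <- matrix(as.numeric((grid$x - 150)^2 + (grid$y - 150)^2 <= 15^2),
                  200, 200) * 100
  both <- pmax(disk, disk2)
  a2 <- quantify_gfp_area(disk2, method = "fixed", threshold = 50)
  expect_equal(quantify_gfp_area(both, method = "fixed", threshold = 50),
               a1 + a2)

  # Otsu threshold lands between the foreground and background modes
  skip_if_not_installed("EBImage")
  withr::with_seed(41, {
    noisy <- disk + matrix(runif(200 * 200, 0, 5), 200, 200)
  })
  a3 <- quantify_gfp_area(noisy, method = "otsu")
  expect_lt(abs(a3 - pi * r^2) / (pi * r^2), 0.05)

  # Pixel calibration scales area quadratically
  expect_equal(quantify_gfp_area(disk, method = "fixed", threshold = 50,
                                 pixel_size = 2), 4 * a1)
  expect_error(quantify_gfp_area(matrix(-1, 2, 2), method = "fixed",
                                 threshold = 0), "non-negative")
})

test_that("percent killing anchors per round and is not clamped", {
  ks <- tibble::tibble(
    product = "p", et_ratio = "2:1", round = 1,
    hours = c(0, 7, 14, 21),
    area = c(1000, 1000, 0, 2000)
  )
  pct <- percent_killing(ks)
  expect_equal(pct$pct_killing, c(0, 0, 100, -100))

  # Shifting one round's absolute areas by a common factor changes nothing
  ks2 <- ks; ks2$area <- ks2$area * 7.3
  expect_equal(percent_killing(ks2)$pct_killing, pct$pct_killing)

  # Zero anchor area: flagged NA
  ks3 <- ks; ks3$area[1] <- 0
  expect_warning(pct3 <- percent_killing(ks3), "zero anchor")
  expect_true(all(is.na(pct3$pct_killing)))

  expect_error(percent_killing(ks[, -5]), "Missing column")
})

test_that("3-day and 33-day IVs are sums with the stated arithmetic", {
  # Instant full kill, 11 rounds x 10 post-anchor frames: iv3 = 1000, iv33 = 11000
  inst <- simulate_killing_series(killing_params(kill_rate = Inf),
                                  et_ratios = "2:1")
  iv3 <- killing_iv3(percent_killing(inst))
  expect_equal(iv3$iv3, rep(1000, 11))
  iv33 <- killing_iv33(iv3)
  expect_equal(iv33$iv33, 11000)

  # Zero kill, zero growth: all IVs 0
  none <- simulate_killing_series(killing_params(kill_rate = 0, growth_rate = 0),
                                  et_ratios = "2:1")
  expect_equal(killing_iv33(percent_killing(none))$iv33, 0)

  # Exponential decay round matches the closed-form geometric sum
  g <- 0; k <- 0.05
  one <- simulate_killing_series(
    killing_params(growth_rate = g, kill_rate = k, rounds = 1),
    et_ratios = "2:1"
  )
  iv <- killing_iv3(percent_killing(one))
  t <- 7 * (0:10)
  expect_equal(iv$iv3, sum(100 * (1 - exp(-k * t))), tolerance = 1e-9)

  # Missing frames: summed over what exists, with a warning
  short <- percent_killing(inst)[-2, ]
  expect_warning(iv_short <- killing_iv3(short), "Unequal frame")
  expect_equal(iv_short$n_frames[1], 10)
  expect_warning(killing_iv33(iv_short[iv_short$round < 5, ]), "Fewer than")
})

test_that("iv33 is linear in percent killing and monotone in kill rate", {
  pct <- percent_killing(simulate_killing_series(
    killing_params(kill_rate = 0.04), et_ratios = "2:1"
  ))
  doubled <- pct
  doubled$pct_killing <- doubled$pct_killing * 2
  expect_equal(killing_iv33(doubled)$iv33, 2 * killing_iv33(pct)$iv33)

  # 20 products with graded kill rate, equal growth, no noise: exact ordering
  rates <- seq(0.01, 0.2, length.out = 20)
  iv <- purrr::map2_dfr(sprintf("p%02d", 1:20), rates, function(p, k) {
    ks <- simulate_killing_series(killing_params(kill_rate = k),
                                  et_ratios = "2:1", product = p)
    killing_iv33(percent_killing(ks))
  })
  expect_identical(order(iv$iv33), order(rates))
})
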