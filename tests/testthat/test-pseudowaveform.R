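test_that("percentile filtering matches an independent order-statistic oracle", {
  # degenerate cloud: all heights equal, nothing removed
  flat <- data.frame(x = runif(50), y = runif(50), h = rep(7, 50))
  expect_equal(nrow(filter_height_anomalies(flat)), 50)

  # integer heights 1..1000 against the brute-force oracle
  withr::with_seed(17, {
    pts <- data.frame(x = runif(1000), y = runif(1000), h = sample(1:1000))
  })
  kept <- filter_height_anomalies(pts, 1, 99)
  lo <- oracle_percentile(pts$h, 1); hi <- oracle_percentile(pts$h, 99)
  expect_setequal(kept$h, pts$h[pts$h >= lo & pts$h <= hi])

  # a single far-below-ground return among canopy points is removed
  withr::with_seed(18, {
    cloud <- data.frame(x = runif(501), y = runif(501),
                        h = c(rnorm(500, 20, 3), -50))
  })
  expect_false(-50 %in% filter_height_anomalies(cloud)$h)

  expect_error(filter_height_anomalies(cloud[0, ]), "empty")

  # removal never exceeds ceil((lower + 100-upper)/100 * n) + 1 for
  # continuous heights
  withr::with_seed(19, {
    for (i in 1:10) {
      n <- sample(20:500, 1)
      cl <- data.frame(x = runif(n), y = runif(n), h = rnorm(n, 15, 6))
      lp <- runif(1, 0, 10); up <- runif(1, 90, 100)
      removed <- n - nrow(filter_height_anomalies(cl, lp, up))
      expect_lte(removed, ceiling((lp + 100 - up) / 100 * n) + 1)
    }
  })
})

test_that("pseudo-waveforms bin clipped points over 39 bins spanning 0-40 m", {
  pts <- data.frame(x = runif(10, 0, 2), y = runif(10, 0, 2), h = rep(3.5, 10))
  wf <- compute_pseudowaveform(pts, c(0, 0, 2, 2))
  expect_length(wf$proportions, 39)
  expect_equal(range(wf$bin_edges), c(0, 40))
  expect_equal(wf$total_points, 10)
  expect_equal(max(wf$proportions), 1)
  expect_equal(sum(wf$proportions > 0), 1)

  # crown with no points: the zero waveform, not an error
  empty <- compute_pseudowaveform(pts, c(10, 10, 12, 12))
  expect_equal(empty$total_points, 0)
  expect_true(all(empty$proportions == 0))
  expect_equal(waveform_features(empty), rep(0, 40))
})

test_that("bin counts conserve the clipped point total and ignore ordering", {
  withr::with_seed(23, {
    for (i in 1:10) {
      n <- sample(50:400, 1)
      pts <- data.frame(x = runif(n, 0, 20), y = runif(n, 0, 20),
                        h = runif(n, 0, 39.9))
      bb <- c(2, 2, 2 + runif(1, 2, 10), 2 + runif(1, 2, 10))
      wf <- compute_pseudowaveform(pts, bb)
      inside <- sum(pts$x >= bb[1] & pts$x < bb[3] & pts$y >= bb[2] & pts$y < bb[4])
      expect_equal(wf$total_points, inside)
      if (inside > 0) expect_equal(sum(wf$proportions), 1, tolerance = 1e-9)
      shuf <- pts[sample(n), ]
      expect_equal(compute_pseudowaveform(shuf, bb)$proportions, wf$proportions)
    }
  })
})

test_that("out-of-range heights are clamped into the edge bins, not lost", {
  pts <- data.frame(x = rep(1, 4), y = rep(1, 4), h = c(45, 41, 5, -0.5))
  expect_message(wf <- compute_pseudowaveform(pts, c(0, 0, 2, 2)), "clamped")
  expect_equal(wf$total_points, 4)
  expect_equal(wf$proportions[39], 0.5)   # two above-max points in the top bin
  expect_equal(sum(wf$proportions), 1)

  feats <- waveform_features(suppressMessages(compute_pseudowaveform(pts, NULL)))
  expect_length(feats, 40)
  expect_equal(feats[40], 4)  # last element is the total point count
})
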