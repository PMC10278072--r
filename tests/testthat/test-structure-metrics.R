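test_that("COG distance is plain geometry and rigid-motion invariant", {
  m <- toy_model(rbind(c(0, 0, 0), c(3, 4, 0)), resno = c(1L, 2L))
  expect_equal(domain_cog_distance(m, domain_selection(c(1, 1)),
                                   domain_selection(c(2, 2))), 5)
  s <- gen_cdh_structure(seed = 2)
  sel_cyt <- domain_selection(c(1, 194))
  sel_dh <- domain_selection(c(232, 810))
  d0 <- domain_cog_distance(s, sel_cyt, sel_dh)
  set.seed(10)
  for (i in 1:5) {
    # random rotation (QR of a Gaussian matrix) plus translation
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    shift <- rnorm(3, sd = 20)
    xyz <- as.matrix(s[, c("x", "y", "z")]) %*% q
    s2 <- s
    s2$x <- xyz[, 1] + shift[1]; s2$y <- xyz[, 2] + shift[2]
    s2$z <- xyz[, 3] + shift[3]
    expect_equal(domain_cog_distance(s2, sel_cyt, sel_dh), d0,
                 tolerance = 1e-9)
  }
  expect_error(domain_cog_distance(s, domain_selection(c(900, 910)), sel_dh),
               "empty selection")
})

test_that("residue-pair distances come from named atoms", {
  m <- toy_model(rbind(c(1, 1, 1), c(1, 1, 1), c(2, 3, 6)),
                 resno = c(1L, 2L, 3L))
  expect_equal(residue_pair_distance(m, 1, 2), 0)
  m2 <- toy_model(rbind(c(0, 0, 0), c(2, 3, 6)), resno = c(1L, 2L))
  expect_equal(residue_pair_distance(m2, 1, 2), 7)
  expect_error(residue_pair_distance(m2, 1, 5), "residue 5")
  m3 <- m2; m3$atom_name[1] <- "CB"
  expect_error(residue_pair_distance(m3, 1, 2), "no CA")
})

test_that("Savitzky-Golay smoothing preserves polynomials and matches the least-squares oracle", {
  t <- seq_len(600)
  quad <- 3 + 0.2 * t - 1e-4 * t^2
  expect_equal(smooth_series(quad), quad, tolerance = 1e-9,
               ignore_attr = TRUE)
  const <- rep(4.2, 300)
  expect_equal(smooth_series(const), const, ignore_attr = TRUE)
  expect_error(smooth_series(quad, window = 100), "odd")

  # interior values equal a direct windowed least-squares fit
  set.seed(5)
  noisy <- 10 + 0.05 * t + rnorm(600, 0, 0.5)
  sm <- smooth_series(noisy, 101, 2)
  for (center in c(120, 300, 481)) {
    expect_equal(sm[center], oracle_sg_point(noisy, center, 101, 2),
                 tolerance = 1e-8)
  }
  # noise suppression on a linear ramp: >= 10x residual variance reduction
  truth <- 10 + 0.05 * t
  inner <- 60:540
  expect_gte(var((noisy - truth)[inner]) / var((sm - truth)[inner]), 10)
})

test_that("window shrinks with a warning on short series", {
  x <- seq_len(51) * 0.1
  expect_warning(sm <- smooth_series(x, 101, 2), "shorter than window")
  expect_equal(attr(sm, "window_used"), 51L)
  expect_equal(as.numeric(sm), x, tolerance = 1e-9)  # linear is preserved
})

test_that("pull analysis finds the analytic ramp crossing and windows correctly", {
  gen <- gen_pull_series(n_frames = 1500, noise_sd = 0, seed = 1)
  pa <- analyze_pull(gen$frames)
  expect_equal(pa$crossing_frame, gen$truth$true_crossing_frame)
  expect_equal(pa$crossing_time, 600)
  expect_equal(pa$max_cog_distance, 40 + 0.05 * 599, tolerance = 1e-6)
  # pair range over the pre-crossing window of the 0.005 ramp
  expect_equal(pa$pair_distance_range, 0.005 * 599, tolerance = 1e-6)

  # distortion never reaches the cutoff: no crossing, window is all frames
  flat <- gen_pull_series(distortion_rate = 0, n_frames = 400, seed = 2)
  pf <- analyze_pull(flat$frames)
  expect_true(is.na(pf$crossing_frame))
  expect_equal(pf$max_cog_distance, 40 + 0.05 * 399, tolerance = 1e-6)

  # constant tracked pair gives a zero range
  ft <- frame_table(0:299, data.frame(
    cog_distance = 40 + 0.05 * (0:299),
    distortion = rep(5, 300), pair_distance = rep(8, 300)))
  expect_equal(analyze_pull(ft, window = 101)$pair_distance_range, 0,
               tolerance = 1e-9)
  expect_error(analyze_pull(ft[, c("time", "distortion")]),
               "cog_distance")
})

test_that("max extension before distortion is non-decreasing in the cutoff", {
  gen <- gen_pull_series(n_frames = 1200, noise_sd = 0.2, seed = 9)
  maxima <- vapply(c(8, 9, 10, 11, 12),
                   function(co) analyze_pull(gen$frames, cutoff = co)$max_cog_distance,
                   1.0)
  expect_true(all(diff(maxima) >= 0))
})

test_that("structure-frame input equals the precomputed distance table", {
  base <- gen_cdh_structure(seed = 4)
  sel_cyt <- domain_selection(c(1, 194)); sel_dh <- domain_selection(c(232, 810))
  models <- lapply(0:6, function(k) {
    m <- base
    m$x[m$residue_number >= 232] <- m$x[m$residue_number >= 232] + 0.5 * k
    m
  })
  # independent channel computation straight from coordinates
  chans <- t(vapply(models, function(m) {
    cyt <- m[m$residue_number <= 194 & m$atom_name == "CA", ]
    dh <- m[m$residue_number >= 232 & m$atom_name == "CA", ]
    cogc <- colMeans(cyt[, c("x", "y", "z")])
    cogd <- colMeans(dh[, c("x", "y", "z")])
    ca211 <- unlist(m[m$residue_number == 211, c("x", "y", "z")])
    ca218 <- unlist(m[m$residue_number == 218, c("x", "y", "z")])
    ca459 <- unlist(m[m$residue_number == 459, c("x", "y", "z")])
    c(cog_distance = sqrt(sum((cogc - cogd)^2)),
      distortion = sqrt(sum((cogc - ca211)^2)),
      pair_distance = sqrt(sum((ca218 - ca459)^2)))
  }, c(cog_distance = 0, distortion = 0, pair_distance = 0)))
  manual <- frame_table(1:7, as.data.frame(chans))
  from_struct <- suppressWarnings(
    analyze_pull(models, sel_cyt = sel_cyt, sel_dh = sel_dh,
                 distortion_res = 211, tracked_pair = c(218, 459),
                 window = 5))
  from_table <- suppressWarnings(analyze_pull(manual, window = 5))
  expect_equal(from_struct$smoothed, from_table$smoothed, tolerance = 1e-9)
  expect_equal(from_struct$max_cog_distance, from_table$max_cog_distance)
})
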