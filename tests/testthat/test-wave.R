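# imaging statistics: normalization, centre of fluorescence, displacement,
# wave speed, classification and group comparison

test_that("maximum z-projection takes the per-pixel maximum", {
  one <- array(runif(12), dim = c(1, 3, 4))
  expect_equal(max_z_projection(one), one[1, , ])
  two <- array(0, dim = c(2, 3, 4))
  two[1, 1, 1] <- 5; two[2, 3, 4] <- 7
  pr <- max_z_projection(two)
  expect_equal(pr[1, 1], 5)
  expect_equal(pr[3, 4], 7)
  expect_equal(sum(pr > 0), 2)
  expect_equal(max_z_projection(array(0, dim = c(3, 2, 2))),
               matrix(0, 2, 2))
  expect_error(max_z_projection(matrix(0, 2, 2)), "invalid input")
})

test_that("line profiles match an independent bilinear oracle", {
  # constant image: constant profile
  stk <- time_lapse_stack(array(3, dim = c(2, 10, 12)), 1.28, 2)
  lp <- extract_line_profile(stk, rbind(c(2, 5), c(11, 5)), width = 3)
  expect_true(all(lp$intensity == 3))
  expect_equal(lp$distance_um[1], 0)
  expect_true(all(diff(lp$distance_um) > 0))
  expect_equal(lp$total_length_um, 9 * 2)
  # step edge at a known column
  img <- matrix(0, 10, 12); img[, 7:12] <- 1
  stk2 <- time_lapse_stack(array(img, dim = c(1, 10, 12)), 1.28, 2)
  lp2 <- extract_line_profile(stk2, rbind(c(1, 4), c(12, 4)))
  expect_equal(lp2$intensity[1, ], c(rep(0, 6), rep(1, 6)))
  # sampling between the pixel centres sees the interpolated half-step
  lp2b <- extract_line_profile(stk2, rbind(c(6.5, 4), c(7.5, 4)))
  expect_equal(lp2b$intensity[1, 1], 0.5)
  # diagonal line on a smooth ramp: every sample equals the textbook
  # bilinear interpolation at that point
  ramp <- outer(1:20, 1:20, function(y, x) 0.3 * x + 0.1 * y + 0.01 * x * y)
  stk3 <- time_lapse_stack(array(ramp, dim = c(1, 20, 20)), 1.28, 1.5)
  ep <- rbind(c(2.3, 3.1), c(17.8, 15.4))
  lp3 <- extract_line_profile(stk3, ep)
  n_s <- length(lp3$distance_um)
  tt <- seq(0, 1, length.out = n_s)
  xs <- ep[1, 1] + tt * (ep[2, 1] - ep[1, 1])
  ys <- ep[1, 2] + tt * (ep[2, 2] - ep[1, 2])
  oracle <- vapply(seq_len(n_s), function(i)
    bilinear_oracle(ramp, xs[i], ys[i]), numeric(1))
  expect_equal(lp3$intensity[1, ], oracle, tolerance = 1e-12)
  expect_error(extract_line_profile(stk, rbind(c(0, 5), c(11, 5))),
               "invalid input")
  expect_error(extract_line_profile(stk, rbind(c(2, 1), c(11, 1)),
                                    width = 9), "invalid input")
})

test_that("relative concentration is anchored at 0 and 1", {
  v <- c(100, 100, 100, 150, 300, 250)
  tr <- fluorescence_trace(v, "fluorogenic")
  cc <- relative_concentration(tr)
  expect_equal(cc[1], 0)
  expect_equal(cc[which.max(v)], 1)
  expect_equal(relative_concentration(tr, 4), 0.25)
  # midpoint example: F0 = 100, F_final = 300, Fluo = 200 -> 0.5
  expect_equal(relative_concentration(fluorescence_trace(
    c(100, 100, 100, 200, 300), "fluorogenic"), 4), 0.5)
  # affine rescaling (gain and offset) leaves C unchanged
  tr2 <- fluorescence_trace(7 * v + 40, "fluorogenic")
  expect_equal(relative_concentration(tr2), cc)
  # quenching mode anchors at the minimum
  q <- c(200, 200, 200, 120, 80, 90)
  trq <- fluorescence_trace(q, "quenching")
  expect_equal(relative_concentration(trq, 5), 1)
  expect_equal(relative_concentration(trq, 1), 0)
  expect_error(fluorescence_trace(rep(5, 10), "fluorogenic"), "degenerate")
})

test_that("weighted-mean distance behaves like a centre of mass", {
  expect_equal(weighted_mean_distance(rep(2, 11), seq(0, 30, 3)), 15)
  expect_equal(weighted_mean_distance(c(0, 0, 9, 0), c(0, 5, 12, 20)), 12)
  expect_equal(weighted_mean_distance(c(1, 3), c(0, 4)), 3)
  d <- seq(0, 100, 2)
  w <- dnorm(d, 30, 10)
  wmd <- weighted_mean_distance(w, d)
  # translation equivariance and scale invariance
  expect_equal(weighted_mean_distance(w, d + 17), wmd + 17)
  expect_equal(weighted_mean_distance(5.3 * w, d), wmd)
  # bounded by the sampled range
  expect_true(wmd >= min(d) && wmd <= max(d))
  expect_error(weighted_mean_distance(rep(0, 5), 1:5), "undefined centre")
  expect_error(weighted_mean_distance(1:3, 1:4), "invalid input")
})

test_that("relative displacement is the normalized centre shift", {
  expect_equal(relative_displacement(50, 50, 300), 0)
  expect_equal(relative_displacement(100, 250, 300), 0.5)
  expect_equal(relative_displacement(40, 25, 300), -0.05)
  expect_error(relative_displacement(0, 1, 0), "invalid input")
})

test_that("displacement trajectory and speed follow forced arithmetic", {
  # a single bright pixel advancing 2 um per frame at 1.28 s/frame
  nf <- 20; ns <- 60
  prof <- matrix(0, nf, ns)
  d_um <- seq(0, by = 2, length.out = ns)
  for (f in 1:nf) prof[f, 5 + f] <- 10
  lp <- structure(list(distance_um = d_um, intensity = prof,
                       times_s = (seq_len(nf) - 1) * 1.28,
                       total_length_um = max(d_um), endpoints = NULL,
                       width = 1, pixel_size_um = 2),
                  class = "line_profile")
  r <- displacement_result(lp, window_s = 100, baseline_frames = 3)
  expect_equal(wave_speed(r), 2 / 1.28)
  expect_equal(wave_speed(r), 1.5625)
  # static centre: zero speed and zero displacement
  prof0 <- matrix(0, nf, ns); prof0[, 30] <- 4
  lp0 <- lp; lp0$intensity <- prof0
  r0 <- displacement_result(lp0, window_s = 100, baseline_frames = 3)
  expect_equal(wave_speed(r0), 0)
  expect_equal(r0$relative_displacement, 0)
  # antisymmetry under time reversal of the recording
  lp_rev <- lp; lp_rev$intensity <- prof[nf:1, ]
  r_rev <- displacement_result(lp_rev, window_s = 100, baseline_frames = 3,
                               end_frames = 3)
  wmd <- r$wmd_um
  expect_equal(r_rev$wmd_um, rev(wmd))
  expect_equal(relative_displacement(wmd[1], wmd[nf], max(d_um)),
               -relative_displacement(rev(wmd)[1], rev(wmd)[nf], max(d_um)))
  # fewer than 2 usable frames
  lp1 <- lp; lp1$intensity <- prof[, , drop = FALSE] * 0
  expect_error(displacement_result(lp1, window_s = 100,
                                   baseline_frames = 3),
               "insufficient data")
})

test_that("activation classification thresholds |relative displacement|", {
  mk <- function(rd) structure(list(relative_displacement = rd),
                               class = "displacement_result")
  expect_equal(classify_activation(mk(0)), "simultaneous")
  expect_equal(classify_activation(mk(0.25)), "wave_like")
  expect_equal(classify_activation(mk(-0.25)), "wave_like")
  expect_equal(classify_activation(mk(0.05), threshold = 0.01), "wave_like")
  expect_equal(calibrate_activation_threshold(c(0.3, 0.2), c(0.02, 0.0)),
               (0.25 + 0.01) / 2)
})

test_that("group comparison matches the textbook t-test", {
  g1 <- c(0.30, 0.32, 0.28); g2 <- c(0.02, 0.01, 0.03)
  res <- group_compare(list(a = g1, b = g2))
  orc <- t_test_oracle(g1, g2)
  expect_equal(res$statistic, orc$statistic)
  expect_equal(res$p_value, orc$p)
  expect_lt(res$p_value, 0.01)
  # identical groups: one-tailed p = 0.5
  same <- c(0.1, 0.2, 0.3)
  expect_equal(group_compare(list(a = same, b = same))$p_value, 0.5)
  # swapped direction: p near 1
  expect_gt(group_compare(list(a = g2, b = g1))$p_value, 0.99)
  # Welch variant agrees with stats::t.test
  w <- group_compare(list(a = g1, b = g2), welch = TRUE)
  tw <- t.test(g1, g2, alternative = "greater")
  expect_equal(w$statistic, unname(tw$statistic))
  expect_equal(w$p_value, tw$p.value)
  # ANOVA route
  aa <- group_compare(list(a = g1, b = g2, c = g1 + 0.1), method = "anova")
  expect_true(aa$p_value < 0.01 && aa$statistic > 0)
  # degenerate zero-variance comparison is flagged, not NaN
  dg <- group_compare(list(a = c(1, 1), b = c(1, 1)))
  expect_true(is.na(dg$p_value))
  expect_match(dg$note, "degenerate")
  expect_error(group_compare(list(a = 1:3)), "invalid input")
  expect_error(group_compare(list(a = 1:3, b = 2)), "invalid input")
})
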