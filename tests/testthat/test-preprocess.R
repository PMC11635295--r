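test_that("optical density follows the mean-baseline log-ratio convention", {
  # constant intensity -> zero OD
  intensity <- array(2, c(2, 2, 20))
  raw <- raw_recording(intensity, fs = 11, montage = generic_montage(2))
  expect_equal(optical_density(raw), array(0, c(2, 2, 20)))

  # intensity halved at one sample: dOD = log10(I0 / I) with I0 the
  # geometric temporal mean
  x <- rep(2, 11); x[4] <- 1
  intensity <- array(rep(x, each = 4), c(2, 2, 11))
  raw <- raw_recording(intensity, fs = 11, montage = generic_montage(2))
  od <- optical_density(raw)
  i0 <- 10^mean(log10(x))
  expect_equal(od[1, 1, 4], log10(i0 / 1))
  expect_equal(od[1, 1, 1], log10(i0 / 2))
  expect_equal(mean(od[1, 1, ]), 0)   # zero-mean-log contract

  # gauge invariance: scaling a channel's intensity leaves dOD unchanged
  intensity2 <- intensity
  intensity2[1, , ] <- intensity2[1, , ] * 7.3
  raw2 <- raw_recording(intensity2, fs = 11, montage = generic_montage(2))
  expect_equal(optical_density(raw2), od)

  bad <- intensity
  bad[2, 1, 5] <- 0
  expect_error(raw_recording(bad, fs = 11, montage = generic_montage(2)),
               "channel 2.*sample 5")
})

test_that("MBLL conversion solves the extinction system and round-trips", {
  om <- optical_model()
  # worked single sample against an independent 2x2 solve
  dhb <- c(HbO = 1, HbR = -0.5)
  od <- om$extinction %*% dhb * om$dpf * om$separation
  conc <- solve(om$extinction * om$dpf * om$separation, od)
  expect_equal(as.numeric(conc), c(1, -0.5))

  # zero-mean concentration changes (relative series are defined up to a
  # per-channel constant, which an intensity baseline cannot carry)
  set.seed(1)
  hbt <- matrix(rnorm(5 * 200), 5, 200)
  hbt <- hbt - rowMeans(hbt)
  hemo <- hemo_from_hbt(hbt)
  raw <- forward_to_intensity(hemo, om)
  back <- mbll_convert(raw, om)
  expect_lt(max(abs(back$conc - hemo$conc)) / max(abs(hemo$conc)), 1e-9)

  # zero concentration changes -> constant baseline intensity
  hemo0 <- hemo_from_hbt(matrix(0, 3, 50))
  raw0 <- forward_to_intensity(hemo0, om, baseline = 2.5)
  expect_equal(as.vector(raw0$intensity), rep(2.5, 3 * 2 * 50))
  expect_equal(max(abs(mbll_convert(raw0, om)$conc)), 0)

  # a singular extinction system is rejected at model construction
  expect_error(optical_model(extinction = matrix(c(1, 2, 2, 4), 2)),
               "singular")
})

test_that("HbT = HbO + HbR is enforced and preserved by every stage", {
  set.seed(2)
  hemo <- hemo_from_hbt(matrix(rnorm(4 * 800), 4, 800))
  for (out in list(bandpass(hemo),
                   pca_motion_correct(hemo, 1),
                   select_stable_segment(hemo, 800 / 11 / 2))) {
    expect_equal(out$conc[, 3, ], out$conc[, 1, ] + out$conc[, 2, ])
  }
  bad <- hemo$conc
  bad[1, 3, 1] <- bad[1, 3, 1] + 1
  expect_error(hemo_recording(bad, 11, generic_montage(4)), "HbT")
})

test_that("band-pass keeps the 0.01-0.1 Hz band and rejects cardiac", {
  fs <- 11
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))

  cardiac <- hemo_from_hbt(matrix(sin(2 * pi * 1.0 * t), 1), fs = fs)
  out <- chromophore_matrix(bandpass(cardiac), "HbT")
  expect_lt(max(abs(out[mid])), 0.05)

  slow <- hemo_from_hbt(matrix(sin(2 * pi * 0.05 * t), 1), fs = fs)
  outs <- chromophore_matrix(bandpass(slow), "HbT")
  expect_gt(max(outs[mid]), 0.90)

  # white noise: >= 95% of output power inside a slightly widened band
  set.seed(4)
  wn <- hemo_from_hbt(matrix(rnorm(length(t)), 1), fs = fs)
  outw <- as.numeric(chromophore_matrix(bandpass(wn), "HbT"))
  spec <- Mod(fft(outw - mean(outw)))^2
  freq <- (seq_along(spec) - 1) * fs / length(spec)
  half <- freq <= fs / 2
  inband <- half & freq >= 0.005 & freq <= 0.12
  expect_gt(sum(spec[inband]) / sum(spec[half]), 0.95)

  expect_error(bandpass(wn, low = 0.2, high = 0.1), "band edges")
})

test_that("band-pass filtering is linear", {
  set.seed(5)
  x <- matrix(rnorm(2 * 1000), 2, 1000)
  y <- matrix(rnorm(2 * 1000), 2, 1000)
  fx <- chromophore_matrix(bandpass(hemo_from_hbt(x)), "HbT")
  fy <- chromophore_matrix(bandpass(hemo_from_hbt(y)), "HbT")
  fxy <- chromophore_matrix(bandpass(hemo_from_hbt(2 * x - 3 * y)), "HbT")
  # the 0.01 Hz IIR recursion is ill-conditioned at this sampling rate, so
  # exact linearity holds only to ~1e-6 relative
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-4)
})

test_that("PCA correction removes a planted rank-1 artifact", {
  set.seed(6)
  n <- 1000; nch <- 8
  base <- matrix(rnorm(nch * n, sd = 0.1), nch, n)
  artifact <- rep(0, n); artifact[400:420] <- 8
  hbt <- base + matrix(artifact, nch, n, byrow = TRUE)
  hemo <- hemo_from_hbt(hbt)

  # zero components is the identity
  expect_equal(pca_motion_correct(hemo, 0)$conc, hemo$conc)

  cleaned <- pca_motion_correct(hemo, 1)
  win <- 350:470   # spans the artifact and its onset/offset edges
  var_before <- sum(apply(hbt[, win], 1, var))
  var_after <- sum(apply(chromophore_matrix(cleaned, "HbT")[, win], 1, var))
  expect_lt(var_after, 0.1 * var_before)
  expect_gt(cleaned$provenance$pca$HbO$removed_variance, 0.5)

  # removing all permitted components of a rank-limited input leaves only
  # the (preserved) channel means: zero residual fluctuation
  rank1 <- outer(c(1, 2, 3, 4), rnorm(n))
  res <- pca_motion_correct(hemo_from_hbt(rank1), 3)
  expect_lt(max(apply(chromophore_matrix(res, "HbT"), 1, sd)), 1e-8)

  expect_error(pca_motion_correct(hemo, 8), "8 components")
})

test_that("stable-segment selection avoids transients and breaks ties early", {
  fs <- 11
  # exactly the requested length: whole recording, offset 1
  hemo <- hemo_from_hbt(matrix(rnorm(2 * 330), 2, 330), fs = fs)
  seg <- select_stable_segment(hemo, 30)
  expect_equal(seg$provenance$segment$offset, 1L)
  expect_equal(dim(seg$conc)[3], 330L)

  # big spike early in a long recording: the chosen window excludes it
  set.seed(8)
  n <- 1200 * fs / 2
  hbt <- matrix(rnorm(3 * n, sd = 0.1), 3, n)
  spike_at <- round(n * 0.2)
  hbt[, spike_at] <- hbt[, spike_at] + 50
  seg2 <- select_stable_segment(hemo_from_hbt(hbt, fs = fs), 300)
  off <- seg2$provenance$segment$offset
  expect_true(spike_at < off || spike_at > off + 300 * fs - 1)

  # constant series: every window ties, the earliest wins
  segc <- select_stable_segment(hemo_from_hbt(matrix(1, 2, 4000), fs = fs), 60)
  expect_equal(segc$provenance$segment$offset, 1L)

  expect_error(select_stable_segment(hemo, 31), "shorter")
})
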