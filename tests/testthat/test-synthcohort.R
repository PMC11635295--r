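test_that("latent mixing has the documented closed-form correlations", {
  # two coupled channels: population r equals the coupling strength
  a <- matrix(0, 2, 2); a[1, 2] <- a[2, 1] <- 1
  for (c0 in c(0.3, 0.6, 0.9)) {
    x <- latent_to_hbt(a, c0, 1e5, seed = 10)
    expect_equal(cor(x[1, ], x[2, ]), c0, tolerance = 0.02)
    expect_equal(attr(x, "coupling_eff"), c0)
    expect_equal(latent_population_correlation(a, c0)[1, 2], c0)
  }

  # coupling 0: sample cross-correlations within +/- 3/sqrt(n) of zero
  a4 <- matrix(0, 4, 4)
  x0 <- latent_to_hbt(a4, 0, 4e4, seed = 11)
  cc <- cor(t(x0))
  expect_lt(max(abs(cc[upper.tri(cc)])), 3 / sqrt(4e4))

  # complete graph, c -> 1: all pairwise r -> 1
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  x1 <- latent_to_hbt(k5, 0.999, 2e4, seed = 12)
  cc1 <- cor(t(x1))
  expect_true(all(cc1[upper.tri(cc1)] > 0.99))

  expect_error(latent_to_hbt(a, 1.0, 100), "coupling_strength")
  expect_error(latent_to_hbt(matrix(c(0, 1, 0, 0), 2), 0.5, 100), "symmetric")
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- synth_config(n_group_a = 1, n_group_b = 1, n_channels = 8,
                      duration = 300, seed = 99,
                      bad_channel_plan = list(list(channel = 2,
                                                   defect = "low_snr")))
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$recordings[[1]]$intensity, c2$recordings[[1]]$intensity)
  expect_identical(c1$recordings[[2]]$intensity, c2$recordings[[2]]$intensity)
  expect_identical(c1$truth$latent_adjacency, c2$truth$latent_adjacency)
  c3 <- generate_cohort(synth_config(n_group_a = 1, n_group_b = 1,
                                     n_channels = 8, duration = 300,
                                     seed = 100))
  expect_false(identical(c1$recordings[[1]]$intensity,
                         c3$recordings[[1]]$intensity))
})

test_that("null structure: no coupling and no confounds give independent channels", {
  cfg <- clean_config(5, n_group_a = 1, n_group_b = 0, n_channels = 10,
                      latent_density_a = 0, coupling_strength = 0,
                      density_jitter = 0)
  coh <- generate_cohort(cfg)
  fc <- fc_matrix(mbll_convert(coh$recordings[[1]]))
  off <- fc[upper.tri(fc)]
  expect_lt(mean(abs(off)), 0.05)
  expect_lt(max(abs(off)), 0.15)

  # with the latent amplitude also zero the channels are flat
  cfg0 <- synth_config(n_group_a = 1, n_group_b = 0, n_channels = 4,
                       duration = 300, seed = 6, latent_amplitude = 0,
                       coupling_strength = 0, motion_spike_rate = 0,
                       noise_amplitudes = list(cardiac = 0, respiration = 0,
                                               mayer = 0, systemic = 0,
                                               drift = 0, white = 0))
  coh0 <- generate_cohort(cfg0)
  expect_equal(max(abs(diff(t(coh0$recordings[[1]]$intensity[, 1, ])))), 0)
})

test_that("ground truth records what was planted", {
  plan <- list(list(channel = 3, defect = "low_snr"),
               list(channel = 7, defect = "no_cardiac"))
  cfg <- synth_config(n_group_a = 2, n_group_b = 1, n_channels = 12,
                      duration = 300, seed = 21, bad_channel_plan = plan,
                      motion_spike_rate = 2)
  coh <- generate_cohort(cfg)
  tr <- coh$truth
  expect_equal(tr$labels, c("MCS", "MCS", "UWS"))
  expect_length(tr$latent_adjacency, 3)
  for (a in tr$latent_adjacency) {
    expect_equal(a, t(a))
    expect_true(all(diag(a) == 0))
  }
  expect_equal(vapply(tr$planted_bad_channels, `[[`, 1L, "channel"),
               c(3L, 7L))
  expect_gt(nrow(tr$injected_spikes), 0)
  expect_true(all(tr$injected_spikes$channel %in% 1:12))

  expect_error(generate_cohort(synth_config(n_group_a = 0, n_group_b = 0)),
               "at least one subject")
  expect_error(generate_cohort(synth_config(duration = 60)), ">= 300")
  expect_error(synth_config(latent_density_a = 1.3), "densities")
  expect_error(synth_config(coupling_strength = 1), "coupling_strength")
})

test_that("denser coupling graphs yield more integrated latent networks", {
  # population-level check on the generator's correlation model
  set.seed(31)
  auc_for <- function(dens) mean(replicate(6, {
    a <- latent_adjacency(48, dens)
    network_metrics(fnirsdoc:::cohort_correlation(a, 0.8),
                    metrics = "Eg")$auc
  }))
  eg <- vapply(c(0.2, 0.4, 0.6), auc_for, numeric(1))
  expect_true(all(diff(eg) > 0))
})

test_that("cohorts round-trip through the CSV + JSON on-disk format", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_group_a = 1, n_group_b = 1, n_channels = 6,
                      duration = 300, seed = 13)
  coh <- generate_cohort(cfg)
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "sub01.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_cohort(dir)
  expect_equal(back$labels, coh$truth$labels)
  expect_equal(back$recordings[[1]]$intensity, coh$recordings[[1]]$intensity,
               tolerance = 1e-12)
  expect_equal(back$recordings[[2]]$fs, cfg$fs)
  expect_equal(back$recordings[[1]]$montage$regions,
               coh$recordings[[1]]$montage$regions)
})
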