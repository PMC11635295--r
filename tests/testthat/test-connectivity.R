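test_that("Pearson FC matrix has the expected exact values", {
  x <- rnorm(200)
  hbt <- rbind(x, x, -2 * x + 7)
  fc <- fc_matrix(hemo_from_hbt(hbt))
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_equal(diag(unclass(fc)), rep(1, 3), ignore_attr = TRUE)
  expect_equal(unclass(fc), t(unclass(fc)), ignore_attr = TRUE)

  # channel-wise positive affine transforms leave r unchanged
  fc2 <- fc_matrix(hemo_from_hbt(hbt * c(2, 0.5, 10) + c(1, -3, 7)))
  expect_equal(unclass(fc2), unclass(fc))

  # zero-variance channel flagged missing with a warning
  hbt3 <- rbind(x, rep(1, 200), rnorm(200))
  expect_warning(fc3 <- fc_matrix(hemo_from_hbt(hbt3)), "zero-variance")
  expect_true(all(is.na(fc3[2, ])))
  expect_false(is.na(fc3[1, 3]))
})

test_that("sample FC approaches the generator's population correlation", {
  a <- matrix(0, 6, 6); a[1, 2] <- a[2, 1] <- 1; a[3, 4] <- a[4, 3] <- 1
  x <- latent_to_hbt(a, 0.7, 1e5, seed = 51)
  fc <- fc_matrix(hemo_from_hbt(x))
  pop <- latent_population_correlation(a, 0.7)
  expect_equal(fc[1, 2], 0.7, tolerance = 0.02)
  expect_equal(fc[3, 4], 0.7, tolerance = 0.02)
  expect_lt(max(abs(unclass(fc) - pop)), 0.02)
})

test_that("ROI means average exactly the within-region active pairs", {
  r <- sym_from_upper(4, c(0.2, 0.4, 0.9, 0.6, 0.8, 0.7))
  m <- new_montage(4, list(R_PFC = 1:3, L_PFC = c(1, 4)))
  fc <- structure(r, class = "fc_matrix", active = rep(TRUE, 4),
                  subject = "t", dimnames = list(1:4, 1:4))
  rm <- roi_mean(fc, m)
  expect_equal(rm$mean_r[1], mean(c(0.2, 0.4, 0.6)))  # pairs (1,2),(1,3),(2,3)
  expect_equal(rm$n_pairs[1], 3L)
  expect_equal(rm$mean_r[2], 0.9)                     # pair (1,4)

  # constant matrix: region mean equals the constant
  rc <- sym_from_upper(4, rep(0.4, 6))
  fcc <- structure(rc, class = "fc_matrix", active = rep(TRUE, 4),
                   subject = "t", dimnames = list(1:4, 1:4))
  expect_equal(roi_mean(fcc, m)$mean_r, c(0.4, 0.4))

  # region with a single active channel is missing
  fc1 <- fc; fc1[4, ] <- NA; fc1[, 4] <- NA
  attr(fc1, "active") <- c(TRUE, TRUE, TRUE, FALSE)
  expect_true(is.na(roi_mean(fc1, m)$mean_r[2]))
})

test_that("connectivity histograms count upper-triangle entries per bin", {
  f1 <- structure(sym_from_upper(3, rep(0.05, 3)), class = "fc_matrix",
                  active = rep(TRUE, 3), subject = "a")
  h1 <- fc_distribution(list(f1), edges = c(0, 0.1, 1))
  expect_equal(h1$count, c(3L, 0L))

  f2 <- structure(sym_from_upper(3, c(-0.5, 0.05, 0.5)), class = "fc_matrix",
                  active = rep(TRUE, 3), subject = "b")
  h2 <- fc_distribution(list(f2), edges = c(-1, 0, 0.1, 1))
  expect_equal(h2$count, c(1L, 1L, 1L))

  # identical groups give identical histograms
  h3 <- fc_distribution(list(f2, f2), groups = c("g1", "g2"))
  expect_equal(h3$count[h3$group == "g1"], h3$count[h3$group == "g2"])

  expect_error(fc_distribution(list()), "empty")
  expect_error(fc_distribution(list(f1), edges = c(0.5, 0.1)), "increasing")
})

test_that("group-mean FC averages only subjects where both channels are active", {
  r1 <- sym_from_upper(3, c(0.2, 0.4, 0.6))
  r2 <- sym_from_upper(3, c(0.4, 0.6, 0.8))
  f1 <- structure(r1, class = "fc_matrix", active = rep(TRUE, 3), subject = "a")
  f2 <- structure(r2, class = "fc_matrix", active = rep(TRUE, 3), subject = "b")
  gm <- group_mean_fc(list(f1, f2))
  expect_equal(gm[1, 2], 0.3)

  # subject 2 loses channel 3: pair (1,3) falls back to subject 1 alone
  r2b <- r2; r2b[3, ] <- NA; r2b[, 3] <- NA
  f2b <- structure(r2b, class = "fc_matrix", active = c(TRUE, TRUE, FALSE),
                   subject = "b")
  gm2 <- group_mean_fc(list(f1, f2b))
  expect_equal(gm2[1, 3], 0.4)
  expect_equal(gm2[1, 2], 0.3)
  gm3 <- group_mean_fc(list(f1, f2b), min_subjects = 2)
  expect_true(is.na(gm3[1, 3]))
  expect_equal(gm3[1, 2], 0.3)
})

test_that("suprathreshold edge extraction is exact and ordered", {
  z <- structure(sym_from_upper(3, rep(0, 3)), class = "fc_matrix",
                 active = rep(TRUE, 3), subject = "z")
  expect_equal(nrow(suprathreshold_edges(z)), 0L)

  one <- structure(sym_from_upper(3, c(0.36, 0.1, 0.2)), class = "fc_matrix",
                   active = rep(TRUE, 3), subject = "o")
  e1 <- suprathreshold_edges(one)
  expect_equal(e1$i, 1L); expect_equal(e1$j, 2L); expect_equal(e1$r, 0.36)

  m4 <- sym_from_upper(4, c(0.5, 0.1, 0.45, 0.2, 0.36, 0.35))
  fc4 <- structure(m4, class = "fc_matrix", active = rep(TRUE, 4),
                   subject = "m")
  e4 <- suprathreshold_edges(fc4)
  # entries > 0.35: (1,2)=0.5, (1,4)=0.45, (2,4)=0.36; 0.35 itself excluded
  expect_equal(e4$i, c(1L, 1L, 2L))
  expect_equal(e4$j, c(2L, 4L, 4L))
  expect_equal(e4$r, c(0.5, 0.45, 0.36))
})

test_that("mean connectivity strength matches the hand-computed mean", {
  r <- sym_from_upper(3, c(0.1, 0.2, 0.6))
  fc <- structure(r, class = "fc_matrix", active = rep(TRUE, 3), subject = "s")
  expect_equal(mean_fc_strength(fc), 0.3)
})

test_that("node/edge export writes parseable text files", {
  dir <- withr::local_tempdir()
  m <- sym_from_upper(4, c(0.5, 0.1, 0.45, 0.2, 0.36, 0.3))
  fc <- structure(m, class = "fc_matrix", active = rep(TRUE, 4),
                  subject = "m", dimnames = list(1:4, 1:4))
  paths <- write_node_edge(fc, generic_montage(4), file.path(dir, "net"))
  nodes <- read.table(paths[1], sep = "\t")
  edges <- as.matrix(read.table(paths[2], sep = "\t"))
  expect_equal(nrow(nodes), 4L)
  expect_equal(dim(edges), c(4L, 4L))
  expect_equal(sum(edges > 0) / 2, 3)
})
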