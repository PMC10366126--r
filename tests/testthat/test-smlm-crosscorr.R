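test_that("rasterization conserves mass and rejects out-of-bounds points", {
  pts <- data.frame(x_nm = runif(1000, 0, 500), y_nm = runif(1000, 0, 500))
  for (px in c(10, 25, 50)) {
    g <- rasterize_density(pts, px, c(0, 500, 0, 500))
    expect_equal(sum(g$values) * px^2, 1000)
  }
  one <- rasterize_density(data.frame(x_nm = 3, y_nm = 4), 10,
                           c(0, 10, 0, 10))
  expect_equal(one$values, matrix(1 / 100, 1, 1))
  none <- rasterize_density(data.frame(x_nm = numeric(0),
                                       y_nm = numeric(0)), 10,
                            c(0, 100, 0, 100))
  expect_true(all(none$values == 0))
  expect_error(rasterize_density(data.frame(x_nm = 600, y_nm = 0), 10,
                                 c(0, 500, 0, 500)), "outside bounds")
})

test_that("cross-correlation matches hand evaluations on tiny grids", {
  same <- cross_correlation_2d(grid_from_matrix(matrix(c(2, 0), 1, 2)),
                               grid_from_matrix(matrix(c(2, 0), 1, 2)), 0)
  expect_equal(same$c[1, 1], 1)
  anti <- cross_correlation_2d(grid_from_matrix(matrix(c(2, 0), 1, 2)),
                               grid_from_matrix(matrix(c(0, 2), 1, 2)), 0)
  expect_equal(anti$c[1, 1], -1)
  flat <- cross_correlation_2d(grid_from_matrix(matrix(3, 4, 4)),
                               grid_from_matrix(matrix(5, 4, 4)), 2)
  expect_true(all(flat$c == 0))
  expect_error(cross_correlation_2d(grid_from_matrix(matrix(0, 3, 3)),
                                    grid_from_matrix(matrix(1, 3, 3)), 1),
               "empty channel")
})

test_that("fft and direct evaluations agree and obey the reflection symmetry", {
  set.seed(11)
  for (rep in 1:5) {
    nr <- sample(5:20, 1); nc <- sample(5:20, 1)
    v1 <- matrix(rexp(nr * nc), nr, nc)
    v2 <- matrix(rexp(nr * nc), nr, nc)
    g1 <- grid_from_matrix(v1); g2 <- grid_from_matrix(v2)
    m <- 3
    a <- cross_correlation_2d(g1, g2, m, method = "fft")
    b <- cross_correlation_2d(g1, g2, m, method = "direct")
    expect_lt(max(abs(a$c - b$c)), 1e-10)
    # c(dx,dy) from (1,2) equals c(-dx,-dy) from (2,1)
    sw <- cross_correlation_2d(g2, g1, m, method = "fft")
    expect_equal(a$c, sw$c[rev(seq_len(2 * m + 1)), rev(seq_len(2 * m + 1))],
                 tolerance = 1e-12, ignore_attr = TRUE)
    # spot-check one displacement against the standalone helper oracle
    expect_equal(a$c[m + 2, m + 1], xcorr_at(v1, v2, 1, 0),
                 tolerance = 1e-12)
  }
})

test_that("radial averaging reproduces constants, point masses and closed forms", {
  c2d <- cross_correlation_2d(grid_from_matrix(matrix(3, 8, 8)),
                              grid_from_matrix(matrix(5, 8, 8)), 3)
  c2d$c[] <- 7  # constant field
  prof <- radial_average(c2d)
  expect_true(all(prof$c[prof$n > 0] == 7))
  expect_true(all(diff(prof$r_nm) > 0))

  c2d$c[] <- 0
  c2d$c[4, 4] <- 5  # value only at (0,0)
  prof0 <- radial_average(c2d)
  expect_equal(prof0$c[1], 5)

  # rotationally symmetric Gaussian sampled on the displacement grid:
  # angular averaging must return the radial closed form at each bin center
  sigma <- 2.5
  c2d$c <- outer(c2d$dx_px, c2d$dy_px,
                 function(dx, dy) exp(-(dx^2 + dy^2) / (2 * sigma^2)))
  fine <- radial_average(c2d, r_bin_nm = 0.25)
  keep <- fine$n > 0
  # bin centers hold all samples at (almost) the same radius; compare to the
  # mean of the closed form over the exact radii landing in each bin
  r_exact <- sqrt(outer(c2d$dx_px^2, c2d$dy_px^2, `+`))
  for (b in which(keep)[1:10]) {
    in_bin <- r_exact >= fine$r_nm[b] - 0.125 & r_exact < fine$r_nm[b] + 0.125
    expect_equal(fine$c[b], mean(exp(-r_exact[in_bin]^2 / (2 * sigma^2))),
                 tolerance = 1e-12)
  }
})

test_that("correlation magnitude summarizes the requested radius window", {
  prof <- data.frame(r_nm = c(25, 75, 125), c = c(4, 2, 0), n = c(4, 8, 12))
  class(prof) <- c("radial_profile", "data.frame")
  expect_equal(correlation_magnitude(prof, 100), 3)
  expect_equal(correlation_magnitude(prof, 150), 2)
  zero <- prof; zero$c <- 0
  expect_equal(correlation_magnitude(zero, 150), 0)
  expect_error(correlation_magnitude(prof, 10), "no populated")
})

test_that("randomized control enumerates cross pairs and is seed-stable", {
  sim <- gen_smlm_rois(2, n_bg_per_channel = 50, n_clusters = 5, seed = 3)
  all_pairs <- randomized_control(sim$rois, scheme = "all")
  expect_equal(nrow(all_pairs), 2)
  expect_setequal(all_pairs$roi_id, c("roi001xroi002", "roi002xroi001"))

  sim5 <- gen_smlm_rois(5, n_bg_per_channel = 30, n_clusters = 3, seed = 4)
  d1 <- randomized_control(sim5$rois, seed = 9)
  d2 <- randomized_control(sim5$rois, seed = 9)
  expect_identical(d1, d2)
  # derangement: no ROI paired with itself, one pair per ROI
  expect_equal(nrow(d1), 5)
  expect_false(any(grepl("(roi[0-9]+)x\\1", d1$roi_id)))
  expect_error(randomized_control(sim$rois[1]), "single ROI")
})

test_that("experimental vs randomized comparison matches the Welch oracle", {
  same <- compare_exp_vs_random(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_equal(same$t, 0)

  a <- c(1, 1.1, 0.9); b <- c(0, 0.1, -0.1)
  got <- compare_exp_vs_random(a, b)
  # textbook Welch formula
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  df_hand <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(got$t, t_hand)
  expect_equal(got$p, 2 * pt(-abs(t_hand), df_hand))
  expect_equal(got$mean_exp, 1)
  expect_equal(got$sem_rnd, sd(b) / sqrt(3))

  const <- compare_exp_vs_random(c(2, 2), c(2, 2))
  expect_equal(const$p, 1)
})

test_that("perfectly colocalized channels peak at zero displacement", {
  sim <- gen_smlm_rois(1, n_bg_per_channel = 0, n_clusters = 20,
                       cluster_sigma_nm = 1e-3, co_fraction = 1, seed = 5)
  r <- sim$rois[[1]]
  g1 <- rasterize_density(r$channels$ch1, 20, c(0, 2000, 0, 2000))
  g2 <- rasterize_density(r$channels$ch2, 20, c(0, 2000, 0, 2000))
  cc <- cross_correlation_2d(g1, g2, 5)
  expect_equal(which(cc$c == max(cc$c), arr.ind = TRUE)[1, ],
               c(row = 6, col = 6))
})
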