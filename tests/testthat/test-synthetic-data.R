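test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_smlm_rois(3, seed = 7), gen_smlm_rois(3, seed = 7))
  expect_identical(gen_genes(10, seed = 7), gen_genes(10, seed = 7))
  g <- gen_genes(5, seed = 1)
  expect_identical(gen_crosslink_track(g, seed = 7),
                   gen_crosslink_track(g, seed = 7))
  expect_identical(gen_rip_counts(50, 5, seed = 7),
                   gen_rip_counts(50, 5, seed = 7))
  expect_identical(gen_fiber_measurements(20, seed = 7),
                   gen_fiber_measurements(20, seed = 7))
})

test_that("gene placement respects lengths, overlap and the TSS convention", {
  one <- gen_genes(1, chrom_length = 1000, length_range = c(100, 100),
                   seed = 3)
  expect_equal(one$end - one$start, 100)

  g <- gen_genes(50, chrom_length = 2e5, length_range = c(500, 2000),
                 seed = 9)
  expect_true(all(g$start >= 0 & g$end <= 2e5))
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))  # non-overlapping, sorted

  tss <- tss_positions(g)
  plus <- g$strand == "+"
  expect_equal(tss[plus], g$start[plus])
  expect_equal(tss[!plus], g$end[!plus] - 1L)

  expect_error(gen_genes(100, chrom_length = 1000,
                         length_range = c(100, 100)), "cannot place")
})

test_that("crosslink track generator hits its Poisson expectation", {
  g <- gen_genes(5, seed = 1)
  zero <- gen_crosslink_track(g, background_rate = 0, sites_per_gene = 0)
  expect_equal(nrow(zero$track$events), 0)
  expect_equal(zero$track$library_size, 0)

  one_gene <- gen_genes(1, chrom_length = 1e4, length_range = c(500, 500),
                        seed = 2)
  single <- gen_crosslink_track(one_gene, background_rate = 0,
                                sites_per_gene = 1, site_events = 10,
                                seed = 3)
  expect_equal(single$track$library_size, 10)
  expect_equal(nrow(single$track$events), 1)
  expect_equal(single$track$events$pos, single$truth$pos)

  # 1e5 gene-nt at rate 0.01: total ~ Poisson(1000), check within 4*sqrt(1000)
  big <- gen_genes(100, chrom_length = 2e6, length_range = c(1000, 1000),
                   seed = 4)
  bg <- gen_crosslink_track(big, background_rate = 0.01, sites_per_gene = 0,
                            seed = 4)
  expect_lt(abs(bg$track$library_size - 1000), 4 * sqrt(1000))

  # events never fall outside genes, and strands match
  gr_ev <- bg$track$events
  gene_of <- oricorr:::assign_to_genes(gr_ev$chrom, gr_ev$pos, gr_ev$strand,
                                       big)
  expect_false(any(is.na(gene_of)))
})

test_that("RIP count generator reduces to Poisson at zero dispersion", {
  sim <- gen_rip_counts(5000, 0, mean_range = c(50, 50), dispersion = 0,
                        seed = 5)
  # Poisson: variance ~ mean; NB with dispersion would inflate variance
  ratio <- var(sim$counts$ip) / mean(sim$counts$ip)
  expect_lt(abs(ratio - 1), 0.1)
  expect_error(gen_rip_counts(100, 10, fold_change = 1), "fold_change")
})

test_that("RIP counts are overdispersed at the requested dispersion", {
  sim <- gen_rip_counts(5000, 0, mean_range = c(100, 100), dispersion = 0.2,
                        seed = 6)
  # NB: var = mu + dispersion * mu^2
  expected_var <- 100 + 0.2 * 100^2
  expect_lt(abs(var(sim$counts$ip) / expected_var - 1), 0.15)
})

test_that("coverage track generator produces quantile-scaled TSS bumps", {
  g <- gen_genes(6, chrom_length = 2e5, length_range = c(2000, 2000),
                 seed = 7)
  sim <- gen_coverage_tracks(g, quantile_labels = 1:6, base_amplitude = 1,
                             amplitude_step = 1, noise_sd = 0,
                             condition_effect = 1, flank_bp = 2000, seed = 7)
  expect_identical(sim$track_a, sim$track_b)
  # peak value at the TSS equals the quantile amplitude exactly
  tss <- tss_positions(g)
  for (i in seq_len(nrow(g))) {
    at_tss <- sim$track_a$value[sim$track_a$start == tss[i]]
    expect_equal(at_tss, sim$truth$amplitude_a[i])
  }
  # Q1 (strongest) has the largest amplitude
  expect_equal(which.max(sim$truth$amplitude_a),
               which.min(sim$truth$quantile))

  halved <- gen_coverage_tracks(g, 1:6, condition_effect = 0.5,
                                affected_genes = g$name[1], noise_sd = 0,
                                flank_bp = 2000, seed = 7)
  expect_equal(halved$truth$amplitude_b[1],
               halved$truth$amplitude_a[1] * 0.5)
  expect_equal(halved$truth$amplitude_b[-1], halved$truth$amplitude_a[-1])
})

test_that("peak replicate generator honors dropout limits", {
  origins <- data.frame(chrom = "chrS1",
                        start = seq(0L, 49L * 2000L, by = 2000L),
                        end = seq(0L, 49L * 2000L, by = 2000L) + 300L)
  clean <- gen_peak_replicates(origins, 3, jitter_sd = 0, dropout = 0,
                               extra_rate = 0, seed = 1)
  for (rep in clean$peaks) for (caller in rep)
    expect_equal(caller[, c("chrom", "start", "end")],
                 origins, ignore_attr = TRUE)

  expect_error(gen_peak_replicates(origins, 3, dropout = 1), "dropout")
  near_total <- gen_peak_replicates(origins, 2, dropout = 0.999,
                                    extra_rate = 0, seed = 2)
  expect_lt(sum(vapply(near_total$peaks,
                       function(r) nrow(r[[1]]), integer(1))), 3)
})

test_that("fiber generator arithmetic and round trip are exact at zero noise", {
  sim <- gen_fiber_measurements(10, fork_speed_kb_min = 1.295,
                                pulse_min = 20, noise = 0, seed = 1)
  expect_equal(sim$fibers$idu_um, rep(10, 10))
  expect_equal(fork_rate(sim$fibers$idu_um), rep(1.295, 10))

  spaced <- gen_fiber_measurements(10, n_origins = 30, n_origin_fibers = 40,
                                   spacing_mean_kb = 100, noise = 0,
                                   seed = 2)
  d <- inter_origin_distances(spaced$origins)
  se <- 100 / sqrt(length(d))  # exponential: sd = mean
  expect_lt(abs(mean(d) - 100), 4 * se)
})
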