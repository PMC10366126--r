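test_that("coverage matrix dimensions, constants and linearity behave", {
  genes <- gen_genes(4, chrom_length = 1e5, length_range = c(3000, 3000),
                     seed = 2)
  const <- data.frame(chrom = "chrS1", start = 0L, end = 1e5L, value = 1)
  m <- coverage_matrix(const, genes, flank_bp = 5000, bin_bp = 10)
  expect_equal(ncol(m), 1000)
  expect_true(all(m == 1))

  bump <- data.frame(chrom = "chrS1", start = c(100L, 500L),
                     end = c(200L, 600L), value = c(2, 4))
  g1 <- data.frame(chrom = "chrS1", start = 0L, end = 2000L, name = "g",
                   score = 0L, strand = "+")
  m1 <- coverage_matrix(bump, g1, flank_bp = 1000, bin_bp = 10)
  bump3 <- bump; bump3$value <- bump3$value * 3
  m3 <- coverage_matrix(bump3, g1, flank_bp = 1000, bin_bp = 10)
  expect_equal(m3, 3 * m1)
})

test_that("minus-strand rows read promoter to gene body", {
  track <- data.frame(chrom = "chrS1", start = 59L, end = 61L, value = 5)
  gplus <- data.frame(chrom = "chrS1", start = 50L, end = 90L, name = "p",
                      score = 0L, strand = "+")
  gminus <- data.frame(chrom = "chrS1", start = 20L, end = 61L, name = "m",
                       score = 0L, strand = "-")
  # + gene TSS = 50, window covers 30..69 in 8 bins of 5; positions 59 and
  # 60 sit 9-10 nt downstream of the TSS -> bins 6 and 7 (downstream half)
  mp <- coverage_matrix(track, gplus, flank_bp = 20, bin_bp = 5)
  expect_equal(unname(which(mp[1, ] != 0)), c(6, 7))
  expect_equal(unname(mp[1, c(6, 7)]), c(1, 1))
  # - gene TSS = 60, window covers 40..79; after the orientation flip the
  # TSS (pos 60) and pos 59 (1 nt downstream, transcription runs leftward)
  # land in bins 4 and 5 around the window center
  mm <- coverage_matrix(track, gminus, flank_bp = 20, bin_bp = 5)
  expect_equal(unname(which(mm[1, ] != 0)), c(4, 5))
  expect_equal(unname(mm[1, c(4, 5)]), c(1, 1))
})

test_that("noiseless Gaussian bumps are recovered to analytic bin means", {
  # keep TSS windows disjoint (gap >= 2 * flank) so each row carries exactly
  # one analytically known bump
  genes <- gen_genes(6, chrom_length = 3e5, length_range = c(4000, 4000),
                     gap_min = 10000, seed = 6)
  sim <- gen_coverage_tracks(genes, 1:6, base_amplitude = 1,
                             amplitude_step = 2, peak_width = 250,
                             noise_sd = 0, flank_bp = 5000, seed = 6)
  m <- coverage_matrix(sim$track_a, genes, flank_bp = 5000, bin_bp = 10)
  tss <- tss_positions(genes)
  for (i in seq_len(nrow(genes))) {
    offsets <- (-5000):(4999)                      # genomic pos - TSS
    vals <- sim$truth$amplitude_a[i] *
      exp(-offsets^2 / (2 * 250^2))
    vals[tss[i] + offsets < 0] <- 0                # truncated windows
    analytic <- colMeans(matrix(vals, nrow = 10))
    if (genes$strand[i] == "-") analytic <- rev(analytic)
    expect_lt(max(abs(m[i, ] - analytic)), 1e-9)
  }
})

test_that("profile comparison reports distance, fold change and paired t", {
  genes <- gen_genes(5, chrom_length = 2e5, length_range = c(2000, 2000),
                     seed = 3)
  sim <- gen_coverage_tracks(genes, 1:5, noise_sd = 0, flank_bp = 2000,
                             seed = 3)
  mA <- coverage_matrix(sim$track_a, genes, flank_bp = 2000, bin_bp = 10)

  same <- profile_compare(mA, mA)
  expect_equal(same$distance, 0)
  expect_equal(same$fold_change, 1)
  expect_equal(same$p, 1)

  half <- profile_compare(mA, mA * 0.5)
  expect_equal(half$fold_change, 2)
  expect_equal(half$distance, 0.5 * sqrt(sum(colMeans(mA)^2)))
  # all paired differences positive: match the textbook paired-t oracle
  d <- colMeans(mA) - colMeans(mA * 0.5)
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(half$t, t_hand)
  expect_lt(half$p, 1e-10)

  expect_error(profile_compare(mA, mA[, 1:10]), "share")
})

test_that("metagene distance obeys the triangle inequality", {
  genes <- gen_genes(5, chrom_length = 2e5, length_range = c(2000, 2000),
                     seed = 4)
  mats <- lapply(1:3, function(k) {
    sim <- gen_coverage_tracks(genes, 1:5, noise_sd = 0.2, flank_bp = 2000,
                               seed = k)
    coverage_matrix(sim$track_a, genes, flank_bp = 2000, bin_bp = 10)
  })
  d12 <- profile_compare(mats[[1]], mats[[2]])$distance
  d23 <- profile_compare(mats[[2]], mats[[3]])$distance
  d13 <- profile_compare(mats[[1]], mats[[3]])$distance
  expect_lte(d13, d12 + d23 + 1e-12)
})

test_that("enrichment score matches hand walks and degenerate limits", {
  rk <- data.frame(gene = c("g1", "g2", "g3"), stat = c(3, 2, 1))
  expect_equal(gsea_enrichment_score(rk, "g2"), 0.5)
  expect_equal(gsea_enrichment_score(rk, "g1"), 1)
  expect_equal(gsea_enrichment_score(rk, rk$gene), 1)
  expect_error(gsea_enrichment_score(rk, "absent"), "disjoint")
  dup <- rbind(rk, rk[1, ])
  expect_error(gsea_enrichment_score(dup, "g1"), "duplicate")
})

test_that("enrichment score equals brute-force evaluation on small problems", {
  set.seed(23)
  for (n in c(3, 5, 8)) {
    stats <- sort(round(rnorm(n), 2), decreasing = TRUE)
    genes <- sprintf("g%d", seq_len(n))
    rk <- data.frame(gene = genes, stat = stats)
    for (mask in 1:(2^n - 1)) {
      hit <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
      expect_equal(gsea_enrichment_score(rk, genes[hit]),
                   es_bruteforce(stats, hit), tolerance = 1e-12)
    }
  }
})

test_that("reversing the ranking flips the enrichment score sign", {
  set.seed(29)
  genes <- sprintf("g%02d", 1:40)
  stats <- sort(rnorm(40), decreasing = TRUE)
  rk <- data.frame(gene = genes, stat = stats)
  rev_rk <- data.frame(gene = rev(genes), stat = -rev(stats))
  for (i in 1:5) {
    set_i <- sample(genes, 8)
    expect_equal(gsea_enrichment_score(rev_rk, set_i, weight = 1),
                 -gsea_enrichment_score(rk, set_i, weight = 1),
                 tolerance = 1e-12)
  }
})

test_that("permutation p is seed-stable and extreme for a top-loaded set", {
  genes <- sprintf("g%03d", 1:300)
  rk <- data.frame(gene = genes, stat = sort(rnorm(300, sd = 2),
                                             decreasing = TRUE))
  top <- genes[1:30]
  r1 <- gsea_permutation_p(rk, top, n_perm = 500, seed = 3)
  r2 <- gsea_permutation_p(rk, top, n_perm = 500, seed = 3)
  expect_identical(r1, r2)
  expect_gt(r1$es, 0.5)
  expect_lt(r1$p, 0.01)
  expect_error(gsea_permutation_p(rk, top, n_perm = 10), "n_perm")
})
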