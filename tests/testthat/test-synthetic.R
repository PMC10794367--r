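# Synthetic-data generators: determinism, degenerate limits, and the
# distributional identities each generator is built to satisfy.

test_that("generators are pure functions of their seed", {
  cfg <- sim_config(seed = 42, genome_length_bp = 5e6)
  expect_identical(simulate_true_map(cfg), simulate_true_map(cfg))
  expect_identical(simulate_markers(cfg), simulate_markers(cfg))
  tm <- simulate_true_map(cfg); mk <- simulate_markers(cfg)
  expect_identical(simulate_rho_windows(tm, mk, cfg, 1000, 100),
                   simulate_rho_windows(tm, mk, cfg, 1000, 100))
  big <- uniform_map(100e6, 1.5)
  expect_identical(simulate_ibd_pairs(big, 5, 3, seed = 7),
                   simulate_ibd_pairs(big, 5, 3, seed = 7))
  expect_identical(simulate_ancestry_tracks(3, 20, seed = 7),
                   simulate_ancestry_tracks(3, 20, seed = 7))
  expect_identical(simulate_haplotypes(uniform_map(2e6, 25), 20, 200,
                                       N_wf = 20, generations = 10, seed = 5),
                   simulate_haplotypes(uniform_map(2e6, 25), 20, 200,
                                       N_wf = 20, generations = 10, seed = 5))
  expect_identical(simulate_imputation_results(30, 40, seed = 3),
                   simulate_imputation_results(30, 40, seed = 3))
})

test_that("degenerate landscape settings give an exactly uniform map", {
  cfg <- sim_config(seed = 1, genome_length_bp = 20e6,
                    background_rate_cM_per_Mb = 1.3,
                    background_shape = Inf, hotspot_density_per_Mb = 0)
  tm <- simulate_true_map(cfg)
  expect_equal(tm$rate_cM_per_Mb, rep(1.3, length(tm$rate_cM_per_Mb)))
  expect_equal(map_length_cM(tm), 20 * 1.3)   # rate x distance
})

test_that("noiseless rho windows equal 4Ne * r exactly and share overlaps", {
  cfg <- sim_config(seed = 3, genome_length_bp = 10e6, rho_noise_sigma = 0)
  tm <- simulate_true_map(cfg)
  mk <- simulate_markers(cfg)
  ws <- simulate_rho_windows(tm, mk, cfg, snps_per_window = 1500, overlap = 100)
  g <- interpolate_cM(tm, mk)
  r_bar <- diff(g) / (diff(mk) / 1e6)
  for (i in seq_along(ws$windows)) {
    w <- ws$windows[[i]]
    idx <- match(w$snp_pos[1], mk)
    expected <- cfg$fourNe * r_bar[idx:(idx + length(w$snp_pos) - 2)] * 1e-5
    expect_equal(w$rho_per_kb, expected)
    if (i > 1) {
      prev <- ws$windows[[i - 1]]
      o <- w$n_overlap_left
      expect_identical(utils::tail(prev$snp_pos, o), utils::head(w$snp_pos, o))
    }
  }
  expect_error(simulate_rho_windows(tm, mk[1:50], cfg,
                                    snps_per_window = 1500, overlap = 100),
               "fewer markers")
})

test_that("lognormal noise has the predicted multiplicative mean", {
  # E[rho]/(4Ne r) = exp(sigma^2/2); checked by direct sampling at ~1e5
  # intervals on a uniform landscape
  cfg <- sim_config(seed = 8, genome_length_bp = 50e6,
                    background_shape = Inf, hotspot_density_per_Mb = 0,
                    rho_noise_sigma = 0.5, marker_density_per_kb = 2)
  tm <- simulate_true_map(cfg)
  mk <- simulate_markers(cfg)
  ws <- simulate_rho_windows(tm, mk, cfg)
  rho <- unlist(lapply(ws$windows, `[[`, "rho_per_kb"))
  rho_true <- cfg$fourNe * cfg$background_rate_cM_per_Mb * 1e-5
  expect_gt(length(rho), 9e4)
  expect_equal(mean(rho) / rho_true, exp(0.5^2 / 2), tolerance = 0.01)
})

test_that("IBD pair generator matches its kinship targets", {
  maps <- lapply(1:20, function(i) uniform_map(175e6, 1, chrom = i))
  L <- map_length_cM(maps)
  # parent-offspring: one full-span segment per chromosome on one channel
  po <- simulate_ibd_pairs(maps, 3, meioses = 1, seed = 2)
  per_pair <- tapply(po$segments$length_cM, po$segments$id1, sum)
  expect_true(all(abs(per_pair - L) < 1e-9))
  expect_equal(nrow(po$segments), 3 * 20)
  # many meioses -> expected sharing collapses
  far <- simulate_ibd_pairs(maps, 40, meioses = 10, seed = 3)
  expect_lt(sum(far$segments$length_cM) / 40, 4 * 2^-11 * L * 1.5)
  # law of large numbers on the summed length (m = 2, 1000 pairs)
  sim <- simulate_ibd_pairs(maps, 1000, meioses = 2, seed = 4)
  mean_sum <- sum(sim$segments$length_cM) / 1000
  expect_equal(mean_sum, 4 * 2^-3 * L, tolerance = 0.10)
  # generator self-consistency for m = 4 (spec'd band +/-15%)
  sim4 <- simulate_ibd_pairs(maps, 500, meioses = 4, seed = 5)
  phi_hat <- sum(sim4$segments$length_cM) / 500 / (4 * L)
  expect_equal(phi_hat, 2^-5, tolerance = 0.15)
})

test_that("crossover counts per meiosis are Poisson(L_cM/100)", {
  set.seed(11)
  counts <- replicate(2000, length(recombmap:::draw_crossovers(250)))
  lambda <- 2.5
  ub <- max(counts, 8)
  obs <- tabulate(counts + 1L, nbins = ub + 1L)
  p <- dpois(0:ub, lambda); p[ub + 1L] <- 1 - ppois(ub - 1L, lambda)
  # pool bins with small expectation, chi-square GOF at alpha = 0.01
  keep <- p * 2000 >= 5
  obs2 <- c(obs[keep], sum(obs[!keep]))
  p2 <- c(p[keep], sum(p[!keep]))
  gof <- suppressWarnings(chisq.test(obs2, p = p2 / sum(p2)))
  expect_gt(gof$p.value, 0.01)
})

test_that("Wright-Fisher respects the no-recombination limit and neutrality", {
  # zero-cM map: every sampled haplotype is a copy of one of the 4 founders
  zmap <- genetic_map("1", c(0, 2e6), rate_cM_per_Mb = 0)
  hm <- simulate_haplotypes(zmap, 4, 300, N_wf = 2, generations = 6, seed = 6)
  expect_lte(nrow(unique(hm$haps)), 4)
  # with abundant recombination the same setup yields recombinant mosaics
  rmap <- genetic_map("1", c(0, 2e6), rate_cM_per_Mb = 250)
  hr <- simulate_haplotypes(rmap, 4, 300, N_wf = 2, generations = 6, seed = 6)
  expect_gte(nrow(unique(hr$haps)), nrow(unique(hm$haps)))

  # s = 0: sweep-site frequency is a martingale (mean over 200 reps
  # within 3 SE of the starting frequency)
  freqs <- vapply(1:200, function(s) {
    h <- simulate_haplotypes(uniform_map(1e6, 5), 50, 40, N_wf = 25,
                             generations = 25,
                             sweep = list(position = 5e5, s = 0,
                                          start_freq = 0.5), seed = 100 + s)
    sp <- attr(h, "sweep_pos")
    if (is.null(sp)) mean(h$haps[, which.min(abs(h$pos - 5e5))])
    else mean(h$haps[, which(h$pos == sp)])
  }, numeric(1))
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.5), 3 * se)
})

test_that("marker gaps thin the Poisson process as configured", {
  cfg <- sim_config(seed = 10, genome_length_bp = 20e6,
                    marker_density_per_kb = 0.5,
                    gap_regions = data.frame(start = 5e6, end = 7e6),
                    gap_density_factor = 0.01)
  mk <- simulate_markers(cfg)
  in_gap <- sum(mk >= 5e6 & mk < 7e6)
  outside_rate <- (length(mk) - in_gap) / (18e6 / 1000)
  expect_equal(outside_rate, 0.5, tolerance = 0.05)
  expect_lt(in_gap, 0.05 * 0.5 * 2000)   # ~1% of the outside density
})

test_that("ancestry tracks honour their probability invariants", {
  sim <- simulate_ancestry_tracks(6, 40, flip_prob = 0.05, seed = 12)
  for (tr in list(sim$a, sim$b)) {
    sums <- apply(tr$probs, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    argmax <- apply(tr$probs, c(1, 2), which.max)
    expect_true(all(argmax == tr$calls))   # called label is the argmax
  }
})
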