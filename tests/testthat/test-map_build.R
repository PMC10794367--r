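# Window stitching, 4Ne regression, rescaling, binning.

make_window <- function(chrom, idx, snp_pos, rho, ol, or) {
  structure(list(chrom = chrom, window_index = idx, snp_pos = snp_pos,
                 rho_per_kb = rho, n_overlap_left = as.integer(ol),
                 n_overlap_right = as.integer(or)), class = "rho_window")
}

make_window_set <- function(pos, bounds, values, overlap) {
  # bounds: list of (start_idx, end_idx) per window; values: constant per window
  ws <- lapply(seq_along(bounds), function(i) {
    idx <- bounds[[i]][1]:bounds[[i]][2]
    ol <- if (i == 1) 0 else bounds[[i - 1]][2] - bounds[[i]][1] + 1
    or <- if (i == length(bounds)) 0 else bounds[[i]][2] - bounds[[i + 1]][1] + 1
    make_window("1", i, pos[idx], rep(values[i], length(idx) - 1), ol, or)
  })
  structure(list(chrom = "1", windows = ws), class = "rho_window_set")
}

# brute-force stitching oracle: assign each global interval to its source
# window by the distal-half rule, interval by interval
oracle_stitch <- function(pos, bounds, values, k_rule = function(o) max(floor(o / 2), 1)) {
  n_int <- length(pos) - 1
  src <- rep(1L, n_int)
  for (i in 2:length(bounds)) {
    o <- bounds[[i - 1]][2] - bounds[[i]][1] + 1
    cut_idx <- bounds[[i]][1] + k_rule(o) - 1   # global index of cut SNP
    src[cut_idx:n_int] <- i
  }
  values[src]
}

test_that("stitching follows the distal-half rule and matches the oracle", {
  pos <- seq(0, by = 1000, length.out = 30)
  # agreement case: same values everywhere
  ws <- make_window_set(pos, list(c(1, 14), c(11, 24), c(21, 30)), c(2, 2, 2), 4)
  tr <- stitch_windows(ws)
  expect_equal(tr$snp_pos, pos)
  expect_true(all(tr$rho_per_kb == 2))
  # distinct constants, overlap 4 (k = 2): switch at each overlap midpoint
  ws2 <- make_window_set(pos, list(c(1, 14), c(11, 24), c(21, 30)), c(1, 2, 3), 4)
  tr2 <- stitch_windows(ws2)
  expect_equal(length(tr2$rho_per_kb), length(pos) - 1)
  expect_equal(tr2$rho_per_kb,
               oracle_stitch(pos, list(c(1, 14), c(11, 24), c(21, 30)), c(1, 2, 3)))
  # every output interval traceable to exactly one source window
  expect_true(all(tr2$rho_per_kb %in% c(1, 2, 3)))
  # odd overlap: documented floor tie-break, cut after floor(o/2) shared SNPs
  ws3 <- make_window_set(pos, list(c(1, 15), c(11, 30)), c(1, 2), 5)
  tr3 <- stitch_windows(ws3)
  expect_equal(tr3$rho_per_kb,
               oracle_stitch(pos, list(c(1, 15), c(11, 30)), c(1, 2)))
  # diverging overlap positions are a hard error naming the position
  bad <- ws2
  bad$windows[[2]]$snp_pos[1] <- bad$windows[[2]]$snp_pos[1] + 1
  expect_error(stitch_windows(bad), "diverge")
})

test_that("noiseless windows stitch back to 4Ne * r on every interval", {
  cfg <- sim_config(seed = 5, genome_length_bp = 10e6, rho_noise_sigma = 0)
  tm <- simulate_true_map(cfg)
  mk <- simulate_markers(cfg)
  tr <- stitch_windows(simulate_rho_windows(tm, mk, cfg, 1200, 80))
  expect_equal(tr$snp_pos, mk)
  r_bar <- diff(interpolate_cM(tm, mk)) / (diff(mk) / 1e6)
  expect_equal(tr$rho_per_kb, cfg$fourNe * r_bar * 1e-5)
})

test_that("4Ne regression is exact on proportional input and scale-equivariant", {
  set.seed(2)
  ref <- genetic_map("1", sort(c(0, sample.int(30e6, 200), 30e6)),
                     rate_cM_per_Mb = runif(201, 0.2, 3))
  mk <- sort(sample.int(30e6, 5000))
  r_bar <- diff(interpolate_cM(ref, mk)) / (diff(mk) / 1e6)
  tr <- rho_track("1", mk, 10000 * r_bar * 1e-5)
  fit <- estimate_fourNe(tr, ref)
  expect_equal(fit$fourNe, 10000, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_gte(fit$n_windows, 2)
  # homogeneity: doubling rho doubles the slope
  tr2 <- rho_track("1", mk, tr$rho_per_kb * 2)
  expect_equal(estimate_fourNe(tr2, ref)$fourNe, 20000, tolerance = 1e-6)
  # equivariance under arbitrary positive scaling, with noise present
  noisy <- rho_track("1", mk, tr$rho_per_kb * exp(rnorm(length(mk) - 1, 0, 0.4)))
  f1 <- estimate_fourNe(noisy, ref)
  f3 <- estimate_fourNe(rho_track("1", mk, noisy$rho_per_kb * 3.7), ref)
  expect_equal(f3$fourNe / f1$fourNe, 3.7, tolerance = 1e-9)
})

test_that("rescaling converts rho to cM/Mb with the right units", {
  mk <- seq(0, 5e6, by = 1e4)
  tr <- rho_track("1", mk, rep(0.4, length(mk) - 1))
  fit <- structure(list(fourNe = 10000), class = "ne_fit")
  m <- rescale_to_cM(tr, fit)
  expect_true(all(abs(m$rate_cM_per_Mb - 4.0) < 1e-12))  # 0.4/kb / 1e4 = 4 cM/Mb
  expect_equal(m$cum_cM[1], 0)
  m2 <- rescale_to_cM(tr, structure(list(fourNe = 20000), class = "ne_fit"))
  expect_equal(m2$rate_cM_per_Mb, m$rate_cM_per_Mb / 2)
})

test_that("end-to-end noiseless pipeline reproduces the true map", {
  cfg <- sim_config(seed = 9, genome_length_bp = 20e6, rho_noise_sigma = 0)
  tm <- simulate_true_map(cfg)
  mk <- simulate_markers(cfg)
  tr <- stitch_windows(simulate_rho_windows(tm, mk, cfg))
  fit <- estimate_fourNe(tr, tm)
  expect_equal(fit$fourNe, cfg$fourNe, tolerance = 1e-9)
  rebuilt <- rescale_to_cM(tr, fit)
  r_true <- diff(interpolate_cM(tm, mk)) / (diff(mk) / 1e6)
  expect_equal(rebuilt$rate_cM_per_Mb, r_true, tolerance = 1e-9)
})

test_that("binning takes bp-weighted means, handles masks and coarsens consistently", {
  u <- uniform_map(1e6, 1)
  b <- bin_map(u, 5e4)
  expect_true(all(b$mean_rate[!b$missing] == 1))
  # bin fully inside a mask is missing
  bm <- bin_map(u, 5e4, mask = mask_set("1", 2e5, 3e5))
  expect_true(all(bm$missing[b$bin_start >= 2e5 & b$bin_start < 3e5]))
  expect_false(bm$missing[1])
  # hand-built 3-interval map vs per-bp averaging oracle at 50 kb
  m3 <- genetic_map("1", c(0, 7e4, 1.2e5, 3e5), rate_cM_per_Mb = c(2, 0.5, 1))
  b3 <- bin_map(m3, 5e4)
  rate_at <- function(x) c(2, 0.5, 1)[findInterval(x, c(0, 7e4, 1.2e5))]
  oracle <- vapply(b3$bin_start, function(s)
    mean(rate_at(seq(s, s + 5e4 - 1))), numeric(1))
  expect_equal(b3$mean_rate, oracle, tolerance = 1e-6)
  # coarsening consistency on fully covered bins: 10 kb -> 20 kb == direct 20 kb
  set.seed(7)
  mr <- genetic_map("1", seq(0, 4e5, by = 1e4), rate_cM_per_Mb = runif(40, 0, 3))
  fine <- bin_map(mr, 1e4)
  direct <- bin_map(mr, 2e4)
  re <- vapply(seq(1, 40, by = 2), function(i)
    mean(fine$mean_rate[i:(i + 1)]), numeric(1))
  expect_equal(re, direct$mean_rate, tolerance = 1e-12)
})
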