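# Synthetic-data generators.  Every input the pipeline consumes can be
# produced here with the statistical structure the downstream analyses assume:
# piecewise-constant recombination landscapes with hotspots, multiplicatively
# noisy population-scaled rho tracks (rho = 4*Ne*r*eps), marker grids with
# planted low-density gaps, IBD segments consistent with a target kinship,
# four-way ancestry mosaics, Wright-Fisher haplotypes with optional selection,
# and MAF-stratified imputation dosages.
#
# All generators are pure functions of their configuration and seed: the same
# seed gives byte-identical output.  Generators derived from a sim_config use
# fixed offsets from cfg$seed (map +0, markers +1, rho windows +2) so the
# stages of one simulated study draw independent streams.

#' Simulation configuration
#'
#' Bundles the parameters of one simulated study.  Defaults describe a
#' human-like autosomal segment: background rate 1 cM/Mb varying between
#' 10 kb blocks (gamma, shape 2), hotspots every ~100 kb of width 2 kb and
#' 20-fold intensity, a scaled population size 4Ne = 20,000, lognormal
#' multiplicative noise sigma = 0.3 on the rho estimates, and an array-like
#' marker density of 0.485/kb (242.5 markers per 500 kb).
#'
#' @param seed integer seed; fixing it makes every generator deterministic.
#' @param genome_length_bp simulated chromosome length.
#' @param background_rate_cM_per_Mb mean background recombination rate.
#' @param background_shape gamma shape for per-10 kb block rates; `Inf` gives
#'   a constant background (zero variance).
#' @param hotspot_density_per_Mb expected hotspots per Mb (Poisson).
#' @param hotspot_width_bp hotspot width.
#' @param hotspot_multiplier rate multiplier inside hotspots.
#' @param fourNe scaled effective population size (the factor in
#'   rho = 4*Ne*r).
#' @param rho_noise_sigma lognormal sigma of the multiplicative noise on rho.
#' @param marker_density_per_kb mean marker density (Poisson process).
#' @param gap_regions optional data frame (`start`, `end`) of regions where
#'   marker density is multiplied by `gap_density_factor`.
#' @param gap_density_factor density multiplier inside gap regions.
#' @param chrom chromosome label.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length_bp = 50e6,
                       background_rate_cM_per_Mb = 1.0,
                       background_shape = 2,
                       hotspot_density_per_Mb = 10,
                       hotspot_width_bp = 2000,
                       hotspot_multiplier = 20,
                       fourNe = 20000,
                       rho_noise_sigma = 0.3,
                       marker_density_per_kb = 0.485,
                       gap_regions = NULL,
                       gap_density_factor = 0.01,
                       chrom = "1") {
  cfg <- list(seed = as.integer(seed), genome_length_bp = genome_length_bp,
              background_rate_cM_per_Mb = background_rate_cM_per_Mb,
              background_shape = background_shape,
              hotspot_density_per_Mb = hotspot_density_per_Mb,
              hotspot_width_bp = hotspot_width_bp,
              hotspot_multiplier = hotspot_multiplier,
              fourNe = fourNe, rho_noise_sigma = rho_noise_sigma,
              marker_density_per_kb = marker_density_per_kb,
              gap_regions = gap_regions,
              gap_density_factor = gap_density_factor,
              chrom = chrom)
  num <- c("genome_length_bp", "background_rate_cM_per_Mb",
           "hotspot_density_per_Mb", "hotspot_width_bp",
           "hotspot_multiplier", "fourNe", "rho_noise_sigma",
           "marker_density_per_kb", "gap_density_factor")
  if (any(unlist(cfg[num]) < 0)) stop("rates and densities must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a "true" recombination landscape
#'
#' Piecewise-constant map: the background rate is drawn per 10 kb block from a
#' gamma distribution with mean `background_rate_cM_per_Mb`, and hotspots are
#' placed by a Poisson process with the configured density, each of width
#' `hotspot_width_bp` and rate multiplied by `hotspot_multiplier`
#' (overlapping hotspots are unioned and multiplied once).
#'
#' @param cfg a [sim_config()].
#' @return a `genetic_map`.
#' @export
simulate_true_map <- function(cfg) {
  with_seed(cfg$seed, {
    L <- cfg$genome_length_bp
    bs <- 1e4
    n_blocks <- as.integer(ceiling(L / bs))
    rates <- if (is.finite(cfg$background_shape)) {
      stats::rgamma(n_blocks, shape = cfg$background_shape,
                    rate = cfg$background_shape / cfg$background_rate_cM_per_Mb)
    } else rep(cfg$background_rate_cM_per_Mb, n_blocks)
    hs <- ls_ <- numeric(0)
    if (cfg$hotspot_density_per_Mb > 0) {
      n_h <- stats::rpois(1, cfg$hotspot_density_per_Mb * L / 1e6)
      if (n_h > 0) {
        starts <- floor(stats::runif(n_h, 0, max(L - cfg$hotspot_width_bp, 1)))
        mg <- merge_interval_vecs(starts, starts + cfg$hotspot_width_bp)
        hs <- mg$start; ls_ <- pmin(mg$end, L)
      }
    }
    breaks <- sort(unique(c(seq(0, L, by = bs), L, hs, ls_)))
    breaks <- breaks[breaks >= 0 & breaks <= L]
    mid <- (breaks[-length(breaks)] + breaks[-1]) / 2
    rate <- rates[pmin(floor(mid / bs) + 1L, n_blocks)]
    if (length(hs)) {
      in_h <- rep(FALSE, length(mid))
      for (j in seq_along(hs)) in_h <- in_h | (mid >= hs[j] & mid < ls_[j])
      rate[in_h] <- rate[in_h] * cfg$hotspot_multiplier
    }
    genetic_map(cfg$chrom, breaks, rate_cM_per_Mb = rate)
  })
}

#' Simulate marker positions
#'
#' Homogeneous Poisson process at `marker_density_per_kb`, thinned inside
#' `gap_regions` by `gap_density_factor` (thinning a Poisson process yields
#' exactly the reduced-intensity process).
#'
#' @param cfg a [sim_config()].
#' @return sorted integer marker positions (0-based bp).
#' @export
simulate_markers <- function(cfg) {
  with_seed(cfg$seed + 1L, {
    L <- cfg$genome_length_bp
    n <- stats::rpois(1, cfg$marker_density_per_kb * L / 1000)
    pos <- sort(unique(floor(stats::runif(n, 0, L))))
    if (!is.null(cfg$gap_regions) && nrow(cfg$gap_regions) > 0) {
      keep <- rep(TRUE, length(pos))
      u <- stats::runif(length(pos))
      for (i in seq_len(nrow(cfg$gap_regions))) {
        g <- pos >= cfg$gap_regions$start[i] & pos < cfg$gap_regions$end[i]
        keep[g] <- keep[g] & (u[g] < cfg$gap_density_factor)
      }
      pos <- pos[keep]
    }
    pos
  })
}

#' Simulate overlapping windows of population-scaled rho estimates
#'
#' Emulates the per-window output of an LD-based estimator: the marker list is
#' split into windows of `snps_per_window` SNPs with `overlap` SNPs shared
#' between neighbours, and each marker interval gets
#' `rho/kb = 4Ne * r * eps` where `r` is the true map's bp-weighted mean rate
#' over the interval and `eps ~ lognormal(0, rho_noise_sigma)` is drawn
#' independently per interval *and per window* (shared SNP positions are
#' identical between neighbours, but their estimates are independent,
#' emulating independent per-window MCMC runs).
#'
#' @param true_map the underlying `genetic_map`.
#' @param markers sorted marker positions (bp), e.g. from
#'   [simulate_markers()].
#' @param cfg a [sim_config()] (supplies `fourNe` and `rho_noise_sigma`).
#' @param snps_per_window,overlap window layout in SNPs.
#' @param seed RNG seed for the noise draws (default `cfg$seed + 2`).
#' @return a `rho_window_set`.
#' @export
simulate_rho_windows <- function(true_map, markers, cfg,
                                 snps_per_window = 4000, overlap = 200,
                                 seed = cfg$seed + 2L) {
  n <- length(markers)
  if (n <= overlap) stop("fewer markers than the window overlap")
  if (overlap >= snps_per_window) stop("overlap must be < snps_per_window")
  g <- interpolate_cM(true_map, markers)
  r_bar <- diff(g) / (diff(markers) / 1e6)              # cM/Mb per interval
  rho_true <- cfg$fourNe * r_bar * 1e-5                 # rho per kb
  stride <- snps_per_window - overlap
  starts <- seq(1L, n, by = stride)
  ends <- pmin(starts + snps_per_window - 1L, n)
  keep <- c(TRUE, ends[-1] > ends[-length(ends)])       # drop contained tails
  starts <- starts[keep]; ends <- ends[keep]
  keep2 <- ends > starts                                # need >= 1 interval
  starts <- starts[keep2]; ends <- ends[keep2]
  windows <- with_seed(seed, lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    n_int <- length(idx) - 1L
    eps <- if (cfg$rho_noise_sigma > 0)
      stats::rlnorm(n_int, 0, cfg$rho_noise_sigma) else rep(1, n_int)
    ol_left <- if (i == 1L) 0L else ends[i - 1L] - starts[i] + 1L
    ol_right <- if (i == length(starts)) 0L else ends[i] - starts[i + 1L] + 1L
    structure(list(chrom = true_map$chrom, window_index = i,
                   snp_pos = markers[idx],
                   rho_per_kb = rho_true[idx[-length(idx)]] * eps,
                   n_overlap_left = as.integer(ol_left),
                   n_overlap_right = as.integer(ol_right)),
              class = "rho_window")
  }))
  structure(list(chrom = true_map$chrom, windows = windows),
            class = "rho_window_set")
}

# crossover breakpoints (cM) for one meiosis on a map of total length L_cM
draw_crossovers <- function(L_cM) {
  stats::runif(stats::rpois(1, L_cM / 100), 0, L_cM)
}

#' Simulate IBD segments for pairs at a target relatedness
#'
#' Pairs separated by `meioses` m share an expected summed IBD length of
#' `4 * phi * L_cM` with `phi = 2^-(m+1)`: parent-offspring (m = 1) is one
#' fully shared haplotype pair per chromosome; for m >= 2,
#' `round(4*phi*L/mean_len)` segments with Exponential(mean `100/m` cM)
#' genetic lengths are placed uniformly, without overlap, on one of the four
#' haplotype-pair channels, and physical coordinates are obtained by inverse
#' interpolation through the map.
#'
#' @param maps a `genetic_map` or list of maps (one per chromosome).
#' @param n_pairs number of individual pairs.
#' @param meioses meioses separating each pair (m >= 1).
#' @param seed RNG seed.
#' @param mean_len_cM mean segment genetic length (default `100/meioses`).
#' @return list with `segments` (an `ibd_table`) and `truth` (data frame of
#'   pair ids, meioses, expected kinship `phi` and its degree category).
#' @export
simulate_ibd_pairs <- function(maps, n_pairs, meioses, seed = 1L,
                               mean_len_cM = 100 / meioses) {
  if (inherits(maps, "genetic_map")) maps <- list(maps)
  if (meioses < 1) stop("meioses must be >= 1")
  L_c <- vapply(maps, map_length_cM, numeric(1))
  L <- sum(L_c)
  phi <- 2^-(meioses + 1)
  channels <- cbind(hap1 = c(1L, 1L, 2L, 2L), hap2 = c(1L, 2L, 1L, 2L))
  per_pair <- with_seed(seed, lapply(seq_len(n_pairs), function(k) {
    id1 <- sprintf("P%05d_a", k); id2 <- sprintf("P%05d_b", k)
    if (meioses == 1) {
      return(data.frame(
        id1 = id1, hap1 = 1L, id2 = id2, hap2 = 1L,
        chrom = vapply(maps, function(m) m$chrom, character(1)),
        start = vapply(maps, function(m) m$pos[1], numeric(1)),
        end = vapply(maps, function(m) m$pos[length(m$pos)], numeric(1)),
        length_cM = L_c, stringsAsFactors = FALSE))
    }
    n_seg <- round(4 * phi * L / mean_len_cM)
    if (n_seg == 0) return(NULL)
    lens <- stats::rexp(n_seg, 1 / mean_len_cM)
    lens <- lens[order(-lens)]   # place long segments first (fewer failures)
    chs <- sample.int(length(maps), n_seg, replace = TRUE, prob = L_c)
    chans <- sample.int(4L, n_seg, replace = TRUE)
    placed <- list()  # keyed by chrom-channel: matrix of (gs, ge)
    chrom <- character(n_seg); start <- end <- glen <- numeric(n_seg)
    hap1 <- hap2 <- integer(n_seg)
    w <- 0L
    for (j in seq_len(n_seg)) {
      m <- maps[[chs[j]]]
      Lc <- L_c[chs[j]]
      len <- min(lens[j], Lc)
      key <- paste0(chs[j], "_", chans[j])
      prev <- placed[[key]]
      for (try in 1:50) {
        gs <- if (Lc > len) stats::runif(1, 0, Lc - len) else 0
        ge <- gs + len
        ok <- is.null(prev) || all(ge <= prev[, 1] | gs >= prev[, 2])
        if (ok) {
          placed[[key]] <- rbind(prev, c(gs, ge))
          c0 <- m$cum_cM[1]
          bp_s <- invert_cM(m, c0 + gs); bp_e <- invert_cM(m, c0 + ge)
          if (bp_e > bp_s) {
            w <- w + 1L
            chrom[w] <- m$chrom; start[w] <- bp_s; end[w] <- bp_e
            glen[w] <- len
            hap1[w] <- channels[chans[j], 1]; hap2[w] <- channels[chans[j], 2]
          }
          break
        }
      }
    }
    if (w == 0L) return(NULL)
    idx <- seq_len(w)
    data.frame(id1 = id1, hap1 = hap1[idx], id2 = id2, hap2 = hap2[idx],
               chrom = chrom[idx], start = start[idx], end = end[idx],
               length_cM = glen[idx], stringsAsFactors = FALSE)
  }))
  per_pair <- per_pair[!vapply(per_pair, is.null, logical(1))]
  if (length(per_pair) == 0L)
    stop("no segments generated; increase n_pairs or reduce meioses")
  segs <- ibd_table(do.call(rbind, per_pair))
  truth <- data.frame(
    id1 = sprintf("P%05d_a", seq_len(n_pairs)),
    id2 = sprintf("P%05d_b", seq_len(n_pairs)),
    meioses = meioses, phi_expected = phi,
    degree_expected = classify_kinship_degree(phi),
    stringsAsFactors = FALSE)
  list(segments = segs, truth = truth)
}

#' Simulate a pair of local-ancestry tracks
#'
#' Track A is a per-haplotype Markov mosaic over `k` ancestry labels
#' (switching with `switch_prob` per site step).  Track B copies A, re-labels
#' each haplotype-site to a different label with probability `flip_prob`, and
#' swaps the two haplotype columns of each individual with probability 0.5
#' (phasing between runs is arbitrary, which the concordance metric must
#' absorb).  Marginal probability vectors are Dirichlet draws concentrated on
#' the called label (`alpha = prob_concentration` on the call, 1 elsewhere);
#' if the draw's maximum lands elsewhere it is swapped into the called slot so
#' the called-label-is-argmax invariant holds.
#'
#' @param n_ind number of individuals.
#' @param n_sites number of sites.
#' @param k number of ancestries (4 uses the PNS/AFR/EAS/EUR labels).
#' @param switch_prob per-site label switch probability.
#' @param flip_prob per-haplotype-site relabel probability in track B.
#' @param prob_concentration Dirichlet concentration on the called label.
#' @param seed RNG seed.
#' @param chrom chromosome label.
#' @return list with `a`, `b` (both `ancestry_track`) and `swapped`
#'   (logical per individual).
#' @export
simulate_ancestry_tracks <- function(n_ind, n_sites, k = 4,
                                     switch_prob = 0.01, flip_prob = 0.02,
                                     prob_concentration = 20, seed = 1L,
                                     chrom = "1") {
  anc <- if (k == 4) ANCESTRIES else paste0("A", seq_len(k))
  n_hap <- 2L * n_ind
  ids <- sprintf("I%04d", seq_len(n_ind))
  hap_names <- as.vector(rbind(paste0(ids, ".1"), paste0(ids, ".2")))
  pos <- seq_len(n_sites) * 1000
  draw_probs <- function(calls_mat) {
    total <- length(calls_mat)
    alpha <- matrix(1, total, k)
    alpha[cbind(seq_len(total), as.vector(calls_mat))] <- prob_concentration
    g <- matrix(stats::rgamma(total * k, shape = as.vector(alpha)), total, k)
    p <- g / rowSums(g)
    mx <- max.col(p)
    fix <- which(mx != as.vector(calls_mat))
    if (length(fix)) {
      ci <- as.vector(calls_mat)[fix]
      tmp <- p[cbind(fix, ci)]
      p[cbind(fix, ci)] <- p[cbind(fix, mx[fix])]
      p[cbind(fix, mx[fix])] <- tmp
    }
    array(p, c(nrow(calls_mat), ncol(calls_mat), k))
  }
  with_seed(seed, {
    calls_a <- matrix(0L, n_sites, n_hap, dimnames = list(NULL, hap_names))
    for (h in seq_len(n_hap)) {
      lab <- integer(n_sites)
      lab[1] <- sample.int(k, 1)
      sw <- which(stats::runif(n_sites - 1) < switch_prob)
      cur <- lab[1]; prev <- 1L
      for (s in c(sw, n_sites)) {
        lab[prev:s] <- cur
        cur <- ((cur - 1L + sample.int(k - 1L, 1)) %% k) + 1L
        prev <- s + 1L
      }
      calls_a[, h] <- lab
    }
    probs_a <- draw_probs(calls_a)
    calls_b <- calls_a
    flips <- which(matrix(stats::runif(n_sites * n_hap), n_sites) < flip_prob)
    if (length(flips)) {
      shift <- sample.int(k - 1L, length(flips), replace = TRUE)
      calls_b[flips] <- ((calls_b[flips] - 1L + shift) %% k) + 1L
    }
    probs_b <- draw_probs(calls_b)
    swapped <- stats::runif(n_ind) < 0.5
    for (i in which(swapped)) {
      c1 <- 2L * i - 1L; c2 <- 2L * i
      calls_b[, c(c1, c2)] <- calls_b[, c(c2, c1)]
      probs_b[, c(c1, c2), ] <- probs_b[, c(c2, c1), ]
    }
    list(a = ancestry_track(chrom, pos, calls_a, probs_a, anc),
         b = ancestry_track(chrom, pos, calls_b, probs_b, anc),
         swapped = swapped)
  })
}

#' Simulate phased haplotypes by Wright-Fisher forward simulation
#'
#' Discrete-generation Wright-Fisher population of `N_wf` diploids with
#' recombination: per meiosis, crossovers are placed by a Poisson process with
#' intensity given by the map's genetic length (expected `L_cM/100` per
#' meiosis).  Sites are seeded at initialization with independent derived
#' allele frequencies drawn from a 1/p density on `init_freq_range`; LD and
#' haplotype structure then accrue through drift and recombination.  An
#' optional additive selection coefficient `s` acts on the sweep allele
#' (diploid fitness `1 + s*g`).  If the sweep allele is lost the simulation is
#' restarted with a perturbed seed, up to `max_retries` times.
#'
#' @param map a `genetic_map` covering the simulated region.
#' @param n_hap number of haplotypes to sample at the end (`<= 2*N_wf`).
#' @param n_snp number of sites to seed (monomorphic sites in the final
#'   sample are dropped, so fewer may be returned).
#' @param N_wf diploid population size.
#' @param generations generations to evolve.
#' @param sweep `NULL`, or `list(position, s, start_freq)`.
#' @param seed RNG seed.
#' @param init_freq_range range for initial derived allele frequencies.
#' @param max_retries restarts allowed when the sweep allele is lost.
#' @return a `haplotype_matrix`; attribute `sweep_pos` holds the sweep SNP's
#'   position when a sweep was simulated and the site is still segregating.
#' @export
simulate_haplotypes <- function(map, n_hap, n_snp, N_wf = 150,
                                generations = 120, sweep = NULL, seed = 1L,
                                init_freq_range = c(0.05, 0.95),
                                max_retries = 10L) {
  if (n_hap > 2 * N_wf) stop("n_hap cannot exceed 2*N_wf")
  L_cM <- map_length_cM(map)
  span <- range(map$pos)
  for (r in 0:max_retries) {
    res <- with_seed(seed + r * 1000003L, {
      pos <- sort(unique(floor(stats::runif(n_snp, span[1], span[2]))))
      S <- length(pos)
      lo <- init_freq_range[1]; hi <- init_freq_range[2]
      p0 <- lo * (hi / lo)^stats::runif(S)
      H <- 2L * N_wf
      pop <- matrix(stats::rbinom(H * S, 1L, rep(p0, each = H)), nrow = H)
      sweep_idx <- NA_integer_
      if (!is.null(sweep)) {
        sweep_idx <- which.min(abs(pos - sweep$position))
        pop[, sweep_idx] <- 0L
        k0 <- max(1L, round(H * sweep$start_freq))
        pop[sample.int(H, k0), sweep_idx] <- 1L
      }
      gpos <- interpolate_cM(map, pos) - map$cum_cM[1]
      storage.mode(pop) <- "integer"
      wf <- .wf_core(pop, gpos, L_cM, as.integer(generations),
                     if (is.null(sweep)) -1L else sweep_idx - 1L,
                     if (is.null(sweep)) 0 else sweep$s)
      if (wf$lost) NULL else {
        pop <- wf$pop
        rows <- sample.int(H, n_hap)
        haps <- pop[rows, , drop = FALSE]
        cs <- colSums(haps)
        poly <- cs > 0L & cs < n_hap
        hm <- haplotype_matrix(haps[, poly, drop = FALSE], pos[poly],
                               chrom = map$chrom)
        if (!is.null(sweep) && poly[sweep_idx])
          attr(hm, "sweep_pos") <- pos[sweep_idx]
        hm
      }
    })
    if (!is.null(res)) {
      attr(res, "retries") <- r
      return(res)
    }
  }
  stop("sweep allele lost in every attempt; increase s, start_freq or retries")
}

#' Simulate paired imputation results with planted accuracy structure
#'
#' True genotypes are Binomial(2, MAF) with MAFs cycling through the given
#' bins; two dosage sets add Gaussian noise with bin-specific standard
#' deviations (`sigma_a`, `sigma_b`), clipped to [0, 2], so a planted accuracy
#' difference (or equality) between two "maps" is recoverable downstream.
#'
#' @param n_snp,n_ind table dimensions.
#' @param maf_bins bin edges for MAF (default the 0.5-1%, 1-5%, 5-50% bins).
#' @param sigma_a,sigma_b per-bin dosage noise SDs for the two sets.
#' @param seed RNG seed.
#' @return list with `maf`, `bin` (per SNP), `truth`, `dosage_a`, `dosage_b`
#'   (matrices `n_ind x n_snp`).
#' @export
simulate_imputation_results <- function(n_snp, n_ind,
                                        maf_bins = c(0.005, 0.01, 0.05, 0.5),
                                        sigma_a = c(0.4, 0.3, 0.2),
                                        sigma_b = sigma_a, seed = 1L) {
  nb <- length(maf_bins) - 1L
  stopifnot(length(sigma_a) == nb, length(sigma_b) == nb)
  with_seed(seed, {
    bin <- rep_len(seq_len(nb), n_snp)
    maf <- stats::runif(n_snp, maf_bins[bin], maf_bins[bin + 1L])
    truth <- matrix(stats::rbinom(n_ind * n_snp, 2L, rep(maf, each = n_ind)),
                    nrow = n_ind)
    noisy <- function(sig) {
      e <- matrix(stats::rnorm(n_ind * n_snp, 0, rep(sig[bin], each = n_ind)),
                  nrow = n_ind)
      d <- truth + e
      d[] <- pmin(2, pmax(0, d))
      d
    }
    list(maf = maf, bin = bin, truth = truth,
         dosage_a = noisy(sigma_a), dosage_b = noisy(sigma_b))
  })
}
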