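# Shared fixtures and independent brute-force oracles used across tests.
# Oracles are deliberately naive (per-bp scans, all-pairs comparisons,
# literal rule transcriptions) and never call the code paths they check.

uniform_map <- function(L, rate = 1, chrom = "1") {
  genetic_map(chrom, c(0, L), rate_cM_per_Mb = rate)
}

# brute-force tiling-window mask: literal transcription of the rule,
# evaluated window by window with a dumb count loop
oracle_density_mask <- function(markers, chrom_length, window_bp = 500000,
                                step_bp = 50000, min_markers = 15,
                                chrom = "1") {
  starts <- seq(0, chrom_length - 1, by = step_bp)
  flag_s <- numeric(0); flag_e <- numeric(0)
  for (s in starts) {
    e <- min(s + window_bp, chrom_length)
    w <- e - s
    thr <- if (w < window_bp) ceiling(min_markers * w / window_bp) else min_markers
    cnt <- sum(markers >= s & markers < e)
    if (cnt < thr) { flag_s <- c(flag_s, s); flag_e <- c(flag_e, e) }
  }
  mask_set(chrom, flag_s, flag_e)
}

# per-bp membership subtraction oracle (small coordinates only)
oracle_subtract_bp <- function(s, e, mask_s, mask_e) {
  bp <- seq(s, e - 1)
  masked <- rep(FALSE, length(bp))
  for (j in seq_along(mask_s))
    masked <- masked | (bp >= mask_s[j] & bp < mask_e[j])
  keep <- bp[!masked]
  if (length(keep) == 0) return(cbind(start = numeric(0), end = numeric(0)))
  brk <- c(0, which(diff(keep) > 1), length(keep))
  t(vapply(seq_len(length(brk) - 1), function(i) {
    c(keep[brk[i] + 1], keep[brk[i + 1]] + 1)
  }, numeric(2)))
}

# all-pairs EHH oracle: proportion of carrier pairs identical over the
# inclusive SNP span from the core to column j
oracle_ehh_at <- function(haps, carriers, core, j) {
  cols <- seq(min(core, j), max(core, j))
  k <- length(carriers)
  n_id <- 0
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    if (all(haps[carriers[a], cols] == haps[carriers[b], cols])) n_id <- n_id + 1
  }
  n_id / (k * (k - 1) / 2)
}

# literal one-direction iHH oracle: step outward, all-pairs EHH at every SNP,
# trapezoid against cM, stop after the first point below the cutoff
oracle_ihh_side <- function(haps, carriers, core, step, gpos, pos,
                            cutoff = 0.05, max_gap = 200000) {
  S <- length(pos)
  prev_g <- gpos[core]; prev_p <- pos[core]; prev_e <- 1
  area <- 0
  j <- core
  repeat {
    j <- j + step
    if (j < 1 || j > S) return(list(ihh = NA, reason = "boundary"))
    if (abs(pos[j] - prev_p) > max_gap) return(list(ihh = NA, reason = "gap"))
    e <- oracle_ehh_at(haps, carriers, core, j)
    area <- area + 0.5 * (prev_e + e) * abs(gpos[j] - prev_g)
    prev_g <- gpos[j]; prev_p <- pos[j]; prev_e <- e
    if (e < cutoff) return(list(ihh = area, reason = "ok"))
  }
}

oracle_ihs_at <- function(hm, map, s, cutoff = 0.05, max_gap = 200000) {
  gpos <- interpolate_cM(map, hm$pos)
  vals <- numeric(2)
  for (al in 1:0) {
    carriers <- which(hm$haps[, s] == al)
    l <- oracle_ihh_side(hm$haps, carriers, s, -1, gpos, hm$pos, cutoff, max_gap)
    r <- oracle_ihh_side(hm$haps, carriers, s, 1, gpos, hm$pos, cutoff, max_gap)
    if (is.na(l$ihh) || is.na(r$ihh))
      return(list(ihs = NA, reason = c(l$reason, r$reason)))
    vals[2 - al] <- l$ihh + r$ihh   # vals[1] derived, vals[2] ancestral
  }
  list(ihs = log(vals[2] / vals[1]), ihh_derived = vals[1],
       ihh_ancestral = vals[2], reason = "ok")
}

# hard-call LAI concordance oracle: literal per-site, per-individual pairing
oracle_lai_hard <- function(a, b) {
  n_ind <- ncol(a$calls) / 2
  agree <- 0; total <- 0
  for (i in seq_len(n_ind)) {
    c1 <- 2 * i - 1; c2 <- 2 * i
    for (s in seq_along(a$pos)) {
      id <- (a$calls[s, c1] == b$calls[s, c1]) + (a$calls[s, c2] == b$calls[s, c2])
      sw <- (a$calls[s, c1] == b$calls[s, c2]) + (a$calls[s, c2] == b$calls[s, c1])
      agree <- agree + max(id, sw)
      total <- total + 2
    }
  }
  100 * agree / total
}

# random small ancestry track (valid probabilities, argmax = call)
random_track <- function(n_ind, n_sites, seed, k = 4) {
  set.seed(seed)
  hap_names <- as.vector(rbind(paste0("I", seq_len(n_ind), ".1"),
                               paste0("I", seq_len(n_ind), ".2")))
  calls <- matrix(sample.int(k, n_sites * 2 * n_ind, replace = TRUE),
                  n_sites, 2 * n_ind, dimnames = list(NULL, hap_names))
  probs <- array(stats::runif(n_sites * 2 * n_ind * k, 0.01, 0.2),
                 c(n_sites, 2 * n_ind, k))
  for (s in seq_len(n_sites)) for (h in seq_len(2 * n_ind))
    probs[s, h, calls[s, h]] <- 1
  probs <- probs / array(rep(apply(probs, c(1, 2), sum), k),
                         dim(probs))
  ancestry_track("1", seq_len(n_sites) * 1000, calls, probs,
                 if (k == 4) c("PNS", "AFR", "EAS", "EUR") else paste0("A", 1:k))
}

swap_individual <- function(track, inds) {
  for (i in inds) {
    c1 <- 2 * i - 1; c2 <- 2 * i
    track$calls[, c(c1, c2)] <- track$calls[, c(c2, c1)]
    track$probs[, c(c1, c2), ] <- track$probs[, c(c2, c1), ]
  }
  track
}

# small deterministic haplotype matrix fixture
random_hm <- function(n_hap, n_snp, seed, L = NULL) {
  set.seed(seed)
  pos <- sort(sample.int(L %||% (n_snp * 2000), n_snp))
  repeat {
    haps <- matrix(rbinom(n_hap * n_snp, 1, runif(n_snp, 0.2, 0.8)),
                   n_hap, n_snp, byrow = TRUE)
    cs <- colSums(haps)
    if (all(cs > 0 & cs < n_hap)) break
  }
  haplotype_matrix(haps, pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
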