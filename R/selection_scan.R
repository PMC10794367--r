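# EHH / iHS selection scan under a supplied genetic map, frequency-bin
# normalization, cross-map discordance at |Z| thresholds, and a same-map
# permutation null for the expected between-run discordance.

#' Construct a phased haplotype matrix
#'
#' @param haps `n_hap x n_snp` matrix of phased alleles in {0, 1}
#'   (1 = derived).
#' @param pos SNP positions (bp, strictly increasing).
#' @param chrom chromosome label.
#' @return a `haplotype_matrix`.
#' @export
haplotype_matrix <- function(haps, pos, chrom = "1") {
  if (!is.matrix(haps)) stop("haps must be a matrix")
  if (ncol(haps) != length(pos)) stop("one position per SNP column required")
  if (any(diff(pos) <= 0)) stop("positions must be strictly increasing")
  if (!all(haps %in% c(0L, 1L))) stop("alleles must be 0/1")
  storage.mode(haps) <- "integer"
  structure(list(haps = haps, pos = as.numeric(pos),
                 chrom = norm_chrom(chrom)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes x %d SNPs on chr%s\n",
              nrow(x$haps), ncol(x$haps), x$chrom))
  invisible(x)
}

#' Subset haplotypes, dropping sites monomorphic in the subset
#'
#' @param hm a `haplotype_matrix`.
#' @param rows haplotype (row) indices to keep.
#' @return a `haplotype_matrix`.
#' @export
subset_haplotypes <- function(hm, rows) {
  h <- hm$haps[rows, , drop = FALSE]
  cs <- colSums(h)
  poly <- cs > 0L & cs < nrow(h)
  haplotype_matrix(h[, poly, drop = FALSE], hm$pos[poly], hm$chrom)
}

# one-direction EHH walk over carrier haplotypes; refines a grouping of the
# carriers SNP by SNP and returns pair-homozygosity at each step.  Carriers
# whose group becomes a singleton contribute nothing downstream and are
# dropped, so walks over decayed regions cost almost nothing.
# Returns up to the step where EHH < stop_below (that step included) or 0.
ehh_walk <- function(haps, carriers, core, step, n_snp, stop_below = 0) {
  k0 <- length(carriers)
  tot <- k0 * (k0 - 1) / 2
  act <- carriers
  g <- rep(1L, k0)
  cap <- 256L
  out_idx <- integer(cap); out_ehh <- numeric(cap)
  n_out <- 0L
  j <- core
  repeat {
    j <- j + step
    if (j < 1L || j > n_snp) break
    key <- g * 2L + haps[act, j]
    g <- match(key, key[!duplicated(key)])
    sz <- tabulate(g)
    cur <- (sum(sz * sz) - length(act)) / (2 * tot)
    n_out <- n_out + 1L
    if (n_out > cap) {
      cap <- cap * 2L
      out_idx <- c(out_idx, integer(cap / 2L))
      out_ehh <- c(out_ehh, numeric(cap / 2L))
    }
    out_idx[n_out] <- j; out_ehh[n_out] <- cur
    if (cur < stop_below || cur == 0) break
    keep <- sz[g] > 1L
    if (!all(keep)) {
      act <- act[keep]
      gk <- g[keep]
      g <- match(gk, gk[!duplicated(gk)])
    }
  }
  list(idx = out_idx[seq_len(n_out)], ehh = out_ehh[seq_len(n_out)])
}

#' Extended haplotype homozygosity around a core SNP
#'
#' EHH at a flanking SNP is the proportion of carrier haplotype pairs that
#' are identical over every SNP from the core to that SNP (inclusive);
#' EHH = 1 at the core and is non-increasing outward.
#'
#' @param hm a `haplotype_matrix`.
#' @param core_snp core SNP column index.
#' @param core_allele 0 or 1; carriers of this allele at the core define the
#'   haplotype set.
#' @return list with `left` and `right` data frames (`idx`, `pos`, `ehh`),
#'   each starting at the core (EHH = 1) and extending to the chromosome end.
#' @export
ehh <- function(hm, core_snp, core_allele) {
  carriers <- which(hm$haps[, core_snp] == core_allele)
  if (length(carriers) < 2L) stop("need >= 2 carrier haplotypes")
  S <- ncol(hm$haps)
  side <- function(step) {
    w <- ehh_walk(hm$haps, carriers, core_snp, step, S, stop_below = 0)
    # once EHH hits 0 it stays 0 to the chromosome end
    idx <- w$idx; e <- w$ehh
    last <- if (length(idx)) idx[length(idx)] else core_snp
    rest <- if (step > 0 && last < S) seq(last + 1L, S)
    else if (step < 0 && last > 1L) seq(last - 1L, 1L) else integer(0)
    idx <- c(core_snp, idx, rest)
    e <- c(1, e, rep(0, length(rest)))
    data.frame(idx = idx, pos = hm$pos[idx], ehh = e)
  }
  list(left = side(-1L), right = side(1L))
}

#' Unstandardized integrated haplotype scores
#'
#' For each candidate SNP, the EHH curve of the derived- and
#' ancestral-allele carriers is integrated against genetic distance (cM via
#' [interpolate_cM()]) in both directions, truncated where EHH drops below
#' `ehh_cutoff`; the unstandardized score is `ln(iHH_ancestral /
#' iHH_derived)`.  A SNP is flagged (score `NA`, with a reason) if the
#' truncation hits a chromosome end before the cutoff, a physical gap larger
#' than `max_gap_bp` is crossed, either allele has fewer than 2 carriers, or
#' either integral is zero.
#'
#' @param hm a `haplotype_matrix` (1 = derived).
#' @param map a `genetic_map` covering all SNP positions.
#' @param ehh_cutoff stop integrating when EHH falls below this value.
#' @param max_gap_bp largest physical gap the integration may cross.
#' @param min_maf skip SNPs with minor allele frequency below this.
#' @return data frame of class `ihs_records`: `pos`, `freq` (derived),
#'   `ihh_derived`, `ihh_ancestral`, `ihs`, `ok`, `reason`.
#' @export
ihs_unstandardized <- function(hm, map, ehh_cutoff = 0.05,
                               max_gap_bp = 200000, min_maf = 0.05) {
  if (min(hm$pos) < min(map$pos) || max(hm$pos) > max(map$pos))
    stop("map does not cover all SNP positions")
  n <- nrow(hm$haps)
  S <- ncol(hm$haps)
  gpos <- interpolate_cM(map, hm$pos)
  cs <- colSums(hm$haps)
  freq <- cs / n
  # integer-count MAF so the candidate set is exactly allele-label symmetric
  cand <- which(pmin(cs, n - cs) >= min_maf * n)
  res <- .ihs_core(hm$haps, hm$pos, gpos, cand, ehh_cutoff, max_gap_bp)
  reason <- c("ok", "boundary", "gap", "carriers")[res$code + 1L]
  ihs <- rep(NA_real_, length(cand))
  ok <- res$code == 0L & !is.na(res$ihh_derived) &
    res$ihh_derived > 0 & res$ihh_ancestral > 0
  zero <- res$code == 0L & !ok
  reason[zero] <- "zero_ihh"
  ihs[ok] <- log(res$ihh_ancestral[ok] / res$ihh_derived[ok])
  out <- data.frame(pos = hm$pos[cand], freq = freq[cand],
                    ihh_derived = res$ihh_derived,
                    ihh_ancestral = res$ihh_ancestral,
                    ihs = ihs, ok = ok, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("ihs_records", "data.frame")
  out
}

#' Normalize iHS within derived-allele-frequency bins
#'
#' SNPs with a defined unstandardized score are binned into `n_freq_bins`
#' equal-width derived-frequency bins over (0, 1); bins with fewer than 2
#' SNPs (or zero score variance) are merged with their nearest populated
#' neighbour; `Z = (iHS - bin mean) / bin SD`.  Flagged SNPs keep `z = NA`
#' and the dropped count is attached as attribute `n_excluded`.
#'
#' @param records an `ihs_records` data frame.
#' @param n_freq_bins number of equal-width frequency bins.
#' @return the records with a `z` column, classed `score_track` as well (so
#'   [write_score_track()] applies).
#' @export
normalize_ihs <- function(records, n_freq_bins = 50) {
  use <- records$ok & is.finite(records$ihs)
  z <- rep(NA_real_, nrow(records))
  if (sum(use) >= 2L) {
    bin <- pmin(n_freq_bins, pmax(1L, ceiling(records$freq * n_freq_bins)))
    bin[!use] <- NA_integer_
    repeat {
      cnt <- table(bin)
      sds <- tapply(records$ihs[use], bin[use], stats::sd)
      bad <- names(cnt)[cnt < 2 | (names(cnt) %in% names(sds) &
                                     sds[names(cnt)] == 0)]
      bad <- bad[!is.na(bad)]
      if (length(bad) == 0L || length(cnt) == 1L) break
      b <- as.integer(bad[1])
      others <- as.integer(setdiff(names(cnt), bad[1]))
      if (length(others) == 0L) others <- as.integer(setdiff(names(cnt), NA))
      tgt <- others[which.min(abs(others - b))]
      bin[!is.na(bin) & bin == b] <- tgt
    }
    mu <- tapply(records$ihs[use], bin[use], mean)
    sd_ <- tapply(records$ihs[use], bin[use], stats::sd)
    bk <- as.character(bin[use])
    zz <- (records$ihs[use] - mu[bk]) / sd_[bk]
    zz[!is.finite(zz)] <- NA_real_
    z[use] <- zz
  }
  records$z <- z
  attr(records, "n_excluded") <- sum(!use)
  class(records) <- c("score_track", "ihs_records", "data.frame")
  records
}

#' Run the full iHS scan: unstandardized scores plus normalization
#'
#' Convenience wrapper around [ihs_unstandardized()] and [normalize_ihs()].
#'
#' @inheritParams ihs_unstandardized
#' @inheritParams normalize_ihs
#' @return a `score_track` data frame with `pos`, `freq`, `ihs`, `z` (and
#'   the diagnostic columns of `ihs_records`).
#' @export
ihs_scan <- function(hm, map, ehh_cutoff = 0.05, max_gap_bp = 200000,
                     min_maf = 0.05, n_freq_bins = 50) {
  normalize_ihs(ihs_unstandardized(hm, map, ehh_cutoff = ehh_cutoff,
                                   max_gap_bp = max_gap_bp,
                                   min_maf = min_maf),
                n_freq_bins = n_freq_bins)
}

#' Cross-map discordant SNPs at |Z| thresholds
#'
#' SNPs scored under two maps whose normalized score is significant under one
#' map (`|Z| > hi`) but attenuated under the other (`|Z| < lo`), in both
#' directions, grouped into loci by single-linkage clustering at
#' `cluster_bp`.
#'
#' @param za,zb score tables (with `pos` and `z`) from the two maps.
#' @param hi,lo significance and attenuation thresholds (defaults 4 and 2).
#' @param cluster_bp clustering distance for locus grouping.
#' @return list with `a_not_b`, `b_not_a` (data frames `pos`, `z_a`, `z_b`,
#'   `locus`), the counts `n_a_not_b`, `n_b_not_a`, and `n_total`.
#' @export
cross_map_discordance <- function(za, zb, hi = 4, lo = 2, cluster_bp = 1e5) {
  m <- merge(data.frame(pos = za$pos, z_a = za$z),
             data.frame(pos = zb$pos, z_b = zb$z), by = "pos")
  m <- m[is.finite(m$z_a) & is.finite(m$z_b), , drop = FALSE]
  pick <- function(zx, zy) {
    d <- m[abs(zx) > hi & abs(zy) < lo, c("pos", "z_a", "z_b"), drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    d$locus <- if (nrow(d)) cumsum(c(1, diff(d$pos) > cluster_bp)) else integer(0)
    rownames(d) <- NULL
    d
  }
  a_not_b <- pick(m$z_a, m$z_b)
  b_not_a <- pick(m$z_b, m$z_a)
  list(a_not_b = a_not_b, b_not_a = b_not_a,
       n_a_not_b = nrow(a_not_b), n_b_not_a = nrow(b_not_a),
       n_total = nrow(a_not_b) + nrow(b_not_a))
}

#' Same-map permutation null for cross-run |Z| discordance
#'
#' Between-run variability baseline: per permutation, two disjoint random
#' subsets of the haplotypes are scored and normalized independently under
#' the *same* map, and SNPs meeting the discordance criterion (significant in
#' one subset, attenuated in the other, both directions) are counted.  This
#' subsample re-analysis is one reading of a "permutations using the same
#' map" null; see the methods vignette.
#'
#' @param hm a `haplotype_matrix`.
#' @param map the analysis `genetic_map`.
#' @param n_perm number of permutations.
#' @param subset_size haplotypes per subset (`2*subset_size <= n_hap`).
#' @param seed RNG seed.
#' @param hi,lo discordance thresholds.
#' @param force_identical debugging switch: use the same subset twice (every
#'   count is then 0 by construction).
#' @inheritParams ihs_scan
#' @return list with `counts` (length `n_perm`) and `mean`.
#' @export
permutation_null <- function(hm, map, n_perm = 500, subset_size, seed = 1L,
                             hi = 4, lo = 2, ehh_cutoff = 0.05,
                             max_gap_bp = 200000, min_maf = 0.05,
                             n_freq_bins = 50, force_identical = FALSE) {
  n <- nrow(hm$haps)
  if (!force_identical && 2 * subset_size > n)
    stop("2*subset_size exceeds the number of haplotypes")
  counts <- integer(n_perm)
  if (n_perm == 0L) return(list(counts = counts, mean = NaN))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      pick <- sample.int(n, if (force_identical) subset_size
                         else 2L * subset_size)
      s1 <- pick[seq_len(subset_size)]
      s2 <- if (force_identical) s1 else pick[-seq_len(subset_size)]
      z1 <- ihs_scan(subset_haplotypes(hm, s1), map, ehh_cutoff = ehh_cutoff,
                     max_gap_bp = max_gap_bp, min_maf = min_maf,
                     n_freq_bins = n_freq_bins)
      z2 <- ihs_scan(subset_haplotypes(hm, s2), map, ehh_cutoff = ehh_cutoff,
                     max_gap_bp = max_gap_bp, min_maf = min_maf,
                     n_freq_bins = n_freq_bins)
      counts[p] <- cross_map_discordance(z1, z2, hi = hi, lo = lo)$n_total
    }
  })
  list(counts = counts, mean = mean(counts))
}
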