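# Assembling windowed population-scaled estimates into chromosome-scale maps:
# overlap-aware stitching, 4Ne estimation by regression against a reference
# map, rescaling rho to cM/Mb, and fixed-resolution binning.

#' Construct a rho track
#'
#' A genome-contiguous track of per-interval population-scaled recombination
#' rates: `snp_pos` (strictly increasing bp) and `rho_per_kb` (one value per
#' interval between consecutive SNPs).
#'
#' @param chrom chromosome label.
#' @param snp_pos SNP positions (0-based bp).
#' @param rho_per_kb per-interval rho (per kb), `length(snp_pos) - 1`.
#' @return a `rho_track`.
#' @export
rho_track <- function(chrom, snp_pos, rho_per_kb) {
  snp_pos <- as.numeric(snp_pos)
  if (any(diff(snp_pos) <= 0)) stop("SNP positions must be strictly increasing")
  if (length(rho_per_kb) != length(snp_pos) - 1L)
    stop("rho_per_kb must have one value per SNP interval")
  if (any(rho_per_kb < 0)) stop("rho must be >= 0")
  structure(list(chrom = norm_chrom(chrom), snp_pos = snp_pos,
                 rho_per_kb = as.numeric(rho_per_kb)),
            class = "rho_track")
}

#' Stitch overlapping estimation windows into one contiguous track
#'
#' Adjacent windows share their declared overlapping SNPs; the distal half of
#' each overlap is discarded: for an overlap of `o` shared SNPs the left
#' window contributes per-interval estimates up to the `floor(o/2)`-th shared
#' SNP and the right window contributes from there on (for `o = 1` the single
#' shared SNP is the cut).  Every input interval is covered exactly once and
#' non-overlap intervals pass through unchanged.
#'
#' @param windows a `rho_window_set`.
#' @return a `rho_track`.
#' @export
stitch_windows <- function(windows) {
  ws <- windows$windows
  if (length(ws) == 0L) stop("no windows to stitch")
  out_pos <- ws[[1]]$snp_pos
  out_rho <- ws[[1]]$rho_per_kb
  if (length(ws) > 1L) {
    for (i in 2L:length(ws)) {
      left <- ws[[i - 1L]]; right <- ws[[i]]
      o <- right$n_overlap_left
      if (o != left$n_overlap_right)
        stop("inconsistent declared overlap between windows ",
             i - 1L, " and ", i)
      if (o < 1L) stop("adjacent windows share no SNPs")
      shared_l <- utils::tail(left$snp_pos, o)
      shared_r <- utils::head(right$snp_pos, o)
      div <- which(shared_l != shared_r)
      if (length(div))
        stop(sprintf("overlap positions diverge between windows %d and %d at position %s (vs %s)",
                     i - 1L, i, fmt_num(shared_l[div[1]]), fmt_num(shared_r[div[1]])))
      k <- max(floor(o / 2), 1L)
      cut_pos <- shared_l[k]
      keep_left <- out_pos <= cut_pos
      out_pos <- out_pos[keep_left]
      out_rho <- out_rho[seq_len(sum(keep_left) - 1L)]
      idx_cut <- match_pos(cut_pos, right$snp_pos)
      out_pos <- c(out_pos, right$snp_pos[-seq_len(idx_cut)])
      out_rho <- c(out_rho,
                   right$rho_per_kb[idx_cut:length(right$rho_per_kb)])
    }
  }
  rho_track(windows$chrom, out_pos, out_rho)
}

#' Estimate 4Ne by regressing rho on a reference map's rates
#'
#' The reference map's rate is first projected onto the rho track's SNP
#' intervals (bp-weighted mean per interval), then both tracks are aggregated
#' into fixed windows (`window_bp`, default 5 Mb, anchored at 0) as
#' bp-weighted means over unmasked bp, and the window means of rho (per bp)
#' are regressed on the window means of r (per bp).  Because rho = 4*Ne*r, the
#' slope of a no-intercept ordinary least squares fit is the dimensionless
#' 4Ne.
#'
#' @param rho a `rho_track`.
#' @param reference a `genetic_map` overlapping the track; SNP intervals
#'   outside the reference's span are dropped.
#' @param window_bp aggregation window (bp).
#' @param mask optional `mask_set`; masked bp are excluded from the window
#'   means.
#' @param intercept fit with an intercept instead (the slope is still
#'   reported as `fourNe`).
#' @return a list of class `ne_fit`: `fourNe` (slope), `n_windows`,
#'   `r_squared`, `intercept`.
#' @export
estimate_fourNe <- function(rho, reference, window_bp = 5e6, mask = NULL,
                            intercept = FALSE) {
  s <- rho$snp_pos[-length(rho$snp_pos)]
  e <- rho$snp_pos[-1]
  y <- rho$rho_per_kb / 1000                         # rho per bp
  ref_span <- range(reference$pos)
  keep <- s >= ref_span[1] & e <= ref_span[2]
  s <- s[keep]; e <- e[keep]; y <- y[keep]
  if (length(s) == 0L) stop("rho track and reference map do not overlap")
  gg <- interpolate_cM(reference, c(s, e))
  x <- (gg[seq_along(s) + length(s)] - gg[seq_along(s)]) / (e - s) / 100  # r per bp
  w <- e - s
  mk <- mask_for_chrom(mask, rho$chrom)
  if (length(mk$start)) w <- w - overlap_bp_vec(s, e, mk$start, mk$end)
  # split interval weights at window edges; x and y are constant per interval
  sp <- split_at_bins(s, e, seq_along(s), window_bp)
  frac <- (sp$end - sp$start) / (e[sp$value] - s[sp$value])
  ww <- w[sp$value] * frac
  xw <- tapply(x[sp$value] * ww, sp$bin, sum) / tapply(ww, sp$bin, sum)
  yw <- tapply(y[sp$value] * ww, sp$bin, sum) / tapply(ww, sp$bin, sum)
  ok <- is.finite(xw) & is.finite(yw)
  xw <- xw[ok]; yw <- yw[ok]
  if (length(xw) < 2L) stop("need at least 2 aggregation windows")
  if (all(xw == 0)) stop("reference rate is zero in every window")
  if (intercept) {
    slope <- stats::cov(xw, yw) / stats::var(xw)
    alpha <- mean(yw) - slope * mean(xw)
    rss <- sum((yw - alpha - slope * xw)^2)
    tss <- sum((yw - mean(yw))^2)
  } else {
    slope <- sum(xw * yw) / sum(xw^2)
    alpha <- 0
    rss <- sum((yw - slope * xw)^2)
    tss <- sum(yw^2)            # no-intercept convention
  }
  if (slope <= 0) stop("non-positive 4Ne estimate")
  structure(list(fourNe = slope, n_windows = length(xw),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 intercept = alpha),
            class = "ne_fit")
}

#' Rescale a rho track to a genetic map in cM/Mb
#'
#' Per interval, `r = rho / 4Ne` (per bp), i.e. `rate_cM_per_Mb =
#' rho_per_kb * 1e5 / fourNe`; cumulative cM starts at 0 at the first SNP.
#'
#' @param rho a `rho_track`.
#' @param fit an `ne_fit` (or a bare positive number taken as 4Ne).
#' @return a `genetic_map`.
#' @export
rescale_to_cM <- function(rho, fit) {
  fourNe <- if (inherits(fit, "ne_fit")) fit$fourNe else as.numeric(fit)
  if (fourNe <= 0) stop("4Ne must be positive")
  genetic_map(rho$chrom, rho$snp_pos,
              rate_cM_per_Mb = rho$rho_per_kb * 1e5 / fourNe)
}

#' Bin a map or rho track at a fixed resolution
#'
#' Non-overlapping bins of `resolution_bp`, anchored at coordinate 0 for
#' cross-population comparability.  Each bin's value is the bp-weighted mean
#' rate over its unmasked, covered bp; bins with no unmasked coverage, or more
#' than `max_masked_frac` of their width masked, are flagged missing.
#'
#' @param x a `genetic_map` (values in cM/Mb) or `rho_track` (values in
#'   rho/kb).
#' @param resolution_bp bin width, e.g. 1e4, 5e4, 1e5, 5e5, 1e6, 5e6.
#' @param mask optional `mask_set`.
#' @param max_masked_frac bins masked beyond this fraction are missing.
#' @return a data frame of class `binned_map` with columns `bin_start`,
#'   `mean_rate`, `missing`; attributes `resolution_bp` and `chrom`.
#' @export
bin_map <- function(x, resolution_bp, mask = NULL, max_masked_frac = 0.9) {
  if (inherits(x, "genetic_map")) {
    s <- x$pos[-length(x$pos)]; e <- x$pos[-1]; v <- x$rate_cM_per_Mb
    chrom <- x$chrom
  } else if (inherits(x, "rho_track")) {
    s <- x$snp_pos[-length(x$snp_pos)]; e <- x$snp_pos[-1]; v <- x$rho_per_kb
    chrom <- x$chrom
  } else stop("x must be a genetic_map or rho_track")
  n_bins <- as.integer(ceiling(max(e) / resolution_bp))
  mk <- mask_for_chrom(mask, chrom)
  # remove masked bp from the intervals, then split at bin edges
  if (length(mk$start)) {
    parts_s <- parts_e <- parts_v <- vector("list", length(s))
    for (i in seq_along(s)) {
      sub <- subtract_one_interval(s[i], e[i], mk$start, mk$end)
      parts_s[[i]] <- sub$start; parts_e[[i]] <- sub$end
      parts_v[[i]] <- rep(v[i], length(sub$start))
    }
    s <- unlist(parts_s); e <- unlist(parts_e); v <- unlist(parts_v)
  }
  mean_rate <- rep(NA_real_, n_bins)
  covered <- numeric(n_bins)
  if (length(s)) {
    sp <- split_at_bins(s, e, v, resolution_bp)
    bp <- sp$end - sp$start
    sums <- tapply(sp$value * bp, sp$bin, sum)
    wts <- tapply(bp, sp$bin, sum)
    idx <- as.integer(names(wts)) + 1L
    mean_rate[idx] <- sums / wts
    covered[idx] <- wts
  }
  masked_bp <- numeric(n_bins)
  if (length(mk$start)) {
    msp <- split_at_bins(mk$start, pmin(mk$end, n_bins * resolution_bp),
                         rep(1, length(mk$start)), resolution_bp)
    if (nrow(msp)) {
      mb <- tapply(msp$end - msp$start, msp$bin, sum)
      masked_bp[as.integer(names(mb)) + 1L] <- mb
    }
  }
  missing <- covered == 0 | masked_bp / resolution_bp > max_masked_frac
  mean_rate[missing] <- NA_real_
  out <- data.frame(bin_start = (seq_len(n_bins) - 1L) * resolution_bp,
                    mean_rate = mean_rate, missing = missing)
  attr(out, "resolution_bp") <- resolution_bp
  attr(out, "chrom") <- chrom
  class(out) <- c("binned_map", "data.frame")
  out
}
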