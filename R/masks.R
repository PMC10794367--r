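# Marker-density analysis masks: construction from tiling-window marker
# counts, application to genetic maps (zeroing genetic distance), and interval
# subtraction for segment data.

#' Build a low-marker-density analysis mask
#'
#' Tiling windows of `window_bp` (default 500 kb), shifted in `step_bp`
#' (default 50 kb) increments, are flagged when they contain fewer than
#' `min_markers` markers; flagged windows are unioned into a mask of regions
#' whose inferred recombination rates are considered unreliable.  Window
#' membership is half-open `[s, s + window_bp)`.  A trailing partial window of
#' width `w < window_bp` is evaluated against the proportionally scaled
#' threshold `ceiling(min_markers * w / window_bp)` so chromosome ends are not
#' masked automatically.
#'
#' @param marker_positions sorted marker positions (bp, 0-based).
#' @param chrom_length chromosome length in bp (`>= window_bp`).
#' @param window_bp tiling window length (bp).
#' @param step_bp window shift (bp).
#' @param min_markers flag a full window containing fewer than this many
#'   markers.
#' @param chrom chromosome label for the resulting mask.
#' @param granularity `"window"` masks the whole flagged window (default,
#'   conservative); `"step"` masks only the window's leading `step_bp`.
#' @return a `mask_set`.
#' @export
build_density_mask <- function(marker_positions, chrom_length,
                               window_bp = 500000, step_bp = 50000,
                               min_markers = 15, chrom = "1",
                               granularity = c("window", "step")) {
  granularity <- match.arg(granularity)
  if (is.unsorted(marker_positions, strictly = FALSE))
    stop("marker positions must be sorted")
  if (chrom_length < window_bp)
    stop("chrom_length must be at least window_bp")
  m <- as.numeric(marker_positions)
  starts <- seq(0, chrom_length - 1, by = step_bp)
  ends <- pmin(starts + window_bp, chrom_length)
  width <- ends - starts
  # markers in [s, e): count of m < e minus count of m < s
  cnt <- findInterval(ends - 0.5, m) - findInterval(starts - 0.5, m)
  thr <- ifelse(width < window_bp,
                ceiling(min_markers * width / window_bp), min_markers)
  flag <- cnt < thr
  if (!any(flag)) return(mask_set())
  if (granularity == "window") {
    mask_set(chrom, starts[flag], ends[flag])
  } else {
    mask_set(chrom, starts[flag], pmin(starts[flag] + step_bp, chrom_length))
  }
}

#' Zero the genetic distance of a map across masked regions
#'
#' Every map interval has its genetic length reduced in proportion to the
#' masked bp it overlaps (fully masked intervals drop to zero rate);
#' cumulative cM is recomputed, so the total map length decreases by exactly
#' the genetic length that fell inside the mask.  Map positions are unchanged.
#'
#' @param map a `genetic_map`.
#' @param mask a `mask_set` (intervals on other chromosomes are ignored).
#' @return a `genetic_map`.
#' @export
apply_mask_to_map <- function(map, mask) {
  mk <- mask_for_chrom(mask, map$chrom)
  if (length(mk$start) == 0L) return(map)
  s <- map$pos[-length(map$pos)]
  e <- map$pos[-1]
  masked <- overlap_bp_vec(s, e, mk$start, mk$end)
  keep_frac <- 1 - masked / (e - s)
  genetic_map(map$chrom, map$pos,
              cum_cM = map$cum_cM[1] +
                c(0, cumsum(diff(map$cum_cM) * keep_frac)))
}

#' Subtract masked regions from a set of intervals
#'
#' Standard half-open interval subtraction: pieces of each input interval that
#' overlap the mask are removed, splitting intervals that span a masked
#' region.  All other columns of `intervals` are carried through to the
#' surviving pieces.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end` (plus
#'   arbitrary extra columns), 0-based half-open.
#' @param mask a `mask_set`.
#' @return data frame of the same shape; an `ibd_table` input stays an
#'   `ibd_table`.
#' @export
mask_intersect <- function(intervals, mask) {
  was_ibd <- inherits(intervals, "ibd_table")
  df <- as.data.frame(intervals)
  if (nrow(df) == 0L || is.null(mask) || nrow(mask) == 0L)
    return(intervals)
  pieces <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    mk <- mask_for_chrom(mask, df$chrom[i])
    sub <- subtract_one_interval(df$start[i], df$end[i], mk$start, mk$end)
    if (length(sub$start) == 0L) next
    row <- df[rep(i, length(sub$start)), , drop = FALSE]
    row$start <- sub$start
    row$end <- sub$end
    pieces[[i]] <- row
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  out <- if (length(pieces)) do.call(rbind, pieces) else df[0, , drop = FALSE]
  rownames(out) <- NULL
  if (was_ibd) class(out) <- c("ibd_table", "data.frame")
  out
}
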