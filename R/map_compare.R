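# Comparing recombination landscapes between populations: multi-resolution
# Pearson correlations of binned rates and sharing of top-percentile hotspot
# windows, both mask-aware through bin_map's missing flags.

#' Pearson correlation between two binned maps
#'
#' Computed over jointly non-missing bins only (masked or uncovered bins are
#' excluded pairwise, never imputed).
#'
#' @param a,b `binned_map`s at the same resolution.
#' @return the Pearson correlation coefficient.
#' @export
correlate_maps <- function(a, b) {
  if (attr(a, "resolution_bp") != attr(b, "resolution_bp"))
    stop("binned maps have different resolutions")
  n <- min(nrow(a), nrow(b))
  joint <- !a$missing[seq_len(n)] & !b$missing[seq_len(n)]
  if (sum(joint) < 3L) stop("fewer than 3 jointly non-missing bins")
  x <- a$mean_rate[seq_len(n)][joint]
  y <- b$mean_rate[seq_len(n)][joint]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the maps over the joint bins")
  stats::cor(x, y)
}

#' Call recombination hotspots as top-percentile bins
#'
#' Hotspots are the `ceiling(q * n)` non-missing bins with the highest mean
#' rate, where `n` is the number of non-missing bins.  Ties at the threshold
#' are broken in favour of the lower bin index.
#'
#' @param binned a `binned_map` (conventionally at 50 kb resolution).
#' @param q quantile, e.g. 0.01 (top 1\%) or 0.10 (top 10\%).
#' @return a list of class `hotspot_set`: `resolution_bp`, `q`, `bins`
#'   (sorted bin indices, 1-based), `n_bins` (non-missing universe size).
#' @export
call_hotspots <- function(binned, q) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  nm <- which(!binned$missing)
  if (length(nm) == 0L) stop("no non-missing bins")
  n_hot <- as.integer(ceiling(q * length(nm)))
  ord <- nm[order(-binned$mean_rate[nm], nm)]
  structure(list(resolution_bp = attr(binned, "resolution_bp"), q = q,
                 bins = sort(ord[seq_len(n_hot)]), n_bins = length(nm)),
            class = "hotspot_set")
}

#' Proportion of shared hotspots between two populations
#'
#' `|a intersect b| / |a|`; the two sets have equal size by construction
#' (same quantile over the same bin universe), so the measure is symmetric.
#'
#' @param a,b `hotspot_set`s at the same resolution and quantile.
#' @return proportion in [0, 1].
#' @export
hotspot_sharing <- function(a, b) {
  if (a$resolution_bp != b$resolution_bp || a$q != b$q)
    stop("hotspot sets must share resolution and quantile")
  length(intersect(a$bins, b$bins)) / length(a$bins)
}

#' Pairwise landscape comparison suite
#'
#' For every pair of maps, Pearson correlation matrices at each requested
#' resolution and hotspot-sharing matrices (at 50 kb, or the smallest
#' requested resolution) for each quantile, all mask-aware.
#'
#' @param maps named list of `genetic_map`s (or `rho_track`s).
#' @param resolutions bin widths in bp.
#' @param q_list hotspot quantiles.
#' @param mask optional `mask_set`.
#' @param out_dir optional directory; matrices are written there as TSV.
#' @return list with `correlations` (named by resolution) and `sharing`
#'   (named by quantile), each a symmetric matrix.
#' @export
compare_suite <- function(maps, resolutions = c(1e4, 5e4, 1e5, 1e6, 5e6),
                          q_list = c(0.01, 0.10), mask = NULL,
                          out_dir = NULL) {
  nm <- names(maps)
  if (is.null(nm)) stop("maps must be a named list")
  k <- length(maps)
  correlations <- list()
  for (res in resolutions) {
    binned <- lapply(maps, bin_map, resolution_bp = res, mask = mask)
    m <- diag(1, k); dimnames(m) <- list(nm, nm)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      m[i, j] <- m[j, i] <- correlate_maps(binned[[i]], binned[[j]])
    correlations[[format(res, scientific = FALSE)]] <- m
  }
  hot_res <- if (5e4 %in% resolutions) 5e4 else min(resolutions)
  binned_hot <- lapply(maps, bin_map, resolution_bp = hot_res, mask = mask)
  sharing <- list()
  for (q in q_list) {
    hs <- lapply(binned_hot, call_hotspots, q = q)
    m <- diag(1, k); dimnames(m) <- list(nm, nm)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      m[i, j] <- m[j, i] <- hotspot_sharing(hs[[i]], hs[[j]])
    sharing[[format(q)]] <- m
  }
  out <- list(correlations = correlations, sharing = sharing)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (res in names(correlations))
      utils::write.table(correlations[[res]],
                         file.path(out_dir, paste0("correlation_", res, "bp.tsv")),
                         sep = "\t", quote = FALSE)
    for (q in names(sharing))
      utils::write.table(sharing[[q]],
                         file.path(out_dir, paste0("hotspot_sharing_q", q, ".tsv")),
                         sep = "\t", quote = FALSE)
  }
  out
}
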