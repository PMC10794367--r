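# IBD-segment post-processing and kinship: gap-based merging of nearby
# segments, mask trimming, the kinship coefficient
# phi = sum(IBD segments) / (4 * genome length), and cross-map comparison.
#
# The merge step is gap-only: the genotype-discordance check ("1 allowed
# error") of the Refined IBD merge tool needs genotypes, which are outside
# this pipeline's scope, and is deliberately not performed.

# canonical haplotype-pair key: order the (id, hap) tuples lexicographically
canonical_pairs <- function(tab) {
  swap <- tab$id2 < tab$id1 | (tab$id2 == tab$id1 & tab$hap2 < tab$hap1)
  out <- tab
  out$id1[swap] <- tab$id2[swap]; out$hap1[swap] <- tab$hap2[swap]
  out$id2[swap] <- tab$id1[swap]; out$hap2[swap] <- tab$hap1[swap]
  out
}

#' Merge nearby IBD segments on the same haplotype pair
#'
#' Segments on the same haplotype pair and chromosome whose genetic gap
#' (between the end of one and the start of the next, via
#' [interpolate_cM()]) is less than `max_gap_cM` are merged into one spanning
#' segment (overlapping segments always merge); merging is applied
#' transitively.  Genetic lengths of all rows are (re)computed from the map.
#'
#' @param tab an `ibd_table`.
#' @param map a `genetic_map` or list of maps (one per chromosome).
#' @param max_gap_cM merge threshold; the field default for kinship work is
#'   0.6 cM (0.5 cM is conventional when feeding IBD-based map inference).
#' @return an `ibd_table` with merged segments and recomputed `length_cM`.
#' @export
merge_segments <- function(tab, map, max_gap_cM = 0.6) {
  tab <- canonical_pairs(tab)
  key <- paste(tab$id1, tab$hap1, tab$id2, tab$hap2, tab$chrom, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    g <- tab[idx, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    m <- map_for_chrom(map, g$chrom[1])
    out_i <- 1L
    for (i in seq_len(nrow(g))[-1]) {
      gap <- interpolate_cM(m, g$start[i]) - interpolate_cM(m, g$end[out_i])
      if (gap < max_gap_cM) {
        g$end[out_i] <- max(g$end[out_i], g$end[i])
        g$lod[out_i] <- NA_real_
      } else {
        out_i <- out_i + 1L
        g[out_i, ] <- g[i, ]
      }
    }
    g[seq_len(out_i), , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  for (ch in unique(out$chrom)) {
    m <- map_for_chrom(map, ch)
    sel <- out$chrom == ch
    out$length_cM[sel] <- interpolate_cM(m, out$end[sel]) -
      interpolate_cM(m, out$start[sel])
  }
  ibd_table(out)
}

#' Trim IBD segments against an analysis mask and re-measure them
#'
#' Portions of segments overlapping masked regions are excised (segments are
#' split where a mask falls inside them) and the genetic length of each
#' surviving piece is recomputed from the masked map, i.e. the map with
#' genetic distance zeroed across the mask.
#'
#' @param tab an `ibd_table`.
#' @param map a `genetic_map` or list of maps.
#' @param mask a `mask_set` (`NULL` for no trimming; lengths are still
#'   recomputed).
#' @return an `ibd_table`.
#' @export
trim_and_measure <- function(tab, map, mask = NULL) {
  out <- if (is.null(mask) || nrow(mask) == 0L) tab else
    mask_intersect(tab, mask)
  if (nrow(out) == 0L) return(out)
  for (ch in unique(out$chrom)) {
    m <- map_for_chrom(map, ch)
    if (!is.null(mask)) m <- apply_mask_to_map(m, mask)
    sel <- out$chrom == ch
    out$length_cM[sel] <- interpolate_cM(m, out$end[sel]) -
      interpolate_cM(m, out$start[sel])
  }
  ibd_table(out)
}

#' Classify a kinship coefficient into a relatedness degree
#'
#' Standard powers-of-two thresholds: `> 0.354` duplicate/MZ, `(0.177,
#' 0.354]` 1st degree, `(0.0884, 0.177]` 2nd, `(0.0442, 0.0884]` 3rd, and
#' `<= 0.0442` unrelated/distant.  The 3rd-degree cutoff is strict: a pair at
#' exactly 0.0442 is *not* 3rd degree or closer.
#'
#' @param phi kinship coefficient(s).
#' @return character vector of degree labels.
#' @export
classify_kinship_degree <- function(phi) {
  ifelse(phi > 0.354, "duplicate",
         ifelse(phi > 0.177, "1st",
                ifelse(phi > 0.0884, "2nd",
                       ifelse(phi > 0.0442, "3rd", "unrelated"))))
}

#' Kinship coefficients from IBD segments
#'
#' For each pair of individuals, `phi = sum(length_cM) / (4 *
#' genome_length_cM)`, where the genome length is the total genetic length of
#' the (masked) map — the denominator is specific to the map and mask used,
#' matching the numerator's scale.  Segments should already be merged and
#' trimmed ([merge_segments()], [trim_and_measure()]); this function sums all
#' haplotype-pair segments of a pair.
#'
#' @param tab an `ibd_table` with `length_cM` filled in.
#' @param map a `genetic_map` or list of maps.
#' @param mask optional `mask_set` applied to the genome-length denominator
#'   (apply the same mask via [trim_and_measure()] for the numerator).
#' @return data frame of class `kinship_table`: `id1`, `id2`, `sum_cM`,
#'   `genome_length_cM`, `phi`, `degree`.
#' @export
kinship <- function(tab, map, mask = NULL) {
  if (inherits(map, "genetic_map")) map <- list(map)
  maps <- map
  if (!is.null(mask)) maps <- lapply(maps, apply_mask_to_map, mask = mask)
  genome_cM <- map_length_cM(maps)
  if (genome_cM <= 0) stop("masked genome length is zero")
  if (anyNA(tab$length_cM))
    stop("segments have no genetic lengths; run trim_and_measure() or merge_segments() first")
  tab <- canonical_pairs(tab)
  key <- paste(tab$id1, tab$id2, sep = "\r")
  sums <- tapply(tab$length_cM, key, sum)
  ids <- do.call(rbind, strsplit(names(sums), "\r", fixed = TRUE))
  phi <- as.numeric(sums) / (4 * genome_cM)
  out <- data.frame(id1 = ids[, 1], id2 = ids[, 2],
                    sum_cM = as.numeric(sums),
                    genome_length_cM = genome_cM, phi = phi,
                    degree = classify_kinship_degree(phi),
                    stringsAsFactors = FALSE)
  out <- out[order(out$id1, out$id2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kinship_table", "data.frame")
  out
}

#' Compare kinship estimates between two maps
#'
#' Restricted to the intersection of pairs with estimated IBD sharing under
#' both maps; reports the Pearson correlation of phi across maps and the
#' per-pair deltas.
#'
#' @param est_a,est_b `kinship_table`s from the two maps.
#' @return list with `n_pairs`, `pearson_r`, and `pairs` (data frame with
#'   `phi_a`, `phi_b`, `delta`).
#' @export
compare_kinship <- function(est_a, est_b) {
  m <- merge(as.data.frame(est_a)[c("id1", "id2", "phi")],
             as.data.frame(est_b)[c("id1", "id2", "phi")],
             by = c("id1", "id2"), suffixes = c("_a", "_b"))
  if (nrow(m) < 2L) stop("fewer than 2 shared pairs")
  m$delta <- m$phi_a - m$phi_b
  list(n_pairs = nrow(m),
       pearson_r = stats::cor(m$phi_a, m$phi_b),
       pairs = m)
}
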