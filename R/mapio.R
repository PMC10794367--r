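# Readers/writers and coordinate utilities for the on-disk formats the
# pipeline touches: genetic map text dialects, BED masks, Refined-IBD style
# segment tables, msp-style local-ancestry tracks and normalized score tables.
#
# Internal convention: coordinates are 0-based half-open.  Genetic-map and IBD
# files use their native 1-based positions on disk and are converted here.

# ---------------------------------------------------------------------------
# GeneticMap

#' Construct a genetic map
#'
#' A genetic map is a set of strictly increasing physical positions with the
#' cumulative genetic distance (cM) at each position; the per-interval
#' recombination rate in cM/Mb is derived from consecutive positions.  Either
#' `cum_cM` (length `length(pos)`) or `rate_cM_per_Mb` (length
#' `length(pos) - 1`, integrated from 0 at the first position) must be given.
#'
#' @param chrom chromosome label (single string; "chr" prefixes are stripped).
#' @param pos physical positions in bp (0-based), strictly increasing.
#' @param cum_cM cumulative genetic distance at each position, non-decreasing.
#' @param rate_cM_per_Mb per-interval rate between consecutive positions.
#' @return an object of class `genetic_map`.
#' @export
genetic_map <- function(chrom, pos, cum_cM = NULL, rate_cM_per_Mb = NULL) {
  chrom <- norm_chrom(chrom)
  pos <- as.numeric(pos)
  n <- length(pos)
  if (n < 2L) stop("a genetic map needs at least two positions")
  if (any(diff(pos) <= 0)) stop("positions must be strictly increasing")
  if (is.null(cum_cM)) {
    if (is.null(rate_cM_per_Mb) || length(rate_cM_per_Mb) != n - 1L)
      stop("supply cum_cM, or rate_cM_per_Mb of length length(pos) - 1")
    if (any(rate_cM_per_Mb < 0)) stop("negative recombination rate")
    cum_cM <- c(0, cumsum(rate_cM_per_Mb * diff(pos) / 1e6))
  } else {
    cum_cM <- as.numeric(cum_cM)
    if (length(cum_cM) != n) stop("cum_cM must match pos in length")
    if (cum_cM[1] < 0 || any(diff(cum_cM) < -1e-12))
      stop("cum_cM must be non-negative and non-decreasing")
    cum_cM <- cummax(cum_cM)  # clamp float dust
  }
  rate <- diff(cum_cM) / (diff(pos) / 1e6)
  structure(list(chrom = chrom, pos = pos, cum_cM = cum_cM,
                 rate_cM_per_Mb = rate),
            class = "genetic_map")
}

norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: chr%s, %d positions, %.0f bp span, %.3f cM\n",
              x$chrom, length(x$pos), diff(range(x$pos)), map_length_cM(x)))
  invisible(x)
}

#' Total genetic length of a map (or list of maps) in cM
#' @param map a `genetic_map` or list of them.
#' @return total cM.
#' @export
map_length_cM <- function(map) {
  if (inherits(map, "genetic_map"))
    return(map$cum_cM[length(map$cum_cM)] - map$cum_cM[1])
  sum(vapply(map, map_length_cM, numeric(1)))
}

# Fetch the map for a chromosome from a genetic_map or a list of them.
map_for_chrom <- function(map, chrom) {
  chrom <- norm_chrom(chrom)
  if (inherits(map, "genetic_map")) {
    if (norm_chrom(map$chrom) != chrom)
      stop(sprintf("map is for chr%s, segment on chr%s", map$chrom, chrom))
    return(map)
  }
  for (m in map) if (norm_chrom(m$chrom) == chrom) return(m)
  stop(sprintf("no map supplied for chromosome %s", chrom))
}

#' Interpolate cumulative genetic distance at physical positions
#'
#' Linear interpolation between flanking map points.  Positions before the
#' first map point return the first cumulative value and positions beyond the
#' last return the last (clamped, zero-rate extrapolation), so the function is
#' total on any valid map and non-decreasing in `bp`.
#'
#' @param map a `genetic_map`.
#' @param bp physical position(s), 0-based bp.
#' @return cumulative cM at each position.
#' @export
interpolate_cM <- function(map, bp) {
  stats::approx(map$pos, map$cum_cM, xout = bp, rule = 2, ties = "ordered")$y
}

#' Invert a genetic map: physical position at a cumulative genetic distance
#'
#' Inverse of [interpolate_cM()].  Across zero-rate stretches (flat cumulative
#' distance) the left endpoint is returned; values outside the map's range are
#' clamped to its ends.
#'
#' @param map a `genetic_map`.
#' @param cM cumulative genetic distance(s).
#' @return physical position(s), 0-based bp.
#' @export
invert_cM <- function(map, cM) {
  cum <- map$cum_cM; pos <- map$pos
  n <- length(pos)
  cM <- pmin(pmax(cM, cum[1]), cum[n])
  i <- findInterval(cM, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  dg <- cum[i + 1L] - cum[i]
  frac <- ifelse(dg > 0, (cM - cum[i]) / dg, 0)
  pos[i] + frac * (pos[i + 1L] - pos[i])
}

# ---------------------------------------------------------------------------
# Genetic map file dialects

map_dialects <- c("eagle3col", "hapmap4col")

#' Read a genetic map from a text file
#'
#' Two dialects are supported, both with a single header line:
#' \describe{
#'   \item{eagle3col}{whitespace-separated `chr position rate(cM/Mb)
#'     cum(cM)`, the layout of the map shipped with common phasing software.}
#'   \item{hapmap4col}{tab-separated `chrom pos rate cM` (HapMap style).}
#' }
#' Files carrying only a rate column (`chrom pos rate`) are accepted for
#' either dialect; cumulative cM is then reconstructed by piecewise-constant
#' integration starting at 0 at the first position.  "chr" prefixes are
#' tolerated and stripped.  When a cumulative-cM column is present it is
#' authoritative and per-interval rates are recomputed from it.
#'
#' @param path file path.
#' @param dialect one of `"eagle3col"`, `"hapmap4col"`.
#' @return a `genetic_map`.
#' @export
read_genetic_map <- function(path, dialect = c("eagle3col", "hapmap4col")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("map file has no data rows: ", path)
  fields <- strsplit(trimws(lines[-1]), "[ \t]+")
  ncols <- lengths(fields)
  keep <- ncols > 0L
  fields <- fields[keep]
  line_no <- which(keep) + 1L            # 1-based file line numbers
  nc <- unique(lengths(fields))
  if (length(nc) != 1L || !(nc %in% c(3L, 4L)))
    stop("expected 3 or 4 columns in every row of ", path)
  m <- do.call(rbind, fields)
  chrom <- norm_chrom(m[, 1])
  if (length(unique(chrom)) != 1L)
    stop("multiple chromosomes in one map file: ", path)
  pos1 <- suppressWarnings(as.numeric(m[, 2]))
  rate <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(pos1) || anyNA(rate))
    stop(sprintf("non-numeric field at line %d of %s",
                 line_no[which(is.na(pos1) | is.na(rate))[1]], path))
  bad <- which(diff(pos1) <= 0)
  if (length(bad))
    stop(sprintf("positions not strictly increasing at line %d of %s",
                 line_no[bad[1] + 1L], path))
  if (any(rate < 0))
    stop(sprintf("negative rate at line %d of %s",
                 line_no[which(rate < 0)[1]], path))
  pos <- pos1 - 1                        # to 0-based
  if (nc == 4L) {
    cum <- suppressWarnings(as.numeric(m[, 4]))
    if (anyNA(cum))
      stop(sprintf("non-numeric cM at line %d of %s",
                   line_no[which(is.na(cum))[1]], path))
    genetic_map(chrom[1], pos, cum_cM = cum)
  } else {
    genetic_map(chrom[1], pos, rate_cM_per_Mb = rate[-length(rate)])
  }
}

#' Write a genetic map to a text file
#'
#' Inverse of [read_genetic_map()]; positions are serialized 1-based.  The
#' rate column holds the per-interval rate of the interval starting at each
#' row (0 on the last row).  Writing is byte-stable: writing a just-read map
#' reproduces the file.
#'
#' @param map a `genetic_map`.
#' @param path output path.
#' @param dialect one of `"eagle3col"`, `"hapmap4col"`.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path, dialect = c("eagle3col", "hapmap4col")) {
  dialect <- match.arg(dialect)
  rate <- c(map$rate_cM_per_Mb, 0)
  if (dialect == "eagle3col") {
    header <- "chr position COMBINED_rate(cM/Mb) Genetic_Map(cM)"
    rows <- sprintf("%s %s %s %s", paste0("chr", map$chrom),
                    fmt_num(map$pos + 1), fmt_num(rate), fmt_num(map$cum_cM))
  } else {
    header <- "Chromosome\tPosition(bp)\tRate(cM/Mb)\tMap(cM)"
    rows <- sprintf("%s\t%s\t%s\t%s", map$chrom,
                    fmt_num(map$pos + 1), fmt_num(rate), fmt_num(map$cum_cM))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

# shortest decimal representation that round-trips a double
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  redo <- as.numeric(out) != x
  out[redo] <- sprintf("%.17g", x[redo])
  out
}

# ---------------------------------------------------------------------------
# MaskSet + BED

#' Construct a mask set
#'
#' A mask set is a collection of genomic intervals (0-based, half-open)
#' excluded from analyses.  Intervals are normalized per chromosome: sorted,
#' with overlapping or abutting intervals merged.
#'
#' @param chrom chromosome label per interval (recycled if length 1).
#' @param start,end interval bounds, 0-based half-open, `end > start`.
#' @return an object of class `mask_set` (a data frame with columns
#'   `chrom`, `start`, `end`).
#' @export
mask_set <- function(chrom = character(0), start = numeric(0), end = numeric(0)) {
  if (length(start) != length(end)) stop("start and end must match in length")
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  chrom <- norm_chrom(chrom)
  out <- list(chrom = character(0), start = numeric(0), end = numeric(0))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    mg <- merge_interval_vecs(as.numeric(start[sel]), as.numeric(end[sel]))
    out$chrom <- c(out$chrom, rep(ch, length(mg$start)))
    out$start <- c(out$start, mg$start)
    out$end <- c(out$end, mg$end)
  }
  df <- data.frame(chrom = out$chrom, start = out$start, end = out$end,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mask_set", "data.frame")
  df
}

# mask rows for one chromosome as list(start, end)
mask_for_chrom <- function(mask, chrom) {
  if (is.null(mask) || nrow(mask) == 0L)
    return(list(start = numeric(0), end = numeric(0)))
  sel <- mask$chrom == norm_chrom(chrom)
  list(start = mask$start[sel], end = mask$end[sel])
}

#' Total masked length in bp (and cM given a map)
#'
#' @param mask a `mask_set`.
#' @param map optional `genetic_map` (or list of maps) used to express the
#'   masked span on the genetic scale of the unmasked map.
#' @return list with `bp` and (if `map` given) `cM`.
#' @export
masked_length <- function(mask, map = NULL) {
  bp <- if (nrow(mask)) sum(mask$end - mask$start) else 0
  out <- list(bp = bp)
  if (!is.null(map)) {
    cM <- 0
    if (nrow(mask)) {
      for (i in seq_len(nrow(mask))) {
        m <- map_for_chrom(map, mask$chrom[i])
        cM <- cM + interpolate_cM(m, mask$end[i]) -
          interpolate_cM(m, mask$start[i])
      }
    }
    out$cM <- cM
  }
  out
}

#' Read/write masks as BED
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' pass through unchanged; abutting intervals are merged on read.
#'
#' @param path file path.
#' @return `read_bed` returns a `mask_set`; `write_bed` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(mask_set())
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) < 3L))
    stop(sprintf("malformed BED row at line %d of %s",
                 which(lengths(fields) < 3L)[1], path))
  m <- do.call(rbind, lapply(fields, `[`, 1:3))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop(sprintf("malformed BED row at line %d of %s", bad[1], path))
  mask_set(m[, 1], start, end)
}

#' @rdname read_bed
#' @param mask a `mask_set`.
#' @export
write_bed <- function(mask, path) {
  rows <- if (nrow(mask))
    sprintf("%s\t%s\t%s", mask$chrom, fmt_num(mask$start), fmt_num(mask$end))
  else character(0)
  writeLines(rows, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# IBD segment tables (Refined-IBD tab layout)

#' Construct an IBD segment table
#'
#' Rows are haplotype-pair segments: `(id1, hap1, id2, hap2, chrom, start,
#' end, lod, length_cM)` with `hap* in {1,2}`, coordinates 0-based half-open.
#'
#' @param df data frame with the columns above (`lod`, `length_cM` optional).
#' @return an `ibd_table` (data frame subclass).
#' @export
ibd_table <- function(df) {
  need <- c("id1", "hap1", "id2", "hap2", "chrom", "start", "end")
  if (!all(need %in% names(df))) stop("missing IBD columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (!"lod" %in% names(df)) df$lod <- NA_real_
  if (!"length_cM" %in% names(df)) df$length_cM <- NA_real_
  df$chrom <- norm_chrom(df$chrom)
  if (any(df$end <= df$start)) stop("IBD segment end must exceed start")
  if (!all(df$hap1 %in% c(1L, 2L)) || !all(df$hap2 %in% c(1L, 2L)))
    stop("haplotype indices must be 1 or 2")
  if (any(df$id1 == df$id2 & df$hap1 == df$hap2))
    stop("segment pairs a haplotype with itself")
  if (any(!is.na(df$length_cM) & df$length_cM < 0))
    stop("negative genetic length")
  df <- df[c("id1", "hap1", "id2", "hap2", "chrom", "start", "end",
             "lod", "length_cM")]
  rownames(df) <- NULL
  class(df) <- c("ibd_table", "data.frame")
  df
}

#' Read/write Refined-IBD style segment tables
#'
#' Tab-separated, no header: `sample1 hap1 sample2 hap2 chrom start end LOD
#' cM`.  File coordinates are 1-based inclusive and converted to the internal
#' 0-based half-open convention.
#'
#' @param path file path.
#' @return `read_ibd_table` returns an `ibd_table`; the writer returns
#'   `path` invisibly.
#' @export
read_ibd_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines_keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[lines_keep], "\t")
  line_no <- which(lines_keep)
  if (length(fields) == 0L)
    return(ibd_table(data.frame(id1 = character(0), hap1 = integer(0),
                                id2 = character(0), hap2 = integer(0),
                                chrom = character(0), start = numeric(0),
                                end = numeric(0))))
  if (any(lengths(fields) != 9L))
    stop(sprintf("malformed IBD row at line %d of %s",
                 line_no[which(lengths(fields) != 9L)[1]], path))
  m <- do.call(rbind, fields)
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  start1 <- num(6); end1 <- num(7)
  bad <- which(is.na(start1) | is.na(end1) | end1 <= start1 - 1)
  if (length(bad))
    stop(sprintf("malformed IBD row (end <= start or non-numeric) at line %d of %s",
                 line_no[bad[1]], path))
  ibd_table(data.frame(
    id1 = m[, 1], hap1 = as.integer(m[, 2]),
    id2 = m[, 3], hap2 = as.integer(m[, 4]),
    chrom = m[, 5], start = start1 - 1, end = end1,
    lod = num(8), length_cM = num(9), stringsAsFactors = FALSE))
}

#' @rdname read_ibd_table
#' @param tab an `ibd_table`.
#' @export
write_ibd_table <- function(tab, path) {
  rows <- sprintf("%s\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%s",
                  tab$id1, as.integer(tab$hap1), tab$id2, as.integer(tab$hap2),
                  tab$chrom, fmt_num(tab$start + 1), fmt_num(tab$end),
                  fmt_num(tab$lod), fmt_num(tab$length_cM))
  writeLines(rows, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Ancestry tracks (msp-style calls + marginal probabilities)

ANCESTRIES <- c("PNS", "AFR", "EAS", "EUR")

#' Construct a local-ancestry track
#'
#' Per-site, per-haplotype ancestry calls over a fixed panel of ancestries
#' (default the four-way model PNS/AFR/EAS/EUR), with a marginal probability
#' vector per call.  Haplotype columns are named `<id>.1`, `<id>.2`.
#'
#' @param chrom chromosome label.
#' @param pos site positions (bp, strictly increasing).
#' @param calls integer matrix `n_sites x n_haplotypes` of ancestry codes
#'   (1-based indices into `ancestries`); column names `<id>.<hap>`.
#' @param probs array `n_sites x n_haplotypes x n_ancestries` of marginal
#'   probabilities; each vector must sum to 1 within 1e-6.
#' @param ancestries character vector of ancestry labels.
#' @return an `ancestry_track`.
#' @export
ancestry_track <- function(chrom, pos, calls, probs, ancestries = ANCESTRIES) {
  k <- length(ancestries)
  if (any(diff(pos) <= 0)) stop("site positions must be strictly increasing")
  if (!is.matrix(calls) || nrow(calls) != length(pos))
    stop("calls must be an n_sites x n_haplotypes matrix")
  if (ncol(calls) %% 2L != 0L) stop("haplotype columns must come in pairs")
  if (is.null(colnames(calls))) stop("calls needs '<id>.<hap>' column names")
  if (!all(calls %in% seq_len(k))) stop("ancestry codes out of range")
  if (!all(dim(probs) == c(length(pos), ncol(calls), k)))
    stop("probs must be n_sites x n_haplotypes x n_ancestries")
  sums <- apply(probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) stop("probability vectors must sum to 1")
  structure(list(chrom = norm_chrom(chrom), pos = as.numeric(pos),
                 calls = calls, probs = probs, ancestries = ancestries),
            class = "ancestry_track")
}

#' Read/write ancestry tracks
#'
#' Tab-separated with two header lines: `#ancestries=<comma list>` then a
#' column header `chrom pos` followed by, per haplotype, a call column
#' `<id>.<hap>` and probability columns `<id>.<hap>:<ancestry>`.
#'
#' @param path file path.
#' @return `read_ancestry_track` returns an `ancestry_track`; the writer
#'   returns `path` invisibly.
#' @export
read_ancestry_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1], "#ancestries="))
    stop("not an ancestry track file: ", path)
  anc <- strsplit(sub("^#ancestries=", "", lines[1]), ",")[[1]]
  k <- length(anc)
  hdr <- strsplit(lines[2], "\t")[[1]]
  hap_names <- hdr[seq(3, length(hdr), by = k + 1L)]
  n_hap <- length(hap_names)
  fields <- strsplit(lines[-(1:2)], "\t")
  if (any(lengths(fields) != 2L + n_hap * (k + 1L)))
    stop(sprintf("malformed row at line %d of %s",
                 which(lengths(fields) != 2L + n_hap * (k + 1L))[1] + 2L, path))
  m <- do.call(rbind, fields)
  pos <- as.numeric(m[, 2])
  n <- length(pos)
  calls <- matrix(0L, n, n_hap, dimnames = list(NULL, hap_names))
  probs <- array(0, c(n, n_hap, k))
  for (h in seq_len(n_hap)) {
    base <- 2L + (h - 1L) * (k + 1L)
    calls[, h] <- as.integer(m[, base + 1L])
    for (j in seq_len(k)) probs[, h, j] <- as.numeric(m[, base + 1L + j])
  }
  ancestry_track(m[1, 1], pos, calls, probs, ancestries = anc)
}

#' @rdname read_ancestry_track
#' @param track an `ancestry_track`.
#' @export
write_ancestry_track <- function(track, path) {
  k <- length(track$ancestries)
  n_hap <- ncol(track$calls)
  hdr2 <- c("chrom", "pos")
  cols <- vector("list", 2L + n_hap * (k + 1L))
  cols[[1]] <- rep(track$chrom, length(track$pos))
  cols[[2]] <- fmt_num(track$pos)
  j <- 3L
  for (h in seq_len(n_hap)) {
    nm <- colnames(track$calls)[h]
    hdr2 <- c(hdr2, nm, paste0(nm, ":", track$ancestries))
    cols[[j]] <- as.character(track$calls[, h]); j <- j + 1L
    for (a in seq_len(k)) {
      cols[[j]] <- fmt_num(track$probs[, h, a]); j <- j + 1L
    }
  }
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(paste0("#ancestries=", paste(track$ancestries, collapse = ",")),
               paste(hdr2, collapse = "\t"), body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Score tracks (selscan-style normalized iHS tables)

#' Read/write normalized score tables
#'
#' Tab-separated with header `pos freq ihs z` (positions 1-based on disk, as
#' in selscan `.norm` output).
#'
#' @param path file path.
#' @return `read_score_track` returns a data frame of class `score_track`
#'   with columns `pos`, `freq`, `ihs`, `z`; the writer returns `path`
#'   invisibly.
#' @export
read_score_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "numeric")
  if (!all(c("pos", "freq", "ihs", "z") %in% names(df)))
    stop("score track needs columns pos, freq, ihs, z: ", path)
  df$pos <- df$pos - 1
  class(df) <- c("score_track", "data.frame")
  df
}

#' @rdname read_score_track
#' @param track a `score_track` data frame.
#' @export
write_score_track <- function(track, path) {
  rows <- sprintf("%s\t%s\t%s\t%s", fmt_num(track$pos + 1),
                  fmt_num(track$freq), fmt_num(track$ihs), fmt_num(track$z))
  writeLines(c("pos\tfreq\tihs\tz", rows), path)
  invisible(path)
}
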