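# Internal helpers shared across modules.  All genomic coordinates inside the
# package are 0-based, half-open [start, end); 1-based file conventions are
# converted at the I/O boundary (see mapio).

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All generators in the package route their randomness through this helper so
#' that identical seeds give identical output without disturbing the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sort and merge a set of intervals; abutting or overlapping intervals are
# coalesced.  Returns a list(start, end) of disjoint intervals sorted by start.
merge_interval_vecs <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) return(list(start = numeric(0), end = numeric(0)))
  if (any(end <= start)) stop("interval end must exceed start")
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  k <- 1L
  if (length(start) > 1L) {
    for (i in 2L:length(start)) {
      if (start[i] <= out_e[k]) {         # overlap or abut -> extend
        out_e[k] <- max(out_e[k], end[i])
      } else {
        k <- k + 1L
        out_s[k] <- start[i]; out_e[k] <- end[i]
      }
    }
  }
  list(start = out_s, end = out_e)
}

# bp of [s, e) overlapped by the (disjoint, sorted) intervals (ms, me).
# Vectorized over s/e.
overlap_bp_vec <- function(s, e, ms, me) {
  if (length(ms) == 0L) return(numeric(length(s)))
  out <- numeric(length(s))
  for (j in seq_along(ms)) {
    out <- out + pmax(0, pmin(e, me[j]) - pmax(s, ms[j]))
  }
  out
}

# Subtract the (disjoint, sorted) intervals (ms, me) from a single interval
# [s, e); returns list(start, end) of the surviving pieces.
subtract_one_interval <- function(s, e, ms, me) {
  if (length(ms) == 0L) return(list(start = s, end = e))
  keep <- me > s & ms < e
  ms <- ms[keep]; me <- me[keep]
  if (length(ms) == 0L) return(list(start = s, end = e))
  starts <- c(s, pmin(me, e))
  ends <- c(pmax(ms, s), e)
  ok <- ends > starts
  list(start = starts[ok], end = ends[ok])
}

# Split piecewise-constant intervals (s, e, v) at fixed-width bin edges
# anchored at coordinate 0.  Returns data.frame(bin, start, end, value).
split_at_bins <- function(s, e, v, resolution) {
  if (length(s) == 0L) {
    return(data.frame(bin = integer(0), start = numeric(0),
                      end = numeric(0), value = numeric(0)))
  }
  b0 <- floor(s / resolution)
  b1 <- ceiling(e / resolution) - 1   # last bin index touched
  n_span <- as.integer(b1 - b0 + 1)
  idx <- rep.int(seq_along(s), n_span)
  bin <- unlist(lapply(seq_along(s), function(i) seq.int(b0[i], b1[i])),
                use.names = FALSE)
  ps <- pmax(s[idx], bin * resolution)
  pe <- pmin(e[idx], (bin + 1) * resolution)
  ok <- pe > ps
  data.frame(bin = as.integer(bin[ok]), start = ps[ok], end = pe[ok],
             value = v[idx][ok])
}

# first index of a strictly increasing vector equal to `x`, else NA
match_pos <- function(x, pos) {
  i <- findInterval(x, pos)
  ifelse(i >= 1L & pos[pmax(i, 1L)] == x, i, NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
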