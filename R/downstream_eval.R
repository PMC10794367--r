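# Downstream impact metrics: local-ancestry concordance between two sets of
# calls (haplotype-matching, probability-mass weighted) and imputation
# accuracy (per-SNP dosage r^2) with a paired MAF-binned comparison.

#' Local-ancestry concordance between two call sets
#'
#' Haplotype labels are arbitrary between runs, so for every site and
#' individual both pairings of the two haplotype calls (identity and swap)
#' are evaluated and the pairing with more label agreements is kept (ties go
#' to the identity pairing).  For each matched haplotype the joint
#' probability of the two calls — the product of the tracks' marginal
#' probabilities for their called labels — is accumulated into the cell
#' (call in a, call in b) of a k x k joint matrix (rows: track a's
#' ancestries; columns: track b's); concordance is the percentage of joint
#' mass on the diagonal, i.e. where both runs called the same ancestry.
#' With `hard_calls = TRUE` the matrix counts matched calls instead of
#' probability mass.
#'
#' @param a,b `ancestry_track`s over identical sites and individuals.
#' @param hard_calls use argmax calls instead of marginal probabilities.
#' @return list with `joint` (k x k matrix, rows/cols in the tracks' ancestry
#'   order) and `concordance` (percent).
#' @export
lai_concordance <- function(a, b, hard_calls = FALSE) {
  if (!identical(a$pos, b$pos)) stop("site universes differ")
  if (!identical(sort(colnames(a$calls)), sort(colnames(b$calls))))
    stop("individual universes differ")
  if (!identical(a$ancestries, b$ancestries)) stop("ancestry panels differ")
  k <- length(a$ancestries)
  ord <- match(colnames(a$calls), colnames(b$calls))
  bc <- b$calls[, ord, drop = FALSE]
  bp <- b$probs[, ord, , drop = FALSE]
  n_ind <- ncol(a$calls) %/% 2L
  joint <- matrix(0, k, k, dimnames = list(a$ancestries, a$ancestries))
  accumulate <- function(sites, a_col, b_col) {
    if (length(sites) == 0L) return()
    ai <- a$calls[sites, a_col]
    bi <- bc[sites, b_col]
    w <- if (hard_calls) rep(1, length(sites)) else
      a$probs[cbind(sites, a_col, ai)] * bp[cbind(sites, b_col, bi)]
    add <- tapply(w, list(factor(ai, 1:k), factor(bi, 1:k)), sum,
                  default = 0)
    joint <<- joint + add
  }
  pair_mass <- function(a1, b1, a2, b2) {
    n_s <- nrow(a$calls)
    a$probs[cbind(seq_len(n_s), a1, a$calls[, a1])] *
      bp[cbind(seq_len(n_s), b1, bc[, b1])] +
      a$probs[cbind(seq_len(n_s), a2, a$calls[, a2])] *
      bp[cbind(seq_len(n_s), b2, bc[, b2])]
  }
  for (i in seq_len(n_ind)) {
    c1 <- 2L * i - 1L; c2 <- 2L * i
    agree_id <- (a$calls[, c1] == bc[, c1]) + (a$calls[, c2] == bc[, c2])
    agree_sw <- (a$calls[, c1] == bc[, c2]) + (a$calls[, c2] == bc[, c1])
    # pairing with more agreements wins; agreement ties are resolved by the
    # larger joint probability mass so the choice is invariant under
    # haplotype column order (exact ties contribute identically either way)
    swap <- agree_sw > agree_id |
      (agree_sw == agree_id &
         pair_mass(c1, c2, c2, c1) > pair_mass(c1, c1, c2, c2))
    accumulate(which(!swap), c1, c1); accumulate(which(!swap), c2, c2)
    accumulate(which(swap), c1, c2); accumulate(which(swap), c2, c1)
  }
  list(joint = joint,
       concordance = 100 * sum(diag(joint)) / sum(joint))
}

#' Per-SNP imputation accuracy (dosage r-squared)
#'
#' Squared Pearson correlation of the sequenced genotype with the imputed
#' dosage across individuals, per SNP.  SNPs with zero variance in either
#' vector are dropped; the count is attached as attribute `n_dropped`.
#'
#' @param dosage,truth matrices `n_ind x n_snp` (dosage in [0, 2], truth in
#'   {0, 1, 2}); columns may be named with SNP ids.
#' @return data frame with `snp` and `r2`; attribute `n_dropped`.
#' @export
imputation_accuracy <- function(dosage, truth) {
  stopifnot(all(dim(dosage) == dim(truth)))
  n_snp <- ncol(truth)
  ids <- colnames(truth) %||% as.character(seq_len(n_snp))
  vd <- apply(dosage, 2, stats::sd)
  vt <- apply(truth, 2, stats::sd)
  ok <- vd > 0 & vt > 0
  r2 <- rep(NA_real_, n_snp)
  if (any(ok)) {
    cc <- vapply(which(ok), function(j) stats::cor(dosage[, j], truth[, j]),
                 numeric(1))
    r2[ok] <- cc^2
  }
  out <- data.frame(snp = ids[ok], r2 = r2[ok], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Compare imputation accuracy between two maps
#'
#' SNP-matched paired comparison of per-SNP r^2: a Wilcoxon signed-rank test
#' over all shared SNPs (exact for n <= 25 non-zero differences, normal
#' approximation with continuity correction otherwise; zero differences are
#' dropped, classical treatment) plus per-MAF-bin medians and counts.  With no
#' non-zero differences the test degenerates and p = 1 is reported.
#'
#' @param table_a,table_b data frames from [imputation_accuracy()].
#' @param maf named numeric vector (or data frame with `snp`, `maf`) giving
#'   each SNP's minor allele frequency from the sequenced truth.
#' @param maf_bins bin edges; default the 0.5-1\%, 1-5\%, 5-50\% bins (SNPs
#'   with MAF below the first edge are excluded from the bin summary but kept
#'   in the signed-rank test).
#' @return list with `p_value`, `n_pairs`, `n_zero_diff`, `median_delta`
#'   (a minus b), and `per_bin` (data frame of bin, n, median r^2 for each
#'   map).
#' @export
compare_accuracy <- function(table_a, table_b, maf,
                             maf_bins = c(0.005, 0.01, 0.05, 0.5)) {
  if (is.data.frame(maf)) maf <- stats::setNames(maf$maf, maf$snp)
  m <- merge(table_a, table_b, by = "snp", suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) stop("no shared SNPs")
  d <- m$r2_a - m$r2_b
  nz <- d[d != 0]
  p <- if (length(nz) == 0L) 1 else
    stats::wilcox.test(nz, mu = 0, exact = length(nz) <= 25,
                       correct = TRUE)$p.value
  mf <- maf[m$snp]
  bin <- cut(mf, breaks = c(maf_bins[-length(maf_bins)],
                            maf_bins[length(maf_bins)] + 1e-12),
             right = FALSE, include.lowest = FALSE)
  per_bin <- do.call(rbind, lapply(levels(bin), function(lv) {
    sel <- !is.na(bin) & bin == lv
    data.frame(bin = lv, n = sum(sel),
               median_r2_a = stats::median(m$r2_a[sel]),
               median_r2_b = stats::median(m$r2_b[sel]))
  }))
  list(p_value = p, n_pairs = nrow(m), n_zero_diff = sum(d == 0),
       median_delta = stats::median(d), per_bin = per_bin)
}
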