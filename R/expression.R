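#' Per-locus library support
#'
#' Counts, for each locus, the number of libraries with FPKM strictly above
#' `fpkm_min`.
#'
#' @param mat Numeric FPKM matrix, loci in rows, libraries in columns.
#' @param fpkm_min Expression threshold (exclusive), default 1.
#' @return Named integer vector of counts in `[0, ncol(mat)]`.
#' @export
library_support <- function(mat, fpkm_min = 1) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  counts <- rowSums(mat > fpkm_min)
  setNames(as.integer(counts), rownames(mat))
}

#' Reproducibility classes from library-support counts
#'
#' Partitions loci into `low` (supported by at most `low_max` libraries),
#' `high` (at least `high_min` libraries) and `others` in between.
#'
#' @param counts Integer vector from [library_support()].
#' @param low_max Upper bound (inclusive) of the low class, default 20.
#' @param high_min Lower bound (inclusive) of the high class, default 100.
#' @return Factor with levels `low`, `others`, `high`.
#' @export
classify_reproducibility <- function(counts, low_max = 20, high_min = 100) {
  stopifnot(low_max < high_min)
  cls <- ifelse(counts <= low_max, "low",
    ifelse(counts >= high_min, "high", "others")
  )
  factor(cls, levels = c("low", "others", "high"))
}

#' Cumulative library-support distribution
#'
#' Fraction of loci expressed in at least `k` libraries, for `k` from 1 to
#' the maximum observed count.
#'
#' @param counts Integer vector from [library_support()].
#' @return Data frame `k, fraction`; `fraction` is non-increasing in `k`.
#' @export
support_cdf <- function(counts) {
  stopifnot(length(counts) > 0)
  kmax <- max(counts, 1L)
  k <- seq_len(kmax)
  frac <- vapply(k, function(kk) mean(counts >= kk), numeric(1))
  data.frame(k = k, fraction = frac)
}

#' Per-locus developmental stage profile
#'
#' Averages `log2(FPKM + pseudocount)` within each stage and reports the
#' stage of highest expression per locus; argmax ties resolve to the
#' earliest stage (in the order of `levels(stages)` or first appearance)
#' and are flagged.
#'
#' @param mat Numeric FPKM matrix, loci in rows, libraries in columns.
#' @param stages Stage label per library (length `ncol(mat)`).
#' @param pseudocount Added before the log transform, default 1.
#' @return A list with `profile` (loci x stages matrix of mean log2
#'   expression) and `peak` (data frame `locus, peak_stage, tie`).
#' @export
stage_profile <- function(mat, stages, pseudocount = 1) {
  stopifnot(length(stages) == ncol(mat))
  stages <- if (is.factor(stages)) stages else factor(stages, levels = unique(stages))
  lg <- log2(mat + pseudocount)
  prof <- vapply(
    levels(stages),
    function(s) rowMeans(lg[, stages == s, drop = FALSE]),
    numeric(nrow(mat))
  )
  prof <- matrix(prof,
    nrow = nrow(mat),
    dimnames = list(rownames(mat), levels(stages))
  )
  peak_idx <- apply(prof, 1, which.max) # first max = earliest stage
  tie <- apply(prof, 1, function(r) sum(r == max(r)) > 1)
  list(
    profile = prof,
    peak = data.frame(
      locus = rownames(mat),
      peak_stage = colnames(prof)[peak_idx],
      tie = unname(tie),
      stringsAsFactors = FALSE
    )
  )
}
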