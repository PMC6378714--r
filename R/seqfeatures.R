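#' Extract strand-aware sequences for ranges from a DNAStringSet genome
#' @noRd
extract_seqs <- function(genome, gr) {
  chrom <- as.character(seqnames(gr))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing)) {
    stop("chromosomes absent from the genome: ", paste(missing, collapse = ", "))
  }
  out <- vector("list", length(gr))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    seqs <- Biostrings::extractAt(genome[[ch]], ranges(gr)[i])
    out[i] <- as.list(seqs)
  }
  seqs <- DNAStringSet(out)
  minus <- as.character(strand(gr)) == "-"
  if (any(minus)) {
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  }
  seqs
}

#' GC fraction over a set of intervals
#'
#' Computes `(G + C) / (A + C + G + T)` over the union of the given
#' intervals; ambiguous bases (N, ...) are excluded from the denominator.
#'
#' @param intervals `GRanges` (overlaps are collapsed before counting) or a
#'   `GRangesList` (one value per element).
#' @param genome Named `DNAStringSet`.
#' @return A numeric GC fraction (vector for a `GRangesList`); `NaN` when no
#'   unambiguous bases are covered.
#' @export
gc_content <- function(intervals, genome) {
  if (is(intervals, "GRangesList")) {
    return(vapply(as.list(intervals), gc_content, numeric(1), genome = genome))
  }
  merged <- reduce(intervals, ignore.strand = TRUE)
  if (length(merged) == 0) return(NaN)
  seqs <- extract_seqs(genome, unstrand(merged))
  counts <- colSums(letterFrequency(seqs, c("G", "C", "A", "T")))
  gc <- counts[["G"]] + counts[["C"]]
  denom <- sum(counts)
  if (denom == 0) NaN else gc / denom
}

#' Spliced, strand-respecting locus sequence
#' @noRd
spliced_seq <- function(locus, genome) {
  locus <- sort(locus, ignore.strand = TRUE)
  minus <- as.character(strand(locus)[1]) == "-"
  if (minus) locus <- rev(locus)
  seqs <- extract_seqs(genome, locus) # reverse-complements "-" ranges
  do.call(Biostrings::xscat, as.list(seqs))
}

#' Metagene GC profile across loci
#'
#' Splits each locus's spliced sequence (5' to 3') into `n_windows`
#' equal-length windows -- remainder bases go to the last window, so the
#' windows exactly partition the sequence -- and summarises GC content per
#' window across loci by the 5th percentile, median and 95th percentile.
#' The flanking-intergenic GC baseline is computed over `flank` bases on
#' each side of each locus span.
#'
#' @param loci `GRangesList` of locus exon models.
#' @param genome Named `DNAStringSet`.
#' @param n_windows Number of windows, default 10.
#' @param flank Width (bp) of the flanking sequence used for the baseline.
#' @return A list with `profile` (data frame `window, p5, median, p95, n`)
#'   and `baseline` (flanking GC fraction). Loci shorter than `n_windows`
#'   bases are excluded with a warning.
#' @export
metagene_gc <- function(loci, genome, n_windows = 10, flank = 500) {
  stopifnot(length(loci) >= 1)
  lens <- sum(width(loci))
  short <- lens < n_windows
  if (any(short)) {
    warning(sum(short), " locus/loci shorter than ", n_windows,
            " nt excluded from the metagene profile")
    loci <- loci[!short]
  }
  if (length(loci) == 0) stop("no locus long enough for a metagene profile")

  gc_win <- matrix(NA_real_, length(loci), n_windows)
  for (i in seq_along(loci)) {
    s <- spliced_seq(loci[[i]], genome)
    L <- length(s)
    w <- rep(L %/% n_windows, n_windows)
    w[n_windows] <- w[n_windows] + L - sum(w)
    ends <- cumsum(w)
    starts <- c(1, ends[-n_windows] + 1)
    v <- Biostrings::Views(s, start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
    gc_win[i, ] <- (freq[, "G"] + freq[, "C"]) / rowSums(freq)
  }
  profile <- data.frame(
    window = seq_len(n_windows),
    p5 = apply(gc_win, 2, quantile, probs = 0.05, na.rm = TRUE),
    median = apply(gc_win, 2, median, na.rm = TRUE),
    p95 = apply(gc_win, 2, quantile, probs = 0.95, na.rm = TRUE),
    n = colSums(!is.na(gc_win))
  )

  spans <- unlist(range(loci, ignore.strand = TRUE))
  chrom_len <- setNames(width(genome), names(genome))
  left <- GRanges(
    seqnames(spans),
    IRanges(pmax(1L, start(spans) - flank), pmax(1L, start(spans) - 1L))
  )
  right_end <- pmin(
    chrom_len[as.character(seqnames(spans))],
    end(spans) + flank
  )
  right <- GRanges(
    seqnames(spans),
    IRanges(pmin(end(spans) + 1L, right_end), right_end)
  )
  flank_gr <- c(left[width(left) > 1], right[width(right) > 1])
  baseline <- gc_content(flank_gr, genome)
  list(profile = profile, baseline = baseline)
}

#' Mean conservation score per locus
#'
#' Averages available per-base track scores over the exonic positions of
#' each locus; track ranges wider than one base contribute every covered
#' base. Loci with no covered base get `NA`.
#'
#' @param loci `GRangesList` of locus exon models (or a `GRanges`, treated
#'   as one locus per range).
#' @param track `GRanges` with a numeric `score`, e.g. from
#'   [read_scores_wig()].
#' @return Numeric vector of per-locus means, named by locus.
#' @export
conservation_summary <- function(loci, track) {
  single <- is(loci, "GRanges")
  if (single) loci <- split(loci, seq_along(loci))
  exons <- unlist(loci, use.names = FALSE)
  grp <- rep(seq_along(loci), lengths(loci))
  hits <- findOverlaps(exons, track, ignore.strand = TRUE)
  out <- rep(NA_real_, length(loci))
  if (length(hits)) {
    ov <- pintersect(
      exons[queryHits(hits)], track[subjectHits(hits)],
      ignore.strand = TRUE
    )
    w <- width(ov)
    sc <- track$score[subjectHits(hits)]
    g <- grp[queryHits(hits)]
    tot <- tapply(w * sc, g, sum)
    cov <- tapply(w, g, sum)
    out[as.integer(names(tot))] <- tot / cov
  }
  names(out) <- names(loci)
  out
}

#' Kruskal-Wallis comparison of named groups
#'
#' Rank-based comparison of two or more groups of per-locus values (GC,
#' conservation, ...), with the chi-square approximation and tie correction
#' of `stats::kruskal.test`, or an exact permutation p-value for small
#' samples. The Bonferroni-corrected p multiplies the raw p by
#' `n_comparisons` and caps at 1.
#'
#' @param groups Named list of numeric vectors; each group must be
#'   non-empty.
#' @param n_comparisons Bonferroni multiplier (number of tests in the
#'   family), default 1.
#' @param exact If `TRUE`, compute the p-value by label permutation
#'   (`n_perm` draws) instead of the chi-square approximation.
#' @param n_perm Permutations for `exact = TRUE`.
#' @return A list with `H`, `df`, `p`, `p_bonferroni`.
#' @export
compare_groups <- function(groups, n_comparisons = 1, exact = FALSE,
                           n_perm = 10000) {
  stopifnot(length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes == 0)) {
    stop("empty group(s): ", paste(names(groups)[sizes == 0], collapse = ", "))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes))
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  p <- kt$p.value
  if (exact) {
    kw_stat <- function(xx) stats::kruskal.test(xx, g)$statistic
    null_H <- replicate(n_perm, kw_stat(sample(x)))
    p <- (1 + sum(null_H >= H - 1e-12)) / (1 + n_perm)
  }
  list(
    H = H, df = unname(kt$parameter), p = p,
    p_bonferroni = min(1, p * n_comparisons)
  )
}
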