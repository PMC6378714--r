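#' Place query intervals uniformly at random within a workspace
#'
#' Each query interval is placed independently, preserving its length, at a
#' start position drawn uniformly among all positions that keep it inside a
#' single workspace segment (segments are chosen with probability
#' proportional to their number of valid start positions).
#'
#' @param query `GRanges` whose widths are to be re-placed.
#' @param workspace `GRanges` of permitted segments (assumed disjoint;
#'   overlapping segments are reduced).
#' @return A `GRanges` of placed intervals, unstranded.
#' @details Draws from the current RNG stream; seed management belongs to
#'   the caller (see [test_enrichment()]).
#' @export
permute_intervals <- function(query, workspace) {
  workspace <- reduce(workspace, ignore.strand = TRUE)
  if (length(query) == 0) return(GRanges())
  seg_w <- width(workspace)
  widths <- width(query)
  if (max(widths) > max(seg_w)) {
    stop("query interval of width ", max(widths),
         " fits in no workspace segment (max ", max(seg_w), ")")
  }
  chrom <- character(length(query))
  starts <- integer(length(query))
  for (w in unique(widths)) {
    idx <- which(widths == w)
    slots <- pmax(0L, seg_w - w + 1L)
    seg <- sample.int(length(workspace), length(idx),
      replace = TRUE, prob = slots
    )
    off <- floor(stats::runif(length(idx)) * slots[seg])
    chrom[idx] <- as.character(seqnames(workspace))[seg]
    starts[idx] <- start(workspace)[seg] + off
  }
  GRanges(chrom, IRanges(starts, width = widths))
}

## flatten a disjoint workspace to a single 1..G axis; returns mapping tables
flatten_workspace <- function(workspace) {
  w <- width(workspace)
  offset <- cumsum(c(0L, w[-length(w)]))
  list(
    seg_chrom = as.character(seqnames(workspace)),
    seg_start = start(workspace),
    seg_w = w,
    offset = offset,
    total = sum(w)
  )
}

#' Permutation test of genomic-interval association
#'
#' Tests whether the query intervals overlap the annotation more (or less)
#' than expected if the query were placed uniformly at random within the
#' workspace, preserving interval lengths and keeping each interval inside a
#' single workspace segment. The statistic is the total base-pair overlap
#' (`statistic = "count"` counts overlapping query intervals instead). The
#' empirical p-value uses the add-one estimator
#' `(1 + #permutations at least as extreme) / (1 + n_perm)`, computed for
#' both tails; the reported direction is the smaller tail.
#'
#' @param query,annotation,workspace `GRanges` on a shared coordinate
#'   system; query intervals must fit inside workspace segments.
#' @param n_perm Number of permutations, default 10000.
#' @param seed Integer seed for the placement RNG.
#' @param statistic `"bp"` (base-pair overlap, default) or `"count"`.
#' @return An object of class `enrichment_result`: a list with
#'   `observed`, `expected`, `fold`, `p`, `direction`
#'   (`"enriched"`/`"depleted"`), `p_enriched`, `p_depleted`, `n_perm`,
#'   `seed`, `statistic`, `workspace_bp`.
#' @details When both observed and expected overlap are zero the result is
#'   reported as `fold = 1`, `p = 1` (nothing can be concluded).
#' @export
test_enrichment <- function(query, annotation, workspace, n_perm = 10000,
                            seed = 1, statistic = c("bp", "count")) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 1)
  workspace <- reduce(workspace, ignore.strand = TRUE)
  annotation <- reduce(annotation, ignore.strand = TRUE)
  query <- unstrand(query)

  observed <- overlap_stat(query, annotation, statistic)

  ## flattened annotation indicator cumsum for fast permutation overlap
  fl <- flatten_workspace(workspace)
  if (fl$total > 2e8) {
    stop("workspace too large to flatten (", fl$total, " bp)")
  }
  ind <- numeric(fl$total)
  hits <- findOverlaps(annotation, workspace, ignore.strand = TRUE)
  for (h in seq_along(hits)) {
    a <- annotation[queryHits(hits)[h]]
    s <- subjectHits(hits)[h]
    lo <- max(start(a), fl$seg_start[s]) - fl$seg_start[s] + 1L + fl$offset[s]
    hi <- min(end(a), fl$seg_start[s] + fl$seg_w[s] - 1L) -
      fl$seg_start[s] + 1L + fl$offset[s]
    ind[lo:hi] <- 1
  }
  csum <- c(0, cumsum(ind))

  widths <- width(query)
  if (max(widths) > max(fl$seg_w)) {
    stop("query interval wider than every workspace segment")
  }
  set.seed(child_seed(seed, "enrichment"))
  nq <- length(query)
  perm_stats <- numeric(n_perm)
  slots_by_w <- lapply(
    stats::setNames(nm = unique(widths)),
    function(w) pmax(0L, fl$seg_w - as.integer(w) + 1L)
  )
  for (p in seq_len(n_perm)) {
    flat_start <- integer(nq)
    for (w in unique(widths)) {
      idx <- which(widths == w)
      slots <- slots_by_w[[as.character(w)]]
      seg <- sample.int(length(fl$seg_w), length(idx),
        replace = TRUE, prob = slots
      )
      off <- floor(stats::runif(length(idx)) * slots[seg])
      flat_start[idx] <- fl$offset[seg] + off + 1L
    }
    ov <- csum[flat_start + widths] - csum[flat_start]
    perm_stats[p] <- if (statistic == "bp") sum(ov) else sum(ov > 0)
  }

  expected <- mean(perm_stats)
  fold <- if (expected == 0 && observed == 0) {
    1
  } else if (expected == 0) {
    Inf
  } else {
    observed / expected
  }
  p_enr <- (1 + sum(perm_stats >= observed)) / (1 + n_perm)
  p_dep <- (1 + sum(perm_stats <= observed)) / (1 + n_perm)
  if (expected == 0 && observed == 0) {
    p_enr <- p_dep <- 1
  }
  direction <- if (p_enr <= p_dep) "enriched" else "depleted"
  structure(
    list(
      observed = observed, expected = expected, fold = fold,
      p = min(p_enr, p_dep), direction = direction,
      p_enriched = p_enr, p_depleted = p_dep,
      n_perm = n_perm, seed = seed, statistic = statistic,
      workspace_bp = fl$total
    ),
    class = "enrichment_result"
  )
}

overlap_stat <- function(query, annotation, statistic) {
  hits <- findOverlaps(query, annotation, ignore.strand = TRUE)
  if (statistic == "count") {
    return(length(unique(queryHits(hits))))
  }
  if (length(hits) == 0) return(0)
  ov <- pintersect(
    query[queryHits(hits)], annotation[subjectHits(hits)],
    ignore.strand = TRUE
  )
  sum(width(ov))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Permutation association test (%s overlap, %d permutations)\n",
    x$statistic, x$n_perm
  ))
  cat(sprintf(
    "  observed %.4g, expected %.4g, fold %.3g (%s), p = %.4g\n",
    x$observed, x$expected, x$fold, x$direction, x$p
  ))
  cat(sprintf("  workspace: %d bp, seed %d\n", x$workspace_bp, x$seed))
  invisible(x)
}
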