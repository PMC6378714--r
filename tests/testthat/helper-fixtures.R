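suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

## quick exon GRanges builder: one row per exon
exons_gr <- function(chrom, start, end, strand = "+", transcript_id,
                     library = "libA") {
  GRanges(chrom, IRanges(start, end), strand,
    transcript_id = transcript_id, library = library
  )
}

## brute-force transitive closure of exon overlap (same strand, "*" matches
## either) between transcripts; returns list of sorted transcript-id sets
brute_merge_groups <- function(transcripts) {
  tid <- transcripts$transcript_id
  ids <- unique(tid)
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- transcripts[tid == ids[i]]
      b <- transcripts[tid == ids[j]]
      adj[i, j] <- length(findOverlaps(a, b)) > 0
    }
  }
  ## transitive closure (Floyd-Warshall style)
  for (k in seq_len(n)) {
    adj <- adj | (adj[, k] %o% adj[k, ])
  }
  groups <- unique(apply(adj, 1, function(r) paste(sort(ids[r]), collapse = ",")))
  sort(groups)
}

## brute-force minimum-cost assignment: rows of `cost` to distinct columns
## (all rows assigned; requires nrow <= ncol)
brute_lap <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  best_asn <- NULL
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in perms(cols)) {
      tot <- sum(cost[cbind(seq_len(n), p)])
      if (tot < best) {
        best <- tot
        best_asn <- p
      }
    }
  }
  list(assignment = best_asn, cost = best)
}

## direct overlap in bp between two GRanges, ignoring strand
bp_overlap <- function(a, b) {
  ints <- intersect(reduce(a, ignore.strand = TRUE),
                    reduce(b, ignore.strand = TRUE),
                    ignore.strand = TRUE)
  sum(width(ints))
}
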