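#' Cluster CAGE 5' tags into strand-specific clusters
#'
#' Same-strand tag positions separated by a gap of at most `merge_dist` bases
#' are chained into one cluster; clusters with fewer than `min_reads` total
#' reads are discarded. Each cluster's summit is the tag position with the
#' highest read count, ties broken to the 5'-most position on the cluster
#' strand.
#'
#' @param tags Width-1 `GRanges` of tag positions with strand and a `score`
#'   read count (absent score = 1 read per row).
#' @param merge_dist Maximum gap (bases strictly between adjacent tags) for
#'   chaining, default 25.
#' @param min_reads Minimum total reads per retained cluster, default 2.
#' @return A `GRanges` of cluster spans with metadata `read_count` and
#'   `summit`.
#' @export
cluster_cage <- function(tags, merge_dist = 25, min_reads = 2) {
  if (length(tags) == 0) {
    gr <- GRanges()
    gr$read_count <- integer(0)
    gr$summit <- integer(0)
    return(gr)
  }
  if (is.null(tags$score)) tags$score <- 1L
  stopifnot(all(width(tags) == 1), all(as.character(strand(tags)) %in% c("+", "-")))
  tags <- sort(tags, ignore.strand = TRUE)

  ## chain same-strand tags whose gap <= merge_dist
  clusters <- reduce(tags, min.gapwidth = merge_dist + 1L, with.revmap = TRUE)
  revmap <- mcols(clusters)$revmap
  read_count <- vapply(revmap, function(i) sum(tags$score[i]), numeric(1))
  summit <- vapply(seq_along(clusters), function(k) {
    i <- revmap[[k]]
    pos <- start(tags)[i]
    cnt <- tags$score[i]
    best <- pos[cnt == max(cnt)]
    if (as.character(strand(clusters)[k]) == "-") max(best) else min(best)
  }, numeric(1))

  keep <- read_count >= min_reads
  out <- clusters[keep]
  mcols(out) <- DataFrame(
    read_count = as.integer(read_count[keep]),
    summit = as.integer(summit[keep])
  )
  out
}

#' Orient mono-exonic loci from CAGE cluster summits
#'
#' Assigns a transcriptional strand to unstranded mono-exonic loci from the
#' strand of the nearest CAGE cluster summit, provided that summit lies
#' within `max_summit_dist` bases of the locus (distance 0 if the summit
#' falls inside it). When the two nearest summits are equally distant but on
#' opposite strands the locus is left unassigned with reason `"ambiguous"`.
#' Multi-exonic and already-stranded loci are untouched.
#'
#' @param loci `GRangesList` from [merge_across_libraries()].
#' @param clusters `GRanges` from [cluster_cage()].
#' @param max_summit_dist Maximum summit-to-locus distance (nt), default 100.
#' @return `loci` with strands updated and metadata columns
#'   `cage_orientation` (`assigned`, `ambiguous`, `none`, or `not-applicable`)
#'   and `cage_distance` (nt to the nearest summit, `NA` if none within
#'   reach).
#' @export
orient_monoexonic <- function(loci, clusters, max_summit_dist = 100) {
  n <- length(loci)
  status <- rep("not-applicable", n)
  cage_dist <- rep(NA_integer_, n)
  if (n == 0) {
    mcols(loci)$cage_orientation <- character(0)
    mcols(loci)$cage_distance <- integer(0)
    return(loci)
  }
  spans <- unlist(range(loci, ignore.strand = TRUE))
  locus_strand <- vapply(
    as.list(strand(loci)), function(s) as.character(s[1]), character(1)
  )
  is_target <- mcols(loci)$class == "mono-exonic" & locus_strand == "*"

  if (length(clusters)) {
    s_chrom <- as.character(seqnames(clusters))
    s_pos <- clusters$summit
    s_strand <- as.character(strand(clusters))
  }
  new_strand <- locus_strand
  for (i in which(is_target)) {
    status[i] <- "none"
    if (length(clusters) == 0) next
    same_chrom <- s_chrom == as.character(seqnames(spans)[i])
    if (!any(same_chrom)) next
    pos <- s_pos[same_chrom]
    str <- s_strand[same_chrom]
    d <- pmax(0L, pmax(start(spans)[i] - pos, pos - end(spans)[i]))
    dmin <- min(d)
    if (dmin > max_summit_dist) next
    best <- which(d == dmin)
    strands <- unique(str[best])
    if (length(strands) == 1) {
      new_strand[i] <- strands
      status[i] <- "assigned"
      cage_dist[i] <- dmin
    } else {
      status[i] <- "ambiguous"
      cage_dist[i] <- dmin
    }
  }
  changed <- which(new_strand != locus_strand)
  if (length(changed)) {
    ex <- unlist(loci, use.names = FALSE)
    grp <- rep(seq_len(n), lengths(loci))
    st <- as.character(strand(ex))
    st[grp %in% changed] <- new_strand[grp][grp %in% changed]
    strand(ex) <- st
    mc <- mcols(loci)
    nm <- names(loci)
    loci <- relist(ex, loci)
    mcols(loci) <- mc
    names(loci) <- nm
  }
  mcols(loci)$cage_orientation <- status
  mcols(loci)$cage_distance <- cage_dist
  loci
}
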