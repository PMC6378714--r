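#' Keep transcripts deemed non-coding by CPC and CPAT
#'
#' A transcript is non-coding iff its CPC score is strictly below `cpc_max`
#' (default 0) and its CPAT score strictly below `cpat_max` (default 0.403,
#' the published CPAT cutoff for C. elegans-sized genomes). Both
#' inequalities are strict: a CPAT score of exactly 0.403 is coding.
#'
#' @param transcripts Exon `GRanges` with a `transcript_id` column.
#' @param scores Data frame `transcript_id, cpc_score, cpat_score`; every
#'   transcript must be scored.
#' @param cpc_max,cpat_max Exclusive upper bounds for the two scores.
#' @return The exon `GRanges` restricted to non-coding transcripts.
#' @seealso [filter_noncoding_loci()] for the locus-level rule (a locus is
#'   kept only if every member transcript is non-coding).
#' @export
noncoding_filter <- function(transcripts, scores, cpc_max = 0, cpat_max = 0.403) {
  keep_ids <- noncoding_ids(
    unique(transcripts$transcript_id), scores, cpc_max, cpat_max
  )
  transcripts[transcripts$transcript_id %in% keep_ids]
}

#' @noRd
noncoding_ids <- function(ids, scores, cpc_max = 0, cpat_max = 0.403) {
  m <- match(ids, scores$transcript_id)
  missing <- ids[is.na(m)]
  if (length(missing)) {
    stop(
      "transcripts without coding-potential scores: ",
      paste(missing, collapse = ", ")
    )
  }
  ok <- scores$cpc_score[m] < cpc_max & scores$cpat_score[m] < cpat_max
  ids[ok]
}

#' Merge transcript calls across libraries into loci
#'
#' Transcripts whose exons overlap by at least 1 bp on the same strand
#' (unstranded transcripts match either strand) are grouped into one locus by
#' transitive closure; the locus exon model is the union of member exons,
#' its class is multi- or mono-exonic by the number of disjoint union blocks,
#' and its library support is the number of distinct source libraries among
#' members.
#'
#' @param transcripts Exon `GRanges` with `transcript_id` and `library`
#'   columns (concatenate per-library calls first), or a list of such
#'   `GRanges` which is concatenated.
#' @return A `GRangesList` of merged exon blocks per locus, with metadata
#'   columns `locus_id`, `class`, `n_exons`, `exonic_length`,
#'   `n_supporting_libraries` and `members` (a `CharacterList` of member
#'   transcript ids). Loci are ordered by genomic position.
#' @export
merge_across_libraries <- function(transcripts) {
  if (is.list(transcripts) && !is(transcripts, "GRanges")) {
    transcripts <- do.call(c, unname(transcripts))
  }
  if (length(transcripts) == 0) {
    return(GRangesList())
  }
  tid <- transcripts$transcript_id
  ids <- unique(tid)
  ## exon-overlap graph between transcripts; "*" matches either strand
  hits <- findOverlaps(transcripts, transcripts)
  a <- match(tid[queryHits(hits)], ids)
  b <- match(tid[subjectHits(hits)], ids)
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(ids) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership

  locus_of <- comp[match(tid, ids)]
  exon_by_locus <- split(unname(transcripts), locus_of)
  blocks <- reduce(exon_by_locus, ignore.strand = TRUE)

  ## locus strand: the unique stranded value among members, else "*"
  strand_of <- vapply(
    split(as.character(strand(transcripts)), locus_of),
    function(s) {
      s <- setdiff(unique(s), "*")
      if (length(s) == 1) s else "*"
    },
    character(1)
  )
  members <- split(tid, locus_of)
  members <- lapply(members, unique)
  libs <- vapply(
    split(transcripts$library, locus_of),
    function(x) length(unique(x)), integer(1)
  )

  ## order loci by position of their first block
  first <- unlist(range(blocks, ignore.strand = TRUE))
  ord <- order(
    as.character(seqnames(first)), start(first)
  )
  blocks <- blocks[ord]
  strand_of <- strand_of[ord]
  members <- members[ord]
  libs <- libs[ord]

  ## stamp locus strand onto the blocks
  blocks <- GRangesList(lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    strand(b) <- strand_of[i]
    b
  }))
  n_exons <- lengths(blocks)
  mcols(blocks) <- DataFrame(
    locus_id = sprintf("LOC_%05d", seq_along(blocks)),
    class = ifelse(n_exons > 1, "multi-exonic", "mono-exonic"),
    n_exons = unname(n_exons),
    exonic_length = unname(sum(width(blocks))),
    n_supporting_libraries = unname(libs),
    members = IRanges::CharacterList(unname(members))
  )
  names(blocks) <- mcols(blocks)$locus_id
  blocks
}

#' Drop loci containing any coding member transcript
#'
#' The locus-level non-coding rule: a merged locus is retained only if every
#' member transcript is deemed non-coding by [noncoding_filter()]'s
#' thresholds.
#'
#' @param loci `GRangesList` from [merge_across_libraries()].
#' @param scores Data frame `transcript_id, cpc_score, cpat_score`.
#' @inheritParams noncoding_filter
#' @return The surviving loci.
#' @export
filter_noncoding_loci <- function(loci, scores, cpc_max = 0, cpat_max = 0.403) {
  if (length(loci) == 0) return(loci)
  all_ids <- unique(unlist(mcols(loci)$members))
  ok_ids <- noncoding_ids(all_ids, scores, cpc_max, cpat_max)
  keep <- vapply(
    as.list(mcols(loci)$members),
    function(m) all(m %in% ok_ids), logical(1)
  )
  loci[keep]
}

#' Intergenic size/overlap/distance filter
#'
#' Keeps loci that (a) have summed exonic length strictly greater than
#' `min_len` (or genomic span, see `length_mode`), (b) overlap no annotated
#' gene on either strand, and (c) lie at least `min_same_strand_dist` bases
#' from the nearest annotated gene on the same strand. Distance is the
#' number of bases strictly between the two features; unstranded loci are
#' subject to rules (a) and (b) only.
#'
#' @param loci `GRangesList` from [merge_across_libraries()].
#' @param annotation `GRanges` of all existing gene models (exons or spans;
#'   coding and previously annotated non-coding alike).
#' @param min_len Length that must be exceeded (nt), default 200.
#' @param min_same_strand_dist Minimum gap to a same-strand gene (nt),
#'   default 50.
#' @param length_mode `"exonic"` (summed exon length, default) or `"span"`
#'   (genomic extent).
#' @return The surviving loci.
#' @export
intergenic_filter <- function(loci, annotation, min_len = 200,
                              min_same_strand_dist = 50,
                              length_mode = c("exonic", "span")) {
  length_mode <- match.arg(length_mode)
  if (length(loci) == 0) return(loci)
  spans <- unlist(range(loci, ignore.strand = TRUE))
  len <- if (length_mode == "exonic") {
    sum(width(loci))
  } else {
    width(spans)
  }
  keep <- len > min_len

  if (length(annotation) == 0) {
    warning("empty gene annotation: overlap and distance rules pass vacuously")
    return(loci[keep])
  }
  ## (b) any-strand overlap
  exons <- unlist(loci, use.names = FALSE)
  ov_idx <- unique(
    rep(seq_along(loci), lengths(loci))[
      queryHits(findOverlaps(exons, annotation, ignore.strand = TRUE))
    ]
  )
  keep[ov_idx] <- FALSE

  ## (c) same-strand distance
  locus_strand <- vapply(
    as.list(strand(loci)),
    function(s) as.character(s[1]), character(1)
  )
  for (s in c("+", "-")) {
    idx <- which(keep & locus_strand == s)
    ann_s <- annotation[as.character(strand(annotation)) == s]
    if (length(idx) == 0 || length(ann_s) == 0) next
    d <- distanceToNearest(spans[idx], ann_s, ignore.strand = TRUE)
    too_close <- queryHits(d)[mcols(d)$distance < min_same_strand_dist]
    keep[idx[too_close]] <- FALSE
  }
  loci[keep]
}
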