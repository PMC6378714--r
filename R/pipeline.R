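#' Run the full intergenic lncRNA annotation arm
#'
#' Chains the annotation operations: merge per-library transcript calls into
#' loci, drop loci with any coding-potential member, apply the intergenic
#' size/overlap/distance filter, and (optionally) orient mono-exonic loci
#' from CAGE clusters and attach GC and conservation features.
#'
#' @param calls Exon `GRanges` with `transcript_id`/`library` columns, or a
#'   list of per-library `GRanges` (e.g. `gen_library_calls()$calls` or
#'   several [read_gtf()] results).
#' @param scores Coding-potential table (`transcript_id, cpc_score,
#'   cpat_score`).
#' @param annotation `GRanges` of existing gene models.
#' @param genome Optional named `DNAStringSet` for GC features.
#' @param cage_tags Optional CAGE tag `GRanges` for mono-exonic orientation.
#' @param conservation Optional score-track `GRanges`.
#' @param cpc_max,cpat_max,min_len,min_same_strand_dist,length_mode,
#'   merge_dist,min_reads,max_summit_dist Filter parameters; see the
#'   individual operations.
#' @return A list with `loci` (the surviving `GRangesList`) and `table` (a
#'   per-locus annotation data frame: position, class, exon count, library
#'   support, CAGE orientation and distance, GC, conservation).
#' @export
annotate_lincrnas <- function(calls, scores, annotation,
                              genome = NULL, cage_tags = NULL,
                              conservation = NULL,
                              cpc_max = 0, cpat_max = 0.403,
                              min_len = 200, min_same_strand_dist = 50,
                              length_mode = "exonic",
                              merge_dist = 25, min_reads = 2,
                              max_summit_dist = 100) {
  loci <- merge_across_libraries(calls)
  loci <- filter_noncoding_loci(loci, scores, cpc_max, cpat_max)
  loci <- intergenic_filter(loci, annotation,
    min_len = min_len,
    min_same_strand_dist = min_same_strand_dist,
    length_mode = length_mode
  )
  if (!is.null(cage_tags)) {
    clusters <- cluster_cage(cage_tags,
      merge_dist = merge_dist, min_reads = min_reads
    )
    loci <- orient_monoexonic(loci, clusters, max_summit_dist = max_summit_dist)
  }
  list(loci = loci, table = locus_table(loci, genome, conservation))
}

#' Per-locus annotation table
#'
#' Summarises a locus set into one row per locus: position, strand, class,
#' exon count, exonic length, library support, CAGE orientation status and
#' distance when present, and GC content and mean conservation when a
#' genome / score track is supplied.
#'
#' @param loci `GRangesList` of locus exon models with the metadata columns
#'   produced by the annotation operations.
#' @param genome Optional named `DNAStringSet`.
#' @param conservation Optional score-track `GRanges`.
#' @return A data frame, one row per locus.
#' @export
locus_table <- function(loci, genome = NULL, conservation = NULL) {
  n <- length(loci)
  if (n == 0) {
    return(data.frame(
      locus_id = character(0), chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0), class = character(0),
      n_exons = integer(0), exonic_length = integer(0),
      n_supporting_libraries = integer(0)
    ))
  }
  spans <- unlist(range(loci, ignore.strand = TRUE))
  mc <- mcols(loci)
  out <- data.frame(
    locus_id = mc$locus_id,
    chrom = as.character(seqnames(spans)),
    start = start(spans),
    end = end(spans),
    strand = vapply(as.list(strand(loci)),
      function(s) as.character(s[1]), character(1)
    ),
    class = mc$class,
    n_exons = mc$n_exons,
    exonic_length = mc$exonic_length,
    n_supporting_libraries = mc$n_supporting_libraries,
    stringsAsFactors = FALSE
  )
  if (!is.null(mc$cage_orientation)) {
    out$cage_orientation <- mc$cage_orientation
    out$cage_distance <- mc$cage_distance
  }
  if (!is.null(genome)) {
    out$gc <- gc_content(loci, genome)
  }
  if (!is.null(conservation)) {
    out$conservation <- unname(conservation_summary(loci, conservation))
  }
  out
}
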