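#' Read exon models from a GTF file
#'
#' Parses a GTF file, keeps `exon` features only, and returns one row per exon
#' as a [GenomicRanges::GRanges] with `transcript_id` and `library` metadata
#' columns. All coordinates follow the GRanges convention (1-based, closed);
#' the GTF conversion happens here at the I/O boundary and nowhere else.
#'
#' @param path Path to a GTF file whose exon lines carry a `transcript_id`
#'   attribute.
#' @param library_id Label recorded in the `library` column, identifying the
#'   source library of these transcript calls. Defaults to the file name
#'   without extension.
#' @return A `GRanges` of exons, sorted by position within each transcript,
#'   with metadata columns `transcript_id` and `library`.
#' @details Non-exon features (CDS, start_codon, ...) are ignored. A
#'   transcript whose exons fall on more than one chromosome or strand is a
#'   validation error.
#' @export
read_gtf <- function(path, library_id = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  if (is.null(library_id)) {
    library_id <- sub("\\.[^.]*$", "", basename(path))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("malformed GTF '", path, "': ", conditionMessage(e))
  )
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0) {
    return(empty_exon_granges(library_id))
  }
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    stop("GTF exon lines without transcript_id in ", path)
  }
  exons <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr), IRanges::ranges(gr), GenomicRanges::strand(gr),
    transcript_id = as.character(gr$transcript_id),
    library = library_id
  )
  validate_transcripts(exons)
  ord <- order(exons$transcript_id, GenomicRanges::start(exons))
  exons[ord]
}

empty_exon_granges <- function(library_id = character(0)) {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    transcript_id = character(0),
    library = character(0)
  )
  gr
}

#' @noRd
validate_transcripts <- function(exons) {
  chrom <- as.character(GenomicRanges::seqnames(exons))
  strand <- as.character(GenomicRanges::strand(exons))
  bad_chrom <- tapply(chrom, exons$transcript_id, function(x) length(unique(x)) > 1)
  if (any(bad_chrom)) {
    stop(
      "transcripts with exons on multiple chromosomes: ",
      paste(names(bad_chrom)[bad_chrom], collapse = ", ")
    )
  }
  bad_strand <- tapply(strand, exons$transcript_id, function(x) length(unique(x)) > 1)
  if (any(bad_strand)) {
    stop(
      "transcripts with exons on multiple strands: ",
      paste(names(bad_strand)[bad_strand], collapse = ", ")
    )
  }
  invisible(TRUE)
}

#' Write exon models to a GTF file
#'
#' @param exons A `GRanges` of exons with a `transcript_id` metadata column,
#'   as returned by [read_gtf()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, source = "lincscreen") {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(exons)),
    source = source,
    feature = "exon",
    start = GenomicRanges::start(exons),
    end = GenomicRanges::end(exons),
    score = ".",
    strand = as.character(GenomicRanges::strand(exons)),
    frame = ".",
    attr = sprintf("transcript_id \"%s\";", exons$transcript_id),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read intervals from a BED file
#'
#' BED 0-based half-open coordinates are converted to the GRanges convention
#' at import. A missing strand column yields unstranded (`*`) intervals.
#'
#' @param path Path to a BED3/BED6 file.
#' @return A `GRanges`, with `name`/`score` metadata columns when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  rtracklayer::import(path, format = "bed")
}

#' Write intervals to a BED file
#'
#' @param intervals A `GRanges`; `name` and `score` metadata columns are used
#'   when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (any(GenomicRanges::start(intervals) < 1)) {
    stop("intervals with start < 1 cannot be written")
  }
  rtracklayer::export(intervals, path, format = "bed")
  invisible(path)
}

#' Read a per-base score track (wiggle fixedStep or bedGraph)
#'
#' The dialect is detected from the first data line. Scores are returned as a
#' `GRanges` with a `score` column; a bedGraph span covers every base of its
#' half-open interval, converted to 1-based closed at import.
#'
#' @param path Path to a fixedStep wiggle or bedGraph file.
#' @return A `GRanges` with numeric `score` metadata; empty input gives an
#'   empty track.
#' @export
read_scores_wig <- function(path) {
  if (!file.exists(path)) stop("score track not found: ", path)
  lines <- readLines(path, n = 50L)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track)", lines)]
  if (length(lines) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$score <- numeric(0)
    return(gr)
  }
  first <- lines[[1]]
  if (grepl("^(fixedStep|variableStep)", first)) {
    fmt <- "wig"
  } else {
    fields <- strsplit(trimws(first), "\\s+")[[1]]
    if (length(fields) == 4 && !anyNA(suppressWarnings(as.numeric(fields[2:4])))) {
      fmt <- "bedGraph"
    } else {
      stop("unrecognized score-track dialect in ", path,
           " (expected fixedStep/variableStep wiggle or bedGraph)")
    }
  }
  rtracklayer::import(path, format = fmt)
}

#' Read a genome from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read an FPKM expression matrix from TSV
#'
#' @param path TSV with a header of library identifiers and locus identifiers
#'   in the first column.
#' @return Numeric matrix, loci in rows, libraries in columns.
#' @export
read_fpkm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("FPKM values must be non-negative")
  m
}

#' Write an FPKM expression matrix to TSV
#'
#' @param mat Numeric matrix, loci in rows, libraries in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fpkm <- function(mat, path) {
  df <- data.frame(locus = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read coding-potential scores from TSV
#'
#' @param path TSV with columns `transcript_id`, `cpc_score`, `cpat_score`.
#' @return A data frame with those three columns; CPAT scores outside `[0, 1]`
#'   are a validation error.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cpc_score", "cpat_score")
  if (!all(need %in% names(df))) {
    stop("score table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$cpat_score < 0 | df$cpat_score > 1, na.rm = TRUE)) {
    stop("cpat_score must lie in [0, 1]")
  }
  df[need]
}
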