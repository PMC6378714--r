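#' Derive a child seed from a root seed
#'
#' Every generator in the package derives its randomness from a root seed via
#' this splitting rule, so adding a generator (or reordering calls) never
#' shifts the stream of another. The rule is a fixed affine hash of the root
#' seed and a text tag, folded into the 31-bit signed-integer range R
#' requires.
#'
#' @param seed Integer root seed.
#' @param tag Character tag naming the consumer.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Specification of a toy genome
#'
#' Describes the synthetic genome the annotation arm is exercised on: a small
#' number of chromosomes carrying non-overlapping protein-coding genes and
#' "true" intergenic lncRNA loci, with region-specific GC content (exon >
#' intron, per the pattern seen in animal genomes) and conservation scores
#' elevated in coding and multi-exonic lncRNA exons.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_coding_genes Protein-coding genes to place.
#' @param n_true_lnc_multi,n_true_lnc_mono True multi-/mono-exonic intergenic
#'   lncRNA loci to place.
#' @param gc_exon,gc_intron,gc_intergenic,gc_lnc_exon GC fractions used to
#'   draw sequence in each region class.
#' @param cons_mu_coding,cons_mu_lnc,cons_mu_bg,cons_sd Normal parameters for
#'   per-base conservation scores (PhyloP-like units) in coding exons,
#'   multi-exonic lncRNA exons, and everywhere else.
#' @param min_gap Minimum gap (bp) enforced between placed loci; kept above
#'   the 50-nt same-strand distance filter so true loci survive it by
#'   construction.
#' @param seed Integer seed.
#' @return A list of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(n_chroms = 2, chrom_length = 100000,
                            n_coding_genes = 30, n_true_lnc_multi = 8,
                            n_true_lnc_mono = 12,
                            gc_exon = 0.42, gc_intron = 0.33,
                            gc_intergenic = 0.30, gc_lnc_exon = 0.38,
                            cons_mu_coding = 2, cons_mu_lnc = 2,
                            cons_mu_bg = 0, cons_sd = 0.5,
                            min_gap = 100, seed = 1) {
  stopifnot(
    n_chroms >= 1, chrom_length >= 1000,
    gc_exon >= 0, gc_exon <= 1, gc_intron >= 0, gc_intron <= 1,
    gc_intergenic >= 0, gc_intergenic <= 1,
    gc_exon > gc_intron,
    min_gap > 50
  )
  structure(as.list(environment()), class = "toy_genome_spec")
}

## draws one gene structure: list(exon widths, intron widths)
random_gene_structure <- function(kind = c("coding", "lnc_multi", "lnc_mono")) {
  kind <- match.arg(kind)
  if (kind == "coding") {
    n_ex <- sample(2:4, 1)
    widths_e <- sample(150:400, n_ex, replace = TRUE)
    widths_i <- sample(60:300, n_ex - 1, replace = TRUE)
  } else if (kind == "lnc_multi") {
    n_ex <- sample(2:3, 1)
    # keep total exonic length comfortably above the 200-nt filter
    widths_e <- sample(120:400, n_ex, replace = TRUE)
    widths_i <- sample(60:250, n_ex - 1, replace = TRUE)
  } else {
    widths_e <- sample(250:800, 1)
    widths_i <- integer(0)
  }
  list(exons = widths_e, introns = widths_i)
}

#' Generate a toy genome with embedded lncRNA loci
#'
#' Places coding genes and true intergenic lncRNA loci without overlap
#' (enforcing `min_gap` between any two loci), draws sequence with
#' region-specific GC content, and draws a per-base conservation track with
#' elevated scores in coding and multi-exonic lncRNA exons. Deterministic
#' given the spec's seed.
#'
#' @param spec A [toy_genome_spec()].
#' @return A list with elements:
#' \describe{
#'   \item{genome}{named `DNAStringSet` of chromosomes}
#'   \item{genes}{`GRanges` of coding exons with `transcript_id`/`gene_id`}
#'   \item{lnc}{`GRanges` of true lncRNA exons with `transcript_id`, `class`}
#'   \item{conservation}{`GRanges` per-base score track}
#'   \item{spec}{the input spec}
#' }
#' @export
gen_genome <- function(spec = toy_genome_spec()) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  set.seed(child_seed(spec$seed, "genome"))
  chroms <- sprintf("chrS%d", seq_len(spec$n_chroms))

  n_total <- spec$n_coding_genes + spec$n_true_lnc_multi + spec$n_true_lnc_mono
  kinds <- c(
    rep("coding", spec$n_coding_genes),
    rep("lnc_multi", spec$n_true_lnc_multi),
    rep("lnc_mono", spec$n_true_lnc_mono)
  )
  kinds <- sample(kinds)
  chrom_of <- sort(rep_len(seq_len(spec$n_chroms), n_total))

  gene_rows <- list()
  cursor <- stats::setNames(rep(1L, spec$n_chroms), chroms)
  idx_coding <- 0L
  idx_lnc <- 0L
  for (i in seq_len(n_total)) {
    ci <- chrom_of[i]
    st <- random_gene_structure(kinds[i])
    span <- sum(st$exons) + sum(st$introns)
    gap <- spec$min_gap + sample(0:400, 1)
    start <- cursor[ci] + gap
    if (start + span - 1 > spec$chrom_length) {
      stop("capacity error: cannot place ", n_total, " loci of this size on ",
           spec$n_chroms, " x ", spec$chrom_length, " bp; enlarge the genome")
    }
    strand <- sample(c("+", "-"), 1)
    if (kinds[i] == "coding") {
      idx_coding <- idx_coding + 1L
      id <- sprintf("gene_%03d", idx_coding)
    } else {
      idx_lnc <- idx_lnc + 1L
      id <- sprintf("lnc_%03d", idx_lnc)
    }
    ex_start <- start + cumsum(c(0L, st$exons[-length(st$exons)] +
                                   if (length(st$introns)) st$introns else integer(0)))
    gene_rows[[i]] <- data.frame(
      chrom = chroms[ci], start = ex_start,
      end = ex_start + st$exons - 1L, strand = strand,
      transcript_id = id, kind = kinds[i], stringsAsFactors = FALSE
    )
    cursor[ci] <- start + span - 1L
  }
  tab <- do.call(rbind, gene_rows)
  all_gr <- GenomicRanges::GRanges(
    tab$chrom, IRanges::IRanges(tab$start, tab$end), tab$strand,
    transcript_id = tab$transcript_id, kind = tab$kind
  )

  ## region classes per base: 0 intergenic, 1 intron, 2 coding exon, 3 lnc exon
  gc_levels <- c(spec$gc_intergenic, spec$gc_intron, spec$gc_exon, spec$gc_lnc_exon)
  genome <- vector("list", spec$n_chroms)
  cons <- vector("list", spec$n_chroms)
  for (ci in seq_len(spec$n_chroms)) {
    L <- spec$chrom_length
    class_vec <- integer(L) # 0-based class codes
    sub <- all_gr[as.character(GenomicRanges::seqnames(all_gr)) == chroms[ci]]
    spans <- range(split(sub, sub$transcript_id))
    spans_gr <- unlist(spans)
    for (j in seq_along(spans_gr)) {
      class_vec[GenomicRanges::start(spans_gr[j]):GenomicRanges::end(spans_gr[j])] <- 1L
    }
    is_coding <- sub$kind == "coding"
    for (j in which(is_coding)) {
      class_vec[GenomicRanges::start(sub[j]):GenomicRanges::end(sub[j])] <- 2L
    }
    for (j in which(!is_coding)) {
      class_vec[GenomicRanges::start(sub[j]):GenomicRanges::end(sub[j])] <- 3L
    }
    gc <- gc_levels[class_vec + 1L]
    is_gc <- stats::runif(L) < gc
    base <- ifelse(is_gc,
      sample(c("G", "C"), L, replace = TRUE),
      sample(c("A", "T"), L, replace = TRUE)
    )
    genome[[ci]] <- paste(base, collapse = "")

    high <- logical(L)
    for (j in which(is_coding)) {
      high[GenomicRanges::start(sub[j]):GenomicRanges::end(sub[j])] <- TRUE
    }
    multi_ids <- unique(sub$transcript_id[sub$kind == "lnc_multi"])
    for (j in which(sub$transcript_id %in% multi_ids)) {
      high[GenomicRanges::start(sub[j]):GenomicRanges::end(sub[j])] <- TRUE
    }
    mu <- ifelse(high, spec$cons_mu_coding, spec$cons_mu_bg)
    mu[high & class_vec == 3L] <- spec$cons_mu_lnc
    cons[[ci]] <- stats::rnorm(L, mu, spec$cons_sd)
  }
  genome <- DNAStringSet(stats::setNames(unlist(genome), chroms))
  cons_gr <- GenomicRanges::GRanges(
    rep(chroms, each = spec$chrom_length),
    IRanges::IRanges(rep(seq_len(spec$chrom_length), spec$n_chroms), width = 1),
    score = unlist(cons)
  )

  list(
    genome = genome,
    genes = all_gr[all_gr$kind == "coding"],
    lnc = lnc_with_class(all_gr[all_gr$kind != "coding"]),
    conservation = cons_gr,
    spec = spec
  )
}

lnc_with_class <- function(gr) {
  gr$class <- ifelse(gr$kind == "lnc_multi", "multi-exonic", "mono-exonic")
  gr$kind <- NULL
  gr
}

#' Simulate per-library transcript calls from a toy genome
#'
#' Emulates the structure of a many-library RNA-Seq compendium: each true
#' locus carries a latent expression level; each library detects it with a
#' probability that saturates with expression, reports its exact exon model
#' when detected, and assigns an FPKM around the latent level. Detected
#' lncRNA transcripts receive non-coding CPC/CPAT scores, coding transcripts
#' coding scores, and false-positive fragments overlapping coding genes are
#' injected at `fp_rate` per gene per library (with non-coding scores, so
#' that only the intergenic filter can remove them).
#'
#' @param truth Output of [gen_genome()].
#' @param n_libraries Number of libraries to simulate.
#' @param detect_k Saturation constant of the detection curve
#'   `p = expr / (expr + detect_k)` applied to latent FPKM.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal parameters of latent locus FPKM.
#' @param fp_rate Per-coding-gene, per-library probability of an injected
#'   false-positive fragment.
#' @param seed Integer seed.
#' @return A list with `calls` (per-library exon `GRanges`, metadata columns
#'   `transcript_id` and `library`), `scores` (transcript_id, cpc_score,
#'   cpat_score), and `fpkm` (locus x library matrix over true lncRNA loci).
#' @export
gen_library_calls <- function(truth, n_libraries = 20, detect_k = 0.5,
                              fpkm_meanlog = 1, fpkm_sdlog = 1,
                              fp_rate = 0.2, seed = 1) {
  stopifnot(n_libraries >= 1)
  set.seed(child_seed(seed, "library_calls"))
  lnc_ids <- unique(truth$lnc$transcript_id)
  gene_ids <- unique(truth$genes$transcript_id)
  expr <- stats::setNames(
    stats::rlnorm(length(lnc_ids), fpkm_meanlog, fpkm_sdlog), lnc_ids
  )
  p_det <- expr / (expr + detect_k)

  fpkm <- matrix(0, length(lnc_ids), n_libraries,
    dimnames = list(lnc_ids, sprintf("lib%03d", seq_len(n_libraries)))
  )
  calls <- vector("list", n_libraries)
  score_rows <- list()
  gene_spans <- unlist(range(split(truth$genes, truth$genes$transcript_id)))

  for (l in seq_len(n_libraries)) {
    lib <- sprintf("lib%03d", l)
    det <- stats::runif(length(lnc_ids)) < p_det
    fpkm[det, l] <- expr[det] * stats::rlnorm(sum(det), 0, 0.3)

    parts <- list()
    if (any(det)) {
      ex <- truth$lnc[truth$lnc$transcript_id %in% lnc_ids[det]]
      tid <- paste0(ex$transcript_id, ".", lib)
      ## mono-exonic calls carry no splice junction, hence no strand --
      ## their orientation is what the CAGE step recovers downstream
      str <- ifelse(ex$class == "mono-exonic", "*",
                    as.character(GenomicRanges::strand(ex)))
      parts$lnc <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(ex)),
        start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
        strand = str,
        transcript_id = tid, noncoding = TRUE, stringsAsFactors = FALSE
      )
    }
    ## coding genes are detected broadly (they are highly expressed)
    det_g <- stats::runif(length(gene_ids)) < 0.9
    if (any(det_g)) {
      ex <- truth$genes[truth$genes$transcript_id %in% gene_ids[det_g]]
      parts$coding <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(ex)),
        start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
        strand = as.character(GenomicRanges::strand(ex)),
        transcript_id = paste0(ex$transcript_id, ".", lib),
        noncoding = FALSE, stringsAsFactors = FALSE
      )
    }
    ## false-positive mono-exonic fragments overlapping coding genes
    fp <- which(stats::runif(length(gene_spans)) < fp_rate)
    if (length(fp)) {
      gs <- gene_spans[fp]
      w <- sample(250:600, length(fp), replace = TRUE)
      anchor <- GenomicRanges::start(gs) +
        floor(stats::runif(length(fp)) * GenomicRanges::width(gs))
      ## fragments stay within 80 bp of the gene span: spurious calls hug
      ## the gene that spawned them rather than bridging to neighbours
      parts$fp <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gs)),
        start = pmax(
          pmax(1L, GenomicRanges::start(gs) - 80L),
          anchor - sample(0:200, length(fp), replace = TRUE)
        ),
        end = pmin(anchor + w, GenomicRanges::end(gs) + 80L),
        strand = sample(c("+", "-"), length(fp), replace = TRUE),
        transcript_id = sprintf("fp_%s_%03d", lib, seq_along(fp)),
        noncoding = TRUE, stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, parts)
    gr <- GenomicRanges::GRanges(
      tab$chrom, IRanges::IRanges(tab$start, tab$end), tab$strand,
      transcript_id = tab$transcript_id, library = lib
    )
    calls[[l]] <- gr
    score_rows[[l]] <- data.frame(
      transcript_id = unique(tab$transcript_id),
      noncoding = tab$noncoding[!duplicated(tab$transcript_id)],
      stringsAsFactors = FALSE
    )
  }
  names(calls) <- colnames(fpkm)
  sc <- do.call(rbind, score_rows)
  n <- nrow(sc)
  scores <- data.frame(
    transcript_id = sc$transcript_id,
    cpc_score = ifelse(sc$noncoding, stats::runif(n, -3, -0.5), stats::runif(n, 1, 5)),
    cpat_score = ifelse(sc$noncoding, stats::runif(n, 0, 0.35), stats::runif(n, 0.6, 1)),
    stringsAsFactors = FALSE
  )
  list(calls = calls, scores = scores, fpkm = fpkm, latent_expr = expr)
}

#' Simulate CAGE 5' tag positions
#'
#' Places `reads_per_tss` tags around the transcription start site of each
#' true lncRNA locus (on the locus strand, with Gaussian positional jitter)
#' plus `noise_tags` uniform single-read tags on random strands.
#'
#' @param truth Output of [gen_genome()], or any exon `GRanges` with
#'   `transcript_id`; the TSS is the 5'-most base of each transcript.
#' @param reads_per_tss Tags drawn per true TSS.
#' @param noise_tags Uniform noise tags across the genome.
#' @param jitter_sigma SD (bases) of tag positions around the TSS.
#' @param seed Integer seed.
#' @return A width-1 `GRanges` of tag positions with a `score` read count.
#' @export
gen_cage <- function(truth, reads_per_tss = 5, noise_tags = 200,
                     jitter_sigma = 3, seed = 1) {
  set.seed(child_seed(seed, "cage"))
  lnc <- if (is.list(truth) && !is.null(truth$lnc)) truth$lnc else truth
  spl <- split(lnc, lnc$transcript_id)
  spans <- unlist(range(spl))
  strand <- as.character(GenomicRanges::strand(spans))
  tss <- ifelse(strand == "-", GenomicRanges::end(spans), GenomicRanges::start(spans))
  chrom <- as.character(GenomicRanges::seqnames(spans))

  pos <- integer(0); chr <- character(0); str <- character(0)
  if (reads_per_tss > 0 && length(spans)) {
    n <- reads_per_tss * length(spans)
    pos <- pmax(1L, as.integer(round(rep(tss, each = reads_per_tss) +
      stats::rnorm(n, 0, jitter_sigma))))
    chr <- rep(chrom, each = reads_per_tss)
    str <- rep(strand, each = reads_per_tss)
  }
  if (noise_tags > 0) {
    if (is.list(truth) && !is.null(truth$spec)) {
      chroms <- sprintf("chrS%d", seq_len(truth$spec$n_chroms))
      clen <- truth$spec$chrom_length
    } else {
      chroms <- unique(chrom)
      clen <- max(GenomicRanges::end(spans))
    }
    chr <- c(chr, sample(chroms, noise_tags, replace = TRUE))
    pos <- c(pos, sample.int(clen, noise_tags, replace = TRUE))
    str <- c(str, sample(c("+", "-"), noise_tags, replace = TRUE))
  }
  if (!length(pos)) {
    gr <- GenomicRanges::GRanges()
    gr$score <- integer(0)
    return(gr)
  }
  ## collapse duplicate positions into read counts
  key <- paste(chr, pos, str)
  cnt <- table(key)
  first <- !duplicated(key)
  gr <- GenomicRanges::GRanges(
    chr[first], IRanges::IRanges(pos[first], width = 1), str[first],
    score = as.integer(cnt[key[first]])
  )
  sort(gr)
}
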