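test_that("child_seed is deterministic, tag-sensitive, and in range", {
  expect_identical(child_seed(1, "a"), child_seed(1, "a"))
  expect_false(child_seed(1, "a") == child_seed(1, "b"))
  expect_false(child_seed(1, "a") == child_seed(2, "a"))
  seeds <- vapply(1:200, function(s) child_seed(s, "video"), integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31 - 1))
  expect_equal(length(unique(seeds)), 200L)
})

test_that("gen_genome is deterministic and places loci without overlap", {
  a <- gen_genome(toy_genome_spec(seed = 4))
  b <- gen_genome(toy_genome_spec(seed = 4))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(start(a$genes), start(b$genes))
  c2 <- gen_genome(toy_genome_spec(seed = 5))
  expect_false(identical(as.character(a$genome), as.character(c2$genome)))

  ## spans of distinct transcripts never overlap and respect min_gap
  all_tx <- c(granges(a$genes), granges(a$lnc))
  all_tx$transcript_id <- c(a$genes$transcript_id, a$lnc$transcript_id)
  spans <- unlist(range(split(all_tx, all_tx$transcript_id)))
  hits <- findOverlaps(spans, spans, ignore.strand = TRUE)
  expect_true(all(queryHits(hits) == subjectHits(hits)))
  gaps <- distanceToNearest(spans, ignore.strand = TRUE)
  ## min_gap = 100 start-to-end offset -> >= 99 bases strictly between
  expect_true(all(mcols(gaps)$distance >= 99))
})

test_that("planted counts and classes match the spec", {
  spec <- toy_genome_spec(n_coding_genes = 10, n_true_lnc_multi = 3,
                          n_true_lnc_mono = 5, seed = 2)
  g <- gen_genome(spec)
  expect_equal(length(unique(g$genes$transcript_id)), 10L)
  lnc_cls <- tapply(g$lnc$class, g$lnc$transcript_id, unique)
  expect_equal(sum(lnc_cls == "multi-exonic"), 3L)
  expect_equal(sum(lnc_cls == "mono-exonic"), 5L)
  ## multi-exonic loci really have > 1 exon, mono exactly 1
  n_ex <- table(g$lnc$transcript_id)
  expect_true(all(n_ex[names(lnc_cls)[lnc_cls == "multi-exonic"]] > 1))
  expect_true(all(n_ex[names(lnc_cls)[lnc_cls == "mono-exonic"]] == 1))
  ## genome size as requested
  expect_equal(length(g$genome), spec$n_chroms)
  expect_true(all(width(g$genome) == spec$chrom_length))
})

test_that("region GC gradients land near their specified levels", {
  g <- gen_genome(toy_genome_spec(seed = 6))
  gc_exon <- gc_content(granges(g$genes), g$genome)
  lnc_ex <- granges(g$lnc)
  gc_lnc <- gc_content(lnc_ex, g$genome)
  ## intergenic: whole genome minus all placed spans
  all_tx <- c(granges(g$genes), lnc_ex)
  chrom_gr <- GRanges(names(g$genome), IRanges(1, width(g$genome)))
  inter <- setdiff(chrom_gr, all_tx + 500, ignore.strand = TRUE)
  gc_inter <- gc_content(inter, g$genome)
  expect_lt(abs(gc_exon - 0.42), 0.02)
  expect_lt(abs(gc_lnc - 0.38), 0.02)
  expect_lt(abs(gc_inter - 0.30), 0.02)
})

test_that("conservation is elevated in coding and multi-exonic lnc exons only", {
  g <- gen_genome(toy_genome_spec(seed = 6))
  cons <- g$conservation
  mean_over <- function(gr) {
    unname(conservation_summary(reduce(gr, ignore.strand = TRUE), cons))
  }
  multi <- g$lnc[g$lnc$class == "multi-exonic"]
  mono <- g$lnc[g$lnc$class == "mono-exonic"]
  expect_gt(mean(mean_over(granges(g$genes))), 1.8)
  expect_gt(mean(mean_over(granges(multi))), 1.8)
  expect_lt(abs(mean(mean_over(granges(mono)))), 0.2)
})

test_that("capacity errors stop generation instead of degrading silently", {
  expect_error(
    gen_genome(toy_genome_spec(chrom_length = 5000, n_coding_genes = 50)),
    "capacity"
  )
  expect_error(video_spec(n_worms = 5000), "capacity")
})

test_that("gen_library_calls produces consistent calls, scores and FPKM", {
  g <- gen_genome(toy_genome_spec(seed = 3))
  lib <- gen_library_calls(g, n_libraries = 5, seed = 3)
  expect_equal(length(lib$calls), 5L)
  expect_equal(colnames(lib$fpkm), names(lib$calls))
  expect_equal(sort(rownames(lib$fpkm)), sort(unique(g$lnc$transcript_id)))
  all_calls <- do.call(c, unname(lib$calls))
  ## every called transcript is scored exactly once
  expect_true(all(unique(all_calls$transcript_id) %in% lib$scores$transcript_id))
  expect_false(any(duplicated(lib$scores$transcript_id)))
  ## lnc-derived calls are scored non-coding, gene-derived coding
  sc <- lib$scores
  lnc_rows <- grepl("^lnc_", sc$transcript_id)
  gene_rows <- grepl("^gene_", sc$transcript_id)
  expect_true(all(sc$cpc_score[lnc_rows] < 0 & sc$cpat_score[lnc_rows] < 0.403))
  expect_true(all(sc$cpc_score[gene_rows] > 0 & sc$cpat_score[gene_rows] >= 0.403))
  ## false positives are also non-coding-scored (the intergenic filter's job)
  fp_rows <- grepl("^fp_", sc$transcript_id)
  if (any(fp_rows)) {
    expect_true(all(sc$cpc_score[fp_rows] < 0))
  }
  ## mono-exonic lnc calls are unstranded (no splice junction to orient them)
  mono_ids <- unique(g$lnc$transcript_id[g$lnc$class == "mono-exonic"])
  mono_calls <- all_calls[sub("\\.lib\\d+$", "", all_calls$transcript_id)
                          %in% mono_ids]
  if (length(mono_calls)) {
    expect_true(all(as.character(strand(mono_calls)) == "*"))
  }
  ## FPKM is only non-zero where the locus was detected in that library
  det_ids <- sub("\\.lib\\d+$", "", all_calls$transcript_id[
    grepl("^lnc_", all_calls$transcript_id)
  ])
  expect_true(all(rowSums(lib$fpkm) [rownames(lib$fpkm) %in% det_ids] > 0))
})

test_that("gen_cage places tag pileups at true TSSs plus uniform noise", {
  g <- gen_genome(toy_genome_spec(seed = 9))
  tags <- gen_cage(g, reads_per_tss = 8, noise_tags = 50, seed = 9)
  expect_true(all(width(tags) == 1))
  expect_true(all(tags$score >= 1))
  ## each true TSS should have substantial tag mass within +-10 nt
  spans <- unlist(range(split(g$lnc, g$lnc$transcript_id)))
  tss <- ifelse(as.character(strand(spans)) == "-", end(spans), start(spans))
  tss_gr <- GRanges(seqnames(spans), IRanges(tss - 10, tss + 10),
                    strand(spans))
  hits <- findOverlaps(tss_gr, tags)
  mass <- tapply(
    tags$score[subjectHits(hits)], queryHits(hits), sum
  )
  covered <- length(mass[mass >= 4])
  expect_gte(covered, length(spans) * 0.9)
})

test_that("gen_video output is consistent with its spec and truth table", {
  spec <- video_spec(n_worms = 4, n_frames = 8, height = 64, width = 80,
                     seed = 5)
  v <- gen_video(spec)
  expect_equal(dim(v$frames), c(64, 80, 8))
  expect_equal(v$timestamps, 0:7)
  expect_equal(v$true_count, 4L)
  expect_equal(nrow(v$truth), 4 * 8)
  expect_true(all(v$truth$x >= 1 & v$truth$x <= 80))
  expect_true(all(v$truth$y >= 1 & v$truth$y <= 64))
  ## determinism
  v2 <- gen_video(spec)
  expect_identical(v$frames, v2$frames)
  ## worms are dark: pixels near a truth position are below background
  r1 <- v$truth[v$truth$frame == 1, ]
  px <- v$frames[cbind(round(r1$y), round(r1$x), 1)]
  expect_true(all(px < 150))
  ## zero worms: pure noise around the background level
  v0 <- gen_video(video_spec(n_worms = 0, n_frames = 3, seed = 1))
  expect_equal(nrow(v0$truth), 0L)
  expect_lt(abs(mean(v0$frames) - 200), 1)
})

test_that("gen_growth_cohort draws logistic trajectories per the model", {
  strains <- data.frame(name = "s", growth_rate = 0.2, asymptote = 1000)
  coh <- gen_growth_cohort(strains, n_animals = 3, obs_noise = 0,
                           animal_cv = 0, t_max = 65 * 3600, seed = 2)
  expect_equal(length(unique(coh$animal)), 3L)
  ## noiseless, no animal variation: exact logistic values
  tt <- coh$t[coh$animal == 1]
  expect_equal(
    coh$area[coh$animal == 1],
    1000 / (1 + exp(-(0.2 / 3600) * (tt - 30 * 3600)))
  )
  expect_equal(coh$length, 3.5 * sqrt(coh$area))
  ## sampling grid: 60-s steps over 65 h
  expect_equal(sort(unique(coh$t)), seq(0, 65 * 3600, by = 60))
})

test_that("gen_brood respects means, day split and censoring flags", {
  strains <- data.frame(name = c("a", "b"), mean_brood = c(240, 120))
  rec <- gen_brood(strains, n_animals = 400, overdispersion = 0,
                   censor_prob = 0, seed = 3)
  expect_equal(nrow(rec), 800L)
  expect_false(any(rec$censored))
  tot <- total_brood(rec)
  ma <- mean(tot$total[tot$strain == "a"])
  mb <- mean(tot$total[tot$strain == "b"])
  expect_lt(abs(ma - 240), 3)
  expect_lt(abs(mb - 120), 3)
  ## day split close to 45/40/15
  da <- colMeans(rec[rec$strain == "a", c("day1", "day2", "day3")])
  expect_lt(max(abs(da / 240 - c(0.45, 0.40, 0.15))), 0.02)
  ## Poisson limit: variance near mean
  va <- var(tot$total[tot$strain == "a"])
  expect_lt(abs(va / 240 - 1), 0.35)
  ## overdispersed: variance well above the mean
  rec2 <- gen_brood(strains, n_animals = 400, overdispersion = 0.05,
                    censor_prob = 0, seed = 4)
  tot2 <- total_brood(rec2)
  expect_gt(var(tot2$total[tot2$strain == "a"]), 2 * 240)
  ## censoring happens at roughly the requested rate
  rec3 <- gen_brood(strains, n_animals = 400, censor_prob = 0.1, seed = 5)
  expect_lt(abs(mean(rec3$censored) - 0.1), 0.04)
})
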