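test_that("coding-potential thresholds are strict on both scores", {
  ex <- exons_gr("chrI", c(1, 101, 201, 301), c(50, 150, 250, 350),
    transcript_id = c("below", "cpat_at_cutoff", "cpc_at_zero", "coding")
  )
  scores <- data.frame(
    transcript_id = c("below", "cpat_at_cutoff", "cpc_at_zero", "coding"),
    cpc_score = c(-1, -1, 0, 2),
    cpat_score = c(0.4029, 0.403, 0.1, 0.9)
  )
  kept <- noncoding_filter(ex, scores)
  ## CPAT exactly 0.403 is coding; CPC exactly 0 is coding
  expect_equal(unique(kept$transcript_id), "below")
})

test_that("unscored transcripts are a hard error, not silently dropped", {
  ex <- exons_gr("chrI", 1, 50, transcript_id = "tx_unscored")
  scores <- data.frame(
    transcript_id = "other", cpc_score = -1, cpat_score = 0.1
  )
  expect_error(noncoding_filter(ex, scores), "tx_unscored")
})

test_that("merging groups transcripts by transitive exon overlap", {
  ## a-b overlap, b-c overlap (a-c do not): one locus by transitivity;
  ## d overlaps nothing; e overlaps a but on the other strand
  tx <- c(
    exons_gr("chrI", 100, 200, "+", "a"),
    exons_gr("chrI", 180, 300, "+", "b", library = "libB"),
    exons_gr("chrI", 290, 400, "+", "c"),
    exons_gr("chrI", 1000, 1100, "+", "d"),
    exons_gr("chrI", 120, 220, "-", "e")
  )
  loci <- merge_across_libraries(tx)
  got <- sort(vapply(
    as.list(mcols(loci)$members),
    function(m) paste(sort(m), collapse = ","), character(1)
  ))
  expect_equal(got, c("a,b,c", "d", "e"))
  expect_equal(got, brute_merge_groups(tx))
  abc <- loci[[which(vapply(as.list(mcols(loci)$members),
                            function(m) "a" %in% m, logical(1)))]]
  ## union model: 100..400 single block
  expect_equal(start(abc), 100L)
  expect_equal(end(abc), 400L)
})

test_that("merging matches a brute-force oracle on random fixtures", {
  for (rep in 1:20) {
    set.seed(6000 + rep)
    n <- sample(3:10, 1)
    tx <- do.call(c, lapply(seq_len(n), function(i) {
      st <- sample.int(2000, 1)
      exons_gr("chrI", st, st + sample(50:300, 1),
        strand = sample(c("+", "-", "*"), 1),
        transcript_id = sprintf("t%02d", i),
        library = sample(c("libA", "libB"), 1)
      )
    }))
    loci <- merge_across_libraries(tx)
    got <- sort(vapply(
      as.list(mcols(loci)$members),
      function(m) paste(sort(m), collapse = ","), character(1)
    ))
    expect_equal(got, brute_merge_groups(tx))
  }
})

test_that("unstranded transcripts bridge strands and locus strand rules hold", {
  ## "*" transcript overlaps both a + and a - transcript: all three merge,
  ## locus strand is "*" (no unique stranded value)
  tx <- c(
    exons_gr("chrI", 100, 200, "+", "p"),
    exons_gr("chrI", 150, 260, "*", "u"),
    exons_gr("chrI", 240, 340, "-", "m")
  )
  loci <- merge_across_libraries(tx)
  expect_equal(length(loci), 1L)
  expect_equal(as.character(strand(loci[[1]])[1]), "*")

  ## "*" + single stranded member: locus takes the stranded value
  tx2 <- c(
    exons_gr("chrI", 100, 200, "-", "m"),
    exons_gr("chrI", 150, 260, "*", "u")
  )
  loci2 <- merge_across_libraries(tx2)
  expect_equal(as.character(strand(loci2[[1]])[1]), "-")
})

test_that("locus metadata: class, exon count, exonic length, library support", {
  tx <- c(
    exons_gr("chrI", c(100, 400), c(200, 500), "+", c("a", "a"), "libA"),
    exons_gr("chrI", c(120, 390), c(210, 520), "+", c("b", "b"), "libB"),
    exons_gr("chrI", 1000, 1300, "+", "c", "libA")
  )
  loci <- merge_across_libraries(tx)
  mc <- mcols(loci)
  i_ab <- which(vapply(as.list(mc$members), function(m) "a" %in% m, logical(1)))
  i_c <- which(vapply(as.list(mc$members), function(m) "c" %in% m, logical(1)))
  expect_equal(mc$class[i_ab], "multi-exonic")
  expect_equal(mc$n_exons[i_ab], 2L)
  ## union blocks: 100..210 (111 nt) and 390..520 (131 nt)
  expect_equal(mc$exonic_length[i_ab], 111L + 131L)
  expect_equal(mc$n_supporting_libraries[i_ab], 2L)
  expect_equal(mc$class[i_c], "mono-exonic")
  expect_equal(mc$n_supporting_libraries[i_c], 1L)
  ## loci come back position-ordered with sequential ids
  expect_equal(mc$locus_id, sprintf("LOC_%05d", seq_along(loci)))
  expect_true(start(loci[[1]])[1] <= start(loci[[2]])[1])
})

test_that("a locus is dropped if any member transcript is coding", {
  tx <- c(
    exons_gr("chrI", 100, 300, "+", "nc1"),
    exons_gr("chrI", 250, 450, "+", "cod"),
    exons_gr("chrI", 1000, 1250, "+", "nc2")
  )
  scores <- data.frame(
    transcript_id = c("nc1", "cod", "nc2"),
    cpc_score = c(-2, 1.5, -1),
    cpat_score = c(0.1, 0.8, 0.2)
  )
  loci <- merge_across_libraries(tx)
  kept <- filter_noncoding_loci(loci, scores)
  expect_equal(length(kept), 1L)
  expect_equal(unlist(mcols(kept)$members), "nc2")
})

test_that("length filter requires exonic length strictly over 200 nt", {
  ## mono-exonic loci of exactly 200 nt and 201 nt, far from any gene
  tx <- c(
    exons_gr("chrI", 1000, 1199, "+", "len200"), # width 200
    exons_gr("chrI", 5000, 5200, "+", "len201") # width 201
  )
  loci <- merge_across_libraries(tx)
  ann <- GRanges("chrI", IRanges(90000, 91000), "+")
  kept <- intergenic_filter(loci, ann)
  expect_equal(unlist(mcols(kept)$members), "len201")
})

test_that("length filter counts summed exonic length, not genomic span", {
  ## two 100-nt exons spanning 500 nt: exonic length 200 -> dropped under
  ## the default, kept under length_mode = "span"
  tx <- exons_gr("chrI", c(1000, 1400), c(1099, 1499), "+", c("tx", "tx"))
  loci <- merge_across_libraries(tx)
  ann <- GRanges("chrI", IRanges(90000, 91000), "+")
  expect_equal(length(intergenic_filter(loci, ann)), 0L)
  expect_equal(length(intergenic_filter(loci, ann, length_mode = "span")), 1L)
})

test_that("any-strand gene overlap removes a locus", {
  tx <- c(
    exons_gr("chrI", 1000, 1300, "+", "hits_plus"),
    exons_gr("chrI", 5000, 5300, "+", "hits_minus"),
    exons_gr("chrI", 9000, 9300, "+", "clear")
  )
  loci <- merge_across_libraries(tx)
  ann <- c(
    GRanges("chrI", IRanges(1290, 1500), "+"), # same strand, 11 bp overlap
    GRanges("chrI", IRanges(5300, 5600), "-") # opposite strand, 1 bp overlap
  )
  kept <- intergenic_filter(loci, ann)
  expect_equal(unlist(mcols(kept)$members), "clear")
})

test_that("same-strand distance rule: 49 nt too close, 50 nt passes", {
  ## one gene at 2000..3000 (+) per chromosome; candidates on separate
  ## chromosomes so they cannot merge with each other.
  ## distance = bases strictly between features.
  tx <- exons_gr(
    c("chrI", "chrII", "chrIII"),
    c(3050, 3051, 3050), # 49, 50 and 49 bases strictly between
    c(3350, 3351, 3350),
    strand = c("+", "+", "-"), # the last is opposite strand, hence exempt
    transcript_id = c("gap49", "gap50", "gap49_minus")
  )
  loci <- merge_across_libraries(tx)
  ann <- GRanges(c("chrI", "chrII", "chrIII"), IRanges(2000, 3000), "+")
  kept <- intergenic_filter(loci, ann)
  got <- sort(unlist(mcols(kept)$members))
  expect_equal(got, c("gap49_minus", "gap50"))
})

test_that("unstranded loci face the overlap rule but not the distance rule", {
  tx <- exons_gr(
    c("chrI", "chrII"), c(3010, 2990), c(3310, 3310), # 9 nt away / overlapping
    strand = "*",
    transcript_id = c("near_unstranded", "overlapping_unstranded")
  )
  loci <- merge_across_libraries(tx)
  ann <- GRanges(c("chrI", "chrII"), IRanges(2000, 3000), "+")
  kept <- intergenic_filter(loci, ann)
  expect_equal(unlist(mcols(kept)$members), "near_unstranded")
})

test_that("empty annotation warns and applies the length rule only", {
  tx <- exons_gr("chrI", 1000, 1300, "+", "tx")
  loci <- merge_across_libraries(tx)
  expect_warning(kept <- intergenic_filter(loci, GRanges()), "vacuously")
  expect_equal(length(kept), 1L)
})
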