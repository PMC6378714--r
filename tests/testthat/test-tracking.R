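test_that("lap_solve solves small known assignment problems", {
  ## classic 3x3 with a unique optimum
  cost <- matrix(c(
    4, 1, 3,
    2, 0, 5,
    3, 2, 2
  ), 3, 3, byrow = TRUE)
  sol <- lap_solve(cost)
  expect_equal(sol$cost, 1 + 2 + 2) # (1,2),(2,1),(3,3)
  expect_equal(sol$assignment, c(2L, 1L, 3L))
  ## identity is optimal on a diagonal-dominant matrix
  d <- matrix(10, 4, 4)
  diag(d) <- 0
  expect_equal(lap_solve(d)$assignment, 1:4)
  expect_equal(lap_solve(d)$cost, 0)
})

test_that("lap_solve matches exhaustive search on random square matrices", {
  set.seed(301)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n, 0, 100), n, n)
    sol <- lap_solve(cost)
    ref <- brute_lap(cost)
    expect_equal(sol$cost, ref$cost, tolerance = 1e-10)
    ## the assignment must be a permutation achieving that cost
    expect_equal(sort(sol$assignment), 1:n)
    expect_equal(sum(cost[cbind(1:n, sol$assignment)]), ref$cost,
      tolerance = 1e-10
    )
  }
})

test_that("lap_solve handles rectangular matrices both ways", {
  set.seed(302)
  for (rep in 1:20) {
    n <- sample(1:4, 1)
    m <- n + sample(1:3, 1)
    ## wide: all rows assigned to distinct columns
    cost <- matrix(runif(n * m, 0, 50), n, m)
    sol <- lap_solve(cost)
    ref <- brute_lap(cost)
    expect_equal(sol$cost, ref$cost, tolerance = 1e-10)
    expect_false(anyNA(sol$assignment))
    expect_equal(length(unique(sol$assignment)), n)
    ## tall: every column gets a distinct row; surplus rows NA
    tall <- t(cost)
    sol2 <- lap_solve(tall)
    expect_equal(sol2$cost, ref$cost, tolerance = 1e-10)
    asn <- sol2$assignment
    expect_equal(sum(!is.na(asn)), n)
    expect_equal(sum(tall[cbind(which(!is.na(asn)), asn[!is.na(asn)])]),
      ref$cost,
      tolerance = 1e-10
    )
  }
})

test_that("lap_solve respects Inf as a forbidden pairing", {
  cost <- matrix(c(
    1, Inf,
    Inf, 1
  ), 2, 2, byrow = TRUE)
  expect_equal(lap_solve(cost)$assignment, c(1L, 2L))
  cost2 <- matrix(c(
    Inf, 1,
    1, Inf
  ), 2, 2, byrow = TRUE)
  expect_equal(lap_solve(cost2)$assignment, c(2L, 1L))
  expect_error(lap_solve(matrix(Inf, 2, 2)), "infeasible")
})

test_that("degenerate inputs give empty assignments", {
  sol <- lap_solve(matrix(numeric(0), 0, 0))
  expect_equal(length(sol$assignment), 0L)
  expect_equal(sol$cost, 0)
})

make_dets <- function(frame, x, y) {
  data.frame(frame = frame, t = frame, x = x, y = y,
             area = 10, length = 5)
}

test_that("link_tracks follows two well-separated moving animals", {
  ## animal A marches right along y=10, animal B along y=100
  det <- rbind(
    make_dets(1:5, x = 10 + 3 * (0:4), y = 10),
    make_dets(1:5, x = 50 - 3 * (0:4), y = 100)
  )
  det <- det[sample(nrow(det)), ] # order must not matter
  tr <- link_tracks(det, max_link_dist = 10)
  expect_equal(length(unique(tr$animal)), 2L)
  counts <- table(tr$animal)
  expect_true(all(counts == 5))
  ## each track keeps a constant y
  ys <- tapply(tr$y, tr$animal, function(v) length(unique(v)))
  expect_true(all(ys == 1))
})

test_that("a jump beyond max_link_dist starts a new trajectory", {
  det <- rbind(
    make_dets(1, 10, 10),
    make_dets(2, 12, 10), # close: same track
    make_dets(3, 90, 90) # far: new track
  )
  tr <- link_tracks(det, max_link_dist = 20)
  tr <- tr[order(tr$frame), ]
  expect_equal(tr$animal[1], tr$animal[2])
  expect_true(tr$animal[3] != tr$animal[1])
})

test_that("max_gap_frames bridges short disappearances", {
  det <- rbind(
    make_dets(1, 10, 10),
    make_dets(2, 13, 10),
    ## missing in frame 3
    make_dets(4, 19, 10)
  )
  ## gap 0: track closed at frame 3, re-detection starts a new one
  tr0 <- link_tracks(det, max_link_dist = 15, max_gap_frames = 0)
  expect_equal(length(unique(tr0$animal)), 2L)
  ## gap 1: the same animal continues
  tr1 <- link_tracks(det, max_link_dist = 15, max_gap_frames = 1)
  expect_equal(length(unique(tr1$animal)), 1L)
})

test_that("crossing animals are assigned by global minimum cost", {
  ## two animals approach and swap x positions; nearest-neighbor greedy
  ## could pair both to one detection, assignment cannot
  det <- rbind(
    make_dets(1, c(10, 20), c(10, 10)),
    make_dets(2, c(14, 16), c(10, 10))
  )
  tr <- link_tracks(det, max_link_dist = 10)
  expect_equal(length(unique(tr$animal)), 2L)
  expect_true(all(table(tr$animal) == 2))
  ## total frame-1 -> frame-2 displacement is minimized: 10->14, 20->16
  a1 <- tr$animal[tr$frame == 1 & tr$x == 10]
  expect_equal(tr$x[tr$animal == a1 & tr$frame == 2], 14)
})

test_that("every detection belongs to exactly one trajectory", {
  set.seed(99)
  det <- do.call(rbind, lapply(1:6, function(f) {
    make_dets(f, x = runif(4, 0, 100), y = runif(4, 0, 100))
  }))
  tr <- link_tracks(det, max_link_dist = 15)
  expect_equal(nrow(tr), nrow(det))
  expect_false(anyNA(tr$animal))
  ## a trajectory has at most one detection per frame
  expect_true(all(table(tr$animal, tr$frame) <= 1))
})

test_that("link_tracks validates input and passes empty frames through", {
  expect_error(link_tracks(data.frame(frame = 1)), "lack columns")
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0))
  out <- link_tracks(empty)
  expect_equal(nrow(out), 0L)
  expect_true("animal" %in% names(out))
})

test_that("tracking a synthetic video recovers roughly the planted count", {
  v <- gen_video(video_spec(n_worms = 5, seed = 11))
  det <- detect_all(v)
  tr <- link_tracks(det, max_link_dist = 3 * 3 + 6, max_gap_frames = 1)
  ## long tracks (>= 5 frames) correspond to real animals
  long <- sum(table(tr$animal) >= 5)
  expect_gte(long, 4)
  expect_lte(long, 7)
})
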