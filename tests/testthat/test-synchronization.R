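# TC3 split, IP/MA anchoring, Viterbi decoding, manual annotations.

# Independent TC3 oracle: literal double loop over splits, recomputing both
# segment means and costs from scratch.
tc3_bruteforce <- function(z) {
  n <- nrow(z)
  best <- Inf; bests <- NA
  for (s in 2:n) {
    cost <- 0
    for (j in seq_len(ncol(z))) {
      m1 <- mean(z[1:(s - 1), j]); m2 <- mean(z[s:n, j])
      cost <- cost + sum((z[1:(s - 1), j] - m1)^2) + sum((z[s:n, j] - m2)^2)
    }
    if (cost < best - 1e-12) { best <- cost; bests <- s }
  }
  list(split = bests, cost = best)
}

zsc <- function(x) apply(as.matrix(x), 2, function(v) {
  s <- sd(v); if (!is.finite(s) || s == 0) s <- 1; (v - mean(v)) / s
})

test_that("TC3 finds a noiseless step exactly and breaks ties to the earliest split", {
  x <- matrix(rep(c(0, 0, 0, 0, 10, 10, 10), 4), ncol = 4)
  expect_equal(tc3_split(x)$split, 5L)     # first frame of the second segment
  const <- matrix(1, 10, 4)
  expect_equal(tc3_split(const)$split, 2L)
  expect_error(tc3_split(matrix(1, 1, 4)), "2 frames")
})

test_that("TC3 equals the exhaustive double-loop cost evaluator on random sequences", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    k <- sample(2:(n - 1), 1)
    x <- matrix(rnorm(n * 4), n, 4)
    x[k:n, ] <- x[k:n, ] + rep(rnorm(4, 0, 2), each = n - k + 1)
    res <- tc3_split(x)
    oracle <- tc3_bruteforce(zsc(x))
    expect_equal(res$split, oracle$split)
    expect_equal(res$cost, oracle$cost, tolerance = 1e-9)
  }
})

test_that("TC3 respects a restricted search range", {
  x <- matrix(rep(c(0, 0, 0, 0, 10, 10, 10, 10), 2), ncol = 2)
  expect_equal(tc3_split(x, search_range = 2:4)$split, 4L)  # clamps inside
  expect_error(tc3_split(x, search_range = c(1, 5)), "search_range")
})

test_that("detect_ip flags trajectories without condensation as low-confidence", {
  set.seed(4)
  flat <- matrix(rnorm(30 * 4, 50, 1), 30, 4)
  r <- detect_ip(flat)
  expect_true(r$low_confidence)
  stepped <- flat
  stepped[15:30, ] <- stepped[15:30, ] + 10
  r2 <- detect_ip(stepped)
  expect_false(r2$low_confidence)
  expect_equal(r2$ip, 15L)
})

test_that("MA repositioning takes the first threshold crossing, falling back to the division frame", {
  d <- c(rep(0, 4), 2, 4, 7, 11)
  expect_equal(reposition_ma(d, division_index = 5, threshold = 6), 7L)
  expect_equal(reposition_ma(d, division_index = 5, threshold = 100), 5L)
})

test_that("Viterbi reproduces a certain path and never emits illegal transitions", {
  certain <- rbind(c(0, 1, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0),
                   c(0, 0, 1, 0), c(0, 0, 0, 1))
  s <- viterbi_decode(certain)
  expect_equal(attr(s, "path"), c(1L, 1L, 2L, 2L, 3L))
  expect_equal(s$ip, 3L); expect_equal(s$ma, 5L); expect_true(s$valid)
  # probabilities favouring the illegal order 1,3,2 decode to a legal path
  illegal <- rbind(c(0, 0.9, 0.05, 0.05), c(0.05, 0.05, 0.1, 0.8),
                   c(0.05, 0.05, 0.8, 0.1))
  p <- attr(viterbi_decode(illegal), "path")
  expect_false(any(diff(p[p > 0]) < 0))
  expect_error(viterbi_decode(rbind(c(0.5, 0.5, 0, 0), c(2, 0, 0, 0))),
               "sum to 1")
})

test_that("decoded state sequences always satisfy the monotone block invariant", {
  set.seed(21)
  for (i in 1:40) {
    TT <- sample(3:20, 1)
    probs <- matrix(runif(TT * 4), TT, 4)
    probs <- probs / rowSums(probs)
    s <- viterbi_decode(probs)
    path <- attr(s, "path")
    if (all(path == 0)) { expect_false(s$valid); next }
    expect_true(all(path > 0))
    expect_true(all(diff(path) >= 0))      # monotone 1 -> 2 -> 3
    if (s$valid) {
      expect_equal(s$states, path)
      expect_lt(s$ip, s$ma)
    }
  }
})

test_that("the all-invalid path marks the track rejected", {
  probs <- matrix(rep(c(0.97, 0.01, 0.01, 0.01), 6), 6, 4, byrow = TRUE)
  s <- viterbi_decode(probs)
  expect_false(s$valid)
  expect_true(all(s$states == 0L))
})

test_that("manual annotations fill states by the two-click convention and copy to the sibling", {
  res <- apply_annotation(90, last_interphase = 30, early_anaphase = 32)
  expect_equal(sum(res$a$states == 1L), 30)
  expect_equal(sum(res$a$states == 2L), 2)
  expect_equal(sum(res$a$states == 3L), 58)
  expect_identical(res$a$states, res$b$states)     # sibling copy rule
  rej <- apply_annotation(90, reject = TRUE)
  expect_false(rej$a$valid)
  expect_true(all(rej$a$states == 0L))
  expect_error(apply_annotation(90, last_interphase = 40,
                                early_anaphase = 35), "rejected annotation")
})

test_that("annotation files round-trip through CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(cell_id = c("d001_a", "d002_a"),
                       last_interphase_frame = c(20, 25),
                       early_anaphase_frame = c(31, 33),
                       reject = c(0, 1)), f, row.names = FALSE)
  a <- load_annotations(f)
  expect_equal(nrow(a), 2L)
  expect_equal(a$last_interphase_frame, c(20, 25))
  expect_error(load_annotations(withr::local_tempfile()), "not found")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), f2, row.names = FALSE)
  expect_error(load_annotations(f2), "lacks column")
})

test_that("the classical pathway and the HMM pathway agree on the fixture within one frame", {
  proj <- small_project()
  gm <- small_sim()
  ok <- 0L; total <- 0L
  for (cell in proj$cells) {
    if (cell$daughter != "a" || !cell$sync$valid) next
    total <- total + 1L
    probs <- builtin_state_probs(
      data.frame(area = cell$ts[, "area"], mean_int = cell$ts[, "mean_int"]),
      distances = cell$ts[, "sister_distance"] / proj$config$pixel_size,
      ma_threshold = proj$config$ma_threshold)
    s <- viterbi_decode(probs)
    if (s$valid && abs(s$ip - cell$sync$ip) <= 1 &&
        abs(s$ma - cell$sync$ma) <= 1) ok <- ok + 1L
  }
  expect_gte(total, 2L)
  expect_gte(ok / total, 0.9)
})
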