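test_that("greedy matching accepts the most certain (smallest) moves first", {
  prev <- tibble::tibble(x = c(0, 0), y = c(0, 3), label = 1:2)   # A, B
  now <- tibble::tibble(x = c(0, 0), y = c(1, 2), label = 1:2)    # a, b
  # distances: A-a 1, A-b 2, B-a 2, B-b 1 -> {A-a, B-b}
  m <- match_frames(now, prev, max_step = 5)
  expect_equal(m$prev, c(1L, 2L))
  expect_equal(m$now, c(1L, 2L))

  # the worked triple: A-a 1, A-b 2, B-b 3 (B-a out of reach)
  prev <- tibble::tibble(x = c(0, 100), y = c(0, 0), label = 1:2)
  now <- tibble::tibble(x = c(1, 2, 103), y = c(0, 0, 0), label = 1:3)
  m <- match_frames(now, prev, max_step = 3)
  expect_equal(nrow(m), 2L)
  expect_equal(m$now[m$prev == 1L], 1L)   # A-a at distance 1
  expect_equal(m$now[m$prev == 2L], 3L)   # B-b at distance 3
})

test_that("stationary well-separated cells match identically", {
  cells <- tibble::tibble(x = c(0, 50, 100), y = c(0, 0, 0), label = 1:3)
  m <- match_frames(cells, cells, max_step = 10)
  expect_equal(m$prev, m$now)
  expect_equal(m$distance, rep(0, 3))
})

test_that("greedy matching agrees with the optimal assignment on most jitter trials", {
  # brute-force minimal-total-distance assignment over all permutations
  brute_force <- function(prev, now, max_step) {
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    n <- nrow(prev)
    best <- NULL; best_cost <- Inf
    for (p in perms(seq_len(n))) {
      d <- sqrt((prev$x - now$x[p])^2 + (prev$y - now$y[p])^2)
      if (any(d > max_step)) next
      if (sum(d) < best_cost) { best_cost <- sum(d); best <- p }
    }
    best
  }
  set.seed(71)
  agree <- 0L
  n_trials <- 200L
  for (trial in seq_len(n_trials)) {
    prev <- tibble::tibble(x = runif(5, 0, 60), y = runif(5, 0, 60), label = 1:5)
    now <- tibble::tibble(x = prev$x + rnorm(5, 0, 2), y = prev$y + rnorm(5, 0, 2),
                          label = 1:5)
    m <- match_frames(now, prev, max_step = 20)
    opt <- brute_force(prev, now, max_step = 20)
    if (!is.null(opt) && nrow(m) == 5 &&
        all(m$now[order(m$prev)] == opt)) agree <- agree + 1L
  }
  expect_gte(agree / n_trials, 0.95)
})

test_that("gap repair inserts the midpoint and respects the distance bound", {
  # cell at (0,0) in frame 1, missing in frame 2, at (2,2) in frame 3
  segs <- list(
    tibble::tibble(x = 0, y = 0),
    tibble::tibble(x = numeric(0), y = numeric(0)),
    tibble::tibble(x = 2, y = 2)
  )
  s <- settings(highest_cell_velocity = 1, shortest_cell_track = 2)
  tr <- build_tracks(segs, s, dt = 10)
  expect_equal(dplyr::n_distinct(tr$track), 1L)
  mid <- tr[tr$frame == 2L, ]
  expect_equal(c(mid$x, mid$y), c(1, 1))
  expect_true(mid$repaired)
  expect_false(any(tr$repaired[tr$frame != 2L]))

  # candidate beyond 2 x max_step is not used for repair
  segs2 <- list(
    tibble::tibble(x = 0, y = 0),
    tibble::tibble(x = numeric(0), y = numeric(0)),
    tibble::tibble(x = 50, y = 0)   # 50 um > 2 * (1 um/min * 10 min)
  )
  tr2 <- build_tracks(segs2, s, dt = 10)
  expect_equal(dplyr::n_distinct(tr2$track), 2L)
  expect_false(any(tr2$repaired))
})

test_that("deleted detections are repaired exactly at the deleted frames", {
  set.seed(72)
  n_frames <- 15
  # three drifting cells; every 7th detection of cell 2 deleted
  base <- lapply(seq_len(n_frames), function(t) {
    tibble::tibble(x = c(10, 60, 110) + t, y = c(10, 60, 110), label = 1:3)
  })
  deleted <- c(7L, 14L)
  segs <- lapply(seq_len(n_frames), function(t) {
    d <- base[[t]]
    if (t %in% deleted) d <- d[-2, ]
    d
  })
  tr <- build_tracks(segs, settings(highest_cell_velocity = 1, shortest_cell_track = 2), dt = 10)
  expect_equal(dplyr::n_distinct(tr$track), 3L)
  lens <- dplyr::count(tr, track)
  expect_equal(lens$n, rep(n_frames, 3))
  rep_frames <- sort(tr$frame[tr$repaired])
  expect_equal(rep_frames, deleted)
})

test_that("K well-separated synthetic cells yield exactly K full-length tracks", {
  spec <- synthetic_spec(width_px = 360, height_px = 360, n_frames = 10,
                         n_cells = 15, sigma_step = 1.5, noise_sd = 2, seed = 73)
  gv <- generate_video(spec)
  run <- track_video(gv$stack, syn_settings())
  expect_equal(dplyr::n_distinct(run$tracks$track), 15L)
  expect_equal(nrow(run$tracks), 15L * 10L)
})

test_that("a division adds one track; the nearest daughter continues the old one", {
  # deterministic detections: cell splits at frame 4
  segs <- lapply(1:8, function(t) {
    if (t < 4) tibble::tibble(x = c(20, 80), y = c(50, 50), label = 1:2)
    else tibble::tibble(x = c(20 - (t - 4), 20 + 8 + (t - 4), 80), y = c(50, 50, 50),
                        label = 1:3)
  })
  tr <- build_tracks(segs, settings(highest_cell_velocity = 1.2, shortest_cell_track = 2), dt = 10)
  expect_equal(dplyr::n_distinct(tr$track), 3L)
  # the continued track keeps its pre-division history
  lens <- sort(dplyr::count(tr, track)$n)
  expect_equal(lens, c(5L, 8L, 8L))
})

test_that("track smoothing is endpoint-preserving, idempotent on lines, contracting on zigzags", {
  line <- make_track(x = seq(0, 40, by = 10), y = seq(0, 20, by = 5))
  expect_equal(smooth_tracks(line, 0), line)
  sm <- smooth_tracks(line, 3)
  expect_equal(sm$x, line$x)
  expect_equal(sm$y, line$y)

  zig <- make_track(x = seq(0, 9) * 5, y = rep(c(0, 4), 5))
  acc <- function(tr) sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  euc <- function(tr) sqrt((tr$x[nrow(tr)] - tr$x[1])^2 + (tr$y[nrow(tr)] - tr$y[1])^2)
  prev <- zig
  for (i in 1:4) {
    cur <- smooth_tracks(prev, 1)
    expect_lt(acc(cur), acc(prev))
    expect_equal(euc(cur), euc(zig))
    prev <- cur
  }
})

test_that("validity filtering is a monotone threshold on track length", {
  set.seed(74)
  tr <- tibble::tibble(
    track = rep(1:6, times = c(2, 3, 5, 7, 9, 4)),
    frame = unlist(lapply(c(2, 3, 5, 7, 9, 4), seq_len)),
    x = rnorm(30), y = rnorm(30), repaired = FALSE)
  attr(tr, "dt") <- 10
  class(tr) <- c("pt_tracks", class(tr))
  expect_equal(dplyr::n_distinct(filter_valid_tracks(tr, 2)$track), 6L)
  expect_equal(dplyr::n_distinct(filter_valid_tracks(tr, 5)$track), 3L)
  counts <- vapply(2:10, function(k) dplyr::n_distinct(filter_valid_tracks(tr, k)$track), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("the linker does not bias Brownian step lengths (KS vs Rayleigh)", {
  spec <- synthetic_spec(width_px = 420, height_px = 420, n_frames = 25,
                         n_cells = 20, sigma_step = 2, noise_sd = 2, seed = 75)
  gv <- generate_video(spec)
  run <- track_video(gv$stack, syn_settings())
  steps <- step_velocities(run$valid_tracks) * run$dt   # step lengths, um
  expect_gte(length(steps), 400)
  ks <- stats::ks.test(steps, function(q) 1 - exp(-q^2 / (2 * 2^2)))
  expect_gt(ks$p.value, 0.01)
})
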