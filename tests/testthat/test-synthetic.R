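test_that("the generator is deterministic and honours its motion model", {
  spec <- synthetic_spec(width_px = 220, height_px = 220, n_frames = 5,
                         n_cells = 8, seed = 101)
  a <- generate_video(spec)
  b <- generate_video(spec)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)

  # sigma = 0, drift = 0: truth static, frames identical up to noise
  spec0 <- synthetic_spec(width_px = 220, height_px = 220, n_frames = 4,
                          n_cells = 8, sigma_step = 0, noise_sd = 0, seed = 102)
  gv0 <- generate_video(spec0)
  expect_identical(gv0$stack$frames[[1]], gv0$stack$frames[[4]])
  spread <- gv0$truth |>
    dplyr::group_by(cell) |>
    dplyr::summarise(dx = diff(range(x)), dy = diff(range(y)))
  expect_equal(max(spread$dx, spread$dy), 0)

  # pure drift advances truth exactly drift um per step
  specd <- synthetic_spec(width_px = 260, height_px = 260, n_frames = 6,
                          n_cells = 5, sigma_step = 0, drift = c(0.3, 0),
                          noise_sd = 0, seed = 103)
  gvd <- generate_video(specd)
  steps <- gvd$truth |>
    dplyr::arrange(cell, frame) |>
    dplyr::group_by(cell) |>
    dplyr::reframe(dx = diff(x), dy = diff(y))
  expect_equal(steps$dx, rep(0.3, nrow(steps)))
  expect_equal(steps$dy, rep(0, nrow(steps)))
})

test_that("ground-truth step lengths follow the requested Brownian model (KS)", {
  spec <- synthetic_spec(width_px = 600, height_px = 600, n_frames = 30,
                         n_cells = 70, sigma_step = 2, noise_sd = 0, seed = 104)
  gv <- generate_video(spec)
  steps <- gv$truth |>
    dplyr::arrange(cell, frame) |>
    dplyr::group_by(cell) |>
    dplyr::reframe(len = sqrt(diff(x)^2 + diff(y)^2)) |>
    dplyr::pull(len)
  expect_gte(length(steps), 2000)
  ks <- stats::ks.test(steps, function(q) 1 - exp(-q^2 / (2 * 2^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("over-crowded specifications fail loudly", {
  expect_error(generate_video(synthetic_spec(width_px = 100, height_px = 100,
                                             n_cells = 60, seed = 105)),
               "crowded")
})

test_that("a perfect tracker fed the truth scores zero switches and zero error", {
  spec <- synthetic_spec(width_px = 300, height_px = 300, n_frames = 8,
                         n_cells = 12, sigma_step = 2, seed = 106)
  gv <- generate_video(spec)
  tracks <- gv$truth |>
    dplyr::transmute(track = cell, frame, x, y, repaired = FALSE)
  attr(tracks, "dt") <- spec$dt
  class(tracks) <- c("pt_tracks", class(tracks))
  ev <- evaluate_tracking(tracks, gv$truth)
  expect_equal(ev$n_switches, 0L)
  expect_equal(max(ev$position_errors), 0)
  expect_equal(ev$fraction_full_length, 1)
})

test_that("noisy detections give Rayleigh-scale position errors without switches", {
  spec <- synthetic_spec(width_px = 420, height_px = 420, n_frames = 12,
                         n_cells = 20, sigma_step = 2, seed = 107)
  gv <- generate_video(spec)
  set.seed(108)
  noisy <- gv$truth |>
    dplyr::transmute(track = cell, frame,
                     x = x + rnorm(dplyr::n()), y = y + rnorm(dplyr::n()),
                     repaired = FALSE)
  attr(noisy, "dt") <- spec$dt
  class(noisy) <- c("pt_tracks", class(noisy))
  ev <- evaluate_tracking(noisy, gv$truth)
  expect_equal(ev$n_switches, 0L)
  # |N(0,1), N(0,1)| is Rayleigh(1): mean sqrt(pi/2)
  expect_equal(mean(ev$position_errors), sqrt(pi / 2), tolerance = 0.1)
})

test_that("crossing cells report their identity switches rather than hiding them", {
  truth <- dplyr::bind_rows(
    tibble::tibble(cell = 1L, frame = 1:9, x = seq(0, 80, by = 10), y = 40),
    tibble::tibble(cell = 2L, frame = 1:9, x = seq(80, 0, by = -10), y = 44))
  # a tracker that swaps cells where the paths cross: each track carries
  # one switch, reported, not hidden
  swapA <- dplyr::bind_rows(truth[truth$cell == 1L & truth$frame <= 4, ],
                            truth[truth$cell == 2L & truth$frame >= 5, ])
  swapB <- dplyr::bind_rows(truth[truth$cell == 2L & truth$frame <= 4, ],
                            truth[truth$cell == 1L & truth$frame >= 5, ])
  tracks <- dplyr::bind_rows(
    dplyr::transmute(swapA, track = 1L, frame, x, y, repaired = FALSE),
    dplyr::transmute(swapB, track = 2L, frame, x, y, repaired = FALSE))
  attr(tracks, "dt") <- 10
  class(tracks) <- c("pt_tracks", class(tracks))
  ev <- evaluate_tracking(tracks, truth, radius = 3)
  expect_equal(ev$n_switches, 2L)
  expect_equal(sort(ev$per_track$switches), c(1L, 1L))

  # the faithful tracker reports zero switches on the same scene
  faithful <- dplyr::transmute(truth, track = cell, frame, x, y, repaired = FALSE)
  attr(faithful, "dt") <- 10
  class(faithful) <- c("pt_tracks", class(faithful))
  expect_equal(evaluate_tracking(faithful, truth, radius = 3)$n_switches, 0L)
})

test_that("rendering then segmenting recovers the cell count at moderate density", {
  for (K in c(5L, 20L, 50L)) {
    spec <- synthetic_spec(width_px = 520, height_px = 520, n_frames = 2,
                           n_cells = K, sigma_step = 0, noise_sd = 2,
                           seed = 110 + K)
    gv <- generate_video(spec)
    seg <- segment_frame(gv$stack$frames[[1]], syn_settings())
    expect_equal(seg$n_identified, K)
  }
})

test_that("synthetic stacks exercise the public TIFF and CSV paths", {
  spec <- synthetic_spec(width_px = 160, height_px = 160, n_frames = 3,
                         n_cells = 4, seed = 115)
  gv <- generate_video(spec)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_stack(gv$stack, tif)
  back <- read_stack(tif, settings(pixel_size = spec$pixel_size,
                                   time_between_images = spec$dt))
  expect_equal(length(back$frames), 3L)
  # lossless round-trip up to the 8-bit quantisation of working floats
  expect_lt(max(abs(back$frames[[1]] - gv$stack$frames[[1]])), 0.5 + 1e-9)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(dplyr::transmute(gv$truth, track = cell, frame, x, y), csv)
  expect_equal(nrow(read_track_csv(csv)), nrow(gv$truth))
})
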