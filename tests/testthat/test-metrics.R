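test_that("track metrics reproduce the collinear and right-angle worked examples", {
  straight <- make_track(x = c(0, 5, 10, 15, 20), y = rep(0, 5), dt = 10)
  m <- track_metrics(straight)
  expect_equal(m$mean_step_velocity, 0.5)
  expect_equal(m$directness, 1)
  expect_equal(m$euclidean_distance, 20)
  expect_equal(m$duration, 40)

  right_angle <- make_track(x = c(0, 10, 10), y = c(0, 0, 10), dt = 10)
  m <- track_metrics(right_angle)
  expect_equal(m$accumulated_distance, 20)
  expect_equal(m$euclidean_distance, sqrt(200))
  expect_equal(m$directness, sqrt(200) / 20)

  down <- make_track(x = rep(0, 4), y = c(0, 5, 10, 15), dt = 10)
  m <- track_metrics(down)
  expect_equal(m$fmi_y, 1)
  expect_equal(m$fmi_x, 0)
})

test_that("directness identity holds to 1e-12 on random tracks and static tracks give NA", {
  set.seed(81)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    tr <- make_track(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)), dt = 10)
    m <- track_metrics(tr)
    expect_gte(m$directness, 0)
    expect_lte(m$directness, 1)
    expect_equal(m$directness, m$euclidean_distance / m$accumulated_distance,
                 tolerance = 1e-12)
    expect_lte(abs(m$fmi_x), 1)
    expect_lte(abs(m$fmi_y), 1)
    expect_lte(m$euclidean_distance, m$accumulated_distance + 1e-12)
  }
  static <- make_track(x = rep(3, 5), y = rep(4, 5), dt = 10)
  m <- track_metrics(static)
  expect_true(is.na(m$directness))
  expect_true(is.na(m$fmi_x))
})

test_that("smoothing never increases accumulated distance, so never decreases directness", {
  set.seed(82)
  for (i in 1:10) {
    tr <- make_track(x = cumsum(rnorm(15)), y = cumsum(rnorm(15)), dt = 10)
    m0 <- track_metrics(tr)
    m1 <- track_metrics(smooth_tracks(tr, 1))
    expect_lte(m1$accumulated_distance, m0$accumulated_distance + 1e-12)
    expect_equal(m1$euclidean_distance, m0$euclidean_distance)
    expect_gte(m1$directness, m0$directness - 1e-12)
  }
})

test_that("wound mode flips FMIy so positive means motion into the wound", {
  # two tracks above the wound moving down, two below moving up
  mk <- function(id, y0, dy) {
    tibble::tibble(track = id, frame = 1:5, x = 0, y = y0 + (0:4) * dy, repaired = FALSE)
  }
  tr <- dplyr::bind_rows(mk(1, 0, 2), mk(2, 10, 2), mk(3, 100, -2), mk(4, 110, -2))
  attr(tr, "dt") <- 10
  class(tr) <- c("pt_tracks", class(tr))
  m <- wound_signed_fmi(track_metrics(tr))
  expect_equal(m$start_side, c("top", "top", "bottom", "bottom"))
  expect_true(all(m$fmi_y > 0))

  # symmetric wound: signed mean positive, unsigned mean ~ 0
  unsigned <- track_metrics(tr)
  expect_equal(mean(unsigned$fmi_y), 0)
  expect_gt(mean(m$fmi_y), 0)
})

test_that("a symmetric synthetic wound gives positive signed and near-zero unsigned FMIy", {
  spec <- synthetic_spec(width_px = 500, height_px = 500, n_frames = 12,
                         n_cells = 40, sigma_step = 1, noise_sd = 2,
                         wound = list(half_width = 60, inflow = 1.5), seed = 150)
  gv <- generate_video(spec)
  run_w <- track_video(gv$stack, syn_settings(wound_healing_mode = TRUE))
  run_u <- track_video(gv$stack, syn_settings())
  expect_gt(mean(run_w$metrics$fmi_y, na.rm = TRUE), 0.5)
  expect_lt(abs(mean(run_u$metrics$fmi_y, na.rm = TRUE)), 0.1)
  expect_setequal(unique(run_w$metrics$start_side), c("top", "bottom"))
})

test_that("mean velocity over time matches drift and the two-stage mean definition", {
  drift <- dplyr::bind_rows(lapply(1:30, function(id) {
    tibble::tibble(track = id, frame = 1:11, x = id * 30 + (0:10) * 3, y = 0,
                   repaired = FALSE)
  }))
  attr(drift, "dt") <- 10
  class(drift) <- c("pt_tracks", class(drift))
  fs <- mean_velocity_over_time(drift)
  expect_equal(nrow(fs), 10L)
  expect_equal(fs$mean_velocity, rep(0.3, 10))
  expect_equal(fs$n, rep(30L, 10))

  # two-stage mean (per-step means averaged over steps) on an uneven fixture
  set.seed(83)
  tr <- dplyr::bind_rows(
    tibble::tibble(track = 1, frame = 1:6, x = cumsum(c(0, runif(5, 0, 5))), y = 0),
    tibble::tibble(track = 2, frame = 3:6, x = 100 + cumsum(c(0, runif(3, 0, 5))), y = 0))
  tr$repaired <- FALSE
  attr(tr, "dt") <- 10
  class(tr) <- c("pt_tracks", class(tr))
  fs <- mean_velocity_over_time(tr)
  direct <- tr |>
    dplyr::arrange(track, frame) |>
    dplyr::group_by(track) |>
    dplyr::reframe(frame = frame[-1], v = sqrt(diff(x)^2 + diff(y)^2) / 10) |>
    dplyr::group_by(frame) |>
    dplyr::summarise(mv = mean(v))
  expect_equal(fs$mean_velocity, direct$mv)
  expect_equal(mean(fs$mean_velocity), mean(direct$mv))

  # static cells -> all zeros
  static <- make_track(x = rep(0, 5), y = rep(0, 5))
  expect_equal(mean_velocity_over_time(static)$mean_velocity, rep(0, 4))
})

test_that("velocity distributions are normalised with a parabola-vertex mode", {
  # symmetric counts around bin 3 -> vertex at the central bin's midpoint
  v <- rep((1:5) - 0.5, times = c(4, 9, 12, 9, 4))
  d <- velocity_distribution(v, bin_width = 1)
  expect_equal(sum(d$bins$pct), 100, tolerance = 1e-9)
  expect_equal(d$bins$cum_pct[nrow(d$bins)], 100, tolerance = 1e-9)
  expect_true(all(diff(d$bins$cum_pct) >= 0))
  expect_equal(d$mode, 2.5, tolerance = 1e-9)

  # asymmetric counts match an independent closed-form quadratic fit
  v2 <- rep((1:5) - 0.5, times = c(2, 6, 12, 10, 3))
  d2 <- velocity_distribution(v2, bin_width = 1)
  x <- (1:5) - 0.5; y <- c(2, 6, 12, 10, 3)
  co <- coef(stats::lm(y ~ x + I(x^2)))
  expect_equal(d2$mode, -co[[2]] / (2 * co[[3]]), tolerance = 1e-9)

  # degenerate single-bin input falls back to the peak bin centre
  expect_warning(d3 <- velocity_distribution(rep(2.2, 50), bin_width = 1),
                 "peak at the histogram edge")
  expect_equal(d3$mode, 2.5)
})

test_that("cell counts per frame equal identified regions and follow proliferation", {
  spec <- synthetic_spec(width_px = 320, height_px = 320, n_frames = 6,
                         n_cells = 10, sigma_step = 1, noise_sd = 2, seed = 84)
  gv <- generate_video(spec)
  segs <- lapply(gv$stack$frames, segment_frame, settings = syn_settings())
  counts <- count_cells_over_time(segs)
  expect_equal(counts$n_identified,
               vapply(segs, function(s) s$n_identified, 0L))
  expect_equal(counts$n_identified, rep(10L, 6))

  # a 72 h proliferation series imaged every 3 h: the exponential growth
  # rate of the identified-cell count recovers the true division rate
  spec2 <- synthetic_spec(width_px = 640, height_px = 640, n_frames = 24,
                          dt = 180, n_cells = 12, sigma_step = 4, noise_sd = 2,
                          division_prob = 0.07, seed = 85)
  gv2 <- generate_video(spec2)
  truth_n <- dplyr::count(gv2$truth, frame)$n
  segs2 <- lapply(gv2$stack$frames, segment_frame,
                  settings = syn_settings(segmentation_limit = -2.5))
  counts2 <- count_cells_over_time(segs2)
  rate <- function(v) coef(stats::lm(log(v) ~ seq_along(v)))[[2]]
  expect_lt(abs(rate(counts2$n_identified) - rate(truth_n)) / rate(truth_n), 0.15)
  expect_gt(truth_n[24], 2 * truth_n[1])
})

test_that("common-origin transform is translation invariant and starts at zero", {
  set.seed(86)
  tr <- dplyr::bind_rows(
    make_track(x = cumsum(rnorm(8)), y = cumsum(rnorm(8)), track = 1L),
    make_track(x = 50 + cumsum(rnorm(8)), y = 50 + cumsum(rnorm(8)), track = 2L))
  co <- common_origin(tr)
  starts <- co |> dplyr::group_by(track) |> dplyr::slice(1)
  expect_equal(starts$x, c(0, 0))
  expect_equal(starts$y, c(0, 0))
  shifted <- tr
  shifted$x <- shifted$x + 123; shifted$y <- shifted$y - 45
  expect_equal(common_origin(shifted)[c("x", "y")], co[c("x", "y")])
})
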