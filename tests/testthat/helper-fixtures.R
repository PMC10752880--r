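# Shared fixtures, built in code at test time.

# analysis settings matched to the synthetic imagery defaults
# (16 um nuclei, shallow smoothing, manual grey limit)
syn_settings <- function(...) {
  settings(gaussian_radius = 3, segmentation_limit = -1.5,
           shift_correction = FALSE, shortest_cell_track = 5, ...)
}

# a frame with dark filled discs on a uniform bright background
disc_frame <- function(width = 100, height = 100, centres, radius = 8,
                       background = 150, depth = 70) {
  f <- matrix(background, height, width)
  cc <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
  rr <- matrix(seq_len(height) - 1, height, width)
  centres <- matrix(centres, ncol = 2)
  radius <- rep_len(radius, nrow(centres))
  for (i in seq_len(nrow(centres))) {
    inside <- (cc - centres[i, 1])^2 + (rr - centres[i, 2])^2 <= radius[i]^2
    f[inside] <- background - depth
  }
  f
}

# brute-force flood-fill labelling oracle (8-connectivity)
flood_fill_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  n <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    n <- n + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  n
}

# simple track tibble from per-frame positions
make_track <- function(x, y, track = 1L, dt = 10) {
  tr <- tibble::tibble(track = track, frame = seq_along(x), x = x, y = y,
                       repaired = FALSE)
  attr(tr, "dt") <- dt
  class(tr) <- c("pt_tracks", class(tr))
  tr
}
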