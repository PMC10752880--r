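# shared small helpers

# clamp numeric vector to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Euclidean length of rows of a 2-column matrix / of (dx, dy)
hypot <- function(dx, dy) sqrt(dx^2 + dy^2)

# vertex of the least-squares parabola through (x, y); x need not be centred.
# Returns NA if the quadratic coefficient is ~0 or points are degenerate.
parabola_vertex <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  a <- fit$coefficients[[3]]
  b <- fit$coefficients[[2]]
  if (!is.finite(a) || abs(a) < .Machine$double.eps * 1e3) return(NA_real_)
  -b / (2 * a)
}

# Bresenham line between integer pixel coords (r0,c0) -> (r1,c1), inclusive.
# Returns a 2-column matrix of (row, col).
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dr - dc
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr)  { err <- err + dc; c <- c + sc }
  }
  out
}

stopf <- function(...) rlang::abort(sprintf(...))
warnf <- function(...) rlang::warn(sprintf(...))
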