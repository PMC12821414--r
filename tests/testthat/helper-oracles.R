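# Independent brute-force oracles, deliberately naive implementations.

# Per-point least-squares polynomial smoother: fit a degree-`order`
# polynomial by lm() on the window centered at each point (truncated
# to the available points at the edges), evaluate at the point.
sg_oracle <- function(y, order, frame) {
  n <- length(y)
  h <- (frame - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    win <- max(1L, i - h):min(n, i + h)
    d <- data.frame(x = win - i, y = y[win])
    unname(stats::coef(stats::lm(y ~ poly(x, degree = order,
                                          raw = TRUE), data = d))[1])
  }, numeric(1))
}

# Exhaustive circle-placement baseline: for each point x, the highest
# value attained at x by any vertical translate of the structuring
# function (the scaled semicircle) that lies entirely below the
# spectrum wherever the spectrum is defined. Centers range over the
# extended grid so circles may protrude past the recorded range.
rc_oracle <- function(y, wavenumber, radius, yrange = NULL) {
  d <- stats::median(diff(wavenumber))
  span <- wavenumber[length(wavenumber)] - wavenumber[1]
  if (is.null(yrange)) yrange <- max(y) - min(y)
  w <- floor(radius / d)
  elem <- (yrange / span) * sqrt(pmax(radius^2 - (seq(-w, w) * d)^2, 0))
  n <- length(y)
  best <- rep(-Inf, n)
  for (c in (1 - w):(n + w)) {
    cover <- (c - w):(c + w)
    ok <- cover >= 1 & cover <= n
    # highest vertical translate keeping the circle below the spectrum
    t_max <- min(y[cover[ok]] - elem[ok])
    idx <- cover[ok]
    cand <- t_max + elem[ok]
    upd <- cand > best[idx]
    best[idx[upd]] <- cand[upd]
  }
  best
}

# Iterated oracle matching the multi-pass semantics; the structuring
# element is fixed from the original spectrum's intensity range.
rc_oracle_passes <- function(y, wavenumber, radius, passes) {
  yr <- max(y) - min(y)
  b <- rc_oracle(y, wavenumber, radius, yrange = yr)
  for (k in seq_len(passes - 1L))
    b <- rc_oracle(pmin(y, b), wavenumber, radius, yrange = yr)
  b
}
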