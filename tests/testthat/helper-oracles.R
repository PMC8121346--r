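# Independent brute-force oracles. These are written directly from the
# windowed-statistic and segmentation definitions and share no code with the
# package internals; tests compare the package against them.

# Fluctuation intensity via run-length encoding of the first-difference signs:
# maximal equal-sign stretches are the monotone runs, zero differences split
# them and contribute nothing.
oracle_fluctuation <- function(w, smin, smax) {
  m <- length(w)
  s <- smax - smin
  if (s <= 0) return(0)
  w <- pmin(pmax(w, smin), smax)
  r <- rle(sign(diff(w)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  total <- 0
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0) next
    total <- total + abs(w[ends[k] + 1] - w[starts[k]]) / r$lengths[k]
  }
  total / (s * (m - 1))
}

# Distribution measure by explicit enumeration of all sorted index pairs.
oracle_distribution <- function(w, smin, smax) {
  m <- length(w)
  s <- smax - smin
  if (s <= 0) return(0)
  y <- sort(pmin(pmax(w, smin), smax))
  u <- s / (m - 1)
  short <- 0
  tot <- 0
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      unif <- (j - i) * u
      tot <- tot + unif
      if (y[j] - y[i] < unif) short <- short + unif - (y[j] - y[i])
    }
  }
  1 - short / tot
}

# Exhaustive best-split recursive segmentation: at each node enumerate every
# admissible split day, take the one minimizing the summed child SSE
# (earliest on ties via which.min), accept when the improvement reaches
# cp * root SSE. Returns the first days of the new segments.
oracle_segment_breakpoints <- function(y, min_seg = 7, cp = 0.01) {
  sse <- function(v) sum((v - mean(v))^2)
  root <- sse(y)
  rec <- function(idx) {
    n <- length(idx)
    if (n < 2 * min_seg) return(integer(0))
    cand <- (min_seg + 1):(n - min_seg + 1)
    child <- vapply(
      cand,
      function(t) sse(y[idx[1:(t - 1)]]) + sse(y[idx[t:n]]),
      numeric(1)
    )
    best <- which.min(child)
    improvement <- sse(y[idx]) - child[best]
    if (!(improvement > 0 && improvement >= cp * root)) return(integer(0))
    t <- cand[best]
    c(rec(idx[1:(t - 1)]), idx[t], rec(idx[t:n]))
  }
  sort(rec(seq_along(y)))
}

# Exact conditional-mean imputation of a gappy AR(1) series with KNOWN
# parameters, via the Gaussian bridge formula (the optimum any smoother can
# attain at the true parameters).
oracle_ar1_impute <- function(y, phi, mu) {
  a <- y - mu
  n <- length(y)
  out <- a
  obs <- which(!is.na(a))
  for (t in which(is.na(a))) {
    l <- suppressWarnings(max(obs[obs < t]))
    r <- suppressWarnings(min(obs[obs > t]))
    if (is.finite(l) && is.finite(r)) {
      dl <- t - l
      dr <- r - t
      d <- r - l
      out[t] <- (phi^dl * (1 - phi^(2 * dr)) * a[l] +
        phi^dr * (1 - phi^(2 * dl)) * a[r]) / (1 - phi^(2 * d))
    } else if (is.finite(l)) {
      out[t] <- phi^(t - l) * a[l]
    } else {
      out[t] <- phi^(r - t) * a[r]
    }
  }
  out + mu
}

# Single-pass independent recount of the duration clock over a full day grid.
oracle_duration <- function(days, event_days) {
  last <- 0
  out <- integer(length(days))
  for (i in seq_along(days)) {
    out[i] <- days[i] - last
    if (days[i] %in% event_days) last <- days[i]
  }
  out
}
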