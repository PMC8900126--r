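# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementations they check.

# Screened-Coulomb potential by direct unvectorized summation (mV).
oracle_screened_potential <- function(charges, points, eps_r, ionic_strength,
                                      temperature = 298) {
  lambda <- 0.304 / sqrt(ionic_strength) * sqrt(temperature / 298)
  ke <- 1.439964 # V*nm per unit charge
  phi <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    acc <- 0
    for (i in seq_len(nrow(charges))) {
      r <- sqrt(sum((points[p, ] - c(charges$x[i], charges$y[i], charges$z[i]))^2))
      acc <- acc + 1000 * ke * charges$q[i] * exp(-r / lambda) / (eps_r * r)
    }
    phi[p] <- acc
  }
  phi
}

# O(n^2) union-find single-linkage clustering with minimum-image distances.
# Returns a list of integer membership vectors (row indices), size >= 2 only.
oracle_clusters <- function(xyz, cutoff, box = NULL) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- xyz[i, ] - xyz[j, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- split(seq_len(n), roots)
  out <- out[lengths(out) >= 2]
  names(out) <- NULL
  lapply(out, as.integer)
}

# Canonical form for comparing cluster partitions.
canon_clusters <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, `[`, integer(1), 1))]
}

# Maximum number of points from `pts` with pairwise distance >= d, by
# exhaustive subset enumeration (tiny inputs only).
oracle_max_packing <- function(pts, d) {
  n <- nrow(pts)
  stopifnot(n <= 15)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1) {
      for (a in seq_along(sel)) for (b in seq_len(a - 1)) {
        if (sqrt(sum((pts[sel[a], ] - pts[sel[b], ])^2)) < d) { ok <- FALSE; break }
      }
    }
    if (ok) best <- length(sel)
  }
  best
}

# Shared default distribution, fitted once per test run.
default_dist <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- fit_pattern_distribution()
    d
  }
})
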