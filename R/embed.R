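# Coarse-grained 3-D embedding of chains: one backbone bead per monomer on a
# freely rotating chain (fixed bond length b, fixed bond angle, uniform
# dihedrals), a charge bead per CM group and an alkyl bead per CM8 group at
# fixed offsets normal to the local backbone tangent. A stand-in for MD
# conformational snapshots: it reproduces ideal worm-like tangent statistics
# (Lp = -b / ln<cos theta>) and sets the length scales that the potential and
# clustering stages need, nothing more.

#' Embed a chain as a coarse-grained bead conformer
#'
#' @param chain a `cmc_chain`.
#' @param b backbone virtual bond length in nm (default 0.515, the cellulose
#'   glucose repeat).
#' @param theta fixed bond angle in radians (0 = rod); give either `theta` or
#'   `lp`.
#' @param lp target persistence length in nm; sets
#'   `cos(theta) = exp(-b / lp)`. Default 5 nm when neither is given.
#' @param charge_offset,alkyl_offset side-bead distances from the backbone
#'   bead in nm, directions drawn uniformly in the plane normal to the local
#'   tangent.
#' @param excluded_volume_radius if non-`NULL`, hard-sphere self-avoidance:
#'   conformers with any nonadjacent backbone pair closer than twice this
#'   radius (nm) are rejected and redrawn.
#' @param max_retries rejection budget for self-avoidance.
#' @param seed integer seed.
#' @return Object of class `cmc_conformer`: `backbone` (N x 3 matrix, nm),
#'   `charge_beads` / `alkyl_beads` (data.frames x, y, z, monomer, pos),
#'   `b`, `chain`, `params`, `seed`.
#' @export
embed_chain <- function(chain, b = 0.515, theta = NULL, lp = NULL,
                        charge_offset = 0.35, alkyl_offset = 0.55,
                        excluded_volume_radius = NULL, max_retries = 200,
                        seed = NULL) {
  stopifnot(inherits(chain, "cmc_chain"), b > 0)
  if (is.null(theta)) {
    if (is.null(lp)) lp <- 5
    theta <- acos(exp(-b / lp))
  }
  N <- chain$N
  with_seed(seed, {
    for (attempt in seq_len(max(1, max_retries))) {
      bb <- .grow_frc_backbone(N, b, theta)
      if (is.null(excluded_volume_radius)) break
      if (N < 3) break
      dmin <- .min_nonadjacent_dist(bb)
      if (dmin >= 2 * excluded_volume_radius) break
      if (attempt == max_retries)
        stop("self-avoiding embedding failed after ", max_retries, " retries")
    }
    side <- .place_side_beads(chain, bb, b, charge_offset, alkyl_offset)
    structure(list(backbone = bb,
                   charge_beads = side$charge, alkyl_beads = side$alkyl,
                   b = b, chain = chain,
                   params = list(theta = theta, lp = lp,
                                 charge_offset = charge_offset,
                                 alkyl_offset = alkyl_offset,
                                 excluded_volume_radius = excluded_volume_radius),
                   seed = seed),
              class = "cmc_conformer")
  })
}

.grow_frc_backbone <- function(N, b, theta) {
  bb <- matrix(0, N, 3)
  if (N == 1) return(bb)
  u <- c(0, 0, 1)
  bb[2, ] <- bb[1, ] + b * u
  if (N > 2) {
    ct <- cos(theta); st <- sin(theta)
    for (i in 3:N) {
      n1 <- .any_normal(u)
      n2 <- c(u[2] * n1[3] - u[3] * n1[2],
              u[3] * n1[1] - u[1] * n1[3],
              u[1] * n1[2] - u[2] * n1[1])
      phi <- stats::runif(1, 0, 2 * pi)
      u <- ct * u + st * (cos(phi) * n1 + sin(phi) * n2)
      u <- u / sqrt(sum(u^2))
      bb[i, ] <- bb[i - 1, ] + b * u
    }
  }
  bb
}

.any_normal <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n <- a - sum(a * u) * u
  n / sqrt(sum(n^2))
}

.min_nonadjacent_dist <- function(bb) {
  d <- as.matrix(stats::dist(bb))
  n <- nrow(bb)
  d[cbind(1:n, 1:n)] <- Inf
  d[cbind(1:(n - 1), 2:n)] <- Inf
  d[cbind(2:n, 1:(n - 1))] <- Inf
  min(d)
}

.place_side_beads <- function(chain, bb, b, charge_offset, alkyl_offset) {
  N <- nrow(bb)
  # local tangent: central difference, one-sided at the ends
  tang <- rbind(bb[min(2, N), ] - bb[1, ],
                if (N > 2) bb[3:N, , drop = FALSE] - bb[1:(N - 2), , drop = FALSE],
                if (N > 1) bb[N, ] - bb[N - 1, ])
  if (N == 1) tang <- matrix(c(0, 0, 1), 1)
  tang <- tang / sqrt(rowSums(tang^2))
  mk <- function(state, offset) {
    w <- which(chain$states == state, arr.ind = TRUE)
    if (nrow(w) == 0)
      return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        monomer = integer(0), pos = integer(0)))
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    out <- matrix(0, nrow(w), 3)
    for (k in seq_len(nrow(w))) {
      i <- w[k, 1]
      n1 <- .any_normal(tang[i, ])
      u <- tang[i, ]
      n2 <- c(u[2] * n1[3] - u[3] * n1[2],
              u[3] * n1[1] - u[1] * n1[3],
              u[1] * n1[2] - u[2] * n1[1])
      phi <- stats::runif(1, 0, 2 * pi)
      out[k, ] <- bb[i, ] + offset * (cos(phi) * n1 + sin(phi) * n2)
    }
    data.frame(x = out[, 1], y = out[, 2], z = out[, 3],
               monomer = as.integer(w[, 1]), pos = as.integer(w[, 2]))
  }
  list(charge = mk("CM", charge_offset), alkyl = mk("CM8", alkyl_offset))
}

#' Estimate persistence length from bond-vector correlations
#'
#' Pools normalized backbone bond vectors over one or more conformers,
#' computes the tangent autocorrelation `C(k) = <u_i . u_(i+k)>` and fits
#' `log C(k) = -(b / Lp) k` (through the origin, since `C(0) = 1`) over the
#' initial run of strictly positive correlations.
#'
#' @param conformers a `cmc_conformer` or list of them (same `b` and length).
#' @param max_lag largest lag used (default half the bond count, capped
#'   at 50).
#' @return list of class `lp_estimate`: `lp` (nm; `Inf` for a rod), `se`,
#'   `slope`, `lags`, `correlations`.
#' @export
estimate_persistence_length <- function(conformers, max_lag = NULL) {
  if (inherits(conformers, "cmc_conformer")) conformers <- list(conformers)
  stopifnot(length(conformers) >= 1)
  N <- nrow(conformers[[1]]$backbone)
  if (N < 10) stop("need chains of at least 10 monomers")
  b <- conformers[[1]]$b
  nb <- N - 1
  if (is.null(max_lag)) max_lag <- min(50, floor(nb / 2))
  ck <- numeric(max_lag); nk <- numeric(max_lag)
  for (cf in conformers) {
    u <- diff(cf$backbone)
    u <- u / sqrt(rowSums(u^2))
    for (k in seq_len(max_lag)) {
      dots <- rowSums(u[1:(nb - k), , drop = FALSE] * u[(1 + k):nb, , drop = FALSE])
      ck[k] <- ck[k] + sum(dots)
      nk[k] <- nk[k] + length(dots)
    }
  }
  ck <- ck / nk
  if (ck[1] <= 0)
    stop("tangent correlation nonpositive already at lag 1; no exponential decay to fit")
  # fit only the first ~2 decay lengths: beyond C(k) ~ exp(-2) the log of the
  # noisy tail would dominate and bias the slope
  kmax <- which(ck <= exp(-2))[1]
  kmax <- if (is.na(kmax)) max_lag else max(1L, kmax - 1L)
  ks <- seq_len(kmax)
  y <- log(ck[ks])
  fit <- stats::lm(y ~ 0 + ks)
  slope <- unname(stats::coef(fit)[1])
  if (slope > -1e-12) {
    return(structure(list(lp = Inf, se = NA_real_, slope = slope, lags = ks,
                          correlations = ck[ks], b = b, rod = TRUE),
                     class = "lp_estimate"))
  }
  se_slope <- if (length(ks) > 1) summary(fit)$coefficients[1, 2] else NA_real_
  structure(list(lp = -b / slope, se = b * se_slope / slope^2, slope = slope,
                 lags = ks, correlations = ck[ks], b = b, rod = FALSE),
            class = "lp_estimate")
}

#' @export
print.lp_estimate <- function(x, ...) {
  if (x$rod) cat("persistence length: infinite (rod-like, no tangent decay)\n")
  else cat(sprintf("persistence length: %.3f nm (SE %.3g, %d lags)\n",
                   x$lp, x$se, length(x$lags)))
  invisible(x)
}
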