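# Screened-Coulomb (linearized Debye-Hueckel) electrostatics on a regular
# grid: a desk-scale surrogate for a nonlinear Poisson-Boltzmann solve in
# uniform high-dielectric solvent. Each charge bead contributes
#   phi(r) = ke * q * exp(-r / lambda_D) / (eps_r * r)
# so the field is a pure superposition with an analytic closed form, which the
# test suite exploits as an independent oracle. The potential is capped at
# its value one grid spacing from each charge to tame the 1/r singularity.

#' Extract point charges (in e) from conformers or packed systems
#'
#' @param x a `cmc_conformer`, list of conformers, `packed_system`, or a
#'   data.frame with columns `x`, `y`, `z`, `q` (nm, e).
#' @return data.frame with columns x, y, z (nm), q (e).
#' @export
collect_charges <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z", "q") %in% names(x)))
    return(x[, c("x", "y", "z", "q")])
  }
  if (inherits(x, "cmc_conformer")) x <- list(x)
  if (inherits(x, "packed_system")) {
    b <- x$beads[x$beads$type == "charge", , drop = FALSE]
    return(data.frame(x = b$x, y = b$y, z = b$z,
                      q = rep(-1, nrow(b))))
  }
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "cmc_conformer")))
  cb <- do.call(rbind, lapply(x, function(cf) cf$charge_beads[, c("x", "y", "z")]))
  data.frame(x = cb$x, y = cb$y, z = cb$z, q = rep(-1, nrow(cb)))
}

#' Screened-Coulomb potential at arbitrary probe points
#'
#' The analytic engine the grid is built on, exposed so callers (and tests)
#' can probe the field anywhere.
#'
#' @param charges data.frame x, y, z (nm), q (e).
#' @param points n x 3 matrix of probe coordinates (nm).
#' @param eps_r relative dielectric constant (default 80, water).
#' @param ionic_strength mol/L (default 0.1).
#' @param temperature K.
#' @param cap distances below `cap` (nm) are evaluated at `cap`; 0 disables.
#' @return numeric vector of potentials in mV.
#' @export
screened_potential <- function(charges, points, eps_r = 80,
                               ionic_strength = 0.1, temperature = 298,
                               cap = 0) {
  points <- matrix(as.numeric(points), ncol = 3)
  ld <- debye_length_nm(ionic_strength, temperature)
  phi <- numeric(nrow(points))
  for (i in seq_len(nrow(charges))) {
    d <- sqrt((points[, 1] - charges$x[i])^2 +
              (points[, 2] - charges$y[i])^2 +
              (points[, 3] - charges$z[i])^2)
    d <- pmax(d, cap)
    phi <- phi + 1000 * .ke_e_Vnm * charges$q[i] * exp(-d / ld) / (eps_r * d)
  }
  phi
}

#' Compute a screened electrostatic potential grid
#'
#' @inheritParams screened_potential
#' @param x charge source: see [collect_charges()].
#' @param spacing grid spacing in nm.
#' @param padding margin added around the charge bounding box (nm) when no
#'   explicit grid is given.
#' @param grid optional list(origin, spacing, dim) overriding the automatic
#'   bounding box.
#' @return Object of class `potential_grid`: `origin` (nm), `spacing`, `dim`,
#'   `values` (3-d array, mV), physical parameters and `lambda_d` (nm), plus
#'   the charges used.
#' @examples
#' ch <- data.frame(x = 0, y = 0, z = 0, q = -1)
#' g <- compute_potential_grid(ch, spacing = 0.25, padding = 1.5)
#' range(g$values)
#' @export
compute_potential_grid <- function(x, spacing = 0.2, padding = 1.0,
                                   eps_r = 80, ionic_strength = 0.1,
                                   temperature = 298, grid = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  charges <- collect_charges(x)
  if (nrow(charges) == 0) {
    warning("no charges; returning a zero grid")
    if (is.null(grid)) grid <- list(origin = c(0, 0, 0), spacing = spacing,
                                    dim = c(2L, 2L, 2L))
  }
  if (is.null(grid)) {
    lo <- c(min(charges$x), min(charges$y), min(charges$z)) - padding
    hi <- c(max(charges$x), max(charges$y), max(charges$z)) + padding
    dim <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
    grid <- list(origin = lo, spacing = spacing, dim = dim)
  }
  ax <- grid$origin[1] + grid$spacing * (seq_len(grid$dim[1]) - 1)
  ay <- grid$origin[2] + grid$spacing * (seq_len(grid$dim[2]) - 1)
  az <- grid$origin[3] + grid$spacing * (seq_len(grid$dim[3]) - 1)
  pts <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  vals <- if (nrow(charges) == 0) numeric(nrow(pts)) else
    screened_potential(charges, pts, eps_r, ionic_strength, temperature,
                       cap = grid$spacing)
  structure(list(origin = grid$origin, spacing = grid$spacing, dim = grid$dim,
                 values = array(vals, dim = grid$dim),
                 eps_r = eps_r, ionic_strength = ionic_strength,
                 temperature = temperature,
                 lambda_d = debye_length_nm(ionic_strength, temperature),
                 cap = grid$spacing, charges = charges),
            class = "potential_grid")
}

# Cartesian coordinates (nm) of voxels given array indices (n x 3).
voxel_coords <- function(grid, ijk) {
  sweep(sweep(ijk - 1, 2, rep(grid$spacing, 3), "*"), 2, grid$origin, "+")
}

#' Detect connected negative-potential hotspots
#'
#' Face-connected components of voxels with potential below `threshold_mV`,
#' of at least `min_voxels` voxels, sorted by their minimum potential
#' (deepest first).
#'
#' @param grid a `potential_grid`.
#' @param threshold_mV negative threshold in mV.
#' @param min_voxels minimum component size.
#' @param charge_radius_nm charge beads within this distance of a hotspot
#'   voxel are listed as its nearby charges.
#' @return list of `hotspot` objects: `voxels` (index matrix), `coords`,
#'   `min_mV`, `centroid` (nm), `n_voxels`, `charge_ids`.
#' @export
find_hotspots <- function(grid, threshold_mV = -10, min_voxels = 5,
                          charge_radius_nm = 0.5) {
  stopifnot(inherits(grid, "potential_grid"))
  if (threshold_mV >= 0) stop("threshold_mV must be negative")
  mask <- grid$values < threshold_mV
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  comp <- .connected_components_3d(mask, idx, grid$dim)
  out <- list()
  for (cid in unique(comp)) {
    vox <- idx[comp == cid]
    if (length(vox) < min_voxels) next
    ijk <- arrayInd(vox, grid$dim)
    coords <- voxel_coords(grid, ijk)
    centroid <- colMeans(coords)
    charge_ids <- integer(0)
    if (nrow(grid$charges) > 0) {
      d <- pairwise_min_image_dist(as.matrix(grid$charges[, c("x", "y", "z")]),
                                   coords)
      charge_ids <- which(apply(d, 1, min) <= charge_radius_nm)
    }
    out[[length(out) + 1]] <- structure(
      list(voxels = ijk, coords = coords, min_mV = min(grid$values[vox]),
           centroid = centroid, n_voxels = length(vox),
           charge_ids = charge_ids),
      class = "hotspot")
  }
  out[order(vapply(out, `[[`, numeric(1), "min_mV"))]
}

# Face-connected component labels for masked voxels of a 3-d array, via a
# graph over adjacent masked voxels.
.connected_components_3d <- function(mask, idx, dims) {
  pos <- arrayInd(idx, dims)
  id_of <- integer(prod(dims))
  id_of[idx] <- seq_along(idx)
  edges <- integer(0)
  for (axis in 1:3) {
    nb <- pos
    nb[, axis] <- nb[, axis] + 1L
    ok <- nb[, axis] <= dims[axis]
    lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] + (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    hit <- id_of[lin] > 0
    if (any(hit)) {
      from <- which(ok)[hit]
      to <- id_of[lin[hit]]
      edges <- c(edges, rbind(from, to))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  igraph::components(g)$membership
}

#' Greedy Zn2+ placement into hotspots
#'
#' Places ions at successive potential minima over all hotspot voxels,
#' skipping candidates within `min_separation` of an already placed ion, and
#' reports per-hotspot occupancy (the bead-level analogue of counting how
#' many Zn2+ a deep acidic well can accumulate).
#'
#' @param grid a `potential_grid`.
#' @param hotspots output of [find_hotspots()].
#' @param min_separation minimum ion-ion distance in nm.
#' @param max_ions overall cap.
#' @return list: `placements` (data.frame x, y, z, mV, hotspot) and
#'   `occupancy` (per-hotspot counts).
#' @export
place_zn_ions <- function(grid, hotspots, min_separation = 0.4,
                          max_ions = Inf) {
  stopifnot(min_separation > 0)
  if (length(hotspots) == 0)
    return(list(placements = data.frame(x = numeric(0), y = numeric(0),
                                        z = numeric(0), mV = numeric(0),
                                        hotspot = integer(0)),
                occupancy = integer(0)))
  cand <- do.call(rbind, lapply(seq_along(hotspots), function(h) {
    hs <- hotspots[[h]]
    v <- grid$values[hs$voxels]
    data.frame(x = hs$coords[, 1], y = hs$coords[, 2], z = hs$coords[, 3],
               mV = v, hotspot = h)
  }))
  cand <- cand[order(cand$mV), ]
  placed <- matrix(numeric(0), ncol = 3)
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep) >= max_ions) break
    p <- as.numeric(cand[i, 1:3])
    if (nrow(placed) > 0) {
      d2 <- rowSums(sweep(placed, 2, p)^2)
      if (min(d2) < min_separation^2) next
    }
    placed <- rbind(placed, p)
    keep <- c(keep, i)
  }
  placements <- cand[keep, , drop = FALSE]
  rownames(placements) <- NULL
  occ <- vapply(seq_along(hotspots),
                function(h) sum(placements$hotspot == h), integer(1))
  list(placements = placements, occupancy = occ)
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("potential_grid: %d x %d x %d voxels, spacing %.3g nm, %d charges\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing, nrow(x$charges)))
  cat(sprintf("  eps_r=%g, I=%g M, T=%g K, lambda_D=%.3f nm; range [%.2f, %.2f] mV\n",
              x$eps_r, x$ionic_strength, x$temperature, x$lambda_d,
              min(x$values), max(x$values)))
  invisible(x)
}
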