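# Density-specified packing of conformers into a periodic cubic box by seeded
# rejection (random rigid-body placement, minimum-image overlap test), and the
# bead-level self-assembly analysis: hydrophobic (alkyl) clusters, acidic
# (carboxylate) clusters, and flagging of acidic clusters that sit at the
# characteristic 10-15 A from an alkyl cluster - the candidate Zn2+ sites.

#' Pack conformers into a periodic cubic box
#'
#' Chains from `conformer_pool` (cycled/sampled) are placed one by one with a
#' uniform random rotation and translation; a placement is rejected if any of
#' its beads comes within `contact_distance` (minimum image) of an already
#' placed bead, and retried up to `max_attempts` times. Bulk density follows
#' from the chain compositions, not from the packing.
#'
#' @param conformer_pool list of `cmc_conformer` objects.
#' @param n_chains number of chains to place (>= 0).
#' @param box_edge cubic box edge length in Angstrom (the conventional unit
#'   for these boxes; converted to nm internally).
#' @param contact_distance inter-chain bead contact distance in nm (default
#'   0.3 nm = 3 A); `0` disables overlap rejection.
#' @param max_attempts placement attempts per chain.
#' @param mass_convention bookkeeping for the density; see
#'   [build_monomer_library()].
#' @param seed integer seed.
#' @return Object of class `packed_system`: `box_edge_A`, `box_nm`,
#'   `periodic`, `beads` (data.frame x, y, z in nm wrapped into the box,
#'   `type` in backbone/charge/alkyl, `chain`), `n_chains`, `chain_masses`
#'   (g/mol, at `mass_convention`), `density` (g/cm^3), `mass_convention`.
#' @export
pack_chains <- function(conformer_pool, n_chains, box_edge,
                        contact_distance = 0.3, max_attempts = 50,
                        mass_convention = c("sodium_salt", "free_acid"),
                        seed = NULL) {
  mass_convention <- match.arg(mass_convention)
  stopifnot(n_chains >= 0, box_edge > 0)
  box_nm <- box_edge / 10
  beads <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      type = character(0), chain = integer(0))
  masses <- masses_na <- masses_ha <- numeric(0)
  with_seed(seed, {
    for (ci in seq_len(n_chains)) {
      cf <- conformer_pool[[(ci - 1) %% length(conformer_pool) + 1]]
      xyz <- rbind(cf$backbone,
                   as.matrix(cf$charge_beads[, c("x", "y", "z")]),
                   as.matrix(cf$alkyl_beads[, c("x", "y", "z")]))
      types <- c(rep("backbone", nrow(cf$backbone)),
                 rep("charge", nrow(cf$charge_beads)),
                 rep("alkyl", nrow(cf$alkyl_beads)))
      xyz <- sweep(xyz, 2, colMeans(xyz))
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        rot <- random_rotation()
        shift <- stats::runif(3, 0, box_nm)
        new <- sweep(xyz %*% t(rot), 2, shift, "+")
        new <- new %% box_nm
        if (contact_distance > 0 && nrow(beads) > 0) {
          d <- pairwise_min_image_dist(new, as.matrix(beads[, 1:3]), box_nm)
          if (min(d) < contact_distance) next
        }
        beads <- rbind(beads, data.frame(x = new[, 1], y = new[, 2],
                                         z = new[, 3], type = types,
                                         chain = ci))
        m_na <- chain_statistics(cf$chain, "sodium_salt")$mean_monomer_mass * cf$chain$N
        m_ha <- chain_statistics(cf$chain, "free_acid")$mean_monomer_mass * cf$chain$N
        masses_na <- c(masses_na, m_na)
        masses_ha <- c(masses_ha, m_ha)
        masses <- c(masses, if (mass_convention == "sodium_salt") m_na else m_ha)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("packing failed at chain ", ci, " of ", n_chains,
             " after ", max_attempts, " attempts (", ci - 1, " placed)")
    }
    structure(list(box_edge_A = box_edge, box_nm = box_nm, periodic = TRUE,
                   beads = beads, n_chains = n_chains, chain_masses = masses,
                   density = packed_density(masses, box_nm),
                   density_sodium = packed_density(masses_na, box_nm),
                   density_acid = packed_density(masses_ha, box_nm),
                   mass_convention = mass_convention, seed = seed),
              class = "packed_system")
  })
}

# Bulk density (g/cm^3) of total molar mass `masses` (g/mol) in a cubic box
# of edge box_nm.
packed_density <- function(masses, box_nm) {
  v_cm3 <- (box_nm * 1e-7)^3
  sum(masses) / (.avogadro * v_cm3)
}

#' Bulk density of an idealized packing, from composition arithmetic
#'
#' Closed-form mass-over-volume density for `n_chains` identical chains of
#' `chain_length` monomers at the given composition in a cubic box - the
#' arithmetic behind the published "2700 100-mers in a 600 A box ~ 0.6
#' g/cm^3" statement, evaluable without performing the packing.
#'
#' @param n_chains,chain_length chain count and length (monomers).
#' @param box_edge_A box edge in Angstrom.
#' @inheritParams mean_monomer_mass
#' @return density in g/cm^3.
#' @examples
#' bulk_density(2700, 100, 600)                     # ~0.52 (sodium salt)
#' bulk_density(2700, 100, 600, mass_convention = "free_acid")
#' @export
bulk_density <- function(n_chains, chain_length, box_edge_A, ds_cm = 0.9,
                         amide_fraction = 200 / 900,
                         mass_convention = c("sodium_salt", "free_acid")) {
  m <- mean_monomer_mass(ds_cm, amide_fraction, match.arg(mass_convention))
  packed_density(rep(m * chain_length, n_chains), box_edge_A / 10)
}

#' Bulk density of a packed system under both mass conventions
#'
#' The published ~0.6 g/cm^3 figure for 2700 100-mers in a 600 A box does not
#' state its mass bookkeeping; this reports the density under both
#' conventions so the discrepancy is visible rather than hidden.
#'
#' @param system a `packed_system`.
#' @return named numeric: `sodium_salt`, `free_acid` (g/cm^3).
#' @export
packed_density_report <- function(system) {
  stopifnot(inherits(system, "packed_system"))
  c(sodium_salt = system$density_sodium, free_acid = system$density_acid)
}

#' Detect hydrophobic alkyl clusters in a packed system
#'
#' Builds a contact graph on alkyl beads with edges at minimum-image distance
#' `cutoff` or less and returns its connected components of two or more
#' beads, each with the number of distinct chains contributing to it (the
#' multi-chain alkyl clusters that nucleate CMC-8 self-assembly).
#'
#' @param system a `packed_system` (or compatible list with `beads`,
#'   `box_nm`, `periodic`).
#' @param cutoff alkyl-alkyl contact distance in nm (default 0.6 nm = 6 A).
#' @return list of class `cluster_report`: `clusters` is a list with, per
#'   cluster, `members` (bead row indices into `system$beads`), `size`,
#'   `chains`, `n_chains`, `centroid` (nm, minimum-image unwrapped);
#'   `bead_type = "alkyl"`.
#' @export
detect_hydrophobic_clusters <- function(system, cutoff = 0.6) {
  .detect_bead_clusters(system, "alkyl", cutoff)
}

.detect_bead_clusters <- function(system, type, cutoff) {
  stopifnot(cutoff > 0)
  rows <- which(system$beads$type == type)
  box <- if (isTRUE(system$periodic)) system$box_nm else NULL
  clusters <- list()
  if (length(rows) >= 2) {
    xyz <- as.matrix(system$beads[rows, c("x", "y", "z")])
    d <- pairwise_min_image_dist(xyz, box = box)
    adj <- d <= cutoff
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
    for (cid in unique(memb)) {
      sel <- which(memb == cid)
      if (length(sel) < 2) next
      members <- rows[sel]
      pts <- xyz[sel, , drop = FALSE]
      # unwrap relative to the first member so centroids of boundary-spanning
      # clusters are meaningful, then wrap back into the box
      if (!is.null(box)) {
        ref <- pts[1, ]
        pts <- sweep(pts, 2, ref)
        pts <- min_image(pts, box)
        pts <- sweep(pts, 2, ref, "+")
      }
      centroid <- colMeans(pts)
      if (!is.null(box)) centroid <- centroid %% box
      clusters[[length(clusters) + 1]] <- list(
        members = members, size = length(members),
        chains = sort(unique(system$beads$chain[members])),
        n_chains = length(unique(system$beads$chain[members])),
        centroid = centroid)
    }
  }
  clusters <- clusters[order(-vapply(clusters, `[[`, numeric(1), "size"))]
  structure(list(clusters = clusters, bead_type = type, cutoff = cutoff),
            class = "cluster_report")
}

#' Detect acidic carboxylate clusters and flag candidate Zn sites
#'
#' Clusters charge (carboxylate) beads at `acid_cutoff`, then flags every
#' acidic cluster whose centroid lies within `proximity_range` of the
#' centroid of any hydrophobic cluster - the geometry of the observed Zn2+
#' binding sites, where a multi-chain carboxylate cluster sits 10-15 A from
#' an alkyl cluster.
#'
#' @param system a `packed_system`.
#' @param hydrophobic_clusters a `cluster_report` from
#'   [detect_hydrophobic_clusters()].
#' @param acid_cutoff carboxylate-carboxylate contact distance in nm
#'   (default 0.8 nm = 8 A).
#' @param proximity_range length-2 numeric, Angstrom (default `c(10, 15)`).
#' @return `cluster_report` whose clusters additionally carry `flagged`
#'   (logical) and `alkyl_distance_A` (distance to the nearest hydrophobic
#'   cluster centroid, Angstrom; `Inf` when there is none).
#' @export
detect_acidic_clusters_near <- function(system, hydrophobic_clusters,
                                        acid_cutoff = 0.8,
                                        proximity_range = c(10, 15)) {
  rep_ <- .detect_bead_clusters(system, "charge", acid_cutoff)
  hcent <- lapply(hydrophobic_clusters$clusters, `[[`, "centroid")
  box <- if (isTRUE(system$periodic)) system$box_nm else NULL
  rep_$clusters <- lapply(rep_$clusters, function(cl) {
    if (length(hcent) == 0) {
      cl$alkyl_distance_A <- Inf
    } else {
      d <- vapply(hcent, function(h) {
        dd <- cl$centroid - h
        if (!is.null(box)) dd <- min_image(dd, box)
        sqrt(sum(dd^2))
      }, numeric(1))
      cl$alkyl_distance_A <- min(d) * 10
    }
    cl$flagged <- cl$alkyl_distance_A >= proximity_range[1] &&
      cl$alkyl_distance_A <= proximity_range[2]
    cl
  })
  rep_$proximity_range_A <- proximity_range
  rep_
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report (%s beads, cutoff %.2f nm): %d clusters\n",
              x$bead_type, x$cutoff, length(x$clusters)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d: %d beads from %d chain(s)%s\n", i, cl$size, cl$n_chains,
                if (!is.null(cl$flagged))
                  sprintf(", nearest alkyl cluster %.1f A%s", cl$alkyl_distance_A,
                          if (cl$flagged) " [flagged Zn site]" else "")
                else ""))
  }
  invisible(x)
}

#' @export
print.packed_system <- function(x, ...) {
  cat(sprintf("packed_system: %d chains, %d beads, box %.0f A, density %.3f g/cm^3 (%s)\n",
              x$n_chains, nrow(x$beads), x$box_edge_A, x$density,
              x$mass_convention))
  invisible(x)
}
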