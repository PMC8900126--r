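# Seed-deterministic synthetic-data generators. Each generator records its
# ground truth in a `truth` attribute (and `.truth.json` sidecar when written
# to disk), so recovery tests read truth only from the sidecar, never from
# the data.

#' Generate a synthetic pyrene I3/I1 titration curve
#'
#' A two-regime piecewise-linear curve over a dilution series: flat(ish)
#' below the true CAC, rising above it, continuous at the kink, with additive
#' i.i.d. Gaussian noise on the ratio. The defaults mirror the measured
#' system: true CAC 0.62 mg/mL on a factor-2 dilution series.
#'
#' @param true_cac kink position in mg/mL.
#' @param left_slope,left_intercept below-CAC line (ratio per mg/mL;
#'   intercept ~0.6, the aqueous I3/I1 baseline).
#' @param right_slope above-CAC slope (ratio per mg/mL).
#' @param noise_sigma additive Gaussian noise SD on the ratio.
#' @param n_points number of concentrations.
#' @param dilution_factor successive dilution factor (default 2).
#' @param start_conc highest concentration in mg/mL.
#' @param seed integer seed.
#' @return Object of classes `titration_curve`/`data.frame` with columns
#'   `conc`, `ratio`; ground truth in `attr(, "truth")`.
#' @export
gen_pyrene_curve <- function(true_cac = 0.62, left_slope = 0.02,
                             right_slope = 0.5, left_intercept = 0.60,
                             noise_sigma = 0.01, n_points = 12,
                             dilution_factor = 2, start_conc = 5,
                             seed = NULL) {
  stopifnot(n_points >= 6, dilution_factor > 1, start_conc > 0)
  conc <- start_conc / dilution_factor^(seq_len(n_points) - 1)
  if (true_cac <= min(conc) || true_cac >= max(conc))
    stop("true_cac must lie strictly inside the generated concentration range")
  right_intercept <- left_intercept + (left_slope - right_slope) * true_cac
  ratio0 <- ifelse(conc <= true_cac,
                   left_intercept + left_slope * conc,
                   right_intercept + right_slope * conc)
  with_seed(seed, {
    ratio <- ratio0 + stats::rnorm(n_points, 0, noise_sigma)
    out <- data.frame(conc = conc, ratio = ratio)
    attr(out, "truth") <- list(generator = "gen_pyrene_curve",
                               true_cac = true_cac, left_slope = left_slope,
                               right_slope = right_slope,
                               left_intercept = left_intercept,
                               right_intercept = right_intercept,
                               noise = list(distribution = "gaussian_additive",
                                            sigma = noise_sigma),
                               n_points = n_points,
                               dilution_factor = dilution_factor,
                               start_conc = start_conc, seed = seed)
    class(out) <- c("titration_curve", "data.frame")
    out
  })
}

#' Generate synthetic TOC/TN elemental-analysis readings
#'
#' Forward model of a total-organic-carbon / total-nitrogen analysis of a
#' dissolved amidated CMC sample: mass concentrations of C and N follow from
#' the per-monomer stoichiometry (6 + 2 ds + 8 ds a carbons, ds a nitrogens)
#' and the mean monomer mass, with multiplicative Gaussian noise.
#'
#' @param amide_ds true amide fraction `a` in \[0, 1\].
#' @param ds_cm carboxymethyl DS.
#' @param sample_conc dissolved polymer concentration in mg/mL (default 0.2).
#' @param noise_rel relative (multiplicative) Gaussian noise SD.
#' @param mass_convention monomer mass bookkeeping (N/C ratio is unaffected).
#' @param seed integer seed.
#' @return Object of class `elemental_measurement`: `toc_mg_l`, `tn_mg_l`,
#'   `sample_mg_ml`, `ds_cm`; truth in `attr(, "truth")`.
#' @export
gen_elemental_readings <- function(amide_ds = 0.22, ds_cm = 0.9,
                                   sample_conc = 0.2, noise_rel = 0,
                                   mass_convention = c("sodium_salt", "free_acid"),
                                   seed = NULL) {
  stopifnot(amide_ds >= 0, amide_ds <= 1, ds_cm > 0, sample_conc > 0)
  mass_convention <- match.arg(mass_convention)
  m <- mean_monomer_mass(ds_cm, amide_ds, mass_convention)
  s_mg_l <- sample_conc * 1000
  toc0 <- s_mg_l * .carbon_per_monomer(ds_cm, amide_ds) * .mass_C / m
  tn0 <- s_mg_l * .nitrogen_per_monomer(ds_cm, amide_ds) * .mass_N / m
  with_seed(seed, {
    toc <- toc0 * (1 + stats::rnorm(1, 0, noise_rel))
    tn <- if (tn0 > 0) tn0 * (1 + stats::rnorm(1, 0, noise_rel)) else 0
    out <- list(toc_mg_l = toc, tn_mg_l = tn, sample_mg_ml = sample_conc,
                ds_cm = ds_cm)
    attr(out, "truth") <- list(generator = "gen_elemental_readings",
                               amide_ds = amide_ds, ds_cm = ds_cm,
                               sample_conc = sample_conc,
                               toc_true = toc0, tn_true = tn0,
                               noise = list(distribution = "gaussian_multiplicative",
                                            sigma = noise_rel),
                               mass_convention = mass_convention, seed = seed)
    class(out) <- "elemental_measurement"
    out
  })
}

#' Construct a packed system with planted bead clusters
#'
#' Builds a `packed_system`-compatible fixture whose cluster-detection
#' answers are known by construction: alkyl clusters of given sizes (beads
#' drawn tightly around well-separated centers, attributed round-robin to a
#' given number of chains), one acidic cluster per alkyl cluster at a
#' prescribed centroid distance, and optional dispersed background beads far
#' from everything. The default plants the observed site geometry: a 5-alkyl
#' cluster from 3 chains with a 9-carboxylate cluster 12 A away.
#'
#' @param planted_alkyl_cluster_sizes integer vector, one alkyl cluster per
#'   entry.
#' @param planted_acid_cluster_sizes integer vector, same length (0 = no
#'   acid cluster for that alkyl cluster).
#' @param alkyl_acid_distance centroid-to-centroid distance(s) in Angstrom.
#' @param chains_per_cluster distinct chains contributing to each alkyl
#'   cluster.
#' @param box_edge box edge in Angstrom.
#' @param cluster_radius bead scatter radius around each planted centroid, nm.
#' @param n_background dispersed lone beads of each type added far apart.
#' @param seed integer seed.
#' @return a `packed_system` (no masses/density: fixture geometry only) with
#'   the plant recorded in `attr(, "truth")`.
#' @export
gen_planted_system <- function(planted_alkyl_cluster_sizes = 5,
                               planted_acid_cluster_sizes = 9,
                               alkyl_acid_distance = 12,
                               chains_per_cluster = 3,
                               box_edge = 120,
                               cluster_radius = 0.15,
                               n_background = 0,
                               seed = NULL) {
  k <- length(planted_alkyl_cluster_sizes)
  stopifnot(length(planted_acid_cluster_sizes) == k)
  dist_nm <- rep(alkyl_acid_distance, length.out = k) / 10
  box_nm <- box_edge / 10
  # well-separated cluster centers on a coarse lattice
  needed <- k + n_background
  per_axis <- ceiling((2 * needed)^(1 / 3))
  pitch <- box_nm / per_axis
  if (pitch < 2 * (max(c(dist_nm, 0)) + 1))
    stop("infeasible geometry: box too small for the requested separations")
  centers <- as.matrix(expand.grid(x = seq_len(per_axis), y = seq_len(per_axis),
                                   z = seq_len(per_axis)))
  centers <- (centers - 0.5) * pitch
  with_seed(seed, {
    centers <- centers[sample.int(nrow(centers)), , drop = FALSE]
    beads <- list()
    chain_counter <- 0
    for (i in seq_len(k)) {
      ctr <- centers[i, ]
      na <- planted_alkyl_cluster_sizes[i]
      pts <- matrix(rep(ctr, each = na), na, 3) +
        matrix(stats::runif(3 * na, -cluster_radius, cluster_radius), na, 3)
      chains <- chain_counter + rep_len(seq_len(chains_per_cluster), na)
      beads[[length(beads) + 1]] <- data.frame(
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        type = "alkyl", chain = chains)
      nq <- planted_acid_cluster_sizes[i]
      if (nq > 0) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        actr <- ctr + dist_nm[i] * dir
        apts <- matrix(rep(actr, each = nq), nq, 3) +
          matrix(stats::runif(3 * nq, -cluster_radius, cluster_radius), nq, 3)
        # recenter so the acid centroid sits exactly at the prescribed
        # distance from the alkyl centroid
        apts <- sweep(apts, 2, colMeans(apts) - actr)
        achains <- chain_counter + rep_len(seq_len(chains_per_cluster), nq)
        beads[[length(beads) + 1]] <- data.frame(
          x = apts[, 1], y = apts[, 2], z = apts[, 3],
          type = "charge", chain = achains)
      }
      # likewise pin the alkyl centroid
      beads[[length(beads) - (nq > 0)]][, 1:3] <-
        sweep(as.matrix(beads[[length(beads) - (nq > 0)]][, 1:3]), 2,
              colMeans(as.matrix(beads[[length(beads) - (nq > 0)]][, 1:3])) - ctr)
      chain_counter <- chain_counter + chains_per_cluster
    }
    for (j in seq_len(n_background)) {
      ctr <- centers[k + j, ]
      chain_counter <- chain_counter + 1
      beads[[length(beads) + 1]] <- data.frame(
        x = ctr[1], y = ctr[2], z = ctr[3],
        type = if (j %% 2 == 0) "alkyl" else "charge",
        chain = chain_counter)
    }
    beads <- do.call(rbind, beads)
    beads[, 1:3] <- as.matrix(beads[, 1:3]) %% box_nm
    out <- structure(list(box_edge_A = box_edge, box_nm = box_nm,
                          periodic = TRUE, beads = beads,
                          n_chains = chain_counter,
                          chain_masses = numeric(0), density = NA_real_,
                          density_sodium = NA_real_, density_acid = NA_real_,
                          mass_convention = NA_character_, seed = seed),
                     class = "packed_system")
    attr(out, "truth") <- list(generator = "gen_planted_system",
                               alkyl_sizes = planted_alkyl_cluster_sizes,
                               acid_sizes = planted_acid_cluster_sizes,
                               alkyl_acid_distance_A = rep(alkyl_acid_distance,
                                                           length.out = k),
                               chains_per_cluster = chains_per_cluster,
                               n_background = n_background, seed = seed)
    out
  })
}

#' Write a generator's ground truth beside its output file
#'
#' @param x an object carrying a `truth` attribute.
#' @param path the data file the truth belongs to; the sidecar is written at
#'   `<path>.truth.json`.
#' @return the sidecar path, invisibly.
#' @export
write_truth_sidecar <- function(x, path) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("object carries no ground-truth record")
  side <- paste0(path, ".truth.json")
  jsonlite::write_json(truth, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(side)
}
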