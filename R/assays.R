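# The two bench computations: critical aggregation concentration (CAC) from a
# pyrene I3/I1 titration, and octyl-amide degree of substitution inverted
# from TOC/TN elemental analysis.

#' Fit the critical aggregation concentration from a pyrene I3/I1 curve
#'
#' Pyrene's I3/I1 emission ratio (I3 ~ 383 nm over I1 ~ 373 nm) reports the
#' polarity of the probe's microenvironment: it stays flat below the CAC and
#' rises once hydrophobic aggregates form. The fit tries every admissible
#' split of the concentration-sorted points into a left and a right segment
#' (each with at least 3 points), fits least-squares lines to both, keeps the
#' split with the smallest total residual sum of squares, and reports the
#' abscissa of the two lines' intersection as the CAC.
#'
#' @param curve a `titration_curve` from [gen_pyrene_curve()], or a
#'   data.frame with columns `conc` (mg/mL, strictly positive) and `ratio`.
#' @param x_transform `"linear"` (default) or `"log10"`: scale on which the
#'   segments are fit. The CAC is always returned in mg/mL.
#' @param parallel_tol minimum slope difference below which the two segments
#'   are declared parallel (error).
#' @return Object of class `cac_fit`: `cac` (mg/mL), `cac_se` (delta-method
#'   standard error from the two fits' covariances), `left` and `right`
#'   (intercept, slope), `split` (points in the left segment), `rss`,
#'   `x_transform`.
#' @examples
#' cv <- gen_pyrene_curve(noise_sigma = 0, seed = 1)
#' fit_cac(cv)$cac    # 0.62
#' @export
fit_cac <- function(curve, x_transform = c("linear", "log10"),
                    parallel_tol = 1e-8) {
  x_transform <- match.arg(x_transform)
  df <- as.data.frame(curve)
  stopifnot(all(c("conc", "ratio") %in% names(df)))
  if (nrow(df) < 6) stop("need at least 6 titration points")
  if (any(df$conc <= 0)) stop("concentrations must be strictly positive")
  df <- df[order(df$conc), ]
  x <- if (x_transform == "log10") log10(df$conc) else df$conc
  y <- df$ratio
  n <- length(x)
  best <- NULL
  for (i in 3:(n - 3)) {
    fl <- stats::lm(y[1:i] ~ x[1:i])
    fr <- stats::lm(y[(i + 1):n] ~ x[(i + 1):n])
    rss <- sum(stats::resid(fl)^2) + sum(stats::resid(fr)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(i = i, fl = fl, fr = fr, rss = rss)
  }
  cl <- unname(stats::coef(best$fl)); cr <- unname(stats::coef(best$fr))
  dslope <- cl[2] - cr[2]
  if (!is.finite(dslope) || abs(dslope) < parallel_tol)
    stop("segments are parallel within tolerance; no intersection (single-regime data?)")
  xc <- (cr[1] - cl[1]) / dslope
  # delta method on (a_l, b_l, a_r, b_r), independent fits
  grad <- c(-1, -xc, 1, xc) / dslope
  V <- matrix(0, 4, 4)
  # vcov -> summary.lm warns on an exactly piecewise-linear (zero-residual) fit
  V[1:2, 1:2] <- suppressWarnings(stats::vcov(best$fl))
  V[3:4, 3:4] <- suppressWarnings(stats::vcov(best$fr))
  se_xc <- sqrt(drop(t(grad) %*% V %*% grad))
  cac <- if (x_transform == "log10") 10^xc else xc
  cac_se <- if (x_transform == "log10") log(10) * cac * se_xc else se_xc
  if (cac < min(df$conc) || cac > max(df$conc))
    warning("fitted CAC lies outside the concentration range of the data")
  structure(list(cac = cac, cac_se = cac_se,
                 left = c(intercept = cl[1], slope = cl[2]),
                 right = c(intercept = cr[1], slope = cr[2]),
                 split = best$i, rss = best$rss, x_transform = x_transform,
                 n = n),
            class = "cac_fit")
}

#' @export
print.cac_fit <- function(x, ...) {
  cat(sprintf("CAC = %.3f mg/mL (SE %.3f), two-segment fit on %d points (%s scale)\n",
              x$cac, x$cac_se, x$n, x$x_transform))
  cat(sprintf("  left: ratio = %.4f + %.4f x; right: ratio = %.4f + %.4f x; RSS %.3g\n",
              x$left[1], x$left[2], x$right[1], x$right[2], x$rss))
  invisible(x)
}

# Carbons / nitrogens per monomer at carboxymethyl DS `ds` and amide
# fraction `a`: 6 ring carbons, 2 per carboxymethyl, 8 extra per octyl
# amide; 1 nitrogen per octyl amide.
.carbon_per_monomer <- function(ds, a) 6 + 2 * ds + 8 * ds * a
.nitrogen_per_monomer <- function(ds, a) ds * a

#' Invert the octyl-amide degree of substitution from elemental C/N analysis
#'
#' The molar nitrogen-to-carbon ratio of an amidated CMC obeys
#' `N/C = ds * a / (6 + 2 ds + 8 ds a)`, where `ds` is the carboxymethyl
#' degree of substitution and `a` the fraction of carboxymethyl groups
#' carrying the octyl amide (each amide contributes one nitrogen and eight
#' extra carbons). Solving for `a` gives
#' `a = r (6 + 2 ds) / (ds (1 - 8 r))`, writing r for the molar N/C ratio.
#'
#' @param measurement an `elemental_measurement` from
#'   [gen_elemental_readings()], or a list/data.frame with `toc_mg_l`,
#'   `tn_mg_l` and optionally `ds_cm`.
#' @param ds_cm assumed carboxymethyl DS (default taken from the
#'   measurement, else 0.9).
#' @param toc_sd,tn_sd optional reading standard deviations (mg/L) for
#'   first-order uncertainty propagation.
#' @return list of class `amide_ds`: `a` (fraction), `a_percent`, `nc_molar`,
#'   `se_percent` (NA when no reading SDs are given).
#' @examples
#' m <- gen_elemental_readings(amide_ds = 0.22, seed = 1, noise_rel = 0)
#' estimate_amide_ds(m)$a_percent   # 22
#' @export
estimate_amide_ds <- function(measurement, ds_cm = NULL,
                              toc_sd = NULL, tn_sd = NULL) {
  toc <- measurement$toc_mg_l
  tn <- measurement$tn_mg_l
  if (is.null(ds_cm)) ds_cm <- measurement$ds_cm
  if (is.null(ds_cm)) ds_cm <- 0.9
  stopifnot(toc > 0, tn >= 0, ds_cm > 0)
  r <- (tn / .mass_N) / (toc / .mass_C)
  r_max <- ds_cm / (6 + 2 * ds_cm + 8 * ds_cm)
  if (r < 0 || r >= r_max)
    stop(sprintf("N/C molar ratio %.4g outside the invertible range [0, %.4g): ",
                 r, r_max),
         "readings are inconsistent with an octyl-amidated CMC at this ds_cm")
  a <- r * (6 + 2 * ds_cm) / (ds_cm * (1 - 8 * r))
  se <- NA_real_
  if (!is.null(toc_sd) && !is.null(tn_sd)) {
    # da/dr, with r's variance from independent TOC/TN noise
    dadr <- (6 + 2 * ds_cm) / (ds_cm * (1 - 8 * r)^2)
    var_r <- r^2 * ((tn_sd / tn)^2 + (toc_sd / toc)^2)
    se <- 100 * dadr * sqrt(var_r)
  }
  structure(list(a = a, a_percent = 100 * a, nc_molar = r,
                 ds_cm = ds_cm, se_percent = se),
            class = "amide_ds")
}

#' @export
print.amide_ds <- function(x, ...) {
  cat(sprintf("octyl-amide DS: %.2f%% of carboxymethyl groups (N/C molar %.4f, ds_cm %.2f)%s\n",
              x$a_percent, x$nc_molar, x$ds_cm,
              if (is.finite(x$se_percent)) sprintf(" +/- %.2f%%", x$se_percent) else ""))
  invisible(x)
}
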