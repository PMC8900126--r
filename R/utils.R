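# Physical constants and small shared helpers.

# Atomic masses (g/mol, IUPAC 2021 abridged)
.mass_C  <- 12.011
.mass_H  <- 1.008
.mass_O  <- 15.999
.mass_N  <- 14.007
.mass_Na <- 22.990

# Anhydroglucose residue C6H10O5
.mass_anhydroglucose <- 6 * .mass_C + 10 * .mass_H + 5 * .mass_O

# Mass increments for replacing a hydroxyl H with a substituent:
#   CM  (sodium salt): -CH2COONa  (C2H2O2Na - H)
#   CM  (free acid)  : -CH2COOH   (C2H3O2  - H)
#   CM8              : -CH2CONHC8H17 (C10H20NO - H), charge-neutral octyl amide
.mass_cm_sodium  <- 2 * .mass_C + 2 * .mass_H + 2 * .mass_O + .mass_Na - .mass_H
.mass_cm_acid    <- 2 * .mass_C + 3 * .mass_H + 2 * .mass_O - .mass_H
.mass_cm8        <- 10 * .mass_C + 20 * .mass_H + .mass_N + .mass_O - .mass_H

# Coulomb constant times elementary charge, in V*nm:
# e / (4 pi eps0) = 1.439964 V*nm, so a unit charge 1 nm away in eps_r = 80
# contributes 1439.964 / 80 ~ 18 mV unscreened.
.ke_e_Vnm <- 1.439964

.avogadro <- 6.02214076e23

#' @keywords internal
#' @noRd
debye_length_nm <- function(ionic_strength, temperature = 298) {
  stopifnot(ionic_strength > 0)
  0.304 / sqrt(ionic_strength) * sqrt(temperature / 298)
}

# Run code with a local RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Uniform random rotation matrix (Arvo/Shoemake via quaternion).
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Minimum-image displacement of coordinate differences in a cubic box (nm).
min_image <- function(d, box) {
  d - box * round(d / box)
}

# Pairwise minimum-image distance matrix between rows of a (and b).
pairwise_min_image_dist <- function(a, b = a, box = NULL) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) d <- min_image(d, box)
    out <- out + d * d
  }
  sqrt(out)
}
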