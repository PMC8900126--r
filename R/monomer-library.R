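#' Enumerate the 27 substituted-glucose monomer states
#'
#' Each anhydroglucose unit of a carboxymethyl cellulose (CMC) chain can carry,
#' at each of the ring positions 2, 3 and 6, either an unmodified hydroxyl
#' (`OH`), a carboxymethyl group (`CM`, charge -1e at neutral pH), or an
#' N-octyl-amidated carboxymethyl group (`CM8`, charge 0, one C8 alkyl tail).
#' The full state space is therefore 3^3 = 27 monomer types.
#'
#' @param mass_convention `"sodium_salt"` (carboxylates as -CH2COONa, the form
#'   CMC is supplied in) or `"free_acid"` (-CH2COOH). Affects masses only.
#' @return A data.frame with one row per monomer state and columns `pos2`,
#'   `pos3`, `pos6` (each `"OH"`, `"CM"` or `"CM8"`), `code` (e.g.
#'   `"CM.OH.CM8"`), `charge` (in e), `n_alkyl`, `n_cm_total` (positions that
#'   are CM or CM8) and `mass` (g/mol).
#' @examples
#' lib <- build_monomer_library()
#' nrow(lib)                                   # 27
#' lib[lib$code == "CM.CM.CM", "charge"]       # -3
#' @export
build_monomer_library <- function(mass_convention = c("sodium_salt", "free_acid")) {
  mass_convention <- match.arg(mass_convention)
  states <- c("OH", "CM", "CM8")
  g <- expand.grid(pos2 = states, pos3 = states, pos6 = states,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(g)
  n_cm  <- rowSums(m == "CM")
  n_cm8 <- rowSums(m == "CM8")
  cm_inc <- if (mass_convention == "sodium_salt") .mass_cm_sodium else .mass_cm_acid
  out <- data.frame(
    g,
    code = paste(g$pos2, g$pos3, g$pos6, sep = "."),
    charge = -n_cm,
    n_alkyl = n_cm8,
    n_cm_total = n_cm + n_cm8,
    mass = .mass_anhydroglucose + n_cm * cm_inc + n_cm8 * .mass_cm8,
    stringsAsFactors = FALSE
  )
  attr(out, "mass_convention") <- mass_convention
  out
}

#' Mean monomer mass of a CMC / CMC-8 composition
#'
#' @param ds_cm carboxymethyl degree of substitution (CM + CM8 per monomer).
#' @param amide_fraction fraction of carboxymethyl groups carrying the octyl
#'   amide.
#' @param mass_convention see [build_monomer_library()].
#' @return mean monomer mass in g/mol.
#' @export
mean_monomer_mass <- function(ds_cm = 0.9, amide_fraction = 200 / 900,
                              mass_convention = c("sodium_salt", "free_acid")) {
  mass_convention <- match.arg(mass_convention)
  cm_inc <- if (mass_convention == "sodium_salt") .mass_cm_sodium else .mass_cm_acid
  .mass_anhydroglucose +
    ds_cm * (1 - amide_fraction) * cm_inc +
    ds_cm * amide_fraction * .mass_cm8
}
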