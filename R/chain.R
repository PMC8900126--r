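#' Generate a CMC / CMC-8 chain from a fitted pattern distribution
#'
#' Draws monomer substitution patterns i.i.d. from `dist`, optionally repairs
#' the draw so the chain carries exactly `round(ds_cm * N)` carboxymethyl
#' groups, and then converts `round(amide_fraction * n_CM)` of those groups
#' (chosen uniformly at random, per group, not per monomer) to N-octyl amides
#' (`CM8`). `amide_fraction = 0` yields unmodified CMC; the default 200/900
#' yields the CMC-8 composition (200 amide groups and 700 charged
#' carboxylates per 1000-mer, i.e. -70e per 100-mer).
#'
#' @param dist a [fit_pattern_distribution()] object.
#' @param N chain length in monomers (>= 1).
#' @param amide_fraction fraction of CM groups amidated, in \[0, 1\].
#' @param enforce_exact_counts repair the i.i.d. draw to the exact CM count
#'   (default `TRUE`); with `FALSE` the draw is left purely i.i.d.
#' @param seed integer seed; identical seed gives an identical chain.
#' @param ds_cm target degree of carboxymethyl substitution; defaults to the
#'   distribution's total CM content (0.9 for the default fit).
#' @return An object of class `cmc_chain`: list with `states` (N x 3 character
#'   matrix over `"OH"/"CM"/"CM8"` for positions 2/3/6), `N`, `ds_cm`,
#'   `amide_fraction`, `enforce_exact_counts`, `seed`.
#' @examples
#' d <- fit_pattern_distribution()
#' ch <- generate_chain(d, N = 100, amide_fraction = 0, seed = 1)
#' chain_charge(ch)   # -90
#' @export
generate_chain <- function(dist, N, amide_fraction = 200 / 900,
                           enforce_exact_counts = TRUE, seed = NULL,
                           ds_cm = dist$ds_total) {
  stopifnot(inherits(dist, "pattern_dist"))
  if (N < 1) stop("N must be >= 1")
  if (amide_fraction < 0 || amide_fraction > 1)
    stop("amide_fraction must be in [0, 1]")
  P <- dist$patterns
  ns <- rowSums(P)
  with_seed(seed, {
    idx <- sample.int(8, N, replace = TRUE, prob = dist$prob)
    if (enforce_exact_counts) {
      target <- round(ds_cm * N)
      if (target > 3 * N) stop("ds_cm implies more than 3 CM groups per monomer")
      # Repair pass: redraw single monomers from the distribution conditioned
      # on a CM count one closer to the target, so conditional pattern
      # frequencies are preserved.
      repeat {
        cur <- sum(ns[idx])
        if (cur == target) break
        step <- sign(target - cur)
        cand <- which(ns[idx] + step >= 0 & ns[idx] + step <= 3)
        pos <- cand[sample.int(length(cand), 1)]
        pool <- which(ns == ns[idx[pos]] + step)
        pr <- dist$prob[pool]
        if (sum(pr) <= 0) pr <- rep(1, length(pool))
        idx[pos] <- pool[sample.int(length(pool), 1, prob = pr)]
      }
    }
    states <- matrix(c("OH", "CM")[P[idx, ] + 1], ncol = 3,
                     dimnames = list(NULL, c("pos2", "pos3", "pos6")))
    cm_pos <- which(states == "CM")
    n_amide <- round(amide_fraction * length(cm_pos))
    if (n_amide > 0) {
      states[cm_pos[sample.int(length(cm_pos), n_amide)]] <- "CM8"
    }
    structure(list(states = states, N = N, ds_cm = ds_cm,
                   amide_fraction = amide_fraction,
                   enforce_exact_counts = enforce_exact_counts, seed = seed),
              class = "cmc_chain")
  })
}

#' Total charge of a chain in elementary charges
#'
#' Each remaining (non-amidated) carboxymethyl group carries -1e.
#' @param chain a `cmc_chain`.
#' @return integer charge in e (<= 0).
#' @export
chain_charge <- function(chain) {
  -sum(chain$states == "CM")
}

#' Sequence-level composition statistics of a chain
#'
#' @param chain a `cmc_chain`.
#' @param mass_convention see [build_monomer_library()].
#' @return list with per-position substituted counts (`position_substituted`,
#'   CM or CM8) and charged counts (`position_charged`, CM only), class counts
#'   `class_counts` (monomers with 0..3 substituted positions), `total_cm`
#'   (CM + CM8 groups), `n_amide`, `charge` (e), `n_alkyl` and
#'   `mean_monomer_mass` (g/mol).
#' @export
chain_statistics <- function(chain, mass_convention = c("sodium_salt", "free_acid")) {
  mass_convention <- match.arg(mass_convention)
  s <- chain$states
  sub <- s != "OH"
  n_sub <- rowSums(sub)
  lib <- build_monomer_library(mass_convention)
  codes <- paste(s[, 1], s[, 2], s[, 3], sep = ".")
  mass <- lib$mass[match(codes, lib$code)]
  list(
    position_substituted = colSums(sub),
    position_charged = colSums(s == "CM"),
    class_counts = stats::setNames(
      vapply(0:3, function(j) sum(n_sub == j), integer(1)),
      paste0("n", 0:3)),
    total_cm = sum(sub),
    n_amide = sum(s == "CM8"),
    charge = chain_charge(chain),
    n_alkyl = sum(s == "CM8"),
    mean_monomer_mass = mean(mass)
  )
}

#' Count candidate negative-potential sites along a chain
#'
#' Tri-carboxymethylated monomers (all of positions 2, 3 and 6 substituted)
#' carry the largest local charge (-3e when none is amidated) and are the
#' loci where screened negative potential concentrates. Two counting rules
#' are provided because the published per-chain site counts do not pin one
#' down: `tri_full` requires all three positions to be charged CM;
#' `tri_ge2` requires a tri-substituted monomer (CM or CM8 at all three
#' positions) to retain at least `min_cm` charged CM groups.
#'
#' @param chain a `cmc_chain`.
#' @param rule `"tri_full"` or `"tri_ge2"`.
#' @param min_cm minimum retained CM groups for `tri_ge2` (default 2).
#' @return list of class `site_report`: `rule`, `count`, `min_cm`, `N`.
#' @export
count_negative_sites <- function(chain, rule = c("tri_full", "tri_ge2"),
                                 min_cm = 2) {
  rule <- match.arg(rule)
  s <- chain$states
  n_cm <- rowSums(s == "CM")
  tri <- rowSums(s != "OH") == 3
  count <- switch(rule,
    tri_full = sum(n_cm == 3),
    tri_ge2 = sum(tri & n_cm >= min_cm)
  )
  structure(list(rule = rule, count = count, min_cm = min_cm, N = chain$N),
            class = "site_report")
}

#' @export
print.cmc_chain <- function(x, ...) {
  st <- chain_statistics(x)
  cat(sprintf("cmc_chain: N=%d, %d CM+CM8 groups (%d amidated), charge %de\n",
              x$N, st$total_cm, st$n_amide, st$charge))
  invisible(x)
}

#' @export
print.site_report <- function(x, ...) {
  cat(sprintf("negative-site count (rule %s%s): %d on a %d-mer\n", x$rule,
              if (x$rule == "tri_ge2") sprintf(", min_cm=%d", x$min_cm) else "",
              x$count, x$N))
  invisible(x)
}
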