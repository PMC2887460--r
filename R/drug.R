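#' Drug specification: binding kinetics and gate-stabilizing factors
#'
#' In the modulated-receptor framework a state-dependent inhibitor is
#' described by five parameters: the association and dissociation rate
#' constants to the resting channel (`ka`, 1/(s*uM); `kd`, 1/s) and three
#' dimensionless gate-stabilizing factors (`CA`, `CF`, `CS`), one per gate.
#' A factor of 1 means no preference for that gate's conformation; a factor
#' greater than 1 stabilizes the closed/inactivated conformation of the gate
#' in drug-bound channels and, equally, increases the binding affinity to
#' channel states in which the gate is already closed. Using the same factor
#' for both roles keeps every reaction cycle microscopically reversible.
#'
#' @param ka Association rate constant to the resting state, 1/(s*uM).
#' @param kd Dissociation rate constant from the resting state, 1/s.
#' @param CA,CF,CS Stabilizing factors for the activation, fast-inactivation
#'   and slow-inactivation gates. All must be positive.
#' @param concentration Drug concentration, uM (>= 0).
#' @param name Optional label.
#' @return An object of class `drug_spec`.
#' @examples
#' # fast-binding, fast-inactivated-state-preferring prototype
#' drug_spec(ka = 0.5, kd = 100, CF = 10, concentration = 30, name = "FI_fb")
#' @export
drug_spec <- function(ka, kd, CA = 1, CF = 1, CS = 1, concentration = 0,
                      name = NULL) {
  stopifnot(ka > 0, kd > 0, concentration >= 0)
  if (any(c(CA, CF, CS) <= 0)) {
    stop("gate-stabilizing factors CA, CF, CS must be positive", call. = FALSE)
  }
  structure(list(ka = ka, kd = kd, CA = CA, CF = CF, CS = CS,
                 concentration = concentration,
                 name = name %||% "drug"),
            class = "drug_spec")
}

#' @export
print.drug_spec <- function(x, ...) {
  cat(sprintf(
    "<drug_spec> %s: ka = %g 1/(s*uM), kd = %g 1/s (Kd = %g uM), CA = %g, CF = %g, CS = %g, %g uM\n",
    x$name, x$ka, x$kd, x$kd / x$ka, x$CA, x$CF, x$CS, x$concentration))
  invisible(x)
}

#' Change the concentration of a drug specification
#'
#' @param drug A [drug_spec()].
#' @param concentration New concentration, uM.
#' @return The drug with the concentration replaced.
#' @export
at_concentration <- function(drug, concentration) {
  stopifnot(inherits(drug, "drug_spec"), concentration >= 0)
  drug$concentration <- concentration
  drug
}

#' Equilibrium stabilization factor of one gate in the drug-bound layer
#'
#' Returns the multiplicative shift of the closed/open equilibrium constant
#' of the named gate when the drug is bound (the corresponding `C` factor).
#'
#' @param drug A [drug_spec()].
#' @param gate `"activation"`, `"fast_inactivation"` or `"slow_inactivation"`.
#' @return The dimensionless equilibrium factor.
#' @export
stabilization_shift <- function(drug, gate) {
  stopifnot(inherits(drug, "drug_spec"))
  switch(match.arg(gate, c("activation", "fast_inactivation",
                           "slow_inactivation")),
         activation = drug$CA,
         fast_inactivation = drug$CF,
         slow_inactivation = drug$CS)
}

#' The four prototypical inhibitor mechanisms
#'
#' Fast- or slow-inactivated state preference (`FI`: CF = 10, CS = 1;
#' `SI`: CS = 10, CF = 1) crossed with fast or slow binding kinetics
#' (`fb`: ka = 0.5 1/(s*uM), kd = 100 1/s; `sb`: ka = 0.005, kd = 1).
#' All four share the resting-state dissociation constant Kd = kd/ka =
#' 200 uM and are, by default, applied at 30 uM.
#'
#' @param concentration Concentration for all four drugs, uM.
#' @return Named list of four [drug_spec()] objects:
#'   `FI_fb`, `FI_sb`, `SI_fb`, `SI_sb`.
#' @export
prototype_drugs <- function(concentration = 30) {
  kin <- list(fb = c(ka = 0.5, kd = 100), sb = c(ka = 0.005, kd = 1))
  out <- list()
  for (pref in c("FI", "SI")) {
    for (speed in c("fb", "sb")) {
      nm <- paste(pref, speed, sep = "_")
      out[[nm]] <- drug_spec(
        ka = kin[[speed]][["ka"]], kd = kin[[speed]][["kd"]],
        CF = if (pref == "FI") 10 else 1,
        CS = if (pref == "SI") 10 else 1,
        concentration = concentration, name = nm)
    }
  }
  out
}

#' The 100-drug parameter grid
#'
#' Ten kinetics pairs, log-spaced with `ka` from 5e-4 to 15 1/(s*uM) and `kd`
#' from 0.1 to 3000 1/s at fixed resting affinity `ka/kd = 5e-3` (Kd =
#' 200 uM), crossed with stabilizing factors 2, 5, 10, 20 and 50 applied
#' either to the fast-inactivation gate (`CF`, family `"FI"`) or to the
#' slow-inactivation gate (`CS`, family `"SI"`).
#'
#' @param factors Stabilizing factor values.
#' @param n_kinetics Number of log-spaced kinetics pairs.
#' @return A tibble with one row per drug: `name`, `family`, `factor`,
#'   `kinetics_rank`, `ka`, `kd` and a list-column `drug` of [drug_spec()]
#'   objects (concentration 0; scale each to its own IC50 before use).
#' @export
drug_grid <- function(factors = c(2, 5, 10, 20, 50), n_kinetics = 10) {
  ka <- 10 ^ seq(log10(5e-4), log10(15), length.out = n_kinetics)
  kd <- ka / 5e-3
  grid <- tidyr::expand_grid(
    family = c("FI", "SI"),
    factor = factors,
    kinetics_rank = seq_len(n_kinetics))
  grid$ka <- ka[grid$kinetics_rank]
  grid$kd <- kd[grid$kinetics_rank]
  grid$name <- sprintf("%s_C%g_k%02d", grid$family, grid$factor,
                       grid$kinetics_rank)
  grid$drug <- purrr::pmap(grid[c("family", "factor", "ka", "kd", "name")],
    function(family, factor, ka, kd, name) {
      drug_spec(ka = ka, kd = kd,
                CF = if (family == "FI") factor else 1,
                CS = if (family == "SI") factor else 1,
                concentration = 0, name = name)
    })
  dplyr::relocate(grid, "name", "family", "factor", "kinetics_rank",
                  "ka", "kd")
}
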