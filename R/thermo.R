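#' Standard Gibbs energy of reaction corrected to in situ T and P
#'
#' Corrects the 25 degree C, 1 bar standard-state reaction Gibbs energy to the
#' in situ temperature and pressure using the integrated Gibbs-Helmholtz
#' relation with a constant reaction enthalpy and a linear pressure term in
#' the reaction volume:
#' \deqn{\Delta G_r^0(T,P) = \Delta G_r^0 \frac{T}{T_{ref}} +
#'   \Delta H_r^0 \left(1 - \frac{T}{T_{ref}}\right) +
#'   \Delta V_r^0 (P - P_{ref}) \times 10^{-4}}
#' with energies in kJ mol^-1, volumes in cm^3 mol^-1 and pressure in bar
#' (1 cm^3 bar = 1e-4 kJ). This linear form is the standard approximation for
#' cold (< 30 degree C), shallow (< 100 bar) porewater systems.
#'
#' @param reaction Reaction name (see [methane_reactions()]), a named signed
#'   stoichiometry vector, or a reaction list.
#' @param species Species table, as from [thermo_constants()].
#' @param T Temperature, K.
#' @param P Pressure, bar.
#' @param constants Physical constants, from [physical_constants()].
#' @return Standard reaction Gibbs energy at T and P, kJ per mol of reaction.
#' @examples
#' standard_gibbs("mg_co2", T = 278.15, P = 40)
#' @export
standard_gibbs <- function(reaction, species = thermo_constants(),
                           T = 278.15, P = 1,
                           constants = physical_constants()) {
  rx <- .get_reaction(reaction)
  stopifnot(is.numeric(T), T > 0, is.numeric(P), P >= 0)
  props <- .species_props(names(rx$stoich), species)
  nu <- rx$stoich
  dG <- sum(nu * props$dGf0_kJ_mol)
  dH <- sum(nu * props$dHf0_kJ_mol)
  dV <- sum(nu * props$V0_cm3_mol)
  tr <- T / constants$T_ref
  dG * tr + dH * (1 - tr) + dV * (P - constants$P_ref) * 1e-4
}

# look up species rows, failing loudly when a species or a property is absent
.species_props <- function(needed, species) {
  idx <- match(needed, species$species)
  if (anyNA(idx)) {
    abort(paste0("Species missing from constants table: ",
                 paste(needed[is.na(idx)], collapse = ", ")))
  }
  props <- species[idx, , drop = FALSE]
  for (col in c("dGf0_kJ_mol", "dHf0_kJ_mol", "V0_cm3_mol")) {
    if (anyNA(props[[col]])) {
      abort(paste0("Missing ", col, " for species: ",
                   paste(props$species[is.na(props[[col]])], collapse = ", ")))
    }
  }
  props
}

#' Thermodynamic activity of a species
#'
#' Converts a molar concentration to a thermodynamic activity according to
#' the species' phase rule: aqueous species use a fixed activity coefficient
#' times the molar concentration, water has unit activity, the proton
#' activity is 10^(-pH), and `fixed_activity` species are pinned at 1.
#'
#' @param species_name Character vector of species names.
#' @param conc Named numeric vector of molar concentrations (mol L^-1);
#'   only consulted for aqueous species.
#' @param pH Porewater pH (needed only for the proton).
#' @param species Species table, as from [thermo_constants()].
#' @return Numeric vector of activities, one per `species_name`.
#' @examples
#' activity("CH4", conc = c(CH4 = 1e-3))      # 1.24e-3
#' activity("H+", pH = 7)                     # 1e-7
#' @export
activity <- function(species_name, conc = numeric(), pH = NULL,
                     species = thermo_constants()) {
  props <- .species_props(species_name, species)
  vapply(seq_along(species_name), function(i) {
    rule <- props$phase_rule[i]
    nm <- props$species[i]
    if (rule == "water" || rule == "fixed_activity") return(1.0)
    if (rule == "proton") {
      if (is.null(pH) || !is.finite(pH)) {
        abort("pH is required to compute the proton activity.")
      }
      return(10^(-pH))
    }
    c_i <- if (nm %in% names(conc)) conc[[nm]] else NA_real_
    if (!is.finite(c_i)) {
      abort(paste0("No concentration supplied for aqueous species '", nm, "'."))
    }
    if (c_i < 0) {
      abort(paste0("Negative concentration for species '", nm, "'."))
    }
    props$gamma[i] * c_i
  }, numeric(1))
}

#' Reaction quotient of activities
#'
#' Computes \eqn{Q_r = \prod_i a_i^{\nu_i}} over all species of the reaction.
#' Species with unit activity (water, proton via pH, fixed-activity species)
#' contribute through their phase rules; any aqueous species with zero
#' concentration and non-zero stoichiometry is a log-singularity and raises
#' an error naming the species.
#'
#' @inheritParams standard_gibbs
#' @param conc Named molar concentrations (mol L^-1).
#' @param pH Porewater pH.
#' @return Dimensionless reaction quotient.
#' @examples
#' reaction_quotient("aom",
#'   conc = c(CH4 = 1e-3 / 1.24, "SO4-2" = 1e-2 / 0.104,
#'            "HCO3-" = 1e-2 / 0.532, "HS-" = 1e-6 / 0.685),
#'   pH = 7)
#' @export
reaction_quotient <- function(reaction, conc, pH,
                              species = thermo_constants()) {
  rx <- .get_reaction(reaction)
  nu <- rx$stoich[rx$stoich != 0]
  a <- activity(names(nu), conc = conc, pH = pH, species = species)
  if (any(a == 0)) {
    abort(paste0("Zero activity (log-singularity) for species: ",
                 paste(names(nu)[a == 0], collapse = ", ")))
  }
  prod(a^nu)
}

#' In situ Gibbs energy of reaction
#'
#' Evaluates \eqn{\Delta G_r = \Delta G_r^0(T,P) + R T \ln Q_r} for one
#' reaction under one set of porewater conditions, returning the
#' T,P-corrected standard energy, the reaction quotient, the in situ energy,
#' and (for reactions with a normalisation basis such as methanol) the energy
#' per mol of the basis substrate.
#'
#' @inheritParams reaction_quotient
#' @param T Temperature, K.
#' @param P Pressure, bar.
#' @param constants Physical constants, from [physical_constants()].
#' @return A one-row tibble with columns `reaction`, `dG0_TP`, `Q`, `dGr`
#'   (all kJ per mol reaction; `Q` dimensionless) and `per_substrate`
#'   (kJ per mol of basis species, NA when no basis is defined).
#' @examples
#' gibbs_energy("mg_co2",
#'   conc = c("HCO3-" = 1e-2, H2 = 1e-8, CH4 = 1e-3),
#'   T = 278.15, P = 40, pH = 7.5)
#' @export
gibbs_energy <- function(reaction, conc, T = 278.15, P = 1, pH = 7,
                         species = thermo_constants(),
                         constants = physical_constants()) {
  rx <- .get_reaction(reaction)
  dG0 <- standard_gibbs(rx, species = species, T = T, P = P,
                        constants = constants)
  Q <- reaction_quotient(rx, conc = conc, pH = pH, species = species)
  dGr <- dG0 + constants$R * T * log(Q)
  basis <- rx$basis %||% NA_character_
  per_sub <- if (!is.na(basis)) dGr / abs(rx$stoich[[basis]]) else NA_real_
  name <- if (is.character(reaction) && length(reaction) == 1) reaction else "custom"
  tibble(reaction = name, dG0_TP = dG0, Q = Q, dGr = dGr,
         per_substrate = per_sub)
}

#' Stoichiometric consistency audit of the built-in reaction set
#'
#' The six built-in reactions are not thermodynamically independent:
#' acetate oxidation followed by CO2 reduction is aceticlastic
#' methanogenesis, and four methyl reductions minus one CO2 reduction is
#' methanol disproportionation. Both identities must hold to machine
#' precision for any conditions because the H2 (and other shared) terms
#' cancel exactly. This audit evaluates all five reactions under the given
#' conditions and returns the larger of the two cycle residuals.
#'
#' @inheritParams gibbs_energy
#' @return Maximum absolute cycle residual, kJ per mol of reaction.
#' @export
hess_check <- function(conc, T = 278.15, P = 1, pH = 7,
                       species = thermo_constants(),
                       constants = physical_constants()) {
  g <- function(rx) {
    gibbs_energy(rx, conc = conc, T = T, P = P, pH = pH,
                 species = species, constants = constants)$dGr
  }
  r1 <- abs(g("aao") + g("mg_co2") - g("mg_aceticlastic"))
  r2 <- abs(g("mg_methanol_disprop") - 4 * g("mg_methyl_reduction") + g("mg_co2"))
  max(r1, r2)
}
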