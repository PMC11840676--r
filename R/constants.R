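#' Physical constants used throughout the package
#'
#' Returns the gas constant, reference temperature and pressure of the
#' standard state, and the biological energy quantum (BEQ) threshold used to
#' classify reaction energies. The BEQ is the minimum free energy yield
#' assumed necessary for catabolic energy conservation, conventionally about
#' -10 kJ per mol of reaction.
#'
#' @param beq Biological energy quantum threshold, kJ per mol reaction.
#'   Must be negative.
#' @return A named list with elements `R` (kJ mol^-1 K^-1), `T_ref` (K),
#'   `P_ref` (bar) and `beq` (kJ mol^-1).
#' @examples
#' physical_constants()$R
#' @export
physical_constants <- function(beq = -10) {
  stopifnot(is.numeric(beq), length(beq) == 1, is.finite(beq), beq < 0)
  list(R = 0.008314, T_ref = 298.15, P_ref = 1, beq = beq)
}

#' Standard-state formation properties and activity coefficients
#'
#' The species table behind all Gibbs energy calculations: standard Gibbs
#' energies and enthalpies of formation (kJ mol^-1), standard molal volumes
#' (cm^3 mol^-1), ionic charge, a fixed dimensionless activity coefficient,
#' and a phase rule that controls how activity is computed:
#' \describe{
#'   \item{aqueous}{activity = gamma times molar concentration}
#'   \item{water}{activity identically 1}
#'   \item{proton}{activity = 10^(-pH)}
#'   \item{fixed_activity}{activity identically 1 regardless of concentration}
#' }
#' Formation properties are 25 degree C, 1 bar aqueous standard-state values
#' from standard compilations; the table ships as an editable TSV
#' (`system.file("extdata", "thermo_constants.tsv", package = "sedmeth")`)
#' so every number is a user-auditable input rather than hard-coded truth.
#' Activity coefficients are fixed seawater-porewater values: HCO3- 0.532,
#' CH4 1.24, SO4-2 0.104, HS- 0.685, with H2 set to that of methane and
#' acetate to that of bicarbonate; methanol carries gamma = 1.
#'
#' @param path Optional path to an alternative constants TSV with the same
#'   columns.
#' @return A tibble with columns `species`, `charge`, `dGf0_kJ_mol`,
#'   `dHf0_kJ_mol`, `V0_cm3_mol`, `gamma`, `phase_rule`.
#' @export
thermo_constants <- function(path = NULL) {
  path <- path %||% system.file("extdata", "thermo_constants.tsv",
                                package = "sedmeth")
  read_thermo_constants(path)
}

#' The built-in set of six methane-cycle reactions
#'
#' Signed stoichiometries (reactants negative, products positive) of the six
#' catabolic reactions analysed by the package:
#' hydrogenotrophic CO2 reduction (HCO3- + 4 H2 + H+ -> CH4 + 3 H2O),
#' aceticlastic methanogenesis (CH3COO- + H2O -> CH4 + HCO3-),
#' methanol disproportionation (4 CH3OH -> 3 CH4 + HCO3- + H2O + H+),
#' H2-dependent methyl reduction (CH3OH + H2 -> CH4 + H2O),
#' anaerobic acetate oxidation (CH3COO- + 4 H2O -> 2 HCO3- + 4 H2 + H+), and
#' sulfate-dependent anaerobic methane oxidation
#' (SO4-2 + CH4 -> HS- + HCO3- + H2O).
#' Methanol reactions carry methanol as the normalisation basis so energies
#' can be expressed per mol of methanol.
#'
#' @return A tibble with columns `reaction`, `species`, `nu` (signed
#'   stoichiometric coefficient) and `basis` (normalisation species or NA).
#' @examples
#' methane_reactions()
#' @export
methane_reactions <- function() {
  purrr::imap_dfr(.reaction_list(), function(rx, nm) {
    tibble(
      reaction = nm,
      species  = names(rx$stoich),
      nu       = unname(rx$stoich),
      basis    = rx$basis %||% NA_character_
    )
  })
}

# internal canonical representation: named stoichiometry vectors
.reaction_list <- function() {
  list(
    mg_co2 = list(
      stoich = c("HCO3-" = -1, "H2" = -4, "H+" = -1, "CH4" = 1, "H2O" = 3),
      basis = NULL
    ),
    mg_aceticlastic = list(
      stoich = c("acetate" = -1, "H2O" = -1, "CH4" = 1, "HCO3-" = 1),
      basis = NULL
    ),
    mg_methanol_disprop = list(
      stoich = c("methanol" = -4, "CH4" = 3, "HCO3-" = 1, "H2O" = 1, "H+" = 1),
      basis = "methanol"
    ),
    mg_methyl_reduction = list(
      stoich = c("methanol" = -1, "H2" = -1, "CH4" = 1, "H2O" = 1),
      basis = "methanol"
    ),
    aao = list(
      stoich = c("acetate" = -1, "H2O" = -4, "HCO3-" = 2, "H2" = 4, "H+" = 1),
      basis = NULL
    ),
    aom = list(
      stoich = c("SO4-2" = -1, "CH4" = -1, "HS-" = 1, "HCO3-" = 1, "H2O" = 1),
      basis = NULL
    )
  )
}

.get_reaction <- function(reaction) {
  rxs <- .reaction_list()
  if (is.character(reaction) && length(reaction) == 1) {
    if (!reaction %in% names(rxs)) {
      abort(paste0("Unknown reaction '", reaction, "'. Built-in reactions: ",
                   paste(names(rxs), collapse = ", ")))
    }
    return(rxs[[reaction]])
  }
  if (is.list(reaction) && !is.null(reaction$stoich)) return(reaction)
  if (is.numeric(reaction) && !is.null(names(reaction))) {
    return(list(stoich = reaction, basis = NULL))
  }
  abort("`reaction` must be a built-in reaction name, a named stoichiometry vector, or a list with a `stoich` element.")
}

# elemental compositions (C, H, O, S per formula unit) of the built-in
# species, used only to audit element/charge balance of the reaction set
.species_elements <- function() {
  m <- rbind(
    "H2O"      = c(C = 0, H = 2, O = 1, S = 0),
    "H+"       = c(C = 0, H = 1, O = 0, S = 0),
    "HCO3-"    = c(C = 1, H = 1, O = 3, S = 0),
    "CH4"      = c(C = 1, H = 4, O = 0, S = 0),
    "H2"       = c(C = 0, H = 2, O = 0, S = 0),
    "acetate"  = c(C = 2, H = 3, O = 2, S = 0),
    "SO4-2"    = c(C = 0, H = 0, O = 4, S = 1),
    "HS-"      = c(C = 0, H = 1, O = 0, S = 1),
    "methanol" = c(C = 1, H = 4, O = 1, S = 0)
  )
  m
}

#' Audit element and charge balance of a reaction
#'
#' Checks that a stoichiometry conserves C, H, O, S and charge, using the
#' built-in species compositions and the charges in the constants table.
#'
#' @param reaction Reaction name, named stoichiometry vector, or reaction list.
#' @param species Species table from [thermo_constants()].
#' @return Named numeric vector of element and charge imbalances (all zero for
#'   a balanced reaction).
#' @export
reaction_balance <- function(reaction, species = thermo_constants()) {
  rx <- .get_reaction(reaction)
  el <- .species_elements()
  missing <- setdiff(names(rx$stoich), rownames(el))
  if (length(missing) > 0) {
    abort(paste0("No elemental composition for species: ",
                 paste(missing, collapse = ", ")))
  }
  imb <- drop(rx$stoich %*% el[names(rx$stoich), , drop = FALSE])
  charges <- setNames(species$charge, species$species)
  imb <- c(imb, charge = sum(rx$stoich * charges[names(rx$stoich)]))
  imb
}
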