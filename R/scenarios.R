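#' Assumed-concentration scenario specification
#'
#' H2, methanol and sulfide porewater concentrations are rarely measured;
#' energy sweeps therefore evaluate each reaction at assumed lower and upper
#' in situ extremes of the unmeasured species. Defaults are H2 0.1-10 nM
#' (spanning sulfate-reducing to methanogenic sediments), methanol 1 nM-1 uM,
#' and sulfide 1 nM-10 mM.
#'
#' @param h2_nM Length-2 numeric, low and high H2 concentration in nM.
#' @param methanol_M Length-2 numeric, low and high methanol in mol L^-1.
#' @param hs_M Length-2 numeric, low and high sulfide (HS-) in mol L^-1.
#' @return A named list of scenario endpoint pairs.
#' @export
scenario_spec <- function(h2_nM = c(0.1, 10),
                          methanol_M = c(1e-9, 1e-6),
                          hs_M = c(1e-9, 1e-2)) {
  for (p in list(h2_nM, methanol_M, hs_M)) {
    stopifnot(length(p) == 2, is.numeric(p), all(p > 0), p[1] < p[2])
  }
  list(h2_nM = h2_nM, methanol_M = methanol_M, hs_M = hs_M)
}

# which assumed species each built-in reaction involves
.assumed_species <- function() {
  list(
    mg_co2              = "H2",
    mg_aceticlastic     = character(),
    mg_methanol_disprop = "methanol",
    mg_methyl_reduction = c("H2", "methanol"),
    aao                 = "H2",
    aom                 = "HS-"
  )
}

# measured profile columns each reaction needs (beyond pH)
.measured_needs <- function() {
  list(
    mg_co2              = c("DIC_mM", "CH4_mM"),
    mg_aceticlastic     = c("acetate_uM", "CH4_mM", "DIC_mM"),
    mg_methanol_disprop = c("CH4_mM", "DIC_mM"),
    mg_methyl_reduction = c("CH4_mM"),
    aao                 = c("acetate_uM", "DIC_mM"),
    aom                 = c("SO4_mM", "CH4_mM", "DIC_mM")
  )
}

# molar concentrations, temperature and pressure for one profile row.
# Pressure, when not measured, follows the hydrostatic approximation
# 1.013 + 0.1013 * (water depth + sediment depth, in m) bar; temperature
# defaults to the site bottom-water value (278.15 K if no metadata).
.row_conditions <- function(row, site_meta = NULL) {
  wd <- 0
  bt <- 278.15
  if (!is.null(site_meta)) {
    i <- match(row$site, site_meta$site)
    if (!is.na(i)) {
      wd <- site_meta$water_depth_m[i]
      bt <- site_meta$bottom_T_K[i]
    }
  }
  t_meas <- if ("T_K" %in% names(row)) row$T_K else NA_real_
  p_meas <- if ("P_bar" %in% names(row)) row$P_bar else NA_real_
  T <- if (is.finite(t_meas)) t_meas else bt
  P <- if (is.finite(p_meas)) {
    p_meas
  } else {
    1.013 + 0.1013 * (wd + row$depth_cm / 100)
  }
  conc <- c(
    "HCO3-"  = .na_num(row$DIC_mM) * 1e-3,
    "CH4"    = .na_num(row$CH4_mM) * 1e-3,
    "SO4-2"  = .na_num(row$SO4_mM) * 1e-3,
    "acetate" = .na_num(row$acetate_uM) * 1e-6
  )
  list(conc = conc, T = T, P = P, pH = .na_num(row$pH))
}

.na_num <- function(x) if (is.null(x) || !is.finite(x)) NA_real_ else x

#' Classify a reaction energy against the biological energy quantum
#'
#' Reaction energies are endergonic when positive, exergonic but below the
#' energy quantum when between the BEQ threshold and zero (insufficient for
#' energy conservation under the BEQ assumption), and exergonic above the
#' quantum when at or beyond the threshold. Zero counts as exergonic.
#'
#' @param dGr Numeric vector of reaction Gibbs energies, kJ per mol reaction.
#' @param constants Physical constants; `constants$beq` is the threshold.
#' @return Factor with levels `endergonic`, `exergonic_below_BEQ`,
#'   `exergonic_above_BEQ`.
#' @export
classify_energetics <- function(dGr, constants = physical_constants()) {
  stopifnot(all(is.finite(dGr)))
  out <- ifelse(dGr > 0, "endergonic",
                ifelse(dGr > constants$beq, "exergonic_below_BEQ",
                       "exergonic_above_BEQ"))
  factor(out, levels = c("endergonic", "exergonic_below_BEQ",
                         "exergonic_above_BEQ"))
}

#' Sweep in situ Gibbs energies over a depth profile
#'
#' Evaluates the built-in reactions at every depth of a porewater profile.
#' Reactions fully determined by measured concentrations are evaluated once
#' per depth; reactions involving assumed species (H2, methanol, sulfide) are
#' evaluated at every combination of the scenario's low/high endpoints for
#' the assumed species they contain. Methanol reactions are additionally
#' normalised per mol of methanol. Depth rows missing a required measurement
#' are skipped with a warning, never dropped silently.
#'
#' @param profile Porewater profile tibble in the documented dialect
#'   (`site`, `depth_cm`, optional `T_K`/`P_bar`, `pH`, `DIC_mM`, `CH4_mM`,
#'   `SO4_mM`, `acetate_uM`, ...).
#' @param site_meta Optional site metadata tibble (see [site_presets()]).
#' @param scenarios Scenario endpoints from [scenario_spec()].
#' @param reactions Character vector of reaction names to evaluate.
#' @param zones Optional zone assignment tibble (`site`, `depth_cm`, `zone`)
#'   joined onto the output.
#' @param species,constants Species table and physical constants.
#' @return An energy table tibble with one row per depth x reaction x
#'   scenario endpoint: `site`, `depth_cm`, `zone`, `reaction`, `scenario`,
#'   `h2_nM`, `methanol_M`, `hs_M`, `dG0_TP`, `Q`, `dGr`, `per_substrate`,
#'   `beq_class`.
#' @export
sweep_energies <- function(profile, site_meta = NULL,
                           scenarios = scenario_spec(),
                           reactions = names(.reaction_list()),
                           zones = NULL,
                           species = thermo_constants(),
                           constants = physical_constants()) {
  stopifnot(is.data.frame(profile), all(c("site", "depth_cm") %in% names(profile)))
  assumed <- .assumed_species()
  needs <- .measured_needs()
  skipped <- character()
  rows <- list()
  for (i in seq_len(nrow(profile))) {
    row <- profile[i, ]
    cond <- .row_conditions(row, site_meta)
    for (rx_name in reactions) {
      need <- needs[[rx_name]]
      # a zero measured concentration is a log-singularity for the quotient,
      # so treat it like a missing measurement for this reaction
      have <- vapply(need, function(cl) {
        v <- .na_num(row[[cl]])
        is.finite(v) && v > 0
      }, logical(1))
      uses_proton <- "H+" %in% names(.reaction_list()[[rx_name]]$stoich)
      if (!all(have) || (uses_proton && !is.finite(cond$pH))) {
        skipped <- c(skipped, paste0(row$site, " ", row$depth_cm, " cm: ",
                                     rx_name))
        next
      }
      grid <- .scenario_grid(assumed[[rx_name]], scenarios)
      for (j in seq_len(nrow(grid))) {
        conc <- cond$conc
        if (is.finite(grid$h2_nM[j])) conc[["H2"]] <- grid$h2_nM[j] * 1e-9
        if (is.finite(grid$methanol_M[j])) conc[["methanol"]] <- grid$methanol_M[j]
        if (is.finite(grid$hs_M[j])) conc[["HS-"]] <- grid$hs_M[j]
        g <- gibbs_energy(rx_name, conc = conc, T = cond$T, P = cond$P,
                          pH = cond$pH, species = species,
                          constants = constants)
        rows[[length(rows) + 1]] <- tibble(
          site = row$site, depth_cm = row$depth_cm,
          reaction = rx_name, scenario = grid$scenario[j],
          h2_nM = grid$h2_nM[j], methanol_M = grid$methanol_M[j],
          hs_M = grid$hs_M[j],
          dG0_TP = g$dG0_TP, Q = g$Q, dGr = g$dGr,
          per_substrate = g$per_substrate
        )
      }
    }
  }
  if (length(skipped) > 0) {
    warn(paste0("Skipped ", length(skipped),
                " depth x reaction combinations with incomplete inputs: ",
                paste(utils::head(skipped, 5), collapse = "; "),
                if (length(skipped) > 5) " ..." else ""))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$beq_class <- classify_energetics(out$dGr, constants)
  if (!is.null(zones)) {
    out <- left_join(out, zones[, c("site", "depth_cm", "zone")],
                     by = c("site", "depth_cm"))
  } else {
    out$zone <- NA_character_
  }
  relocate(out, "zone", .after = "depth_cm")
}

# endpoint combinations for the assumed species a reaction involves
.scenario_grid <- function(assumed, scenarios) {
  vals <- list(
    h2_nM = if ("H2" %in% assumed) scenarios$h2_nM else NA_real_,
    methanol_M = if ("methanol" %in% assumed) scenarios$methanol_M else NA_real_,
    hs_M = if ("HS-" %in% assumed) scenarios$hs_M else NA_real_
  )
  grid <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
  grid <- as_tibble(grid)
  lab <- apply(grid, 1, function(r) {
    parts <- character()
    if (is.finite(r[["h2_nM"]])) parts <- c(parts, paste0("H2=", r[["h2_nM"]], "nM"))
    if (is.finite(r[["methanol_M"]])) parts <- c(parts, paste0("MeOH=", r[["methanol_M"]], "M"))
    if (is.finite(r[["hs_M"]])) parts <- c(parts, paste0("HS=", r[["hs_M"]], "M"))
    if (length(parts) == 0) "measured" else paste(parts, collapse = ",")
  })
  grid$scenario <- lab
  grid
}

#' Closed-form H2 feasibility window for syntrophic acetate conversion
#'
#' Anaerobic acetate oxidation (producing H2) and hydrogenotrophic CO2
#' reduction (consuming H2) can only proceed together inside a narrow range
#' of H2 concentrations. Both reaction energies are linear in ln a(H2) with
#' slopes +4RT and -4RT, so the window has closed-form endpoints. Writing
#' \eqn{C_{MG} = \Delta G^0_{MG} + RT \ln(a_{CH4} / (a_{HCO3} a_{H+}))} and
#' \eqn{C_{AAO} = \Delta G^0_{AAO} + RT \ln(a_{HCO3}^2 a_{H+} / a_{Ac})},
#' the minimum H2 activity (CO2 reduction equilibrium) is
#' \eqn{\exp(C_{MG}/4RT)}, the maximum (acetate oxidation equilibrium) is
#' \eqn{\exp(-C_{AAO}/4RT)}, and both reactions yield equal energy at
#' \eqn{\exp((C_{MG}-C_{AAO})/8RT)}. Activities are converted to
#' concentrations with the H2 activity coefficient.
#'
#' @inheritParams sweep_energies
#' @return A tibble with one row per usable depth: `site`, `depth_cm`,
#'   `zone`, `h2_min_M`, `h2_equal_M`, `h2_max_M`, the same in nM, `exists`
#'   (window non-empty), and `dG_at_equal` (common energy of both reactions
#'   at the equal-energy H2, kJ per mol reaction).
#' @export
h2_feasibility_window <- function(profile, site_meta = NULL, zones = NULL,
                                  species = thermo_constants(),
                                  constants = physical_constants()) {
  stopifnot(is.data.frame(profile))
  gam_h2 <- species$gamma[match("H2", species$species)]
  rows <- purrr::map_dfr(seq_len(nrow(profile)), function(i) {
    row <- profile[i, ]
    cond <- .row_conditions(row, site_meta)
    ok <- all(is.finite(c(cond$conc[["HCO3-"]], cond$conc[["CH4"]],
                          cond$conc[["acetate"]], cond$pH))) &&
      all(c(cond$conc[["HCO3-"]], cond$conc[["CH4"]],
            cond$conc[["acetate"]]) > 0)
    if (!ok) return(tibble())
    RT <- constants$R * cond$T
    a <- activity(c("CH4", "HCO3-", "acetate", "H+"),
                  conc = cond$conc, pH = cond$pH, species = species)
    names(a) <- c("CH4", "HCO3", "Ac", "H")
    dG0_mg <- standard_gibbs("mg_co2", species, T = cond$T, P = cond$P,
                             constants = constants)
    dG0_aao <- standard_gibbs("aao", species, T = cond$T, P = cond$P,
                              constants = constants)
    C_mg <- dG0_mg + RT * log(a[["CH4"]] / (a[["HCO3"]] * a[["H"]]))
    C_aao <- dG0_aao + RT * log(a[["HCO3"]]^2 * a[["H"]] / a[["Ac"]])
    a_min <- exp(C_mg / (4 * RT))
    a_max <- exp(-C_aao / (4 * RT))
    a_eq <- exp((C_mg - C_aao) / (8 * RT))
    tibble(
      site = row$site, depth_cm = row$depth_cm,
      h2_min_M = a_min / gam_h2, h2_equal_M = a_eq / gam_h2,
      h2_max_M = a_max / gam_h2,
      h2_min_nM = 1e9 * a_min / gam_h2, h2_equal_nM = 1e9 * a_eq / gam_h2,
      h2_max_nM = 1e9 * a_max / gam_h2,
      exists = a_min < a_max,
      dG_at_equal = (C_mg + C_aao) / 2
    )
  })
  if (nrow(rows) == 0) return(rows)
  if (!is.null(zones)) {
    rows <- left_join(rows, zones[, c("site", "depth_cm", "zone")],
                      by = c("site", "depth_cm"))
  } else {
    rows$zone <- NA_character_
  }
  relocate(rows, "zone", .after = "depth_cm")
}

#' Which methylotrophic pathway is more exergonic, and where they cross
#'
#' Compares methanol disproportionation and H2-dependent methyl reduction
#' per mol of methanol at each H2 scenario endpoint. Because of the
#' thermodynamic cycle linking the two reactions through CO2 reduction, the
#' per-methanol energy difference (disproportionation minus reduction)
#' equals minus one quarter of the CO2-reduction energy, so it increases
#' strictly monotonically in ln[H2] with slope RT and crosses zero exactly
#' once - at the H2 concentration where CO2 reduction is at equilibrium.
#'
#' @inheritParams sweep_energies
#' @param methanol_M Methanol concentration used for both reactions,
#'   mol L^-1 (default: the scenario's upper endpoint).
#' @return A tibble with one row per depth x H2 endpoint: `site`,
#'   `depth_cm`, `h2_nM`, `dG_disprop_per_mol`, `dG_methyl_red_per_mol`
#'   (kJ per mol methanol), `favored` (the more exergonic pathway), and
#'   `crossover_h2_nM` (H2 at which the two pathways yield equal energy;
#'   independent of methanol concentration).
#' @export
methylotrophic_switch <- function(profile, site_meta = NULL,
                                  scenarios = scenario_spec(),
                                  methanol_M = NULL,
                                  species = thermo_constants(),
                                  constants = physical_constants()) {
  methanol_M <- methanol_M %||% scenarios$methanol_M[2]
  gam_h2 <- species$gamma[match("H2", species$species)]
  purrr::map_dfr(seq_len(nrow(profile)), function(i) {
    row <- profile[i, ]
    cond <- .row_conditions(row, site_meta)
    if (!all(is.finite(c(cond$conc[["HCO3-"]], cond$conc[["CH4"]], cond$pH))))
      return(tibble())
    RT <- constants$R * cond$T
    a <- activity(c("CH4", "HCO3-", "H+"), conc = cond$conc, pH = cond$pH,
                  species = species)
    dG0_mg <- standard_gibbs("mg_co2", species, T = cond$T, P = cond$P,
                             constants = constants)
    C_mg <- dG0_mg + RT * log(a[1] / (a[2] * a[3]))
    cross_nM <- 1e9 * exp(C_mg / (4 * RT)) / gam_h2
    purrr::map_dfr(scenarios$h2_nM, function(h2) {
      conc <- cond$conc
      conc[["H2"]] <- h2 * 1e-9
      conc[["methanol"]] <- methanol_M
      gd <- gibbs_energy("mg_methanol_disprop", conc = conc, T = cond$T,
                         P = cond$P, pH = cond$pH, species = species,
                         constants = constants)$per_substrate
      gm <- gibbs_energy("mg_methyl_reduction", conc = conc, T = cond$T,
                         P = cond$P, pH = cond$pH, species = species,
                         constants = constants)$per_substrate
      tibble(
        site = row$site, depth_cm = row$depth_cm, h2_nM = h2,
        dG_disprop_per_mol = gd, dG_methyl_red_per_mol = gm,
        favored = ifelse(gd < gm, "disproportionation", "methyl_reduction"),
        crossover_h2_nM = cross_nM
      )
    })
  })
}
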