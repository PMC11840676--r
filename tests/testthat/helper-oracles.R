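# Independent brute-force oracles and random-condition generators shared by
# the unit and acceptance tests. Everything here deliberately avoids the
# package's own code paths: energies are summed species by species from the
# constants table, and roots are located by sign change on a dense grid.

oracle_species <- function() {
  # read the shipped constants table directly
  utils::read.delim(system.file("extdata", "thermo_constants.tsv",
                                package = "sedmeth"))
}

# term-by-term Gibbs energy: loops over species, no shared code with the
# package implementation
oracle_dG <- function(stoich, conc, T, P, pH,
                      tbl = oracle_species()) {
  dG <- 0; dH <- 0; dV <- 0; lnQ <- 0
  for (nm in names(stoich)) {
    row <- tbl[tbl$species == nm, ]
    nu <- stoich[[nm]]
    dG <- dG + nu * row$dGf0_kJ_mol
    dH <- dH + nu * row$dHf0_kJ_mol
    dV <- dV + nu * row$V0_cm3_mol
    a <- switch(row$phase_rule,
                water = 1,
                fixed_activity = 1,
                proton = 10^(-pH),
                aqueous = row$gamma * conc[[nm]])
    lnQ <- lnQ + nu * log(a)
  }
  dG0 <- dG * T / 298.15 + dH * (1 - T / 298.15) + dV * (P - 1) * 1e-4
  dG0 + 0.008314 * T * lnQ
}

oracle_stoich <- function(name) {
  switch(name,
    mg_co2 = c("HCO3-" = -1, "H2" = -4, "H+" = -1, "CH4" = 1, "H2O" = 3),
    mg_aceticlastic = c("acetate" = -1, "H2O" = -1, "CH4" = 1, "HCO3-" = 1),
    mg_methanol_disprop = c("methanol" = -4, "CH4" = 3, "HCO3-" = 1,
                            "H2O" = 1, "H+" = 1),
    mg_methyl_reduction = c("methanol" = -1, "H2" = -1, "CH4" = 1,
                            "H2O" = 1),
    aao = c("acetate" = -1, "H2O" = -4, "HCO3-" = 2, "H2" = 4, "H+" = 1),
    aom = c("SO4-2" = -1, "CH4" = -1, "HS-" = 1, "HCO3-" = 1, "H2O" = 1)
  )
}

# random but geochemically plausible porewater conditions
random_conditions <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(
      conc = c(
        "HCO3-" = runif(1, 1e-3, 3e-2),
        "CH4" = 10^runif(1, -6, -2.3),
        "SO4-2" = runif(1, 1e-4, 2.8e-2),
        "acetate" = 10^runif(1, -6.3, -4.7),
        "HS-" = 10^runif(1, -9, -2),
        "H2" = 10^runif(1, -10, -8),
        "methanol" = 10^runif(1, -9, -6)
      ),
      T = runif(1, 274, 290),
      P = runif(1, 1, 60),
      pH = runif(1, 6.5, 8.5)
    )
  })
}

# grid search for the H2 roots of CO2 reduction and acetate oxidation:
# dense log grid, sign-change bracketing, term-by-term energies
oracle_h2_window_grid <- function(cond, n_grid = 1e6,
                                  tbl = oracle_species()) {
  h2 <- 10^seq(-12, -6, length.out = n_grid)
  RT <- 0.008314 * cond$T
  # constants independent of H2, via the term-by-term oracle at a(H2) = 1
  conc1 <- cond$conc
  conc1[["H2"]] <- 1 / tbl$gamma[tbl$species == "H2"]
  C_mg <- oracle_dG(oracle_stoich("mg_co2"), conc1, cond$T, cond$P,
                    cond$pH, tbl)
  C_aao <- oracle_dG(oracle_stoich("aao"), conc1, cond$T, cond$P,
                     cond$pH, tbl)
  a_h2 <- tbl$gamma[tbl$species == "H2"] * h2
  dg_mg <- C_mg - 4 * RT * log(a_h2)
  dg_aao <- C_aao + 4 * RT * log(a_h2)
  bracket <- function(y) {
    s <- which(diff(sign(y)) != 0)
    if (length(s) == 0) return(NA_real_)
    i <- s[1]
    # linear interpolation inside the bracketing interval
    exp(log(h2[i]) + (log(h2[i + 1]) - log(h2[i])) *
          (0 - y[i]) / (y[i + 1] - y[i]))
  }
  list(h2_min = bracket(dg_mg), h2_max = bracket(dg_aao),
       h2_equal = bracket(dg_mg - dg_aao))
}

# zero-noise fixture profiles and truths, built once per test run
zero_noise_sites <- function() {
  specs <- sedmeth::site_presets()
  lapply(specs, function(sp) {
    sedmeth::generate_site_profile(sp, noise_scale = 0, seed = 1)
  })
}

zone_truth_table <- function(gens) {
  dplyr::bind_rows(lapply(gens, function(g) {
    tibble::tibble(site = g$profile$site, depth_cm = g$profile$depth_cm,
                   zone = g$truth$zone)
  }))
}
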