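test_that("standard Gibbs energy reduces to formation sums at reference conditions", {
  sp <- thermo_constants()
  rx <- methane_reactions()
  for (nm in unique(rx$reaction)) {
    stoich <- setNames(rx$nu[rx$reaction == nm], rx$species[rx$reaction == nm])
    expected <- sum(stoich * sp$dGf0_kJ_mol[match(names(stoich), sp$species)])
    expect_equal(standard_gibbs(nm, sp, T = 298.15, P = 1), expected,
                 tolerance = 1e-12)
  }
})

test_that("temperature correction vanishes when reaction enthalpy equals reaction Gibbs energy", {
  sp <- tibble::tibble(
    species = c("A", "B"), charge = 0,
    dGf0_kJ_mol = c(-100, -50), dHf0_kJ_mol = c(-100, -50),
    V0_cm3_mol = 0, gamma = 1, phase_rule = "aqueous"
  )
  rx <- c(A = -1, B = 1)
  g_cold <- standard_gibbs(rx, sp, T = 275, P = 1)
  g_warm <- standard_gibbs(rx, sp, T = 295, P = 1)
  expect_equal(g_cold, g_warm, tolerance = 1e-12)
  expect_equal(g_cold, 50, tolerance = 1e-12)
})

test_that("pressure correction is linear in reaction volume (hand oracle)", {
  sp <- tibble::tibble(
    species = c("A", "B"), charge = 0,
    dGf0_kJ_mol = c(-10, -10), dHf0_kJ_mol = c(-10, -10),
    V0_cm3_mol = c(150, 50), gamma = 1, phase_rule = "aqueous"
  )
  # sum(nu * V0) = -100 cm3/mol; at dP = 50 bar: -100 * 50 * 1e-4 = -0.5 kJ
  rx <- c(A = -1, B = 1)
  at_ref <- standard_gibbs(rx, sp, T = 298.15, P = 1)
  at_50 <- standard_gibbs(rx, sp, T = 298.15, P = 51)
  expect_equal(at_50 - at_ref, -0.5, tolerance = 1e-12)
})

test_that("missing species or properties fail naming the culprit", {
  sp <- thermo_constants()
  expect_error(standard_gibbs(c(unobtainium = -1, CH4 = 1), sp),
               "unobtainium")
  sp2 <- sp
  sp2$dHf0_kJ_mol[sp2$species == "CH4"] <- NA
  expect_error(standard_gibbs("mg_co2", sp2), "CH4")
})

test_that("activities follow the phase rules", {
  expect_identical(activity("H2O"), 1.0)
  expect_equal(activity("CH4", conc = c(CH4 = 1e-3)), 1.24e-3)
  expect_equal(activity("H+", pH = 7), 1e-7)
  expect_equal(activity("H+", pH = 8.2), 10^-8.2)
  expect_error(activity("CH4", conc = c(CH4 = -1e-3)), "Negative")
  expect_error(activity("CH4", conc = c("SO4-2" = 1e-3)), "CH4")
})

test_that("reaction quotient matches hand arithmetic and monomial scaling", {
  sp <- thermo_constants()
  # choose concentrations whose activities are round powers of ten
  conc <- c(CH4 = 1e-3 / 1.24, "SO4-2" = 1e-2 / 0.104,
            "HCO3-" = 1e-2 / 0.532, "HS-" = 1e-6 / 0.685)
  q <- reaction_quotient("aom", conc = conc, pH = 7, species = sp)
  expect_equal(q, (1e-2 * 1e-6) / (1e-3 * 1e-2), tolerance = 1e-12)

  conc2 <- conc
  conc2[["HS-"]] <- 2 * conc2[["HS-"]]  # product with nu = +1
  expect_equal(reaction_quotient("aom", conc2, pH = 7, species = sp), 2 * q,
               tolerance = 1e-12)

  conc3 <- conc
  conc3[["CH4"]] <- 0
  expect_error(reaction_quotient("aom", conc3, pH = 7, species = sp), "CH4")
})

test_that("unit activities give Q = 1 and dGr = dG0", {
  sp <- thermo_constants()
  conc <- c("HCO3-" = 1 / 0.532, H2 = 1 / 1.24, CH4 = 1 / 1.24)
  q <- reaction_quotient("mg_co2", conc = conc, pH = 0, species = sp)
  expect_equal(q, 1, tolerance = 1e-12)
  g <- gibbs_energy("mg_co2", conc = conc, T = 280, P = 10, pH = 0,
                    species = sp)
  expect_equal(g$dGr, g$dG0_TP, tolerance = 1e-12)
})

test_that("the dGr identity and equilibrium hold", {
  cst <- physical_constants()
  conds <- random_conditions(5, seed = 7)
  for (cond in conds) {
    g <- gibbs_energy("aom", conc = cond$conc, T = cond$T, P = cond$P,
                      pH = cond$pH)
    expect_equal(g$dGr, g$dG0_TP + cst$R * cond$T * log(g$Q),
                 tolerance = 1e-9)
  }
  # equilibrium: scale HS- so that Q = exp(-dG0/RT), then dGr = 0
  cond <- conds[[1]]
  g <- gibbs_energy("aom", conc = cond$conc, T = cond$T, P = cond$P,
                    pH = cond$pH)
  target_Q <- exp(-g$dG0_TP / (cst$R * cond$T))
  cond$conc[["HS-"]] <- cond$conc[["HS-"]] * target_Q / g$Q
  g2 <- gibbs_energy("aom", conc = cond$conc, T = cond$T, P = cond$P,
                     pH = cond$pH)
  expect_equal(g2$dGr, 0, tolerance = 1e-9)
})

test_that("per-substrate normalisation divides by the methanol coefficient", {
  cond <- random_conditions(1, seed = 3)[[1]]
  g <- gibbs_energy("mg_methanol_disprop", conc = cond$conc, T = cond$T,
                    P = cond$P, pH = cond$pH)
  expect_equal(g$per_substrate, g$dGr / 4, tolerance = 1e-12)
  g2 <- gibbs_energy("mg_methyl_reduction", conc = cond$conc, T = cond$T,
                     P = cond$P, pH = cond$pH)
  expect_equal(g2$per_substrate, g2$dGr, tolerance = 1e-12)
  g3 <- gibbs_energy("aom", conc = cond$conc, T = cond$T, P = cond$P,
                     pH = cond$pH)
  expect_true(is.na(g3$per_substrate))
})

test_that("all six built-in reactions balance elements and charge", {
  for (nm in unique(methane_reactions()$reaction)) {
    imb <- reaction_balance(nm)
    expect_true(all(abs(imb) < 1e-12), label = nm)
  }
})

test_that("gibbs_energy matches the term-by-term oracle on randomized conditions", {
  conds <- random_conditions(100, seed = 11)
  for (nm in unique(methane_reactions()$reaction)) {
    stoich <- oracle_stoich(nm)
    for (cond in conds) {
      got <- gibbs_energy(nm, conc = cond$conc, T = cond$T, P = cond$P,
                          pH = cond$pH)$dGr
      want <- oracle_dG(stoich, cond$conc, cond$T, cond$P, cond$pH)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("hess_check residual is tiny and invariant to H2, T, P", {
  conds <- random_conditions(10, seed = 5)
  for (cond in conds) {
    expect_lt(hess_check(cond$conc, T = cond$T, P = cond$P, pH = cond$pH),
              1e-9)
  }
  cond <- conds[[1]]
  for (h2 in c(1e-10, 1e-9, 1e-8)) {
    cond$conc[["H2"]] <- h2
    expect_lt(hess_check(cond$conc, T = cond$T, P = cond$P, pH = cond$pH),
              1e-9)
  }
})
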