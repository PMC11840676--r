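gens <- zero_noise_sites()
prof_all <- dplyr::bind_rows(lapply(gens, function(g) g$profile))
zones_all <- zone_truth_table(gens)
meta <- site_meta_table()

test_that("BEQ classification applies the boundary rules", {
  cls <- classify_energetics(c(5, 0, -5, -10, -40))
  expect_equal(as.character(cls),
               c("endergonic", "exergonic_below_BEQ", "exergonic_below_BEQ",
                 "exergonic_above_BEQ", "exergonic_above_BEQ"))
  cls2 <- classify_energetics(-12, physical_constants(beq = -20))
  expect_equal(as.character(cls2), "exergonic_below_BEQ")
})

test_that("scenario endpoints only apply to reactions containing assumed species", {
  prof <- gens$S2$profile
  en <- suppressWarnings(
    sweep_energies(prof, meta, reactions = c("mg_aceticlastic", "mg_co2")))
  ace <- dplyr::filter(en, reaction == "mg_aceticlastic")
  expect_true(all(ace$scenario == "measured"))
  co2 <- dplyr::filter(en, reaction == "mg_co2")
  expect_setequal(unique(co2$scenario), c("H2=0.1nM", "H2=10nM"))
  # aceticlastic energies are untouched by the H2 scenario by construction:
  # one row per depth, each depth appearing once
  expect_equal(nrow(ace), length(unique(ace$depth_cm)))
})

test_that("energy table row count is depths-with-complete-inputs x endpoints", {
  prof <- gens$S3$profile
  en <- suppressWarnings(sweep_energies(prof, meta))
  counts <- dplyr::count(en, reaction)
  n_depth <- nrow(prof)
  # methane and DIC are positive everywhere in the noise-free S3 profile
  expected <- c(mg_co2 = 2L, mg_aceticlastic = 1L, mg_methanol_disprop = 2L,
                mg_methyl_reduction = 4L, aao = 2L)
  for (nm in names(expected)) {
    expect_equal(counts$n[counts$reaction == nm],
                 n_depth * expected[[nm]], label = nm)
  }
  # AOM rows only where sulfate is still nonzero
  n_so4 <- sum(prof$SO4_mM > 0)
  expect_equal(counts$n[counts$reaction == "aom"], n_so4 * 2L)
})

test_that("H2 sensitivity of CO2 reduction is exactly -4RT ln(100) at every depth", {
  cst <- physical_constants()
  en <- suppressWarnings(
    sweep_energies(prof_all, meta, reactions = "mg_co2"))
  wide <- tidyr::pivot_wider(en[, c("site", "depth_cm", "h2_nM", "dGr")],
                             names_from = "h2_nM", values_from = "dGr")
  expect_true(all(is.finite(wide[["0.1"]]) & is.finite(wide[["10"]])))
  delta <- wide[["10"]] - wide[["0.1"]]
  expect_equal(delta, rep(-4 * cst$R * 278.15 * log(100), nrow(wide)),
               tolerance = 1e-9)
})

test_that("AOM and aceticlastic energies are independent of H2 and methanol", {
  cond <- random_conditions(1, seed = 9)[[1]]
  base <- list(
    aom = gibbs_energy("aom", cond$conc, cond$T, cond$P, cond$pH)$dGr,
    ace = gibbs_energy("mg_aceticlastic", cond$conc, cond$T, cond$P,
                       cond$pH)$dGr
  )
  cond$conc[["H2"]] <- cond$conc[["H2"]] * 100
  cond$conc[["methanol"]] <- cond$conc[["methanol"]] * 1000
  expect_equal(gibbs_energy("aom", cond$conc, cond$T, cond$P, cond$pH)$dGr,
               base$aom, tolerance = 1e-12)
  expect_equal(gibbs_energy("mg_aceticlastic", cond$conc, cond$T, cond$P,
                            cond$pH)$dGr, base$ace, tolerance = 1e-12)
})

test_that("aceticlastic energies in the methanic zone sit near equilibrium", {
  en <- suppressWarnings(
    sweep_energies(prof_all, meta, reactions = "mg_aceticlastic",
                   zones = zones_all))
  mz <- dplyr::filter(en, zone == "MZ")
  expect_gt(nrow(mz), 10)
  # weakly exergonic band: close to equilibrium, never strongly exergonic
  expect_true(all(mz$dGr > -15))
  expect_lt(mean(mz$dGr), 0)
})

test_that("closed-form H2 window endpoints are exact roots", {
  w <- h2_feasibility_window(prof_all, meta, zones = zones_all)
  mz <- dplyr::filter(w, zone == "MZ", exists)
  expect_gt(nrow(mz), 10)
  for (i in sample(seq_len(nrow(mz)), 5)) {
    row <- mz[i, ]
    prow <- dplyr::filter(prof_all, site == row$site,
                          depth_cm == row$depth_cm)
    cond <- sedmeth:::.row_conditions(prow, meta)
    conc <- cond$conc
    conc[["H2"]] <- row$h2_min_M
    g_mg <- gibbs_energy("mg_co2", conc, cond$T, cond$P, cond$pH)$dGr
    expect_lt(abs(g_mg), 1e-6)
    conc[["H2"]] <- row$h2_max_M
    g_aao <- gibbs_energy("aao", conc, cond$T, cond$P, cond$pH)$dGr
    expect_lt(abs(g_aao), 1e-6)
    # equal-energy point: both reactions at the same energy
    conc[["H2"]] <- row$h2_equal_M
    g1 <- gibbs_energy("mg_co2", conc, cond$T, cond$P, cond$pH)$dGr
    g2 <- gibbs_energy("aao", conc, cond$T, cond$P, cond$pH)$dGr
    expect_equal(g1, g2, tolerance = 1e-9)
    expect_equal(g1, row$dG_at_equal, tolerance = 1e-9)
    expect_true(row$h2_min_M < row$h2_equal_M &&
                  row$h2_equal_M < row$h2_max_M)
  }
})

test_that("methylotrophic pathway switch behaves as the H2 scenarios dictate", {
  sw <- methylotrophic_switch(prof_all, meta)
  sw <- dplyr::left_join(sw, zones_all, by = c("site", "depth_cm"))
  mz_hi <- dplyr::filter(sw, zone == "MZ", h2_nM == 10)
  expect_true(all(mz_hi$favored == "methyl_reduction"))
  expect_true(all(mz_hi$dG_methyl_red_per_mol < mz_hi$dG_disprop_per_mol))
  sz_lo <- dplyr::filter(sw, zone == "SZ", h2_nM == 0.1)
  expect_true(all(sz_lo$favored == "disproportionation"))
  # both pathways strongly exergonic per mol methanol at 1 uM methanol
  expect_true(all(dplyr::filter(sw, zone == "MZ")$dG_disprop_per_mol < -20))
})

test_that("the pathway crossover is unique, methanol-independent, and matches a grid search", {
  mz_depth <- zones_all$depth_cm[zones_all$site == "S2" &
                                   zones_all$zone == "MZ"][3]
  prow <- dplyr::filter(prof_all, site == "S2", depth_cm == mz_depth)
  sw1 <- methylotrophic_switch(prow, meta, methanol_M = 1e-6)
  sw2 <- methylotrophic_switch(prow, meta, methanol_M = 1e-8)
  expect_equal(sw1$crossover_h2_nM[1], sw2$crossover_h2_nM[1],
               tolerance = 1e-9)
  # grid search on the per-methanol energy difference
  cond <- sedmeth:::.row_conditions(prow, meta)
  h2_grid <- 10^seq(-11, -7, length.out = 2000)
  diffs <- vapply(c(1, 100), function(k) {
    # difference is linear in ln h2; evaluate at two points to find the root
    conc <- cond$conc
    conc[["H2"]] <- 1e-9 * k
    conc[["methanol"]] <- 1e-6
    gd <- gibbs_energy("mg_methanol_disprop", conc, cond$T, cond$P,
                       cond$pH)$per_substrate
    gm <- gibbs_energy("mg_methyl_reduction", conc, cond$T, cond$P,
                       cond$pH)$per_substrate
    gd - gm
  }, numeric(1))
  # exhaustive check by sign change over the grid
  conc <- cond$conc
  conc[["methanol"]] <- 1e-6
  diff_grid <- vapply(h2_grid, function(h2) {
    conc[["H2"]] <- h2
    gibbs_energy("mg_methanol_disprop", conc, cond$T, cond$P,
                 cond$pH)$per_substrate -
      gibbs_energy("mg_methyl_reduction", conc, cond$T, cond$P,
                   cond$pH)$per_substrate
  }, numeric(1))
  sign_changes <- sum(diff(sign(diff_grid)) != 0)
  expect_equal(sign_changes, 1)
  i <- which(diff(sign(diff_grid)) != 0)[1]
  expect_equal(sw1$crossover_h2_nM[1], 1e9 * h2_grid[i],
               tolerance = 1e-2)
  # monotone increasing difference in ln[H2]
  expect_true(all(diff(diff_grid) > 0))
  expect_lt(diffs[1], diffs[2])
})

test_that("depth rows with incomplete inputs are skipped with a warning", {
  prof <- gens$S2$profile[1:4, ]
  prof$acetate_uM[2] <- NA
  expect_warning(
    en <- sweep_energies(prof, meta, reactions = "mg_aceticlastic"),
    "Skipped"
  )
  expect_equal(nrow(en), 3)
})
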