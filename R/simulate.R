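#' Site presets for the synthetic four-station fixture suite
#'
#' Four synthetic stations (S1-S4) emulating a continental-margin gradient
#' from a deep, oligotrophic, sulfate-rich site to a shallow, eutrophic,
#' sulfidic site: sulfate penetration deeper than the core at S1 and at
#' 95, 75 and 20 cm at S2-S4; methane at micromolar background above the
#' transition rising to millimolar below; unimodal delta13C-DIC with its
#' minimum in the transition zone; and a true DIC-CH4 fractionation factor
#' of 1.080 in the methanic zones. Bottom-water temperature defaults to
#' 278.15 K and pressures follow the hydrostatic rule from water depth.
#'
#' @return A list of `site_spec` lists, one per station, each containing
#'   site metadata (`site`, `water_depth_m`, `bottom_T_K`,
#'   `reworking_depth_cm`, `ventilation_depth_cm`, `sed_rate_cm_yr`) and
#'   profile-shape parameters (`so4_seawater_mM`, `so4_penetration_cm`,
#'   `smtz_center_cm`, `smtz_width_cm`, `ch4_max_mM`, `ch4_background_mM`,
#'   `ch4_cap_mM`, DIC and delta13C anchors, acetate/formate baselines and
#'   peaks, `pH_mean`, `pH_sd`, `alpha_true`, noise levels, `depth_grid`).
#' @export
site_presets <- function() {
  base <- list(
    bottom_T_K = 278.15, ch4_background_mM = 0.005, ch4_cap_mM = 3,
    dic_surface_mM = 2.2, pH_mean = 7.6, pH_sd = 0.05,
    noise = list(SO4_mM = 0.3, CH4_rel = 0.05, DIC_mM = 0.3,
                 acetate_uM = 0.5, formate_uM = 0.3, delta = 1),
    d13C_TOC = -23, d13C_CH4_surface = -30, d13C_recover_cm = 5,
    alpha_true = 1.080
  )
  s1 <- utils::modifyList(base, list(
    site = "S1", water_depth_m = 586, reworking_depth_cm = 8,
    ventilation_depth_cm = 5, sed_rate_cm_yr = 0.14,
    so4_seawater_mM = 28, so4_penetration_cm = Inf,
    smtz_center_cm = NA_real_, smtz_width_cm = NA_real_, ch4_max_mM = 0,
    dic_deep_mM = 8, acetate_base_uM = 2, formate_base_uM = 1.5,
    acetate_peak = list(depth_cm = 265, uM = 6, width_cm = 25),
    formate_peak = list(depth_cm = 265, uM = 22, width_cm = 25),
    d13C_DIC_anchor = list(surface = 0, smtz_min = NA, deep = -18),
    d13C_CH4_deep = -41, alpha_true = NA_real_,
    depth_grid = c(seq(2.5, 47.5, by = 5), seq(55, 95, by = 10),
                   seq(112.5, 400, by = 12.5))
  ))
  s2 <- utils::modifyList(base, list(
    site = "S2", water_depth_m = 319, reworking_depth_cm = 40,
    ventilation_depth_cm = 13, sed_rate_cm_yr = 0.27,
    so4_seawater_mM = 28, so4_penetration_cm = 95,
    smtz_center_cm = 85, smtz_width_cm = 6, ch4_max_mM = 4,
    dic_deep_mM = 15, acetate_base_uM = 4, formate_base_uM = 2,
    acetate_peak = list(depth_cm = 101, uM = 14, width_cm = 15),
    formate_peak = NULL,
    d13C_DIC_anchor = list(surface = 0, smtz_min = -30, deep = 3),
    depth_grid = c(seq(2.5, 117.5, by = 5), seq(125, 400, by = 12.5))
  ))
  s3 <- utils::modifyList(base, list(
    site = "S3", water_depth_m = 43, reworking_depth_cm = 35,
    ventilation_depth_cm = 12, sed_rate_cm_yr = 0.30,
    so4_seawater_mM = 26, so4_penetration_cm = 75,
    smtz_center_cm = 65, smtz_width_cm = 5, ch4_max_mM = 3,
    dic_deep_mM = 12, acetate_base_uM = 4, formate_base_uM = 0.9,
    acetate_peak = NULL, formate_peak = NULL,
    d13C_DIC_anchor = list(surface = 0, smtz_min = -46, deep = 14),
    depth_grid = c(seq(2.5, 102.5, by = 5), seq(110, 350, by = 12.5))
  ))
  s4 <- utils::modifyList(base, list(
    site = "S4", water_depth_m = 37, reworking_depth_cm = 0,
    ventilation_depth_cm = 0, sed_rate_cm_yr = 0.33,
    so4_seawater_mM = 22, so4_penetration_cm = 20,
    smtz_center_cm = 15, smtz_width_cm = 2.5, ch4_max_mM = 5,
    dic_surface_mM = 2.5, dic_deep_mM = 30,
    acetate_base_uM = 6, formate_base_uM = 2,
    acetate_peak = NULL, formate_peak = NULL,
    d13C_DIC_anchor = list(surface = 0, smtz_min = -10, deep = 22),
    d13C_CH4_surface = -60, alpha_true = 1.085,
    depth_grid = seq(2, 100, by = 2)
  ))
  list(S1 = s1, S2 = s2, S3 = s3, S4 = s4)
}

#' Site metadata table for a list of presets
#'
#' @param specs List of site specs, as from [site_presets()].
#' @return Tibble with one row per site (`site`, `water_depth_m`,
#'   `bottom_T_K`, `reworking_depth_cm`, `ventilation_depth_cm`,
#'   `sed_rate_cm_yr`).
#' @export
site_meta_table <- function(specs = site_presets()) {
  purrr::map_dfr(specs, function(sp) {
    tibble(site = sp$site, water_depth_m = sp$water_depth_m,
           bottom_T_K = sp$bottom_T_K,
           reworking_depth_cm = sp$reworking_depth_cm,
           ventilation_depth_cm = sp$ventilation_depth_cm,
           sed_rate_cm_yr = sp$sed_rate_cm_yr)
  })
}

# deterministic (noise-free) profile skeleton for one site
.profile_skeleton <- function(sp) {
  z <- sp$depth_grid
  # sulfate: constant within the irrigated interval, then linear to zero at
  # the penetration depth
  vent <- sp$ventilation_depth_cm
  so4 <- rep(sp$so4_seawater_mM, length(z))
  if (is.finite(sp$so4_penetration_cm)) {
    pen <- sp$so4_penetration_cm
    decl <- z > vent
    so4[decl] <- sp$so4_seawater_mM *
      pmax(0, (pen - z[decl]) / (pen - vent))
  }
  # methane: background plus logistic onset centred in the transition
  ch4 <- rep(sp$ch4_background_mM, length(z))
  if (sp$ch4_max_mM > 0) {
    ch4 <- ch4 + sp$ch4_max_mM /
      (1 + exp(-(z - sp$smtz_center_cm) / sp$smtz_width_cm))
  }
  # DIC: saturating increase between surface and deep anchors
  zscale <- max(z) / 3
  dic <- sp$dic_surface_mM +
    (sp$dic_deep_mM - sp$dic_surface_mM) * (1 - exp(-z / zscale))
  gauss_peak <- function(base, peak, z) {
    v <- rep(base, length(z))
    if (!is.null(peak)) {
      v <- v + peak$uM * exp(-0.5 * ((z - peak$depth_cm) / peak$width_cm)^2)
    }
    v
  }
  tibble(
    site = sp$site, depth_cm = z,
    SO4_mM = so4, CH4_mM = ch4, DIC_mM = dic,
    acetate_uM = gauss_peak(sp$acetate_base_uM, sp$acetate_peak, z),
    formate_uM = gauss_peak(sp$formate_base_uM, sp$formate_peak, z),
    pH = rep(sp$pH_mean, length(z))
  )
}

# threshold-based zone truth evaluated on the noise-free skeleton
.skeleton_truth <- function(sp, skel, so4_thr = 0.5, ch4_thr = 0.1) {
  z <- skel$depth_cm
  cross <- .so4_crossing(z, skel$SO4_mM, so4_thr)
  so4_deep <- cross$depth
  censored <- cross$censored
  ch4_idx <- which(skel$CH4_mM >= ch4_thr)
  ch4_onset <- if (length(ch4_idx) > 0) min(z[ch4_idx]) else NA_real_
  smtz_top <- if (is.finite(ch4_onset) && so4_deep >= ch4_onset)
    ch4_onset else NA_real_
  smtz_bottom <- if (is.finite(smtz_top)) so4_deep else NA_real_
  zone <- rep("SZ", length(z))
  if (is.finite(ch4_onset)) {
    mz_from <- if (is.finite(smtz_bottom)) smtz_bottom else ch4_onset
    zone[z > mz_from] <- "MZ"
    if (is.finite(smtz_top)) zone[z >= smtz_top & z <= smtz_bottom] <- "SMTZ"
  }
  zone[z <= sp$reworking_depth_cm] <- "BZ"
  list(
    zone = zone, smtz_top = smtz_top, smtz_bottom = smtz_bottom,
    sulfate_penetration_cm = if (censored) NA_real_ else so4_deep,
    penetration_censored = censored, alpha_true = sp$alpha_true
  )
}

#' Generate one synthetic porewater depth profile with ground truth
#'
#' Builds the deterministic profile skeleton for a site spec (linear sulfate
#' decline, logistic methane onset, saturating DIC, baseline-plus-peak
#' volatile fatty acids, constant pH), derives the true zone boundaries from
#' the skeleton with the default zonation thresholds, then adds seeded
#' Gaussian noise per analyte (clipped at zero; methane noise is relative).
#' Measured methane is additionally capped at the spec's degassing ceiling
#' to mimic outgassing during core retrieval; the cap is recorded in the
#' truth, the truth boundaries are unaffected.
#'
#' @param spec One site spec from [site_presets()].
#' @param noise_scale Multiplier on all noise standard deviations (0 gives
#'   the exact skeleton).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param so4_thr,ch4_thr Zonation thresholds used to define the stored
#'   ground-truth boundaries, mM.
#' @return List with `profile` (tibble in the documented profile dialect,
#'   delta columns included) and `truth` (list: per-depth `zone`,
#'   `smtz_top`, `smtz_bottom`, `sulfate_penetration_cm`,
#'   `penetration_censored`, `alpha_true`, `ch4_cap_mM`).
#' @export
generate_site_profile <- function(spec, noise_scale = 1, seed = 1,
                                  so4_thr = 0.5, ch4_thr = 0.1) {
  if (is.finite(spec$so4_penetration_cm) &&
      max(diff(spec$depth_grid)[spec$depth_grid <= spec$so4_penetration_cm],
          0) > 4 * spec$smtz_width_cm) {
    abort("Depth grid too coarse to resolve the transition width.")
  }
  skel <- .profile_skeleton(spec)
  truth <- .skeleton_truth(spec, skel, so4_thr, ch4_thr)
  truth$ch4_cap_mM <- spec$ch4_cap_mM
  skel <- .add_isotope_skeleton(skel, spec, truth)
  prof <- skel
  if (noise_scale > 0) {
    set.seed(seed)
    ns <- spec$noise
    n <- nrow(prof)
    prof$SO4_mM <- pmax(0, prof$SO4_mM +
                          rnorm(n, 0, ns$SO4_mM * noise_scale))
    prof$CH4_mM <- pmax(0, prof$CH4_mM *
                          (1 + rnorm(n, 0, ns$CH4_rel * noise_scale)))
    prof$DIC_mM <- pmax(0.1, prof$DIC_mM +
                          rnorm(n, 0, ns$DIC_mM * noise_scale))
    prof$acetate_uM <- pmax(0.05, prof$acetate_uM +
                              rnorm(n, 0, ns$acetate_uM * noise_scale))
    prof$formate_uM <- pmax(0.05, prof$formate_uM +
                              rnorm(n, 0, ns$formate_uM * noise_scale))
    prof$pH <- prof$pH + rnorm(n, 0, spec$pH_sd * noise_scale)
    prof$d13C_DIC <- prof$d13C_DIC + rnorm(n, 0, ns$delta * noise_scale)
    prof$d13C_CH4 <- prof$d13C_CH4 + rnorm(n, 0, ns$delta * noise_scale)
    prof$d13C_TOC <- prof$d13C_TOC + rnorm(n, 0, 0.3 * noise_scale)
  }
  # degassing ceiling applies to the measured methane column only
  prof$CH4_mM <- pmin(prof$CH4_mM, spec$ch4_cap_mM)
  list(profile = prof, truth = truth)
}

# deterministic delta13C columns: DIC piecewise-linear through its anchors
# (surface ~0, minimum at the transition centre, steep recovery at the top
# of the methanic zone, positive deep values); CH4 tied to DIC through
# alpha_true inside the MZ and trending heavier toward the seafloor above it
.add_isotope_skeleton <- function(skel, sp, truth) {
  z <- skel$depth_cm
  zmax <- max(z)
  an <- sp$d13C_DIC_anchor
  if (is.finite(truth$smtz_top) && is.finite(an$smtz_min)) {
    # the DIC minimum sits at the transition centre and recovers steeply:
    # by a few cm below the transition bottom delta13C-DIC is back near
    # -2 permil, then rises slowly to the positive deep anchor
    recover_end <- min(truth$smtz_bottom + sp$d13C_recover_cm, zmax - 1)
    xs <- c(0, sp$smtz_center_cm, recover_end, zmax)
    ys <- c(an$surface, an$smtz_min, -2, an$deep)
  } else {
    xs <- c(0, zmax)
    ys <- c(an$surface, an$deep)
  }
  d13c_dic <- stats::approx(xs, ys, xout = z, rule = 2)$y
  if (is.finite(sp$alpha_true) && any(truth$zone == "MZ")) {
    in_mz <- truth$zone == "MZ"
    ch4_mz <- (d13c_dic + 1000) / sp$alpha_true - 1000
    mz_top_i <- min(which(in_mz))
    d13c_ch4 <- numeric(length(z))
    d13c_ch4[in_mz] <- ch4_mz[in_mz]
    above <- seq_len(mz_top_i - 1)
    if (length(above) > 0) {
      d13c_ch4[above] <- stats::approx(
        c(0, z[mz_top_i]), c(sp$d13C_CH4_surface, ch4_mz[mz_top_i]),
        xout = z[above], rule = 2)$y
    }
  } else {
    d13c_ch4 <- stats::approx(c(0, zmax),
                              c(sp$d13C_CH4_surface, sp$d13C_CH4_deep),
                              xout = z, rule = 2)$y
  }
  skel$d13C_TOC <- rep(sp$d13C_TOC, length(z))
  skel$d13C_DIC <- d13c_dic
  skel$d13C_CH4 <- d13c_ch4
  skel
}

#' Generate a synthetic community and qPCR table with trend-category truth
#'
#' Emulates the three-stage succession of methane-cycling archaea: taxa are
#' assigned to the four depth-trend categories (BZ&SZ, SMTZ, MZ, ubiquitous
#' rare); zone-dependent composition templates give each trend taxon a
#' `10^effect_log10`-fold higher weight in its peak zone group; read counts
#' are drawn from a Dirichlet-multinomial at fixed library size; total mcrA
#' copies per sample are log-normal around zone-group means whose log10
#' separations scale with `effect_log10` (at the default effect of 3 the
#' means are 10^4.5, 10^5.5 and 10^6 copies g^-1 in BZ&SZ, SMTZ and MZ,
#' mirroring the observed 2-4 order-of-magnitude increases); 16S totals are
#' log-normal around 10^8.5. All draws are seeded.
#'
#' @param zones Tibble `site`, `depth_cm`, `zone` giving the zone label of
#'   each candidate sample depth (typically the generator truth).
#' @param n_taxa Number of taxa (>= 4).
#' @param effect_log10 Log10 abundance effect size of the succession
#'   (default 3).
#' @param seed Integer seed.
#' @param library_size Reads per sample (default 1e4).
#' @param n_samples Maximum number of sample depths drawn per site
#'   (evenly spaced; default 20).
#' @param dirichlet_conc Dirichlet concentration scaling (larger =
#'   less compositional overdispersion; default 200).
#' @return List with `community` (long tibble `sample`, `taxon`, `reads`),
#'   `qpcr` (`sample`, `site`, `depth_cm`, `zone`, `mcrA_copies_g`,
#'   `x16S_copies_g`), and `truth` (`taxon`, `category`).
#' @export
generate_community <- function(zones, n_taxa = 40, effect_log10 = 3,
                               seed = 1, library_size = 1e4,
                               n_samples = 20, dirichlet_conc = 200) {
  stopifnot(n_taxa >= 4, effect_log10 >= 0)
  set.seed(seed)
  cats <- c("BZ&SZ taxa", "SMTZ taxa", "MZ taxa", "ubiquitous rare taxa")
  n_trend <- max(1, round(0.15 * n_taxa))
  n_cat <- c(n_trend, n_trend, n_trend, n_taxa - 3 * n_trend)
  if (n_cat[4] < 1) abort("n_taxa too small for the category split.")
  category <- rep(cats, times = n_cat)
  taxa <- sprintf("zotu_%03d", seq_len(n_taxa))
  truth <- tibble(taxon = taxa, category = category)
  groups <- c(BZ = "BZSZ", SZ = "BZSZ", SMTZ = "SMTZ", MZ = "MZ")
  peak_of <- c("BZ&SZ taxa" = "BZSZ", "SMTZ taxa" = "SMTZ", "MZ taxa" = "MZ",
               "ubiquitous rare taxa" = "none")
  # evenly thin each site's depths to at most n_samples community samples
  samp <- zones %>%
    group_by(.data$site) %>%
    slice(unique(round(seq(1, n(), length.out = min(n(), n_samples))))) %>%
    ungroup() %>%
    mutate(sample = paste0(.data$site, "_", .data$depth_cm),
           group = unname(groups[.data$zone]))
  # zone-group mean log10 mcrA totals, separations scaling with effect size
  mu_log10 <- c(BZSZ = 4.5, SMTZ = 4.5 + effect_log10 / 3,
                MZ = 4.5 + effect_log10 / 2)
  comm_rows <- vector("list", nrow(samp))
  mcra <- numeric(nrow(samp))
  for (i in seq_len(nrow(samp))) {
    g <- samp$group[i]
    w <- ifelse(category == "ubiquitous rare taxa", 0.02,
                ifelse(peak_of[category] == g, 10^effect_log10, 1))
    frac <- w / sum(w)
    alpha <- frac * dirichlet_conc
    gam <- rgamma(n_taxa, shape = alpha, rate = 1)
    if (sum(gam) == 0) gam <- frac
    reads <- as.integer(rmultinom(1, size = library_size,
                                  prob = gam / sum(gam)))
    comm_rows[[i]] <- tibble(sample = samp$sample[i], taxon = taxa,
                             reads = reads)
    mcra[i] <- 10^rnorm(1, mean = mu_log10[[g]], sd = 0.3)
  }
  qpcr <- tibble(
    sample = samp$sample, site = samp$site, depth_cm = samp$depth_cm,
    zone = samp$zone, mcrA_copies_g = mcra,
    x16S_copies_g = 10^rnorm(nrow(samp), mean = 8.5, sd = 0.2)
  )
  list(community = bind_rows(comm_rows), qpcr = qpcr, truth = truth)
}

#' Write the complete four-station fixture bundle to disk
#'
#' Generates all four preset profiles (with isotope columns), the
#' community and qPCR tables for the multi-zone stations, the thermodynamic
#' constants table, site metadata, and a ground-truth JSON, writing
#' everything as plain TSV/JSON under `dir`. Output is byte-stable under a
#' fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; per-site seeds are derived from it.
#' @param n_taxa,effect_log10 Passed to [generate_community()].
#' @param noise_scale Passed to [generate_site_profile()].
#' @return Invisibly, a named list of the file paths written.
#' @export
make_fixture_suite <- function(dir, seed = 1, n_taxa = 40, effect_log10 = 3,
                               noise_scale = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- site_presets()
  profiles <- list()
  truth_all <- list()
  zone_truth <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    g <- generate_site_profile(sp, noise_scale = noise_scale,
                               seed = seed * 100 + k)
    profiles[[sp$site]] <- g$profile
    truth_all[[sp$site]] <- g$truth[c("smtz_top", "smtz_bottom",
                                      "sulfate_penetration_cm",
                                      "penetration_censored", "alpha_true",
                                      "ch4_cap_mM")]
    zone_truth[[sp$site]] <- tibble(site = sp$site,
                                    depth_cm = g$profile$depth_cm,
                                    zone = g$truth$zone)
  }
  profile_tbl <- bind_rows(profiles)
  zone_tbl <- bind_rows(zone_truth)
  # community tables for the stations that develop an SMTZ and MZ
  multi <- zone_tbl %>% filter(.data$site != "S1")
  cm <- generate_community(multi, n_taxa = n_taxa,
                           effect_log10 = effect_log10,
                           seed = seed * 100 + 99)
  paths <- list(
    profile = file.path(dir, "porewater_profiles.tsv"),
    zones_truth = file.path(dir, "zone_truth.tsv"),
    community = file.path(dir, "community_reads.tsv"),
    qpcr = file.path(dir, "qpcr.tsv"),
    site_meta = file.path(dir, "site_meta.tsv"),
    constants = file.path(dir, "thermo_constants.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  readr::write_tsv(profile_tbl, paths$profile)
  readr::write_tsv(zone_tbl, paths$zones_truth)
  readr::write_tsv(cm$community, paths$community)
  readr::write_tsv(cm$qpcr, paths$qpcr)
  readr::write_tsv(site_meta_table(specs), paths$site_meta)
  readr::write_tsv(thermo_constants(), paths$constants)
  jsonlite::write_json(
    list(seed = seed, sites = truth_all, taxa = cm$truth),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}
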