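#' Read a thermodynamic constants table
#'
#' @param path TSV with columns `species`, `charge`, `dGf0_kJ_mol`,
#'   `dHf0_kJ_mol`, `V0_cm3_mol`, `gamma`, `phase_rule`.
#' @return Validated tibble.
#' @export
read_thermo_constants <- function(path) {
  tb <- .read_tsv_checked(path, c("species", "charge", "dGf0_kJ_mol",
                                  "dHf0_kJ_mol", "V0_cm3_mol", "gamma",
                                  "phase_rule"))
  if (anyDuplicated(tb$species)) {
    abort(paste0(path, ": duplicated species names."))
  }
  if (any(!is.finite(tb$gamma) | tb$gamma <= 0)) {
    abort(paste0(path, ": activity coefficients must be positive."))
  }
  ok_rules <- c("aqueous", "water", "proton", "fixed_activity")
  if (any(!tb$phase_rule %in% ok_rules)) {
    abort(paste0(path, ": unknown phase_rule values: ",
                 paste(setdiff(tb$phase_rule, ok_rules), collapse = ", ")))
  }
  tb
}

#' Read a porewater profile table
#'
#' The profile dialect: one row per site x depth with columns `site`,
#' `depth_cm`, optional `T_K` and `P_bar`, `pH`, `DIC_mM`, `CH4_mM`,
#' `SO4_mM`, `acetate_uM`, `formate_uM`, `d13C_TOC`, `d13C_DIC`,
#' `d13C_CH4` (delta values in permil VPDB; empty cells are allowed and
#' read as missing). Depths must be positive-down, sorted and unique
#' within each site; concentrations must be non-negative.
#'
#' @param path TSV file path.
#' @return Validated profile tibble.
#' @export
read_profile <- function(path) {
  tb <- .read_tsv_checked(path, c("site", "depth_cm", "pH", "DIC_mM",
                                  "CH4_mM", "SO4_mM", "acetate_uM"))
  for (s in unique(tb$site)) {
    z <- tb$depth_cm[tb$site == s]
    if (anyDuplicated(z)) {
      abort(paste0(path, ": duplicated depth rows for site ", s, "."))
    }
    if (is.unsorted(z)) {
      abort(paste0(path, ": depths not sorted for site ", s, "."))
    }
  }
  conc_cols <- intersect(c("DIC_mM", "CH4_mM", "SO4_mM", "acetate_uM",
                           "formate_uM"), names(tb))
  for (cl in conc_cols) {
    bad <- is.finite(tb[[cl]]) & tb[[cl]] < 0
    if (any(bad)) {
      abort(paste0(path, ": negative values in column ", cl, " (row ",
                   which(bad)[1], ")."))
    }
  }
  tb
}

#' Read a qPCR table
#'
#' @param path TSV with columns `sample`, `mcrA_copies_g`, `x16S_copies_g`
#'   (below-detection values recorded as empty cells, read as missing,
#'   never as zero) plus optional `site`, `depth_cm`, `zone`.
#' @return Validated tibble.
#' @export
read_qpcr <- function(path) {
  tb <- .read_tsv_checked(path, c("sample", "mcrA_copies_g",
                                  "x16S_copies_g"))
  for (cl in c("mcrA_copies_g", "x16S_copies_g")) {
    bad <- is.finite(tb[[cl]]) & tb[[cl]] < 0
    if (any(bad)) abort(paste0(path, ": negative copy numbers in ", cl, "."))
  }
  tb
}

#' Read a community read-count table
#'
#' Accepts the long dialect (`sample`, `taxon`, `reads`) or a wide layout
#' with samples in the first column and taxa in the remaining columns
#' (set `orientation = "taxa_by_samples"` for the transposed wide layout).
#'
#' @param path TSV file path.
#' @param orientation `"samples_by_taxa"` (default) or
#'   `"taxa_by_samples"` for wide files.
#' @return Long tibble `sample`, `taxon`, `reads` with non-negative
#'   integer counts.
#' @export
read_community <- function(path, orientation = c("samples_by_taxa",
                                                 "taxa_by_samples")) {
  orientation <- match.arg(orientation)
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("sample", "taxon", "reads") %in% names(tb))) {
    comm <- tb[, c("sample", "taxon", "reads")]
  } else {
    if (orientation == "taxa_by_samples") {
      first <- names(tb)[1]
      comm <- tidyr::pivot_longer(tb, -1, names_to = "sample",
                                  values_to = "reads")
      names(comm)[names(comm) == first] <- "taxon"
      comm <- comm[, c("sample", "taxon", "reads")]
    } else {
      names(tb)[1] <- "sample"
      comm <- tidyr::pivot_longer(tb, -"sample", names_to = "taxon",
                                  values_to = "reads")
    }
  }
  if (any(!is.finite(comm$reads)) || any(comm$reads < 0) ||
      any(comm$reads != round(comm$reads))) {
    abort(paste0(path, ": read counts must be non-negative integers."))
  }
  as_tibble(comm)
}

#' Read a site metadata table
#'
#' @param path TSV with columns `site`, `water_depth_m`, `bottom_T_K`,
#'   `reworking_depth_cm`, `ventilation_depth_cm`, `sed_rate_cm_yr`.
#' @return Validated tibble.
#' @export
read_site_meta <- function(path) {
  .read_tsv_checked(path, c("site", "water_depth_m", "bottom_T_K",
                            "reworking_depth_cm"))
}

.read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tb))
  if (length(missing) > 0) {
    abort(paste0(path, ": missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(tb)
  if (nrow(probs) > 0) {
    abort(paste0(path, ": parse problem at row ", probs$row[1], ", column ",
                 probs$col[1], " (", probs$expected[1], ")."))
  }
  tb
}

#' Run the full analysis pipeline on a fixture or data bundle
#'
#' Chains simulation (optional), zonation, energy sweeps, H2 windows,
#' methylotrophic comparison, isotope summaries, and community succession
#' into one reproducible run, writing every result as TSV plus a JSON run
#' manifest (seed, configuration, package version). With the same seed and
#' inputs the outputs are byte-identical across invocations. When the qPCR
#' or community table is absent the community stage is skipped with an
#' explicit notice while the geochemical stages still run.
#'
#' @param outdir Output directory.
#' @param indir Optional directory holding an existing input bundle (as
#'   written by [make_fixture_suite()]); when NULL a fixture bundle is
#'   simulated under `outdir/inputs` first.
#' @param seed Integer seed controlling simulation.
#' @param so4_thr,ch4_thr Zonation thresholds, mM.
#' @param rare_thr,p_thr Trend-classification thresholds.
#' @param beq Biological energy quantum, kJ mol^-1.
#' @param scenarios Scenario spec for the energy sweeps.
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(outdir, indir = NULL, seed = 1,
                         so4_thr = 0.5, ch4_thr = 0.1,
                         rare_thr = 1e3, p_thr = 0.05, beq = -10,
                         scenarios = scenario_spec()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(indir)) {
    indir <- file.path(outdir, "inputs")
    make_fixture_suite(indir, seed = seed)
  }
  constants <- physical_constants(beq = beq)
  species <- read_thermo_constants(file.path(indir, "thermo_constants.tsv"))
  profile <- read_profile(file.path(indir, "porewater_profiles.tsv"))
  site_meta <- read_site_meta(file.path(indir, "site_meta.tsv"))

  za <- assign_zones(profile, site_meta, so4_thr = so4_thr,
                     ch4_thr = ch4_thr)
  zones <- tidy(za)
  energies <- suppressWarnings(
    sweep_energies(profile, site_meta, scenarios = scenarios,
                   zones = zones, species = species, constants = constants))
  windows <- h2_feasibility_window(profile, site_meta, zones = zones,
                                   species = species, constants = constants)
  switch_tbl <- methylotrophic_switch(profile, site_meta,
                                      scenarios = scenarios,
                                      species = species,
                                      constants = constants)
  alpha <- estimate_alpha_profile(profile, zones)

  paths <- list(
    zones = file.path(outdir, "zones.tsv"),
    boundaries = file.path(outdir, "zone_boundaries.tsv"),
    energies = file.path(outdir, "energies.tsv"),
    windows = file.path(outdir, "h2_windows.tsv"),
    methyl_switch = file.path(outdir, "methylotrophic_switch.tsv"),
    alpha = file.path(outdir, "alpha_by_zone.tsv")
  )
  readr::write_tsv(zones, paths$zones)
  readr::write_tsv(glance(za), paths$boundaries)
  readr::write_tsv(energies, paths$energies)
  readr::write_tsv(windows, paths$windows)
  readr::write_tsv(switch_tbl, paths$methyl_switch)
  readr::write_tsv(tidy(alpha), paths$alpha)

  qpcr_path <- file.path(indir, "qpcr.tsv")
  comm_path <- file.path(indir, "community_reads.tsv")
  if (file.exists(qpcr_path) && file.exists(comm_path)) {
    qpcr <- read_qpcr(qpcr_path)
    community <- read_community(comm_path)
    abund <- taxon_absolute_abundance(community, qpcr)
    sample_zones <- qpcr[, c("sample", "zone")]
    trends <- suppressWarnings(
      zone_trend_classification(abund, sample_zones,
                                rare_thr = rare_thr, p_thr = p_thr))
    ratios <- mcra_to_16s_ratio(qpcr)
    div <- richness_evenness(community)
    env <- dplyr::inner_join(
      qpcr[, c("sample", "site", "depth_cm")],
      profile[, c("site", "depth_cm", "CH4_mM", "SO4_mM", "DIC_mM")],
      by = c("site", "depth_cm"))
    corr <- env_correlations(abund, env[, c("sample", "CH4_mM", "SO4_mM",
                                            "DIC_mM")])
    paths$abundance <- file.path(outdir, "taxon_abundance.tsv")
    paths$trends <- file.path(outdir, "taxon_trends.tsv")
    paths$ratios <- file.path(outdir, "mcra_16s_ratios.tsv")
    paths$diversity <- file.path(outdir, "diversity.tsv")
    paths$correlations <- file.path(outdir, "env_correlations.tsv")
    readr::write_tsv(abund, paths$abundance)
    readr::write_tsv(tidy(trends), paths$trends)
    readr::write_tsv(ratios, paths$ratios)
    readr::write_tsv(div, paths$diversity)
    readr::write_tsv(corr, paths$correlations)
  } else {
    inform("qPCR or community table absent: community stage skipped.")
  }

  manifest <- list(
    package = "sedmeth",
    version = as.character(utils::packageVersion("sedmeth")),
    seed = seed,
    thresholds = list(so4_thr = so4_thr, ch4_thr = ch4_thr,
                      rare_thr = rare_thr, p_thr = p_thr, beq = beq),
    scenarios = scenarios,
    outputs = lapply(paths, basename)
  )
  manifest_path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$manifest <- manifest_path
  invisible(paths)
}
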