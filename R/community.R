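#' Taxon-specific absolute abundances from qPCR totals and read fractions
#'
#' Converts relative marker-gene read compositions into absolute gene copy
#' concentrations by scaling each sample's read fractions with its total
#' mcrA qPCR copy number:
#' \eqn{A_{st} = mcrA_s \times reads_{st} / \sum_t reads_{st}}.
#' Per-sample abundances therefore sum exactly to the qPCR total
#' (conservation). Samples with below-detection (missing) qPCR totals
#' propagate NA abundances rather than zeros.
#'
#' @param community Long tibble of read counts with columns `sample`,
#'   `taxon`, `reads` (or a wide data frame, first column `sample`,
#'   remaining columns taxa, which is pivoted automatically).
#' @param qpcr Tibble with columns `sample` and `mcrA_copies_g` (copies per
#'   gram sediment; also carries `x16S_copies_g` when available).
#' @return Long tibble `sample`, `taxon`, `reads`, `fraction`,
#'   `abundance_copies_g`.
#' @export
taxon_absolute_abundance <- function(community, qpcr) {
  comm <- .as_long_community(community)
  stopifnot(all(c("sample", "mcrA_copies_g") %in% names(qpcr)))
  orphans_c <- setdiff(unique(comm$sample), qpcr$sample)
  orphans_q <- setdiff(qpcr$sample, unique(comm$sample))
  if (length(orphans_c) > 0) {
    abort(paste0("Samples in community table without qPCR totals: ",
                 paste(orphans_c, collapse = ", ")))
  }
  if (length(orphans_q) > 0) {
    warn(paste0("qPCR samples absent from community table (ignored): ",
                paste(orphans_q, collapse = ", ")))
  }
  totals <- comm %>% group_by(.data$sample) %>%
    summarise(total_reads = sum(.data$reads), .groups = "drop")
  if (any(totals$total_reads <= 0)) {
    abort(paste0("Zero total reads for sample(s): ",
                 paste(totals$sample[totals$total_reads <= 0], collapse = ", ")))
  }
  comm %>%
    left_join(totals, by = "sample") %>%
    left_join(qpcr[, c("sample", "mcrA_copies_g")], by = "sample") %>%
    mutate(fraction = .data$reads / .data$total_reads,
           abundance_copies_g = .data$mcrA_copies_g * .data$fraction) %>%
    select("sample", "taxon", "reads", "fraction", "abundance_copies_g")
}

.as_long_community <- function(community) {
  stopifnot(is.data.frame(community))
  if (all(c("sample", "taxon", "reads") %in% names(community))) {
    comm <- as_tibble(community[, c("sample", "taxon", "reads")])
  } else {
    stopifnot(names(community)[1] == "sample")
    comm <- tidyr::pivot_longer(community, -"sample", names_to = "taxon",
                                values_to = "reads")
  }
  if (any(!is.finite(comm$reads)) || any(comm$reads < 0)) {
    abort("Read counts must be finite and non-negative.")
  }
  comm
}

#' Ratio of mcrA to total 16S rRNA gene copies
#'
#' The fraction of the total microbial community (bacterial plus archaeal
#' 16S copies) accounted for by methane-cycling archaea, reported both as a
#' fraction and as a percentage. Zero 16S totals give a missing ratio with a
#' warning.
#'
#' @param qpcr Tibble with `sample`, `mcrA_copies_g`, `x16S_copies_g`.
#' @return `qpcr` with `ratio` and `ratio_percent` columns appended.
#' @examples
#' mcra_to_16s_ratio(tibble::tibble(sample = "a", mcrA_copies_g = 1e4,
#'                                  x16S_copies_g = 1e9))
#' @export
mcra_to_16s_ratio <- function(qpcr) {
  stopifnot(all(c("sample", "mcrA_copies_g", "x16S_copies_g") %in% names(qpcr)))
  bad <- is.finite(qpcr$x16S_copies_g) & qpcr$x16S_copies_g <= 0
  if (any(bad)) {
    warn(paste0("Zero 16S totals; ratio set to missing for sample(s): ",
                paste(qpcr$sample[bad], collapse = ", ")))
  }
  qpcr %>%
    mutate(ratio = ifelse(.data$x16S_copies_g > 0,
                          .data$mcrA_copies_g / .data$x16S_copies_g, NA_real_),
           ratio_percent = 100 * .data$ratio)
}

#' Richness, Shannon diversity, and Pielou's evenness per sample
#'
#' Richness S is the number of taxa observed (count > 0); Shannon diversity
#' H' = -sum p ln p (nats) over present taxa; Pielou's evenness J = H'/ln S,
#' defined only when S > 1 and bounded in [0, 1].
#'
#' @param community Long or wide community table (see
#'   [taxon_absolute_abundance()]).
#' @return Tibble `sample`, `richness`, `shannon`, `evenness`.
#' @export
richness_evenness <- function(community) {
  comm <- .as_long_community(community)
  comm %>%
    group_by(.data$sample) %>%
    summarise(
      richness = sum(.data$reads > 0),
      shannon = {
        tot <- sum(.data$reads)
        if (tot <= 0) abort(paste0("All-zero sample: ", .data$sample[1]))
        p <- .data$reads[.data$reads > 0] / tot
        -sum(p * log(p))
      },
      .groups = "drop"
    ) %>%
    mutate(evenness = ifelse(.data$richness > 1,
                             .data$shannon / log(.data$richness), NA_real_))
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' \eqn{BC = \sum_i |a_i - b_i| / \sum_i (a_i + b_i)}, bounded in [0, 1],
#' 0 for identical vectors and 1 for disjoint ones.
#'
#' @param a,b Non-negative numeric vectors over the same taxon set.
#' @return Dissimilarity in [0, 1].
#' @examples
#' bray_curtis(c(1, 2), c(2, 1)) # 1/3
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  tot <- sum(a + b)
  if (tot == 0) abort("Bray-Curtis undefined: both samples are all-zero.")
  sum(abs(a - b)) / tot
}

#' Pairwise Bray-Curtis distance matrix for a community table
#'
#' @param community Long or wide community table.
#' @return A `dist` object over samples.
#' @export
bray_curtis_matrix <- function(community) {
  comm <- .as_long_community(community)
  wide <- tidyr::pivot_wider(comm, names_from = "taxon",
                             values_from = "reads", values_fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(wide$sample, wide$sample))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  stats::as.dist(d)
}

#' Two-sided Wilcoxon rank-sum test (normal approximation, tie-corrected)
#'
#' Rank-sum (Mann-Whitney) test used for zone-wise abundance comparisons.
#' Uses the large-sample normal approximation with the standard tie
#' correction of the rank variance and no continuity correction.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (Mann-Whitney U for `x`), `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) return(list(statistic = NA_real_, p_value = NA_real_))
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = W, p_value = 1))
  z <- (W - n1 * n2 / 2) / sqrt(sigma2)
  list(statistic = W, p_value = 2 * pnorm(-abs(z)))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Spearman's rho computed as the Pearson correlation of average ranks
#' (midranks for ties), with a two-sided p-value from the large-sample t
#' approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 5) return(list(rho = NA_real_, p_value = NA_real_, n = n))
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0, n = n))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(t), df = n - 2), n = n)
}

#' Classify taxa into depth-trend categories across geochemical zones
#'
#' Mirrors the absolute-abundance trend analysis of methane-cycling archaea:
#' for each taxon, mean abundances are computed in three zone groups -
#' merged BZ&SZ (bioturbated plus sulfatic), SMTZ, and MZ - and the taxon is
#' assigned to the group with the highest mean provided that (a) this
#' maximum reaches `rare_thr` copies per gram and (b) a two-sided Wilcoxon
#' rank-sum test against at least one other zone group is significant at
#' `p_thr`. Taxa failing either condition are "ubiquitous rare taxa".
#' Below-detection (missing) abundances are excluded from means, not imputed
#' as zero. Zone groups with fewer than two samples are skipped in testing
#' and flagged.
#'
#' @param abundance Long abundance tibble from [taxon_absolute_abundance()].
#' @param sample_zones Tibble `sample`, `zone` with zone labels
#'   (BZ/SZ/SMTZ/MZ) per sample.
#' @param rare_thr Minimum peak-group mean abundance, copies g^-1
#'   (default 1e3).
#' @param p_thr Significance threshold for the rank-sum comparisons
#'   (default 0.05).
#' @return An object of class `trend_classification`: tibble with one row
#'   per taxon (`taxon`, `category`, `mean_BZSZ`, `mean_SMTZ`, `mean_MZ`,
#'   `p_vs_*` columns, `n_*` group sizes). `tidy()` returns the table,
#'   `glance()` counts per category.
#' @export
zone_trend_classification <- function(abundance, sample_zones,
                                      rare_thr = 1e3, p_thr = 0.05) {
  stopifnot(all(c("sample", "taxon", "abundance_copies_g") %in% names(abundance)),
            all(c("sample", "zone") %in% names(sample_zones)))
  groups <- c(BZ = "BZSZ", SZ = "BZSZ", SMTZ = "SMTZ", MZ = "MZ")
  sz <- sample_zones %>%
    mutate(group = unname(groups[.data$zone])) %>%
    filter(!is.na(.data$group))
  d <- abundance %>%
    dplyr::inner_join(sz[, c("sample", "group")], by = "sample") %>%
    filter(is.finite(.data$abundance_copies_g))
  grp_names <- c("BZSZ", "SMTZ", "MZ")
  n_by_group <- vapply(grp_names, function(g) {
    length(unique(d$sample[d$group == g]))
  }, integer(1))
  small <- grp_names[n_by_group < 2]
  if (length(small) > 0) {
    warn(paste0("Zone group(s) with < 2 samples skipped in testing: ",
                paste(small, collapse = ", ")))
  }
  res <- d %>%
    group_by(.data$taxon) %>%
    summarise(
      mean_BZSZ = .group_mean(.data$abundance_copies_g, .data$group, "BZSZ"),
      mean_SMTZ = .group_mean(.data$abundance_copies_g, .data$group, "SMTZ"),
      mean_MZ   = .group_mean(.data$abundance_copies_g, .data$group, "MZ"),
      p_BZSZ_SMTZ = .group_test(.data$abundance_copies_g, .data$group,
                                "BZSZ", "SMTZ", n_by_group),
      p_BZSZ_MZ   = .group_test(.data$abundance_copies_g, .data$group,
                                "BZSZ", "MZ", n_by_group),
      p_SMTZ_MZ   = .group_test(.data$abundance_copies_g, .data$group,
                                "SMTZ", "MZ", n_by_group),
      .groups = "drop"
    )
  cat_names <- c(BZSZ = "BZ&SZ taxa", SMTZ = "SMTZ taxa", MZ = "MZ taxa")
  res$category <- vapply(seq_len(nrow(res)), function(i) {
    means <- c(BZSZ = res$mean_BZSZ[i], SMTZ = res$mean_SMTZ[i],
               MZ = res$mean_MZ[i])
    if (all(is.na(means))) return("ubiquitous rare taxa")
    peak <- names(means)[which.max(means)]
    if (!is.finite(means[peak]) || means[peak] < rare_thr) {
      return("ubiquitous rare taxa")
    }
    ps <- switch(peak,
      BZSZ = c(res$p_BZSZ_SMTZ[i], res$p_BZSZ_MZ[i]),
      SMTZ = c(res$p_BZSZ_SMTZ[i], res$p_SMTZ_MZ[i]),
      MZ   = c(res$p_BZSZ_MZ[i], res$p_SMTZ_MZ[i])
    )
    if (any(is.finite(ps) & ps < p_thr)) cat_names[[peak]]
    else "ubiquitous rare taxa"
  }, character(1))
  res <- relocate(res, "category", .after = "taxon")
  attr(res, "n_by_group") <- n_by_group
  structure(res, class = c("trend_classification", class(res)))
}

.group_mean <- function(x, g, which) {
  v <- x[g == which]
  if (length(v) == 0) NA_real_ else mean(v)
}

.group_test <- function(x, g, g1, g2, n_by_group) {
  if (n_by_group[[g1]] < 2 || n_by_group[[g2]] < 2) return(NA_real_)
  rank_sum_test(x[g == g1], x[g == g2])$p_value
}

#' @export
tidy.trend_classification <- function(x, ...) as_tibble(unclass_keep(x))

#' @export
glance.trend_classification <- function(x, ...) {
  tab <- table(x$category)
  tibble(category = names(tab), n_taxa = as.integer(tab))
}

#' @export
print.trend_classification <- function(x, ...) {
  cat("Taxon depth-trend classification\n")
  print(as_tibble(unclass_keep(x)), ...)
  invisible(x)
}

#' Taxon-environment Spearman correlations
#'
#' Correlates each taxon's absolute abundance with each environmental
#' variable across samples, using tie-aware Spearman rank correlation and a
#' two-sided t-approximation p-value, and flags strong associations
#' (|rho| > `rho_flag` and p < `p_flag`, defaults matching the conventional
#' rho > 0.6, p < 0.001 reporting threshold).
#'
#' @param abundance Long abundance tibble from [taxon_absolute_abundance()].
#' @param env Tibble with a `sample` column and numeric environmental
#'   columns.
#' @param rho_flag,p_flag Flagging thresholds.
#' @return Tibble `taxon`, `variable`, `rho`, `p_value`, `n`, `flagged`.
#' @export
env_correlations <- function(abundance, env, rho_flag = 0.6, p_flag = 0.001) {
  stopifnot("sample" %in% names(env))
  vars <- setdiff(names(env), "sample")
  wide <- tidyr::pivot_wider(abundance[, c("sample", "taxon",
                                           "abundance_copies_g")],
                             names_from = "taxon",
                             values_from = "abundance_copies_g")
  merged <- dplyr::inner_join(wide, env, by = "sample")
  taxa <- setdiff(names(wide), "sample")
  purrr::map_dfr(taxa, function(tx) {
    purrr::map_dfr(vars, function(v) {
      r <- spearman_rho(merged[[tx]], merged[[v]])
      tibble(taxon = tx, variable = v, rho = r$rho, p_value = r$p_value,
             n = r$n,
             flagged = is.finite(r$rho) && abs(r$rho) > rho_flag &&
               is.finite(r$p_value) && r$p_value < p_flag)
    })
  })
}
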