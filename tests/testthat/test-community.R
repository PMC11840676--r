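test_that("absolute abundances conserve qPCR totals and scale read fractions", {
  community <- tibble::tibble(
    sample = rep(c("a", "b", "c"), each = 2),
    taxon = rep(c("t1", "t2"), 3),
    reads = c(25, 75, 100, 0, 0, 40)
  )
  qpcr <- tibble::tibble(sample = c("a", "b", "c"),
                         mcrA_copies_g = c(1e5, 2e4, 3e3),
                         x16S_copies_g = 1e9)
  ab <- taxon_absolute_abundance(community, qpcr)
  # fraction 0.25 of 1e5 -> 2.5e4
  expect_equal(ab$abundance_copies_g[ab$sample == "a" & ab$taxon == "t1"],
               2.5e4)
  # zero reads -> zero copies
  expect_equal(ab$abundance_copies_g[ab$sample == "b" & ab$taxon == "t2"], 0)
  # single-taxon sample carries the full total
  expect_equal(ab$abundance_copies_g[ab$sample == "c" & ab$taxon == "t2"],
               3e3)
  sums <- dplyr::summarise(dplyr::group_by(ab, sample),
                           s = sum(abundance_copies_g))
  expect_equal(sums$s, qpcr$mcrA_copies_g, tolerance = 1e-15)

  expect_error(
    taxon_absolute_abundance(community, qpcr[1:2, ]), "orphan|without")
})

test_that("mcrA:16S ratios cover the observed dynamic range", {
  q <- tibble::tibble(sample = c("a", "b", "c", "d"),
                      mcrA_copies_g = c(1e4, 0, 1e9, 1e4),
                      x16S_copies_g = c(1e9, 1e9, 1e9, 0))
  expect_warning(r <- mcra_to_16s_ratio(q), "Zero 16S")
  expect_equal(r$ratio[1], 1e-5)
  expect_equal(r$ratio_percent[1], 0.001)
  expect_equal(r$ratio[2], 0)
  expect_equal(r$ratio_percent[3], 100)
  expect_true(is.na(r$ratio[4]))
})

test_that("richness, Shannon and Pielou evenness match hand values", {
  comm <- tibble::tibble(
    sample = c("u", "u", "u", "v", "v", "w", "w"),
    taxon = c("t1", "t2", "t3", "t1", "t2", "t1", "t2"),
    reads = c(5, 5, 5, 3, 1, 7, 0)
  )
  d <- richness_evenness(comm)
  u <- d[d$sample == "u", ]
  expect_equal(u$richness, 3)
  expect_equal(u$evenness, 1, tolerance = 1e-12)  # uniform counts
  v <- d[d$sample == "v", ]
  expect_equal(v$shannon, -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(v$shannon, 0.56233, tolerance = 1e-4)
  expect_equal(v$evenness, 0.81128, tolerance = 1e-4)
  w <- d[d$sample == "w", ]
  expect_equal(w$richness, 1)
  expect_true(is.na(w$evenness))
})

test_that("Bray-Curtis matches hand values and its metric properties", {
  expect_equal(bray_curtis(c(1, 2), c(2, 1)), 2 / 6, tolerance = 1e-12)
  expect_equal(bray_curtis(c(3, 0, 1), c(3, 0, 1)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(8)
  for (i in 1:20) {
    a <- rpois(6, 4)
    b <- rpois(6, 4)
    if (sum(a) + sum(b) == 0) next
    d1 <- bray_curtis(a, b)
    expect_equal(d1, bray_curtis(b, a))          # symmetric
    expect_true(d1 >= 0 && d1 <= 1)              # bounded
    if (d1 == 0) expect_identical(a, b)          # 0 iff identical
  }
})

test_that("diversity and distance agree with vegan on random communities", {
  set.seed(31)
  for (i in 1:50) {
    m <- matrix(rpois(5 * 8, lambda = 3) +
                  matrix(rbinom(5 * 8, 1, 0.3) * rpois(5 * 8, 20), 5, 8),
                nrow = 5)
    m[rowSums(m) == 0, 1] <- 1
    comm <- tibble::tibble(
      sample = rep(paste0("s", 1:5), times = 8),
      taxon = rep(paste0("t", 1:8), each = 5),
      reads = as.vector(m)
    )
    d <- richness_evenness(comm)
    expect_equal(d$shannon, unname(vegan::diversity(m)), tolerance = 1e-12)
    got_bc <- as.matrix(bray_curtis_matrix(comm))
    want_bc <- as.matrix(vegan::vegdist(m, method = "bray"))
    dimnames(want_bc) <- dimnames(got_bc)
    expect_equal(got_bc, want_bc, tolerance = 1e-12)
  }
})

test_that("rank-sum test matches the reference normal approximation", {
  set.seed(17)
  for (i in 1:50) {
    n1 <- sample(3:12, 1)
    n2 <- sample(3:12, 1)
    # mix of continuous and heavily tied integer data
    if (i %% 2 == 0) {
      x <- rnorm(n1)
      y <- rnorm(n2, 0.5)
    } else {
      x <- rpois(n1, 3)
      y <- rpois(n2, 5)
    }
    got <- rank_sum_test(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("Spearman correlation matches the reference t approximation", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    x <- if (i %% 2 == 0) rnorm(n) else rpois(n, 4)
    y <- 0.5 * x + if (i %% 2 == 0) rnorm(n) else rpois(n, 3)
    got <- spearman_rho(x, y)
    ref <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-3)
  }
  expect_equal(spearman_rho(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_rho(1:10, 11 - (1:10))$rho, -1)
  expect_true(is.na(spearman_rho(rep(1, 10), rnorm(10))$rho))
})

test_that("trend classification follows zone means and significance", {
  set.seed(23)
  zones <- tibble::tibble(
    sample = paste0("s", 1:24),
    zone = rep(c("BZ", "SZ", "SMTZ", "MZ"), each = 6)
  )
  mk <- function(bzsz, smtz, mz) {
    c(rlnorm(12, log(bzsz + 1), 0.3), rlnorm(6, log(smtz + 1), 0.3),
      rlnorm(6, log(mz + 1), 0.3))
  }
  ab <- dplyr::bind_rows(
    tibble::tibble(sample = zones$sample, taxon = "mz_lover",
                   abundance_copies_g = mk(10, 100, 5e4)),
    tibble::tibble(sample = zones$sample, taxon = "flat_rare",
                   abundance_copies_g = rlnorm(24, log(100), 0.2)),
    tibble::tibble(sample = zones$sample, taxon = "smtz_only",
                   abundance_copies_g = c(rep(0, 12), rlnorm(6, log(2e4), 0.3),
                                          rep(0, 6)))
  )
  tc <- zone_trend_classification(ab, zones)
  res <- tidy(tc)
  expect_equal(res$category[res$taxon == "mz_lover"], "MZ taxa")
  expect_equal(res$category[res$taxon == "flat_rare"],
               "ubiquitous rare taxa")
  expect_equal(res$category[res$taxon == "smtz_only"], "SMTZ taxa")
  counts <- glance(tc)
  expect_equal(sum(counts$n_taxa), 3)
})

test_that("environment correlations recover a noisy monotone association", {
  set.seed(29)
  n <- 20
  ch4 <- sort(runif(n, 0.01, 5))
  # noisy monotone abundance: true Spearman rho around 0.85
  abund_val <- 1e4 * ch4 * exp(rnorm(n, 0, 0.5))
  ab <- tibble::tibble(sample = paste0("s", 1:n), taxon = "t",
                       abundance_copies_g = abund_val)
  env <- tibble::tibble(sample = paste0("s", 1:n), CH4_mM = ch4,
                        constant = 1)
  ec <- env_correlations(ab, env)
  ch4_row <- ec[ec$variable == "CH4_mM", ]
  expect_gt(ch4_row$rho, 0.6)
  expect_true(ch4_row$flagged)
  expect_true(is.na(ec$rho[ec$variable == "constant"]))
  # perfectly monotone pairs
  ab2 <- tibble::tibble(sample = paste0("s", 1:n), taxon = "t",
                        abundance_copies_g = ch4^3)
  ec2 <- env_correlations(ab2, env[, c("sample", "CH4_mM")])
  expect_equal(ec2$rho, 1)
})
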