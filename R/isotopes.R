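#' Carbon isotope fractionation between DIC and methane
#'
#' Computes the permil offset and the fractionation factor between dissolved
#' inorganic carbon and methane for paired delta13C measurements:
#' \deqn{\varepsilon = \delta_{CH4} - \delta_{DIC}, \qquad
#'   \alpha = \frac{\delta_{DIC} + 1000}{\delta_{CH4} + 1000}}
#' The convention is substrate over product, so alpha exceeds 1 when methane
#' is isotopically depleted relative to DIC; values of 1.075-1.085 are
#' characteristic of methanogenic CO2 reduction.
#'
#' @param data A data frame with delta13C columns (permil VPDB), or NULL when
#'   using the vector arguments.
#' @param d13C_DIC,d13C_CH4 Column names (tidy-select style strings) in
#'   `data`, or numeric vectors when `data` is NULL.
#' @return `data` (or a new tibble) with columns `epsilon_offset` (permil)
#'   and `alpha` appended.
#' @examples
#' fractionation_factor(d13C_DIC = 10, d13C_CH4 = -70) # alpha ~ 1.086
#' @export
fractionation_factor <- function(data = NULL, d13C_DIC = "d13C_DIC",
                                 d13C_CH4 = "d13C_CH4") {
  if (is.null(data)) {
    dic <- d13C_DIC
    ch4 <- d13C_CH4
    data <- tibble(d13C_DIC = dic, d13C_CH4 = ch4)
  } else {
    dic <- data[[d13C_DIC]]
    ch4 <- data[[d13C_CH4]]
  }
  if (any(is.finite(ch4) & ch4 <= -1000)) {
    abort("delta13C-CH4 at or below -1000 permil is degenerate (zero 13C).")
  }
  data$epsilon_offset <- ch4 - dic
  data$alpha <- (dic + 1000) / (ch4 + 1000)
  as_tibble(data)
}

#' Predict methane delta13C from DIC delta13C under a fixed fractionation
#'
#' Inverse of [fractionation_factor()]: under CO2-reduction dominance the
#' methane delta13C tracks the DIC delta13C with a fixed fractionation
#' factor, \eqn{\delta_{CH4} = (\delta_{DIC} + 1000)/\alpha - 1000}.
#'
#' @param d13C_DIC Numeric vector, permil VPDB.
#' @param alpha Fractionation factor, > 0.
#' @return Predicted delta13C-CH4, permil VPDB.
#' @examples
#' predict_methane_delta(14, 1.08) # about -61.1
#' @export
predict_methane_delta <- function(d13C_DIC, alpha) {
  stopifnot(all(alpha > 0))
  (d13C_DIC + 1000) / alpha - 1000
}

#' Per-zone summary of the DIC-methane fractionation factor
#'
#' Joins zone labels onto a porewater profile and summarises the apparent
#' fractionation factor and permil offset per geochemical zone. The methanic
#' zone (MZ) summary is the headline output: under CO2-reduction dominance
#' the MZ offset is near constant and alpha falls in the 1.07-1.09 range.
#' Zones with no usable delta pairs are reported absent (NA rows), never as
#' zero.
#'
#' @param profile Porewater profile with `d13C_DIC` and `d13C_CH4` columns.
#' @param zones Zone assignment tibble (`site`, `depth_cm`, `zone`), e.g.
#'   from [assign_zones()].
#' @return An object of class `alpha_profile`: a tibble with one row per
#'   site x zone (`n`, `alpha_mean`, `alpha_min`, `alpha_max`,
#'   `offset_mean`, `offset_min`, `offset_max`), with the per-observation
#'   pairs stored in attribute `pairs`. `tidy()` returns the per-zone table,
#'   `glance()` the MZ headline row(s).
#' @export
estimate_alpha_profile <- function(profile, zones) {
  stopifnot(is.data.frame(profile), is.data.frame(zones))
  d <- left_join(profile, zones[, c("site", "depth_cm", "zone")],
                 by = c("site", "depth_cm"))
  d <- filter(d, is.finite(.data$d13C_DIC), is.finite(.data$d13C_CH4))
  d <- fractionation_factor(d)
  zone_levels <- c("BZ", "SZ", "SMTZ", "MZ")
  summ <- d %>%
    filter(!is.na(.data$zone)) %>%
    group_by(.data$site, .data$zone) %>%
    summarise(
      n = n(),
      alpha_mean = mean(.data$alpha),
      alpha_min = min(.data$alpha),
      alpha_max = max(.data$alpha),
      offset_mean = mean(.data$epsilon_offset),
      offset_min = min(.data$epsilon_offset),
      offset_max = max(.data$epsilon_offset),
      .groups = "drop"
    ) %>%
    mutate(zone = factor(.data$zone, levels = zone_levels)) %>%
    arrange(.data$site, .data$zone)
  # flag absent MZ explicitly per site
  sites <- unique(profile$site)
  missing_mz <- setdiff(sites, summ$site[summ$zone == "MZ"])
  if (length(missing_mz) > 0) {
    summ <- bind_rows(summ, tibble(
      site = missing_mz, zone = factor("MZ", levels = zone_levels),
      n = 0L, alpha_mean = NA_real_, alpha_min = NA_real_,
      alpha_max = NA_real_, offset_mean = NA_real_, offset_min = NA_real_,
      offset_max = NA_real_
    ))
  }
  structure(summ, class = c("alpha_profile", class(summ)), pairs = d)
}

#' @export
tidy.alpha_profile <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

#' @export
glance.alpha_profile <- function(x, ...) {
  out <- as_tibble(unclass_keep(x))
  filter(out, .data$zone == "MZ")
}

#' @export
print.alpha_profile <- function(x, ...) {
  cat("Per-zone DIC-CH4 fractionation summary\n")
  print(as_tibble(unclass_keep(x)), ...)
  invisible(x)
}

# strip the S3 subclass and heavy attributes without losing the tibble
unclass_keep <- function(x) {
  attr(x, "pairs") <- NULL
  class(x) <- setdiff(class(x), c("alpha_profile", "zone_assignment",
                                  "trend_classification"))
  x
}
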