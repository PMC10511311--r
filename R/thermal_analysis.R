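#' Boltzmann-standardized temperature
#'
#' Standardizes water temperature as
#' \eqn{x = 1/(k_B T_c) - 1/(k_B T)} (1/eV), with T in kelvin and the
#' reference temperature Tc = 15 deg C, so that the slope of ln(flux) on x
#' is the apparent activation energy in eV and x = 0 exactly at Tc. x
#' increases with temperature.
#'
#' @param t_water Water temperature, deg C (> -273.15).
#' @param constants A [ch4_constants()] list (Boltzmann constant and Tc).
#' @return Standardized temperature, 1/eV.
#' @export
#' @examples
#' standardize_temperature(15)  # 0
standardize_temperature <- function(t_water, constants = ch4_constants()) {
  stopifnot(all(t_water > -273.15))
  kb <- constants$boltzmann_ev
  t_ref_k <- constants$t_ref_c + 273.15
  1 / (kb * t_ref_k) - 1 / (kb * (t_water + 273.15))
}

#' Apparent activation energies of diffusive CH4 emissions
#'
#' Regresses ln(diffusive flux) on Boltzmann-standardized temperature,
#' per site for every site with at least `min_n` usable observations, and
#' pooled over all usable observations. The slope is the apparent
#' activation energy E_M in eV. Non-positive fluxes cannot enter the log
#' regression and are excluded, with the count reported.
#'
#' @param observations Table with `site_id`, `flux_diff`
#'   (mmol m^-2 day^-1) and `t_water` (deg C).
#' @param min_n Minimum observations for a site-level fit (default 20,
#'   exceeded strictly: sites need more than `min_n` observations).
#' @param constants A [ch4_constants()] list.
#' @return List: `site_fits` (tibble `site_id`, `n_obs`, `e_m`,
#'   `intercept`, `se`), `pooled` (one-row tibble with
#'   `site_id = "pooled"`), `n_excluded_nonpositive`.
#' @export
site_activation_energies <- function(observations, min_n = 20,
                                     constants = ch4_constants()) {
  usable <- observations[!is.na(observations$flux_diff) &
                           !is.na(observations$t_water), , drop = FALSE]
  n_nonpos <- sum(usable$flux_diff <= 0)
  usable <- usable[usable$flux_diff > 0, , drop = FALSE]
  usable$x <- standardize_temperature(usable$t_water, constants)
  usable$ly <- log(usable$flux_diff)

  fit_one <- function(d, label) {
    if (nrow(d) < 3 || stats::sd(d$x) == 0) return(NULL)
    f <- stats::lm(ly ~ x, data = d)
    s <- summary(f)$coefficients
    tibble::tibble(site_id = label, n_obs = nrow(d),
                   e_m = unname(stats::coef(f)[2]),
                   intercept = unname(stats::coef(f)[1]),
                   se = if (nrow(s) == 2) s[2, 2] else NA_real_)
  }
  counts <- table(usable$site_id)
  qualifying <- names(counts)[counts > min_n]
  site_fits <- dplyr::bind_rows(lapply(qualifying, function(s)
    fit_one(usable[usable$site_id == s, ], s)))
  if (length(qualifying) == 0) {
    warning("no sites with more than ", min_n, " observations")
    site_fits <- tibble::tibble(site_id = character(), n_obs = integer(),
                                e_m = numeric(), intercept = numeric(),
                                se = numeric())
  }
  pooled <- fit_one(usable, "pooled")
  list(site_fits = site_fits, pooled = pooled,
       n_excluded_nonpositive = n_nonpos)
}

#' Compare riverine activation energies with other freshwater systems
#'
#' Two-sided Wilcoxon rank-sum test between the distribution of per-site
#' riverine E_M values and a reference set (e.g. lakes, wetlands and rice
#' paddies), with medians, interquartile ranges, and kernel density
#' estimates on a shared grid.
#'
#' @param river_em Numeric vector of riverine per-site E_M values, eV.
#' @param reference_em Numeric vector of reference E_M values, eV.
#' @param grid_n Points in the shared density grid.
#' @return List: `p_value`, `statistic`, `summary` (per-group median and
#'   IQR), `density` (tibble `group`, `e_m`, `density`).
#' @export
compare_em_distributions <- function(river_em, reference_em, grid_n = 256) {
  if (length(river_em) < 2 || length(reference_em) < 2) {
    stop("each group needs at least 2 values")
  }
  wt <- stats::wilcox.test(river_em, reference_em, exact = FALSE)
  rng <- range(c(river_em, reference_em))
  pad <- 0.2 * diff(rng)
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = grid_n)
  dens <- function(x, label) {
    d <- stats::density(x, from = min(grid), to = max(grid), n = grid_n)
    tibble::tibble(group = label, e_m = d$x, density = d$y)
  }
  summary_tbl <- tibble::tibble(
    group = c("rivers", "reference"),
    n = c(length(river_em), length(reference_em)),
    median = c(stats::median(river_em), stats::median(reference_em)),
    iqr_lo = c(stats::quantile(river_em, 0.25),
               stats::quantile(reference_em, 0.25)),
    iqr_hi = c(stats::quantile(river_em, 0.75),
               stats::quantile(reference_em, 0.75)))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       summary = summary_tbl,
       density = dplyr::bind_rows(dens(river_em, "rivers"),
                                  dens(reference_em, "reference")))
}
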