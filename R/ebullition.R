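#' Pair and filter diffusive/ebullitive flux observations
#'
#' Keeps observations that report both a diffusive and an ebullitive flux,
#' drops negligible or uncertain fluxes below a floor (default
#' 0.0001 mmol m^-2 day^-1 on either pathway), and drops observations
#' whose k600 was modelled from hydraulic relationships rather than
#' measured, since those diffusive estimates are unreliable locally.
#'
#' @param observations Table with `flux_diff`, `flux_eb`, `k_method`.
#' @param min_flux Flux floor, mmol m^-2 day^-1.
#' @param excluded_k_methods k-method labels to exclude (default
#'   `"hydraulic_model"`).
#' @return List: `pairs` (retained tibble), `n_input`, `n_retained`,
#'   counts of each exclusion reason.
#' @export
pair_and_filter <- function(observations, min_flux = 1e-4,
                            excluded_k_methods = "hydraulic_model") {
  has_both <- !is.na(observations$flux_diff) & !is.na(observations$flux_eb)
  x <- observations[has_both, , drop = FALSE]
  too_small <- x$flux_diff < min_flux | x$flux_eb < min_flux
  bad_k <- x$k_method %in% excluded_k_methods
  keep <- !too_small & !bad_k
  if (!any(keep)) stop("no flux pairs remain after filtering")
  list(pairs = x[keep, , drop = FALSE],
       n_input = nrow(observations),
       n_paired = nrow(x),
       n_below_floor = sum(too_small),
       n_bad_k = sum(bad_k & !too_small),
       n_retained = sum(keep))
}

#' Fit the log-log relation between ebullitive and diffusive fluxes
#'
#' Ordinary least squares of log ebullitive on log diffusive flux
#' (natural log internally). The residual standard deviation parameterizes
#' prediction intervals used to bound the upscaled ebullitive estimate.
#'
#' @param pairs Filtered pair table from [pair_and_filter()].
#' @return Object of class `ch4_ebullition`: `slope`, `intercept`
#'   (natural-log space), `sigma` (residual s.d.), `n`, medians of both
#'   flux columns, and the underlying `lm` fit.
#' @export
fit_ebullition_model <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- pairs$pairs
  if (nrow(pairs) < 3) stop("need at least 3 pairs to fit")
  if (stats::sd(log(pairs$flux_diff)) == 0) {
    stop("degenerate predictor: diffusive fluxes have no spread")
  }
  d <- data.frame(lx = log(pairs$flux_diff), ly = log(pairs$flux_eb))
  fit <- stats::lm(ly ~ lx, data = d)
  # suppress the perfect-fit note: zero residual s.d. is a legitimate
  # degenerate case (exact 1:1 pairs) handled downstream
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    sigma = suppressWarnings(summary(fit))$sigma,
    n = nrow(pairs),
    median_diff = stats::median(pairs$flux_diff),
    median_eb = stats::median(pairs$flux_eb),
    fit = fit), class = "ch4_ebullition")
}

#' Prediction interval of the ebullition regression
#'
#' @param model A `ch4_ebullition` fit.
#' @param diffusive Diffusive flux value(s) at which to predict (natural
#'   units).
#' @param level Interval level (default 0.95); `level = 0` collapses to
#'   the regression line.
#' @return Tibble `fit`, `lwr`, `upr` in natural (back-transformed) units.
#' @export
ebullition_interval <- function(model, diffusive, level = 0.95) {
  stopifnot(inherits(model, "ch4_ebullition"), all(diffusive > 0))
  p <- stats::predict(model$fit,
                      newdata = data.frame(lx = log(diffusive)),
                      interval = "prediction", level = max(level, 1e-12))
  out <- tibble::as_tibble(exp(p))
  if (level == 0) out$lwr <- out$upr <- out$fit
  out
}

#' Upscale ebullitive emissions from the diffusive total
#'
#' Applies the fitted log-log relation to the central diffusive estimate
#' to obtain the central ebullitive total, and composes the uncertainty
#' interval from the Monte Carlo distribution of the diffusive total: the
#' lower bound is the lower prediction bound evaluated at the diffusive
#' 2.5th percentile, the upper bound the upper prediction bound at the
#' 97.5th percentile.
#'
#' @param model A `ch4_ebullition` fit.
#' @param diffusive_total Central diffusive estimate, Tg/yr.
#' @param diffusive_draws Monte Carlo draws of the diffusive total (Tg/yr),
#'   used for its 2.5th/97.5th percentiles; optional when both percentile
#'   arguments are given.
#' @param q_low,q_high Diffusive percentiles overriding `diffusive_draws`.
#' @param level Prediction-interval level (default 0.95).
#' @return List: `central_tg`, `lower_tg`, `upper_tg`, `total_with_diffusive_tg`.
#' @export
upscale_ebullition <- function(model, diffusive_total,
                               diffusive_draws = NULL,
                               q_low = NULL, q_high = NULL, level = 0.95) {
  stopifnot(inherits(model, "ch4_ebullition"))
  if (is.null(q_low) || is.null(q_high)) {
    if (is.null(diffusive_draws)) {
      stop("provide diffusive_draws or explicit percentiles")
    }
    q <- stats::quantile(diffusive_draws, c(0.025, 0.975))
    q_low <- q[[1]]; q_high <- q[[2]]
  }
  central <- ebullition_interval(model, diffusive_total, level = 0)$fit
  lower <- ebullition_interval(model, max(q_low, .Machine$double.xmin),
                               level = level)$lwr
  upper <- ebullition_interval(model, q_high, level = level)$upr
  list(central_tg = central, lower_tg = lower, upper_tg = upper,
       total_with_diffusive_tg = central + diffusive_total)
}
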