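#' Filter observations by site category
#'
#' Drops observations from targeted sites (e.g. below wastewater treatment
#' plants, below dams, fracking-affected) and from locations a reach-scale
#' hydrography cannot represent (ditches, canals, glacial termini, thaw
#' slumps). Categories not in the configured vocabulary are kept, with a
#' warning.
#'
#' @param observations Observation table with a `site_category` column.
#' @param excluded_categories Character vector of categories to exclude.
#' @param known_categories Vocabulary used to warn on unknown labels.
#' @return List: `retained` (tibble), `report` (per-category kept/excluded
#'   counts).
#' @export
filter_observations <- function(observations,
                                excluded_categories = c(
                                  "fracking", "below_dam", "below_wwtp",
                                  "ditch", "glacial_terminus", "canal",
                                  "thaw_slump"),
                                known_categories = c(
                                  "normal", "fracking", "below_dam",
                                  "below_wwtp", "ditch", "glacial_terminus",
                                  "canal", "thaw_slump")) {
  cat <- observations$site_category
  unknown <- setdiff(unique(cat), known_categories)
  if (length(unknown)) {
    warning("unknown site categories retained by default: ",
            paste(unknown, collapse = ", "))
  }
  keep <- !(cat %in% excluded_categories)
  report <- tibble::as_tibble(table(category = cat, excluded = !keep))
  list(retained = observations[keep, , drop = FALSE], report = report)
}

#' Snap observation sites to the nearest river reach
#'
#' Maps each site to its nearest reach midpoint by great-circle distance.
#' Sites farther than `max_dist_m` from any reach are flagged unmapped and
#' excluded from downstream aggregation.
#'
#' @param observations Observation table with `site_id`, `latitude`,
#'   `longitude` (one row per observation is fine; sites are deduplicated).
#' @param reaches Reach table with `reach_id`, `latitude`, `longitude`
#'   (representative midpoint coordinates).
#' @param max_dist_m Mapping threshold in metres (default 500).
#' @return Tibble `site_id`, `reach_id`, `dist_m`, `mapped`.
#' @export
snap_sites <- function(observations, reaches, max_dist_m = 500) {
  if (nrow(reaches) == 0) stop("no reaches to snap to")
  sites <- unique(observations[c("site_id", "latitude", "longitude")])
  dmat <- geosphere::distm(
    cbind(sites$longitude, sites$latitude),
    cbind(reaches$longitude, reaches$latitude))
  nearest <- apply(dmat, 1, which.min)
  dist_m <- dmat[cbind(seq_len(nrow(sites)), nearest)]
  tibble::tibble(
    site_id = sites$site_id,
    reach_id = reaches$reach_id[nearest],
    dist_m = dist_m,
    mapped = dist_m <= max_dist_m
  )
}

#' Aggregate observations to one value per reach and month
#'
#' Two-stage temporal-then-spatial aggregation: observations are first
#' combined across years within each site-month, then across sites within
#' each reach-month. Each stage's statistic (mean or median) is a switch;
#' the default is mean at both stages.
#'
#' @param observations Observation table with `site_id`, `month`, and the
#'   value column.
#' @param snap Output of [snap_sites()]; only mapped sites are used.
#' @param value_col Column to aggregate (default `"c_ch4"`).
#' @param stat_year,stat_site `"mean"` or `"median"` for the within-site
#'   and across-site stages.
#' @return Tibble `reach_id`, `month`, aggregated value column, `n_sites`.
#' @export
aggregate_to_reach_month <- function(observations, snap,
                                     value_col = "c_ch4",
                                     stat_year = c("mean", "median"),
                                     stat_site = c("mean", "median")) {
  stat_year <- match.arg(stat_year)
  stat_site <- match.arg(stat_site)
  f1 <- if (stat_year == "mean") mean else stats::median
  f2 <- if (stat_site == "mean") mean else stats::median
  mapped <- snap[snap$mapped, c("site_id", "reach_id")]
  observations |>
    dplyr::inner_join(mapped, by = "site_id") |>
    dplyr::filter(!is.na(.data[[value_col]])) |>
    dplyr::group_by(.data$reach_id, .data$site_id, .data$month) |>
    dplyr::summarise(value = f1(.data[[value_col]]), .groups = "drop") |>
    dplyr::group_by(.data$reach_id, .data$month) |>
    dplyr::summarise(!!value_col := f2(.data$value),
                     n_sites = dplyr::n(), .groups = "drop")
}

#' Build the three-month training window for one monthly model
#'
#' Selects rows whose month is the target month or an adjacent one
#' (December and January wrap around), then splits them 80/20 into
#' training and test sets under the given seed.
#'
#' @param dataset Reach-month table with a `month` column.
#' @param month Target month, 1-12.
#' @param test_frac Fraction withheld for testing (default 0.2).
#' @param seed Integer seed for the split.
#' @return The windowed tibble with a `split` column (`"train"`/`"test"`).
#' @export
build_monthly_window <- function(dataset, month, test_frac = 0.2, seed = 42) {
  stopifnot(month %in% 1:12)
  window <- ((month - 1 + c(-1, 0, 1)) %% 12) + 1
  rows <- dataset[dataset$month %in% window, , drop = FALSE]
  if (nrow(rows) == 0) stop("empty window for month ", month)
  n_test <- round(test_frac * nrow(rows))
  idx <- withr::with_seed(seed, sample.int(nrow(rows), n_test))
  rows$split <- "train"
  rows$split[idx] <- "test"
  rows
}

#' Prune correlated predictors and log-transform skewed ones
#'
#' Greedily removes predictors so that no retained pair has
#' |Pearson r| above `r_max`, honouring an ordered keep-priority list
#' (earlier names win their pairwise conflicts). Constant columns are
#' dropped with a warning. Columns whose sample skewness exceeds
#' `skew_threshold` are log-transformed, with an offset for non-positive
#' values; all actions are returned in a log.
#'
#' @param dataset Data frame; only the columns in `predictors` are acted on.
#' @param predictors Character vector of predictor column names.
#' @param r_max Correlation threshold (default 0.95).
#' @param keep_priority Ordered character vector; names earlier in the
#'   list are preferred when a correlated pair must lose a member.
#'   Unlisted predictors rank below listed ones, ties broken by column
#'   order.
#' @param skew_threshold Absolute skewness above which a column is
#'   log-transformed; `Inf` disables transformation.
#' @return List: `dataset` (transformed), `predictors` (retained names,
#'   transformed columns renamed `log_<name>`), `log` (tibble of actions).
#' @export
prune_predictors <- function(dataset, predictors, r_max = 0.95,
                             keep_priority = character(),
                             skew_threshold = 2) {
  actions <- list()
  keep <- predictors
  # drop constants
  consts <- keep[vapply(dataset[keep], function(x) stats::sd(x) == 0 ||
                          !is.finite(stats::sd(x)), logical(1))]
  if (length(consts)) {
    warning("dropping constant predictors: ", paste(consts, collapse = ", "))
    actions <- c(actions, lapply(consts, function(v)
      tibble::tibble(variable = v, action = "dropped_constant")))
    keep <- setdiff(keep, consts)
  }
  rank_of <- function(v) {
    i <- match(v, keep_priority)
    ifelse(is.na(i), length(keep_priority) + match(v, predictors), i)
  }
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(dataset[keep]))
    diag(cm) <- 0
    if (max(cm) <= r_max) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    drop <- pair[which.max(rank_of(pair))]
    actions <- c(actions, list(tibble::tibble(
      variable = drop, action = "dropped_correlated",
      detail = sprintf("r=%.3f with %s", max(cm), setdiff(pair, drop)))))
    keep <- setdiff(keep, drop)
  }
  # log-transform skewed columns
  out_names <- keep
  for (v in keep) {
    x <- dataset[[v]]
    sk <- skewness(x)
    if (is.finite(sk) && abs(sk) > skew_threshold) {
      offset <- if (any(x <= 0)) abs(min(x)) + 1 else 0
      newv <- paste0("log_", v)
      dataset[[newv]] <- log(x + offset)
      dataset[[v]] <- NULL
      out_names[out_names == v] <- newv
      actions <- c(actions, list(tibble::tibble(
        variable = v, action = "log_transformed",
        detail = sprintf("skewness=%.2f offset=%g", sk, offset))))
    }
  }
  list(dataset = dataset, predictors = out_names,
       log = dplyr::bind_rows(actions))
}

# sample skewness (method-of-moments)
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}
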