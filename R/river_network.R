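#' Per-reach, per-month hydraulic geometry and effective surface area
#'
#' Applies the configured power laws V(Q), W(Q), D(Q) to each reach's
#' monthly mean discharge and derives water-surface area (width x reach
#' length) and effective area, the latter discounted multiplicatively for
#' the ice-covered and dry fractions of each month. A month with zero
#' discharge has zero width and hence zero area; a month with an ice-free
#' fraction of zero has zero effective area and therefore emits nothing
#' downstream of this state.
#'
#' @param reaches Reach table: `reach_id`, `length_m`, `slope`,
#'   `elevation_m`, `stream_order`, `basin_group`, `latitude`, `q_cv`, and
#'   monthly columns `q_01..q_12` (m^3/s), `ice_01..ice_12` (ice-free
#'   fraction in \[0,1\]) and `dry_01..dry_12` (dry fraction in \[0,1\]).
#'   Missing ice/dry columns default to 1 and 0.
#' @param coeffs A [hydraulic_coefficients()] list.
#' @param months Months to compute (default 1:12).
#' @return Tibble with one row per reach-month: `q_m3s`, `velocity_ms`,
#'   `width_m`, `depth_m`, `area_m2`, `effective_area_m2`,
#'   `ice_free_frac`, `dry_frac`, `length_m`.
#' @export
hydraulic_geometry <- function(reaches, coeffs = hydraulic_coefficients(),
                               months = 1:12) {
  stopifnot(all(months %in% 1:12))
  validate_reaches(reaches)
  long <- reach_months_long(reaches, months)
  bad <- !is.finite(long$q_m3s)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("missing discharge for reach %s month %d",
                 long$reach_id[i], long$month[i]))
  }
  long |>
    dplyr::mutate(
      velocity_ms = coeffs$a_v * .data$q_m3s^coeffs$b_v,
      width_m = coeffs$a_w * .data$q_m3s^coeffs$b_w,
      depth_m = coeffs$a_d * .data$q_m3s^coeffs$b_d,
      area_m2 = .data$width_m * .data$length_m,
      effective_area_m2 = .data$area_m2 * .data$ice_free_frac *
        (1 - .data$dry_frac)
    )
}

validate_reaches <- function(reaches) {
  need <- c("reach_id", "length_m", "slope", sprintf("q_%02d", 1:12))
  miss <- setdiff(need, names(reaches))
  if (length(miss)) stop("reach table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(reaches$length_m <= 0)) stop("reach length must be positive")
  if (any(reaches$slope < 0)) stop("reach slope must be non-negative")
  qs <- as.matrix(reaches[sprintf("q_%02d", 1:12)])
  if (any(qs < 0, na.rm = TRUE)) stop("monthly discharge must be non-negative")
  invisible(reaches)
}

# pivot the 12-column monthly blocks of a reach table to reach-month rows
reach_months_long <- function(reaches, months = 1:12) {
  get_block <- function(prefix, default) {
    cols <- sprintf("%s_%02d", prefix, 1:12)
    if (all(cols %in% names(reaches))) {
      as.matrix(reaches[cols])
    } else {
      matrix(default, nrow(reaches), 12)
    }
  }
  q <- get_block("q", NA_real_)
  ice <- get_block("ice", 1)
  dry <- get_block("dry", 0)
  dplyr::bind_rows(lapply(months, function(m) {
    tibble::tibble(
      reach_id = reaches$reach_id,
      month = m,
      q_m3s = q[, m],
      ice_free_frac = ice[, m],
      dry_frac = dry[, m],
      length_m = reaches$length_m
    )
  }))
}

#' Extrapolate the river network below the smallest resolved order
#'
#' Resolved hydrography misses the smallest channels. For each basin group
#' this extends the network with Horton-style geometric progressions: each
#' synthetic order step below the smallest resolved order has mean width
#' `width_ratio` times the previous step and total length `length_ratio`
#' times the previous step, terminating before widths fall below
#' `min_width_m` (default 0.3 m). Monthly widths scale with the resolved
#' first-order monthly widths, and the basin's first-order ice/dry
#' fractions carry over. Downstream, these synthetic streams are assigned
#' the k600 and CH4 concentration of the basin's first-order reaches.
#'
#' @param reaches Reach table (see [hydraulic_geometry()]); needs
#'   `stream_order` and `basin_group`.
#' @param hydraulics Output of [hydraulic_geometry()] for the same table.
#' @param coeffs A [hydraulic_coefficients()] list.
#' @param fit_ratios If `TRUE` and a basin group resolves >= 3 stream
#'   orders, the width and length ratios are re-fitted per group from
#'   log-linear regressions of mean width and total length on order;
#'   otherwise the configured ratios are used.
#' @return Tibble: `basin_group`, `order_step` (1 = first synthetic order
#'   below the resolved network), `month`, `width_m`, `added_length_m`,
#'   `area_m2`, `effective_area_m2`. Empty (with a message) when the
#'   resolved first-order width is already at or below the floor.
#' @export
extrapolate_small_streams <- function(reaches, hydraulics,
                                      coeffs = hydraulic_coefficients(),
                                      fit_ratios = FALSE) {
  stopifnot(all(c("stream_order", "basin_group") %in% names(reaches)))
  empty <- tibble::tibble(basin_group = character(), order_step = integer(),
                          month = integer(), width_m = numeric(),
                          added_length_m = numeric(), area_m2 = numeric(),
                          effective_area_m2 = numeric())
  if (nrow(reaches) == 0) return(empty)

  hj <- hydraulics |>
    dplyr::inner_join(
      dplyr::select(reaches, "reach_id", "stream_order", "basin_group"),
      by = "reach_id"
    )
  out <- lapply(split(hj, hj$basin_group), function(bg) {
    o1 <- min(bg$stream_order)
    first <- bg[bg$stream_order == o1, ]
    # per-month mean width and the annual mean that fixes the class ladder
    w_month <- tapply(first$width_m, first$month, mean)
    months <- as.integer(names(w_month))
    w1 <- mean(w_month)
    l1 <- sum(first$length_m[first$month == months[1]])
    wr <- coeffs$width_ratio
    lr <- coeffs$length_ratio
    if (fit_ratios) {
      by_order <- bg[bg$month == months[1], ] |>
        dplyr::group_by(.data$stream_order) |>
        dplyr::summarise(w = mean(.data$width_m), l = sum(.data$length_m),
                         .groups = "drop")
      if (nrow(by_order) >= 3) {
        wr_fit <- exp(stats::coef(stats::lm(log(w) ~ stream_order,
                                            data = by_order))[2])
        lr_fit <- exp(-stats::coef(stats::lm(log(l) ~ stream_order,
                                             data = by_order))[2])
        if (is.finite(wr_fit) && wr_fit > 0 && wr_fit < 1) wr <- wr_fit
        if (is.finite(lr_fit) && lr_fit > 0) lr <- lr_fit
      }
    }
    if (w1 <= coeffs$min_width_m) {
      message("basin ", bg$basin_group[1],
              ": resolved first-order width already <= minimum; no ",
              "extrapolation")
      return(NULL)
    }
    n_steps <- 0L
    while (w1 * wr^(n_steps + 1L) >= coeffs$min_width_m) n_steps <- n_steps + 1L
    if (n_steps == 0L) return(NULL)
    steps <- seq_len(n_steps)
    grid <- expand.grid(order_step = steps, month = months)
    ice <- tapply(first$ice_free_frac, first$month, mean)[as.character(grid$month)]
    dry <- tapply(first$dry_frac, first$month, mean)[as.character(grid$month)]
    width <- as.numeric(w_month[as.character(grid$month)]) * wr^grid$order_step
    added_len <- l1 * lr^grid$order_step
    tibble::tibble(
      basin_group = bg$basin_group[1],
      order_step = as.integer(grid$order_step),
      month = as.integer(grid$month),
      width_m = width,
      added_length_m = added_len,
      area_m2 = width * added_len,
      effective_area_m2 = width * added_len * as.numeric(ice) *
        (1 - as.numeric(dry))
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else res
}

#' Aggregate per-reach emissions into latitudinal bands
#'
#' Bins reaches into half-open latitude bands \[lo, hi) running south to
#' north (the northernmost band closed at 90) and sums emissions per band
#' and month. Band totals sum exactly to the global total.
#'
#' @param emissions Data frame with `latitude`, `month` and the emission
#'   column named by `value_col`.
#' @param bin_width Band width in degrees (default 10).
#' @param value_col Name of the column holding the per-reach emission.
#' @return Tibble `lat_lo`, `lat_hi`, `month`, `emission` sorted south to
#'   north.
#' @export
latitudinal_bins <- function(emissions, bin_width = 10,
                             value_col = "emission_g") {
  lat <- emissions$latitude
  if (any(lat < -90 | lat > 90, na.rm = TRUE) || any(is.na(lat))) {
    stop("latitude outside [-90, 90]")
  }
  edges <- seq(-90, 90, by = bin_width)
  idx <- findInterval(lat, edges, rightmost.closed = TRUE)
  tibble::tibble(
    lat_lo = edges[idx],
    lat_hi = edges[idx + 1],
    month = emissions$month,
    emission = emissions[[value_col]]
  ) |>
    dplyr::group_by(.data$lat_lo, .data$lat_hi, .data$month) |>
    dplyr::summarise(emission = sum(.data$emission), .groups = "drop") |>
    dplyr::arrange(.data$lat_lo, .data$month)
}
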