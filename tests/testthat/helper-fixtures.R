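# Small in-code fixtures shared across test files.

# A hand-built four-reach, single-basin network with simple round numbers.
# Reach r3 freezes over in winter (months 12, 1, 2); r4 is partly dry.
toy_reaches <- function() {
  r <- tibble::tibble(
    reach_id = c("r1", "r2", "r3", "r4"),
    downstream_id = c(NA, "r1", "r2", "r2"),
    length_m = c(8000, 6000, 5000, 4000),
    slope = c(0.001, 0.005, 0.02, 0.03),
    elevation_m = c(50, 200, 600, 800),
    stream_order = c(3L, 2L, 1L, 1L),
    basin_group = "basin_01",
    latitude = c(46, 46.2, 46.4, 46.5),
    longitude = c(8, 8.1, 8.2, 8.3),
    q_cv = c(0.2, 0.3, 0.4, 0.4)
  )
  for (m in 1:12) {
    r[[sprintf("q_%02d", m)]] <- c(9, 4, 2, 1) *
      (1 + 0.3 * cos(2 * pi * (m - 7) / 12))
    r[[sprintf("ice_%02d", m)]] <- if (m %in% c(12, 1, 2)) {
      c(1, 1, 0, 0.5)
    } else {
      rep(1, 4)
    }
    r[[sprintf("dry_%02d", m)]] <- if (m %in% 7:8) {
      c(0, 0, 0, 0.2)
    } else {
      rep(0, 4)
    }
  }
  r
}

# constant air temperature table for the toy network
toy_air_temp <- function(reaches, t = 12) {
  expand.grid(reach_id = reaches$reach_id, month = 1:12,
              stringsAsFactors = FALSE) |>
    dplyr::mutate(t_air_c = t + 8 * cos(2 * pi * (month - 7) / 12))
}

# flat concentration field with configurable uncertainty
toy_concentrations <- function(reaches, c_hat = 0.8, c_sd = 0) {
  expand.grid(reach_id = reaches$reach_id, month = 1:12,
              stringsAsFactors = FALSE) |>
    dplyr::mutate(c_hat = c_hat, c_sd = c_sd)
}

# haversine distance in metres, independent of geosphere (brute-force oracle)
haversine_m <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6378137 * asin(pmin(1, sqrt(a)))
}
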