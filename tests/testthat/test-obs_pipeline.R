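make_obs <- function(n = 10, category = "normal") {
  tibble::tibble(
    site_id = sprintf("s%02d", seq_len(n)),
    latitude = 46 + seq_len(n) / 100,
    longitude = 8 + seq_len(n) / 100,
    month = rep(1:12, length.out = n),
    c_ch4 = exp(rnorm(n)),
    site_category = category
  )
}

test_that("category filtering excludes targeted sites and reports counts", {
  set.seed(1)
  obs <- make_obs(10)
  obs$site_category[c(2, 5, 9)] <- "below_wwtp"
  f <- filter_observations(obs)
  expect_equal(nrow(f$retained), 7)
  expect_true(all(f$retained$site_category == "normal"))
  rep_wwtp <- f$report[f$report$category == "below_wwtp" &
                         f$report$excluded == "TRUE", ]
  expect_equal(rep_wwtp$n, 3)
  # empty exclusion list is the identity
  expect_equal(nrow(filter_observations(obs, character())$retained), 10)
  # unknown labels are retained with a warning
  obs$site_category[1] <- "volcanic_spring"
  expect_warning(f2 <- filter_observations(obs), "volcanic_spring")
  expect_true("volcanic_spring" %in% f2$retained$site_category)
})

test_that("snapping maps sites to the nearest reach within the threshold", {
  reaches <- toy_reaches()
  # one site exactly on a midpoint, one ~600 m east of r1
  obs <- tibble::tibble(
    site_id = c("a", "b"),
    latitude = c(reaches$latitude[2], reaches$latitude[1]),
    longitude = c(reaches$longitude[2], reaches$longitude[1] +
                    600 / (111320 * cos(pi * reaches$latitude[1] / 180))))
  snap <- snap_sites(obs, reaches, max_dist_m = 500)
  expect_equal(snap$reach_id[snap$site_id == "a"], "r2")
  expect_equal(snap$dist_m[snap$site_id == "a"], 0, tolerance = 1e-6)
  expect_false(snap$mapped[snap$site_id == "b"])
  expect_error(snap_sites(obs, reaches[0, ]), "no reaches")
})

test_that("snap assignment agrees with a brute-force nearest-neighbour search", {
  set.seed(42)
  cfg <- synth_config(n_reaches = 40, seed = 5)
  reaches <- generate_network(cfg)
  sites <- tibble::tibble(
    site_id = sprintf("s%03d", 1:100),
    latitude = sample(reaches$latitude, 100, TRUE) + rnorm(100, 0, 0.01),
    longitude = sample(reaches$longitude, 100, TRUE) + rnorm(100, 0, 0.01))
  snap <- snap_sites(sites, reaches)
  brute <- vapply(seq_len(nrow(sites)), function(i) {
    d <- haversine_m(sites$latitude[i], sites$longitude[i],
                     reaches$latitude, reaches$longitude)
    reaches$reach_id[which.min(d)]
  }, character(1))
  expect_equal(snap$reach_id, brute)
})

test_that("aggregation is two-stage: across years within site, then across sites", {
  reaches <- toy_reaches()
  obs <- tibble::tibble(
    site_id = c("a", "a", "b"),
    latitude = reaches$latitude[1], longitude = reaches$longitude[1],
    month = 3,
    c_ch4 = c(1.0, 3.0, 4.0))  # site a: two years of March
  snap <- snap_sites(obs, reaches)
  agg <- aggregate_to_reach_month(obs, snap)
  # site a -> 2.0, then mean(2.0, 4.0) = 3.0 on the shared reach
  expect_equal(agg$c_ch4, 3.0)
  expect_equal(agg$n_sites, 2L)
  # median switch at the across-site stage
  obs2 <- dplyr::bind_rows(obs, tibble::tibble(
    site_id = "c", latitude = reaches$latitude[1],
    longitude = reaches$longitude[1], month = 3, c_ch4 = 100))
  agg_med <- aggregate_to_reach_month(obs2, snap_sites(obs2, reaches),
                                      stat_site = "median")
  expect_equal(agg_med$c_ch4, 4.0)  # median of 2, 4, 100
})

test_that("filtering and aggregation are invariant to input row order", {
  set.seed(7)
  cfg <- synth_config(n_reaches = 20, n_obs = 150, seed = 9)
  reaches <- generate_network(cfg)
  obs <- generate_observations(reaches, generate_predictors(reaches, cfg),
                               cfg)
  run <- function(o) {
    f <- filter_observations(o)$retained
    s <- snap_sites(f, reaches)
    aggregate_to_reach_month(f, s)
  }
  shuffled <- obs[sample.int(nrow(obs)), ]
  expect_equal(run(obs), run(shuffled))
})

test_that("monthly windows wrap around the year and split 80/20", {
  d <- tibble::tibble(month = rep(1:12, each = 10), y = rnorm(120))
  w1 <- build_monthly_window(d, 1)
  expect_setequal(unique(w1$month), c(12, 1, 2))
  expect_equal(nrow(w1), 30)
  expect_equal(sum(w1$split == "test"), 6)
  expect_equal(sum(w1$split == "train"), 24)
  # deterministic under the seed
  expect_equal(build_monthly_window(d, 4, seed = 99)$split,
               build_monthly_window(d, 4, seed = 99)$split)
  expect_error(build_monthly_window(d[d$month %in% 5:7, ], 1), "empty window")
})

test_that("predictor pruning enforces the correlation ceiling and logs transforms", {
  set.seed(3)
  n <- 200
  d <- tibble::tibble(
    a = rnorm(n),
    c = rnorm(n),
    skewed = exp(rnorm(n, 0, 1.5)),
    mild = rnorm(n, 10, 2),
    flat = rep(1, n))
  d$b <- d$a  # exact duplicate
  expect_warning(
    pr <- prune_predictors(d, c("a", "b", "c", "skewed", "mild", "flat"),
                           keep_priority = "a", skew_threshold = 1),
    "constant")
  expect_false("b" %in% pr$predictors)
  expect_true("a" %in% pr$predictors)
  expect_false("flat" %in% pr$predictors)
  expect_true("log_skewed" %in% pr$predictors)
  expect_true("mild" %in% pr$predictors)  # skewness ~0: untouched
  # assertable invariant: no retained pair above the ceiling
  cm <- abs(cor(pr$dataset[pr$predictors]))
  diag(cm) <- 0
  expect_true(all(cm <= 0.95))
  # independent noise columns all survive
  noise <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 6), n)))
  pr2 <- prune_predictors(noise, names(noise), skew_threshold = Inf)
  expect_setequal(pr2$predictors, names(noise))
})
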