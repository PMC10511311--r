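#' Random-forest regressor backend
#'
#' The default backend for the monthly concentration models: a ranger
#' random forest with permutation importance (mean decrease in accuracy)
#' and per-prediction standard errors of the mean from the infinitesimal
#' jackknife (falling back to the spread of the mean across trees when
#' the jackknife estimator fails numerically). Default hyperparameters:
#' mtry = 13 (capped at the number of predictors), min.node.size = 8,
#' 1200 trees.
#'
#' Any list with the same `fit`/`predict`/`importance` closures can be
#' supplied wherever a backend is accepted, so the modelling layer is
#' backend-agnostic.
#'
#' @param num_trees,mtry,min_n Forest hyperparameters.
#' @return A backend list with elements `name`, `uncertainty`, `fit`,
#'   `predict`, `importance`.
#' @export
regressor_ranger <- function(num_trees = 1200, mtry = 13, min_n = 8) {
  list(
    name = "ranger",
    uncertainty = "infinitesimal_jackknife",
    fit = function(data, predictors, response, seed) {
      f <- stats::reformulate(predictors, response)
      # single-threaded so fits and jackknife s.e. are bit-reproducible
      m <- ranger::ranger(
        f, data = data, num.trees = num_trees,
        mtry = min(mtry, length(predictors)),
        min.node.size = min_n, keep.inbag = TRUE,
        importance = "permutation", seed = seed, num.threads = 1)
      list(model = m, predictors = predictors, response = response,
           seed = seed)
    },
    predict = function(fit, newdata) {
      # the jackknife s.e. consumes the session RNG; pin it to the fit
      # seed so repeated predictions are identical
      p <- tryCatch(
        withr::with_seed(fit$seed,
          stats::predict(fit$model, data = newdata, type = "se",
                         se.method = "infjack", num.threads = 1)),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(p) && all(is.finite(p$se))) {
        return(list(mean = p$predictions, se = p$se))
      }
      pa <- stats::predict(fit$model, data = newdata, predict.all = TRUE,
                           num.threads = 1)
      mu <- rowMeans(pa$predictions)
      se <- apply(pa$predictions, 1, stats::sd) /
        sqrt(ncol(pa$predictions))
      list(mean = mu, se = se)
    },
    importance = function(fit) ranger::importance(fit$model)
  )
}

#' Fit the twelve monthly concentration models
#'
#' For each month, builds the three-month training window (see
#' [build_monthly_window()]), splits 80/20, fits the backend regressor on
#' the training rows and evaluates R^2 and RMSE on the withheld rows.
#' Permutation importances are collected per monthly model so their
#' median and s.d. across the twelve models can be reported.
#'
#' @param dataset Reach-month table containing the response and predictor
#'   columns plus `month`.
#' @param predictors Character vector of predictor column names.
#' @param response Response column name (typically a log-transformed
#'   concentration).
#' @param backend A regressor backend, e.g. [regressor_ranger()].
#' @param months Months to fit (default 1:12).
#' @param test_frac Withheld fraction (default 0.2).
#' @param seed Integer seed; each month uses `seed + month` for its split
#'   and forest.
#' @return An object of class `ch4_monthly_models`: fitted models, the
#'   training windows, a per-month report (`r2_test`, `rmse_test`,
#'   `n_train`, `n_test`) and a long importance table.
#' @export
fit_monthly_models <- function(dataset, predictors, response,
                               backend = regressor_ranger(),
                               months = 1:12, test_frac = 0.2, seed = 42) {
  miss <- setdiff(c(predictors, response, "month"), names(dataset))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  models <- list(); train_sets <- list()
  reports <- list(); imps <- list()
  for (m in months) {
    win <- build_monthly_window(dataset, m, test_frac, seed = seed + m)
    train <- win[win$split == "train", ]
    test <- win[win$split == "test", ]
    if (nrow(train) < 5 || nrow(test) < 2) {
      stop("window for month ", m, " too small for an 80/20 split")
    }
    fit <- backend$fit(train, predictors, response, seed = seed + m)
    pred <- backend$predict(fit, test)$mean
    y <- test[[response]]
    sse <- sum((y - pred)^2)
    sst <- sum((y - mean(y))^2)
    reports[[as.character(m)]] <- tibble::tibble(
      month = m,
      r2_test = if (sst > 0) 1 - sse / sst else NA_real_,
      rmse_test = sqrt(mean((y - pred)^2)),
      n_train = nrow(train), n_test = nrow(test))
    imp <- backend$importance(fit)
    imps[[as.character(m)]] <- tibble::tibble(
      month = m, variable = names(imp), importance = unname(imp))
    models[[as.character(m)]] <- fit
    train_sets[[as.character(m)]] <- train
  }
  structure(list(models = models, train_sets = train_sets,
                 report = dplyr::bind_rows(reports),
                 importance = dplyr::bind_rows(imps),
                 predictors = predictors, response = response,
                 backend = backend$name,
                 uncertainty = backend$uncertainty,
                 backend_obj = backend, seed = seed),
            class = "ch4_monthly_models")
}

#' Summarize permutation importance across the monthly models
#'
#' @param fits A `ch4_monthly_models` object.
#' @return Tibble `variable`, `importance_median`, `importance_sd`, sorted
#'   by decreasing median importance.
#' @export
importance_summary <- function(fits) {
  fits$importance |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(importance_median = stats::median(.data$importance),
                     importance_sd = stats::sd(.data$importance),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$importance_median))
}

#' Predict per-reach-month concentrations with uncertainty
#'
#' Applies each monthly model to the matching rows of the prediction
#' table and returns the modelled concentration, the standard deviation
#' of the mean prediction, and an extrapolation flag (any predictor
#' outside the training quantile range). When the models were fitted on a
#' log response (the default pipeline), predictions are back-transformed
#' with the delta-method s.d.; the optional lognormal bias correction
#' multiplies the mean by exp(se^2/2).
#'
#' @param fits A `ch4_monthly_models` object.
#' @param newdata Table with `reach_id`, `month` and the predictor columns.
#' @param log_response Whether the response was log-transformed (default
#'   `TRUE`); back-transforms predictions to concentration units.
#' @param bias_correction Lognormal back-transform bias correction
#'   (default off).
#' @param flag_quantiles Training quantile range for the extrapolation
#'   flag.
#' @return Tibble `reach_id`, `month`, `c_hat`, `c_sd`,
#'   `extrapolation_flag`.
#' @export
predict_with_uncertainty <- function(fits, newdata, log_response = TRUE,
                                     bias_correction = FALSE,
                                     flag_quantiles = c(0.01, 0.99)) {
  miss <- setdiff(fits$predictors, names(newdata))
  if (length(miss)) stop("newdata lacks predictor columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(names(fits$models), function(mname) {
    m <- as.integer(mname)
    rows <- newdata[newdata$month == m, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    p <- fits$backend_obj$predict(fits$models[[mname]], rows)
    if (log_response) {
      c_hat <- exp(p$mean)
      if (bias_correction) c_hat <- c_hat * exp(p$se^2 / 2)
      c_sd <- c_hat * p$se
    } else {
      c_hat <- pmax(0, p$mean)
      c_sd <- p$se
    }
    flag <- flag_extrapolation(fits$train_sets[[mname]], rows,
                               fits$predictors, flag_quantiles)
    tibble::tibble(reach_id = rows$reach_id, month = m,
                   c_hat = c_hat, c_sd = c_sd, extrapolation_flag = flag)
  })
  dplyr::bind_rows(out)
}

#' Flag predictions outside the observed predictor domain
#'
#' A row is flagged when any predictor falls outside the configured
#' quantile range of the training data for that predictor. This range
#' check is a deliberate simplification of convex-region
#' extrapolation-domain procedures.
#'
#' @param train Training table.
#' @param newdata Prediction table sharing the predictor columns.
#' @param predictors Predictor names to check.
#' @param quantiles Lower/upper training quantiles (default 1%/99%).
#' @return Logical vector, one element per `newdata` row.
#' @export
flag_extrapolation <- function(train, newdata, predictors,
                               quantiles = c(0.01, 0.99)) {
  flagged <- rep(FALSE, nrow(newdata))
  for (v in predictors) {
    rng <- stats::quantile(train[[v]], quantiles, na.rm = TRUE)
    flagged <- flagged | newdata[[v]] < rng[1] | newdata[[v]] > rng[2]
  }
  flagged
}

#' Partial dependence of the modelled concentration on one predictor
#'
#' Clamps the chosen predictor to each grid value in turn and averages
#' the model predictions over the supplied rows (conventionally yearly
#' site averages) and over the monthly models, yielding the marginal
#' effect of that predictor.
#'
#' @param fits A `ch4_monthly_models` object.
#' @param data Rows over which to marginalize (predictor columns).
#' @param variable Predictor name.
#' @param grid Grid values; default 25 points spanning the data range.
#' @return Tibble `grid`, `response` (mean prediction, response scale of
#'   the fit).
#' @export
partial_dependence <- function(fits, data, variable, grid = NULL) {
  if (!variable %in% fits$predictors) {
    stop("unknown variable: ", variable)
  }
  if (is.null(grid)) {
    grid <- seq(min(data[[variable]]), max(data[[variable]]),
                length.out = 25)
  }
  resp <- vapply(grid, function(g) {
    d <- data
    d[[variable]] <- g
    mean(vapply(fits$models, function(m)
      mean(fits$backend_obj$predict(m, d)$mean), numeric(1)))
  }, numeric(1))
  tibble::tibble(grid = grid, response = resp)
}
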