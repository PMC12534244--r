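#' Construct a validated trial dataset
#'
#' The unit of analysis for all models in this package: one row per
#' participant of a two-arm trial with individual-level total costs and
#' quality-adjusted life years (QALYs) over a fixed horizon, plus the
#' baseline covariates used by the regression models (baseline cost,
#' baseline utility, site).
#'
#' The contract is a complete-case one: any missing value is an error, all
#' costs must be non-negative and finite, and QALYs must lie strictly inside
#' `(0, horizon_max)` — the Beta likelihood used by two of the models has no
#' mass at the endpoints.
#'
#' @param data A data.frame with columns `id`, `arm` (0 = control,
#'   1 = intervention), `baseline_cost`, `baseline_utility`, `site` (0/1),
#'   `total_cost`, `qaly`.
#' @param horizon_max Upper bound of the QALY support; 0.5 for a 6-month
#'   horizon on an EQ-5D scale.
#' @param currency_label Text label for the cost unit (default "GBP").
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(data, horizon_max = 0.5, currency_label = "GBP") {
  required <- c("id", "arm", "baseline_cost", "baseline_utility",
                "site", "total_cost", "qaly")
  if (!is.data.frame(data)) stop("`data` must be a data.frame")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- data[, required]
  if (!is.numeric(horizon_max) || length(horizon_max) != 1 || horizon_max <= 0) {
    stop("`horizon_max` must be a single positive number")
  }
  num_cols <- setdiff(required, "id")
  for (col in num_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) stop("column `", col, "` must be numeric")
    if (anyNA(v)) {
      stop("missing value in column `", col, "` at row ",
           which(is.na(v))[1], " (complete cases required)")
    }
    if (any(!is.finite(v))) {
      stop("non-finite value in column `", col, "` at row ",
           which(!is.finite(v))[1])
    }
  }
  if (!all(data$arm %in% c(0, 1))) {
    stop("`arm` must be coded 0 (control) / 1 (intervention); bad row ",
         which(!data$arm %in% c(0, 1))[1])
  }
  if (!all(data$site %in% c(0, 1))) {
    stop("`site` must be a binary 0/1 indicator; bad row ",
         which(!data$site %in% c(0, 1))[1])
  }
  bad_cost <- which(data$total_cost < 0 | data$baseline_cost < 0)
  if (length(bad_cost) > 0) {
    stop("negative cost at row ", bad_cost[1])
  }
  bad_qaly <- which(data$qaly <= 0 | data$qaly >= horizon_max)
  if (length(bad_qaly) > 0) {
    stop("QALY outside (0, ", horizon_max, ") at row ", bad_qaly[1])
  }
  if (sum(data$arm == 0) == 0 || sum(data$arm == 1) == 0) {
    stop("both arms must be non-empty")
  }
  structure(
    list(data = data, horizon_max = horizon_max,
         currency_label = currency_label),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- table(factor(x$data$arm, levels = c(0, 1)))
  cat("<trial_dataset> ", nrow(x$data), " participants (control ",
      n[["0"]], ", intervention ", n[["1"]], ")\n", sep = "")
  cat("  QALY horizon: (0, ", x$horizon_max, "); currency: ",
      x$currency_label, "\n", sep = "")
  invisible(x)
}

#' Read a trial dataset from CSV
#'
#' Expects the canonical dialect written by [write_trial_csv()]:
#' comma-separated, UTF-8, header
#' `id,arm,baseline_cost,baseline_utility,site,total_cost,qaly`.
#' Row order is preserved and the result is validated by [trial_dataset()].
#'
#' @param path Path to the CSV file.
#' @inheritParams trial_dataset
#' @return A `trial_dataset`.
#' @export
load_trial_csv <- function(path, horizon_max = 0.5, currency_label = "GBP") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  trial_dataset(df, horizon_max = horizon_max, currency_label = currency_label)
}

#' Write a trial dataset to CSV
#'
#' Inverse of [load_trial_csv()]; the round trip is byte-stable for data
#' written by this function.
#'
#' @param ds A `trial_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(ds, path) {
  stopifnot(inherits(ds, "trial_dataset"))
  utils::write.csv(ds$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-arm summary of costs and QALYs
#'
#' Returns, per arm, the sample size, mean/SD/min/max of total costs and
#' QALYs, and the count and percentage of participants accruing zero costs
#' (percentage reported to 2 decimal places).
#'
#' @param ds A `trial_dataset`.
#' @return A data.frame with one row per arm.
#' @export
summarise_dataset <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  out <- lapply(c(0, 1), function(a) {
    d <- ds$data[ds$data$arm == a, ]
    n_zero <- sum(d$total_cost == 0)
    data.frame(
      arm = a,
      n = nrow(d),
      mean_cost = mean(d$total_cost),
      sd_cost = stats::sd(d$total_cost),
      min_cost = min(d$total_cost),
      max_cost = max(d$total_cost),
      mean_qaly = mean(d$qaly),
      sd_qaly = stats::sd(d$qaly),
      min_qaly = min(d$qaly),
      max_qaly = max(d$qaly),
      n_zero_cost = n_zero,
      pct_zero_cost = round(100 * n_zero / nrow(d), 2)
    )
  })
  do.call(rbind, out)
}
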