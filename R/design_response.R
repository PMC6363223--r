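## Time-delay-aware design and response construction.
##
## Expression responds to TF activity with a delay tau: for a time-series
## sample measured at t_n the regression design uses activities at t_n - tau,
## and activity estimation uses expression advanced by tau/2. Times off the
## measurement grid are obtained by linear interpolation along each series;
## times outside a series are clamped to its first/last sample (interpolation
## only, never extrapolation). Steady-state samples map to themselves.

## Reconstruct absolute times by accumulating delta_t along previous_sample
## chains; series ids group samples belonging to one chain.
sample_times <- function(metadata) {
  n <- nrow(metadata)
  prev <- stats::setNames(metadata$previous_sample, metadata$sample)
  t_abs <- stats::setNames(rep(NA_real_, n), metadata$sample)
  series <- stats::setNames(rep(NA_character_, n), metadata$sample)
  for (s in metadata$sample) {
    chain <- s
    cur <- s
    while (!is.na(prev[[cur]])) {
      cur <- prev[[cur]]
      chain <- c(chain, cur)
      if (length(chain) > n) stop_msg("previous_sample chain broken at %s", s)
    }
    root <- chain[length(chain)]
    series[s] <- root
    tt <- 0
    for (x in rev(chain)[-1]) tt <- tt + metadata$delta_t[metadata$sample == x]
    t_abs[s] <- tt
  }
  ts_flag <- stats::setNames(metadata$is_timeseries, metadata$sample)
  t_abs[!ts_flag] <- 0
  series[!ts_flag] <- metadata$sample[!ts_flag]
  data.frame(sample = metadata$sample, time = unname(t_abs),
             series = unname(series),
             is_timeseries = metadata$is_timeseries,
             stringsAsFactors = FALSE)
}

## For each sample, the pair of source samples and convex weights realizing
## linear interpolation at time (t_n + shift) within its series, clamped to
## the series range. Steady-state samples map to themselves with weight 1.
interpolation_map <- function(metadata, shift) {
  tm <- sample_times(metadata)
  out <- vector("list", nrow(tm))
  names(out) <- tm$sample
  for (i in seq_len(nrow(tm))) {
    s <- tm$sample[i]
    if (!tm$is_timeseries[i] || shift == 0) {
      out[[s]] <- list(samples = s, weights = 1)
      next
    }
    members <- tm[tm$series == tm$series[i] & tm$is_timeseries, , drop = FALSE]
    members <- members[order(members$time), , drop = FALSE]
    if (nrow(members) == 1L) {
      out[[s]] <- list(samples = members$sample, weights = 1)
      next
    }
    target <- tm$time[i] + shift
    target <- min(max(target, members$time[1]), members$time[nrow(members)])
    j <- findInterval(target, members$time, rightmost.closed = TRUE)
    t0 <- members$time[j]
    if (target == t0 || j == nrow(members)) {
      out[[s]] <- list(samples = members$sample[j], weights = 1)
    } else {
      t1 <- members$time[j + 1]
      w1 <- (target - t0) / (t1 - t0)
      out[[s]] <- list(samples = c(members$sample[j], members$sample[j + 1]),
                       weights = c(1 - w1, w1))
    }
  }
  out
}

apply_interpolation <- function(values, map) {
  out <- sapply(names(map), function(s) {
    m <- map[[s]]
    as.vector(values[, m$samples, drop = FALSE] %*% m$weights)
  })
  rownames(out) <- rownames(values)
  out
}

#' Pair expression with time-shifted activities for regression
#'
#' Builds the per-dataset design/response pair used by the per-gene
#' regressions: the response is the expression matrix and the design column
#' for a time-series sample at time t is the activity matrix linearly
#' interpolated at t - tau (clamped to the series start). Steady-state
#' samples pair expression with same-sample activities.
#'
#' @param expression an [expression_dataset()].
#' @param activities an activity matrix (TFs x samples) as returned by
#'   [estimate_activities()], over the same samples.
#' @param tau non-negative time delay, in the metadata's time units.
#' @return A list of class `task_data` with elements `dataset_id`, `design`
#'   (TFs x samples), `response` (genes x samples), `n`, and the
#'   interpolation `map` used.
#' @export
build_regression_pairs <- function(expression, activities, tau = 0) {
  if (tau < 0) stop_msg("tau must be non-negative")
  av <- if (inherits(activities, "activity_matrix")) activities$values else activities
  if (!identical(colnames(av), expression$samples))
    stop_msg("activities and expression must share sample ids in order")
  map <- interpolation_map(expression$metadata, -tau)
  design <- apply_interpolation(av, map)
  colnames(design) <- expression$samples
  structure(list(dataset_id = expression$dataset_id,
                 design = design,
                 response = expression$values,
                 n = length(expression$samples),
                 tau = tau, map = map),
            class = "task_data")
}

#' Advance expression by half the regulatory delay
#'
#' For activity estimation the expression of each time-series sample is taken
#' at t + tau/2 (linear interpolation between measured samples, clamped at
#' the series end); steady-state samples are unchanged. With `tau = 0` the
#' input matrix is returned as-is.
#'
#' @inheritParams build_regression_pairs
#' @return genes x samples numeric matrix.
#' @export
build_halftau_response <- function(expression, tau = 0) {
  if (tau < 0) stop_msg("tau must be non-negative")
  map <- interpolation_map(expression$metadata, tau / 2)
  out <- apply_interpolation(expression$values, map)
  colnames(out) <- expression$samples
  out
}
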