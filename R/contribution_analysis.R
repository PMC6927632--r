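# How much raw-abundance information feeds a stream type's general
# degradation module, and whether that predicts classification deviations.

#' Contribution of one non-fauna-index metric to the GDM
#'
#' With the fauna index fixed at 50% of the module, each of the remaining
#' n - 1 metrics contributes `0.5 / (n - 1)`; a single-metric module's lone
#' metric contributes 1.
#'
#' @param n_gdm_metrics number of metrics in the module (>= 1).
#' @return fraction in (0, 1].
#' @export
c_metric <- function(n_gdm_metrics) {
  n <- as.integer(n_gdm_metrics)
  if (any(is.na(n)) || any(n < 1)) stop("n_gdm_metrics must be >= 1")
  ifelse(n == 1, 1, 0.5 / (n - 1))
}

#' Cumulative raw-abundance contribution to the GDM
#'
#' `c_metric(n)` multiplied by the number of module metrics whose family is
#' `raw_abundance_based`. The fauna index is class-based and never counts.
#'
#' @param config a [stream_type_config].
#' @return fraction in \[0, 1\].
#' @export
c_ab <- function(config) {
  stopifnot(inherits(config, "stream_type_config"))
  n <- length(config$gdm_metrics)
  n_raw <- sum(vapply(config$gdm_metrics, function(m) {
    m$family == "raw_abundance_based" && !m$fauna_index
  }, logical(1)))
  c_metric(n) * n_raw
}

#' Per-stream-type contribution records
#'
#' Joins the analytic contribution fractions of each configuration with the
#' observed deviation magnitude of that stream type. Deviation magnitude is
#' operationalized as the share of samples whose final class changed
#' (default) or as the mean absolute class shift.
#'
#' @param configs named list of [stream_type_config].
#' @param ab_class,pa_class paired final classes in 1..5.
#' @param stream_type stream type id per pair.
#' @param magnitude `"share_changed"` or `"mean_abs_shift"`.
#' @return data frame: `stream_type_id`, `n_gdm_metrics`,
#'   `n_raw_abundance_metrics`, `c_metric`, `c_ab`, `n_samples`,
#'   `deviation_share`.
#' @export
contribution_records <- function(configs, ab_class, pa_class, stream_type,
                                 magnitude = c("share_changed",
                                               "mean_abs_shift")) {
  magnitude <- match.arg(magnitude)
  stopifnot(length(ab_class) == length(pa_class),
            length(stream_type) == length(ab_class))
  rows <- lapply(names(configs), function(st) {
    cfg <- configs[[st]]
    idx <- stream_type == st
    n_st <- sum(idx)
    dev <- if (n_st == 0) NA_real_ else {
      sh <- abs(pa_class[idx] - ab_class[idx])
      if (magnitude == "share_changed") mean(sh > 0) else mean(sh)
    }
    n <- length(cfg$gdm_metrics)
    n_raw <- sum(vapply(cfg$gdm_metrics, function(m) {
      m$family == "raw_abundance_based" && !m$fauna_index
    }, logical(1)))
    data.frame(stream_type_id = st, n_gdm_metrics = n,
               n_raw_abundance_metrics = n_raw,
               c_metric = c_metric(n), c_ab = c_ab(cfg),
               n_samples = n_st, deviation_share = dev,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Correlate abundance contribution with deviation magnitude
#'
#' Spearman rank correlation between `c_ab` and `deviation_share` across
#' stream types.
#'
#' @param records data frame from [contribution_records()] (needs columns
#'   `c_ab` and `deviation_share`).
#' @return list with `spearman_rho`, `p_value`, `n`, `defined`.
#' @export
contribution_vs_deviation <- function(records) {
  stopifnot(all(c("c_ab", "deviation_share") %in% names(records)))
  ok <- stats::complete.cases(records$c_ab, records$deviation_share)
  x <- records$c_ab[ok]; y <- records$deviation_share[ok]
  if (length(x) < 3) stop("need at least 3 stream types")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(spearman_rho = NA_real_, p_value = NA_real_, n = length(x),
                defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(spearman_rho = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), defined = TRUE)
}
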