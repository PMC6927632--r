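# Score normalization, module aggregation (OPM / GDM / AM), five-band
# classification and the worst-of rule.

#' Normalize a raw metric value to a [0, 1] quality score
#'
#' Linear map sending the worst anchor to 0 and the best anchor to 1,
#' clipped to \[0, 1\]. Direction is encoded in the anchor order: for
#' metrics where smaller values indicate better condition, pass
#' `anchors = c(worst, best)` with `worst > best`.
#'
#' @param value raw metric value (vectorized).
#' @param spec a [metric_spec] supplying the anchors.
#' @return score(s) in \[0, 1\]; `NA` propagates.
#' @export
normalize_metric <- function(value, spec) {
  stopifnot(inherits(spec, "metric_spec"))
  worst <- spec$anchors[1]; best <- spec$anchors[2]
  pmin(1, pmax(0, (value - worst) / (best - worst)))
}

#' Aggregate general-degradation-module scores
#'
#' The fauna index always carries weight 0.5; the remaining 0.5 is split
#' equally among the other metrics: with n metrics the module score is
#' \eqn{0.5\,s_{FI} + \sum_{m \ne FI} s_m \cdot 0.5/(n-1)}. A single-metric
#' module takes that metric's score unchanged. Weights always sum to 1.
#' A missing (non-assessable) metric score renders the module not
#' assessable.
#'
#' @param scores named numeric vector of metric scores (names = metric ids);
#'   `NA` marks a non-assessable metric.
#' @param config a [stream_type_config].
#' @return list with `score`, `esc`, `assessable`, `weights`.
#' @export
aggregate_gdm <- function(scores, config) {
  specs <- config$gdm_metrics
  ids <- vapply(specs, function(m) m$metric_id, character(1))
  n <- length(specs)
  if (!all(ids %in% names(scores))) {
    miss <- setdiff(ids, names(scores))
    stop(sprintf("missing score(s) for metric(s): %s",
                 paste(miss, collapse = ", ")))
  }
  s <- unname(scores[ids])
  if (n == 1) {
    w <- 1
  } else {
    fi <- vapply(specs, function(m) m$fauna_index, logical(1))
    w <- ifelse(fi, 0.5, 0.5 / (n - 1))
  }
  if (anyNA(s)) {
    return(list(score = NA_real_, esc = NA_integer_, assessable = FALSE,
                weights = stats::setNames(w, ids)))
  }
  score <- sum(w * s)
  list(score = score, esc = classify(score, config$esc_boundaries),
       assessable = TRUE, weights = stats::setNames(w, ids))
}

#' Classify a module score into an ecological status class
#'
#' Five bands on the \[0, 1\] score scale: class 1 (high) for scores at or
#' above the first boundary down to class 5 (bad) below the last. A score
#' exactly on a boundary takes the better class.
#'
#' @param score score(s) in \[0, 1\].
#' @param boundaries strictly decreasing thresholds, default
#'   `c(0.8, 0.6, 0.4, 0.2)`.
#' @return integer class(es) in 1..5.
#' @export
classify <- function(score, boundaries = c(0.8, 0.6, 0.4, 0.2)) {
  stopifnot(all(diff(boundaries) < 0))
  vapply(score, function(x) {
    if (is.na(x)) return(NA_integer_)
    1L + sum(x < boundaries)
  }, integer(1))
}

#' Classify a saprobic index through saprobic class boundaries
#'
#' Saprobic quality degrades with increasing index, so boundaries ascend;
#' an index exactly on a boundary takes the better class.
#'
#' @param si saprobic index value(s).
#' @param boundaries 4 strictly increasing saprobic-index thresholds.
#' @return integer class(es) in 1..5.
#' @export
classify_saprobic <- function(si, boundaries) {
  stopifnot(length(boundaries) == 4, all(diff(boundaries) > 0))
  vapply(si, function(x) {
    if (is.na(x)) return(NA_integer_)
    1L + sum(x > boundaries)
  }, integer(1))
}

#' Assess one sample under one stream-type configuration
#'
#' Computes every configured metric on the sample's basis, normalizes the
#' general-degradation (and acidification) metrics to scores, aggregates the
#' modules, classifies each, and applies the worst-of rule: the final
#' ecological status class is the numerically largest (worst) class among
#' the assessable modules. The organic pollution module is classified
#' directly from the saprobic index through the per-type saprobic class
#' boundaries; its score column is the anchor-normalized index, reported for
#' reference. Modules that are not assessable are excluded from the
#' worst-of rule; if no module is assessable the result is flagged.
#'
#' @param sample a [community_sample].
#' @param traits a [trait_table].
#' @param config a [stream_type_config] for the sample's stream type.
#' @param scheme an [abundance_class_scheme].
#' @return an object of class `assessment_result`: list with `sample_id`,
#'   `basis`, `metrics` (data frame of raw values and scores), `modules`
#'   (data frame of module score/class/assessability), `final_esc`,
#'   `assessable`.
#' @export
assess_sample <- function(sample, traits, config,
                          scheme = abundance_class_scheme()) {
  stopifnot(inherits(config, "stream_type_config"))
  if (sample$stream_type_id != config$stream_type_id) {
    stop(sprintf("sample '%s' has stream type '%s' but config is for '%s'",
                 sample$sample_id, sample$stream_type_id,
                 config$stream_type_id))
  }

  opm_res <- compute_metric(sample, traits, config$opm_metric, scheme,
                            config$min_indicator_taxa)
  opm_score <- if (opm_res$assessable) {
    normalize_metric(opm_res$raw_value, config$opm_metric)
  } else NA_real_
  opm_esc <- if (opm_res$assessable) {
    classify_saprobic(opm_res$raw_value, config$si_class_boundaries)
  } else NA_integer_

  gdm_res <- lapply(config$gdm_metrics, function(sp) {
    compute_metric(sample, traits, sp, scheme, config$min_indicator_taxa)
  })
  gdm_ids <- vapply(config$gdm_metrics, function(m) m$metric_id, character(1))
  gdm_scores <- stats::setNames(mapply(function(r, sp) {
    if (r$assessable) normalize_metric(r$raw_value, sp) else NA_real_
  }, gdm_res, config$gdm_metrics), gdm_ids)
  gdm <- aggregate_gdm(gdm_scores, config)

  am <- NULL; am_res <- NULL
  if (!is.null(config$am_metric)) {
    am_res <- compute_metric(sample, traits, config$am_metric, scheme,
                             config$min_indicator_taxa)
    am_score <- if (am_res$assessable) {
      normalize_metric(am_res$raw_value, config$am_metric)
    } else NA_real_
    am <- list(score = am_score,
               esc = classify(am_score, config$esc_boundaries),
               assessable = am_res$assessable)
  }

  all_res <- c(list(opm_res), gdm_res, if (!is.null(am_res)) list(am_res))
  all_scores <- c(opm_score, unname(gdm_scores),
                  if (!is.null(am)) am$score)
  metrics_df <- data.frame(
    metric_id = vapply(all_res, function(r) r$metric_id, character(1)),
    module_id = c("OPM", rep("GDM", length(gdm_res)),
                  if (!is.null(am_res)) "AM"),
    raw_value = vapply(all_res, function(r) r$raw_value, numeric(1)),
    score = all_scores,
    n_contributing_taxa = vapply(all_res, function(r) r$n_contributing_taxa,
                                 integer(1)),
    assessable = vapply(all_res, function(r) r$assessable, logical(1)),
    stringsAsFactors = FALSE)

  modules_df <- data.frame(
    module_id = c("OPM", "GDM", if (!is.null(am)) "AM"),
    score = c(opm_score, gdm$score, if (!is.null(am)) am$score),
    esc = c(opm_esc, gdm$esc, if (!is.null(am)) am$esc),
    assessable = c(opm_res$assessable, gdm$assessable,
                   if (!is.null(am)) am$assessable),
    stringsAsFactors = FALSE)

  ok <- modules_df$assessable
  final <- if (any(ok)) max(modules_df$esc[ok]) else NA_integer_
  structure(list(sample_id = sample$sample_id, basis = sample$basis,
                 stream_type_id = sample$stream_type_id,
                 metrics = metrics_df, modules = modules_df,
                 final_esc = as.integer(final), assessable = any(ok)),
            class = "assessment_result")
}

#' @export
print.assessment_result <- function(x, ...) {
  cat(sprintf("<assessment_result> %s (%s basis): final ESC %s\n",
              x$sample_id, x$basis,
              if (x$assessable) x$final_esc else "not assessable"))
  print(x$modules, row.names = FALSE)
  invisible(x)
}

#' Flatten assessment results into a report table
#'
#' One row per sample with module scores, module classes and the final
#' class; the layout of the assessment report CSV.
#'
#' @param results list of `assessment_result` objects.
#' @return data frame.
#' @export
assessment_report <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    g <- function(mod, col) {
      i <- match(mod, r$modules$module_id)
      if (is.na(i)) NA else r$modules[[col]][i]
    }
    data.frame(sample_id = r$sample_id, stream_type_id = r$stream_type_id,
               basis = r$basis,
               opm_score = g("OPM", "score"), opm_esc = g("OPM", "esc"),
               gdm_score = g("GDM", "score"), gdm_esc = g("GDM", "esc"),
               am_score = g("AM", "score"), am_esc = g("AM", "esc"),
               final_esc = r$final_esc, assessable = r$assessable,
               stringsAsFactors = FALSE)
  }))
}
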