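# Metric kernels for the three data families: presence-based,
# abundance-class-based, raw-abundance-based.

#' Transform a sample to the presence/absence basis
#'
#' Every retained abundance is replaced by 1 and the basis flag is set; the
#' taxon set is unchanged. Idempotent: applying twice equals applying once.
#'
#' @param sample a [community_sample].
#' @return a [community_sample] on the `presence_absence` basis.
#' @export
to_presence_absence <- function(sample) {
  stopifnot(inherits(sample, "community_sample"))
  if (sample$basis == "presence_absence") return(sample)
  sample$records$abundance <- rep(1, nrow(sample$records))
  sample$basis <- "presence_absence"
  sample
}

#' Map counts to abundance classes
#'
#' @param count vector of counts, all >= 1.
#' @param scheme an [abundance_class_scheme].
#' @return integer vector of classes in 1..K, non-decreasing in count.
#' @export
abundance_class <- function(count, scheme = abundance_class_scheme()) {
  stopifnot(inherits(scheme, "abundance_class_scheme"))
  count <- as.numeric(count)
  if (any(count < 1)) stop("count must be >= 1")
  findInterval(count, scheme$upper_bounds + 0.5) + 1L
}

#' Build a metric result record
#' @keywords internal
metric_result <- function(metric_id, raw_value, basis, n_contributing_taxa,
                          assessable = TRUE) {
  structure(list(metric_id = metric_id,
                 raw_value = if (assessable) raw_value else NA_real_,
                 basis = basis,
                 n_contributing_taxa = as.integer(n_contributing_taxa),
                 assessable = assessable),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result> %s = %s (%s basis, %d taxa%s)\n", x$metric_id,
              if (x$assessable) format(round(x$raw_value, 4)) else "NA",
              x$basis, x$n_contributing_taxa,
              if (x$assessable) "" else ", not assessable"))
  invisible(x)
}

# Membership weight in [0, 1] of each sample record under a selector:
# 1/0 for group-flag membership, the fractional preference share for
# preference selectors, 1 for the all-taxa selector.
selector_weights <- function(matched, selector) {
  n <- nrow(matched)
  if (is.null(selector) || isTRUE(selector$all)) return(rep(1, n))
  if (!is.null(selector$groups)) {
    flags <- strsplit(ifelse(is.na(matched$group_flags), "",
                             matched$group_flags), ";", fixed = TRUE)
    want <- tolower(trimws(selector$groups))
    return(vapply(flags, function(f) {
      as.numeric(any(tolower(trimws(f)) %in% want))
    }, numeric(1)))
  }
  if (!is.null(selector$preference)) {
    col <- paste0("pref_", selector$preference)
    if (!col %in% names(matched)) return(rep(0, n))
    w <- matched[[col]]
    w[is.na(w)] <- 0
    return(w)
  }
  stop("unknown selector type")
}

#' Saprobic index
#'
#' Abundance-class-weighted mean of taxon saprobic values:
#' \deqn{SI = \frac{\sum_i s_i A_i G_i}{\sum_i A_i G_i}}
#' over taxa carrying a saprobic value \eqn{s_i} and indicator weight
#' \eqn{G_i}, with \eqn{A_i} the abundance class of the taxon's count. Under
#' the presence/absence basis all \eqn{A_i = 1} and the index reduces to the
#' G-weighted mean of the saprobic values. The index is flagged not
#' assessable (no exception) when fewer than `min_indicator_taxa` indicator
#' taxa are present.
#'
#' @param sample a [community_sample].
#' @param traits a [trait_table].
#' @param scheme an [abundance_class_scheme].
#' @param min_indicator_taxa minimum indicator taxa for a valid index.
#' @return a `metric_result` with `metric_id` `"saprobic_index"`.
#' @export
saprobic_index <- function(sample, traits, scheme = abundance_class_scheme(),
                           min_indicator_taxa = 5L) {
  m <- match_traits(sample, traits)
  idx <- !is.na(m$saprobic_value) & !is.na(m$saprobic_weight)
  n <- sum(idx)
  if (n < min_indicator_taxa) {
    return(metric_result("saprobic_index", NA_real_, sample$basis, n,
                         assessable = FALSE))
  }
  a <- abundance_class(m$abundance[idx], scheme)
  s <- m$saprobic_value[idx]
  g <- m$saprobic_weight[idx]
  metric_result("saprobic_index", sum(s * a * g) / sum(a * g), sample$basis, n)
}

#' Class-weighted indicator index
#'
#' Abundance-class-weighted mean of an indicator score column:
#' \deqn{I = \frac{\sum_i v_i A_i}{\sum_i A_i}}
#' over taxa scored in `score_column`. Serves the German-fauna-index family
#' (fauna index, rheo index, Potamon type index, lake-outlet typology index)
#' by pointing `score_column` at the relevant trait column. Under
#' presence/absence all \eqn{A_i = 1}, giving the unweighted mean score.
#'
#' @inheritParams saprobic_index
#' @param score_column name of the trait column holding indicator scores.
#' @param metric_id identifier for the result (default the score column).
#' @return a `metric_result`.
#' @export
class_weighted_indicator_index <- function(sample, traits, score_column,
                                           scheme = abundance_class_scheme(),
                                           metric_id = score_column) {
  m <- match_traits(sample, traits)
  if (!score_column %in% names(m)) {
    return(metric_result(metric_id, NA_real_, sample$basis, 0L,
                         assessable = FALSE))
  }
  v <- m[[score_column]]
  idx <- !is.na(v)
  n <- sum(idx)
  if (n == 0) {
    return(metric_result(metric_id, NA_real_, sample$basis, 0L,
                         assessable = FALSE))
  }
  a <- abundance_class(m$abundance[idx], scheme)
  metric_result(metric_id, sum(v[idx] * a) / sum(a), sample$basis, n)
}

#' Proportion metric
#'
#' Percentage of weight carried by selected taxa,
#' \eqn{100 \sum_{i} u_i w_i / \sum_i w_i}, where \eqn{w_i} is the taxon's
#' raw count (`raw_individuals`) or abundance class (`class_units`) and
#' \eqn{u_i} the selector membership weight — 1/0 for group selectors (e.g.
#' EPT specimens), fractional for preference-share selectors (e.g. share of
#' mud-dwelling individuals). Taxa without traits contribute to the
#' denominator only.
#'
#' @inheritParams saprobic_index
#' @param selector selection predicate (see [metric_spec()]).
#' @param basis_mode `"raw_individuals"` or `"class_units"`.
#' @param metric_id identifier for the result.
#' @return a `metric_result`; value in \[0, 100\].
#' @export
proportion_metric <- function(sample, traits, selector,
                              basis_mode = c("raw_individuals", "class_units"),
                              scheme = abundance_class_scheme(),
                              metric_id = "proportion") {
  basis_mode <- match.arg(basis_mode)
  m <- match_traits(sample, traits)
  if (nrow(m) == 0) {
    return(metric_result(metric_id, NA_real_, sample$basis, 0L,
                         assessable = FALSE))
  }
  w <- if (basis_mode == "raw_individuals") m$abundance
       else abundance_class(m$abundance, scheme)
  u <- selector_weights(m, selector)
  metric_result(metric_id, 100 * sum(u * w) / sum(w), sample$basis,
                sum(u > 0))
}

#' Richness metric
#'
#' Number of distinct taxa matching a group selector. Purely presence-based:
#' identical under the abundance and presence/absence bases.
#'
#' @inheritParams proportion_metric
#' @return a `metric_result`; non-negative integer value.
#' @export
richness_metric <- function(sample, traits, selector = NULL,
                            metric_id = "richness") {
  m <- match_traits(sample, traits)
  if (nrow(m) == 0) {
    return(metric_result(metric_id, 0, sample$basis, 0L))
  }
  u <- selector_weights(m, selector)
  n <- sum(u > 0)
  metric_result(metric_id, as.numeric(n), sample$basis, n)
}

#' Compute one configured metric on a sample
#'
#' Dispatches a [metric_spec] to its kernel.
#'
#' @param sample a [community_sample].
#' @param traits a [trait_table].
#' @param spec a [metric_spec].
#' @param scheme an [abundance_class_scheme].
#' @param min_indicator_taxa passed to the saprobic kernel.
#' @return a `metric_result`.
#' @export
compute_metric <- function(sample, traits, spec,
                           scheme = abundance_class_scheme(),
                           min_indicator_taxa = 5L) {
  stopifnot(inherits(spec, "metric_spec"))
  switch(spec$kernel,
    richness = richness_metric(sample, traits, spec$selector,
                               metric_id = spec$metric_id),
    saprobic = {
      r <- saprobic_index(sample, traits, scheme, min_indicator_taxa)
      r$metric_id <- spec$metric_id
      r
    },
    class_weighted_indicator =
      class_weighted_indicator_index(sample, traits, spec$score_column,
                                     scheme, metric_id = spec$metric_id),
    proportion = proportion_metric(sample, traits, spec$selector,
                                   spec$basis_mode, scheme,
                                   metric_id = spec$metric_id)
  )
}
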