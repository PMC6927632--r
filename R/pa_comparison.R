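# Paired abundance vs presence/absence assessment, class-deviation
# cross-tabulation, congruence shares and concordance statistics.

#' Assess samples under both data bases
#'
#' Each sample is assessed once on its abundance basis and once after
#' transformation to presence/absence. Samples for which assessment fails
#' (no assessable module) on either basis are excluded and counted.
#'
#' @param samples list of [community_sample] objects (abundance basis).
#' @param traits a [trait_table].
#' @param configs named list of [stream_type_config], keyed by
#'   `stream_type_id`.
#' @param scheme an [abundance_class_scheme].
#' @return list with `pairs` (list of `list(abundance =, presence_absence =)`
#'   assessment results), `excluded` (data frame `sample_id`, `reason`),
#'   `n_input`, `n_pairs`.
#' @export
paired_assess <- function(samples, traits, configs,
                          scheme = abundance_class_scheme()) {
  pairs <- list()
  excluded <- list()
  for (s in samples) {
    cfg <- configs[[s$stream_type_id]]
    if (is.null(cfg)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(sample_id = s$sample_id, reason = "no config",
                   stringsAsFactors = FALSE)
      next
    }
    ab <- assess_sample(s, traits, cfg, scheme)
    pa <- assess_sample(to_presence_absence(s), traits, cfg, scheme)
    if (!ab$assessable || !pa$assessable) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(sample_id = s$sample_id, reason = "not assessable",
                   stringsAsFactors = FALSE)
      next
    }
    pairs[[length(pairs) + 1L]] <- list(abundance = ab, presence_absence = pa)
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(sample_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  list(pairs = pairs, excluded = excluded,
       n_input = length(samples), n_pairs = length(pairs))
}

#' Cross-tabulate paired class labels
#'
#' Builds the 5x5 deviation table of abundance-based class (rows) against
#' presence/absence-based class (columns), together with the shift spectrum.
#' The shift of a pair is column minus row: positive shifts mean the
#' presence/absence classification is numerically larger, i.e. worse.
#'
#' @param ab_class integer vector of abundance-based classes in 1..5.
#' @param pa_class integer vector of presence/absence-based classes in 1..5.
#' @return an object of class `deviation_table`: list with `matrix` (5x5
#'   counts), `n_total` and `shift_counts` (named vector, shifts -4..+4).
#' @export
tabulate_deviations <- function(ab_class, pa_class) {
  stopifnot(length(ab_class) == length(pa_class))
  ab_class <- as.integer(ab_class); pa_class <- as.integer(pa_class)
  if (any(is.na(ab_class)) || any(is.na(pa_class)) ||
      any(ab_class < 1 | ab_class > 5) || any(pa_class < 1 | pa_class > 5)) {
    stop("class labels must be integers in 1..5")
  }
  m <- matrix(0L, 5, 5, dimnames = list(abundance = 1:5,
                                        presence_absence = 1:5))
  for (i in seq_along(ab_class)) {
    m[ab_class[i], pa_class[i]] <- m[ab_class[i], pa_class[i]] + 1L
  }
  shifts <- pa_class - ab_class
  sc <- stats::setNames(integer(9), as.character(-4:4))
  tab <- table(shifts)
  sc[names(tab)] <- as.integer(tab)
  structure(list(matrix = m, n_total = length(ab_class), shift_counts = sc),
            class = "deviation_table")
}

#' Build a deviation table directly from a 5x5 count matrix
#'
#' @param m 5x5 matrix of non-negative integer counts (rows = abundance
#'   basis, columns = presence/absence basis).
#' @return a `deviation_table`.
#' @export
deviation_table_from_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 5, ncol(m) == 5)
  if (any(m < 0) || any(m != round(m))) {
    stop("matrix cells must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(abundance = 1:5, presence_absence = 1:5)
  sc <- stats::setNames(integer(9), as.character(-4:4))
  for (i in 1:5) for (j in 1:5) {
    k <- as.character(j - i)
    sc[k] <- sc[k] + m[i, j]
  }
  structure(list(matrix = m, n_total = sum(m), shift_counts = sc),
            class = "deviation_table")
}

#' @export
print.deviation_table <- function(x, ...) {
  cat(sprintf("<deviation_table> n = %d, unchanged = %d\n", x$n_total,
              sum(diag(x$matrix))))
  print(x$matrix)
  invisible(x)
}

#' Congruence shares of a deviation table
#'
#' Percentage of paired classifications that were unchanged, shifted one
#' class worse / better under presence/absence, or shifted by two or more
#' classes in either direction. Raw (unrounded) percentages are returned;
#' round only at report time.
#'
#' @param table a `deviation_table`.
#' @return list with `n_total`, `n_unchanged`, and percentages
#'   `pct_unchanged`, `pct_worse_one`, `pct_better_one`, `pct_worse_multi`,
#'   `pct_better_multi`, `pct_multi`, plus the full `pct_by_shift` vector.
#' @export
congruence_stats <- function(table) {
  stopifnot(inherits(table, "deviation_table"))
  if (table$n_total == 0) stop("empty deviation table")
  sc <- table$shift_counts
  n <- table$n_total
  pct <- 100 * sc / n
  list(n_total = n,
       n_unchanged = unname(sc["0"]),
       pct_unchanged = unname(pct["0"]),
       pct_worse_one = unname(pct["1"]),
       pct_better_one = unname(pct["-1"]),
       pct_worse_multi = unname(sum(pct[c("2", "3", "4")])),
       pct_better_multi = unname(sum(pct[c("-2", "-3", "-4")])),
       pct_multi = unname(sum(pct[c("-4", "-3", "-2", "2", "3", "4")])),
       pct_by_shift = pct)
}

#' Count shifts across one class boundary, both directions
#'
#' @param table a `deviation_table`.
#' @param from_class,to_class classes in 1..5.
#' @return list with `from_to` (count of pairs classified `from_class` on
#'   the abundance basis and `to_class` under presence/absence) and
#'   `to_from` (the reverse).
#' @export
boundary_shift_report <- function(table, from_class, to_class) {
  stopifnot(inherits(table, "deviation_table"),
            from_class %in% 1:5, to_class %in% 1:5)
  list(from_to = unname(table$matrix[from_class, to_class]),
       to_from = unname(table$matrix[to_class, from_class]))
}

#' Concordance between paired value vectors
#'
#' Spearman rank correlation (average ranks for ties) with its p-value, and
#' the ordinary-least-squares slope of y on x. By convention x holds the
#' abundance-based values and y the presence/absence-based values, so a
#' slope below 1 indicates compression of the value spectrum under
#' presence/absence.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list with `spearman_rho`, `p_value`, `ols_slope`, `n`,
#'   `defined` (FALSE when a vector is constant, leaving the rank
#'   correlation undefined).
#' @export
concordance <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    slope <- if (stats::sd(x) == 0) NA_real_ else
      unname(stats::coef(stats::lm(y ~ x))[2])
    return(list(spearman_rho = NA_real_, p_value = NA_real_,
                ols_slope = slope, n = length(x), defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  slope <- unname(stats::coef(stats::lm(y ~ x))[2])
  list(spearman_rho = unname(ct$estimate), p_value = ct$p.value,
       ols_slope = slope, n = length(x), defined = TRUE)
}

#' Per-stratum deviation report
#'
#' Splits paired final classes by a grouping key (typically stream type) and
#' reports one row per stratum with sample count and congruence shares,
#' rounded half-up to `digits` decimals.
#'
#' @param ab_class,pa_class paired class vectors in 1..5.
#' @param stratum grouping vector (e.g. stream type id), same length.
#' @param digits decimals for reported percentages (default 1); use
#'   `digits = NULL` to leave values unrounded.
#' @return data frame with columns `stratum`, `n`, `pct_unchanged`,
#'   `pct_better_one`, `pct_worse_one`, `pct_better_multi`,
#'   `pct_worse_multi`.
#' @export
deviation_by_stratum <- function(ab_class, pa_class, stratum, digits = 1) {
  stopifnot(length(ab_class) == length(pa_class),
            length(stratum) == length(ab_class))
  out <- lapply(split(seq_along(stratum), stratum), function(idx) {
    cs <- congruence_stats(tabulate_deviations(ab_class[idx], pa_class[idx]))
    data.frame(stratum = stratum[idx[1]], n = cs$n_total,
               pct_unchanged = cs$pct_unchanged,
               pct_better_one = cs$pct_better_one,
               pct_worse_one = cs$pct_worse_one,
               pct_better_multi = cs$pct_better_multi,
               pct_worse_multi = cs$pct_worse_multi,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  if (!is.null(digits)) {
    pc <- grep("^pct_", names(df))
    df[pc] <- lapply(df[pc], round_half_up, digits = digits)
  }
  df
}

#' Round half away from zero
#'
#' Report-time rounding rule for percentages: exact halves round up (e.g.
#' 76.55 to 76.6), unlike banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimals.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
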