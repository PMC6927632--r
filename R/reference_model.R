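# ---- taxon name handling ----------------------------------------------------

#' Normalize a taxon name for matching
#'
#' Matching between taxa lists and trait tables is exact after whitespace
#' normalization and case folding; no fuzzy synonym resolution is attempted.
#'
#' @param x character vector of taxon names.
#' @return character vector of matching keys.
#' @keywords internal
normalize_taxon <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

# ---- CommunitySample --------------------------------------------------------

#' Construct a community sample
#'
#' A community sample is one site/date taxa list with counts: the atomic
#' assessment input. Duplicate taxa are merged by summing abundance,
#' zero-abundance records (absences) are dropped, and records are ordered by
#' taxon name so that loading is order-insensitive.
#'
#' @param sample_id sample identifier.
#' @param stream_type_id stream-type identifier used to pick the assessment
#'   configuration.
#' @param records data frame with columns `taxon_name` and `abundance`.
#' @param basis data basis, `"abundance"` (counts of individuals) or
#'   `"presence_absence"` (all abundances 1).
#' @return an object of class `community_sample`.
#' @export
community_sample <- function(sample_id, stream_type_id, records,
                             basis = c("abundance", "presence_absence")) {
  basis <- match.arg(basis)
  stopifnot(is.data.frame(records),
            all(c("taxon_name", "abundance") %in% names(records)))
  name <- gsub("\\s+", " ", trimws(as.character(records$taxon_name)))
  abundance <- as.numeric(records$abundance)
  if (any(is.na(abundance))) stop("non-numeric abundance in records")
  if (any(abundance < 0)) {
    stop(sprintf("negative abundance for taxon '%s'",
                 name[which(abundance < 0)[1]]))
  }
  if (any(!nzchar(name))) stop("empty taxon_name after whitespace normalization")
  keep <- abundance > 0
  name <- name[keep]
  abundance <- abundance[keep]
  key <- normalize_taxon(name)
  if (anyDuplicated(key)) {
    abundance <- as.numeric(tapply(abundance, key, sum)[unique(key)])
    name <- name[!duplicated(key)]
    key <- unique(key)
  }
  ord <- order(key)
  if (basis == "presence_absence") abundance <- rep(1, length(abundance))
  structure(list(
    sample_id = as.character(sample_id),
    stream_type_id = as.character(stream_type_id),
    basis = basis,
    records = data.frame(taxon_name = name[ord],
                         taxon_key = key[ord],
                         abundance = abundance[ord],
                         stringsAsFactors = FALSE)
  ), class = "community_sample")
}

#' @export
print.community_sample <- function(x, ...) {
  cat(sprintf("<community_sample> %s (type %s, basis %s): %d taxa, %s individuals\n",
              x$sample_id, x$stream_type_id, x$basis,
              nrow(x$records), format(sum(x$records$abundance))))
  invisible(x)
}

#' Read community samples from a delimited text file
#'
#' Expects columns `sample_id`, `stream_type_id`, `taxon_name`, `abundance`
#' (one row per taxon per sample). Zero-abundance rows are dropped and
#' duplicate taxa within a sample are merged by summing their abundances.
#' Samples are returned ordered by `sample_id`; within a sample, records are
#' ordered by taxon name, so row order in the file is immaterial.
#'
#' @param path path to a delimited UTF-8 text file.
#' @param basis data basis to assign to the samples; under
#'   `"presence_absence"` every retained abundance is set to 1.
#' @param delim field delimiter (default comma).
#' @param decimal_comma set `TRUE` for files using decimal commas; abundance
#'   fields are converted before parsing.
#' @return named list of [community_sample] objects.
#' @export
read_samples <- function(path, basis = c("abundance", "presence_absence"),
                         delim = ",", decimal_comma = FALSE) {
  basis <- match.arg(basis)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "stream_type_id", "taxon_name", "abundance")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  ab <- df$abundance
  if (decimal_comma) ab <- gsub(",", ".", ab, fixed = TRUE)
  ab <- suppressWarnings(as.numeric(ab))
  if (any(is.na(ab))) {
    stop(sprintf("non-numeric abundance at row %d", which(is.na(ab))[1]))
  }
  if (any(ab < 0)) {
    stop(sprintf("negative abundance at row %d", which(ab < 0)[1]))
  }
  df$abundance <- ab
  ids <- unique(df$sample_id)
  ids <- ids[order(ids)]
  out <- lapply(ids, function(id) {
    sub <- df[df$sample_id == id, , drop = FALSE]
    st <- unique(sub$stream_type_id)
    if (length(st) != 1) {
      stop(sprintf("sample '%s' maps to multiple stream types", id))
    }
    community_sample(id, st, sub[, c("taxon_name", "abundance")], basis = basis)
  })
  names(out) <- ids
  out
}

#' Write community samples to a delimited text file
#'
#' Inverse of [read_samples()]; a write/read round trip reproduces identical
#' in-memory samples.
#'
#' @param samples list of [community_sample] objects.
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_samples <- function(samples, path, delim = ",") {
  rows <- lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, stream_type_id = s$stream_type_id,
               taxon_name = s$records$taxon_name,
               abundance = s$records$abundance, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---- TraitTable -------------------------------------------------------------

#' Construct a taxon trait table
#'
#' Holds per-taxon indicator attributes: saprobic value `s` in \[1, 4\] with
#' positive indicator weight `G`, a fauna-index indicator score in \[-2, 2\],
#' taxonomic group flags (e.g. Ephemeroptera), and fractional habitat/zonation
#' preference shares (columns named `pref_<category>`, each in \[0, 1\] and
#' summing to at most 1 per taxon). Taxa with no traits are retained: they
#' contribute to metric denominators but never to indicator numerators.
#'
#' @param df data frame with column `taxon_name`; optional columns
#'   `saprobic_value`, `saprobic_weight`, `fauna_index_score`, `group_flags`
#'   (semicolon-separated labels) and any number of `pref_*` columns.
#' @return an object of class `trait_table` (a validated data frame).
#' @export
trait_table <- function(df) {
  stopifnot(is.data.frame(df), "taxon_name" %in% names(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$taxon_name <- gsub("\\s+", " ", trimws(as.character(df$taxon_name)))
  df$taxon_key <- normalize_taxon(df$taxon_name)
  if (anyDuplicated(df$taxon_key)) {
    stop(sprintf("duplicate taxon row: '%s'",
                 df$taxon_name[duplicated(df$taxon_key)][1]))
  }
  for (col in c("saprobic_value", "saprobic_weight", "fauna_index_score")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  if (!"group_flags" %in% names(df)) df$group_flags <- ""
  df$group_flags[is.na(df$group_flags)] <- ""
  sv <- df$saprobic_value
  if (any(!is.na(sv) & (sv < 1 | sv > 4))) {
    stop("saprobic_value outside [1, 4]")
  }
  if (any(!is.na(sv) & is.na(df$saprobic_weight))) {
    stop("saprobic_value present but saprobic_weight missing")
  }
  if (any(!is.na(df$saprobic_weight) & df$saprobic_weight <= 0)) {
    stop("saprobic_weight must be positive")
  }
  fi <- df$fauna_index_score
  if (any(!is.na(fi) & (fi < -2 | fi > 2))) {
    stop("fauna_index_score outside [-2, 2]")
  }
  pref_cols <- grep("^pref_", names(df), value = TRUE)
  for (col in pref_cols) {
    df[[col]] <- as.numeric(df[[col]])
    df[[col]][is.na(df[[col]])] <- 0
    if (any(df[[col]] < 0 | df[[col]] > 1)) {
      stop(sprintf("preference share in '%s' outside [0, 1]", col))
    }
  }
  if (length(pref_cols)) {
    tot <- rowSums(df[, pref_cols, drop = FALSE])
    if (any(tot > 1 + 1e-9)) {
      stop(sprintf("preference shares for taxon '%s' sum to %.3f (> 1)",
                   df$taxon_name[which(tot > 1 + 1e-9)[1]],
                   tot[which(tot > 1 + 1e-9)[1]]))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a trait table from a delimited text file
#'
#' @param path path to a delimited UTF-8 file with one row per taxon.
#' @param delim field delimiter.
#' @return a [trait_table].
#' @export
read_trait_table <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8", check.names = FALSE)
  trait_table(df)
}

#' Write a trait table to a delimited text file
#'
#' @param traits a [trait_table].
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_trait_table <- function(traits, path, delim = ",") {
  df <- as.data.frame(traits)
  df$taxon_key <- NULL
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up trait rows for the taxa of a sample
#'
#' @param sample a [community_sample].
#' @param traits a [trait_table].
#' @return data frame with one row per sample record (order preserved), trait
#'   columns `NA`/empty where the taxon is absent from the table.
#' @keywords internal
match_traits <- function(sample, traits) {
  idx <- match(sample$records$taxon_key, traits$taxon_key)
  out <- sample$records
  for (col in setdiff(names(traits), c("taxon_name", "taxon_key"))) {
    v <- traits[[col]][idx]
    if (is.numeric(traits[[col]]) && grepl("^pref_", col)) v[is.na(v)] <- 0
    if (col == "group_flags") v[is.na(v)] <- ""
    out[[col]] <- v
  }
  out
}

# ---- AbundanceClassScheme ---------------------------------------------------

#' Construct an abundance-class scheme
#'
#' Maps raw counts to ordinal abundance classes 1..K via strictly increasing
#' upper boundaries. The default seven-class scheme bins counts as
#' \[1,2\], \[3,10\], \[11,30\], \[31,100\], \[101,300\], \[301,1000\], >1000.
#'
#' @param upper_bounds strictly increasing upper count boundaries of classes
#'   1..K-1 (class K is unbounded above).
#' @return an object of class `abundance_class_scheme`.
#' @export
abundance_class_scheme <- function(upper_bounds = c(2, 10, 30, 100, 300, 1000)) {
  ub <- as.numeric(upper_bounds)
  if (length(ub) < 1 || any(diff(ub) <= 0)) {
    stop("upper_bounds must be strictly increasing")
  }
  if (ub[1] < 1) stop("first upper bound must be >= 1 so that class(1) = 1")
  structure(list(upper_bounds = ub, n_classes = length(ub) + 1L),
            class = "abundance_class_scheme")
}

# ---- MetricSpec -------------------------------------------------------------

#' Construct a metric specification
#'
#' A metric spec names a computation kernel, the data family it consumes,
#' the taxa it selects, and the normalization anchors mapping its raw value
#' onto the \[0, 1\] quality-score scale.
#'
#' Kernels: `richness` (distinct selected taxa; presence-based), `saprobic`
#' (abundance-class-weighted saprobic mean; class-based),
#' `class_weighted_indicator` (abundance-class-weighted mean of an indicator
#' score column, serving the fauna-index / rheo-index / Potamon-type-index
#' family; class-based), and `proportion` (percentage of individuals, or of
#' class units, carried by selected taxa; raw-abundance- or class-based).
#'
#' @param metric_id metric identifier.
#' @param kernel computation kernel (see Details).
#' @param family data family: `presence_based`, `class_based` or
#'   `raw_abundance_based`.
#' @param anchors length-2 numeric `c(worst, best)`; must be distinct. The
#'   anchor order encodes direction: `worst > best` means smaller is better.
#' @param selector selection predicate: `list(groups = c(...))` for group-flag
#'   membership, `list(preference = "<category>")` for fractional preference
#'   shares, or `NULL` to select all taxa.
#' @param score_column trait column holding indicator scores (for
#'   `class_weighted_indicator`).
#' @param fauna_index logical; flags the 50%-weighted core metric of the
#'   general degradation module.
#' @param basis_mode for `proportion`: weigh by `raw_individuals` (counts) or
#'   `class_units` (abundance classes).
#' @return an object of class `metric_spec`.
#' @export
metric_spec <- function(metric_id,
                        kernel = c("richness", "saprobic",
                                   "class_weighted_indicator", "proportion"),
                        family = c("presence_based", "class_based",
                                   "raw_abundance_based"),
                        anchors,
                        selector = NULL,
                        score_column = NULL,
                        fauna_index = FALSE,
                        basis_mode = c("raw_individuals", "class_units")) {
  kernel <- match.arg(kernel)
  family <- match.arg(family)
  basis_mode <- match.arg(basis_mode)
  anchors <- as.numeric(anchors)
  if (length(anchors) != 2 || anchors[1] == anchors[2] || any(is.na(anchors))) {
    stop(sprintf("metric '%s': anchors must be two distinct numbers", metric_id))
  }
  if (kernel %in% c("saprobic", "class_weighted_indicator") &&
      family != "class_based") {
    stop(sprintf("metric '%s': kernel '%s' implies family 'class_based'",
                 metric_id, kernel))
  }
  if (kernel == "richness" && family != "presence_based") {
    stop(sprintf("metric '%s': kernel 'richness' implies family 'presence_based'",
                 metric_id))
  }
  if (kernel == "class_weighted_indicator" && is.null(score_column)) {
    stop(sprintf("metric '%s': score_column required", metric_id))
  }
  structure(list(metric_id = as.character(metric_id), kernel = kernel,
                 family = family, anchors = anchors, selector = selector,
                 score_column = score_column, fauna_index = isTRUE(fauna_index),
                 basis_mode = basis_mode),
            class = "metric_spec")
}

# ---- StreamTypeConfig -------------------------------------------------------

#' Construct a stream-type assessment configuration
#'
#' Bundles, for one stream type, the organic pollution module (a single
#' saprobic metric classified through its own saprobic-index class
#' boundaries), the general degradation module (one to five metrics, exactly
#' one flagged as the fauna index whenever there is more than one), an
#' optional acidification module, and the score-to-class boundaries of the
#' five-band status scale.
#'
#' @param stream_type_id stream-type identifier.
#' @param opm_metric [metric_spec] with kernel `saprobic`.
#' @param si_class_boundaries ascending saprobic-index values separating
#'   classes 1..5 (a saprobic index at or below a boundary takes the better
#'   class).
#' @param gdm_metrics list of [metric_spec] for the general degradation
#'   module.
#' @param am_metric optional [metric_spec] for the acidification module.
#' @param esc_boundaries strictly decreasing score thresholds in (0, 1)
#'   mapping a module score to classes 1..5; a score at a boundary takes the
#'   better class. Default `c(0.8, 0.6, 0.4, 0.2)`.
#' @param min_indicator_taxa minimum number of saprobic indicator taxa for the
#'   saprobic index to be assessable (default 5).
#' @return an object of class `stream_type_config`.
#' @export
stream_type_config <- function(stream_type_id, opm_metric, si_class_boundaries,
                               gdm_metrics, am_metric = NULL,
                               esc_boundaries = c(0.8, 0.6, 0.4, 0.2),
                               min_indicator_taxa = 5L) {
  stopifnot(inherits(opm_metric, "metric_spec"))
  if (opm_metric$kernel != "saprobic") {
    stop("opm_metric must use the saprobic kernel")
  }
  sib <- as.numeric(si_class_boundaries)
  if (length(sib) != 4 || any(diff(sib) <= 0)) {
    stop("si_class_boundaries must be 4 strictly increasing values")
  }
  if (!is.list(gdm_metrics) || !length(gdm_metrics) ||
      !all(vapply(gdm_metrics, inherits, logical(1), "metric_spec"))) {
    stop("gdm_metrics must be a non-empty list of metric_spec objects")
  }
  n_fi <- sum(vapply(gdm_metrics, function(m) m$fauna_index, logical(1)))
  if (length(gdm_metrics) > 1 && n_fi != 1) {
    stop(sprintf("GDM with %d metrics must flag exactly one fauna index (found %d)",
                 length(gdm_metrics), n_fi))
  }
  if (n_fi > 1) stop("more than one fauna-index flag")
  ids <- vapply(gdm_metrics, function(m) m$metric_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate metric_id in gdm_metrics")
  eb <- as.numeric(esc_boundaries)
  if (length(eb) != 4 || any(diff(eb) >= 0) || any(eb <= 0) || any(eb >= 1)) {
    stop("esc_boundaries must be 4 strictly decreasing values in (0, 1)")
  }
  if (!is.null(am_metric)) stopifnot(inherits(am_metric, "metric_spec"))
  structure(list(stream_type_id = as.character(stream_type_id),
                 opm_metric = opm_metric, si_class_boundaries = sib,
                 gdm_metrics = gdm_metrics, am_metric = am_metric,
                 esc_boundaries = eb,
                 min_indicator_taxa = as.integer(min_indicator_taxa)),
            class = "stream_type_config")
}

metric_spec_to_list <- function(m) {
  out <- list(metric_id = m$metric_id, kernel = m$kernel, family = m$family,
              anchors = list(worst = m$anchors[1], best = m$anchors[2]),
              basis_mode = m$basis_mode)
  if (!is.null(m$selector)) out$selector <- m$selector
  if (!is.null(m$score_column)) out$score_column <- m$score_column
  if (m$fauna_index) out$fauna_index <- TRUE
  out
}

metric_spec_from_list <- function(x) {
  metric_spec(metric_id = x$metric_id, kernel = x$kernel, family = x$family,
              anchors = c(x$anchors$worst, x$anchors$best),
              selector = x$selector, score_column = x$score_column,
              fauna_index = isTRUE(x$fauna_index),
              basis_mode = if (is.null(x$basis_mode)) "raw_individuals"
                           else x$basis_mode)
}

#' Load a stream-type configuration from a YAML file
#'
#' @param path path to a YAML configuration (see
#'   [write_stream_type_config()] for the schema).
#' @return a validated [stream_type_config].
#' @export
load_stream_type_config <- function(path) {
  x <- yaml::read_yaml(path)
  required <- c("stream_type_id", "opm", "gdm", "esc_boundaries")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf("config missing key(s): %s", paste(missing, collapse = ", ")))
  }
  opm <- metric_spec_from_list(x$opm$metric)
  gdm <- lapply(x$gdm$metrics, metric_spec_from_list)
  am <- if (!is.null(x$am)) metric_spec_from_list(x$am$metric) else NULL
  stream_type_config(
    stream_type_id = x$stream_type_id,
    opm_metric = opm,
    si_class_boundaries = unlist(x$opm$si_class_boundaries),
    gdm_metrics = gdm,
    am_metric = am,
    esc_boundaries = unlist(x$esc_boundaries),
    min_indicator_taxa = if (is.null(x$opm$min_indicator_taxa)) 5L
                         else x$opm$min_indicator_taxa
  )
}

#' Write a stream-type configuration to a YAML file
#'
#' Schema: top-level keys `stream_type_id`, `opm` (with `metric`,
#' `si_class_boundaries`, `min_indicator_taxa`), `gdm` (with `metrics`, a
#' list), optional `am` (with `metric`), and `esc_boundaries`. Each metric is
#' a mapping with `metric_id`, `kernel`, `family`, `anchors` (`worst`/`best`),
#' optional `selector`, `score_column`, `fauna_index`, `basis_mode`.
#'
#' @param config a [stream_type_config].
#' @param path output path.
#' @export
write_stream_type_config <- function(config, path) {
  x <- list(
    stream_type_id = config$stream_type_id,
    opm = list(metric = metric_spec_to_list(config$opm_metric),
               si_class_boundaries = config$si_class_boundaries,
               min_indicator_taxa = config$min_indicator_taxa),
    gdm = list(metrics = lapply(config$gdm_metrics, metric_spec_to_list)),
    esc_boundaries = config$esc_boundaries
  )
  if (!is.null(config$am_metric)) {
    x$am <- list(metric = metric_spec_to_list(config$am_metric))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}
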